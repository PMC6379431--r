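# Membrane frame estimation from the transmembrane bundle and measurement
# of the cis-interaction pocket's vertical aperture perpendicular to the
# membrane plane.
#
# A tetraspan bundle defines the membrane normal as the average of its
# four helix-axis directions once each is oriented cytosolic-to-
# extracellular according to the topology (for a claudin: TM1 and TM3 run
# in-to-out, TM2 and TM4 out-to-in, so the latter two are flipped before
# averaging).

#' Claudin default transmembrane ranges and topology
#'
#' Helix boundaries are engineering defaults (the deposited structures
#' print none): TM1 8-27, TM2 78-98, TM3 118-149, TM4 160-182, topology
#' +1, -1, +1, -1 (N-to-C equals cytosolic-to-extracellular for +1).
#'
#' @return list with `tm_ranges` (list of 4 intervals) and `topology`.
#' @export
claudin_tm_defaults <- function() {
  list(tm_ranges = list(TM1 = c(8, 27), TM2 = c(78, 98),
                        TM3 = c(118, 149), TM4 = c(160, 182)),
       topology = c(1, -1, 1, -1))
}

#' Estimate the membrane normal from a transmembrane helix bundle
#'
#' Fits an axis to each transmembrane range, orients each axis
#' cytosolic-to-extracellular using the topology, and returns the
#' normalized mean direction. Near-cancellation of the per-helix
#' directions (mean vector norm < 0.5) indicates a degenerate bundle and
#' is an error.
#'
#' @param model a [structure_model()].
#' @param tm_ranges list of residue intervals, one per helix.
#' @param chain chain id, length 1 or one per range (a multi-chain bundle
#'   fixture uses one chain per helix).
#' @param topology +1/-1 per helix: +1 if the helix runs N-to-C in the
#'   cytosolic-to-extracellular direction.
#' @param window axis-trace smoothing window (residues).
#' @return object of class `membrane_frame`: `normal` (unit vector,
#'   extracellular positive), `center_offset` (projection of the pooled
#'   TM C-alpha centroid on the normal), `helix_axes`.
#' @export
estimate_membrane_normal <- function(model, tm_ranges,
                                     chain = "A",
                                     topology = c(1, -1, 1, -1),
                                     window = 4) {
  stopifnot(inherits(model, "structure_model"))
  nh <- length(tm_ranges)
  chain <- rep_len(chain, nh)
  topology <- rep_len(topology, nh)
  axes <- vector("list", nh)
  dirs <- matrix(NA_real_, nh, 3)
  pooled <- NULL
  for (i in seq_len(nh)) {
    ca <- .arm_calpha(model, chain[i], tm_ranges[[i]], paste0("TM", i))
    ax <- .arm_axis(ca, tm_ranges[[i]], window)
    axes[[i]] <- ax
    dirs[i, ] <- ax$direction * topology[i]
    pooled <- rbind(pooled, .coords(ca))
  }
  mean_dir <- colMeans(dirs)
  if (sqrt(sum(mean_dir^2)) < 0.5)
    stop("degenerate bundle: per-helix directions nearly cancel ",
         "(mean vector norm ", round(sqrt(sum(mean_dir^2)), 3),
         " < 0.5); check the topology")
  normal <- .unit(mean_dir)
  structure(list(normal = normal,
                 center_offset = sum(colMeans(pooled) * normal),
                 helix_axes = axes),
            class = "membrane_frame")
}

#' @export
print.membrane_frame <- function(x, ...) {
  cat(sprintf("membrane_frame: normal (%.3f, %.3f, %.3f), center offset %.1f A\n",
              x$normal[1], x$normal[2], x$normal[3], x$center_offset))
  invisible(x)
}

# side-chain heavy-atom centroid of one residue; C-alpha fallback for
# residues without side-chain heavy atoms (glycine, C-alpha-only models)
.sidechain_centroid <- function(atoms, chain, resno) {
  at <- .geometry_atoms(atoms)
  at <- at[at$chain == chain & at$resno == resno, , drop = FALSE]
  if (nrow(at) == 0) return(NULL)
  # altloc: keep highest-occupancy copy of each atom name
  at <- at[order(at$elety, -at$occ, at$alt), , drop = FALSE]
  at <- at[!duplicated(at$elety), , drop = FALSE]
  sc <- at[!(at$elety %in% c(.BACKBONE, "OXT")), , drop = FALSE]
  if (nrow(sc) == 0) sc <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(sc) == 0) return(NULL)
  colMeans(.coords(sc))
}

#' Vertical aperture of the cis-interaction pocket
#'
#' Projects the side-chain heavy-atom centroid of each rim residue onto
#' the membrane normal and reports the signed width upper - lower (in
#' Angstrom along the normal, extracellular positive), averaged over the
#' residues of each rim. Defaults are the claudin-3 pocket rims:
#' Phe146/Tyr147 on the extracellular edge of TM3 (upper) and
#' Glu158/Met159 on beta5 (lower). A negative width flags rim inversion.
#'
#' @param model a [structure_model()].
#' @param frame a [estimate_membrane_normal()] result.
#' @param upper_residues,lower_residues residue numbers of the two rims.
#' @param chain chain id.
#' @return object of class `pocket_aperture`: per-residue projections,
#'   `upper_projection`, `lower_projection`, `vertical_width` (signed),
#'   `abs_width`.
#' @export
pocket_vertical_width <- function(model, frame,
                                  upper_residues = c(146, 147),
                                  lower_residues = c(158, 159),
                                  chain = "A") {
  stopifnot(inherits(model, "structure_model"),
            inherits(frame, "membrane_frame"))
  if (length(upper_residues) == 0 || length(lower_residues) == 0)
    stop("rim residue sets must be nonempty")
  proj <- function(resnos) {
    p <- vapply(resnos, function(r) {
      ctr <- .sidechain_centroid(model$atoms, chain, r)
      if (is.null(ctr)) return(NA_real_)
      sum(ctr * frame$normal) - frame$center_offset
    }, numeric(1))
    names(p) <- resnos
    p
  }
  up <- proj(upper_residues); lo <- proj(lower_residues)
  missing <- c(names(up)[is.na(up)], names(lo)[is.na(lo)])
  if (length(missing) > 0)
    stop("rim residues missing from chain ", chain, ": ",
         paste(missing, collapse = ", "))
  structure(list(chain_id = chain,
                 upper_residues = upper_residues,
                 lower_residues = lower_residues,
                 upper_per_residue = up, lower_per_residue = lo,
                 upper_projection = mean(up), lower_projection = mean(lo),
                 vertical_width = mean(up) - mean(lo),
                 abs_width = abs(mean(up) - mean(lo))),
            class = "pocket_aperture")
}

#' @export
print.pocket_aperture <- function(x, ...) {
  cat(sprintf("pocket_aperture: chain %s, vertical width %.2f A (upper %.2f, lower %.2f)\n",
              x$chain_id, x$vertical_width, x$upper_projection,
              x$lower_projection))
  invisible(x)
}
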