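# Per-chain B-factor profiling and cross-chain comparison within one
# crystal asymmetric unit. Deposited isotropic B is taken at face value;
# comparisons are only meaningful between chains of the same crystal.

#' Per-residue B-factor profile of a chain
#'
#' Mean B over the chosen atom scope per residue. Backbone scope (N, CA,
#' C, O) is the default: at moderate resolution side-chain disorder would
#' dominate an all-atom average.
#'
#' @param model a [structure_model()].
#' @param chain chain id.
#' @param atom_scope "backbone" or "all" (heavy atoms; waters and
#'   hydrogens are always excluded).
#' @return object of class `bfactor_profile`: data frame `profile`
#'   (resno, mean_b, n_atoms), `chain_id`, `atom_scope`, `model_mean`,
#'   `model_sd`.
#' @export
chain_bfactor_profile <- function(model, chain,
                                  atom_scope = c("backbone", "all")) {
  stopifnot(inherits(model, "structure_model"))
  atom_scope <- match.arg(atom_scope)
  if (!(chain %in% model$atoms$chain))
    stop("unknown chain '", chain, "'")
  at <- .geometry_atoms(model$atoms)
  at <- at[at$chain == chain, , drop = FALSE]
  if (atom_scope == "backbone")
    at <- at[at$elety %in% .BACKBONE, , drop = FALSE]
  if (nrow(at) == 0)
    stop("chain ", chain, " has no ", atom_scope, " atoms")
  # altloc: highest-occupancy copy of each (resno, elety)
  at <- at[order(at$resno, at$elety, -at$occ, at$alt), , drop = FALSE]
  at <- at[!duplicated(paste(at$resno, at$ins, at$elety)), , drop = FALSE]
  agg <- stats::aggregate(at$b, by = list(resno = at$resno), FUN = mean)
  cnt <- stats::aggregate(at$b, by = list(resno = at$resno), FUN = length)
  prof <- data.frame(resno = agg$resno, mean_b = agg$x, n_atoms = cnt$x)
  prof <- prof[order(prof$resno), , drop = FALSE]
  structure(list(profile = prof, chain_id = chain, atom_scope = atom_scope,
                 model_mean = mean(at$b), model_sd = stats::sd(at$b)),
            class = "bfactor_profile")
}

#' Compare B-factors between two chains
#'
#' Per shared residue, delta = B(chain_b) - B(chain_a) of the per-residue
#' means; summarizes the mean delta and the fraction of residues where
#' chain_b is higher (ties count 0.5 each, so identical chains score
#' exactly 0.5). A positive `mean_delta` means chain_b is, on average,
#' more mobile.
#'
#' @param model a [structure_model()].
#' @param chain_a,chain_b chain ids.
#' @param region optional residue interval restricting the comparison.
#' @param atom_scope passed to [chain_bfactor_profile()].
#' @return object of class `bfactor_comparison`: `mean_delta`,
#'   `per_residue_delta` (data frame), `fraction_b_higher`, `n_shared`.
#' @export
compare_chains <- function(model, chain_a, chain_b, region = NULL,
                           atom_scope = c("backbone", "all")) {
  atom_scope <- match.arg(atom_scope)
  pa <- chain_bfactor_profile(model, chain_a, atom_scope)$profile
  pb <- chain_bfactor_profile(model, chain_b, atom_scope)$profile
  if (!is.null(region)) {
    pa <- pa[pa$resno >= min(region) & pa$resno <= max(region), ]
    pb <- pb[pb$resno >= min(region) & pb$resno <= max(region), ]
  }
  shared <- intersect(pa$resno, pb$resno)
  min_overlap <- if (is.null(region)) 10 else 3
  if (length(shared) < min_overlap)
    stop("chains ", chain_a, " and ", chain_b, " share only ",
         length(shared), " residues", if (!is.null(region))
           paste0(" in region ", min(region), "-", max(region)) else "",
         " (need >= ", min_overlap, ")")
  ba <- pa$mean_b[match(shared, pa$resno)]
  bb <- pb$mean_b[match(shared, pb$resno)]
  delta <- bb - ba
  frac <- (sum(delta > 0) + 0.5 * sum(delta == 0)) / length(delta)
  structure(list(chain_a = chain_a, chain_b = chain_b,
                 region = if (is.null(region)) NULL else range(region),
                 mean_delta = mean(delta),
                 per_residue_delta = data.frame(resno = shared, delta = delta),
                 fraction_b_higher = frac, n_shared = length(shared),
                 atom_scope = atom_scope),
            class = "bfactor_comparison")
}

#' @export
print.bfactor_comparison <- function(x, ...) {
  cat(sprintf("bfactor_comparison: B(%s) - B(%s) mean delta %.2f A^2 over %d residues (%.0f%% higher in %s)\n",
              x$chain_b, x$chain_a, x$mean_delta, x$n_shared,
              100 * x$fraction_b_higher, x$chain_b))
  invisible(x)
}
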