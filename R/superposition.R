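# Least-squares rigid superposition (proper rotations only), iterative
# low-RMSD core selection, and per-residue displacement profiling.
#
# Correspondence between models is by identical author residue number --
# adequate for point mutants of one protein; alignment-driven mapping is
# out of scope.

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper orthogonal matrix (checked to 1e-9).
#' @param translation 3-vector, Angstrom.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthogonal")
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation is not proper (det != +1): reflection rejected")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a [rigid_transform()].
#' @param x n x 3 coordinate matrix or a [structure_model()].
#' @return transformed coordinates / model of the same form.
#' @export
apply_transform <- function(transform, x) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(x, "structure_model")) {
    x$atoms[, c("x", "y", "z")] <-
      apply_transform(transform, .coords(x$atoms))
    return(x)
  }
  sweep(x %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Kabsch superposition
#'
#' Closed-form least-squares fit of `Q` onto `P` over proper rotations:
#' the returned transform minimizes the RMSD of `apply_transform(t, Q)`
#' against `P`, with reflections suppressed by sign-correcting the
#' smallest singular direction. For degenerate (collinear) input any
#' minimizing proper rotation is returned; the RMSD is still the true
#' minimum.
#'
#' @param P,Q n x 3 coordinate matrices with row-wise correspondence,
#'   n >= 3.
#' @return list: `transform` (a [rigid_transform()]), `rmsd` (Angstrom).
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) stop("P and Q must have the same number of points")
  if (nrow(P) < 3) stop("superposition needs at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp, "-"); Qc <- sweep(Q, 2, cq, "-")
  H <- crossprod(Qc, Pc)          # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- rigid_transform(R, cp - drop(R %*% cq))
  rmsd <- sqrt(mean(rowSums((apply_transform(tr, Q) - P)^2)))
  list(transform = tr, rmsd = rmsd)
}

# matched C-alpha coordinate pairs for the mapped chains, keyed by
# (chain_a, resno); chain_map: names = chains of a, values = chains of b
.matched_calpha <- function(model_a, model_b, chain_map, residues = NULL) {
  out <- NULL
  for (i in seq_along(chain_map)) {
    ch_a <- names(chain_map)[i]; ch_b <- chain_map[[i]]
    ra <- range(model_a$atoms$resno[model_a$atoms$chain == ch_a])
    ca_a <- select_calpha(model_a, ch_a, ra)
    rb <- range(model_b$atoms$resno[model_b$atoms$chain == ch_b])
    ca_b <- select_calpha(model_b, ch_b, rb)
    shared <- intersect(ca_a$resno, ca_b$resno)
    if (!is.null(residues)) shared <- intersect(shared, residues)
    if (length(shared) == 0) next
    ia <- match(shared, ca_a$resno); ib <- match(shared, ca_b$resno)
    out <- rbind(out, data.frame(
      chain_a = ch_a, chain_b = ch_b, resno = shared,
      xa = ca_a$x[ia], ya = ca_a$y[ia], za = ca_a$z[ia],
      xb = ca_b$x[ib], yb = ca_b$y[ib], zb = ca_b$z[ib]))
  }
  out
}

#' Iterative low-RMSD core superposition
#'
#' Starting from an initial core residue set, repeatedly: fit a Kabsch
#' superposition on the current core, compute per-residue C-alpha
#' deviations, and reject residues deviating more than the threshold.
#' Iteration stops when the core is stable, when it would shrink below
#' 20% of the initial size (floor 3, an error), or at `max_iter`.
#'
#' @param model_a,model_b [structure_model()]s (reference and moving).
#' @param chain_map named character vector mapping chains of `model_a` to
#'   chains of `model_b` (default `c(A = "A")`).
#' @param initial_core integer residue numbers forming the starting core
#'   (applied to every mapped chain; non-shared residues are dropped).
#' @param reject_threshold deviation cutoff in Angstrom (default 2.0,
#'   conventional for a low-RMSD core).
#' @param max_iter iteration cap.
#' @param adaptive if TRUE the cutoff is `2 * current core RMSD` instead
#'   of the fixed threshold.
#' @return object of class `superposition_result`: `transform`,
#'   `core_residues` (data frame chain_a/chain_b/resno), `core_rmsd`,
#'   `iterations`, `rejected_residues`, `chain_map`.
#' @export
core_superpose <- function(model_a, model_b, chain_map = c(A = "A"),
                           initial_core, reject_threshold = 2.0,
                           max_iter = 20, adaptive = FALSE) {
  pairs <- .matched_calpha(model_a, model_b, chain_map, initial_core)
  if (is.null(pairs) || nrow(pairs) < 3)
    stop("fewer than 3 initial core residues shared between the models")
  n0 <- nrow(pairs)
  floor_n <- max(3, ceiling(0.2 * n0))
  active <- rep(TRUE, n0)
  trace <- integer()
  fit <- NULL
  for (iter in seq_len(max_iter)) {
    P <- as.matrix(pairs[active, c("xa", "ya", "za")])
    Q <- as.matrix(pairs[active, c("xb", "yb", "zb")])
    fit <- kabsch(P, Q)
    dev <- sqrt(rowSums((apply_transform(fit$transform, Q) - P)^2))
    cutoff <- if (adaptive) 2 * fit$rmsd else reject_threshold
    drop_ <- dev > cutoff
    trace <- c(trace, sum(active))
    if (!any(drop_)) break
    if (sum(active) - sum(drop_) < floor_n)
      stop("core superposition did not converge: core would shrink below ",
           floor_n, " residues (size trace: ",
           paste(trace, collapse = " -> "), ")")
    active[which(active)[drop_]] <- FALSE
  }
  structure(list(transform = fit$transform,
                 core_residues = pairs[active, c("chain_a", "chain_b", "resno")],
                 core_rmsd = fit$rmsd, iterations = iter,
                 rejected_residues = pairs[!active, c("chain_a", "chain_b", "resno")],
                 chain_map = chain_map),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("superposition_result: core %d residues, rmsd %.3f A, %d iteration(s), %d rejected\n",
              nrow(x$core_residues), x$core_rmsd, x$iterations,
              nrow(x$rejected_residues)))
  invisible(x)
}

#' Per-residue displacement profile after superposition
#'
#' Applies the superposition transform to model B and reports, for each
#' requested residue present in both models, the C-alpha displacement
#' |Ca_A - T(Ca_B)|. Optionally reports the maximum over a designated
#' subset (e.g. the extracellular edge) separately.
#'
#' @param model_a,model_b [structure_model()]s as superposed.
#' @param result a [core_superpose()] result (its transform and chain map
#'   are used).
#' @param residues integer residue numbers to profile.
#' @param edge_residues optional subset whose maximum is reported as
#'   `edge_max`.
#' @return object of class `displacement_profile`: data frame `profile`
#'   (resno, displacement), `max_shift` (list residue/shift), `edge_max`.
#' @export
displacement_profile <- function(model_a, model_b, result, residues,
                                 edge_residues = NULL) {
  stopifnot(inherits(result, "superposition_result"))
  pairs <- .matched_calpha(model_a, model_b, result$chain_map, residues)
  if (is.null(pairs) || nrow(pairs) == 0)
    stop("no requested residues are present in both models")
  Qt <- apply_transform(result$transform,
                        as.matrix(pairs[, c("xb", "yb", "zb")]))
  disp <- sqrt(rowSums((as.matrix(pairs[, c("xa", "ya", "za")]) - Qt)^2))
  prof <- data.frame(chain = pairs$chain_a, resno = pairs$resno,
                     displacement = disp)
  imax <- which.max(disp)
  edge_max <- NA_real_
  if (!is.null(edge_residues)) {
    sel <- prof$resno %in% edge_residues
    if (any(sel)) edge_max <- max(prof$displacement[sel])
  }
  structure(list(profile = prof,
                 max_shift = list(resno = prof$resno[imax],
                                  shift = disp[imax]),
                 edge_max = edge_max),
            class = "displacement_profile")
}

#' @export
print.displacement_profile <- function(x, ...) {
  cat(sprintf("displacement_profile: %d residues, max shift %.2f A at residue %d\n",
              nrow(x$profile), x$max_shift$shift, x$max_shift$resno))
  invisible(x)
}
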