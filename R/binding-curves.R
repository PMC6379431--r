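# One-site saturation binding analysis of FSEC-style peak heights:
# normalization of bound/unbound peak heights to fraction bound (anchored
# at a saturating ligand concentration taken as the maximum), nonlinear
# least-squares fit of f(L) = Bmax * L / (Kd + L), and a simulator for
# parameter-recovery tests.

#' Construct a binding series
#'
#' @param ligand_concentrations micromolar, strictly increasing, >= 4
#'   points (0 allowed).
#' @param fraction_bound same length, values in [0, 1].
#' @param saturating_index index of the concentration treated as full
#'   saturation (default: the last, i.e. highest, concentration).
#' @return object of class `binding_series`.
#' @export
binding_series <- function(ligand_concentrations, fraction_bound,
                           saturating_index = length(ligand_concentrations)) {
  L <- as.numeric(ligand_concentrations); f <- as.numeric(fraction_bound)
  if (length(L) != length(f)) stop("concentration and fraction lengths differ")
  if (length(L) < 4) stop("need at least 4 concentration points")
  if (any(L < 0)) stop("concentrations must be nonnegative")
  if (any(diff(L) <= 0)) stop("concentrations must be strictly increasing")
  if (any(f < -1e-9 | f > 1 + 1e-9)) stop("fractions must lie in [0, 1]")
  f <- pmin(1, pmax(0, f))
  if (saturating_index < 1 || saturating_index > length(L))
    stop("saturating_index out of range")
  structure(list(ligand_concentrations = L, fraction_bound = f,
                 saturating_index = as.integer(saturating_index)),
            class = "binding_series")
}

#' Normalize FSEC peak heights to fraction bound
#'
#' Raw fraction at each point is bound/(bound + unbound) (mode
#' "fraction"; mode "ratio" uses bound/unbound, an alternative reading of
#' peak-height normalization). Raw fractions are then rescaled so the
#' saturating point equals 1 and clipped to [0, 1]. The result is
#' invariant to multiplying all heights by a positive constant.
#'
#' @param bound_heights,unbound_heights equal-length nonnegative peak
#'   heights.
#' @param ligand_concentrations micromolar, one per point.
#' @param saturating_index index treated as full saturation (default:
#'   highest concentration).
#' @param mode "fraction" (default) or "ratio".
#' @return a [binding_series()].
#' @export
normalize_peaks <- function(bound_heights, unbound_heights,
                            ligand_concentrations,
                            saturating_index = length(bound_heights),
                            mode = c("fraction", "ratio")) {
  mode <- match.arg(mode)
  b <- as.numeric(bound_heights); u <- as.numeric(unbound_heights)
  if (length(b) != length(u)) stop("height vectors differ in length")
  if (any(b < 0) || any(u < 0)) stop("peak heights must be nonnegative")
  raw <- if (mode == "fraction") {
    tot <- b + u
    if (any(tot <= 0))
      stop("zero total peak height at point(s) ",
           paste(which(tot <= 0), collapse = ", "))
    b / tot
  } else {
    if (any(u <= 0))
      stop("zero unbound peak height at point(s) ",
           paste(which(u <= 0), collapse = ", "))
    b / u
  }
  if (raw[saturating_index] <= 0)
    stop("raw fraction at the saturating point is zero; cannot anchor")
  f <- pmin(1, pmax(0, raw / raw[saturating_index]))
  binding_series(ligand_concentrations, f, saturating_index)
}

#' Fit a one-site saturation binding model
#'
#' Least-squares fit of f(L) = Bmax * L / (Kd + L) on untransformed
#' fractions, multistarted over log-spaced initial Kd values. In
#' normalized mode (default) Bmax is fixed at 1 because the series is
#' anchored at the saturating point; `fix_bmax = FALSE` frees Bmax for
#' sensitivity checks. Data must bracket the half-saturation point (at
#' least one fraction below 0.8 and one above 0.2), otherwise Kd is not
#' constrained and an error is raised.
#'
#' @param series a [binding_series()].
#' @param fix_bmax fix Bmax = 1 (default TRUE).
#' @return object of class `binding_fit`: `kd` (micromolar), `bmax`,
#'   `rss`, `converged`, `fitted`, `series`.
#' @export
fit_one_site <- function(series, fix_bmax = TRUE) {
  stopifnot(inherits(series, "binding_series"))
  L <- series$ligand_concentrations; f <- series$fraction_bound
  if (!any(f < 0.8) || !any(f > 0.2))
    stop("unidentifiable curve: data do not bracket half-saturation ",
         "(need a fraction below 0.8 and one above 0.2)")
  Lpos <- L[L > 0]
  starts <- exp(seq(log(max(min(Lpos) / 10, 1e-6)),
                    log(max(L) * 10), length.out = 8))
  dat <- data.frame(L = L, f = f)
  best <- NULL
  for (k0 in starts) {
    fit <- tryCatch({
      if (fix_bmax) {
        minpack.lm::nlsLM(f ~ L / (kd + L), data = dat,
                          start = list(kd = k0),
                          lower = c(kd = 1e-9),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(f ~ bmax * L / (kd + L), data = dat,
                          start = list(kd = k0, bmax = max(f)),
                          lower = c(kd = 1e-9, bmax = 1e-6),
                          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("one-site fit failed from every starting value")
  cf <- stats::coef(best$fit)
  structure(list(kd = unname(cf["kd"]),
                 bmax = if (fix_bmax) 1 else unname(cf["bmax"]),
                 rss = best$rss,
                 converged = best$fit$convInfo$isConv,
                 fitted = as.numeric(stats::fitted(best$fit)),
                 fix_bmax = fix_bmax,
                 series = series),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("binding_fit: Kd = %.4g uM, Bmax = %.3g, rss = %.3g (%sconverged)\n",
              x$kd, x$bmax, x$rss, if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Simulate a one-site binding series
#'
#' fractions = L / (Kd + L) + Gaussian noise, clipped to [0, 1];
#' deterministic given the seed.
#'
#' @param kd micromolar, > 0.
#' @param concentrations micromolar; default an FSEC-style titration from
#'   0 to 1 micromolar with the 1 micromolar point saturating.
#' @param noise_sd Gaussian noise on the fractions.
#' @param seed integer seed.
#' @return a [binding_series()].
#' @export
simulate_binding <- function(kd,
                             concentrations = c(0, 0.0125, 0.025, 0.05,
                                                0.1, 0.2, 0.5, 1),
                             noise_sd = 0, seed = 1) {
  if (kd <= 0) stop("kd must be positive")
  L <- as.numeric(concentrations)
  f <- L / (kd + L)
  if (noise_sd > 0) {
    set.seed(seed)
    f <- f + stats::rnorm(length(L), sd = noise_sd)
  }
  binding_series(L, pmin(1, pmax(0, f)),
                 saturating_index = which.max(L))
}

#' Affinity ratio between two fits with a bootstrap interval
#'
#' Point ratio Kd_b / Kd_a with a percentile interval from resampling
#' residuals of each fit (refitting each resampled series). A ratio above
#' 1 means the second fit binds more weakly.
#'
#' @param fit_a,fit_b converged [fit_one_site()] results.
#' @param n_boot bootstrap draws (>= 500 recommended).
#' @param seed integer seed.
#' @param conf confidence level for the percentile interval.
#' @return list: `ratio`, `conf_int` (2-vector), `n_effective` (draws
#'   where both refits succeeded), `boot_ratios`.
#' @export
compare_affinity <- function(fit_a, fit_b, n_boot = 500, seed = 1,
                             conf = 0.95) {
  stopifnot(inherits(fit_a, "binding_fit"), inherits(fit_b, "binding_fit"))
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged))
    stop("both fits must have converged")
  set.seed(seed)
  one_boot <- function(fit) {
    res <- fit$series$fraction_bound - fit$fitted
    f_star <- pmin(1, pmax(0, fit$fitted + sample(res, replace = TRUE)))
    s <- tryCatch(binding_series(fit$series$ligand_concentrations, f_star,
                                 fit$series$saturating_index),
                  error = function(e) NULL)
    if (is.null(s)) return(NA_real_)
    ft <- tryCatch(fit_one_site(s, fix_bmax = fit$fix_bmax),
                   error = function(e) NULL)
    if (is.null(ft)) NA_real_ else ft$kd
  }
  ratios <- vapply(seq_len(n_boot), function(i) {
    ka <- one_boot(fit_a); kb <- one_boot(fit_b)
    if (is.na(ka) || is.na(kb)) NA_real_ else kb / ka
  }, numeric(1))
  ok <- ratios[!is.na(ratios)]
  alpha <- (1 - conf) / 2
  list(ratio = fit_b$kd / fit_a$kd,
       conf_int = unname(stats::quantile(ok, c(alpha, 1 - alpha))),
       n_effective = length(ok),
       boot_ratios = ok)
}

#' Read a binding CSV
#'
#' Expects columns `concentration_uM`, `bound_height`, `unbound_height`.
#'
#' @param path CSV path.
#' @param ... passed to [normalize_peaks()].
#' @return a [binding_series()].
#' @export
read_binding_csv <- function(path, ...) {
  d <- utils::read.csv(path)
  need <- c("concentration_uM", "bound_height", "unbound_height")
  if (!all(need %in% names(d)))
    stop("binding CSV must have columns: ", paste(need, collapse = ", "))
  d <- d[order(d$concentration_uM), , drop = FALSE]
  normalize_peaks(d$bound_height, d$unbound_height, d$concentration_uM, ...)
}
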