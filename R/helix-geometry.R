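# Vertex-anchored bend-angle measurement for transmembrane helices.
#
# The bend angle of a helix at a designated vertex residue is the deviation
# from collinearity between the axes of the two arms flanking the vertex: a
# perfectly straight helix scores ~0 deg. Arm axes are total-least-squares
# line fits; to keep the fit unbiased on short arms (~15 residues) the fit
# is applied to the helix axis trace -- a running mean of C-alpha positions
# over approximately one helical turn -- which cancels the spiral component
# that otherwise tilts the principal axis of raw C-alpha coordinates.

# total-least-squares line through points (no minimum-count policy);
# direction sign-oriented from the first toward the last point
.line_fit <- function(P) {
  ctr <- colMeans(P)
  C <- sweep(P, 2, ctr, "-")
  v <- svd(C)$v[, 1]
  if (sum(v * (P[nrow(P), ] - P[1, ])) < 0) v <- -v
  perp <- C - (C %*% v) %*% t(v)
  list(centroid = ctr, direction = v,
       rms_residual = sqrt(mean(rowSums(perp^2))))
}

# running mean of w consecutive points (w ~ one helical turn); the trace of
# axis points used for arm-axis fitting
.axis_trace <- function(P, window = 4) {
  n <- nrow(P)
  w <- min(window, n - 1)
  if (w <= 1) return(P)
  t(vapply(seq_len(n - w + 1),
           function(i) colMeans(P[i:(i + w - 1), , drop = FALSE]),
           numeric(3)))
}

#' Fit a helix axis by total least squares
#'
#' The direction is the principal eigenvector of the centered point
#' covariance, sign-oriented from the first toward the last residue
#' (N to C). The residual is the RMS perpendicular distance of the points
#' to the fitted line (approximately the helix radius for raw C-alpha
#' input).
#'
#' @param points n x 3 matrix of ordered C-alpha positions, or the data
#'   frame returned by [select_calpha()].
#' @param residue_range optional interval recorded in the result.
#' @return object of class `helix_axis`: `centroid`, `direction` (unit,
#'   N to C), `rms_residual`, `n_points`, `residue_range`.
#' @export
fit_axis <- function(points, residue_range = NULL) {
  if (is.data.frame(points)) {
    if (is.null(residue_range) && nrow(points) > 0)
      residue_range <- range(points$resno)
    points <- .coords(points)
  }
  if (nrow(points) < 5)
    stop("axis fit needs at least 5 points, got ", nrow(points))
  f <- .line_fit(points)
  structure(list(centroid = f$centroid, direction = f$direction,
                 rms_residual = f$rms_residual, n_points = nrow(points),
                 residue_range = residue_range),
            class = "helix_axis")
}

#' @export
print.helix_axis <- function(x, ...) {
  cat(sprintf("helix_axis: direction (%.3f, %.3f, %.3f), %d points, rms residual %.2f A\n",
              x$direction[1], x$direction[2], x$direction[3],
              x$n_points, x$rms_residual))
  invisible(x)
}

# select an arm's C-alphas with coverage checking (>= 80% of the range)
.arm_calpha <- function(model, chain, rng, label) {
  ca <- select_calpha(model, chain, rng)
  width <- diff(range(rng)) + 1
  if (nrow(ca) < 0.8 * width) {
    miss <- attr(ca, "missing_residues")
    stop(label, " arm ", min(rng), "-", max(rng), " covers only ",
         nrow(ca), "/", width, " residues (missing: ",
         paste(miss, collapse = ", "), ")")
  }
  if (nrow(ca) < 5)
    stop(label, " arm ", min(rng), "-", max(rng),
         " yields fewer than 5 C-alpha positions")
  ca
}

# axis of one arm: one-turn running mean, then TLS line fit
.arm_axis <- function(ca, rng, window = 4) {
  P <- .coords(ca)
  f <- .line_fit(.axis_trace(P, window))
  perp <- sweep(P, 2, f$centroid, "-")
  perp <- perp - (perp %*% f$direction) %*% t(f$direction)
  structure(list(centroid = f$centroid, direction = f$direction,
                 rms_residual = sqrt(mean(rowSums(perp^2))),
                 n_points = nrow(P), residue_range = range(rng)),
            class = "helix_axis")
}

#' Vertex-anchored helix bend angle
#'
#' Measures how much a helix bends at a vertex residue: both arm axes are
#' fitted N to C and the angle is arccos of their dot product, so a
#' straight helix reads near 0 deg and larger values mean a stronger kink.
#' The vertex residue belongs to neither arm. Arms must cover at least 80%
#' of their stated range after gap handling.
#'
#' @param model a [structure_model()].
#' @param chain chain id.
#' @param proximal_range,distal_range inclusive residue intervals for the
#'   two arms, sequence-before and sequence-after the vertex.
#' @param vertex_residue residue number of the vertex, strictly between
#'   the two arm ranges.
#' @param window axis-trace smoothing window in residues (~one turn).
#' @return object of class `bend_measurement` with the fitted arm axes and
#'   `angle` in degrees.
#' @export
bend_angle <- function(model, chain, proximal_range, vertex_residue,
                       distal_range, window = 4) {
  stopifnot(inherits(model, "structure_model"))
  if (vertex_residue >= min(distal_range) || vertex_residue <= max(proximal_range))
    stop("vertex residue ", vertex_residue,
         " must lie strictly between the proximal and distal arm ranges")
  prox <- .arm_calpha(model, chain, proximal_range, "proximal")
  dist <- .arm_calpha(model, chain, distal_range, "distal")
  ax_p <- .arm_axis(prox, proximal_range, window)
  ax_d <- .arm_axis(dist, distal_range, window)
  ang <- angle_between(ax_p$direction, ax_d$direction)
  structure(list(chain_id = chain, vertex_residue = vertex_residue,
                 proximal_range = range(proximal_range),
                 distal_range = range(distal_range),
                 proximal_axis = ax_p, distal_axis = ax_d, angle = ang),
            class = "bend_measurement")
}

#' @export
print.bend_measurement <- function(x, ...) {
  cat(sprintf("bend_measurement: chain %s, vertex %d, angle %.2f deg (arms %d-%d / %d-%d)\n",
              x$chain_id, x$vertex_residue, x$angle,
              x$proximal_range[1], x$proximal_range[2],
              x$distal_range[1], x$distal_range[2]))
  invisible(x)
}

#' Mean bend angle over chains
#'
#' Averages the vertex-anchored bend angle over the copies of the molecule
#' in the model (e.g. the two complexes of a crystal asymmetric unit).
#' Chains that fail coverage are reported; if all fail, an error is raised.
#'
#' @inheritParams bend_angle
#' @param chains character vector of chain ids.
#' @return list: `mean_angle` (degrees), `per_chain` (named numeric),
#'   `measurements`, `failed` (named character error messages).
#' @export
mean_bend <- function(model, chains, proximal_range, vertex_residue,
                      distal_range, window = 4) {
  meas <- list(); fails <- character()
  for (ch in chains) {
    m <- tryCatch(bend_angle(model, ch, proximal_range, vertex_residue,
                             distal_range, window),
                  error = function(e) conditionMessage(e))
    if (inherits(m, "bend_measurement")) meas[[ch]] <- m
    else fails[[ch]] <- m
  }
  if (length(meas) == 0)
    stop("bend angle failed on every chain: ",
         paste(sprintf("[%s] %s", names(fails), fails), collapse = "; "))
  per_chain <- vapply(meas, function(m) m$angle, numeric(1))
  list(mean_angle = mean(per_chain), per_chain = per_chain,
       measurements = meas, failed = fails)
}

#' Difference between two bend angles
#'
#' Signed difference a - b in degrees (convention: bent form minus
#' straight form, so a positive value is the extra bend attributable to
#' the helix-breaking residue).
#'
#' @param measurement_a,measurement_b numbers (degrees), or
#'   `bend_measurement` objects, or `mean_bend()` results.
#' @return degrees.
#' @export
bend_difference <- function(measurement_a, measurement_b) {
  val <- function(m) {
    if (is.numeric(m)) return(m)
    if (inherits(m, "bend_measurement")) return(m$angle)
    if (is.list(m) && !is.null(m$mean_angle)) return(m$mean_angle)
    stop("cannot extract an angle from object of class ",
         paste(class(m), collapse = "/"))
  }
  val(measurement_a) - val(measurement_b)
}
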