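# Synthetic coordinate generators with known ground truth. Every geometric
# stage of the package is validated by parameter recovery against these
# constructions, so no external coordinate files are needed for testing.
#
# The generators emit C-alpha-only chains (residue name GLY, so side-chain
# dependent operations fall back to C-alpha as documented). Defaults are
# canonical alpha-helix values: rise 1.5 A/residue, twist 100 deg/residue,
# C-alpha radius 2.3 A.

#' Ideal-helix specification
#'
#' @param n_residues integer >= 5.
#' @param rise_per_residue axial rise, Angstrom (canonical 1.5).
#' @param twist_per_residue rotation per residue, degrees (canonical 100).
#' @param radius C-alpha radius about the axis, Angstrom (canonical 2.3).
#' @param axis_direction unit 3-vector for the helix axis (N to C).
#' @param origin 3-vector; position of the axis at the first residue.
#' @return object of class `helix_spec`.
#' @export
helix_spec <- function(n_residues, rise_per_residue = 1.5,
                       twist_per_residue = 100, radius = 2.3,
                       axis_direction = c(0, 0, 1), origin = c(0, 0, 0)) {
  if (n_residues < 5) stop("n_residues must be >= 5")
  if (rise_per_residue <= 0 || radius <= 0)
    stop("rise_per_residue and radius must be positive")
  structure(list(n_residues = as.integer(n_residues),
                 rise = rise_per_residue, twist = twist_per_residue,
                 radius = radius, axis = .unit(axis_direction),
                 origin = origin),
            class = "helix_spec")
}

#' Kinked-helix specification
#'
#' Describes an ideal helix broken at a vertex residue: the distal arm is
#' the ideal continuation rotated by `kink_angle` about an axis
#' perpendicular to the helix axis at the vertex C-alpha. The vertex itself
#' belongs to neither arm, matching the bend-angle measurement convention.
#'
#' @param helix a [helix_spec()].
#' @param vertex_index integer position of the vertex within the helix
#'   (strictly between 1 and n_residues).
#' @param kink_angle degrees in [0, 180).
#' @param kink_plane_azimuth degrees; direction of the bend around the
#'   helix axis.
#' @return object of class `kink_spec`.
#' @export
kink_spec <- function(helix, vertex_index, kink_angle,
                      kink_plane_azimuth = 0) {
  stopifnot(inherits(helix, "helix_spec"))
  if (vertex_index <= 1 || vertex_index >= helix$n_residues)
    stop("vertex_index must satisfy 1 < vertex_index < n_residues")
  if (kink_angle < 0 || kink_angle >= 180)
    stop("kink_angle must be in [0, 180)")
  structure(list(helix = helix, vertex_index = as.integer(vertex_index),
                 kink_angle = kink_angle, azimuth = kink_plane_azimuth),
            class = "kink_spec")
}

# canonical-frame helix C-alpha coordinates (axis = z, first residue z = 0)
.helix_points <- function(spec, phase = 0) {
  i <- seq_len(spec$n_residues) - 1
  phi <- .deg2rad(phase + i * spec$twist)
  cbind(spec$radius * cos(phi), spec$radius * sin(phi), i * spec$rise)
}

# place canonical-frame points into the spec's axis/origin frame
.place_points <- function(P, spec) {
  R <- .rotation_between(c(0, 0, 1), spec$axis)
  sweep(P %*% t(R), 2, spec$origin, "+")
}

.calpha_model <- function(identifier, xyz, chain, resno, b = 30, resid = "GLY") {
  structure_model(identifier, data.frame(
    chain = chain, resno = as.integer(resno), ins = "",
    resid = resid, elety = "CA", alt = "",
    occ = 1, b = b, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE))
}

#' Generate an ideal alpha-helix (C-alpha trace)
#'
#' @param spec a [helix_spec()].
#' @param chain chain id (default "A").
#' @param resno_start first residue number (default 1).
#' @param b constant B-factor assigned to all atoms.
#' @return a [structure_model()] with one C-alpha per residue.
#' @export
make_ideal_helix <- function(spec, chain = "A", resno_start = 1, b = 30) {
  stopifnot(inherits(spec, "helix_spec"))
  P <- .place_points(.helix_points(spec), spec)
  .calpha_model("ideal_helix", P, chain,
                seq(resno_start, length.out = spec$n_residues), b = b)
}

#' Generate a kinked alpha-helix with known bend angle
#'
#' Proximal arm is an ideal helix; residues past the vertex are the ideal
#' continuation rotated rigidly by exactly `kink_angle` about an axis
#' perpendicular to the helix axis through the vertex C-alpha. Continuity
#' at the vertex is preserved (rotation about a point on the chain), and
#' generation fails if the kink brings any non-bonded C-alpha pair closer
#' than 2 Angstrom.
#'
#' @param spec a [kink_spec()].
#' @param chain chain id.
#' @param resno_start first residue number.
#' @param b constant B-factor.
#' @return a [structure_model()].
#' @export
make_kinked_helix <- function(spec, chain = "A", resno_start = 1, b = 30) {
  stopifnot(inherits(spec, "kink_spec"))
  hs <- spec$helix
  P <- .helix_points(hs)
  v <- spec$vertex_index
  if (spec$kink_angle > 0) {
    az <- .deg2rad(spec$azimuth)
    rot_axis <- c(cos(az), sin(az), 0)   # perpendicular to canonical axis z
    R <- rotation_about_axis(rot_axis, spec$kink_angle)
    pivot <- P[v, ]
    idx <- (v + 1):hs$n_residues
    P[idx, ] <- sweep(sweep(P[idx, , drop = FALSE], 2, pivot, "-") %*% t(R),
                      2, pivot, "+")
  }
  D <- as.matrix(stats::dist(P))
  nonbonded <- abs(row(D) - col(D)) > 1
  if (any(D[nonbonded] < 2.0))
    stop("kink of ", spec$kink_angle,
         " deg causes self-intersection (non-bonded C-alpha pair < 2 A)")
  P <- .place_points(P, hs)
  m <- .calpha_model("kinked_helix", P, chain,
                     seq(resno_start, length.out = hs$n_residues), b = b)
  m$identifier <- sprintf("kinked_helix_%g", spec$kink_angle)
  m
}

#' Construct a two-model pair with a known rigid displacement
#'
#' Model A is `core` plus `mobile`; model B is `core` plus the rigidly
#' transformed `mobile`, optionally with isotropic Gaussian coordinate
#' noise on all atoms of B. The returned ground truth gives, per mobile
#' residue, the C-alpha displacement implied by the applied transform
#' (before noise) -- the oracle for displacement-profile recovery.
#'
#' @param core,mobile [structure_model()]s on the same chain with disjoint
#'   residue numbers.
#' @param rotation 3x3 proper rotation applied to the mobile domain.
#' @param translation 3-vector, Angstrom.
#' @param noise_sd isotropic Gaussian noise added to model B, Angstrom.
#' @param seed integer seed for the noise.
#' @return list with elements `a`, `b` (structure models) and `truth`
#'   (data frame `resno`, `displacement`).
#' @export
make_domain_pair <- function(core, mobile, rotation = diag(3),
                             translation = c(0, 0, 0), noise_sd = 0,
                             seed = 1) {
  stopifnot(inherits(core, "structure_model"),
            inherits(mobile, "structure_model"))
  shared <- intersect(unique(core$atoms$resno), unique(mobile$atoms$resno))
  if (length(shared) > 0)
    stop("core and mobile share residue numbers: ",
         paste(utils::head(shared, 5), collapse = ", "))
  mob_t <- mobile
  Pm <- .coords(mobile$atoms)
  Pt <- sweep(Pm %*% t(rotation), 2, translation, "+")
  mob_t$atoms[, c("x", "y", "z")] <- Pt
  disp <- sqrt(rowSums((Pt - Pm)^2))
  ca <- mobile$atoms$elety == "CA"
  truth <- data.frame(resno = mobile$atoms$resno[ca],
                      displacement = disp[ca])
  a <- structure_model("domain_pair_a", rbind(core$atoms, mobile$atoms))
  b_atoms <- rbind(core$atoms, mob_t$atoms)
  if (noise_sd > 0) {
    set.seed(seed)
    b_atoms[, c("x", "y", "z")] <- as.matrix(b_atoms[, c("x", "y", "z")]) +
      matrix(stats::rnorm(3 * nrow(b_atoms), sd = noise_sd), ncol = 3)
  }
  b <- structure_model("domain_pair_b", b_atoms)
  list(a = a, b = b, truth = truth)
}

#' Generate a helix bundle with known mean axis
#'
#' Packs `n_helices` ideal helices on a circle of radius `spacing`, one
#' chain each (A, B, C, ...), each tilted from the membrane normal (z) by
#' its listed angle, with the tilt applied radially. Helices alternate
#' N-to-C direction (odd helices run +z, even run -z), the antiparallel
#' topology of a tetraspan bundle; [estimate_membrane_normal()] with the
#' matching topology recovers the known mean axis stored in the
#' `true_normal` attribute.
#'
#' @param n_helices integer >= 2.
#' @param tilt_angles degrees, one per helix (recycled if length 1).
#' @param spacing circle radius in Angstrom (centers of adjacent helices).
#' @param n_residues residues per helix.
#' @return a [structure_model()]; attributes `true_normal` (analytic mean
#'   of the cytosolic-to-extracellular per-helix directions) and
#'   `topology` (+1 for N-to-C = extracellular, -1 otherwise).
#' @export
make_helix_bundle <- function(n_helices = 4, tilt_angles = 0, spacing = 10,
                              n_residues = 20) {
  if (n_helices < 2) stop("n_helices must be >= 2")
  tilt_angles <- rep_len(tilt_angles, n_helices)
  chains <- LETTERS[seq_len(n_helices)]
  topology <- ifelse(seq_len(n_helices) %% 2 == 1, 1L, -1L)
  atoms <- NULL
  dirs <- matrix(NA_real_, n_helices, 3)
  height <- (n_residues - 1) * 1.5
  for (i in seq_len(n_helices)) {
    psi <- 2 * pi * (i - 1) / n_helices
    radial <- c(cos(psi), sin(psi), 0)
    tangent <- c(-sin(psi), cos(psi), 0)
    up <- rotation_about_axis(tangent, tilt_angles[i]) %*% c(0, 0, 1)
    axis_nc <- drop(up) * topology[i]          # N-to-C direction
    origin <- spacing * radial +
      if (topology[i] > 0) c(0, 0, 0) else drop(up) * height
    spec <- helix_spec(n_residues, axis_direction = axis_nc, origin = origin)
    m <- make_ideal_helix(spec, chain = chains[i])
    atoms <- rbind(atoms, m$atoms)
    dirs[i, ] <- drop(up)                      # cytosolic-to-extracellular
  }
  model <- structure_model("helix_bundle", atoms)
  # clash check between different helices
  P <- .coords(model$atoms)
  ch <- model$atoms$chain
  D <- as.matrix(stats::dist(P))
  inter <- outer(ch, ch, "!=")
  if (any(D[inter] < 2.0))
    stop("helix spacing ", spacing, " A causes clashes between helices")
  attr(model, "true_normal") <- .unit(colMeans(dirs))
  attr(model, "topology") <- topology
  model
}

#' Assign B-factors with known chain offsets
#'
#' B = base + per-chain offset + gradient * z + Gaussian jitter, clamped at
#' zero. The chain offset is the recoverable ground truth for the
#' cross-chain B-factor comparison.
#'
#' @param model a [structure_model()].
#' @param per_chain_offset named numeric vector, Angstrom^2 per chain;
#'   chains not named get offset 0.
#' @param gradient_along_z Angstrom^2 per Angstrom of z.
#' @param base baseline B, Angstrom^2.
#' @param jitter_sd standard deviation of per-atom Gaussian jitter.
#' @param seed integer seed.
#' @return the model with replaced B-factors.
#' @export
assign_bfactors <- function(model, per_chain_offset = numeric(),
                            gradient_along_z = 0, base = 30,
                            jitter_sd = 1, seed = 1) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  missing_ch <- setdiff(names(per_chain_offset), unique(at$chain))
  if (length(missing_ch) > 0)
    stop("per_chain_offset names chains not in the model: ",
         paste(missing_ch, collapse = ", "))
  off <- rep(0, nrow(at))
  for (ch in names(per_chain_offset))
    off[at$chain == ch] <- per_chain_offset[[ch]]
  set.seed(seed)
  jit <- if (jitter_sd > 0) stats::rnorm(nrow(at), sd = jitter_sd) else 0
  at$b <- pmax(0, base + off + gradient_along_z * at$z + jit)
  model$atoms <- at
  model
}
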