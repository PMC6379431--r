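# Shared fixture builders. Everything is generated in code; nothing is
# downloaded.

# add isotropic Gaussian coordinate noise to every atom
perturb_model <- function(model, sd, seed) {
  set.seed(seed)
  model$atoms[, c("x", "y", "z")] <-
    as.matrix(model$atoms[, c("x", "y", "z")]) +
    matrix(rnorm(3 * nrow(model$atoms), sd = sd), ncol = 3)
  model
}

# apply a random proper rigid motion to a model
random_rigid_motion <- function(model, seed) {
  R <- random_rotation(seed)
  set.seed(seed + 1)
  tr <- rigid_transform(R, rnorm(3, sd = 20))
  apply_transform(tr, model)
}

# standard kinked-helix fixture: n = 34, vertex 17, arms 1-16 / 18-34
kinked_fixture <- function(theta, azimuth = 0) {
  make_kinked_helix(kink_spec(helix_spec(34), vertex_index = 17,
                              kink_angle = theta,
                              kink_plane_azimuth = azimuth))
}

measure_kink <- function(model, chain = "A") {
  bend_angle(model, chain, c(1, 16), 17, c(18, 34))$angle
}

# core (residues 1-30) + mobile (101-120) pair with a pure translation
translated_domain_pair <- function(shift = 5, noise_sd = 0, seed = 1) {
  core <- make_ideal_helix(helix_spec(30), resno_start = 1)
  mobile <- make_ideal_helix(helix_spec(20, origin = c(10, 0, 0)),
                             resno_start = 101)
  make_domain_pair(core, mobile, translation = c(shift, 0, 0),
                   noise_sd = noise_sd, seed = seed)
}

# write a temporary aligned FASTA and return its path
write_alignment <- function(seqs, path = tempfile(fileext = ".fasta")) {
  con <- file(path, "w")
  for (id in names(seqs)) writeLines(c(paste0(">", id), seqs[[id]]), con)
  close(con)
  path
}

# the family-style toy alignment: 10 sequences, column 4 holds
# 5 P / 3 G / 2 A (the conserved helix-breaking position)
thenar_toy_alignment <- function() {
  res <- c(rep("P", 5), rep("G", 3), rep("A", 2))
  seqs <- vapply(seq_along(res),
                 function(i) paste0("MKL", res[i], "VVW"), character(1))
  names(seqs) <- paste0("seq", seq_along(res))
  seqs
}

# brute-force minimal RMSD over a 3-angle Euler rotation grid (independent
# of the closed-form solver): rmsd^2 = (sum|Pc|^2 + sum|Qc|^2
# - 2 tr(R Qc^T Pc)) / n, minimized by maximizing tr(R Qc^T Pc)
grid_min_rmsd <- function(P, Q, step = 6) {
  Pc <- scale(P, scale = FALSE); Qc <- scale(Q, scale = FALSE)
  H <- crossprod(Qc, Pc)
  S <- sum(Pc^2) + sum(Qc^2)
  n <- nrow(P)
  rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  ry <- function(b) matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  best <- -Inf
  as_ <- seq(0, 2 * pi, by = step * pi / 180)
  bs_ <- seq(0, pi, by = step * pi / 180)
  for (a in as_) for (b in bs_) {
    RzaRyb <- rz(a) %*% ry(b)
    for (c_ in as_) {
      tr_ <- sum(diag(RzaRyb %*% rz(c_) %*% H))
      if (tr_ > best) best <- tr_
    }
  }
  sqrt(max(0, (S - 2 * best) / n))
}
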