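# Composite synthetic fixture: a claudin-like single-chain model with the
# claudin-style architecture -- a four-helix transmembrane bundle, a bent or
# straight TM3 with a designated vertex residue, an extracellular domain
# hinged on the distal TM3 arm, and the two rims of the cis-interaction
# pocket. All ground truth (kink angle, hinge displacements, pocket
# geometry) is known by construction, so the full analysis pipeline can be
# exercised end to end without external coordinates.
#
# Residue layout (claudin author numbering):
#   TM1 8-27 (up), ECD 28-77 (grid sheet above the membrane, hinged on
#   TM3), TM2 78-98 (down), TM3 118-149 (up, vertex 134, distal arm
#   135-149 rotated by the kink), beta5 stub 155-159 (static; 158-159 =
#   lower pocket rim), TM4 160-182 (down). Upper pocket rim = 146-147 on
#   the distal TM3 arm.

#' Generate a claudin-like synthetic structure
#'
#' Builds one or more copies (chains) of a claudin-like molecule whose
#' TM3 is kinked by a known angle at residue 134. The extracellular
#' domain (residues 28-77) and the upper pocket rim (146-147) ride on the
#' distal TM3 arm and rotate with the kink about the vertex C-alpha
#' (hinge construction); the transmembrane bundle, lower rim (158-159)
#' and the rest are identical across kink angles. Comparing two models
#' generated with different kink angles therefore has analytic ground
#' truth: every hinged atom moves by 2*sin(delta/2)*r, with r its
#' distance from the hinge axis.
#'
#' @param kink_angle TM3 bend in degrees.
#' @param chains chain ids; copies are translated 60 Angstrom apart.
#' @param b_base,b_chain_offset,b_jitter_sd,seed B-factor assignment
#'   passed to [assign_bfactors()].
#' @return a [structure_model()]; attribute `vertex_position` holds the
#'   vertex C-alpha of the first chain.
#' @export
make_claudin_like <- function(kink_angle = 25, chains = c("A", "C"),
                              b_base = 30, b_chain_offset = numeric(),
                              b_jitter_sd = 0, seed = 1) {
  one_chain <- function(ch, shift) {
    tm1 <- make_ideal_helix(helix_spec(20, origin = c(0, 0, 0)),
                            chain = ch, resno_start = 8)
    tm2 <- make_ideal_helix(helix_spec(21, axis_direction = c(0, 0, -1),
                                       origin = c(12, 0, 30)),
                            chain = ch, resno_start = 78)
    tm3 <- make_kinked_helix(
      kink_spec(helix_spec(32, origin = c(12, 12, 0)),
                vertex_index = 17, kink_angle = kink_angle,
                kink_plane_azimuth = 90),
      chain = ch, resno_start = 118)
    tm4 <- make_ideal_helix(helix_spec(23, axis_direction = c(0, 0, -1),
                                       origin = c(0, 12, 33)),
                            chain = ch, resno_start = 160)
    vertex <- c(12 + 2.3 * cos(.deg2rad(16 * 100)),
                12 + 2.3 * sin(.deg2rad(16 * 100)), 16 * 1.5)
    # ECD: 5 x 10 grid sheet, strands along y, 33 A above the vertex,
    # widest lateral offset 14 A -> max hinge radius ~35.8 A
    gx <- vertex[1] + rep(seq(-14, 14, length.out = 5), each = 10)
    gy <- vertex[2] + rep(seq(-15.75, 15.75, length.out = 10), times = 5)
    gz <- rep(vertex[3] + 33, 50)
    ecd <- cbind(gx, gy, gz)
    # beta5 stub 155-159 (lower pocket rim 158-159), static, 10 A above
    # the vertex next to TM3
    b5 <- cbind(vertex[1] + 4 + 0.5 * (0:4), vertex[2] + 3.5 * (0:4) - 7,
                rep(vertex[3] + 10, 5))
    if (kink_angle > 0) {
      R <- rotation_about_axis(c(0, 1, 0), kink_angle)
      hinge <- function(P)
        sweep(sweep(P, 2, vertex, "-") %*% t(R), 2, vertex, "+")
      ecd <- hinge(ecd)
    }
    mk <- function(P, resno) data.frame(
      chain = ch, resno = resno, ins = "", resid = "GLY", elety = "CA",
      alt = "", occ = 1, b = 30, x = P[, 1], y = P[, 2], z = P[, 3],
      stringsAsFactors = FALSE)
    at <- rbind(tm1$atoms, mk(ecd, 28:77), tm2$atoms, tm3$atoms,
                mk(b5, 155:159), tm4$atoms)
    at[, c("x", "y", "z")] <- at[, c("x", "y", "z")] +
      rep(shift, each = nrow(at))
    at
  }
  atoms <- NULL
  for (i in seq_along(chains))
    atoms <- rbind(atoms, one_chain(chains[i], c(60 * (i - 1), 0, 0)))
  m <- structure_model(sprintf("claudin_like_kink%g", kink_angle), atoms)
  m <- assign_bfactors(m, per_chain_offset = b_chain_offset,
                       base = b_base, jitter_sd = b_jitter_sd, seed = seed)
  attr(m, "kink_angle") <- kink_angle
  attr(m, "vertex_position") <-
    c(12 + 2.3 * cos(.deg2rad(16 * 100)),
      12 + 2.3 * sin(.deg2rad(16 * 100)), 16 * 1.5)
  m
}
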