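tm_cfg <- claudin_tm_defaults()

bundle_ranges <- list(c(1, 20), c(1, 20), c(1, 20), c(1, 20))
bundle_chains <- c("A", "B", "C", "D")

test_that("membrane normal of an untilted bundle is the z axis", {
  b <- make_helix_bundle(4, tilt_angles = 0, spacing = 10)
  f <- estimate_membrane_normal(b, bundle_ranges, chain = bundle_chains,
                                topology = c(1, -1, 1, -1))
  expect_lt(angle_between(f$normal, c(0, 0, 1)), 1)
})

test_that("tilted bundles recover the analytic mean direction", {
  b <- make_helix_bundle(4, tilt_angles = c(10, -10, 10, -10), spacing = 10)
  f <- estimate_membrane_normal(b, bundle_ranges, chain = bundle_chains,
                                topology = c(1, -1, 1, -1))
  expect_lt(angle_between(f$normal, attr(b, "true_normal")), 1)
  # two-helix boundary case still returns a frame
  b2 <- make_helix_bundle(2, tilt_angles = 5, spacing = 10)
  f2 <- estimate_membrane_normal(b2, bundle_ranges[1:2], chain = c("A", "B"),
                                 topology = c(1, -1))
  expect_s3_class(f2, "membrane_frame")
})

test_that("membrane normal is equivariant under whole-model rotation", {
  b <- make_helix_bundle(4, tilt_angles = c(10, -10, 10, -10), spacing = 10)
  f <- estimate_membrane_normal(b, bundle_ranges, chain = bundle_chains,
                                topology = c(1, -1, 1, -1))
  R0 <- random_rotation(3)
  b_rot <- apply_transform(rigid_transform(R0, c(5, -3, 2)), b)
  f_rot <- estimate_membrane_normal(b_rot, bundle_ranges,
                                    chain = bundle_chains,
                                    topology = c(1, -1, 1, -1))
  expect_lt(angle_between(f_rot$normal, drop(R0 %*% f$normal)), 0.1)
})

test_that("a wrong topology that cancels the axes is a degenerate bundle", {
  b <- make_helix_bundle(4, tilt_angles = 0, spacing = 10)
  expect_error(
    estimate_membrane_normal(b, bundle_ranges, chain = bundle_chains,
                             topology = c(1, 1, 1, 1)),
    "degenerate")
})

test_that("pocket width matches a hand-built two-rim construction", {
  # upper rim C-alphas at z = 10, lower at z = 4, frame normal = z
  at <- rbind(
    data.frame(chain = "A", resno = c(146, 147), ins = "", resid = "GLY",
               elety = "CA", alt = "", occ = 1, b = 10,
               x = c(0, 2), y = 0, z = 10),
    data.frame(chain = "A", resno = c(158, 159), ins = "", resid = "GLY",
               elety = "CA", alt = "", occ = 1, b = 10,
               x = c(0, 2), y = 1, z = 4))
  m <- structure_model("rims", at)
  frame <- structure(list(normal = c(0, 0, 1), center_offset = 0),
                     class = "membrane_frame")
  pa <- pocket_vertical_width(m, frame, c(146, 147), c(158, 159), "A")
  expect_equal(pa$vertical_width, 6)
  # swapping rims negates the width exactly
  pa_swap <- pocket_vertical_width(m, frame, c(158, 159), c(146, 147), "A")
  expect_equal(pa_swap$vertical_width, -6)
  expect_error(pocket_vertical_width(m, frame, c(146, 200), c(158, 159), "A"),
               "200")
})

test_that("side-chain centroids are used when side chains exist", {
  at <- rbind(
    data.frame(chain = "A", resno = 146, ins = "", resid = "PHE",
               elety = c("N", "CA", "C", "O", "CB", "CG"), alt = "",
               occ = 1, b = 10, x = 0, y = 0,
               z = c(8, 8, 8, 8, 11, 13)),   # side chain centroid z = 12
    data.frame(chain = "A", resno = 158, ins = "", resid = "GLY",
               elety = c("N", "CA", "C", "O"), alt = "", occ = 1, b = 10,
               x = 1, y = 1, z = c(4, 5, 4, 4)))  # glycine -> CA z = 5
  m <- structure_model("sidechains", at)
  frame <- structure(list(normal = c(0, 0, 1), center_offset = 0),
                     class = "membrane_frame")
  pa <- pocket_vertical_width(m, frame, 146, 158, "A")
  expect_equal(pa$upper_projection, 12)
  expect_equal(pa$lower_projection, 5)
  expect_equal(pa$vertical_width, 7)
})

test_that("pocket width is invariant under rigid motion with frame refit", {
  m <- make_claudin_like(25, chains = "A")
  f <- estimate_membrane_normal(m, tm_cfg$tm_ranges, "A", tm_cfg$topology)
  w0 <- pocket_vertical_width(m, f, chain = "A")$vertical_width
  for (s in 1:3) {
    m2 <- random_rigid_motion(m, seed = s)
    f2 <- estimate_membrane_normal(m2, tm_cfg$tm_ranges, "A",
                                   tm_cfg$topology)
    w2 <- pocket_vertical_width(m2, f2, chain = "A")$vertical_width
    expect_lt(abs(w2 - w0), 1e-6)
  }
})

test_that("pocket width decreases strictly with the constructed kink", {
  widths <- vapply(seq(0, 40, 5), function(theta) {
    m <- make_claudin_like(theta, chains = "A")
    f <- estimate_membrane_normal(m, tm_cfg$tm_ranges, "A", tm_cfg$topology)
    pocket_vertical_width(m, f, chain = "A")$vertical_width
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})
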