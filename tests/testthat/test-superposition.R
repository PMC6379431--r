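test_that("kabsch recovers identity and random applied transforms", {
  set.seed(1)
  P <- matrix(rnorm(30, sd = 5), ncol = 3)
  fit <- kabsch(P, P)
  expect_equal(fit$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit$transform$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_lt(fit$rmsd, 1e-9)
  for (s in 1:5) {
    R0 <- random_rotation(s)
    t0 <- rnorm(3, sd = 10)
    Q <- sweep(P %*% t(R0), 2, t0, "+")
    fit <- kabsch(P, Q)  # transform maps Q back onto P
    expect_lt(fit$rmsd, 1e-9)
    expect_equal(fit$transform$rotation %*% R0, diag(3), tolerance = 1e-9)
  }
})

test_that("kabsch rotation is always proper, even for mirrored input", {
  set.seed(2)
  for (s in 1:10) {
    P <- matrix(rnorm(15), ncol = 3)
    Q <- P %*% diag(c(-1, 1, 1))  # reflection: must not be inverted exactly
    fit <- kabsch(P, Q)
    expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-9)
    P2 <- matrix(rnorm(15), ncol = 3)
    fit2 <- kabsch(P, P2)
    expect_equal(det(fit2$transform$rotation), 1, tolerance = 1e-9)
    expect_equal(crossprod(fit2$transform$rotation), diag(3),
                 tolerance = 1e-9)
  }
})

test_that("kabsch rmsd matches brute-force rotation-grid minimization", {
  set.seed(3)
  for (s in 1:3) {
    P <- matrix(rnorm(15, sd = 2), ncol = 3)
    Q <- matrix(rnorm(15, sd = 2), ncol = 3)
    direct <- kabsch(P, Q)$rmsd
    gridded <- grid_min_rmsd(P, Q, step = 6)
    # closed form can only be better; grid can exceed it by its resolution
    expect_gte(gridded, direct - 1e-9)
    rmax <- max(sqrt(rowSums(scale(Q, scale = FALSE)^2)))
    expect_lte(gridded - direct, 2 * sin(1.5 * 6 * pi / 180 / 2) * rmax)
  }
})

test_that("degenerate collinear input still yields the exact minimum rmsd", {
  P <- cbind(0:4, 0, 0)
  Q <- cbind(0, 0:4, 0)
  fit <- kabsch(P, Q)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch(P[1:2, ], Q[1:2, ]), "at least 3")
  expect_error(kabsch(P, Q[1:4, ]), "same number")
})

test_that("core superposition of identical models converges immediately", {
  m <- make_claudin_like(25)
  res <- core_superpose(m, m, c(A = "A"), initial_core = c(8:27, 78:98))
  expect_equal(res$iterations, 1)
  expect_lt(res$core_rmsd, 1e-9)
  expect_equal(nrow(res$core_residues), 41)
  expect_equal(nrow(res$rejected_residues), 0)
})

test_that("core superposition rejects the displaced mobile domain", {
  pair <- translated_domain_pair(shift = 5, noise_sd = 0)
  res <- core_superpose(pair$a, pair$b, c(A = "A"),
                        initial_core = c(1:30, 101:120))
  expect_true(all(res$core_residues$resno %in% 1:30))
  expect_lt(res$core_rmsd, 1e-6)
  expect_true(all(101:120 %in% res$rejected_residues$resno))
})

test_that("core superposition is idempotent at convergence", {
  pair <- translated_domain_pair(shift = 5, noise_sd = 0.1, seed = 4)
  res <- core_superpose(pair$a, pair$b, c(A = "A"),
                        initial_core = c(1:30, 101:120))
  res2 <- core_superpose(pair$a, pair$b, c(A = "A"),
                         initial_core = res$core_residues$resno)
  expect_equal(res2$transform$rotation, res$transform$rotation,
               tolerance = 1e-9)
  expect_equal(res2$transform$translation, res$transform$translation,
               tolerance = 1e-9)
  expect_equal(res2$core_rmsd, res$core_rmsd, tolerance = 1e-9)
})

test_that("a loose threshold keeps the full core in a single fit", {
  pair <- translated_domain_pair(shift = 5, noise_sd = 0)
  res <- core_superpose(pair$a, pair$b, c(A = "A"),
                        initial_core = c(1:30, 101:120),
                        reject_threshold = 100)
  expect_equal(res$iterations, 1)
  expect_equal(nrow(res$core_residues), 50)
})

test_that("displacement profile recovers the constructed 5 A plateau", {
  pair <- translated_domain_pair(shift = 5, noise_sd = 0)
  res <- core_superpose(pair$a, pair$b, c(A = "A"),
                        initial_core = c(1:30, 101:120))
  prof <- displacement_profile(pair$a, pair$b, res, residues = 101:120)
  expect_true(all(abs(prof$profile$displacement - 5) < 0.01))
  expect_equal(prof$max_shift$shift, 5, tolerance = 0.01)
  # and zero on the static core
  core_prof <- displacement_profile(pair$a, pair$b, res, residues = 1:30)
  expect_true(all(core_prof$profile$displacement < 1e-6))
  expect_error(displacement_profile(pair$a, pair$b, res, residues = 500:510),
               "no requested residues")
})

test_that("a rigidly moved copy shows uniformly zero displacement", {
  m <- make_claudin_like(25)
  m2 <- random_rigid_motion(m, seed = 9)
  res <- core_superpose(m, m2, c(A = "A"),
                        initial_core = unique(m$atoms$resno))
  prof <- displacement_profile(m, m2, res,
                               residues = unique(m$atoms$resno))
  expect_lt(max(prof$profile$displacement), 1e-6)
})

test_that("displacement truth of noisy pairs is matched within 3 sigma", {
  pair <- translated_domain_pair(shift = 5, noise_sd = 0.2, seed = 5)
  res <- core_superpose(pair$a, pair$b, c(A = "A"),
                        initial_core = 1:30)
  expect_true(res$core_rmsd > 0.1 && res$core_rmsd < 0.4)
  prof <- displacement_profile(pair$a, pair$b, res, residues = 101:120)
  truth <- pair$truth$displacement[match(prof$profile$resno,
                                         pair$truth$resno)]
  expect_true(all(abs(prof$profile$displacement - truth) < 3 * 0.2 + 0.2))
})

test_that("hinge pairs show displacement growing away from the vertex", {
  ma <- make_claudin_like(25, chains = "A")
  mb <- make_claudin_like(17, chains = "A")
  res <- core_superpose(ma, mb, c(A = "A"),
                        initial_core = c(8:27, 78:98, 118:133, 160:182))
  prof <- displacement_profile(ma, mb, res, residues = 135:149)
  # raw displacements wobble with the helical phase; the one-turn
  # running mean must grow monotonically away from the hinge
  d <- prof$profile$displacement
  rm4 <- stats::filter(d, rep(1 / 4, 4), sides = 1)[-(1:3)]
  expect_true(all(diff(rm4) > -1e-9))
  expect_gt(d[length(d)], d[1])
})

test_that("rigid_transform rejects reflections and non-orthogonal input", {
  expect_error(rigid_transform(diag(c(-1, 1, 1))), "proper")
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthogonal")
})
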