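# Stokes algebra, the analyzer model, calibration and feature extraction.

test_that("ideal analyzer matrix projects canonical states correctly", {
  A <- ideal_psa_matrix()
  expect_equal(as.numeric(A %*% stokes(1, 0, 0, 0)), rep(0.5, 4))
  rcp <- as.numeric(A %*% stokes(1, 0, 0, 1))
  expect_equal(rcp[4], 1)  # right-circular channel passes all
  expect_equal(rcp[3], 0)  # left-circular channel extinguishes
  # 0-degree linear input: channel values from the matrix-vector product
  expect_equal(as.numeric(A %*% stokes(1, 1, 0, 0)), c(1, 0.5, 0.5, 0.5))
  expect_false(is.na(attr(A, "cond")))
})

test_that("stokes_to_features implements the normalized parameters and DOP", {
  f <- stokes_to_features(stokes(2, 0, 0, 0))
  expect_equal(unlist(f[, c("I", "q", "u", "v", "DOP")]),
               c(I = 2, q = 0, u = 0, v = 0, DOP = 0))
  f <- stokes_to_features(stokes(1, 1, 0, 0))
  expect_equal(unlist(f[, c("q", "u", "v", "DOP")]),
               c(q = 1, u = 0, v = 0, DOP = 1))
  f <- stokes_to_features(stokes(2, 0.6, 0, 0.8))
  expect_equal(unlist(f[, c("I", "q", "u", "v", "DOP")]),
               c(I = 2, q = 0.3, u = 0, v = 0.4, DOP = 0.5))
  expect_error(stokes_to_features(stokes(0, 0, 0, 0)), "non-positive")
})

test_that("DOP dominates each normalized component and clipping is counted", {
  S <- random_physical_stokes(200, seed = 11)
  f <- stokes_to_features(S)
  expect_true(all(f$DOP + 1e-12 >= pmax(abs(f$q), abs(f$u), abs(f$v))))
  # mild excess above 1 is clipped and counted, not altered silently beyond
  f2 <- stokes_to_features(c(1, 1.01, 0, 0), clip_tol = 0.05)
  expect_equal(f2$DOP, 1)
  expect_equal(attr(f2, "n_clipped"), 1L)
  expect_false(f2$unphysical)
  f3 <- stokes_to_features(c(1, 1.2, 0, 0), clip_tol = 0.05)
  expect_true(f3$unphysical)
  expect_gt(f3$DOP, 1.1)  # value preserved, only flagged
})

test_that("features are scale-invariant except intensity", {
  S <- random_physical_stokes(50, seed = 3)
  f1 <- stokes_to_features(S)
  f5 <- stokes_to_features(S * 5)
  expect_equal(f5$I, f1$I * 5)
  expect_equal(f5[, c("q", "u", "v", "DOP")], f1[, c("q", "u", "v", "DOP")],
               tolerance = 1e-12)
})

test_that("DOP is invariant under rotation of the linear reference frame", {
  S <- random_physical_stokes(40, seed = 5)
  for (phi in c(0.3, 1.2, -0.7)) {
    Sr <- S %*% t(rotation_mueller(phi))
    expect_equal(stokes_dop(Sr), stokes_dop(S), tolerance = 1e-12)
  }
  expect_equal(rotation_mueller(0), diag(4))
})

test_that("rotating a Mueller matrix by zero is the identity conjugation", {
  M <- mie_scattering_matrix(2)
  expect_equal(rotate_mueller(M, 0), M)
  # conjugation composes: R(a) then R(b) equals R(a+b)
  Mab <- rotate_mueller(rotate_mueller(M, 0.4), 0.3)
  expect_equal(Mab, rotate_mueller(M, 0.7), tolerance = 1e-12)
})

test_that("invert_stokes round-trips and flags unphysical results", {
  A <- ideal_psa_matrix()
  S <- stokes(1.5, 0.3, -0.2, 0.6)
  expect_equal(as.numeric(invert_stokes(as.numeric(A %*% S), A)),
               as.numeric(S), tolerance = 1e-12)
  expect_equal(as.numeric(invert_stokes(c(0.5, 0.5, 0.5, 0.5), A)),
               c(1, 0, 0, 0))
  # a channel vector implying DOP >> 1 is flagged but not altered
  bad <- as.numeric(A %*% c(1, 1.4, 0, 0))
  S_bad <- invert_stokes(bad, A)
  expect_true(attr(S_bad, "unphysical"))
  expect_equal(as.numeric(S_bad), c(1, 1.4, 0, 0), tolerance = 1e-12)
  expect_error(invert_stokes(c(1, 1, 1, 1), matrix(0, 4, 4)), "singular")
})

test_that("channel perturbations obey the linear-algebra error bound", {
  A <- random_instrument_matrix(seed = 21)
  Ainv_norm <- norm(solve(A), "2")
  set.seed(22)
  for (i in 1:20) {
    S <- drop(random_physical_stokes(1, seed = 100 + i))
    ch <- drop(A %*% S)
    dc <- numeric(4); dc[sample(4, 1)] <- 0.01 * ch[sample(4, 1)]
    S2 <- invert_stokes(ch + dc, A)
    expect_lte(sqrt(sum((S2 - S)^2)), Ainv_norm * sqrt(sum(dc^2)) + 1e-12)
  }
})

test_that("noise-free calibration recovers the analyzer exactly", {
  states <- calibration_states()
  A0 <- ideal_psa_matrix()
  channels <- states %*% t(unclass(A0))
  A_hat <- calibrate_instrument(states, channels)
  expect_lt(max(abs(unclass(A_hat) - unclass(A0))), 1e-10)
  expect_equal(attr(A_hat, "provenance"), "calibrated")
  expect_lt(attr(A_hat, "residual_norm"), 1e-10)
})

test_that("three calibration states give a rank-deficiency error", {
  states <- calibration_states()[1:3, ]
  A0 <- ideal_psa_matrix()
  channels <- states %*% t(unclass(A0))
  expect_error(calibrate_instrument(states, channels), "rank-deficient")
})

test_that("calibration under channel noise stays near truth across seeds", {
  states <- calibration_states()
  A0 <- unclass(ideal_psa_matrix())
  clean <- states %*% t(A0)
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    noisy <- clean + matrix(rnorm(16, 0, 1e-3), 4)
    mean(abs(unclass(calibrate_instrument(states, noisy)) - A0))
  }, numeric(1))
  expect_lt(mean(errs), 1e-2)
})

test_that("calibration estimator is unbiased under zero-mean channel noise", {
  states <- calibration_states()
  A0 <- unclass(ideal_psa_matrix())
  clean <- states %*% t(A0)
  n_seeds <- 1000
  acc <- matrix(0, 4, 4)
  acc2 <- matrix(0, 4, 4)
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    noisy <- clean + matrix(rnorm(16, 0, 1e-3), 4)
    Ah <- unclass(calibrate_instrument(states, noisy))
    acc <- acc + Ah
    acc2 <- acc2 + Ah^2
  }
  mean_A <- acc / n_seeds
  sem <- sqrt(pmax(acc2 / n_seeds - mean_A^2, 0) / n_seeds)
  expect_true(all(abs(mean_A - A0) <= 3 * sem + 1e-12))
})

test_that("instrument-matrix files round-trip with provenance", {
  path <- tempfile(fileext = ".txt")
  A <- ideal_psa_matrix()
  write_instrument_matrix(A, path)
  A2 <- read_instrument_matrix(path)
  expect_equal(unclass(A2)[, ], unclass(A)[, ], tolerance = 1e-15)
  expect_equal(attr(A2, "provenance"), "ideal")
})
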