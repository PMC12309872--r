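test_that("ideal Hadamard encodings score unit SNR efficiency", {
  for (ord in c(4, 8, 12)) {
    eff <- snr_efficiency(hadamard(ord))
    expect_equal(unname(eff), rep(1, ord - 1), tolerance = 1e-9)
  }
})

test_that("SNR efficiency scales linearly and detects rank deficiency", {
  H <- hadamard(8)
  A <- H
  A[, 1:7] <- 0.5 * A[, 1:7]
  expect_equal(unname(snr_efficiency(A)), rep(0.5, 7), tolerance = 1e-9)
  bad <- H
  bad[, 2] <- bad[, 1]
  expect_warning(eff <- snr_efficiency(bad), "rank deficient")
  expect_equal(unname(eff), rep(0, 7))
})

test_that("simulated efficiencies stay within the unit interval", {
  set.seed(7)
  for (i in 1:25) {
    A <- cbind(matrix(runif(8 * 5, -1, 1), 8, 5), 1)
    eff <- suppressWarnings(snr_efficiency(A))
    expect_true(all(eff <= 1 + 1e-9))
    expect_true(all(eff >= 0))
  }
})

test_that("motion study is anchored at the unperturbed baseline", {
  v <- make_vessels("neck4")
  s <- ioes(v, n_iter = 10, seed = 2)
  m1 <- motion_robustness(s, v, sd_grid = c(0, 2), n_rep = 10, seed = 5)
  m2 <- motion_robustness(s, v, sd_grid = c(0, 2), n_rep = 10, seed = 5)
  base <- mean(snr_efficiency(scheme_matrix(s, include_ns_label = FALSE)))
  expect_identical(m1$mean_efficiency[1], base)
  expect_identical(m1$mean_efficiency, m2$mean_efficiency) # seeded
  expect_lt(m1$mean_efficiency[2], m1$mean_efficiency[1])
})

test_that("efficiency collapses once motion dwarfs the wavelengths", {
  v <- make_vessels("neck4")
  s <- ioes(v, n_iter = 10, seed = 2)
  m <- motion_robustness(s, v, sd_grid = c(0, 200), n_rep = 40, seed = 8)
  # shared-translation motion rotates each cycle's phase coherently, so the
  # decorrelation floor sits near half the baseline rather than at zero
  expect_lt(m$mean_efficiency[2], 0.6 * m$mean_efficiency[1])
})

test_that("relative inversion efficiency follows its defining ratio", {
  expect_equal(relative_inversion_efficiency(1, -1, -1), 1)
  expect_equal(relative_inversion_efficiency(1, -1, 1), 0)
  expect_equal(relative_inversion_efficiency(1, -1, 0), 0.5)
  # affine invariance
  expect_equal(relative_inversion_efficiency(1 + 5, -1 + 5, 0.2 + 5),
               relative_inversion_efficiency(1, -1, 0.2))
  expect_error(relative_inversion_efficiency(1, 1, 0), "differ")
})

test_that("off-resonance on the ACAs degrades mean efficiency monotonically", {
  v <- make_vessels("cow9")
  tab <- off_resonance_study(v, aca = "ACA", intervals = 1560,
                             offsets = c(0, 50, 100), n_iter = 5,
                             seed = 4, n_theta = 32, dt = 8)
  expect_equal(nrow(tab), 3)
  expect_true(all(diff(tab$mean_efficiency) <= 1e-9))
})

test_that("territory signal curves match the design on clean data", {
  v <- make_vessels("neck4")
  s <- ioes(v, n_iter = 10, seed = 2)
  syn <- synthesize_stack(v, s, phantom_spec(grid = c(16, 16, 2),
                                             noise_sd = 0, seed = 1))
  mask <- syn$truth == 2
  curve <- territory_signal_curve(syn$stack, mask)
  expect_equal(attr(curve, "vessel"), 2)
  expect_equal(curve$measured, curve$predicted, tolerance = 1e-10)
  expect_error(territory_signal_curve(syn$stack, syn$truth == 99), "empty")
  # with noise the curves agree within a few standard errors
  synn <- synthesize_stack(v, s, phantom_spec(grid = c(16, 16, 2),
                                              noise_sd = 0.3, seed = 2))
  cn <- territory_signal_curve(synn$stack, synn$truth == 2, vessel = 2)
  se <- 0.3 / sqrt(8 * sum(synn$truth == 2))
  expect_lt(max(abs(cn$measured - cn$predicted)), 6 * se)
})
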