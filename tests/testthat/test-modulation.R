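# midpoint of the label region (value < 0), for shift detection
label_center <- function(profile) {
  th <- c(profile$theta, 2 * pi)
  v <- c(profile$value, profile$value[1])
  neg <- which(v < 0)
  mean(th[neg])
}

test_that("profile endpoints reproduce the control and label conditions", {
  prof <- fixture_profile()
  expect_equal(modulation_at(prof, 0), 1) # normalized control
  r <- simulate_spin(opt_params, blood, spin_trajectory(30),
                     condition = "label", dt = 8)
  alpha <- inversion_efficiency(r$mz, r$t_cross, r$t_end, blood$t1)
  expect_equal(modulation_at(prof, pi), -(2 * alpha - 1), tolerance = 0.02)
  expect_true(all(abs(prof$value) <= 1 + 1e-3))
})

test_that("interpolation is exact at nodes, periodic, linear between", {
  prof <- fixture_profile()
  expect_equal(modulation_at(prof, prof$theta), prof$value)
  th <- c(0.3, 2.2, 5.1)
  expect_equal(modulation_at(prof, th + 2 * pi), modulation_at(prof, th))
  mid <- (prof$theta[5] + prof$theta[6]) / 2
  expect_equal(modulation_at(prof, mid),
               (prof$value[5] + prof$value[6]) / 2)
  expect_error(simulate_modulation(opt_params, blood, "sideways"))
})

test_that("bipolar profile is symmetric about the label center", {
  prof <- fixture_profile()
  d <- seq(0.2, 2.8, by = 0.4)
  expect_equal(modulation_at(prof, pi + d), modulation_at(prof, pi - d),
               tolerance = 5e-3)
})

test_that("off-resonance attenuates bipolar labeling but shifts unipolar", {
  bi50 <- simulate_modulation(opt_params, blood, "bipolar",
                              off_resonance = 50, n_theta = 32, dt = 8)
  bi100 <- simulate_modulation(opt_params, blood, "bipolar",
                               off_resonance = 100, n_theta = 32, dt = 8)
  prof0 <- fixture_profile()
  # attenuation only: |label value| shrinks with offset
  expect_lt(abs(modulation_at(bi50, pi)), abs(modulation_at(prof0, pi)))
  expect_lt(modulation_at(bi50, pi), 0) # still labeling at 50 Hz
  expect_lte(abs(modulation_at(bi100, pi)), abs(modulation_at(prof0, pi)))
  # the label region stays centered for bipolar ...
  expect_equal(label_center(bi50), pi, tolerance = 0.25)
  # ... but shifts for unipolar
  uni0 <- simulate_modulation(opt_params, blood, "unipolar", n_theta = 32,
                              dt = 8)
  uni50 <- simulate_modulation(opt_params, blood, "unipolar",
                               off_resonance = 50, n_theta = 32, dt = 8)
  expect_gt(abs(label_center(uni50) - label_center(uni0)), 0.2)
})

test_that("label-region widths: analytic cosine and polarity ordering", {
  # pure cosine: value < 0 exactly on (pi/2, 3*pi/2)
  cosine <- cosine_profile(n_theta = 256)
  cos_tab <- structure(list(theta = cosine$theta, value = cos(cosine$theta),
                            analytic = NULL),
                       class = "modulation_profile")
  expect_equal(veasl:::label_region_width(cos_tab), pi, tolerance = 0.01)
  # identical profiles have identical widths by construction
  prof <- fixture_profile()
  expect_equal(veasl:::label_region_width(prof),
               veasl:::label_region_width(prof))
  # unipolar label region is much narrower than bipolar at the optimal
  # (thin-plane) settings
  w <- compare_polarity_widths(opt_params, blood, n_theta = 32, dt = 8)
  expect_lt(w$unipolar_width, w$bipolar_width)
})
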