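test_that("zero flip angle leaves the magnetization at equilibrium", {
  p <- pcasl_params(9, 0.45, 870, 1560, 1e-4)
  r <- simulate_spin(p, blood, spin_trajectory(30), condition = "label",
                     dt = 8)
  expect_equal(r$mz, 1, tolerance = 1e-6)
  expect_equal(inversion_efficiency(r$mz, r$t_cross, r$t_end, blood$t1), 0,
               tolerance = 1e-6)
})

test_that("the control condition returns the spin near equilibrium", {
  for (p in list(opt_params, def_params)) {
    r <- simulate_spin(p, blood, spin_trajectory(30), condition = "control",
                       dt = 8)
    expect_lt(abs(1 - r$mz), 0.02)
  }
})

test_that("label condition at the optimal settings inverts efficiently", {
  r <- simulate_spin(opt_params, blood, spin_trajectory(30),
                     condition = "label", dt = 5)
  eff <- inversion_efficiency(r$mz, r$t_cross, r$t_end, blood$t1)
  expect_gt(eff, 0.85)
})

test_that("magnetization norm never exceeds one", {
  for (v in c(2, 30, 80)) {
    r <- simulate_spin(opt_params, blood, spin_trajectory(v),
                       condition = "label", dt = 8)
    expect_lte(r$max_norm, 1 + 1e-9)
  }
})

test_that("T1 correction inverts pure relaxation exactly", {
  # closed-form: Mz = 0 reached after exactly T1*ln(2) of recovery rewinds
  # to a perfect inversion
  expect_equal(inversion_efficiency(-1, 1, 1, 1650), 1)
  expect_equal(inversion_efficiency(1, 1, 1, 1650), 0)
  expect_equal(inversion_efficiency(0, 0, 1.65 * log(2), 1650), 1)
  # rewinding a signal that only relaxed recovers the at-crossing value
  mz0 <- -0.8
  dt <- 0.37
  mz_end <- 1 - (1 - mz0) * exp(-dt / 1.65)
  expect_equal(inversion_efficiency(mz_end, 0, dt, 1650), (1 - mz0) / 2,
               tolerance = 1e-12)
  expect_error(inversion_efficiency(0, 1, 0.5, 1650), "t_end")
})

test_that("simulator rejects invalid step sizes and velocities", {
  expect_error(simulate_spin(opt_params, blood, spin_trajectory(30),
                             dt = 1000), "time step")
  expect_error(spin_trajectory(0), "velocity")
  # unreachable rewinder amplitude is surfaced, not silently clipped
  p <- pcasl_params(9, 0.1, 940, 950, 20)
  expect_error(simulate_spin(p, blood, spin_trajectory(30)), "rewinder")
})

test_that("laminar averaging degenerates to plug flow at n_sub = 1", {
  plug <- laminar_average_efficiency(opt_params, blood, 30, n_sub = 1,
                                     dt = 8)
  r <- simulate_spin(opt_params, blood, spin_trajectory(30),
                     condition = "label", dt = 8)
  expect_equal(plug,
               inversion_efficiency(r$mz, r$t_cross, r$t_end, blood$t1),
               tolerance = 1e-12)
  expect_error(laminar_average_efficiency(opt_params, blood, -3), "positive")
})

test_that("optimal settings hold efficiency at high velocity better than
           the defaults", {
  hi_opt <- lam_eff_coarse(opt_params, 50)
  hi_def <- lam_eff_coarse(def_params, 50)
  expect_gt(hi_opt, hi_def)
  expect_gte(lam_eff_coarse(opt_params, 30),
             lam_eff_coarse(def_params, 50))
})

test_that("angulation leaves efficiency high up to 60 degrees", {
  sweep <- angulation_sweep(opt_params, blood, 30, angles = c(0, 60, 85),
                            dt = 8)
  base <- simulate_spin(opt_params, blood, spin_trajectory(30),
                        condition = "label", dt = 8)
  expect_equal(sweep$efficiency[1],
               inversion_efficiency(base$mz, base$t_cross, base$t_end,
                                    blood$t1))
  expect_gte(sweep$efficiency[2], 0.75)
  expect_true(all(is.finite(sweep$efficiency))) # slow-flow limit defined
  sweep_def <- angulation_sweep(def_params, blood, 30, angles = 60, dt = 8)
  expect_gte(sweep_def$efficiency[1], 0.75)
})

test_that("parameter search reports infeasibility under impossible limits", {
  space <- pcasl_search_space(g_max = c(2, 3), rf_duration = c(200, 300),
                              width_limit_mm = 1)
  res <- optimize_pcasl(space)
  expect_false(res$feasible)
  expect_null(res$params)
})
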