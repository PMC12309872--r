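# Shared fixtures, built once per test run.  Bloch-based objects use reduced
# resolution (coarser theta grids, dt = 8 us) to keep the suite fast; the
# acceptance tests use the full-resolution settings.

opt_params <- optimal_pcasl_params()
def_params <- default_pcasl_params()
blood <- blood_properties()

# laminar efficiency with a coarse sub-velocity grid (test-speed variant)
lam_eff_coarse <- function(params, vbar, n_sub = 10, dt = 8)
  laminar_average_efficiency(params, blood, vbar, n_sub = n_sub, dt = dt)

# modest-resolution bipolar modulation profile at the optimal settings
fixture_profile <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_modulation(opt_params, blood, "bipolar",
                                    n_theta = 32, dt = 8)
    cache
  }
})

# brute-force oracle for the Fourier cycle matcher: dense Cartesian k grid
# over the admissible band, same weighted objective, independent of the
# polar-grid search path
oracle_cycle <- function(vessels, targets, M = 4, n_grid = 301) {
  X <- as.matrix(as.data.frame(vessels)[, c("x_mm", "y_mm")])
  kmax <- pi / M
  ks <- seq(-kmax, kmax, length.out = n_grid)
  K <- as.matrix(expand.grid(kx = ks, ky = ks))
  keep <- sqrt(rowSums(K^2)) < kmax & sqrt(rowSums(K^2)) > 1e-6
  K <- K[keep, , drop = FALSE]
  S <- exp(1i * (K %*% t(X))) %*% targets
  lam <- 2 * pi / sqrt(rowSums(K^2))
  score <- Mod(S) * lam / (lam + M / 2)
  k <- K[which.max(score), ]
  list(k = as.numeric(k), lambda = 2 * pi / sqrt(sum(k^2)),
       score = max(score))
}

weighted_cycle_score <- function(vessels, cycle, targets, M = 4) {
  X <- as.matrix(as.data.frame(vessels)[, c("x_mm", "y_mm")])
  S <- Mod(sum(targets * exp(1i * as.vector(X %*% cycle$k))))
  S * cycle$lambda / (cycle$lambda + M / 2)
}
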