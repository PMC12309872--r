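make_fixture_scheme <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- ioes(make_vessels("cow9"), n_iter = 25, seed = 7)
    cache
  }
})

test_that("noiseless decoding inverts the encoding exactly", {
  v <- make_vessels("cow9")
  s <- make_fixture_scheme()
  syn <- synthesize_stack(v, s, phantom_spec(noise_sd = 0, seed = 1))
  dec <- decode_linear(syn$stack)
  for (j in seq_len(9)) {
    terr <- syn$truth == j
    expect_lt(max(abs(dec$perfusion[, , , j][terr] - syn$amplitude[j])),
              1e-10)
    expect_lt(max(abs(dec$baseline[terr] - 10)), 1e-10)
  }
  # re-encoding reproduces the input stack
  d <- dim(syn$stack$data)
  coef <- cbind(matrix(dec$components, prod(d[1:3]), 9),
                as.vector(dec$tissue))
  recon <- coef %*% t(syn$stack$matrix)
  expect_lt(max(abs(recon - matrix(syn$stack$data, prod(d[1:3]), d[4]))),
            1e-10)
})

test_that("orthogonal designs decode by matched filtering", {
  H <- hadamard(8)
  set.seed(3)
  coefs <- matrix(rnorm(16 * 8), 16, 8)
  Y <- coefs %*% t(H)
  stack <- vti_stack(array(Y, c(4, 4, 1, 8)), H)
  dec <- decode_linear(stack)
  mf <- Y %*% H / 8 # pseudoinverse identity for a Hadamard design
  got <- cbind(matrix(dec$components, 16, 7), as.vector(dec$tissue))
  expect_equal(got, mf, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("stack constructor and decoder reject inconsistent input", {
  H <- hadamard(4)
  expect_error(vti_stack(array(0, c(4, 4, 1, 5)), H), "5 cycles")
  bad <- cbind(H, H[, 2])
  stack <- vti_stack(array(rnorm(4 * 4 * 1 * 4), c(4, 4, 1, 4)), bad)
  expect_error(decode_linear(stack), "rank deficient")
})

test_that("territories are recovered near-perfectly at SNR 10", {
  v <- make_vessels("cow9")
  s <- make_fixture_scheme()
  ph <- phantom_spec(noise_sd = sqrt(8) / 10, n_averages = 8, seed = 2)
  expect_equal(phantom_snr(ph), 10)
  syn <- synthesize_stack(v, s, ph)
  map <- classify_territories(syn$stack, noise_sd = 0.1)
  perfused <- syn$truth > 0
  expect_gte(mean(map$assignment[perfused] == syn$truth[perfused]), 0.99)
  expect_gt(mean(map$confidence[perfused]), 0.95)
})

test_that("zero-signal voxels are assigned to static tissue", {
  v <- make_vessels("cow9")
  s <- make_fixture_scheme()
  syn <- synthesize_stack(v, s, phantom_spec(noise_sd = 0, seed = 1))
  map <- classify_territories(syn$stack, noise_sd = 1e-6)
  expect_true(all(map$assignment[syn$truth == 0] == 0))
  expect_equal(mean(map$assignment == syn$truth), 1)
})

test_that("classification is invariant to global intensity scaling", {
  v <- make_vessels("cow9")
  s <- make_fixture_scheme()
  syn <- synthesize_stack(v, s, phantom_spec(noise_sd = sqrt(8) / 10,
                                             seed = 4))
  m1 <- classify_territories(syn$stack, noise_sd = 0.1)
  scaled <- vti_stack(syn$stack$data * 40, syn$stack$matrix,
                      vessel_names = syn$stack$vessel_names)
  m2 <- classify_territories(scaled, noise_sd = 0.1 * 40)
  expect_identical(m1$assignment, m2$assignment)
  expect_equal(m1$confidence, m2$confidence, tolerance = 1e-9)
})

test_that("noise estimation recovers the simulated background SD", {
  v <- make_vessels("cow9")
  s <- make_fixture_scheme()
  syn <- synthesize_stack(v, s, phantom_spec(noise_sd = sqrt(8) * 0.05,
                                             seed = 6))
  est <- estimate_noise_sd(syn$stack)
  expect_equal(est, 0.05, tolerance = 0.35)
})

test_that("reduced-average decoding stays consistent with the full set", {
  v <- make_vessels("cow9")
  s <- make_fixture_scheme()
  # effectively noiseless: identical maps
  r0 <- reduced_average_study(v, s, phantom_spec(noise_sd = 1e-6), 4, 3,
                              seed = 5)
  expect_equal(r0$agreement, 1)
  # moderate SNR: high but imperfect agreement, with a confidence interval
  r1 <- reduced_average_study(v, s, phantom_spec(noise_sd = sqrt(8) / 10),
                              8, 6, seed = 5)
  expect_gt(r1$agreement, 0.75)
  expect_lt(r1$agreement, 1)
  expect_true(r1$conf_int[1] < r1$agreement & r1$agreement < r1$conf_int[2])
  # very low SNR: decoding accuracy drops to near chance and the maps
  # disagree, while much of the volume falls back to the static hypothesis
  r2 <- reduced_average_study(v, s, phantom_spec(noise_sd = 50), 2, 1,
                              seed = 5)
  perfused <- r2$truth > 0
  expect_lt(mean(r2$reduced$assignment[perfused] == r2$truth[perfused]),
            0.3)
  expect_lt(r2$agreement, 0.8)
  expect_gt(min(r2$frac_static), 0.2)
})
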