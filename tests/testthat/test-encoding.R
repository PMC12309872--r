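test_that("Hadamard constructions are orthogonal and normalized", {
  for (ord in c(2, 4, 8, 12)) {
    H <- hadamard(ord)
    expect_equal(crossprod(H), ord * diag(ord), ignore_attr = TRUE)
    expect_true(all(H[1, ] == 1))
    expect_true(all(H[, 1] == 1))
    expect_true(all(H %in% c(-1, 1)))
  }
  expect_error(hadamard(6), "order")
})

test_that("provisional ideal matrices use the smallest admissible order", {
  expect_equal(provisional_ideal(3, canonical = TRUE)$order, 4)
  expect_equal(provisional_ideal(6, canonical = TRUE)$order, 8)
  expect_equal(provisional_ideal(9, canonical = TRUE)$order, 12)
  expect_error(provisional_ideal(12), "max 11")
  # the all-ones tissue column is never assigned to a vessel
  set.seed(42)
  for (i in 1:20) {
    pi9 <- provisional_ideal(9)
    expect_false(1 %in% pi9$columns)
    expect_false(any(colSums(pi9$matrix == 1) == nrow(pi9$matrix)))
  }
})

test_that("vessel sets validate and merge near-duplicates", {
  expect_error(vessel_set("a", 0, 0), "at least 2")
  expect_error(vessel_set(c("a", "b"), c(0, Inf), c(0, 0)), "finite")
  expect_warning(v <- vessel_set(c("a", "b", "c"), c(0, 0.5, 10), c(0, 0, 0)),
                 "merging")
  expect_equal(nrow(v), 2)
  expect_equal(v$name[1], "a+b")
})

test_that("cycle matcher solves the two-vessel geometry analytically", {
  v <- vessel_set(c("a", "b"), c(0, 10), c(0, 0))
  cy <- oes_cycle(v, c(1, -1), M = 4)
  expect_equal(cy$kind, "selective")
  # the half-wavelength sits close to the vessel spacing (the gentle
  # low-frequency roll-off shifts it slightly long of exactly 20 mm)
  expect_equal(cy$lambda, 20, tolerance = 0.06)
  expect_lt(abs(cy$k[2]), 0.02) # k points along the vessel axis
  mod <- cos(c(0, 10) %*% t(cy$k[1]) + cy$phase)
  expect_equal(as.numeric(mod), c(1, -1), tolerance = 0.01)
})

test_that("cycle matcher matches the brute-force oracle", {
  geoms <- list(
    vessel_set(c("a", "b"), c(0, 10), c(0, 0)),
    vessel_set(c("a", "b"), c(0, 6), c(0, 0)),
    vessel_set(c("a", "b", "c"), c(-8, 4, 9), c(0, 7, -6)),
    make_vessels("neck4"))
  targets <- list(c(1, -1), c(1, -1), c(1, -1, -1), c(1, -1, 1, -1))
  for (i in seq_along(geoms)) {
    cy <- oes_cycle(geoms[[i]], targets[[i]], M = 4)
    or <- oracle_cycle(geoms[[i]], targets[[i]], M = 4)
    got <- weighted_cycle_score(geoms[[i]], cy, targets[[i]], M = 4)
    expect_gte(got, or$score * 0.995)
    expect_gt(cy$lambda, 8) # admissibility: lambda/2 > M
  }
})

test_that("tight displacement bounds force a long-wavelength compromise", {
  v <- vessel_set(c("a", "b"), c(0, 6), c(0, 0))
  cy4 <- oes_cycle(v, c(1, -1), M = 4)
  expect_equal(cy4$lambda, 12, tolerance = 0.08) # near-full modulation
  cy7 <- oes_cycle(v, c(1, -1), M = 7)
  expect_gt(cy7$lambda, 14)
  mod <- cos(c(0, 6) * cy7$k[1] + cy7$phase)
  expect_lt(max(abs(mod)), 1) # partial modulation only
  # all-control / all-label rows become nonselective cycles
  expect_equal(oes_cycle(v, c(1, 1))$kind, "nonselective_control")
  expect_equal(oes_cycle(v, c(-1, -1))$kind, "nonselective_label")
})

test_that("simulated matrix under the exact cosine equals the ideal", {
  v <- make_vessels("neck4")
  scheme <- ioes(v, cosine_profile(), n_iter = 30, seed = 11)
  A <- scheme_matrix(scheme)
  expect_true(all(A >= -1 - 1e-9 & A <= 1 + 1e-9))
  expect_true(all(A[, 5] == 1)) # static-tissue column
  # near-perfect realization on the near-rectangle
  expect_equal(unname(A), unname(scheme_matrix(scheme, which = "ideal")),
               tolerance = 0.15)
  # displacing a vessel by half a wavelength along k flips its entry
  cy <- scheme$cycles[[which(vapply(scheme$cycles, function(c)
    c$kind == "selective", logical(1)))[1]]]
  khat <- cy$k / sqrt(sum(cy$k^2))
  v2 <- v
  v2$x_mm[2] <- v2$x_mm[2] + khat[1] * cy$lambda / 2
  v2$y_mm[2] <- v2$y_mm[2] + khat[2] * cy$lambda / 2
  a1 <- modulation_at(cosine_profile(),
                      sum(c(v$x_mm[2], v$y_mm[2]) * cy$k) + cy$phase)
  a2 <- modulation_at(cosine_profile(),
                      sum(c(v2$x_mm[2], v2$y_mm[2]) * cy$k) + cy$phase)
  expect_equal(a2, -a1, tolerance = 1e-9)
})

test_that("cost function arithmetic, monotonicity and admissibility", {
  expect_equal(encoding_cost(1, 100, 4), (1 / (100 / 8 - 1))^2)
  expect_equal(encoding_cost(1, 100, 4), 0.0075614, tolerance = 1e-4)
  expect_equal(encoding_cost(1, 1e9, 4), 0, tolerance = 1e-15)
  expect_lt(encoding_cost(1.2, 50, 4), encoding_cost(1.7, 50, 4))
  expect_error(encoding_cost(1, 7.9, 4), "inadmissible")
  expect_error(encoding_cost(0.5, 50, 4), "condition")
})

test_that("IOES never scores worse than canonical OES and is reproducible", {
  for (tmpl in c("neck4", "cow9")) {
    v <- make_vessels(tmpl)
    base <- oes(v)
    improved <- ioes(v, n_iter = 20, seed = 3)
    expect_lte(improved$cost, base$cost)
    expect_gt(improved$lambda_min, 2 * improved$M)
    again <- ioes(v, n_iter = 20, seed = 3)
    expect_identical(improved$simulated, again$simulated)
    expect_equal(vapply(improved$cycles, function(c) c$lambda, numeric(1)),
                 vapply(again$cycles, function(c) c$lambda, numeric(1)))
  }
})

test_that("a single canonical iteration reproduces the OES baseline", {
  v <- make_vessels("neck4")
  a <- oes(v)
  b <- ioes(v, n_iter = 1, seed = 99) # iteration 1 is always canonical
  expect_equal(a$cost, b$cost)
  expect_equal(a$simulated, b$simulated)
})

test_that("schemes append the nonselective label cycle for in vivo use", {
  v <- make_vessels("cow9")
  s <- ioes(v, n_iter = 5, seed = 1)
  expect_equal(s$hadamard_order, 12)
  expect_equal(length(s$cycles), 13) # 12 design cycles + appended label
  expect_equal(s$cycles[[13]]$kind, "nonselective_label")
  expect_equal(s$n_design_cycles, 12)
  kinds <- vapply(s$cycles, function(c) c$kind, character(1))
  expect_equal(sum(kinds == "nonselective_control"), 1)
  A <- scheme_matrix(s, include_ns_label = FALSE)
  expect_equal(nrow(A), 12)
})

test_that("collinear degenerate geometries still yield admissible cycles", {
  v <- vessel_set(c("a", "b", "c", "d"), c(0, 9, 18, 27), rep(0, 4))
  s <- oes(v)
  lam <- vapply(s$cycles, function(c) c$lambda, numeric(1))
  expect_true(all(lam[!is.na(lam)] > 2 * s$M))
  expect_true(is.finite(s$cost))
})
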