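test_that("detrending matches hand OLS and handles edge cases", {
  d <- detrend(c(4, 6, 5))
  expect_equal(d$slope, 0.5)
  expect_equal(d$residuals, c(-0.5, 1, -0.5))
  expect_equal(mean(d$residuals), 0, tolerance = 1e-12)
  lin <- detrend(2 + 3 * (0:9))
  expect_equal(lin$residuals, rep(0, 10))
  expect_equal(lin$slope, 3)
  cst <- detrend(rep(7, 5))
  expect_equal(cst$slope, 0)
  expect_equal(cst$residuals, rep(0, 5))
  expect_error(detrend(c(1, 2)), "at least 3")
})

test_that("temporal stability is detrended 1/CV with degenerate flagging", {
  expect_equal(temporal_stability(c(4, 6, 5)), 5 / sqrt(0.75))
  expect_equal(temporal_stability(c(4, 6, 5)), 5.7735, tolerance = 1e-4)
  expect_true(is.na(temporal_stability(c(10, 10, 10))))
  x <- c(3, 9, 5, 8, 6)
  expect_equal(temporal_stability(2 * x), temporal_stability(x))
  expect_error(temporal_stability(c(-4, 1, 2)), "positive mean")
})

test_that("population stability follows the summed mean/sd ratio", {
  ## exact construction: a zero-mean, zero-slope fluctuation pattern
  ## rescaled so the two taxa have (mu, sigma) = (10, 2) and (5, 3);
  ## PS = (10 + 5) / (2 + 3) = 3
  b <- c(1, -2, 1) / sd(c(1, -2, 1))
  m <- cbind(10 + 2 * b, 5 + 3 * b)
  expect_equal(population_stability(m), 3)
  one <- matrix(c(4, 6, 5), ncol = 1)
  expect_equal(population_stability(one), temporal_stability(c(4, 6, 5)))
  two <- cbind(c(4, 6, 5), c(4, 6, 5))
  expect_equal(population_stability(two), population_stability(one))
})

test_that("synchrony phi matches the covariance-sum oracle and bounds", {
  m <- cbind(c(1, 5, 3, 6), c(2, 10, 6, 12))   # perfectly correlated
  expect_equal(synchrony_phi(m)$phi, 1, tolerance = 1e-10)
  a <- c(1, 4, 2, 5)
  m2 <- cbind(a, 10 - a)                        # perfect compensation
  expect_equal(synchrony_phi(m2)$phi, 0, tolerance = 1e-10)
  expect_equal(synchrony_phi(m2)$asynchrony, 1, tolerance = 1e-10)
  set.seed(42)
  for (i in 1:20) {
    m3 <- random_cover_matrix(3, 11)
    res <- apply(m3, 2, function(x) detrend(x)$residuals)
    phi_oracle <- sum(cov(res)) / sum(apply(res, 2, sd))^2
    expect_equal(synchrony_phi(m3)$phi, phi_oracle, tolerance = 1e-10)
    expect_gte(synchrony_phi(m3)$phi, 0)
    expect_lte(synchrony_phi(m3)$phi, 1)
  }
})

test_that("statistical averaging spans [1, sqrt(S)]", {
  expect_equal(statistical_averaging(matrix(c(4, 6, 5), ncol = 1)), 1)
  ## equal-sigma taxa reach sqrt(S)
  x <- c(1, 5, 2, 6, 3)
  m <- cbind(x, rev(x), x[c(3, 1, 5, 2, 4)])
  sig <- apply(m, 2, function(v) sd(detrend(v)$residuals))
  expect_equal(statistical_averaging(cbind(x, 10 - x)), sqrt(2))
  ## sigma = (3, 4) -> 7/5
  expect_equal(sum(c(3, 4)) / sqrt(sum(c(3, 4)^2)), 1.4)
  set.seed(7)
  m4 <- random_cover_matrix(6)
  sa <- statistical_averaging(m4)
  expect_gte(sa, 1)
  expect_lte(sa, sqrt(6))
})

test_that("compositional stability is 1 - mean consecutive Bray-Curtis", {
  m <- matrix(rep(c(10, 5, 2), each = 4), nrow = 4)   # constant composition
  expect_equal(compositional_stability(m), 1)
  ## complete turnover every step
  m2 <- rbind(c(10, 0), c(0, 10), c(10, 0))
  expect_equal(compositional_stability(m2), 0)
  ## (10, 0) -> (5, 5): BC = 10/20
  m3 <- rbind(c(10, 0), c(5, 5))
  expect_equal(compositional_stability(m3), 0.5)
  ## both-empty census pairs are skipped
  m4 <- rbind(c(10, 0), c(5, 5), c(0, 0), c(0, 0))
  steps <- c(0.5, 1)   # (10,0)->(5,5), (5,5)->(0,0); (0,0)->(0,0) skipped
  expect_equal(compositional_stability(m4), 1 - mean(steps))
})

test_that("the decomposition identity holds and the profile matches the naive reference", {
  set.seed(11)
  for (i in 1:100) {
    m <- random_cover_matrix(sample(2:8, 1), 11)
    pr <- stability_profile(m)
    ref <- naive_profile(m)
    expect_equal(pr$TS, ref$TS, tolerance = 1e-10)
    expect_equal(pr$PS, ref$PS, tolerance = 1e-10)
    expect_equal(pr$phi, ref$phi, tolerance = 1e-10)
    expect_equal(pr$SA, ref$SA, tolerance = 1e-10)
    expect_equal(pr$CS, ref$CS, tolerance = 1e-10)
    expect_equal(pr$TS, pr$PS / sqrt(pr$phi), tolerance = 1e-10)
  }
})

test_that("profiles are invariant to taxon order, scaling and zero taxa", {
  set.seed(3)
  m <- random_cover_matrix(5)
  base <- stability_profile(m)
  perm <- stability_profile(m[, sample(5)])
  for (col in c("TS", "CS", "PS", "phi", "SA"))
    expect_equal(perm[[col]], base[[col]])
  scl <- stability_profile(3.7 * m)
  for (col in c("TS", "CS", "PS", "phi", "SA"))
    expect_equal(scl[[col]], base[[col]], tolerance = 1e-12)
  zer <- stability_profile(cbind(m, 0))
  for (col in c("TS", "CS", "PS", "phi", "SA"))
    expect_equal(zer[[col]], base[[col]], tolerance = 1e-12)
})

test_that("single-taxon tiles collapse the decomposition", {
  m <- matrix(c(8, 12, 9, 13, 10), ncol = 1)
  pr <- stability_profile(m)
  expect_equal(pr$TS, pr$PS)
  expect_equal(pr$phi, 1)
  expect_equal(pr$SA, 1)
})

test_that("degenerate tiles are flagged, not infinite", {
  m <- matrix(5, nrow = 4, ncol = 2)
  pr <- stability_profile(m)
  expect_true(pr$degenerate)
  expect_true(is.na(pr$TS))
  expect_true(is.na(pr$phi))
  expect_equal(pr$CS, 1)   # constant composition is still maximally stable
})

test_that("stability_profiles covers every tile of a cover table", {
  d <- generate_design(2, 2, c(0.3, 0.7), seed = 2)
  cv <- simulate_covers(d, synth_params(seed = 14))
  st <- stability_profiles(cv)
  expect_setequal(st$tile_id, d$tile_id)
  expect_true(all(st$phi >= 0 & st$phi <= 1, na.rm = TRUE))
  expect_true(all(st$CS >= 0 & st$CS <= 1, na.rm = TRUE))
})

test_that("total-only detrending is available and stays bounded", {
  set.seed(21)
  m <- random_cover_matrix(5)
  alt <- stability_profile(m, detrending = "total_only")
  ref <- stability_profile(m)
  expect_gte(alt$phi, 0); expect_lte(alt$phi, 1)
  expect_gte(alt$SA, 1); expect_lte(alt$SA, sqrt(5))
  ## TS shares the detrended-total definition under both conventions
  expect_equal(alt$TS, ref$TS)
  ## per-taxon sigmas now include trend variance, so PS can differ
  expect_false(isTRUE(all.equal(alt$PS, ref$PS)))
})
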