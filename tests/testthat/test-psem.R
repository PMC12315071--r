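test_that("Fisher's C matches hand values and contracts", {
  expect_equal(fishers_c(c(0.5, 0.5))$C, -4 * log(0.5))
  expect_equal(fishers_c(c(0.5, 0.5))$C, 2.7726, tolerance = 1e-4)
  expect_equal(fishers_c(c(0.5, 0.5))$df, 4)
  expect_equal(fishers_c(c(1, 1, 1))$C, 0)
  empty <- fishers_c(numeric(0))
  expect_equal(unlist(empty), c(C = 0, df = 0, p = 1))
  expect_error(fishers_c(c(0.5, 1.2)), "0, 1")
  expect_error(fishers_c(c(0.5, 0)), "0, 1")
  ## monotone: smaller p, larger C
  expect_gt(fishers_c(c(0.2, 0.5))$C, fishers_c(c(0.3, 0.5))$C)
})

test_that("standardisation rescales slopes by the sd ratio", {
  expect_equal(standardise(2, 1, 2), 1)
  expect_equal(standardise(0, 3, 5), 0)
  expect_equal(standardise(-0.5, 2, 1), -1)
  expect_error(standardise(1, 0, 1), "positive")
})

test_that("a single-edge model reduces to the simple regression slope", {
  d <- test_design(2)
  set.seed(10)
  d$x <- zscore(rnorm(70))
  d$w <- 0.6 * d$x + rnorm(70, 0, 0.8)
  sp <- psem_spec("x -> w")
  fit <- suppressWarnings(psem(sp, d, nesting = FALSE, test = FALSE))
  slope <- coef(lm(w ~ x, data = d))[["x"]]
  expect_equal(fit$edges$estimate, slope, tolerance = 1e-8)
  expect_equal(fit$edges$spc, slope * sd(d$x) / sd(d$w), tolerance = 1e-8)
})

test_that("SPCs are invariant to affine rescaling of variables", {
  sp <- default_sem_spec()
  d <- simulate_sem(sp, c("het->richness" = 0.4,
                          "richness->asynchrony" = 0.5,
                          "asynchrony->temp_stability" = 0.5),
                    test_design(4), seed = 77)
  f1 <- suppressWarnings(psem(sp, d, test = FALSE, keep_models = FALSE))
  d2 <- d
  d2$richness <- 100 + 7 * d2$richness     # different units
  d2$temp_stability <- d2$temp_stability / 3
  f2 <- suppressWarnings(psem(sp, d2, test = FALSE, keep_models = FALSE))
  expect_equal(f1$edges$spc, f2$edges$spc, tolerance = 1e-6)
})

test_that("d-separation claims detect a truly missing path", {
  sp_gen <- psem_spec(c("a -> b", "b -> c", "a -> c"))
  sp_fit <- psem_spec(c("a -> b", "b -> c"))   # a -> c missing
  hits <- vapply(1:30, function(i) {
    d <- test_design(i)
    set.seed(i)
    d$a <- rnorm(70)
    d$b <- 0.5 * d$a + rnorm(70, 0, 0.8)
    d$c <- 0.5 * d$b + 0.6 * d$a + rnorm(70, 0, 0.7)
    cl <- suppressWarnings(dsep_tests(sp_fit, d, nesting = FALSE))
    cl$p[1] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("claim p values are roughly uniform under the true model", {
  sp <- psem_spec(c("a -> b", "b -> c"))
  ps <- vapply(1:60, function(i) {
    d <- test_design(i)
    set.seed(i + 300)
    d$a <- rnorm(70)
    d$b <- 0.5 * d$a + rnorm(70, 0, sqrt(0.75))
    d$c <- 0.5 * d$b + rnorm(70, 0, sqrt(0.75))
    suppressWarnings(dsep_tests(sp, d, nesting = FALSE))$p[1]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("the pSEM recovers generating standardised coefficients", {
  sp <- default_sem_spec()
  truth <- c("het->richness" = 0.4, "het->dominant" = -0.45,
             "het->consumers" = -0.35, "het->pop_stability" = 0.35,
             "emersion->richness" = -0.4, "emersion->dominant" = 0.5,
             "consumers->ephemerals" = -0.45,
             "richness->asynchrony" = 0.45,
             "pop_stability->comp_stability" = 0.4,
             "asynchrony->temp_stability" = 0.45,
             "comp_stability->temp_stability" = 0.35)
  ests <- sapply(1:25, function(i) {
    d <- simulate_sem(sp, truth, test_design(i), seed = i * 13)
    fit <- suppressWarnings(psem(sp, d, test = FALSE, keep_models = FALSE))
    key <- paste(fit$edges$from, fit$edges$to, sep = "->")
    fit$edges$spc[match(names(truth), key)]
  })
  bias <- rowMeans(ests) - truth
  expect_lt(max(abs(bias)), 0.08)
  ## sign recovery for |SPC| >= 0.35
  signs <- sweep(sign(ests), 1, sign(truth), "==")
  expect_gt(mean(signs), 0.95)
})

test_that("multigroup frees only group-varying paths and falls back cleanly", {
  sp <- default_sem_spec()
  base <- c("het->richness" = 0.3, "emersion->richness" = -0.3,
            "richness->asynchrony" = 0.4,
            "asynchrony->temp_stability" = 0.4,
            "pop_stability->comp_stability" = 0.3,
            "comp_stability->temp_stability" = 0.3)
  d <- simulate_sem(sp, base, test_design(3),
                    group_coefs = list(low = c("het->richness" = 0.8),
                                       high = c("het->richness" = -0.2)),
                    seed = 5)
  fit <- suppressWarnings(psem(sp, d, group = "zone", test = FALSE,
                               keep_models = FALSE))
  e <- fit$edges
  expect_setequal(unique(e$group), c("low", "mid", "high"))
  freed <- unique(paste(e$from, e$to)[e$freed])
  expect_true("het richness" %in% freed)
  ## freed estimates differ by group; constrained ones are shared
  her <- e[e$from == "het" & e$to == "richness", ]
  expect_gt(max(her$estimate) - min(her$estimate), 0.3)
  con <- e[!e$freed & e$from == "richness" & e$to == "asynchrony", ]
  expect_equal(length(unique(con$estimate)), 1L)
  ## single group reduces to the global fit
  d1 <- d; d1$zone <- factor("low")
  expect_warning(f1 <- psem(sp, d1, group = "zone", test = FALSE,
                            keep_models = FALSE), "single group")
  expect_equal(unique(f1$edges$group), "global")
})

test_that("model simplification reports mixed-vs-fixed discrepancies", {
  sp <- psem_spec(c("x -> w", "w -> v"))
  d <- test_design(6)
  set.seed(20)
  d$x <- rnorm(70); d$w <- 0.5 * d$x + rnorm(70, 0, 0.8)
  d$v <- 0.5 * d$w + rnorm(70, 0, 0.8)
  out <- suppressWarnings(model_simplify(sp, d, threshold = 0.1))
  ## negligible transect structure here: no flags expected
  expect_true(all(abs(out$delta_spc) < 0.1))
  expect_false(any(out$flagged))
  ## contract: flag iff |delta| > threshold or sign flip
  out2 <- suppressWarnings(model_simplify(sp, d, threshold = 0))
  expect_equal(out2$flagged, abs(out2$delta_spc) > 0 | out2$sign_flip)
})

test_that("component-model failure names the offending node", {
  sp <- psem_spec("x -> w")
  d <- test_design(1)
  d$x <- rnorm(70)
  expect_error(psem(sp, d, test = FALSE), "w")
})
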