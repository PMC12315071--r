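test_that("simulation is deterministic and respects cover bounds", {
  d <- generate_design(2, 3, c(0.2, 0.8), seed = 5)
  p <- synth_params(seed = 42)
  a <- simulate_covers(d, p)
  b <- simulate_covers(d, p)
  expect_identical(a, b)
  expect_true(all(a$cover >= 0 & a$cover <= 100))
  expect_false(anyNA(a$cover))
  ## dense table: every tile x census x taxon combination present
  expect_equal(nrow(a), nrow(d) * p$n_censuses * nrow(p$taxa))
  expect_equal(sort(unique(a$census_index)), 0:(p$n_censuses - 1))
})

test_that("the null model is constant in time and identical across pairs", {
  d <- generate_design(2, 3, c(0.2, 0.8), seed = 5)
  p <- synth_params(
    path_coefficients = list(het_popstab = 0, het_richness = 0,
                             het_dominant = 0, het_consumer = 0,
                             consumer_ephemeral = 0,
                             hetxemersion_richness = 0),
    seasonal_amplitude = c(dominant_nonnative = 0, native_barnacle = 0,
                           consumer = 0, ephemeral_alga = 0, other = 0),
    noise_sd = 0, n_points = Inf, seed = 9)
  cv <- simulate_covers(d, p)
  ## constant over censuses for every tile x taxon
  spread <- tapply(cv$cover, list(cv$tile_id, cv$taxon_id),
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))
  ## heterogeneous and flat tile of each pair identical (no noise, no
  ## treatment paths, infinite point count)
  des <- merge(cv, as.data.frame(d)[, c("tile_id", "station_id",
                                        "heterogeneity")], by = "tile_id")
  wide <- reshape(des[des$census_index == 0,
                      c("station_id", "heterogeneity", "taxon_id", "cover")],
                  direction = "wide", idvar = c("station_id", "taxon_id"),
                  timevar = "heterogeneity")
  expect_equal(wide$cover.0, wide$cover.1, tolerance = 1e-12)
})

test_that("point-count sampling noise matches the binomial closed form", {
  d <- generate_design(5, 7, c(0.2, 0.8), seed = 5)
  p0 <- synth_params(
    path_coefficients = list(het_popstab = 0, het_richness = 0,
                             het_dominant = 0, het_consumer = 0,
                             consumer_ephemeral = 0),
    seasonal_amplitude = c(dominant_nonnative = 0, native_barnacle = 0,
                           consumer = 0, ephemeral_alga = 0, other = 0),
    noise_sd = 0, n_censuses = 50L, n_points = Inf, seed = 13)
  latent <- simulate_covers(d, p0)          # exact expected cover
  p1 <- p0; p1$n_points <- 500
  obs <- simulate_covers(d, p1)
  truth <- latent$cover[latent$census_index == 0]
  key0 <- paste(latent$tile_id, latent$taxon_id)[latent$census_index == 0]
  names(truth) <- key0
  ## per tile x taxon: sd over censuses of observed cover vs
  ## 100 * sqrt(p (1 - p) / n).  Pool taxa with expected cover near 10%.
  sds <- tapply(obs$cover, paste(obs$tile_id, obs$taxon_id), sd)
  sel <- names(truth)[truth > 5 & truth < 20]
  theo <- 100 * sqrt((truth[sel] / 100) * (1 - truth[sel] / 100) / 500)
  ratio <- mean(sds[sel]) / mean(theo)
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
  ## spot value from the closed form: expected 10% cover -> sd ~ 1.34
  expect_equal(100 * sqrt(0.1 * 0.9 / 500), 1.3416, tolerance = 1e-4)
})

test_that("a positive richness path raises richness on pitted tiles", {
  d <- generate_design(5, 7, c(0.1, 0.9), seed = 2)
  gap <- replicate(60, NA_real_)
  for (i in seq_along(gap)) {
    p <- synth_params(path_coefficients = list(het_richness = 0.5),
                      seed = 2000 + i)
    cv <- simulate_covers(d, p)
    s <- summarise_tiles(cv, default_group_map())
    m <- merge(s, as.data.frame(d), by = "tile_id")
    gap[i] <- mean(m$mean_richness[m$heterogeneity == 1]) -
      mean(m$mean_richness[m$heterogeneity == 0])
  }
  expect_gt(mean(gap), 0)
  expect_gt(mean(gap > 0), 0.9)
})

test_that("stronger dominant suppression widens the dominant cover gap", {
  d <- generate_design(5, 7, c(0.1, 0.9), seed = 2)
  levels_ <- c(0, -0.5, -1)
  gaps <- sapply(seq_along(levels_), function(k) {
    mean(vapply(1:25, function(r) {
      p <- synth_params(path_coefficients = list(het_dominant = levels_[k]),
                        seed = 3000 + k * 1000 + r)
      cv <- simulate_covers(d, p)
      s <- summarise_tiles(cv, default_group_map())
      m <- merge(s, as.data.frame(d), by = "tile_id")
      mean(m$cover_dominant_nonnative[m$heterogeneity == 1]) -
        mean(m$cover_dominant_nonnative[m$heterogeneity == 0])
    }, numeric(1)))
  })
  expect_true(all(diff(gaps) < 0))   # monotone decrease of the het - flat gap
})

test_that("ground truth passes through and composes indirect products", {
  p <- synth_params(path_coefficients = list(het_consumer = -0.3,
                                             consumer_ephemeral = -0.4))
  gt <- ground_truth(p)
  expect_equal(gt$het_consumer, -0.3)
  expect_equal(gt$het_ephemeral_indirect, 0.12)
  p0 <- synth_params(path_coefficients = list(
    het_popstab = 0, het_richness = 0, het_dominant = 0, het_consumer = 0,
    consumer_ephemeral = 0, hetxemersion_richness = 0))
  expect_true(all(unlist(ground_truth(p0)) == 0))
})

test_that("invalid parameters are rejected with clear messages", {
  expect_error(synth_params(ar1_rho = 1), "rho")
  expect_error(synth_params(n_points = 0), "n_points")
  expect_error(synth_params(path_coefficients = list(het_dominant = NaN)),
               "finite")
  expect_error(synth_params(path_coefficients = list(bogus = 1)), "unknown")
  bad_taxa <- data.frame(taxon_id = "x", group = "carnivorous_plant")
  expect_error(synth_params(taxa = bad_taxa), "group")
  d <- generate_design(1, 1, c(0.5, 0.5))
  expect_error(simulate_covers(d[0, ], synth_params()), "empty")
})

test_that("the null generator produces no spurious treatment effects", {
  ## zero treatment paths: a paired comparison of consumer-group cover
  ## between heterogeneity levels should reject at the nominal rate
  d <- generate_design(5, 7, c(0.1, 0.9), seed = 31)
  cons <- default_taxa()$taxon_id[default_taxa()$group == "consumer"]
  null_paths <- list(het_popstab = 0, het_richness = 0, het_dominant = 0,
                     het_consumer = 0, consumer_ephemeral = 0,
                     hetxemersion_richness = 0)
  p_vals <- vapply(1:300, function(i) {
    p <- synth_params(path_coefficients = null_paths, seed = 40000 + i)
    cv <- simulate_covers(d, p)
    cm <- cv[cv$taxon_id %in% cons, ]
    tile_mean <- tapply(cm$cover, cm$tile_id, mean)
    het <- d$heterogeneity[match(names(tile_mean), d$tile_id)]
    st <- d$station_id[match(names(tile_mean), d$tile_id)]
    diffs <- tile_mean[het == 1][order(st[het == 1])] -
      tile_mean[het == 0][order(st[het == 0])]
    stats::t.test(diffs)$p.value
  }, numeric(1))
  rej <- mean(p_vals < 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.08)
})
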