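## Simulation studies that characterise the pipeline's statistical
## behaviour: decomposition identities, d-separation calibration,
## coefficient recovery, multigroup specificity and the
## counteracting-pathways scenario.  Used by the test suite and by
## scripts that report the package's operating characteristics.

#' Stability-identity stress study
#'
#' Generates random census-by-taxon cover matrices and verifies the
#' decomposition identity `TS = PS * phi^(-1/2)`, the metric bounds and
#' the taxon-order/scale invariances.
#'
#' @param n_matrices Number of random matrices.
#' @param seed Integer seed.
#' @return A list: `max_identity_error`, `bounds_ok` (logical),
#'   `max_invariance_error`, `n` (matrices checked).
#' @export
stability_identity_study <- function(n_matrices = 1000L, seed = 1L) {
  with_seed(seed, {
    max_id <- 0; max_inv <- 0; bounds_ok <- TRUE
    for (i in seq_len(n_matrices)) {
      s <- sample(5:20, 1)
      m <- matrix(stats::runif(s * 11, 0, 50), 11, s)
      m[sample(length(m), floor(length(m) / 8))] <- 0
      pr <- stability_profile(m)
      if (!pr$degenerate) {
        max_id <- max(max_id, abs(pr$TS - pr$PS / sqrt(pr$phi)))
        bounds_ok <- bounds_ok && pr$phi >= 0 && pr$phi <= 1 &&
          pr$SA >= 1 && pr$SA <= sqrt(s) + 1e-12 &&
          pr$CS >= 0 && pr$CS <= 1
      }
      if (i %% 20L == 0L) {
        alt1 <- stability_profile(m[, sample(s)])
        alt2 <- stability_profile(m * stats::runif(1, 0.5, 3))
        for (col in c("TS", "CS", "PS", "phi", "SA")) {
          max_inv <- max(max_inv, abs(alt1[[col]] - pr[[col]]),
                         abs(alt2[[col]] - pr[[col]]), na.rm = TRUE)
        }
      }
    }
    list(max_identity_error = max_id, bounds_ok = bounds_ok,
         max_invariance_error = max_inv, n = n_matrices)
  })
}

#' Fisher's C calibration under the true model
#'
#' Simulates tile-level data from a causal specification with known
#' coefficients, fits every d-separation claim model (nested mixed
#' models, Satterthwaite p values) and records the Fisher's C global
#' rejection rate at `alpha` plus one claim p value per
#' replicate (rotating through the basis set, so the retained p values
#' are independent across replicates).
#'
#' @param n_rep Number of simulated datasets.
#' @param spec Causal specification (default [default_sem_spec()]).
#' @param coefs Generating coefficients (default [default_sem_coefs()]).
#' @param alpha Rejection level for Fisher's C.
#' @param seed Integer seed.
#' @return A list: `rejection_rate`, `claim_p` (vector, one per
#'   replicate), `ks_p` (uniformity test of `claim_p`), `n`.
#' @export
fisherc_calibration <- function(n_rep = 160L, spec = default_sem_spec(),
                                coefs = default_sem_coefs(),
                                alpha = 0.05, seed = 1L) {
  design <- generate_design(5, 7, c(0.1, 0.9), seed = child_seed(seed, 0L))
  n_claims <- length(basis_set(spec))
  rej <- logical(n_rep); claim_p <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    d <- simulate_sem(spec, coefs, design, seed = child_seed(seed, i))
    claims <- suppressWarnings(dsep_tests(spec, d, nesting = TRUE))
    keep <- claims[!claims$excluded, ]
    rej[i] <- fishers_c(keep$p)$p < alpha
    claim_p[i] <- keep$p[(i - 1L) %% nrow(keep) + 1L]
  }
  list(rejection_rate = mean(rej),
       claim_p = claim_p,
       ks_p = stats::ks.test(claim_p, "punif")$p.value,
       n = n_rep, n_claims = n_claims)
}

#' Standardised-coefficient recovery study
#'
#' Simulates from the causal model and refits, recording sign recovery
#' and root-mean-square error of the standardised path coefficients for
#' edges whose generating magnitude is at least `min_mag`.
#'
#' @inheritParams fisherc_calibration
#' @param min_mag Magnitude threshold defining the evaluated edges.
#' @return A list: `sign_recovery`, `rmse`, `n`, `n_edges`.
#' @export
spc_recovery <- function(n_rep = 150L, spec = default_sem_spec(),
                         coefs = default_sem_coefs(), min_mag = 0.3,
                         seed = 1L) {
  design <- generate_design(5, 7, c(0.1, 0.9), seed = child_seed(seed, 0L))
  keys <- names(coefs)[abs(coefs) >= min_mag]
  truth <- coefs[keys]
  err <- matrix(NA_real_, n_rep, length(keys))
  signs <- matrix(NA, n_rep, length(keys))
  for (i in seq_len(n_rep)) {
    d <- simulate_sem(spec, coefs, design, seed = child_seed(seed, i))
    fit <- suppressWarnings(psem(spec, d, group = NULL, test = FALSE,
                                 keep_models = FALSE))
    key <- paste(fit$edges$from, fit$edges$to, sep = "->")
    est <- fit$edges$spc[match(keys, key)]
    err[i, ] <- est - truth
    signs[i, ] <- sign(est) == sign(truth)
  }
  list(sign_recovery = mean(signs), rmse = sqrt(mean(err^2)),
       n = n_rep, n_edges = length(keys))
}

#' Multigroup detection and specificity study
#'
#' Simulates data in which only the heterogeneity-to-richness path
#' varies across shore zones (absent in the high zone, increasingly
#' positive in mid and low), fits the multigroup pSEM, and records how
#' often that path is freed, how often each homogeneous path is
#' falsely freed, and how often the varying path is the only freed one.
#'
#' @inheritParams fisherc_calibration
#' @param contrast Named numeric: zone-specific values of the
#'   heterogeneity-to-richness coefficient.
#' @param vary Set `FALSE` to keep all paths homogeneous (null run for
#'   the false-free rate alone).
#' @return A list: `detection_rate`, `false_free_rate`,
#'   `only_freed_rate`, `n`.
#' @export
multigroup_specificity <- function(n_rep = 120L,
                                   spec = default_sem_spec(),
                                   coefs = default_sem_coefs(),
                                   contrast = c(low = 0.7, mid = 0.35,
                                                high = 0),
                                   vary = TRUE, seed = 1L) {
  design <- generate_design(5, 7, c(0.1, 0.9), seed = child_seed(seed, 0L))
  gc <- if (vary) lapply(contrast, function(v) c("het->richness" = v))
        else NULL
  target <- "het richness"
  detect <- only <- logical(n_rep)
  false_free <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    d <- simulate_sem(spec, coefs, design, group_coefs = gc,
                      seed = child_seed(seed, i))
    fit <- suppressWarnings(psem(spec, d, group = "zone", test = FALSE,
                                 keep_models = FALSE))
    e <- fit$edges[!duplicated(paste(fit$edges$from, fit$edges$to)), ]
    freed <- paste(e$from, e$to)[e$freed]
    detect[i] <- target %in% freed
    false_free[i] <- length(setdiff(freed, target)) /
      max(nrow(e) - 1L, 1L)
    only[i] <- identical(freed, target)
  }
  list(detection_rate = mean(detect),
       false_free_rate = mean(false_free),
       only_freed_rate = mean(only), n = n_rep)
}

#' Counteracting-pathways scenario study
#'
#' Runs the full pipeline (community generator with the default
#' counteracting scenario, survey metrics, stability decomposition,
#' global pSEM, cascade census and station-bootstrap net-effect
#' interval) for several seeds and summarises the headline outcome:
#' the number of significant heterogeneity-origin causal chains to
#' temporal stability, and whether the bootstrap interval for the net
#' effect covers zero.
#'
#' @param seeds Integer vector of master seeds.
#' @param n_boot Bootstrap replicates per seed.
#' @param alpha Per-edge significance level.
#' @return A `data.frame`, one row per seed: `seed`, `n_chains`,
#'   `n_significant`, `net`, `lo95`, `hi95`, `covers_zero`.
#' @export
counteracting_study <- function(seeds = 1:3, n_boot = 100L, alpha = 0.05) {
  rows <- lapply(seeds, function(sd) {
    design <- generate_design(5, 7, c(0.1, 0.9),
                              seed = child_seed(sd, 1L))
    covers <- simulate_covers(design,
                              synth_params(seed = child_seed(sd, 2L)))
    summaries <- summarise_tiles(covers, default_group_map())
    stab <- suppressMessages(stability_profiles(covers))
    tiles <- tile_table(design, summaries, stab)
    spec <- default_sem_spec()
    fit <- suppressWarnings(psem(spec, tiles, group = NULL, test = FALSE,
                                 keep_models = FALSE, alpha = alpha))
    ce <- cascade_effect(fit, "het", "temp_stability", alpha = alpha)
    bc <- suppressWarnings(bootstrap_cascades(
      spec, tiles, "het", "temp_stability", n_boot = n_boot,
      seed = child_seed(sd, 3L), group = NULL, alpha = alpha))
    data.frame(seed = sd, n_chains = ce$n_chains,
               n_significant = ce$n_contributing, net = ce$net,
               lo95 = bc$lo95, hi95 = bc$hi95,
               covers_zero = bc$lo95 <= 0 && bc$hi95 >= 0)
  })
  do.call(rbind, rows)
}
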