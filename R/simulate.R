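## Synthetic multitrophic community generator.
##
## Latent Gaussian states per tile x taxon x census are mapped through a
## logistic link to expected percent cover, then observed by binomial
## point-count subsampling.  Configurable ground-truth pathways mirror
## the mechanisms a substrate-heterogeneity experiment probes:
## refugia (variance damping), richness gains of marginal taxa,
## suppression of a dominant space-holder, and suppression of mobile
## consumers which otherwise control ephemeral algae.

GROUP_LEVELS <- c("dominant_nonnative", "native_barnacle", "consumer",
                  "ephemeral_alga", "other")

#' Default taxon list
#'
#' Twenty taxa in five functional groups: one dominant non-native
#' barnacle, four native barnacles, two macroinvertebrate consumers,
#' three ephemeral macroalgae and ten other (mostly marginal) taxa.
#'
#' @return A `data.frame` with columns `taxon_id`, `group`.
#' @export
default_taxa <- function() {
  data.frame(
    taxon_id = c("dom_barnacle",
                 paste0("nat_barnacle_", 1:4),
                 paste0("consumer_", 1:2),
                 paste0("ephemeral_", 1:3),
                 paste0("other_", sprintf("%02d", 1:10))),
    group = rep(GROUP_LEVELS, times = c(1L, 4L, 2L, 3L, 10L)),
    stringsAsFactors = FALSE)
}

#' Ground-truth simulation parameters
#'
#' Bundles and validates the configuration of [simulate_covers()].  The
#' default `path_coefficients` encode the counteracting-pathways
#' scenario: positive refugia (`het_popstab`) and richness
#' (`het_richness`) effects of heterogeneity balanced against negative
#' effects on the dominant barnacle (`het_dominant`) and on consumers
#' (`het_consumer`), with consumers suppressing ephemeral algae
#' (`consumer_ephemeral`).  Coefficients are signed targets on the
#' standardised (per-SD) scale of the tile-level summaries.
#'
#' @param taxa Taxon table (`taxon_id`, `group`); see [default_taxa()].
#' @param n_censuses Number of seasonal censuses (default 11).
#' @param path_coefficients Named list of signed standardised effects.
#'   Recognised names: `het_popstab`, `het_richness`, `het_dominant`,
#'   `het_consumer`, `consumer_ephemeral`, `hetxemersion_richness`.
#' @param seasonal_amplitude Named per-group seasonal forcing (latent
#'   SD units).
#' @param ar1_rho Temporal autocorrelation of latent noise, |rho| < 1.
#' @param noise_sd Latent noise scale; tile/station/transect random
#'   effects scale with it.
#' @param n_points Point-count sample size per census image (default
#'   500; `Inf` returns expected cover exactly).
#' @param presence_threshold Latent suitability below which a taxon is
#'   absent from a tile (emergent richness).
#' @param seed Integer seed; one RNG stream drives all draws.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(taxa = default_taxa(),
                         n_censuses = 11L,
                         path_coefficients = list(),
                         seasonal_amplitude = c(dominant_nonnative = 0.7,
                                                native_barnacle = 0.5,
                                                consumer = 0.25,
                                                ephemeral_alga = 0.9,
                                                other = 1.1),
                         ar1_rho = 0.4,
                         noise_sd = 0.6,
                         n_points = 500,
                         presence_threshold = -2.6,
                         seed = 1L) {
  assert_cols(taxa, c("taxon_id", "group"), "taxa table")
  if (anyDuplicated(taxa$taxon_id))
    stop_("duplicated taxon_id in taxa table")
  bad <- setdiff(unique(taxa$group), GROUP_LEVELS)
  if (length(bad))
    stop_("unknown functional group(s): %s", paste(bad, collapse = ", "))
  if (abs(ar1_rho) >= 1) stop_("ar1_rho must satisfy |rho| < 1")
  if (!is.infinite(n_points) && n_points < 1) stop_("n_points must be >= 1")
  if (n_censuses < 1L) stop_("n_censuses must be >= 1")

  paths <- default_paths()
  unknown <- setdiff(names(path_coefficients), names(paths))
  if (length(unknown))
    stop_("unknown path coefficient(s): %s", paste(unknown, collapse = ", "))
  paths[names(path_coefficients)] <- path_coefficients
  if (any(!vapply(paths, is.finite, logical(1))))
    stop_("path coefficients must all be finite")

  amp <- seasonal_amplitude
  if (is.null(names(amp)) || !all(GROUP_LEVELS %in% names(amp)))
    stop_("seasonal_amplitude must be named for all five groups")

  structure(list(taxa = taxa, n_censuses = as.integer(n_censuses),
                 path_coefficients = paths,
                 seasonal_amplitude = amp, ar1_rho = ar1_rho,
                 noise_sd = noise_sd, n_points = n_points,
                 presence_threshold = presence_threshold,
                 seed = as.integer(seed)),
            class = "synth_params")
}

## Counteracting-pathways defaults: the stabilising refugia and
## richness routes are balanced by suppression of the stabilising
## dominant and consumers.
default_paths <- function() {
  list(het_popstab = 0.30,
       het_richness = 0.3,
       het_dominant = -0.7,
       het_consumer = -0.4,
       consumer_ephemeral = -0.45,
       hetxemersion_richness = 0)
}

## Fixed group-level ecology: logistic baseline in emersion, maximum
## attainable cover, group noise multipliers, persistence offsets on
## the AR(1) autocorrelation (barnacles persistent, ephemeral algae
## fast-turnover) and seasonal phases (ephemeral algae peak opposite
## barnacle recruitment).
group_profiles <- function() {
  data.frame(
    group = GROUP_LEVELS,
    intercept = c(1.2, -0.6, -0.8, -0.5, -2.3),
    em_slope = c(2.0, 1.5, -2.0, -2.5, -1.0),
    lmax = c(90, 40, 25, 60, 45),
    noise_mult = c(0.5, 0.8, 0.7, 1.4, 1.1),
    rho_offset = c(0.3, 0.3, 0.2, -0.3, 0.1),
    phase = c(0, 0, pi / 2, pi, NA),   # NA: per-taxon phase (drawn)
    stringsAsFactors = FALSE)
}

#' Simulate community cover time series
#'
#' Generates a long-format cover table from a tile design and a
#' [synth_params()] configuration.  Each taxon's latent state combines
#' a logistic-in-emersion group baseline, treatment effects per the
#' ground-truth path coefficients, a group-phased seasonal sinusoid and
#' stationary AR(1) noise; heterogeneity damps latent noise (refugia),
#' consumers suppress ephemeral-algal expected cover multiplicatively,
#' and taxa whose tile-level suitability falls below the presence
#' threshold record zero cover (emergent richness).  Expected cover is
#' observed by binomial point-count subsampling with `n_points` trials.
#'
#' @param design A `tile_design` from [generate_design()].
#' @param params A [synth_params()] object.
#' @return A `data.frame` of class `cover_table` with columns `tile_id`,
#'   `census_index` (0-based), `census_date` (integer day offset),
#'   `taxon_id`, `cover` (percent); dense in tile x census x taxon.
#' @export
simulate_covers <- function(design, params) {
  if (!inherits(params, "synth_params"))
    stop_("params must come from synth_params()")
  assert_cols(design, c("tile_id", "station_id", "transect_id",
                        "heterogeneity", "emersion_ratio"), "design")
  if (nrow(design) == 0L) stop_("design is empty")

  with_seed(params$seed, {
    taxa <- params$taxa
    prof <- group_profiles()
    gi <- match(taxa$group, prof$group)
    n_tiles <- nrow(design)
    n_taxa <- nrow(taxa)
    n_cens <- params$n_censuses
    paths <- params$path_coefficients

    ## per-taxon intercept offsets stagger suitability within a group so
    ## that richness can respond to treatment shifts
    offset <- numeric(n_taxa)
    for (g in unique(taxa$group)) {
      ix <- which(taxa$group == g)
      spread <- if (g == "other") 1.5 else 1   # 'other' taxa are marginal
      offset[ix] <- if (length(ix) == 1L) 0 else
        seq(-spread, spread, length.out = length(ix))
    }

    ## per-taxon seasonal phase: group phase with jitter; 'other' taxa
    ## get staggered phenologies evenly spaced around the year, so each
    ## additional coloniser actively compensates community fluctuations
    phase <- prof$phase[gi]
    jitter <- stats::runif(n_taxa, -pi / 3, pi / 3)
    oth <- which(is.na(phase))
    if (length(oth)) {
      phase[oth] <- 2 * pi * (seq_along(oth) - 1L) / length(oth)
      jitter[oth] <- jitter[oth] / 2
    }
    phase <- phase + jitter

    ## nested random effects, scaled to the latent noise level
    sd0 <- params$noise_sd
    tr_lev <- unique(design$transect_id)
    st_lev <- unique(design$station_id)
    w_tr <- stats::setNames(stats::rnorm(length(tr_lev), 0, 0.5 * sd0), tr_lev)
    v_st <- stats::setNames(stats::rnorm(length(st_lev), 0, 0.5 * sd0), st_lev)
    u_tile <- matrix(stats::rnorm(n_tiles * n_taxa, 0, 0.8 * sd0),
                     n_tiles, n_taxa)

    em <- design$emersion_ratio
    em_z <- if (stats::sd(em) > 0) (em - mean(em)) / stats::sd(em) else em * 0
    het <- design$heterogeneity

    ## tile x taxon latent suitability (mean level)
    m <- matrix(0, n_tiles, n_taxa)
    for (i in seq_len(n_taxa)) {
      g <- taxa$group[i]
      p <- prof[gi[i], ]
      eff <- switch(g,
        dominant_nonnative = 2.4 * paths$het_dominant * het,
        consumer = 2.0 * paths$het_consumer * het,
        other = 1.6 * paths$het_richness * het +
          1.6 * paths$hetxemersion_richness * het * em_z,
        0)
      m[, i] <- p$intercept + p$em_slope * (em - 0.5) + offset[i] + eff +
        w_tr[design$transect_id] + v_st[design$station_id] + u_tile[, i]
    }
    present <- m > params$presence_threshold

    ## tile-level consumer pressure (deterministic expected share of
    ## the consumer guild): drives both the suppression of ephemeral
    ## mean cover and the consumer filtering of ephemeral fluctuations
    cons <- which(taxa$group == "consumer")
    eph <- which(taxa$group == "ephemeral_alga")
    pressure <- if (length(cons)) {
      rowMeans(matrix(stats::plogis(m[, cons]) * present[, cons],
                      n_tiles, length(cons)))
    } else {
      numeric(n_tiles)
    }

    ## stationary AR(1) noise per tile x taxon; heterogeneity damps the
    ## fluctuation scale on pitted tiles (refugia pathway).  Group
    ## persistence offsets differentiate slow space-holders (barnacles)
    ## from fast-turnover ephemeral algae.
    refugia <- exp(-0.5 * paths$het_popstab * het)    # length n_tiles
    rho <- pmin(pmax(params$ar1_rho + prof$rho_offset[gi], -0.95), 0.95)
    rho_m <- matrix(rho, n_tiles, n_taxa, byrow = TRUE)
    z <- array(0, dim = c(n_tiles, n_taxa, n_cens))
    sig <- outer(sd0 * refugia, prof$noise_mult[gi])  # tiles x taxa
    ## consumer filtering: grazing clips ephemeral bloom-crash cycles,
    ## slowing their apparent dynamics (higher persistence -> less
    ## census-to-census compositional turnover) on consumer-rich tiles
    ## without changing their marginal fluctuation scale
    if (length(eph)) {
      rho_m[, eph] <- pmin(rho_m[, eph] +
                             (0.9 - rho_m[, eph]) *
                               (1 - exp(6 * paths$consumer_ephemeral *
                                          pressure)), 0.95)
    }
    e_prev <- matrix(stats::rnorm(n_tiles * n_taxa), n_tiles, n_taxa) * sig
    tau <- (seq_len(n_cens) - 1L) * 0.25              # quarterly censuses
    season_amp <- unname(params$seasonal_amplitude[taxa$group])
    for (t in seq_len(n_cens)) {
      if (t > 1L) {
        eta <- matrix(stats::rnorm(n_tiles * n_taxa), n_tiles, n_taxa) * sig
        e_prev <- rho_m * e_prev + sqrt(1 - rho_m^2) * eta
      }
      seas <- matrix(season_amp * sin(2 * pi * tau[t] + phase),
                     n_tiles, n_taxa, byrow = TRUE)
      ## refugia also damp seasonal forcing of stress-driven
      ## fluctuation, and consumer filtering clips seasonal ephemeral
      ## blooms
      seas <- seas * refugia
      z[, , t] <- m + seas + e_prev
    }

    ## expected percent cover through the logistic link
    lmax <- prof$lmax[gi]
    expected <- array(0, dim = dim(z))
    for (t in seq_len(n_cens))
      expected[, , t] <- matrix(lmax, n_tiles, n_taxa, byrow = TRUE) *
        stats::plogis(z[, , t])

    ## absent taxa record zero cover throughout
    for (t in seq_len(n_cens)) expected[, , t][!present] <- 0

    ## consumers suppress ephemeral-algal expected cover
    ## multiplicatively, in proportion to consumer pressure on the tile
    if (length(cons) && length(eph)) {
      mult <- exp(3.5 * paths$consumer_ephemeral * pressure)
      for (t in seq_len(n_cens))
        expected[, eph, t] <- expected[, eph, t] * mult
    }

    ## binomial point-count observation
    np <- params$n_points
    pr <- pmin(pmax(expected / 100, 0), 1)
    if (is.infinite(np)) {
      obs <- pr * 100
    } else {
      obs <- array(stats::rbinom(length(pr), size = np, prob = pr) / np * 100,
                   dim = dim(pr))
    }

    out <- data.frame(
      tile_id = rep(design$tile_id, times = n_taxa * n_cens),
      census_index = rep(0:(n_cens - 1L), each = n_tiles * n_taxa),
      census_date = rep(as.integer(round(tau * 365)),
                        each = n_tiles * n_taxa),
      taxon_id = rep(rep(taxa$taxon_id, each = n_tiles), times = n_cens),
      cover = as.vector(obs),
      stringsAsFactors = FALSE)
    class(out) <- c("cover_table", "data.frame")
    out
  })
}

#' Ground-truth standardised paths implied by generator parameters
#'
#' Returns the configured direct path coefficients, plus the indirect
#' effects implied by chaining them through the generator's causal
#' graph (currently the heterogeneity -> consumer -> ephemeral chain).
#'
#' @param params A [synth_params()] object.
#' @return Named list of signed standardised effects.
#' @export
ground_truth <- function(params) {
  if (!inherits(params, "synth_params"))
    stop_("params must come from synth_params()")
  p <- params$path_coefficients
  c(p, list(het_ephemeral_indirect = p$het_consumer * p$consumer_ephemeral))
}
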