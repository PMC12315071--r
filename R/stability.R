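## Per-tile stability decomposition.
##
## All five metrics are computed from one set of per-taxon linearly
## detrended residuals so that the decomposition identity
## TS = PS * phi^(-1/2) holds exactly: linear detrending is additive in
## the taxa, hence the residual of the total series equals the sum of
## the per-taxon residuals at every census.

#' Linearly detrend a cover time series
#'
#' Fits an ordinary least-squares line on the (0-based) census index and
#' returns the residuals together with the fitted intercept and slope.
#' Detrending isolates temporal fluctuations from a weak directional
#' trend before variability-based stability metrics are computed.
#'
#' @param series Numeric vector of per-census values (at least 3).
#' @return A list with components `residuals`, `intercept`, `slope`.
#' @examples
#' detrend(c(4, 6, 5))
#' @export
detrend <- function(series) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 3L)
    stop_("detrend() needs at least 3 censuses, got %d", n)
  if (anyNA(series)) stop_("detrend() requires complete series")
  t_idx <- seq_len(n) - 1
  tc <- t_idx - mean(t_idx)
  slope <- sum(tc * series) / sum(tc^2)
  intercept <- mean(series) - slope * mean(t_idx)
  list(residuals = series - (intercept + slope * t_idx),
       intercept = intercept, slope = slope)
}

## residual sd with n-1 denominator; series already detrended
resid_sd <- function(r) stats::sd(r)

#' Temporal stability (inverse coefficient of variation)
#'
#' `TS = mu / sigma` where `mu` is the raw temporal mean of the series
#' and `sigma` the sample standard deviation (n-1) of its linearly
#' detrended residuals.  Zero residual variance is reported as `NA`
#' (degenerate), never as `Inf`.
#'
#' @param series Numeric vector of per-census total covers (>= 3).
#' @return A single number, or `NA_real_` for degenerate series.
#' @export
temporal_stability <- function(series) {
  mu <- mean(series)
  if (mu <= 0) stop_("temporal_stability() requires a positive mean")
  s <- resid_sd(detrend(series)$residuals)
  if (s == 0) return(NA_real_)
  mu / s
}

## Shared residual machinery: `mat` is censuses x taxa.
detrend_matrix <- function(mat) {
  apply(mat, 2L, function(x) detrend(x)$residuals)
}

#' Population stability
#'
#' Aggregate species-level stability `PS = sum(mu_i) / sum(sigma_i)`
#' over the taxa on a tile, with `sigma_i` taken from per-taxon linearly
#' detrended residuals.
#'
#' @param mat Numeric matrix, censuses in rows, taxa in columns.
#' @return A single number, or `NA_real_` when all taxa are constant.
#' @export
population_stability <- function(mat) {
  mat <- as.matrix(mat)
  mu <- colMeans(mat)
  sig <- apply(detrend_matrix(mat), 2L, resid_sd)
  if (sum(sig) == 0) return(NA_real_)
  sum(mu) / sum(sig)
}

#' Community synchrony and asynchrony
#'
#' The Loreau-de Mazancourt variance-ratio synchrony
#' `phi = sigma_T^2 / (sum_i sigma_i)^2` computed on detrended
#' residuals, bounded in \[0, 1\]; asynchrony is `1 - phi`.
#'
#' @inheritParams population_stability
#' @return A list with `phi` and `asynchrony` (both `NA` if degenerate).
#' @export
synchrony_phi <- function(mat) {
  mat <- as.matrix(mat)
  res <- detrend_matrix(mat)
  sig <- apply(res, 2L, resid_sd)
  denom <- sum(sig)^2
  if (denom == 0) return(list(phi = NA_real_, asynchrony = NA_real_))
  phi <- stats::var(rowSums(res)) / denom
  phi <- min(max(phi, 0), 1)   # guard numerical spill at the bounds
  list(phi = phi, asynchrony = 1 - phi)
}

#' Statistical averaging (portfolio effect)
#'
#' `SA = sum_i sigma_i / sqrt(sum_i sigma_i^2)`, the variance-evenness
#' form: 1 for a single fluctuating taxon, `sqrt(S)` for S taxa with
#' equal temporal variability.
#'
#' @inheritParams population_stability
#' @return A single number in `[1, sqrt(S)]`, or `NA` if degenerate.
#' @export
statistical_averaging <- function(mat) {
  mat <- as.matrix(mat)
  sig <- apply(detrend_matrix(mat), 2L, resid_sd)
  if (all(sig == 0)) return(NA_real_)
  sum(sig) / sqrt(sum(sig^2))
}

## Bray-Curtis dissimilarity between consecutive censuses (raw covers).
consecutive_bray <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 2L) stop_("compositional stability needs >= 2 censuses")
  tot <- rowSums(mat)
  keep <- which(tot[-n] + tot[-1] > 0)   # skip pairs with both censuses empty
  if (!length(keep)) return(NA_real_)
  ## empty censuses trigger a vegdist warning; the affected pairs are
  ## handled explicitly below (both-empty skipped, NaN never propagated)
  d <- suppressWarnings(vegan::vegdist(mat, method = "bray", na.rm = FALSE))
  dm <- as.matrix(d)
  steps <- dm[cbind(keep, keep + 1L)]
  steps
}

#' Compositional stability
#'
#' One minus the mean Bray-Curtis dissimilarity between consecutive
#' censuses, computed on raw covers: 1 means composition never moves,
#' 0 means complete turnover at every step.  Census pairs in which both
#' censuses are empty are skipped.
#'
#' @inheritParams population_stability
#' @return A single number in `[0, 1]`, or `NA` if all censuses are empty.
#' @export
compositional_stability <- function(mat) {
  steps <- consecutive_bray(mat)
  if (all(is.na(steps))) return(NA_real_)
  1 - mean(steps)
}

#' Five-metric stability profile of one tile
#'
#' Computes temporal stability (TS), compositional stability (CS),
#' population stability (PS), synchrony `phi` (and asynchrony `1 - phi`)
#' and statistical averaging (SA) from a censuses-by-taxa cover matrix,
#' sharing a single linear detrending so that the decomposition
#' `TS = PS * phi^(-1/2)` holds exactly.
#'
#' @inheritParams population_stability
#' @param tile_id Optional identifier stored in the result.
#' @param detrending `"per_taxon"` (default) detrends every taxon and
#'   lets the total inherit the summed residuals, which preserves the
#'   decomposition identity `TS = PS * phi^(-1/2)` exactly;
#'   `"total_only"` detrends only the total series (per-taxon
#'   variability is then computed around each taxon's mean), in which
#'   case the identity is approximate.
#' @return A one-row `data.frame` with columns `tile_id`, `TS`, `CS`,
#'   `PS`, `phi`, `asynchrony`, `SA` and `degenerate` (logical: any
#'   metric undefined because of zero variance).
#' @examples
#' m <- matrix(c(10, 12, 9, 11, 5, 4, 6, 5), ncol = 2)
#' stability_profile(m)
#' @export
stability_profile <- function(mat, tile_id = NA_character_,
                              detrending = c("per_taxon", "total_only")) {
  detrending <- match.arg(detrending)
  mat <- as.matrix(mat)
  if (nrow(mat) < 3L)
    stop_("stability_profile() needs >= 3 censuses, got %d", nrow(mat))
  res <- if (detrending == "per_taxon") detrend_matrix(mat)
         else scale(mat, center = TRUE, scale = FALSE)
  mu_i <- colMeans(mat)
  sig_i <- apply(res, 2L, resid_sd)
  tot_res <- if (detrending == "per_taxon") rowSums(res)
             else detrend(rowSums(mat))$residuals
  sig_T <- resid_sd(tot_res)
  mu_T <- sum(mu_i)

  TS <- if (sig_T == 0 || mu_T <= 0) NA_real_ else mu_T / sig_T
  PS <- if (sum(sig_i) == 0) NA_real_ else sum(mu_i) / sum(sig_i)
  if (sum(sig_i) == 0) {
    phi <- NA_real_
  } else {
    phi <- min(max(sig_T^2 / sum(sig_i)^2, 0), 1)
  }
  SA <- if (all(sig_i == 0)) NA_real_ else sum(sig_i) / sqrt(sum(sig_i^2))
  CS <- compositional_stability(mat)

  data.frame(tile_id = tile_id, TS = TS, CS = CS, PS = PS,
             phi = phi, asynchrony = if (is.na(phi)) NA_real_ else 1 - phi,
             SA = SA,
             degenerate = anyNA(c(TS, CS, PS, phi, SA)),
             stringsAsFactors = FALSE)
}

#' Stability profiles for every tile in a cover table
#'
#' @param cover Long-format cover table with columns `tile_id`,
#'   `census_index`, `taxon_id`, `cover` (see [simulate_covers()]).
#' @param detrending Passed to [stability_profile()].
#' @return A `data.frame` with one row per tile (see
#'   [stability_profile()]); degenerate tiles are kept, flagged and
#'   reported via a message.
#' @export
stability_profiles <- function(cover,
                               detrending = c("per_taxon", "total_only")) {
  detrending <- match.arg(detrending)
  assert_cols(cover, c("tile_id", "census_index", "taxon_id", "cover"),
              "cover table")
  out <- lapply(split(cover, cover$tile_id), function(d) {
    m <- cover_matrix(d)
    stability_profile(m, tile_id = d$tile_id[1], detrending = detrending)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  n_bad <- sum(out$degenerate)
  if (n_bad > 0)
    message(sprintf("stability_profiles: %d degenerate tile(s) flagged", n_bad))
  out
}

## long cover table (one tile) -> censuses x taxa matrix
cover_matrix <- function(d) {
  taxa <- sort(unique(d$taxon_id))
  cens <- sort(unique(d$census_index))
  m <- matrix(0, nrow = length(cens), ncol = length(taxa),
              dimnames = list(cens, taxa))
  m[cbind(match(d$census_index, cens), match(d$taxon_id, taxa))] <- d$cover
  m
}
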