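## Experimental tile designs: paired heterogeneous/flat tiles at
## stations along transects spanning an emersion-stress gradient.

#' Generate a paired-tile experimental design
#'
#' Lays out `n_transects` transects of `stations_per_transect` stations
#' each; every station holds exactly two tiles, one heterogeneous
#' (pitted) and one flat, sharing the station's emersion ratio.
#' Emersion ratios are evenly spread across `emersion_range` within each
#' transect (transect endpoints pinned to the range, interior stations
#' jittered), and stations are classified into `low`/`mid`/`high` shore
#' zones as emersion-ratio terciles with equal group sizes (+/- 1).
#'
#' @param n_transects Number of transects (>= 1).
#' @param stations_per_transect Stations per transect (>= 1).
#' @param emersion_range Length-2 numeric within (0, 1), min <= max.
#' @param seed Integer seed for the station jitter.
#' @return A `data.frame` of class `tile_design` with columns `tile_id`,
#'   `station_id`, `transect_id`, `heterogeneity` (0 flat / 1 pitted),
#'   `emersion_ratio`, `zone` (factor low/mid/high).
#' @examples
#' d <- generate_design(5, 7, c(0.1, 0.9), seed = 1)
#' nrow(d)   # 70 tiles
#' @export
generate_design <- function(n_transects = 5L, stations_per_transect = 7L,
                            emersion_range = c(0.1, 0.9), seed = 1L) {
  if (n_transects < 1L || stations_per_transect < 1L)
    stop_("n_transects and stations_per_transect must both be >= 1")
  if (!is.numeric(emersion_range) || length(emersion_range) != 2L ||
      any(!is.finite(emersion_range)))
    stop_("emersion_range must be two finite numbers")
  lo <- emersion_range[1]; hi <- emersion_range[2]
  if (lo <= 0 || hi >= 1)
    stop_("emersion_range must lie strictly within (0, 1), got [%g, %g]",
          lo, hi)
  if (lo > hi)
    stop_("emersion_range is empty: min (%g) exceeds max (%g)", lo, hi)

  S <- as.integer(stations_per_transect)
  with_seed(seed, {
    rows <- list()
    for (tr in seq_len(n_transects)) {
      if (S == 1L) {
        em <- mean(c(lo, hi))
      } else {
        base <- seq(lo, hi, length.out = S)
        step <- (hi - lo) / (S - 1L)
        jit <- stats::runif(S, -0.3, 0.3) * step
        jit[c(1L, S)] <- 0            # pin endpoints so the range is spanned
        em <- pmin(pmax(base + jit, lo), hi)
      }
      tr_id <- sprintf("T%02d", tr)
      for (s in seq_len(S)) {
        st_id <- sprintf("%s_S%02d", tr_id, s)
        rows[[length(rows) + 1L]] <- data.frame(
          tile_id = paste0(st_id, c("_H", "_F")),
          station_id = st_id, transect_id = tr_id,
          heterogeneity = c(1L, 0L),
          emersion_ratio = em[s],
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    out$zone <- emersion_zones(out$emersion_ratio, out$station_id)
    rownames(out) <- NULL
    class(out) <- c("tile_design", "data.frame")
    out
  })
}

## Tercile shore zones with equal station counts (+/- 1); higher
## emersion ratio = higher on the shore.
emersion_zones <- function(emersion, station_id) {
  st <- !duplicated(station_id)
  ord <- order(emersion[st], station_id[st])
  st_ids <- station_id[st][ord]
  n <- length(st_ids)
  sizes <- rep(n %/% 3L, 3L) + c(n %% 3L >= 1L, n %% 3L >= 2L, FALSE)
  zone_by_station <- stats::setNames(
    rep(c("low", "mid", "high"), times = sizes), st_ids)
  factor(zone_by_station[station_id], levels = c("low", "mid", "high"))
}
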