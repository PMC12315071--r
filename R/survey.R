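## Time-averaged per-tile community descriptors.

#' Species richness of one census
#'
#' Number of taxa with strictly positive cover.  Point-count zeros are
#' taken at face value: no detection threshold is applied.
#'
#' @param covers Named or unnamed numeric vector of per-taxon covers.
#' @return Integer count.
#' @export
richness <- function(covers) {
  covers <- as.numeric(covers)
  if (any(covers < 0)) stop_("negative cover values are not allowed")
  sum(covers > 0)
}

#' Pielou evenness of one census
#'
#' `J = H' / ln(S)` where `H'` is Shannon entropy of the cover shares
#' among the taxa present and `S` their number.  Undefined (returned as
#' `NA`) when fewer than two taxa are present, since `ln(S) = 0`;
#' undefined censuses are excluded from time averaging rather than
#' substituted by 0 or 1.
#'
#' @inheritParams richness
#' @return `J` in `[0, 1]`, or `NA_real_` when undefined.
#' @examples
#' pielou_evenness(c(3, 1))  # 0.8113
#' @export
pielou_evenness <- function(covers) {
  covers <- as.numeric(covers)
  if (any(covers < 0)) stop_("negative cover values are not allowed")
  pos <- covers[covers > 0]
  s <- length(pos)
  if (s <= 1L) return(NA_real_)
  p <- pos / sum(pos)
  h <- -sum(p * log(p))
  h / log(s)
}

#' Summed cover per functional group
#'
#' @inheritParams richness
#' @param covers Named numeric vector (names are taxon ids).
#' @param group_map Named character vector or two-column data.frame
#'   (`taxon_id`, `group`) assigning every taxon to a functional group.
#' @return Named numeric vector of per-group summed covers; groups
#'   declared in the map but absent from `covers` return 0.
#' @export
group_cover <- function(covers, group_map) {
  gm <- as_group_map(group_map)
  taxa <- names(covers)
  if (is.null(taxa)) stop_("covers must be a named vector")
  unmapped <- setdiff(taxa, names(gm))
  if (length(unmapped))
    stop_("taxa not present in group map: %s", paste(unmapped, collapse = ", "))
  groups <- sort(unique(unname(gm)))
  out <- vapply(groups, function(g) {
    sum(covers[taxa[gm[taxa] == g]])
  }, numeric(1))
  names(out) <- groups
  out
}

as_group_map <- function(group_map) {
  if (is.data.frame(group_map)) {
    assert_cols(group_map, c("taxon_id", "group"), "group map")
    stats::setNames(as.character(group_map$group),
                    as.character(group_map$taxon_id))
  } else if (is.character(group_map) && !is.null(names(group_map))) {
    group_map
  } else {
    stop_("group_map must be a named character vector or a data.frame")
  }
}

#' Per-tile time-averaged community summary
#'
#' For each tile, computes richness, Pielou evenness, per-group summed
#' cover and total cover at every census, then averages over censuses
#' with equal weights.  Evenness is averaged over the censuses where it
#' is defined (at least two taxa present); a tile where it is never
#' defined gets `NA`.
#'
#' @param cover Long-format cover table (`tile_id`, `census_index`,
#'   `taxon_id`, `cover`).
#' @param group_map Taxon-to-group assignment, see [group_cover()].
#' @param evenness Convention for the evenness summary:
#'   `"per_census"` (default) computes Pielou J per census and averages
#'   the defined values; `"time_averaged"` computes one J on the
#'   tile's time-averaged cover vector.
#' @return A `data.frame` with one row per tile: `tile_id`,
#'   `mean_richness`, `mean_evenness`, `mean_total_cover`, and one
#'   `cover_<group>` column per functional group.
#' @export
summarise_tiles <- function(cover, group_map,
                            evenness = c("per_census", "time_averaged")) {
  evenness <- match.arg(evenness)
  assert_cols(cover, c("tile_id", "census_index", "taxon_id", "cover"),
              "cover table")
  gm <- as_group_map(group_map)
  groups <- sort(unique(unname(gm)))
  out <- lapply(split(cover, cover$tile_id), function(d) {
    m <- cover_matrix(d)
    if (nrow(m) < 1L) stop_("tile %s has no censuses", d$tile_id[1])
    rich <- apply(m, 1L, richness)
    even <- if (evenness == "per_census") apply(m, 1L, pielou_evenness)
            else pielou_evenness(colMeans(m))
    gc <- do.call(rbind, lapply(seq_len(nrow(m)), function(r)
      group_cover(m[r, ], gm)))
    row <- data.frame(tile_id = d$tile_id[1],
                      mean_richness = mean(rich),
                      mean_evenness = if (all(is.na(even))) NA_real_
                                      else mean(even, na.rm = TRUE),
                      mean_total_cover = mean(rowSums(m)),
                      stringsAsFactors = FALSE)
    for (g in groups) row[[paste0("cover_", g)]] <- mean(gc[, g])
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
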