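## Cascading (indirect) effects: products of significant standardised
## path coefficients along causal chains, summed into net effects, with
## cluster-bootstrap uncertainty.

#' Enumerate simple causal chains between two nodes
#'
#' Depth-first enumeration of all simple directed paths from `source`
#' to `target`, in deterministic lexicographic order.
#'
#' @param spec A [psem_spec()].
#' @param source,target Node names (must differ).
#' @return A list of character vectors (node sequences); empty if the
#'   pair is disconnected.
#' @export
enumerate_chains <- function(spec, source, target) {
  validate_spec(spec)
  if (!all(c(source, target) %in% spec$nodes))
    stop_("source/target must be spec nodes")
  if (source == target) stop_("source and target must differ")
  chains <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == target) {
      chains[[length(chains) + 1L]] <<- path
      return(invisible())
    }
    for (nxt in sort(spec$edges$to[spec$edges$from == last])) {
      if (nxt %in% path) next
      walk(c(path, nxt))
    }
  }
  walk(source)
  chains
}

#' Cascading effect of a source on a target
#'
#' For every simple chain from `source` to `target`, the chain effect
#' is the product of its standardised path coefficients if every edge
#' is significant at `alpha`, else 0.  The direct effect is the
#' single-edge chain's contribution, the indirect effect the sum over
#' chains of length >= 2, and the net effect their sum.  With a
#' multigroup fit the computation is repeated per group using that
#' group's freed/constrained coefficients.  Setting `alpha = 1`
#' disables the significance masking.
#'
#' @param fit A [psem()] fit.
#' @param source,target Node names.
#' @param alpha Per-edge significance level for masking (default the
#'   fit's alpha).
#' @return A `data.frame` of class `cascade_effect`: `group`, `source`,
#'   `target`, `direct`, `indirect`, `net`, `n_chains`,
#'   `n_contributing`.
#' @export
cascade_effect <- function(fit, source, target, alpha = fit$alpha) {
  if (!inherits(fit, "psem_fit")) stop_("fit must be a psem_fit")
  chains <- enumerate_chains(fit$spec, source, target)
  groups <- fit$groups
  e <- fit$edges
  rows <- lapply(groups, function(gr) {
    eg <- e[e$group == gr, , drop = FALSE]
    direct <- 0; indirect <- 0; contributing <- 0L
    for (ch in chains) {
      k <- length(ch) - 1L
      spcs <- numeric(k); ps <- numeric(k)
      for (i in seq_len(k)) {
        hit <- eg$from == ch[i] & eg$to == ch[i + 1L]
        if (!any(hit))
          stop_("edge %s -> %s missing from fit", ch[i], ch[i + 1L])
        spcs[i] <- eg$spc[hit][1]
        ps[i] <- eg$p[hit][1]
      }
      eff <- if (all(ps < alpha)) prod(spcs) else 0
      if (eff != 0) contributing <- contributing + 1L
      if (k == 1L) direct <- direct + eff else indirect <- indirect + eff
    }
    data.frame(group = gr, source = source, target = target,
               direct = direct, indirect = indirect,
               net = direct + indirect, n_chains = length(chains),
               n_contributing = contributing, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cascade_effect", "data.frame")
  out
}

#' Cluster-bootstrap confidence intervals for cascading effects
#'
#' Nonparametric bootstrap resampling whole stations (keeping paired
#' tiles together; stations are resampled within zone strata when the
#' fit is multigroup), refitting the pSEM and recomputing net effects.
#' Percentile 95% intervals are reported.  Replicates whose refit
#' fails are skipped and counted; more than 20% failures triggers a
#' warning.
#'
#' @param spec A [psem_spec()].
#' @param data Tile-level data (with `station_id`).
#' @param source Source node (e.g. the heterogeneity treatment).
#' @param targets Character vector of target nodes.
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param group Grouping column for multigroup fits, or `NULL`.
#' @param alpha Per-edge significance level for chain masking.
#' @param nesting Use nested random effects in refits.
#' @return A `cascade_effect` table with `lo95`, `hi95` and
#'   `n_boot_ok` columns appended.
#' @export
bootstrap_cascades <- function(spec, data, source, targets, n_boot = 200L,
                               seed = 1L, group = NULL, alpha = 0.05,
                               nesting = TRUE) {
  if (n_boot < 100L) stop_("n_boot must be >= 100")
  assert_cols(data, "station_id", "data")
  point <- fit_and_nets(spec, data, source, targets, group, alpha, nesting)
  strata <- if (!is.null(group)) as.character(data[[group]][
    !duplicated(data$station_id)]) else NULL
  stations <- data$station_id[!duplicated(data$station_id)]
  reps <- vector("list", n_boot)
  n_fail <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      pick <- if (is.null(strata)) {
        sample(stations, replace = TRUE)
      } else {
        unlist(lapply(split(stations, strata),
                      function(s) sample(s, replace = TRUE)))
      }
      ## resampled stations become distinct pseudo-stations so the
      ## random-effect grouping keeps its size
      dl <- lapply(seq_along(pick), function(i) {
        d <- data[data$station_id == pick[i], , drop = FALSE]
        d$station_id <- paste0(pick[i], "_b", i)
        d
      })
      db <- do.call(rbind, dl)
      reps[[b]] <- tryCatch(
        fit_and_nets(spec, db, source, targets, group, alpha, nesting),
        error = function(e) NULL)
      if (is.null(reps[[b]])) n_fail <- n_fail + 1L
    }
  })
  if (n_fail > 0.2 * n_boot)
    warning(sprintf("bootstrap: %d/%d replicate fits failed", n_fail, n_boot),
            call. = FALSE)
  ok <- !vapply(reps, is.null, logical(1))
  boot <- do.call(rbind, reps[ok])
  out <- point
  out$lo95 <- NA_real_; out$hi95 <- NA_real_
  for (i in seq_len(nrow(out))) {
    sel <- boot$group == out$group[i] & boot$target == out$target[i]
    qs <- stats::quantile(boot$net[sel], c(0.025, 0.975), na.rm = TRUE,
                          names = FALSE)
    out$lo95[i] <- qs[1]; out$hi95[i] <- qs[2]
  }
  out$n_boot_ok <- sum(ok)
  class(out) <- c("cascade_effect", "data.frame")
  out
}

fit_and_nets <- function(spec, data, source, targets, group, alpha,
                         nesting) {
  fit <- suppressWarnings(
    psem(spec, data, group = group, nesting = nesting, test = FALSE,
         alpha = alpha, keep_models = FALSE))
  do.call(rbind, lapply(targets, function(tg)
    cascade_effect(fit, source, tg, alpha = alpha)))
}
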