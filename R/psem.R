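## Piecewise structural equation modelling: local component
## regressions over a DAG, global evaluation by tests of d-separation
## and Fisher's C, standardised path coefficients, and multigroup
## free/constrained paths along the shore-zone gradient.

#' Standardised path coefficient
#'
#' `SPC = beta * sd_x / sd_y`, computed on the analysis scale within
#' the relevant group.
#'
#' @param beta Regression slope.
#' @param sd_x,sd_y Standard deviations of predictor and response.
#' @return The standardised coefficient.
#' @export
standardise <- function(beta, sd_x, sd_y) {
  if (!is.finite(sd_x) || !is.finite(sd_y) || sd_x <= 0 || sd_y <= 0)
    stop_("standardise() requires positive finite sd_x and sd_y")
  beta * sd_x / sd_y
}

#' Fisher's C global goodness-of-fit statistic
#'
#' `C = -2 * sum(log p_k)` over the d-separation claim p values,
#' chi-squared with `2k` degrees of freedom under the causal model.
#' p values are floored at 1e-16 before logging.  An empty claim set
#' (saturated model) returns `C = 0`, `df = 0`, `p = 1`.
#'
#' @param p_values Numeric vector of claim p values in (0, 1].
#' @return A list with `C`, `df`, `p`.
#' @export
fishers_c <- function(p_values) {
  if (length(p_values) == 0L) return(list(C = 0, df = 0L, p = 1))
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop_("claim p values must lie in (0, 1]")
  p <- pmax(p_values, 1e-16)
  C <- -2 * sum(log(p))
  df <- 2L * length(p)
  list(C = C, df = df, p = stats::pchisq(C, df, lower.tail = FALSE))
}

#' Test the d-separation claims of a specification
#'
#' Each basis-set claim is fitted with the same model family as the
#' component models (nested mixed model by default): the claim's
#' response regressed on the focal predictor plus the conditioning set
#' (and the group variable, when supplied), recording the focal
#' predictor's p value.  Claims whose model cannot be fitted are
#' flagged and excluded from Fisher's C with a warning.
#'
#' @param spec A [psem_spec()].
#' @param data Tile-level data containing all node columns.
#' @param nesting Use the nested random effects (default `TRUE`).
#' @param group Optional grouping column added to every conditioning
#'   set (multigroup claim testing).
#' @return A `data.frame`: `predictor`, `response`, `conditioning`,
#'   `p`, `excluded`.
#' @export
dsep_tests <- function(spec, data, nesting = TRUE, group = NULL) {
  validate_spec(spec, data)
  claims <- basis_set(spec)
  if (!length(claims))
    return(data.frame(predictor = character(), response = character(),
                      conditioning = character(), p = numeric(),
                      excluded = logical()))
  rows <- lapply(claims, function(cl) {
    preds <- c(cl$predictor, cl$conditioning, group)
    p <- tryCatch({
      f <- mixed_fit(data, cl$response, preds, nesting = nesting)
      f$coefficients$p[f$coefficients$term == cl$predictor]
    }, error = function(e) NA_real_)
    if (length(p) != 1L) p <- NA_real_
    data.frame(predictor = cl$predictor, response = cl$response,
               conditioning = paste(cl$conditioning, collapse = "+"),
               p = p, excluded = is.na(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$excluded))
    warning(sprintf("%d d-separation claim(s) unfittable; excluded from Fisher's C",
                    sum(out$excluded)), call. = FALSE)
  out
}

#' Fit a piecewise structural equation model
#'
#' The central fitting function: one component regression per
#' endogenous node (predictors = its parents in the DAG), evaluated
#' globally by d-separation tests and Fisher's C, with standardised
#' path coefficients throughout.  With a grouping variable, the
#' multigroup procedure is used: each path's group interaction is
#' tested in the pooled component model (type-II Wald test); paths with
#' a significant interaction are freed (separate per-group estimates),
#' the rest are constrained to the pooled estimate from the model
#' including the group main effect, so group mean differences never
#' masquerade as path differences.
#'
#' @param spec A [psem_spec()].
#' @param data Tile-level table with one column per node, plus
#'   `transect_id`/`station_id` (if `nesting`) and the grouping column.
#' @param group Grouping column name for multigroup fitting, or `NULL`
#'   for a global fit.  Defaults to the spec's declared group when
#'   `multigroup = TRUE` callers pass it explicitly.
#' @param nesting Use transect/station random intercepts (default
#'   `TRUE`).
#' @param test Run d-separation tests and Fisher's C (default `TRUE`;
#'   skipping them speeds up bootstrap refits).
#' @param alpha Significance level used to free multigroup paths.
#' @param keep_models Retain the fitted component models (default
#'   `TRUE`).
#' @return An object of class `psem_fit` with `print()`, `summary()`,
#'   `coef()` and `residuals()` methods; elements include `edges`
#'   (per-edge, per-group statistics), `claims`, `C` (Fisher's C list)
#'   and `r2` (component-model R2s).
#' @export
psem <- function(spec, data, group = NULL, nesting = TRUE, test = TRUE,
                 alpha = 0.05, keep_models = TRUE) {
  validate_spec(spec, data)
  if (nesting) assert_cols(data, c("transect_id", "station_id"), "data")
  endog <- spec$order[vapply(spec$order,
                             function(n) length(parents_of(spec, n)) > 0,
                             logical(1))]
  if (is.null(group)) {
    fit <- psem_global(spec, data, endog, nesting, keep_models)
  } else {
    fit <- psem_multigroup(spec, data, endog, group, nesting, alpha,
                           keep_models)
  }
  if (test) {
    fit$claims <- dsep_tests(spec, data, nesting = nesting, group = group)
    fit$C <- fishers_c(fit$claims$p[!fit$claims$excluded])
  } else {
    fit$claims <- NULL
    fit$C <- NULL
  }
  fit$spec <- spec
  fit["group"] <- list(group)
  fit$alpha <- alpha
  fit$nesting <- nesting
  fit$n_obs <- nrow(data)
  class(fit) <- "psem_fit"
  fit
}

#' @rdname psem
#' @export
fit_psem <- function(spec, data, ...) psem(spec, data, group = NULL, ...)

#' @rdname psem
#' @param ... Passed on to [psem()].
#' @export
multigroup <- function(spec, data, group = spec$group, ...) {
  if (is.null(group)) stop_("multigroup() needs a grouping variable")
  psem(spec, data, group = group, ...)
}

psem_global <- function(spec, data, endog, nesting, keep_models) {
  sds <- vapply(spec$nodes, function(n) stats::sd(data[[n]]), numeric(1))
  edges <- list(); r2 <- list(); models <- list(); singular <- 0L
  for (nd in endog) {
    pa <- parents_of(spec, nd)
    f <- mixed_fit(data, nd, pa, nesting = nesting)
    singular <- singular + f$singular
    ct <- f$coefficients
    for (p_ in pa) {
      row <- ct[ct$term == p_, ]
      edges[[length(edges) + 1L]] <- data.frame(
        group = "global", from = p_, to = nd,
        estimate = row$estimate, se = row$se, df = row$df, t = row$t,
        p = row$p, spc = standardise(row$estimate, sds[p_], sds[nd]),
        freed = FALSE, p_interaction = NA_real_, stringsAsFactors = FALSE)
    }
    r2v <- nakagawa_r2(f$model)
    r2[[nd]] <- data.frame(node = nd, R2m = unname(r2v["R2m"]),
                           R2c = unname(r2v["R2c"]),
                           stringsAsFactors = FALSE)
    if (keep_models) models[[nd]] <- f$model
  }
  list(edges = do.call(rbind, edges), r2 = do.call(rbind, r2),
       models = if (keep_models) models else NULL, n_singular = singular,
       groups = "global")
}

psem_multigroup <- function(spec, data, endog, group, nesting, alpha,
                            keep_models) {
  g <- factor(data[[group]])
  data[[group]] <- g
  max_pa <- max(vapply(endog, function(n) length(parents_of(spec, n)),
                       integer(1)))
  sizes <- table(g)
  bad <- names(sizes)[sizes < max_pa + 3L]
  if (length(bad)) {
    warning("dropping group(s) with insufficient data: ",
            paste(bad, collapse = ", "), call. = FALSE)
    data <- data[!(g %in% bad), , drop = FALSE]
    data[[group]] <- g <- droplevels(factor(data[[group]]))
  }
  if (nlevels(g) < 2L) {
    warning("single group: multigroup fit reduces to the global fit",
            call. = FALSE)
    return(psem_global(spec, data, endog, nesting, keep_models))
  }
  lev <- levels(g)

  sd_by <- lapply(lev, function(l) {
    vapply(spec$nodes, function(n) stats::sd(data[[n]][g == l]), numeric(1))
  })
  names(sd_by) <- lev

  edges <- list(); r2 <- list(); models <- list(); singular <- 0L
  for (nd in endog) {
    pa <- parents_of(spec, nd)
    ## pooled model with all path-by-group interactions
    int_terms <- c(pa, group, paste(pa, group, sep = ":"))
    f_int <- mixed_fit(data, nd, int_terms, nesting = nesting)
    an <- tryCatch(car::Anova(f_int$model, type = 2),
                   error = function(e) NULL)
    p_int <- stats::setNames(rep(NA_real_, length(pa)), pa)
    if (!is.null(an)) {
      rn <- rownames(an)
      pcol <- grep("^Pr\\(", colnames(an), value = TRUE)[1]
      for (p_ in pa) {
        hit <- rn == paste(p_, group, sep = ":")
        if (any(hit)) p_int[p_] <- an[hit, pcol]
      }
    }
    freed <- !is.na(p_int) & p_int < alpha

    ## pooled model with group main effect: constrained estimates
    f_pool <- mixed_fit(data, nd, c(pa, group), nesting = nesting)
    singular <- singular + f_pool$singular
    ct_pool <- f_pool$coefficients

    ## per-group models, needed where any path into nd is freed
    ct_g <- NULL
    if (any(freed)) {
      ct_g <- lapply(lev, function(l) {
        fg <- mixed_fit(data[g == l, , drop = FALSE], nd, pa,
                        nesting = nesting)
        fg$coefficients
      })
      names(ct_g) <- lev
    }

    for (p_ in pa) {
      for (l in lev) {
        if (freed[p_]) {
          row <- ct_g[[l]][ct_g[[l]]$term == p_, ]
        } else {
          row <- ct_pool[ct_pool$term == p_, ]
        }
        edges[[length(edges) + 1L]] <- data.frame(
          group = l, from = p_, to = nd,
          estimate = row$estimate, se = row$se, df = row$df, t = row$t,
          p = row$p,
          spc = standardise(row$estimate, sd_by[[l]][p_], sd_by[[l]][nd]),
          freed = unname(freed[p_]), p_interaction = unname(p_int[p_]),
          stringsAsFactors = FALSE)
      }
    }
    r2v <- nakagawa_r2(f_pool$model)
    r2[[nd]] <- data.frame(node = nd, R2m = unname(r2v["R2m"]),
                           R2c = unname(r2v["R2c"]),
                           stringsAsFactors = FALSE)
    if (keep_models) models[[nd]] <- f_pool$model
  }
  list(edges = do.call(rbind, edges), r2 = do.call(rbind, r2),
       models = if (keep_models) models else NULL, n_singular = singular,
       groups = lev)
}

#' Compare mixed-model and fixed-effects-only component fits
#'
#' Refits every component model without random effects and reports the
#' per-edge discrepancy in standardised path coefficients against the
#' mixed fit, flagging edges whose SPC shifts by more than `threshold`
#' or whose sign flips.
#'
#' @param spec A [psem_spec()].
#' @param data Tile-level data.
#' @param threshold Absolute SPC discrepancy that triggers a flag
#'   (default 0.1).
#' @param ... Passed to [psem()].
#' @return A `data.frame` with mixed and fixed SPCs per edge,
#'   `delta_spc`, `sign_flip` and `flagged`.
#' @export
model_simplify <- function(spec, data, threshold = 0.1, ...) {
  fm <- psem(spec, data, nesting = TRUE, test = FALSE, keep_models = FALSE,
             ...)
  fl <- psem(spec, data, nesting = FALSE, test = FALSE, keep_models = FALSE,
             ...)
  m <- fm$edges[, c("group", "from", "to", "spc")]
  names(m)[4] <- "spc_mixed"
  l <- fl$edges[, c("group", "from", "to", "spc")]
  names(l)[4] <- "spc_fixed"
  out <- merge(m, l, by = c("group", "from", "to"), sort = FALSE)
  out$delta_spc <- out$spc_fixed - out$spc_mixed
  out$sign_flip <- sign(out$spc_fixed) != sign(out$spc_mixed) &
    out$spc_mixed != 0
  out$flagged <- abs(out$delta_spc) > threshold | out$sign_flip
  out
}

#' @export
print.psem_fit <- function(x, ...) {
  cat(sprintf("Piecewise SEM fit: %d nodes, %d edges, %s\n",
              length(x$spec$nodes), nrow(x$spec$edges),
              if (is.null(x[["group"]])) "global"
              else sprintf("multigroup by %s (%s)", x[["group"]],
                           paste(x$groups, collapse = ", "))))
  if (!is.null(x$C))
    cat(sprintf("Fisher's C = %.2f, df = %d, p = %.3f (%d claims)\n",
                x$C$C, x$C$df, x$C$p, nrow(x$claims)))
  if (x$n_singular > 0)
    cat(sprintf("%d singular component fit(s) retained\n", x$n_singular))
  invisible(x)
}

#' @export
summary.psem_fit <- function(object, ...) {
  print(object)
  cat("\nPaths:\n")
  print(object$edges, digits = 3, row.names = FALSE)
  if (!is.null(object$r2)) {
    cat("\nComponent-model R2:\n")
    print(object$r2, digits = 3, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.psem_fit <- function(object, standardised = TRUE, ...) {
  e <- object$edges
  val <- if (standardised) e$spc else e$estimate
  stats::setNames(val, paste0(e$group, ": ", e$from, "->", e$to))
}

#' @export
residuals.psem_fit <- function(object, ...) {
  if (is.null(object$models))
    stop_("fit was run with keep_models = FALSE")
  lapply(object$models, stats::residuals)
}
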