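## Linear-Gaussian simulation from a pSEM specification with known
## standardised path coefficients and the experiment's nested random
## effects.  This is the oracle generator for calibration and
## parameter-recovery checks of the pSEM machinery: every variable has
## unit marginal variance, so the generating coefficients ARE the
## standardised path coefficients the fit should recover.

#' Simulate tile-level data from a causal specification
#'
#' Draws one row per tile.  The exogenous nodes `het` and `emersion`
#' are taken from the design (z-scored treatment and emersion ratio);
#' every endogenous node is a linear combination of its parents with
#' the supplied standardised coefficients plus transect, station and
#' residual Gaussian components whose variances top the node up to
#' marginal variance 1.  Coefficients may vary by zone to create
#' group-specific paths for multigroup analyses.
#'
#' @param spec A [psem_spec()].
#' @param coefs Named numeric vector of standardised path coefficients,
#'   names `"from->to"` (spaces allowed).  Edges absent from `coefs`
#'   get coefficient 0.
#' @param design A [generate_design()] table (supplies `het`,
#'   `emersion`, `zone` and the nesting).
#' @param group_coefs Optional named list: for each zone level, a named
#'   vector overriding `coefs` for that zone.
#' @param re_prop Length-2 numeric: shares of each node's error
#'   variance assigned to transect and station random intercepts.
#' @param seed Integer seed.
#' @return A `data.frame` with the design columns plus one column per
#'   spec node.
#' @export
simulate_sem <- function(spec, coefs, design, group_coefs = NULL,
                         re_prop = c(transect = 0.08, station = 0.12),
                         seed = NULL) {
  validate_spec(spec)
  coefs <- normalise_coefs(coefs, spec)
  n <- nrow(design)
  with_seed(seed, {
    dat <- as.data.frame(design)
    vals <- list()
    vals[["het"]] <- if ("het" %in% spec$nodes)
      zscore(design$heterogeneity) else NULL
    vals[["emersion"]] <- if ("emersion" %in% spec$nodes)
      zscore(design$emersion_ratio) else NULL
    for (nd in setdiff(spec$exogenous, c("het", "emersion")))
      vals[[nd]] <- stats::rnorm(n)

    ## implied covariance bookkeeping (global coefficients) keeps every
    ## node at unit marginal variance
    S <- diag(length(spec$nodes))
    dimnames(S) <- list(spec$nodes, spec$nodes)

    zone <- as.character(design$zone %||% rep("all", n))
    for (nd in spec$order) {
      if (!is.null(vals[[nd]])) next
      pa <- parents_of(spec, nd)
      if (!length(pa)) { vals[[nd]] <- stats::rnorm(n); next }
      b <- coefs[paste(pa, nd, sep = "->")]
      v_fixed <- as.numeric(t(b) %*% S[pa, pa, drop = FALSE] %*% b)
      if (v_fixed >= 0.9)
        stop_("path coefficients into '%s' imply fixed variance %.2f >= 0.9",
              nd, v_fixed)
      v_err <- 1 - v_fixed
      ## per-row fixed part, honouring zone-specific overrides
      fixed <- numeric(n)
      for (k in seq_along(pa)) {
        bk <- rep(b[k], n)
        if (!is.null(group_coefs)) {
          for (g in names(group_coefs)) {
            ov <- normalise_names(group_coefs[[g]])
            key <- paste(pa[k], nd, sep = "->")
            if (key %in% names(ov)) bk[zone == g] <- ov[[key]]
          }
        }
        fixed <- fixed + bk * vals[[pa[k]]]
      }
      sd_tr <- sqrt(re_prop[[1]] * v_err)
      sd_st <- sqrt(re_prop[[2]] * v_err)
      sd_e <- sqrt((1 - re_prop[[1]] - re_prop[[2]]) * v_err)
      u_tr <- stats::setNames(stats::rnorm(length(unique(design$transect_id)),
                                           0, sd_tr),
                              unique(design$transect_id))
      u_st <- stats::setNames(stats::rnorm(length(unique(design$station_id)),
                                           0, sd_st),
                              unique(design$station_id))
      vals[[nd]] <- fixed + u_tr[design$transect_id] +
        u_st[design$station_id] + stats::rnorm(n, 0, sd_e)
      ## update implied covariance (global coefficients)
      for (other in spec$nodes) {
        if (other == nd) next
        S[nd, other] <- S[other, nd] <-
          sum(b * S[pa, other])
      }
      S[nd, nd] <- 1
    }
    for (nd in spec$nodes) dat[[nd]] <- as.numeric(vals[[nd]])
    dat
  })
}

normalise_names <- function(coefs) {
  stats::setNames(as.numeric(coefs), gsub(" ", "", names(coefs)))
}

normalise_coefs <- function(coefs, spec) {
  coefs <- normalise_names(coefs)
  keys <- paste(spec$edges$from, spec$edges$to, sep = "->")
  unknown <- setdiff(names(coefs), keys)
  if (length(unknown))
    stop_("coefficient(s) for non-edges: %s", paste(unknown, collapse = ", "))
  out <- stats::setNames(numeric(length(keys)), keys)
  out[names(coefs)] <- coefs
  out
}

#' Default standardised coefficients for the causal model
#'
#' Moderate signed effects on the standardised SEM scale mirroring the
#' counteracting-pathways scenario: used to simulate tile-level data
#' from [default_sem_spec()] for calibration and parameter-recovery
#' studies.  Edges not listed default to 0 when simulating.
#'
#' @return Named numeric vector keyed by `"from->to"`.
#' @export
default_sem_coefs <- function() {
  c("het->richness" = 0.35, "het->dominant" = -0.45,
    "het->consumers" = -0.45, "het->pop_stability" = 0.35,
    "emersion->richness" = -0.4, "emersion->dominant" = 0.5,
    "emersion->consumers" = -0.5, "emersion->native" = 0.6,
    "emersion->ephemerals" = -0.6,
    "consumers->ephemerals" = -0.4, "consumers->comp_stability" = 0.3,
    "dominant->asynchrony" = 0.3, "dominant->comp_stability" = 0.3,
    "dominant->pop_stability" = 0.4,
    "richness->asynchrony" = 0.45, "richness->pop_stability" = -0.3,
    "consumers->pop_stability" = 0.3,
    "ephemerals->pop_stability" = -0.3,
    "ephemerals->comp_stability" = -0.3,
    "native->temp_stability" = 0.3,
    "pop_stability->comp_stability" = 0.35,
    "asynchrony->temp_stability" = 0.4,
    "comp_stability->temp_stability" = 0.4)
}
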