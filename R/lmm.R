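## Nested mixed-effects models: response ~ z(heterogeneity) x
## z(emersion) with random intercepts for transect and station nested
## in transect, Satterthwaite denominator df, and Nakagawa R2.

#' z-transform a numeric vector
#'
#' Centres to mean 0 and scales to sample (n-1) standard deviation 1.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return Standardised numeric vector.
#' @export
zscore <- function(x) {
  x <- as.numeric(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop_("zscore() requires at least two distinct finite values")
  (x - mean(x)) / s
}

#' Transform a response variable by a named policy
#'
#' Policies: `identity`, `sqrt`, `log` (strictly positive values only),
#' `log1p` (log of value + 1, the fixed offset used for percent covers
#' that include zeros).
#'
#' @param values Numeric vector.
#' @param policy One of `"identity"`, `"log"`, `"log1p"`, `"sqrt"`.
#' @return The transformed vector, with the policy recorded in
#'   attribute `"transform"`.
#' @export
transform_response <- function(values,
                               policy = c("identity", "log", "log1p", "sqrt")) {
  policy <- match.arg(policy)
  out <- switch(policy,
    identity = values,
    log = {
      if (any(values <= 0))
        stop_("log transform requires strictly positive values; use log1p")
      log(values)
    },
    log1p = {
      if (any(values < 0)) stop_("log1p transform requires values >= 0")
      log1p(values)
    },
    sqrt = {
      if (any(values < 0)) stop_("sqrt transform requires values >= 0")
      sqrt(values)
    })
  attr(out, "transform") <- policy
  out
}

## Low-level fitter shared by the treatment models and every pSEM
## component/claim model.  `predictors` may be length 0 (intercept
## only).  Returns the fitted model plus a coefficient table with
## Satterthwaite df (falling back to residual df if unavailable).
mixed_fit <- function(data, response, predictors, nesting = TRUE,
                      reml = TRUE, df_method = "satterthwaite") {
  rhs <- if (length(predictors)) paste(predictors, collapse = " + ") else "1"
  if (nesting) {
    assert_cols(data, c("transect_id", "station_id"), "model data")
    fml <- stats::as.formula(sprintf(
      "%s ~ %s + (1 | transect_id / station_id)", response, rhs))
    fit <- suppressMessages(lmerTest::lmer(
      fml, data = data, REML = reml,
      control = lme4::lmerControl(calc.derivs = FALSE,
                                  check.conv.singular = "ignore",
                                  optCtrl = list(xtol_abs = 1e-5,
                                                 ftol_abs = 1e-5))))
    ct <- if (df_method == "satterthwaite")
      tryCatch(stats::coef(summary(fit)), error = function(e) NULL)
    else NULL
    if (is.null(ct) || anyNA(ct[, "df"])) {
      ## Satterthwaite failed: residual-df fallback
      b <- lme4::fixef(fit)
      se <- sqrt(diag(as.matrix(stats::vcov(fit))))
      df_res <- nrow(data) - length(b)
      tt <- b / se
      ct <- cbind(Estimate = b, `Std. Error` = se, df = df_res,
                  `t value` = tt,
                  `Pr(>|t|)` = 2 * stats::pt(-abs(tt), df_res))
      if (df_method == "satterthwaite")
        warning("Satterthwaite df unavailable; residual-df t used for ",
                response, call. = FALSE)
    }
    singular <- lme4::isSingular(fit, tol = 1e-4)
  } else {
    fml <- stats::as.formula(sprintf("%s ~ %s", response, rhs))
    fit <- stats::lm(fml, data = data)
    sm <- stats::coef(summary(fit))
    ct <- cbind(Estimate = sm[, 1], `Std. Error` = sm[, 2],
                df = fit$df.residual, `t value` = sm[, 3],
                `Pr(>|t|)` = sm[, 4])
    singular <- FALSE
  }
  coefs <- data.frame(term = rownames(ct), estimate = ct[, "Estimate"],
                      se = ct[, "Std. Error"], df = ct[, "df"],
                      t = ct[, "t value"], p = ct[, "Pr(>|t|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
  list(model = fit, coefficients = coefs, singular = singular)
}

#' Marginal and conditional R-squared for a (mixed) linear model
#'
#' The variance-partition form: marginal R2 is the share of total
#' variance (fixed + random + residual) explained by the fixed effects;
#' conditional R2 adds the random-effect variances to the numerator.
#'
#' @param model A fitted `lmerMod`/`lmerModLmerTest` or `lm`.
#' @return Named numeric vector `c(R2m, R2c)`.
#' @export
nakagawa_r2 <- function(model) {
  if (inherits(model, "merMod")) {
    var_f <- stats::var(stats::predict(model, re.form = NA))
    vc <- lme4::VarCorr(model)
    var_r <- sum(vapply(vc, function(v) v[1, 1], numeric(1)))
    var_e <- attr(vc, "sc")^2
  } else if (inherits(model, "lm")) {
    var_f <- stats::var(stats::fitted(model))
    var_r <- 0
    var_e <- summary(model)$sigma^2
  } else {
    stop_("nakagawa_r2() supports lm and merMod fits")
  }
  tot <- var_f + var_r + var_e
  c(R2m = var_f / tot, R2c = (var_f + var_r) / tot)
}

#' Fit the treatment-by-gradient mixed model for one response
#'
#' Fits `response ~ z(heterogeneity) * z(emersion_ratio)` with random
#' intercepts for transect and for station nested in transect (REML),
#' the model used for every tile-level diversity, cover and stability
#' response.  Fixed-effect p values use Satterthwaite denominator
#' degrees of freedom.  Singular fits (a variance component estimated
#' at zero, common with few transects) are retained and flagged.
#'
#' @param data Tile-level table containing `response`, the predictor
#'   columns, `transect_id` and `station_id`.
#' @param response Column name of the response.
#' @param predictors Two predictor column names (z-scored internally).
#' @param interaction Include the product term (default `TRUE`).
#' @param transform Response transform policy, see
#'   [transform_response()].
#' @param nesting Use the nested random effects (default `TRUE`;
#'   `FALSE` falls back to ordinary least squares).
#' @param df_method Denominator degrees of freedom:
#'   `"satterthwaite"` (default) or `"residual"`.
#' @return An object of class `shorestab_lmm` with `print()`,
#'   `summary()`, `coef()` and `residuals()` methods.
#' @export
fit_lmm <- function(data, response,
                    predictors = c("heterogeneity", "emersion_ratio"),
                    interaction = TRUE,
                    transform = "identity",
                    nesting = TRUE,
                    df_method = c("satterthwaite", "residual")) {
  df_method <- match.arg(df_method)
  assert_cols(data, c(response, predictors), "tile table")
  if (nesting && length(unique(data$transect_id)) < 2L)
    stop_("fit_lmm() needs >= 2 transects for the nested random effects")
  d <- data
  keep <- stats::complete.cases(d[, c(response, predictors)])
  d <- d[keep, , drop = FALSE]
  y <- transform_response(d[[response]], transform)
  d$.y <- as.numeric(y)
  zcols <- paste0(predictors, "_z")
  for (i in seq_along(predictors)) d[[zcols[i]]] <- zscore(d[[predictors[i]]])
  terms <- zcols
  if (interaction && length(zcols) >= 2L)
    terms <- c(zcols, paste(zcols[1], zcols[2], sep = ":"))
  fit <- mixed_fit(d, ".y", terms, nesting = nesting,
                   df_method = df_method)
  r2 <- nakagawa_r2(fit$model)
  structure(list(response = response, transform = transform,
                 coefficients = fit$coefficients,
                 model = fit$model, singular = fit$singular,
                 R2m = unname(r2["R2m"]), R2c = unname(r2["R2c"]),
                 n_obs = nrow(d)),
            class = "shorestab_lmm")
}

#' @export
print.shorestab_lmm <- function(x, ...) {
  cat(sprintf("Nested mixed model: %s (%s transform)%s\n", x$response,
              x$transform, if (x$singular) " [singular fit]" else ""))
  print(x$coefficients, digits = 3)
  cat(sprintf("R2m = %.3f, R2c = %.3f, n = %d\n", x$R2m, x$R2c, x$n_obs))
  invisible(x)
}

#' @export
coef.shorestab_lmm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
summary.shorestab_lmm <- function(object, ...) {
  object
}

#' @export
residuals.shorestab_lmm <- function(object, ...) {
  stats::residuals(object$model)
}

#' Treatment-model table across responses
#'
#' Fits [fit_lmm()] for each response and stacks the tidy coefficient
#' rows, one row per fixed term, with R2 and transform recorded.
#'
#' @inheritParams fit_lmm
#' @param responses Character vector of response columns.
#' @param transforms Optional named character vector mapping responses
#'   to transform policies (default identity for all).
#' @return A `data.frame`: `response`, `term`, `estimate`, `se`, `df`,
#'   `t`, `p`, `R2m`, `R2c`, `transform`, `singular`, `n_obs`.
#' @export
lmm_table <- function(data, responses, transforms = NULL,
                      predictors = c("heterogeneity", "emersion_ratio"),
                      nesting = TRUE) {
  rows <- lapply(responses, function(r) {
    tf <- if (!is.null(transforms) && r %in% names(transforms))
      transforms[[r]] else "identity"
    f <- fit_lmm(data, r, predictors = predictors, transform = tf,
                 nesting = nesting)
    cbind(response = r, f$coefficients, R2m = f$R2m, R2c = f$R2c,
          transform = tf, singular = f$singular, n_obs = f$n_obs,
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Residual diagnostics summary
#'
#' Numeric stand-ins for the visual residual checks of a modelling
#' workflow: Shapiro-Wilk statistic on residuals (QQ summary) and the
#' slope of sqrt(|standardised residuals|) on fitted values
#' (scale-location trend; 0 means no heteroscedasticity trend).
#'
#' @param fit A `shorestab_lmm` object.
#' @return Named numeric vector `c(shapiro_w, shapiro_p,
#'   scale_location_slope)`.
#' @export
residual_diagnostics <- function(fit) {
  r <- stats::residuals(fit$model)
  f <- stats::fitted(fit$model)
  sw <- stats::shapiro.test(r)
  sl <- if (stats::sd(f) > 0)
    unname(stats::coef(stats::lm(sqrt(abs(scale(r))) ~ f))[2]) else 0
  c(shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
    scale_location_slope = sl)
}
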