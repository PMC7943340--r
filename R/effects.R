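# Intervention-effect estimation with nurse-nested linear mixed models.

# Reference categories mirror the adjusted-model presentation of the trial
# report: control arm, female, diabetes nurse, OHA+insulin, current
# depression, disabled/incapacitated, alone, high education, above-average
# income are the reference levels.
ADJUSTED_COVARIATES <- c("bmi", "nurse_type", "medication_type", "hba1c",
                         "depression", "gender", "age", "work", "living",
                         "education", "income")

relevel_for_adjusted <- function(df) {
  refs <- c(nurse_type = "diabetes", medication_type = "both",
            depression = "current", gender = "female", work = "disabled",
            living = "alone", education = "high", income = "above")
  for (v in names(refs)) {
    if (v %in% names(df) && is.factor(df[[v]]))
      df[[v]] <- stats::relevel(df[[v]], ref = refs[[v]])
  }
  df
}

#' Fit the nurse-nested mixed model for an outcome on the Cohen-d scale
#'
#' Fits `outcome ~ arm (+ covariates)` with a random intercept per nurse and
#' returns the intervention coefficient with Satterthwaite degrees of
#' freedom, t statistic, two-sided p value and confidence interval.  When
#' the nurse variance is estimated as zero (singular fit) the model
#' collapses to ordinary least squares; the fallback is applied with a
#' warning and recorded in the estimate's `method`.
#'
#' @param outcomes a [compose_outcomes()] result, or any data.frame with the
#'   outcome column, `arm` and `nurse_id`.
#' @param outcome name of the outcome column (default `"D"`).
#' @param covariates `NULL` for the unadjusted model, `TRUE` for the default
#'   adjusted covariate set, or a character vector of column names present
#'   in `outcomes` (merge participant covariates in first).
#' @param model_tag provenance label stored in the estimate.
#' @param conf_level confidence level, default 0.95.
#' @return an `effect_estimate`.
#' @export
fit_mixed <- function(outcomes, outcome = "D", covariates = NULL,
                      model_tag = "unadjusted", conf_level = 0.95) {
  df <- as.data.frame(outcomes)
  if (all(is.na(df[[outcome]])))
    stop("outcome is entirely missing", call. = FALSE)
  df$arm <- stats::relevel(factor(df$arm), ref = "control")
  covs <- character(0)
  if (isTRUE(covariates)) covs <- intersect(ADJUSTED_COVARIATES, names(df))
  else if (is.character(covariates)) covs <- covariates
  if (length(covs)) df <- relevel_for_adjusted(df)
  fml <- stats::reformulate(c("arm", covs, "(1 | nurse_id)"), response = outcome)
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(fml, data = df,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))))

  if (lme4::isSingular(fit, tol = 1e-5)) {
    warning("nurse variance estimated as zero; falling back to the single-level model",
            call. = FALSE)
    fml2 <- stats::reformulate(c("arm", covs), response = outcome)
    lmfit <- stats::lm(fml2, data = df)
    sm <- summary(lmfit)$coefficients["armintervention", ]
    return(effect_estimate(d = sm[["Estimate"]], se = sm[["Std. Error"]],
                           df = lmfit$df.residual, model_tag = model_tag,
                           conf_level = conf_level, method = "ols-fallback"))
  }
  sm <- summary(fit, ddf = "Satterthwaite")$coefficients["armintervention", ]
  effect_estimate(d = sm[["Estimate"]], se = sm[["Std. Error"]],
                  df = sm[["df"]], model_tag = model_tag,
                  conf_level = conf_level, method = "satterthwaite")
}

#' Crude odds ratio from a 2x2 table
#'
#' `OR = (a*d)/(b*c)` with the Wald interval
#' `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param tab 2x2 matrix of counts, rows = groups, columns = outcome
#'   (e.g. retained / lost).
#' @param conf_level confidence level, default 0.95.
#' @param correct add 0.5 to every cell when a cell is zero (Haldane
#'   correction); if `FALSE` a zero cell is an error.
#' @return an `odds_ratio_estimate`: `or`, `ci_low`, `ci_high`, `p`.
#' @export
crude_or <- function(tab, conf_level = 0.95, correct = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0)) stop("cell counts must be nonnegative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in the 2x2 table", call. = FALSE)
  if (any(tab == 0)) {
    if (!correct) stop("zero cell; set correct = TRUE for the Haldane correction",
                       call. = FALSE)
    tab <- tab + 0.5
  }
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  se <- sqrt(sum(1 / tab))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(or = or,
                 ci_low = exp(log(or) - z * se),
                 ci_high = exp(log(or) + z * se),
                 se_log = se,
                 p = 2 * stats::pnorm(-abs(log(or)) / se),
                 predictor = "2x2 table"),
            class = "odds_ratio_estimate")
}

#' @export
print.odds_ratio_estimate <- function(x, ...) {
  cat(sprintf("%s: OR %.2f (95%% CI %.3f to %.3f), p = %.3g\n",
              x$predictor, x$or, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' Logistic regression for selective attrition
#'
#' Models retention (1 = follow-up completed) on baseline predictors and
#' reports per-predictor odds ratios with Wald 95% confidence intervals.
#'
#' @param data data.frame with a logical/binary `retained` column and the
#'   predictors (one row per participant).
#' @param predictors character vector of predictor columns; default `"arm"`.
#' @param conf_level confidence level, default 0.95.
#' @return list of `odds_ratio_estimate` objects, one per model
#'   coefficient (excluding the intercept).
#' @export
attrition_logistic <- function(data, predictors = "arm", conf_level = 0.95) {
  if (!"retained" %in% names(data)) stop("data needs a `retained` column", call. = FALSE)
  if ("wave" %in% names(data)) data <- data[data$wave == "baseline", ]
  fml <- stats::reformulate(predictors, response = "retained")
  data$retained <- as.integer(data$retained)
  fit <- stats::glm(fml, family = stats::binomial(), data = data)
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  if (any(abs(sm[, "Estimate"]) > 15) || any(sm[, "Std. Error"] > 100))
    stop("separation detected: attrition model coefficients diverge", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- lapply(rownames(sm), function(term) {
    est <- sm[term, "Estimate"]; se <- sm[term, "Std. Error"]
    structure(list(or = exp(est), ci_low = exp(est - z * se),
                   ci_high = exp(est + z * se), se_log = se,
                   p = sm[term, "Pr(>|z|)"], predictor = term),
              class = "odds_ratio_estimate")
  })
  names(out) <- rownames(sm)
  out
}
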