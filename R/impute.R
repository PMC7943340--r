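# Multiple imputation by chained equations with Rubin-rule pooling.
#
# Implemented in-package: numeric variables are imputed by Bayesian linear
# regression draws (posterior sigma from a scaled inverse chi-square, beta
# from its normal posterior, then a noisy prediction), binary factors by a
# logistic model with a normal approximation to the coefficient posterior,
# and multi-level factors by a bootstrap multinomial model
# (nnet::multinom).  Observed values are never altered.

draw_norm <- function(y_obs, X_obs, X_mis) {
  p <- ncol(X_obs)
  ridge <- diag(1e-5, p)
  xtx <- crossprod(X_obs) + ridge
  xtxi <- solve(xtx)
  beta <- xtxi %*% crossprod(X_obs, y_obs)
  res <- y_obs - X_obs %*% beta
  df <- max(length(y_obs) - p, 1)
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  beta_star <- beta + t(chol(xtxi)) %*% rnorm(p) * sqrt(sigma2)
  as.vector(X_mis %*% beta_star + rnorm(nrow(X_mis)) * sqrt(sigma2))
}

draw_logreg <- function(y_obs, X_obs, X_mis, levels) {
  dat <- data.frame(.y = as.integer(y_obs == levels[2]))
  fit <- suppressWarnings(stats::glm.fit(X_obs, dat$.y,
                                         family = stats::binomial()))
  w <- fit$weights
  info <- crossprod(X_obs * sqrt(pmax(w, 1e-8)))
  vc <- solve(info + diag(1e-8, ncol(X_obs)))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0   # rank-deficient columns drop out of the draw
  beta_star <- beta + as.vector(t(chol(vc)) %*% rnorm(ncol(X_obs)))
  pr <- stats::plogis(as.vector(X_mis %*% beta_star))
  factor(levels[1 + (runif(nrow(X_mis)) < pr)], levels = levels)
}

draw_polyreg <- function(y_obs, X_obs, X_mis, levels) {
  boot <- sample.int(length(y_obs), replace = TRUE)
  dat <- data.frame(.y = y_obs[boot], X_obs[boot, -1, drop = FALSE])
  capture.output(fit <- nnet::multinom(.y ~ ., data = dat, trace = FALSE,
                                       maxit = 200))
  pr <- stats::predict(fit, newdata = data.frame(X_mis[, -1, drop = FALSE]),
                       type = "probs")
  if (is.null(dim(pr))) pr <- matrix(pr, ncol = length(fit$lev), byrow = FALSE)
  if (ncol(pr) == 1) pr <- cbind(1 - pr, pr)
  picks <- apply(pr, 1, function(p) sample(colnames(pr) %||% fit$lev, 1, prob = p))
  factor(picks, levels = levels)
}

#' Multiple imputation by chained equations
#'
#' Produces `m` completed copies of a participant-level table.  Variables
#' with missing values are visited in sequence for `maxit` cycles; each is
#' imputed from all other (currently completed) variables.  Observed values
#' are never modified.
#'
#' @param data one row per participant; columns to use as-is plus columns
#'   with missing values to impute.
#' @param m number of completed datasets (>= 2), default 20.
#' @param seed imputation stream seed.
#' @param maxit chained-equation cycles per dataset, default 5.
#' @param exclude columns to carry along but never use as predictors or
#'   impute (identifiers), default `participant_id`/`nurse_id`.
#' @param eligible optional named list of logical vectors: for the named
#'   columns, only rows flagged `TRUE` are imputed; other missing entries
#'   are structural (instrument not applicable) and are left missing.
#' @return list of class `mi_datasets` with `m` completed data.frames.
#' @export
impute_chained <- function(data, m = 20, seed, maxit = 5,
                           exclude = c("participant_id", "nurse_id"),
                           eligible = NULL) {
  if (m < 2) stop_param("m", "must be >= 2")
  if (missing(seed)) stop_param("seed", "a seed is required")
  usable <- setdiff(names(data), exclude)
  miss_frac <- vapply(data[usable], function(x) mean(is.na(x)), 0)
  if (any(miss_frac == 1))
    stop("variable(s) entirely missing: ",
         paste(usable[miss_frac == 1], collapse = ", "), call. = FALSE)
  targets <- usable[miss_frac > 0]

  imputable <- lapply(targets, function(v) {
    el <- if (!is.null(eligible) && v %in% names(eligible)) eligible[[v]]
          else rep(TRUE, nrow(data))
    is.na(data[[v]]) & el
  })
  names(imputable) <- targets
  targets <- targets[vapply(imputable, any, TRUE)]

  set.seed(stage_seed(seed, "impute"))
  out <- vector("list", m)
  for (i in seq_len(m)) {
    cur <- data
    for (v in targets) {
      idx <- imputable[[v]]
      obs <- cur[[v]][!is.na(cur[[v]])]
      cur[[v]][idx] <- sample(obs, sum(idx), replace = TRUE)
    }
    for (it in seq_len(maxit)) {
      for (v in targets) {
        idx <- imputable[[v]]
        preds <- setdiff(usable, v)
        pd <- cur[preds]
        keep <- vapply(pd, function(x) !anyNA(x) && length(unique(x)) > 1, TRUE)
        X <- stats::model.matrix(~ ., data = pd[keep])
        y <- data[[v]]   # original observed values define the fit sample
        obs_rows <- !is.na(y)
        cur[[v]][idx] <-
          if (is.numeric(y)) {
            draw_norm(y[obs_rows], X[obs_rows, , drop = FALSE],
                      X[idx, , drop = FALSE])
          } else {
            lv <- levels(factor(y))
            if (length(lv) == 2)
              draw_logreg(factor(y[obs_rows], levels = lv),
                          X[obs_rows, , drop = FALSE], X[idx, , drop = FALSE], lv)
            else
              draw_polyreg(factor(y[obs_rows], levels = lv),
                           X[obs_rows, , drop = FALSE], X[idx, , drop = FALSE], lv)
          }
      }
    }
    out[[i]] <- cur
  }
  structure(out, class = "mi_datasets", targets = targets, m = m, seed = seed)
}

#' Pool per-dataset effect estimates by Rubin's rules
#'
#' Point estimate = mean of the per-dataset estimates; total variance =
#' within-imputation mean + `(1 + 1/m)` times the between-imputation
#' variance; degrees of freedom by the Barnard-Rubin small-sample
#' adjustment.
#'
#' @param estimates list of `effect_estimate` objects (>= 2).
#' @param model_tag provenance label for the pooled estimate.
#' @param conf_level confidence level, default 0.95.
#' @return an `effect_estimate` with attributes `within`, `between`, `m`.
#' @export
pool_rubin <- function(estimates, model_tag = "mi-pooled", conf_level = 0.95) {
  m <- length(estimates)
  if (m < 2) stop("Rubin pooling needs >= 2 estimates", call. = FALSE)
  q <- vapply(estimates, function(e) e$d, 0)
  se <- vapply(estimates, function(e) e$se, 0)
  nu_com <- mean(vapply(estimates, function(e) e$df, 0))
  W <- mean(se^2)
  B <- stats::var(q)
  Tt <- W + (1 + 1 / m) * B
  if (Tt <= 0) stop("degenerate variance: zero within- and between-imputation variance",
                    call. = FALSE)
  lambda <- (1 + 1 / m) * B / Tt
  df <- if (lambda < .Machine$double.eps) nu_com else {
    df_old <- (m - 1) / lambda^2
    df_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - lambda)
    1 / (1 / df_old + 1 / df_obs)
  }
  est <- effect_estimate(d = mean(q), se = sqrt(Tt), df = df,
                         model_tag = model_tag, conf_level = conf_level,
                         method = "rubin")
  attr(est, "within") <- W; attr(est, "between") <- B; attr(est, "m") <- m
  est
}

# Wide participant-level table used by the imputation model: arm, Table-1
# covariates, baseline and follow-up behavior scores, and a nurse-level
# summary (mean observed D of the nurse's patients).
mi_wide_table <- function(cohort, outcomes) {
  base <- cohort$participants[cohort$participants$wave == "baseline", ]
  sb <- cohort$scores[cohort$scores$wave == "baseline", ]
  sf <- cohort$scores[cohort$scores$wave == "followup", ]
  wide <- base[, c("participant_id", "nurse_id", "arm", "gender", "age",
                   "education", "income", "living", "work", "bmi", "hba1c",
                   "medication_type", "nurse_type", "depression")]
  ib <- match(wide$participant_id, sb$participant_id)
  fi <- match(wide$participant_id, sf$participant_id)
  for (cols in list(c("pa_min", "pa_b", "pa_f"),
                    c("snack_kcal", "snack_b", "snack_f"),
                    c("oha", "oha_b", "oha_f"),
                    c("insulin", "insulin_b", "insulin_f"))) {
    wide[[cols[2]]] <- sb[[cols[1]]][ib]
    wide[[cols[3]]] <- sf[[cols[1]]][fi]
  }
  dmean <- tapply(outcomes$D, outcomes$nurse_id, mean, na.rm = TRUE)
  wide$nurse_mean_d <- as.vector(dmean[wide$nurse_id])
  wide$nurse_mean_d[!is.finite(wide$nurse_mean_d)] <- 0
  wide
}

#' Intention-to-treat mixed-model effect under multiple imputation
#'
#' Builds the participant-level imputation table (arm, covariates, baseline
#' scores, follow-up scores, nurse-level summary), imputes missing
#' follow-up behavior scores and covariates with [impute_chained()]
#' (structural missingness from non-applicable instruments is preserved),
#' rebuilds the composite outcome in each completed dataset using the
#' standardization constants frozen from the complete-pairs sample, fits
#' the nurse-nested mixed model in each, and pools with [pool_rubin()].
#'
#' @param cohort a `trial_cohort` (after [apply_dropout()]).
#' @param m number of imputations, default 20.
#' @param seed imputation stream seed; defaults to the cohort's master seed.
#' @param maxit chained-equation cycles, default 5.
#' @param covariates passed to [fit_mixed()] (`NULL` unadjusted, `TRUE`
#'   adjusted).
#' @param scores optional pre-computed [score_trial()] result; defaults to
#'   the generator scores stored in the cohort.
#' @return list of class `mi_effect`: pooled `effect_estimate` (`pooled`),
#'   per-dataset estimates, the frozen standardization constants.
#' @export
mi_effect <- function(cohort, m = 20, seed = cohort$params$seed, maxit = 5,
                      covariates = NULL, scores = cohort$scores) {
  changes_cc <- behavior_changes(scores)
  outcomes_cc <- compose_outcomes(changes_cc, cohort$participants)
  sds <- attr(outcomes_cc, "pooled_sds")
  wide <- mi_wide_table(cohort, outcomes_cc)

  uses_oha <- wide$medication_type %in% c("oha_only", "both")
  uses_ins <- wide$medication_type %in% c("insulin_only", "both")
  eligible <- list(pa_f = rep(TRUE, nrow(wide)), snack_f = rep(TRUE, nrow(wide)),
                   oha_b = uses_oha, oha_f = uses_oha,
                   insulin_b = uses_ins, insulin_f = uses_ins)
  completed <- impute_chained(wide, m = m, seed = seed, maxit = maxit,
                              eligible = eligible)

  rebuild <- function(w) {
    z <- cbind(pa = (w$pa_f - w$pa_b) / sds$pa,
               snack = -(w$snack_f - w$snack_b) / sds$snack,
               oha = (w$oha_f - w$oha_b) / sds$oha,
               insulin = (w$insulin_f - w$insulin_b) / sds$insulin)
    C <- rowSums(z, na.rm = TRUE)
    data.frame(participant_id = w$participant_id, arm = w$arm,
               nurse_id = w$nurse_id, w[setdiff(ADJUSTED_COVARIATES, names(z))],
               D = C / sds$C)
  }
  fits <- lapply(completed, function(w)
    suppressWarnings(fit_mixed(rebuild(w), covariates = covariates,
                               model_tag = "mi-replicate")))
  tag <- if (isTRUE(covariates)) "adjusted" else "unadjusted"
  pooled <- pool_rubin(fits, model_tag = paste0("mi-", tag))
  structure(list(pooled = pooled, fits = fits, m = m,
                 pooled_sds = sds, complete_case = outcomes_cc),
            class = "mi_effect")
}

#' @export
print.mi_effect <- function(x, ...) {
  print(x$pooled)
  invisible(x)
}
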