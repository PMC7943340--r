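# The primary outcome: a composite standardized change score on the
# Cohen-d scale.
#
# Per behavior, change = follow-up minus baseline (snack kilocalories
# reversed so a larger change is always an improvement); each change is
# divided by the pooled SD of that behavior's changes across both trial
# arms; the standardized changes are summed over the participant's
# applicable behaviors into a composite C; and C is divided by its own
# pooled SD to give D, whose between-arm mean difference reads as Cohen d.

#' Oriented raw change scores per behavior
#'
#' Computes follow-up minus baseline per behavior with the snack change
#' reversed, so that a larger oriented change always means improvement
#' (more PA minutes, fewer kilocalories, higher adherence sums).  A missing
#' wave yields a missing change, never zero; behaviors that do not apply to
#' a participant yield no change entry.
#'
#' @param scores a scores data.frame (see [score_trial()]) containing
#'   `baseline` and `followup` rows.
#' @return data.frame: `participant_id`, oriented changes `pa`, `snack`,
#'   `oha`, `insulin`.
#' @export
behavior_changes <- function(scores) {
  cols <- c(pa = "pa_min", snack = "snack_kcal", oha = "oha", insulin = "insulin")
  b <- scores[scores$wave == "baseline", ]
  f <- scores[scores$wave == "followup", ]
  idx <- match(b$participant_id, f$participant_id)
  out <- data.frame(participant_id = b$participant_id)
  for (nm in names(cols)) {
    delta <- f[[cols[[nm]]]][idx] - b[[cols[[nm]]]]
    out[[nm]] <- ORIENT[[nm]] * delta
  }
  out
}

#' Two-sample pooled standard deviation
#'
#' `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))` across the two trial
#' arms, the classical pooled estimator used to standardize change scores.
#'
#' @param values numeric vector (missing entries dropped).
#' @param arm factor/character of the same length with two levels.
#' @param label quantity name used in error messages.
#' @return the pooled SD (scalar > 0).
#' @export
pooled_sd <- function(values, arm, label = "values") {
  ok <- !is.na(values)
  values <- values[ok]; arm <- factor(arm[ok])
  n <- tapply(values, arm, length)
  if (length(n) < 2 || any(n < 2))
    stop(sprintf("cannot pool %s: each arm needs >= 2 observed values", label),
         call. = FALSE)
  v <- tapply(values, arm, stats::var)
  sp <- sqrt(sum((n - 1) * v) / (sum(n) - 2))
  if (!is.finite(sp) || sp <= 0)
    stop(sprintf("degenerate variance: pooled SD of %s is zero", label),
         call. = FALSE)
  sp
}

#' Standardize behavior changes and compose the primary outcome
#'
#' Divides each behavior's oriented change by the pooled SD of that
#' behavior's observed changes across both arms (computed on the subsample
#' with both waves observed), sums the standardized changes over each
#' participant's applicable observed behaviors into the composite C, and
#' standardizes C by its own pooled SD into D, the primary outcome on the
#' Cohen-d scale.  By construction the pooled SD of every standardized
#' change and of D equals 1 on the standardization sample.
#'
#' The standardization constants are frozen into the result (attribute
#' `pooled_sds`); downstream imputation reuses them rather than re-deriving
#' constants from completed data.
#'
#' @param changes a [behavior_changes()] result.
#' @param participants participant-level data with `participant_id`, `arm`,
#'   `nurse_id` (the baseline rows of a cohort, or any one-row-per-
#'   participant table).
#' @param rescale_by_count divide C by the number of contributing behaviors
#'   before standardizing.  Off by default: the composite is the plain sum
#'   over applicable behaviors.
#' @return data.frame of class `trial_outcomes`: per participant `arm`,
#'   `nurse_id`, `z_pa`, `z_snack`, `z_oha`, `z_insulin`, `n_behaviors`,
#'   `C`, `D`; attributes `pooled_sds` (per behavior and for C).
#' @export
compose_outcomes <- function(changes, participants, rescale_by_count = FALSE) {
  pt <- participants
  if ("wave" %in% names(pt)) pt <- pt[pt$wave == "baseline", ]
  idx <- match(changes$participant_id, pt$participant_id)
  if (anyNA(idx)) stop("changes contain unknown participant ids", call. = FALSE)
  out <- data.frame(participant_id = changes$participant_id,
                    arm = pt$arm[idx], nurse_id = pt$nurse_id[idx])

  sds <- list()
  for (b in BEHAVIORS) {
    obs <- !is.na(changes[[b]])
    if (any(obs)) {
      sds[[b]] <- pooled_sd(changes[[b]], out$arm, label = paste(b, "changes"))
      out[[paste0("z_", b)]] <- changes[[b]] / sds[[b]]
    } else {
      sds[[b]] <- NA_real_
      out[[paste0("z_", b)]] <- NA_real_
    }
  }

  zmat <- as.matrix(out[paste0("z_", BEHAVIORS)])
  out$n_behaviors <- rowSums(!is.na(zmat))
  out$C <- ifelse(out$n_behaviors > 0, rowSums(zmat, na.rm = TRUE), NA_real_)
  if (rescale_by_count) out$C <- out$C / out$n_behaviors
  sds$C <- pooled_sd(out$C, out$arm, label = "composite change scores")
  out$D <- out$C / sds$C

  structure(out, pooled_sds = sds, rescale_by_count = rescale_by_count,
            class = c("trial_outcomes", "data.frame"))
}

#' Between-arm effect on the standardized composite
#'
#' Mean difference in D (intervention minus control) with a pooled-variance
#' two-sample t test and 95% confidence interval.  Because D is scaled to
#' pooled SD 1, the difference reads directly as Cohen d.
#'
#' @param d numeric vector of standardized composite scores (or any
#'   standardized change score; missing entries dropped).
#' @param arm factor/character with levels including `intervention` and
#'   `control`.
#' @param conf_level confidence level, default 0.95.
#' @return an `effect_estimate`: `d`, `ci_low`, `ci_high`, `t`, `df`, `p`,
#'   `model_tag`.
#' @export
arm_effect_d <- function(d, arm, conf_level = 0.95) {
  ok <- !is.na(d)
  d <- d[ok]; arm <- as.character(arm)[ok]
  if (!all(c("intervention", "control") %in% arm))
    stop("both arms must be represented", call. = FALSE)
  x <- d[arm == "intervention"]; y <- d[arm == "control"]
  tt <- stats::t.test(x, y, var.equal = TRUE, conf.level = conf_level)
  effect_estimate(
    d = unname(tt$estimate[1] - tt$estimate[2]),
    se = unname(tt$stderr),
    df = unname(tt$parameter), model_tag = "raw-difference",
    conf_level = conf_level
  )
}

# Common container for effects on the Cohen-d scale.
effect_estimate <- function(d, se, df, model_tag, conf_level = 0.95,
                            method = "t") {
  tval <- d / se
  qt <- stats::qt(1 - (1 - conf_level) / 2, df)
  structure(list(d = d, se = se, ci_low = d - qt * se, ci_high = d + qt * se,
                 t = tval, df = df,
                 p = 2 * stats::pt(-abs(tval), df),
                 model_tag = model_tag, method = method,
                 conf_level = conf_level),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s: d = %.2f (95%% CI %.3f to %.3f), t = %.3f (df %.2f), p = %.3g\n",
              x$model_tag, x$d, x$ci_low, x$ci_high, x$t, x$df, x$p))
  invisible(x)
}
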