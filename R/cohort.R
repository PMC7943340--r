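# Synthetic multibehavior adherence trial cohorts.
#
# The generator reproduces the data structure the analysis pipeline assumes:
# patients nested in nurses, individual randomization stratified by nurse,
# four behavior scores (weekly PA minutes, weekly snack kilocalories, oral
# and insulin ProMAS adherence sums) measured at baseline and 6-month
# follow-up, instrument applicability driven by medication type, a shared
# nurse random intercept inducing a target intraclass correlation on the
# composite change score, and differential dropout between arms.

#' Parameters of a synthetic adherence-trial cohort
#'
#' Defaults mirror the marginals of a published multibehavior adherence
#' trial in type 2 diabetes: baseline PA 868 (SD 1031) min/week, snacks
#' 1746 (SD 1435) kcal/week, oral-medication adherence 13.5 (SD 3.5) of 18,
#' insulin adherence 7.4 (SD 1.8) of 9; 61.5% of patients on oral agents
#' only, 6.7% on insulin only, 31.8% on both; nurse-level intraclass
#' correlation 0.02 on the composite change score; dropout 53% in the
#' intervention arm and 27.5% in the control arm.
#'
#' @param n_nurses number of recruiting nurses (clusters).
#' @param patients_per_nurse patients recruited per nurse.
#' @param allocation_ratio intervention share under individual randomization
#'   (stratified by nurse; both arms always present within a nurse).
#' @param icc target intraclass correlation of the composite change score
#'   attributable to nurses, in `[0, 1)`.
#' @param behavior_baselines named list (`pa`, `snack`, `oha`, `insulin`) of
#'   `c(mean =, sd =)` targets for the observed baseline scores.
#' @param change_sds named vector of target SDs of the observed
#'   follow-up-minus-baseline change per behavior, native units.
#' @param true_effects named vector of per-behavior standardized treatment
#'   effects on the oriented observed change, in pooled-change-SD units
#'   (positive = improvement in the intervention arm).
#' @param applicability fractions of patients using oral agents only,
#'   insulin only, or both; must sum to 1.
#' @param dropout_rate_by_arm named fractions `c(intervention =, control =)`
#'   lost before follow-up.
#' @param dropout_mechanism `"mcar"` (completely at random within arm) or
#'   `"covariate"` (logistic retention model, see `dropout_coef`).
#' @param dropout_coef for the covariate mechanism: a list with elements
#'   `intervention` and `control`, each a named numeric vector of logistic
#'   coefficients on standardized numeric covariates (`age`, `bmi`,
#'   `hba1c`).  Arm intercepts are solved so marginal retention still
#'   matches `dropout_rate_by_arm`.  Zero coefficients reduce to MCAR.
#' @param covariate_effects optional named numeric vector: effect of a
#'   standardized numeric covariate on the shared latent improvement scale
#'   (used to create covariate-outcome dependence, e.g. for
#'   missing-at-random simulations).  Default none.
#' @param seed master seed; every downstream stage derives its own stream.
#' @return an object of class `cohort_params`.
#' @export
cohort_params <- function(n_nurses = 60,
                          patients_per_nurse = 8,
                          allocation_ratio = 0.5,
                          icc = 0.02,
                          behavior_baselines = list(
                            pa      = c(mean = 868,  sd = 1031),
                            snack   = c(mean = 1746, sd = 1435),
                            oha     = c(mean = 13.5, sd = 3.5),
                            insulin = c(mean = 7.4,  sd = 1.8)),
                          change_sds = c(pa = 920, snack = 1200,
                                         oha = 3.1, insulin = 1.5),
                          true_effects = c(pa = 0, snack = 0,
                                           oha = 0, insulin = 0),
                          applicability = c(oha_only = 0.615,
                                            insulin_only = 0.067,
                                            both = 0.318),
                          dropout_rate_by_arm = c(intervention = 0.530,
                                                  control = 0.275),
                          dropout_mechanism = c("mcar", "covariate"),
                          dropout_coef = NULL,
                          covariate_effects = NULL,
                          seed) {
  if (missing(seed)) stop_param("seed", "a master seed is required")
  if (!is.numeric(n_nurses) || n_nurses < 1) stop_param("n_nurses", "must be >= 1")
  if (!is.numeric(patients_per_nurse) || patients_per_nurse < 2)
    stop_param("patients_per_nurse", "must be >= 2 so both arms occur within a nurse")
  check_fraction(allocation_ratio, "allocation_ratio")
  check_fraction(icc, "icc")
  for (b in BEHAVIORS) {
    bl <- behavior_baselines[[b]]
    if (is.null(bl) || is.na(bl[["sd"]]) || bl[["sd"]] <= 0)
      stop_param(paste0("behavior_baselines$", b), "needs mean and sd > 0")
    if (is.na(change_sds[[b]]) || change_sds[[b]] <= 0)
      stop_param(paste0("change_sds[", b, "]"), "must be > 0")
    if (is.na(true_effects[[b]]))
      stop_param(paste0("true_effects[", b, "]"), "must be numeric")
  }
  if (abs(sum(applicability) - 1) > 1e-8 || any(applicability < 0))
    stop_param("applicability", "fractions must be nonnegative and sum to 1")
  for (g in c("intervention", "control"))
    check_fraction(dropout_rate_by_arm[[g]], paste0("dropout_rate_by_arm[", g, "]"))
  dropout_mechanism <- match.arg(dropout_mechanism)

  # Shared nurse intercept variance on the standardized latent change scale.
  # With k applicable behaviors and latent equicorrelation
  # psi = tau2/(1+tau2), the composite ICC is k*psi/(1+(k-1)*psi); solving at
  # the expected applicable count k_bar = 3 + P(both) gives the target icc.
  k_bar <- 3 + applicability[["both"]]
  psi <- icc / (k_bar - (k_bar - 1) * icc)
  tau2 <- psi / (1 - psi)

  structure(list(
    n_nurses = as.integer(n_nurses),
    patients_per_nurse = as.integer(patients_per_nurse),
    allocation_ratio = allocation_ratio,
    icc = icc, tau2 = tau2, k_bar = k_bar,
    behavior_baselines = behavior_baselines,
    change_sds = change_sds,
    true_effects = true_effects[BEHAVIORS],
    applicability = applicability,
    dropout_rate_by_arm = dropout_rate_by_arm,
    dropout_mechanism = dropout_mechanism,
    dropout_coef = dropout_coef,
    covariate_effects = covariate_effects,
    seed = as.integer(seed)
  ), class = "cohort_params")
}

#' @export
print.cohort_params <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d nurses x %d patients (icc %.3f, seed %d)\n",
              x$n_nurses, x$patients_per_nurse, x$icc, x$seed))
  cat("  true effects (d):",
      paste(sprintf("%s=%.2f", BEHAVIORS, x$true_effects), collapse = " "), "\n")
  cat(sprintf("  dropout: intervention %.1f%%, control %.1f%% (%s)\n",
              100 * x$dropout_rate_by_arm[["intervention"]],
              100 * x$dropout_rate_by_arm[["control"]], x$dropout_mechanism))
  invisible(x)
}

#' Per-behavior effects that yield a target composite effect
#'
#' Maps a target Cohen-d on the standardized composite change score to the
#' equal per-behavior standardized effect that produces it, given the
#' applicability mixture and the nurse-induced equicorrelation of the
#' standardized behavior changes.
#'
#' @param d_composite target between-arm effect on the standardized
#'   composite, Cohen-d scale.
#' @param params a [cohort_params()] object (applicability and icc are used).
#' @param calibration optional [calibrate_generator()] result; when given,
#'   the composite variance uses the calibrated loadings and intercept
#'   variance instead of the analytic linear-model approximation.
#' @return named vector of per-behavior effects suitable for `true_effects`.
#' @export
effects_for_composite <- function(d_composite, params, calibration = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  app <- params$applicability
  classes <- list(list(p = app[["oha_only"]], b = c("pa", "snack", "oha")),
                  list(p = app[["insulin_only"]], b = c("pa", "snack", "insulin")),
                  list(p = app[["both"]], b = BEHAVIORS))
  if (is.null(calibration)) {
    psi <- params$tau2 / (1 + params$tau2)
    var_c <- sum(vapply(classes, function(cl) {
      k <- length(cl$b); cl$p * (k + k * (k - 1) * psi)
    }, 0))
  } else {
    lam <- vapply(calibration$behaviors, `[[`, 0, "lambda")
    tau2 <- calibration$tau2
    var_c <- sum(vapply(classes, function(cl) {
      l <- lam[cl$b]
      cl$p * (length(l) + tau2 * (sum(l)^2 - sum(l^2)))
    }, 0))
  }
  delta <- d_composite * sqrt(var_c) / params$k_bar
  stats::setNames(rep(delta, 4), BEHAVIORS)
}

table1_covariates <- function(n) {
  data.frame(
    gender = factor(sample(c("male", "female"), n, TRUE, c(0.676, 0.324)),
                    levels = c("male", "female")),
    age = rnorm(n, 60.2, 6.8),
    education = factor(sample(c("low", "middle", "high"), n, TRUE,
                              c(0.407, 0.229, 0.364)),
                       levels = c("low", "middle", "high")),
    income = factor(ifelse(runif(n) < 0.230, NA,
                           sample(c("under", "above"), n, TRUE, c(0.353, 0.647))),
                    levels = c("under", "above")),
    living = factor(sample(c("together", "alone"), n, TRUE, c(0.776, 0.224)),
                    levels = c("together", "alone")),
    work = factor(sample(c("salaried", "none", "retired", "disabled"), n, TRUE,
                         c(0.433, 0.155, 0.303, 0.109)),
                  levels = c("salaried", "none", "retired", "disabled")),
    bmi = rnorm(n, 31.0, 5.0),
    hba1c = rnorm(n, 56.9, 11.8),
    depression = factor(sample(c("never_past", "current"), n, TRUE,
                               c(0.946, 0.054)),
                        levels = c("never_past", "current"))
  )
}

#' Generate a synthetic trial dataset
#'
#' Draws a full item-level two-wave trial dataset from a calibrated latent
#' model: observed baseline scores match the requested marginals, observed
#' change scores have the requested SDs and the intervention arm exceeds the
#' control arm by `true_effects` pooled change-SDs in expectation, and the
#' shared nurse intercept induces the requested composite-change ICC.  All
#' participants are generated with both waves (`retained = TRUE`); apply
#' attrition afterwards with [apply_dropout()].
#'
#' @param params a [cohort_params()] object.
#' @param include_items emit item-level instrument responses (SQUASH
#'   activity entries, FFQ snack frequencies, ProMAS indicator items)
#'   consistent with the generated scores.  Scoring the emitted items
#'   recovers the generated scores exactly; disabling saves time in large
#'   simulations.
#' @param calibration optional pre-computed [calibrate_generator()] result.
#' @return an object of class `trial_cohort`: a list with `participants`
#'   (one row per participant and wave), `scores` (one row per participant
#'   and wave), `items` (long form, or `NULL`), `nurses`, and `params`.
#' @export
generate_cohort <- function(params, include_items = TRUE, calibration = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  calibration <- calibration %||% calibrate_generator(params)
  set.seed(stage_seed(params$seed, "cohort"))

  J <- params$n_nurses; m <- params$patients_per_nurse; n <- J * m
  nurses <- data.frame(
    nurse_id = sprintf("N%03d", seq_len(J)),
    nurse_type = factor(sample(c("practice", "diabetes"), J, TRUE,
                               c(0.715, 0.285)),
                        levels = c("practice", "diabetes")),
    u = rnorm(J, 0, sqrt(calibration$tau2))
  )

  # individual randomization, stratified by nurse: both arms within a nurse
  n_int <- min(max(round(m * params$allocation_ratio), 1), m - 1)
  arm <- as.vector(vapply(seq_len(J), function(j)
    sample(c(rep("intervention", n_int), rep("control", m - n_int))),
    character(m)))

  pt <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    nurse_id = rep(nurses$nurse_id, each = m),
    arm = factor(arm, levels = c("control", "intervention")),
    table1_covariates(n),
    medication_type = factor(
      sample(c("oha_only", "insulin_only", "both"), n, TRUE,
             params$applicability[c("oha_only", "insulin_only", "both")]),
      levels = c("oha_only", "insulin_only", "both"))
  )
  pt$nurse_type <- nurses$nurse_type[match(pt$nurse_id, nurses$nurse_id)]

  # shared latent improvement: nurse intercept + optional covariate effects
  h <- nurses$u[match(pt$nurse_id, nurses$nurse_id)]
  if (!is.null(params$covariate_effects)) {
    for (v in names(params$covariate_effects)) {
      x <- pt[[v]]
      if (!is.numeric(x)) stop_param("covariate_effects", "only numeric covariates supported")
      h <- h + params$covariate_effects[[v]] * as.vector(scale(x))
    }
  }

  trt <- as.integer(pt$arm == "intervention")
  uses_oha <- pt$medication_type %in% c("oha_only", "both")
  uses_ins <- pt$medication_type %in% c("insulin_only", "both")
  applicable <- cbind(pa = rep(TRUE, n), snack = rep(TRUE, n),
                      oha = uses_oha, insulin = uses_ins)

  base_sc <- fup_sc <- matrix(NA_real_, n, 4, dimnames = list(NULL, BEHAVIORS))
  for (b in BEHAVIORS) {
    cb <- calibration$behaviors[[b]]
    g <- score_transform(b)
    x <- cb$mu + cb$sigma * rnorm(n)
    e <- rnorm(n)
    dlat <- ORIENT[[b]] * (cb$effect_shift * trt + cb$change_scale * h) +
      cb$change_scale * e
    base_sc[, b] <- g(x)
    fup_sc[, b] <- g(x + dlat)
    base_sc[!applicable[, b], b] <- NA
    fup_sc[!applicable[, b], b] <- NA
  }

  scores <- rbind(
    data.frame(participant_id = pt$participant_id, wave = "baseline",
               pa_min = base_sc[, "pa"], snack_kcal = base_sc[, "snack"],
               oha = base_sc[, "oha"], insulin = base_sc[, "insulin"]),
    data.frame(participant_id = pt$participant_id, wave = "followup",
               pa_min = fup_sc[, "pa"], snack_kcal = fup_sc[, "snack"],
               oha = fup_sc[, "oha"], insulin = fup_sc[, "insulin"])
  )

  participants <- rbind(
    transform(pt, wave = "baseline"),
    transform(pt, wave = "followup")
  )
  participants$retained <- TRUE
  ord <- order(participants$participant_id, participants$wave)
  participants <- participants[ord, ]
  rownames(participants) <- NULL

  items <- if (include_items) emit_items(scores, params$seed) else NULL

  structure(list(participants = participants, scores = scores, items = items,
                 nurses = nurses[c("nurse_id", "nurse_type")],
                 params = params),
            class = "trial_cohort")
}

#' @export
print.trial_cohort <- function(x, ...) {
  n <- length(unique(x$participants$participant_id))
  ret <- x$participants[x$participants$wave == "baseline", "retained"]
  cat(sprintf("trial_cohort: %d participants, %d nurses, %d retained (%.1f%%)\n",
              n, nrow(x$nurses), sum(ret), 100 * mean(ret)))
  if (!is.null(x$items)) cat(sprintf("  %d item-level responses\n", nrow(x$items)))
  invisible(x)
}

# Emit item-level responses consistent with the generated scores.  Item
# patterns only need to be valid, not behaviorally realistic: scoring the
# emitted items reproduces the target scores.
emit_items <- function(scores, seed) {
  set.seed(stage_seed(seed, "items"))
  met <- default_met_table(); kcal <- default_kcal_table()
  qual <- met$activity_id[met$met >= 3]
  sub <- met$activity_id[met$met < 3]
  out <- vector("list", 6); oi <- 1

  sc <- scores[!is.na(scores$pa_min), c("participant_id", "wave", "pa_min")]
  nn <- nrow(sc)
  a1 <- sample(qual, nn, TRUE)
  a2 <- sample(qual, nn, TRUE)
  clash <- a2 == a1
  a2[clash] <- qual[(match(a1[clash], qual) %% length(qual)) + 1L]
  share <- runif(nn, 0.2, 0.8)
  d1 <- sample(1:7, nn, TRUE); d2 <- sample(1:7, nn, TRUE)
  m1 <- share * sc$pa_min / d1; m2 <- (1 - share) * sc$pa_min / d2
  # a below-threshold activity for roughly half of the records: excluded by
  # scoring, keeps the exclusion pathway exercised
  has_sub <- runif(nn) < 0.5
  a3 <- sample(sub, nn, TRUE); d3 <- sample(1:7, nn, TRUE)
  m3 <- runif(nn, 10, 60)
  sq <- rbind(
    data.frame(participant_id = sc$participant_id, wave = sc$wave,
               instrument = "squash", item_id = paste0(a1, ".days"), value = d1),
    data.frame(participant_id = sc$participant_id, wave = sc$wave,
               instrument = "squash", item_id = paste0(a1, ".min"), value = m1),
    data.frame(participant_id = sc$participant_id, wave = sc$wave,
               instrument = "squash", item_id = paste0(a2, ".days"), value = d2),
    data.frame(participant_id = sc$participant_id, wave = sc$wave,
               instrument = "squash", item_id = paste0(a2, ".min"), value = m2),
    data.frame(participant_id = sc$participant_id[has_sub], wave = sc$wave[has_sub],
               instrument = "squash", item_id = paste0(a3[has_sub], ".days"),
               value = d3[has_sub]),
    data.frame(participant_id = sc$participant_id[has_sub], wave = sc$wave[has_sub],
               instrument = "squash", item_id = paste0(a3[has_sub], ".min"),
               value = m3[has_sub])
  )
  out[[oi]] <- sq; oi <- oi + 1

  sc <- scores[!is.na(scores$snack_kcal), c("participant_id", "wave", "snack_kcal")]
  nn <- nrow(sc)
  picks <- t(vapply(seq_len(nn), function(i) sample(kcal$snack_id, 3),
                    character(3)))
  w <- matrix(runif(3 * nn), nn, 3); w <- w / rowSums(w)
  ff <- do.call(rbind, lapply(1:3, function(k) {
    kc <- kcal$kcal[match(picks[, k], kcal$snack_id)]
    data.frame(participant_id = sc$participant_id, wave = sc$wave,
               instrument = "ffq", item_id = picks[, k],
               value = w[, k] * sc$snack_kcal / kc)
  }))
  out[[oi]] <- ff; oi <- oi + 1

  for (spec in list(list(col = "oha", n_items = 18L, prefix = "oha_%02d",
                         instrument = "promas_oha"),
                    list(col = "insulin", n_items = 9L, prefix = "ins_%d",
                         instrument = "promas_insulin"))) {
    sc <- scores[!is.na(scores[[spec$col]]),
                 c("participant_id", "wave", spec$col)]
    if (nrow(sc) == 0) next
    k <- as.integer(sc[[spec$col]])
    resp <- t(vapply(k, function(ki) {
      v <- integer(spec$n_items); v[sample.int(spec$n_items, ki)] <- 1L; v
    }, integer(spec$n_items)))
    pm <- data.frame(
      participant_id = rep(sc$participant_id, spec$n_items),
      wave = rep(sc$wave, spec$n_items),
      instrument = spec$instrument,
      item_id = rep(sprintf(spec$prefix, seq_len(spec$n_items)), each = nrow(sc)),
      value = as.vector(resp)
    )
    out[[oi]] <- pm; oi <- oi + 1
  }
  items <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  items <- items[order(items$participant_id, items$wave,
                       items$instrument, items$item_id), ]
  rownames(items) <- NULL
  items
}

#' Apply attrition to a generated cohort
#'
#' Marks participants as retained or lost to follow-up and removes the
#' follow-up rows (participants, scores, items) of those lost.  Under the
#' `"mcar"` mechanism each arm loses its configured fraction completely at
#' random; under `"covariate"` retention follows a logistic model on
#' standardized numeric covariates with arm intercepts solved so marginal
#' retention still matches `1 - dropout_rate_by_arm`.
#'
#' @param cohort a [generate_cohort()] result in which every participant
#'   still has a follow-up row.
#' @param params optional [cohort_params()] override; defaults to the
#'   parameters stored in the cohort.
#' @return the cohort with `retained` flags set and follow-up rows of
#'   dropouts removed.
#' @export
apply_dropout <- function(cohort, params = cohort$params) {
  stopifnot(inherits(cohort, "trial_cohort"))
  base <- cohort$participants[cohort$participants$wave == "baseline", ]
  fup_ids <- cohort$participants$participant_id[cohort$participants$wave == "followup"]
  if (!all(base$participant_id %in% fup_ids))
    stop("apply_dropout() requires follow-up rows for all participants", call. = FALSE)
  set.seed(stage_seed(params$seed, "dropout"))

  p_ret <- numeric(nrow(base))
  for (g in c("intervention", "control")) {
    sel <- base$arm == g
    target <- 1 - params$dropout_rate_by_arm[[g]]
    if (params$dropout_mechanism == "mcar" || is.null(params$dropout_coef)) {
      p_ret[sel] <- target
    } else {
      cf <- params$dropout_coef[[g]] %||% numeric(0)
      lin <- rep(0, sum(sel))
      for (v in names(cf)) lin <- lin + cf[[v]] * as.vector(scale(base[[v]][sel]))
      a <- stats::uniroot(function(a) mean(stats::plogis(a + lin)) - target,
                          c(-20, 20), tol = 1e-10)$root
      p_ret[sel] <- stats::plogis(a + lin)
    }
  }
  retained <- runif(nrow(base)) < p_ret
  names(retained) <- base$participant_id

  keep_fup <- function(df) {
    df[df$wave != "followup" | retained[df$participant_id], , drop = FALSE]
  }
  cohort$participants$retained <- retained[cohort$participants$participant_id]
  cohort$participants <- keep_fup(cohort$participants)
  cohort$scores <- keep_fup(cohort$scores)
  if (!is.null(cohort$items)) {
    cohort$items <- keep_fup(cohort$items)
    rownames(cohort$items) <- NULL
  }
  rownames(cohort$participants) <- rownames(cohort$scores) <- NULL
  cohort
}
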