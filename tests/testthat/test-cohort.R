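test_that("invalid cohort parameters are rejected with the offending field named", {
  expect_error(cohort_params(seed = 1, icc = 1.2), "icc")
  expect_error(cohort_params(seed = 1,
                             dropout_rate_by_arm = c(intervention = 1.0, control = 0.2)),
               "dropout_rate_by_arm")
  expect_error(cohort_params(seed = 1,
                             applicability = c(oha_only = 0.5, insulin_only = 0.5,
                                               both = 0.5)),
               "applicability")
  expect_error(cohort_params(), "seed")
  expect_error(cohort_params(seed = 1, patients_per_nurse = 1), "patients_per_nurse")
})

test_that("generation is bit-reproducible under a fixed seed", {
  p <- cohort_params(n_nurses = 8, seed = 404)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a$participants, b$participants)
  expect_identical(a$scores, b$scores)
  expect_identical(a$items, b$items)
})

test_that("scored baseline marginals match the configured targets", {
  p <- cohort_params(n_nurses = 400, seed = 2101)
  coh <- generate_cohort(p, include_items = FALSE)
  sb <- coh$scores[coh$scores$wave == "baseline", ]
  checks <- list(pa = "pa_min", snack = "snack_kcal", oha = "oha",
                 insulin = "insulin")
  for (b in names(checks)) {
    x <- sb[[checks[[b]]]]
    x <- x[!is.na(x)]
    tgt <- p$behavior_baselines[[b]]
    sem <- tgt[["sd"]] / sqrt(length(x))
    expect_lt(abs(mean(x) - tgt[["mean"]]), 3 * sem)
    # SD of the observed scores, SE approx sd/sqrt(2n)
    expect_lt(abs(sd(x) - tgt[["sd"]]), 3 * tgt[["sd"]] / sqrt(2 * length(x)) +
                0.01 * tgt[["sd"]])
  }
  # change-score SDs are positive and near their targets
  ch <- behavior_changes(coh$scores)
  for (b in names(checks)) {
    s <- sd(ch[[b]], na.rm = TRUE)
    expect_gt(s, 0)
    expect_lt(abs(s - p$change_sds[[b]]) / p$change_sds[[b]], 0.06)
  }
})

test_that("null configuration produces a null composite effect", {
  p <- cohort_params(n_nurses = 150, icc = 0, seed = 515)
  coh <- generate_cohort(p, include_items = FALSE)
  o <- compose_outcomes(behavior_changes(coh$scores), coh$participants)
  e <- arm_effect_d(o$D, o$arm)
  expect_lt(abs(e$d), 3 * e$se)
})

test_that("pipeline composite equals a brute-force oracle recomputation on the same draws", {
  p <- cohort_params(n_nurses = 1250, seed = 606,
                     true_effects = c(pa = 0.4, snack = 0.4, oha = 0.4,
                                      insulin = 0.4))
  coh <- generate_cohort(p, include_items = FALSE)
  sm <- score_matrices(coh)
  d_oracle <- oracle_D(sm$base, sm$fup, sm$arm)
  d_pipe <- pipeline_D(coh)
  expect_lt(max(abs(d_oracle - d_pipe), na.rm = TRUE), 1e-9)
})

test_that("empirical composite ICC converges to the configured value", {
  p <- cohort_params(n_nurses = 200, patients_per_nurse = 8, icc = 0.1,
                     seed = 707)
  coh <- generate_cohort(p, include_items = FALSE)
  o <- compose_outcomes(behavior_changes(coh$scores), coh$participants)
  fit <- lme4::lmer(D ~ 1 + (1 | nurse_id), data = o)
  vc <- as.data.frame(lme4::VarCorr(fit))
  icc_hat <- vc$vcov[1] / sum(vc$vcov)
  # MC SE of the one-way ICC estimator at rho, J clusters of size m
  rho <- 0.1; J <- 200; m <- 8
  mc_se <- sqrt(2 * (1 - rho)^2 * (1 + (m - 1) * rho)^2 / (m * (m - 1) * J))
  expect_lt(abs(icc_hat - rho), 3 * mc_se)
})

test_that("randomization is individual within nurse: both arms in every cluster", {
  p <- cohort_params(n_nurses = 40, seed = 808)
  coh <- generate_cohort(p, include_items = FALSE)
  base <- coh$participants[coh$participants$wave == "baseline", ]
  arms_per_nurse <- tapply(base$arm, base$nurse_id,
                           function(a) length(unique(a)))
  expect_true(all(arms_per_nurse == 2))
})

test_that("dropout reproduces the per-arm retention rates", {
  p <- cohort_params(n_nurses = 400, seed = 909)
  coh <- apply_dropout(generate_cohort(p, include_items = FALSE))
  base <- coh$participants[coh$participants$wave == "baseline", ]
  for (g in c("intervention", "control")) {
    target <- 1 - p$dropout_rate_by_arm[[g]]
    n_g <- sum(base$arm == g)
    ret <- mean(base$retained[base$arm == g])
    expect_lt(abs(ret - target), 3 * sqrt(target * (1 - target) / n_g))
  }
  # follow-up rows exist iff retained
  fup_ids <- coh$participants$participant_id[coh$participants$wave == "followup"]
  expect_setequal(fup_ids, base$participant_id[base$retained])
  expect_true(all(fup_ids %in% coh$scores$participant_id[coh$scores$wave == "followup"]))
})

test_that("zero dropout retains everyone and double application errors", {
  p <- cohort_params(n_nurses = 6, seed = 111,
                     dropout_rate_by_arm = c(intervention = 0, control = 0))
  coh <- apply_dropout(generate_cohort(p, include_items = FALSE))
  expect_true(all(coh$participants$retained))
  p2 <- cohort_params(n_nurses = 10, seed = 112)
  dropped <- apply_dropout(generate_cohort(p2, include_items = FALSE))
  expect_error(apply_dropout(dropped), "follow-up rows")
})

test_that("covariate-dependent dropout follows the logistic link and its null reduces to MCAR", {
  # zero coefficients: same marginal retention as MCAR
  p0 <- cohort_params(n_nurses = 150, seed = 221,
                      dropout_mechanism = "covariate",
                      dropout_coef = list(intervention = c(age = 0),
                                          control = c(age = 0)))
  coh0 <- apply_dropout(generate_cohort(p0, include_items = FALSE))
  base0 <- coh0$participants[coh0$participants$wave == "baseline", ]
  for (g in c("intervention", "control")) {
    target <- 1 - p0$dropout_rate_by_arm[[g]]
    ret <- mean(base0$retained[base0$arm == g])
    expect_lt(abs(ret - target), 3 * sqrt(target * (1 - target) / sum(base0$arm == g)))
  }
  # negative age coefficient: older participants retained less often
  p1 <- cohort_params(n_nurses = 300, seed = 222,
                      dropout_mechanism = "covariate",
                      dropout_coef = list(intervention = c(age = -1),
                                          control = c(age = -1)))
  coh1 <- apply_dropout(generate_cohort(p1, include_items = FALSE))
  base1 <- coh1$participants[coh1$participants$wave == "baseline", ]
  old <- base1$age > stats::median(base1$age)
  expect_gt(mean(base1$retained[!old]), mean(base1$retained[old]))
})
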