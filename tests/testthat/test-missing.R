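small_cohort <- function(seed, n_nurses = 40, effects = 0.25,
                         dropout = c(intervention = 0.4, control = 0.25)) {
  p <- cohort_params(n_nurses = n_nurses, seed = seed,
                     true_effects = c(pa = effects, snack = effects,
                                      oha = effects, insulin = effects),
                     dropout_rate_by_arm = dropout)
  apply_dropout(generate_cohort(p, include_items = FALSE))
}

test_that("chained imputation leaves complete data untouched and is reproducible", {
  set.seed(3)
  df <- data.frame(participant_id = sprintf("P%02d", 1:40),
                   x = rnorm(40), y = rnorm(40),
                   g = factor(sample(c("a", "b"), 40, TRUE)))
  imp <- impute_chained(df, m = 3, seed = 9)
  for (d in imp) expect_identical(d, df)
  # with missingness: observed cells are bitwise identical, missing filled
  df2 <- df; df2$y[c(3, 8, 15)] <- NA
  imp2 <- impute_chained(df2, m = 4, seed = 9)
  for (d in imp2) {
    expect_identical(d$y[-c(3, 8, 15)], df2$y[-c(3, 8, 15)])
    expect_identical(d$x, df2$x)
    expect_false(anyNA(d$y))
  }
  imp3 <- impute_chained(df2, m = 4, seed = 9)
  expect_identical(imp2[[1]]$y, imp3[[1]]$y)
  # different seed: different draws
  imp4 <- impute_chained(df2, m = 4, seed = 10)
  expect_false(identical(imp2[[1]]$y[c(3, 8, 15)], imp4[[1]]$y[c(3, 8, 15)]))
  # fully missing variable is a configuration error
  df3 <- df; df3$y <- NA_real_
  expect_error(impute_chained(df3, m = 2, seed = 1), "entirely missing")
})

test_that("structural (not-applicable) missingness is never imputed", {
  set.seed(8)
  df <- data.frame(participant_id = sprintf("P%02d", 1:30),
                   x = rnorm(30), oha_f = c(rnorm(20), rep(NA, 10)))
  elig <- list(oha_f = c(rep(TRUE, 25), rep(FALSE, 5)))
  imp <- impute_chained(df, m = 2, seed = 4, eligible = elig)
  for (d in imp) {
    expect_false(anyNA(d$oha_f[21:25]))
    expect_true(all(is.na(d$oha_f[26:30])))
  }
})

test_that("Rubin pooling follows the textbook formulas", {
  e <- function(d, se, df = 100) effect_estimate_stub(d, se, df)
  # two estimates 0.2 (SE .1) and 0.4 (SE .1): point 0.3, T = .01 + 1.5*.02
  ests <- list(e(0.2, 0.1), e(0.4, 0.1))
  pooled <- pool_rubin(ests)
  expect_equal(pooled$d, 0.3, tolerance = 1e-12)
  expect_equal(pooled$se^2, 0.01 + 1.5 * 0.02, tolerance = 1e-12)
  expect_lte(pooled$df, 100)
  # identical estimates: pooled equals them, between-variance zero
  same <- pool_rubin(list(e(0.25, 0.08), e(0.25, 0.08), e(0.25, 0.08)))
  expect_equal(same$d, 0.25)
  expect_equal(attr(same, "between"), 0)
  expect_equal(same$se, 0.08)
  expect_error(pool_rubin(list(e(0.2, 0.1))), ">= 2")
})

test_that("pooled CI is at least as wide as the narrowest per-dataset CI", {
  coh <- small_cohort(1501)
  mi <- mi_effect(coh, m = 4, seed = 1501, maxit = 3)
  widths <- vapply(mi$fits, function(f) f$ci_high - f$ci_low, 0)
  expect_gte(mi$pooled$ci_high - mi$pooled$ci_low, min(widths))
  expect_true(is.finite(mi$pooled$p))
})

test_that("scenario imputation matches an independently coded draw on the same stream", {
  set.seed(77)
  o <- data.frame(participant_id = sprintf("P%02d", 1:10),
                  arm = rep(c("intervention", "control"), each = 5),
                  nurse_id = rep(c("N1", "N2"), 5),
                  D = c(0.5, -0.2, NA, 1.1, NA, -0.4, NA, 0.3, NA, -0.9))
  spec <- scenario_spec("pessimistic", "unequal")
  got <- scenario_impute(o, spec, seed = 123)
  # oracle: same stream, intervention arm first, missing filled in row order
  oracle <- o$D
  set.seed(compadhere:::stage_seed(123, "scenario"))
  io <- which(o$arm == "intervention" & is.na(o$D))
  mu_i <- mean(o$D[o$arm == "intervention"], na.rm = TRUE)
  sd_i <- sd(o$D[o$arm == "intervention"], na.rm = TRUE)
  oracle[io] <- rnorm(length(io), mu_i - 1.0 * sd_i, sd_i)
  co <- which(o$arm == "control" & is.na(o$D))
  mu_c <- mean(o$D[o$arm == "control"], na.rm = TRUE)
  sd_c <- sd(o$D[o$arm == "control"], na.rm = TRUE)
  oracle[co] <- rnorm(length(co), mu_c - 1.5 * sd_c, sd_c)
  expect_equal(got$D, oracle, tolerance = 1e-12)
  # observed values untouched, bitwise
  expect_identical(got$D[!is.na(o$D)], o$D[!is.na(o$D)])
  expect_identical(got$D_imputed, is.na(o$D))
})

test_that("zero shift multipliers centre imputations on the arm means", {
  coh <- small_cohort(1601, n_nurses = 120)
  o <- compose_outcomes(behavior_changes(coh$scores), coh$participants)
  spec0 <- scenario_spec("optimistic", "equal", shift_int = 0, shift_ctrl = 0)
  filled <- scenario_impute(o, spec0, seed = 5)
  cc <- arm_effect_d(o$D, o$arm)
  sc <- arm_effect_d(filled$D, filled$arm)
  expect_lt(abs(sc$d - cc$d), 3 * cc$se)
})

test_that("optimistic beats pessimistic on the same data and seed, and variants differ only in the control arm", {
  coh <- small_cohort(1701, n_nurses = 150)
  o <- compose_outcomes(behavior_changes(coh$scores), coh$participants)
  opt <- scenario_impute(o, scenario_spec("optimistic", "equal"), seed = 31)
  pes <- scenario_impute(o, scenario_spec("pessimistic", "equal"), seed = 31)
  d_opt <- arm_effect_d(opt$D, opt$arm)$d
  d_pes <- arm_effect_d(pes$D, pes$arm)$d
  expect_gt(d_opt, d_pes)
  # equal vs unequal: identical intervention-arm draws, different control
  oe <- scenario_impute(o, scenario_spec("optimistic", "equal"), seed = 31)
  ou <- scenario_impute(o, scenario_spec("optimistic", "unequal"), seed = 31)
  ii <- which(oe$D_imputed & oe$arm == "intervention")
  ic <- which(oe$D_imputed & oe$arm == "control")
  expect_identical(oe$D[ii], ou$D[ii])
  expect_false(any(oe$D[ic] == ou$D[ic]))
})

test_that("with no missing data every scenario equals the complete-case estimate", {
  p <- cohort_params(n_nurses = 60, seed = 1801,
                     dropout_rate_by_arm = c(intervention = 0, control = 0))
  coh <- apply_dropout(generate_cohort(p, include_items = FALSE))
  o <- compose_outcomes(behavior_changes(coh$scores), coh$participants)
  suite <- run_sensitivity_suite(o, seed = 8)
  for (e in suite$scenarios)
    expect_equal(e$d, suite$complete_case$d, tolerance = 1e-12)
  # spec coverage is enforced
  expect_error(run_sensitivity_suite(o, specs = list(scenario_spec("optimistic", "equal")),
                                     seed = 1),
               "cover")
})

test_that("scenario draws change with the seed but keep their distribution", {
  set.seed(64)
  o <- data.frame(participant_id = sprintf("P%05d", 1:12000),
                  arm = rep(c("intervention", "control"), each = 6000),
                  nurse_id = "N1",
                  D = c(rnorm(6000, 0.3), rnorm(6000, 0)))
  o$D[sample(12000, 5000)] <- NA
  spec <- scenario_spec("optimistic", "equal")
  a <- scenario_impute(o, spec, seed = 1)
  b <- scenario_impute(o, spec, seed = 2)
  ia <- a$D[a$D_imputed]; ib <- b$D[b$D_imputed]
  expect_false(identical(ia, ib))
  ks <- suppressWarnings(stats::ks.test(ia, ib))
  expect_gt(ks$p.value, 0.001)
})
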