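scores_row <- function(id, wave, pa = NA, snack = NA, oha = NA, insulin = NA) {
  data.frame(participant_id = id, wave = wave, pa_min = pa, snack_kcal = snack,
             oha = oha, insulin = insulin)
}

test_that("raw change scores subtract baseline from follow-up with snacks reversed", {
  sc <- rbind(scores_row("P1", "baseline", pa = 300, snack = 1857, oha = 13),
              scores_row("P1", "followup", pa = 300, snack = 1269, oha = 15),
              scores_row("P2", "baseline", pa = 500, snack = 900, oha = 10,
                         insulin = 6),
              scores_row("P2", "followup", pa = 500, snack = 900, oha = 10,
                         insulin = 6),
              scores_row("P3", "baseline", pa = 100, snack = 1000))
  ch <- behavior_changes(sc)
  # snack 1857 -> 1269 kcal: oriented improvement +588
  expect_equal(ch$snack[ch$participant_id == "P1"], 588)
  expect_equal(ch$oha[ch$participant_id == "P1"], 2)
  # insulin not applicable: no change entry
  expect_true(is.na(ch$insulin[ch$participant_id == "P1"]))
  # identical waves: all changes zero
  expect_equal(unlist(ch[ch$participant_id == "P2", c("pa", "snack", "oha", "insulin")]),
               c(pa = 0, snack = 0, oha = 0, insulin = 0))
  # missing follow-up wave: change is missing, not zero
  expect_true(all(is.na(ch[ch$participant_id == "P3", c("pa", "snack")])))
})

test_that("pooled SD follows the two-sample (n-1)-denominator formula", {
  arm <- c("intervention", "intervention", "control", "control")
  expect_equal(pooled_sd(c(-1, 1, -1, 1), arm), sqrt(2))
  # equal-size arms with SDs 3 and 4 -> sqrt((9+16)/2)
  x1 <- c(-3, 0, 3); x2 <- c(-4, 0, 4)         # sample SDs 3 and 4
  expect_equal(pooled_sd(c(x1, x2), rep(c("intervention", "control"), each = 3)),
               sqrt((9 + 16) / 2))
  # one arm constant: reduces to the varying arm's weighted SD
  x <- c(5, 5, 5, -2, 0, 2)
  g <- rep(c("intervention", "control"), each = 3)
  expect_equal(pooled_sd(x, g), sqrt((0 + 2 * 4) / 4))
  expect_error(pooled_sd(c(1, 2, 3), c("intervention", "intervention", "control")),
               ">= 2")
  expect_error(pooled_sd(rep(1, 6), g), "degenerate|zero")
})

test_that("standardization yields unit pooled SDs and sums only applicable behaviors", {
  set.seed(11)
  n <- 120
  pt <- data.frame(participant_id = sprintf("P%03d", 1:n),
                   arm = rep(c("control", "intervention"), n / 2),
                   nurse_id = rep(sprintf("N%02d", 1:10), each = n / 10))
  ch <- data.frame(participant_id = pt$participant_id,
                   pa = rnorm(n, 0, 300), snack = rnorm(n, 0, 800),
                   oha = rnorm(n, 0, 3), insulin = NA_real_)
  ch$insulin[1:40] <- rnorm(40, 0, 1.5)
  o <- compose_outcomes(ch, pt)
  for (col in c("z_pa", "z_snack", "z_oha", "z_insulin"))
    expect_equal(pooled_sd(o[[col]], o$arm), 1, tolerance = 1e-9)
  expect_equal(pooled_sd(o$D, o$arm), 1, tolerance = 1e-9)
  # participant with only PA and snacks applicable: C = z_pa + z_snack
  ch2 <- ch; ch2$oha[45] <- NA   # row 45 has no insulin either
  o2 <- compose_outcomes(ch2, pt)
  expect_equal(o2$C[45], o2$z_pa[45] + o2$z_snack[45])
  # frozen constants exposed
  expect_true(all(c("pa", "snack", "oha", "insulin", "C") %in%
                  names(attr(o, "pooled_sds"))))
})

test_that("a 12-participant toy table matches the independent oracle exactly", {
  base <- cbind(pa = c(600, 0, 850, 1200, 300, 450, 2000, 100, 700, 950, 60, 480),
                snack = c(1500, 2400, 800, 1746, 3000, 1100, 950, 2000, 1300,
                          1857, 2200, 640),
                oha = c(13, 15, NA, 10, 18, 12, NA, 9, 14, 17, 11, 16),
                insulin = c(NA, 7, 8, NA, 5, NA, 9, 6, NA, 4, 7, NA))
  fup <- cbind(pa = c(760, 150, 850, 1000, 420, 450, 1800, 260, 700, 1150, 0, 480),
               snack = c(1250, 2400, 950, 1269, 2500, 1340, 950, 1700, 1210,
                         1500, 2350, 700),
               oha = c(15, 14, NA, 13, 18, 11, NA, 12, 15, 16, 13, 17),
               insulin = c(NA, 8, 7, NA, 7, NA, 9, 8, NA, 6, 6, NA))
  arm <- rep(c("intervention", "control"), 6)
  pt <- data.frame(participant_id = sprintf("T%02d", 1:12), arm = arm,
                   nurse_id = rep(c("N1", "N2"), each = 6))
  sc <- rbind(
    data.frame(participant_id = pt$participant_id, wave = "baseline",
               pa_min = base[, "pa"], snack_kcal = base[, "snack"],
               oha = base[, "oha"], insulin = base[, "insulin"]),
    data.frame(participant_id = pt$participant_id, wave = "followup",
               pa_min = fup[, "pa"], snack_kcal = fup[, "snack"],
               oha = fup[, "oha"], insulin = fup[, "insulin"]))
  o <- compose_outcomes(behavior_changes(sc), pt)
  expect_equal(o$D, oracle_D(base, fup, arm), tolerance = 1e-12)
})

test_that("the composite is invariant to positive rescaling of one behavior", {
  set.seed(21)
  n <- 80
  pt <- data.frame(participant_id = sprintf("P%03d", 1:n),
                   arm = rep(c("control", "intervention"), n / 2),
                   nurse_id = "N1")
  ch <- data.frame(participant_id = pt$participant_id,
                   pa = rnorm(n, 50, 300), snack = rnorm(n, -100, 900),
                   oha = rnorm(n, 0.5, 3), insulin = rnorm(n, 0, 1.5))
  o1 <- compose_outcomes(ch, pt)
  ch2 <- ch; ch2$pa <- ch$pa * 7.3
  o2 <- compose_outcomes(ch2, pt)
  expect_equal(o1$z_pa, o2$z_pa, tolerance = 1e-12)
  expect_equal(o1$C, o2$C, tolerance = 1e-12)
  expect_equal(o1$D, o2$D, tolerance = 1e-12)
})

test_that("reducing a participant's follow-up snack intake raises their composite", {
  set.seed(31)
  n <- 100
  pt <- data.frame(participant_id = sprintf("P%03d", 1:n),
                   arm = rep(c("control", "intervention"), n / 2),
                   nurse_id = "N1")
  mk_scores <- function(fup_snack) {
    rbind(data.frame(participant_id = pt$participant_id, wave = "baseline",
                     pa_min = rep(600, n), snack_kcal = rep(1700, n),
                     oha = NA_real_, insulin = NA_real_),
          data.frame(participant_id = pt$participant_id, wave = "followup",
                     pa_min = rnorm(n, 600, 300), snack_kcal = fup_snack,
                     oha = NA_real_, insulin = NA_real_))
  }
  fs <- rnorm(n, 1700, 600)
  set.seed(31)
  o1 <- compose_outcomes(behavior_changes(mk_scores(fs)), pt)
  i <- which.min(abs(fs - stats::median(fs)))
  fs2 <- fs; fs2[i] <- fs2[i] - 400
  set.seed(31)
  o2 <- compose_outcomes(behavior_changes(mk_scores(fs2)), pt)
  expect_gt(o2$D[i], o1$D[i])
})

test_that("the arm effect on D is the mean difference with a pooled t test", {
  x <- c(0.2, 0.5, -0.1); y <- c(-0.3, 0.1, 0.0)
  e <- arm_effect_d(c(x, y), rep(c("intervention", "control"), each = 3))
  md <- mean(x) - mean(y)
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  se <- sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(e$d, md, tolerance = 1e-12)
  expect_equal(e$t, md / se, tolerance = 1e-12)
  expect_equal(e$df, 4)
  expect_equal(e$ci_low, md - qt(0.975, 4) * se, tolerance = 1e-12)
  expect_error(arm_effect_d(x, rep("intervention", 3)), "both arms")
  # known shift recovered
  set.seed(99)
  d <- c(rnorm(4000, 0.5), rnorm(4000, 0))
  arm <- rep(c("intervention", "control"), each = 4000)
  e2 <- arm_effect_d(d, arm)
  expect_lt(abs(e2$d - 0.5), 3 * e2$se)
})
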