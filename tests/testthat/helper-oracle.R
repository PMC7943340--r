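# Independent, deliberately plain recomputation of the composite outcome,
# written as explicit loops and textbook formulas so it shares no code with
# the package's vectorized pipeline.

oracle_pooled_sd <- function(x, arm) {
  g1 <- x[arm == "intervention"]; g1 <- g1[!is.na(g1)]
  g2 <- x[arm == "control"]; g2 <- g2[!is.na(g2)]
  n1 <- length(g1); n2 <- length(g2)
  sqrt(((n1 - 1) * stats::var(g1) + (n2 - 1) * stats::var(g2)) / (n1 + n2 - 2))
}

# base, fup: n x 4 matrices with columns pa, snack, oha, insulin (NA where
# a wave is missing or an instrument does not apply); arm: length-n vector.
oracle_D <- function(base, fup, arm) {
  n <- nrow(base)
  behaviors <- c("pa", "snack", "oha", "insulin")
  delta <- matrix(NA_real_, n, 4, dimnames = list(NULL, behaviors))
  for (i in seq_len(n)) {
    for (b in behaviors) {
      d <- fup[i, b] - base[i, b]
      if (b == "snack") d <- -d
      delta[i, b] <- d
    }
  }
  z <- delta
  for (b in behaviors) {
    if (all(is.na(delta[, b]))) next
    sp <- oracle_pooled_sd(delta[, b], arm)
    for (i in seq_len(n)) z[i, b] <- delta[i, b] / sp
  }
  C <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    zi <- z[i, ][!is.na(z[i, ])]
    if (length(zi) > 0) C[i] <- sum(zi)
  }
  C / oracle_pooled_sd(C, arm)
}

# score matrices (baseline/followup) for a cohort, aligned to baseline ids
score_matrices <- function(cohort) {
  sb <- cohort$scores[cohort$scores$wave == "baseline", ]
  sf <- cohort$scores[cohort$scores$wave == "followup", ]
  idx <- match(sb$participant_id, sf$participant_id)
  cols <- c(pa = "pa_min", snack = "snack_kcal", oha = "oha", insulin = "insulin")
  base <- fup <- matrix(NA_real_, nrow(sb), 4,
                        dimnames = list(NULL, names(cols)))
  for (b in names(cols)) {
    base[, b] <- sb[[cols[[b]]]]
    fup[, b] <- sf[[cols[[b]]]][idx]
  }
  pt <- cohort$participants[cohort$participants$wave == "baseline", ]
  arm <- as.character(pt$arm[match(sb$participant_id, pt$participant_id)])
  list(base = base, fup = fup, arm = arm, participant_id = sb$participant_id)
}

# pipeline D aligned with the oracle's row order
pipeline_D <- function(cohort) {
  ch <- behavior_changes(cohort$scores)
  o <- compose_outcomes(ch, cohort$participants)
  o$D[match(cohort$scores$participant_id[cohort$scores$wave == "baseline"],
            o$participant_id)]
}

quiet_fit_mixed <- function(...) suppressWarnings(fit_mixed(...))

effect_estimate_stub <- function(d, se, df = 100) {
  compadhere:::effect_estimate(d, se, df, model_tag = "stub")
}
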