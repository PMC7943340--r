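# Design: sample-size arithmetic with a cluster design effect, and
# simulation-based power for the nurse-nested mixed-model test.

#' Trial design specification
#'
#' @param d_target detectable difference in the primary end point between
#'   arms, Cohen-d scale; default 0.4.
#' @param alpha two-sided type-I error rate; default 0.05.
#' @param power target power; default 0.80.
#' @param icc intraclass correlation attributable to nurses; default 0.02.
#' @param cluster_size expected patients per nurse; default 8 (the
#'   recruitment floor).
#' @param attrition expected fraction lost before follow-up; default 0.50.
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(d_target = 0.4, alpha = 0.05, power = 0.80,
                        icc = 0.02, cluster_size = 8, attrition = 0.50) {
  if (alpha <= 0 || alpha >= 1) stop_param("alpha", "must be in (0,1)")
  if (power <= 0 || power >= 1) stop_param("power", "must be in (0,1)")
  check_fraction(icc, "icc")
  check_fraction(attrition, "attrition")
  if (cluster_size < 1) stop_param("cluster_size", "must be >= 1")
  structure(list(d_target = d_target, alpha = alpha, power = power,
                 icc = icc, cluster_size = cluster_size,
                 attrition = attrition),
            class = "design_spec")
}

#' Required sample size with a cluster design effect
#'
#' Normal-approximation two-sample formula inflated by the design effect
#' `1 + (m - 1) * icc`:
#' `n_group = ceil(2 (z_{1-alpha/2} + z_{power})^2 / d^2 * deff)`,
#' and a baseline inclusion target
#' `ceil(2 n_group / (1 - attrition))` to survive the expected attrition.
#'
#' @param design a [design_spec()].
#' @param n_group optional externally fixed per-group follow-up sample size;
#'   when supplied only the baseline inclusion target is derived from it.
#' @return list: `n_group` (per-group follow-up n), `baseline_total`,
#'   `design_effect`, `design`.
#' @export
required_n <- function(design = design_spec(), n_group = NULL) {
  stopifnot(inherits(design, "design_spec"))
  if (is.null(n_group)) {
    if (design$d_target == 0) stop_param("d_target", "must be nonzero")
    zz <- stats::qnorm(1 - design$alpha / 2) + stats::qnorm(design$power)
    deff <- 1 + (design$cluster_size - 1) * design$icc
    n_group <- ceiling(2 * zz^2 / design$d_target^2 * deff)
  } else {
    deff <- 1 + (design$cluster_size - 1) * design$icc
  }
  list(n_group = as.integer(n_group),
       baseline_total = as.integer(ceiling(2 * n_group / (1 - design$attrition))),
       design_effect = deff,
       design = design)
}

#' Simulation-based power of the primary-outcome test
#'
#' Estimates the rejection rate of the unadjusted nurse-nested mixed-model
#' test at a design point by repeatedly generating cohorts with
#' [generate_cohort()] (individual randomization within nurses, shared
#' nurse intercept at the design ICC, per-behavior effects mapped from the
#' target composite effect with [effects_for_composite()]), running the
#' scoring/composition/fit pipeline, and counting two-sided rejections at
#' `alpha`.
#'
#' @param design a [design_spec()]; `d_target` is the true composite effect
#'   simulated (0 gives the size of the test).
#' @param n_group participants per arm at follow-up (no attrition is
#'   simulated: the design point is the analyzed sample).
#' @param replicates number of simulated trials (>= 100).
#' @param seed master seed for the simulation stream.
#' @param params_template optional [cohort_params()] whose marginals are
#'   used for the cohorts (defaults to the package's published-marginal
#'   defaults).
#' @return list of class `power_estimate`: `power`, `se` (binomial),
#'   `replicates`, `n_group`, `rejections`, `design`.
#' @export
simulate_power <- function(design = design_spec(), n_group, replicates = 500,
                           seed, params_template = NULL) {
  stopifnot(inherits(design, "design_spec"))
  if (replicates < 100) stop_param("replicates", "must be >= 100")
  if (missing(seed)) stop_param("seed", "a seed is required")
  m <- design$cluster_size
  n_nurses <- ceiling(2 * n_group / m)
  base <- params_template %||% cohort_params(seed = 1)
  params <- cohort_params(
    n_nurses = n_nurses, patients_per_nurse = m,
    allocation_ratio = 0.5, icc = design$icc,
    behavior_baselines = base$behavior_baselines,
    change_sds = base$change_sds,
    applicability = base$applicability,
    dropout_rate_by_arm = c(intervention = 0, control = 0),
    seed = 1)
  calib <- calibrate_generator(params)
  params$true_effects <- effects_for_composite(design$d_target, params, calib)
  calib <- recalibrate_effects(calib, params)

  sub_seeds <- (as.numeric(stage_seed(seed, "power")) + seq_len(replicates)) %%
    (2^31 - 1)
  rej <- logical(replicates)
  for (r in seq_len(replicates)) {
    params$seed <- sub_seeds[r]
    coh <- generate_cohort(params, include_items = FALSE, calibration = calib)
    ch <- behavior_changes(coh$scores)
    outc <- compose_outcomes(ch, coh$participants)
    est <- suppressWarnings(fit_mixed(outc, model_tag = "power-replicate"))
    rej[r] <- est$p < design$alpha
  }
  structure(list(power = mean(rej),
                 se = sqrt(mean(rej) * (1 - mean(rej)) / replicates),
                 replicates = replicates, n_group = n_group,
                 rejections = sum(rej), design = design),
            class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("Simulated power: %.1f%% (MC SE %.1f%%) at n = %d/group, d = %.2f, %d replicates\n",
              100 * x$power, 100 * x$se, x$n_group, x$design$d_target,
              x$replicates))
  invisible(x)
}
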