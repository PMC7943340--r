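# Optimistic/pessimistic sensitivity imputation scenarios for the primary
# outcome.
#
# Dropouts' missing standardized composite scores are drawn from a normal
# distribution centred at the arm mean shifted by a multiple of the arm SD:
# +1 SD in both arms (optimistic equal), -1 SD (pessimistic equal), or a
# 1.5 SD shift in the control arm only (the unequal variants, reflecting
# the possibility that control dropouts changed more than intervention
# dropouts).  Scenarios operate directly on the primary outcome D; the
# standardization constants stay frozen at their complete-pairs values.

#' Specify a sensitivity-imputation scenario
#'
#' @param direction `"optimistic"` (dropouts improved, shift sign +1) or
#'   `"pessimistic"` (deteriorated, sign -1).
#' @param variant `"equal"` (1 SD shift in both arms) or `"unequal"`
#'   (1 SD in the intervention arm, 1.5 SD in the control arm).
#' @param shift_int,shift_ctrl override the per-arm SD-shift multipliers.
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(direction = c("optimistic", "pessimistic"),
                          variant = c("equal", "unequal"),
                          shift_int = NULL, shift_ctrl = NULL) {
  direction <- match.arg(direction)
  variant <- match.arg(variant)
  shift_int <- shift_int %||% 1.0
  shift_ctrl <- shift_ctrl %||% if (variant == "equal") 1.0 else 1.5
  if (shift_int < 0 || shift_ctrl < 0)
    stop_param("shift", "multipliers must be >= 0")
  structure(list(direction = direction, variant = variant,
                 sign = if (direction == "optimistic") 1 else -1,
                 shift_int = shift_int, shift_ctrl = shift_ctrl,
                 name = paste(direction, variant, sep = "-")),
            class = "scenario_spec")
}

#' The four standard sensitivity scenarios
#'
#' Optimistic/pessimistic crossed with equal/unequal per-arm shifts.
#' @return named list of [scenario_spec()] objects.
#' @export
default_scenarios <- function() {
  specs <- list(scenario_spec("optimistic", "equal"),
                scenario_spec("optimistic", "unequal"),
                scenario_spec("pessimistic", "equal"),
                scenario_spec("pessimistic", "unequal"))
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Impute missing primary-outcome values under a scenario
#'
#' Each missing D in arm g is drawn from
#' `Normal(mean_g + sign * shift_g * SD_g, SD_g)`, where `mean_g` and
#' `SD_g` are the arm's observed-D moments.  Observed values are never
#' touched.  Draws are reproducible: the scenario stream is seeded from
#' `seed`, and missing entries are filled in row order, intervention arm
#' first, then control.
#'
#' @param outcomes a [compose_outcomes()] result (or data.frame with `D`,
#'   `arm`).
#' @param spec a [scenario_spec()].
#' @param seed scenario stream seed.
#' @return `outcomes` with missing `D` filled and a logical column
#'   `D_imputed`.
#' @export
scenario_impute <- function(outcomes, spec, seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (missing(seed)) stop_param("seed", "a seed is required")
  out <- outcomes
  out$D_imputed <- is.na(out$D)
  set.seed(stage_seed(seed, "scenario"))
  for (g in c("intervention", "control")) {
    sel <- out$arm == g
    obs <- out$D[sel & !out$D_imputed]
    if (length(obs) < 2)
      stop(sprintf("scenario error: arm %s has < 2 observed outcomes", g),
           call. = FALSE)
    mu <- mean(obs); sdv <- stats::sd(obs)
    shift <- if (g == "intervention") spec$shift_int else spec$shift_ctrl
    miss <- which(sel & out$D_imputed)
    if (length(miss))
      out$D[miss] <- rnorm(length(miss), mu + spec$sign * shift * sdv, sdv)
  }
  out
}

#' Run the four-scenario sensitivity suite
#'
#' Applies each scenario to the outcomes, fits the unadjusted nurse-nested
#' mixed model on each completed dataset, and returns one tagged estimate
#' per scenario alongside the complete-case estimate.
#'
#' @param outcomes a [compose_outcomes()] result with missing D for
#'   dropouts.
#' @param specs list of [scenario_spec()]s; default [default_scenarios()].
#' @param seed scenario stream seed.
#' @return list of class `sensitivity_suite`: `complete_case` and
#'   `scenarios`, all `effect_estimate`s tagged `scenario:<name>`.
#' @export
run_sensitivity_suite <- function(outcomes, specs = default_scenarios(), seed) {
  dirs <- vapply(specs, `[[`, "", "direction")
  vars <- vapply(specs, `[[`, "", "variant")
  if (!all(c("optimistic", "pessimistic") %in% dirs) ||
      !all(c("equal", "unequal") %in% vars))
    stop("specs must cover {optimistic, pessimistic} x {equal, unequal}",
         call. = FALSE)
  cc <- suppressWarnings(fit_mixed(outcomes[!is.na(outcomes$D), ],
                                   model_tag = "complete-case"))
  est <- lapply(specs, function(sp) {
    filled <- scenario_impute(outcomes, sp, seed)
    suppressWarnings(fit_mixed(filled, model_tag = paste0("scenario:", sp$name)))
  })
  names(est) <- vapply(specs, `[[`, "", "name")
  structure(list(complete_case = cc, scenarios = est, seed = seed),
            class = "sensitivity_suite")
}

#' @export
print.sensitivity_suite <- function(x, ...) {
  print(x$complete_case)
  for (e in x$scenarios) print(e)
  invisible(x)
}
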