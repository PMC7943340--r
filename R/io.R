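# File formats and the analysis driver.
#
# CSVs are UTF-8, comma-delimited, "." decimal, header row, empty field =
# missing.  JSON outputs carry full-precision numbers; the markdown report
# rounds for display.

FACTOR_LEVELS <- list(
  arm = c("control", "intervention"),
  gender = c("male", "female"),
  education = c("low", "middle", "high"),
  income = c("under", "above"),
  living = c("together", "alone"),
  work = c("salaried", "none", "retired", "disabled"),
  medication_type = c("oha_only", "insulin_only", "both"),
  nurse_type = c("practice", "diabetes"),
  depression = c("never_past", "current")
)

#' Write a trial dataset to CSV files
#'
#' Emits `participants.csv` (one row per participant and wave: identifiers,
#' arm, covariates, retention) and, when present, `items.csv` (long form:
#' participant, wave, instrument, item, value) and `scores.csv`.
#'
#' @param cohort a `trial_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_trial_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(cohort$items))
    utils::write.csv(cohort$items, file.path(dir, "items.csv"),
                     row.names = FALSE, na = "")
  if (!is.null(cohort$scores))
    utils::write.csv(cohort$scores, file.path(dir, "scores.csv"),
                     row.names = FALSE, na = "")
  invisible(dir)
}

#' Read a trial dataset from CSV files
#'
#' Inverse of [write_trial_csv()]; factor columns are restored with their
#' canonical level order so a write/read cycle is loss-free.
#'
#' @param dir directory containing `participants.csv` and optionally
#'   `items.csv` / `scores.csv`.
#' @return a `trial_cohort` (without generator parameters).
#' @export
read_trial_csv <- function(dir) {
  pfile <- file.path(dir, "participants.csv")
  if (!file.exists(pfile)) stop("participants.csv not found in ", dir, call. = FALSE)
  pt <- utils::read.csv(pfile, stringsAsFactors = FALSE, na.strings = "")
  for (v in names(FACTOR_LEVELS))
    if (v %in% names(pt)) pt[[v]] <- factor(pt[[v]], levels = FACTOR_LEVELS[[v]])
  pt$retained <- as.logical(pt$retained)
  items <- NULL
  if (file.exists(file.path(dir, "items.csv")))
    items <- utils::read.csv(file.path(dir, "items.csv"),
                             stringsAsFactors = FALSE, na.strings = "")
  scores <- NULL
  if (file.exists(file.path(dir, "scores.csv")))
    scores <- utils::read.csv(file.path(dir, "scores.csv"),
                              stringsAsFactors = FALSE, na.strings = "")
  nurses <- unique(pt[, c("nurse_id", "nurse_type")])
  rownames(nurses) <- NULL
  structure(list(participants = pt, scores = scores, items = items,
                 nurses = nurses, params = NULL),
            class = "trial_cohort")
}

#' Read a run configuration (YAML or JSON)
#'
#' The configuration names either an input dataset directory (`input$dir`)
#' or a `synthesis` block of [cohort_params()] fields (exactly one of the
#' two), a master `seed`, an `output_dir`, optional scoring-table paths
#' (`tables$met`, `tables$kcal`) and an `analysis` block (`m_imputations`,
#' `adjusted`, `alpha`, `per_behavior`).
#'
#' @param path configuration file; format chosen by extension
#'   (`.yaml`/`.yml` or `.json`).
#' @return the validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  has_input <- !is.null(cfg$input$dir)
  has_synth <- !is.null(cfg$synthesis)
  if (has_input == has_synth)
    stop("config must name exactly one of input$dir or a synthesis block",
         call. = FALSE)
  if (is.null(cfg$seed)) stop("config must carry a master seed", call. = FALSE)
  cfg$analysis <- cfg$analysis %||% list()
  cfg
}

params_from_config <- function(cfg) {
  sy <- cfg$synthesis
  args <- list(seed = cfg$seed)
  for (f in c("n_nurses", "patients_per_nurse", "allocation_ratio", "icc"))
    if (!is.null(sy[[f]])) args[[f]] <- sy[[f]]
  if (!is.null(sy$dropout))
    args$dropout_rate_by_arm <- c(intervention = sy$dropout$intervention,
                                  control = sy$dropout$control)
  if (!is.null(sy$true_effects))
    args$true_effects <- unlist(sy$true_effects)[BEHAVIORS]
  p <- do.call(cohort_params, args)
  if (!is.null(sy$composite_effect))
    p$true_effects <- effects_for_composite(sy$composite_effect, p)
  p
}

est_to_list <- function(e) {
  e[c("d", "ci_low", "ci_high", "t", "df", "p", "se", "model_tag", "method")]
}

or_to_list <- function(o) o[c("predictor", "or", "ci_low", "ci_high", "p")]

#' Run the full trial analysis from a configuration
#'
#' Loads or synthesizes the dataset, scores items, builds the composite
#' outcome, estimates intention-to-treat effects under multiple imputation
#' (unadjusted, and covariate-adjusted if configured), the per-protocol
#' complete-case effects (overall and per behavior), the four-scenario
#' sensitivity suite, and the attrition model; writes `outcomes.csv`,
#' `effects.json`, `sensitivity.json`, `attrition.json` and `report.md`
#' into the output directory.
#'
#' @param config a configuration list from [read_run_config()] (or a path).
#' @return list with all fitted objects, invisibly; side effect: files in
#'   `config$output_dir`.
#' @export
run_trial_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  outdir <- config$output_dir %||% "."
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$input$dir)) {
    cohort <- read_trial_csv(config$input$dir)
  } else {
    params <- params_from_config(config)
    cohort <- apply_dropout(generate_cohort(params))
  }
  met <- if (!is.null(config$tables$met)) read_met_table(config$tables$met)
         else default_met_table()
  kcal <- if (!is.null(config$tables$kcal)) read_kcal_table(config$tables$kcal)
          else default_kcal_table()
  scores <- if (!is.null(cohort$items)) score_trial(cohort, met, kcal)
            else cohort$scores

  changes <- behavior_changes(scores)
  outcomes <- compose_outcomes(changes, cohort$participants)
  utils::write.csv(outcomes, file.path(outdir, "outcomes.csv"),
                   row.names = FALSE, na = "")

  an <- config$analysis
  m <- an$m_imputations %||% 20
  seed <- config$seed

  effects <- list()
  mi_un <- mi_effect(cohort, m = m, seed = seed, scores = scores)
  effects[["mi-unadjusted"]] <- mi_un$pooled
  if (isTRUE(an$adjusted)) {
    mi_adj <- mi_effect(cohort, m = m, seed = seed, covariates = TRUE,
                        scores = scores)
    effects[["mi-adjusted"]] <- mi_adj$pooled
  }
  pp <- suppressWarnings(fit_mixed(outcomes[!is.na(outcomes$D), ],
                                   model_tag = "per-protocol"))
  effects[["per-protocol"]] <- pp
  for (b in BEHAVIORS) {
    zb <- paste0("z_", b)
    sub <- outcomes[!is.na(outcomes[[zb]]), ]
    if (nrow(sub) > 4)
      effects[[paste0("per-protocol-", b)]] <-
        suppressWarnings(fit_mixed(sub, outcome = zb,
                                   model_tag = paste0("per-protocol-", b)))
  }

  sens <- run_sensitivity_suite(outcomes, seed = seed)
  attr_fit <- attrition_logistic(cohort$participants)

  ej <- lapply(effects, est_to_list)
  jsonlite::write_json(ej, file.path(outdir, "effects.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  sj <- c(list(`complete-case` = est_to_list(sens$complete_case)),
          lapply(sens$scenarios, est_to_list))
  jsonlite::write_json(sj, file.path(outdir, "sensitivity.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(lapply(attr_fit, or_to_list),
                       file.path(outdir, "attrition.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_report(ej, file.path(outdir, "report.md"), sensitivity = sj,
               attrition = lapply(attr_fit, or_to_list))

  invisible(list(cohort = cohort, scores = scores, outcomes = outcomes,
                 effects = effects, sensitivity = sens, attrition = attr_fit))
}

fmt_est_row <- function(name, e) {
  sprintf("| %s | %.2f | %.3f to %.3f | %.3f (%.2f) | %.3g |\n",
          name, e$d, e$ci_low, e$ci_high, e$t, e$df, e$p)
}

#' Write the human-readable analysis report
#'
#' Renders effect estimates (as serialized in `effects.json`) into a
#' markdown report with primary-outcome, per-behavior and sensitivity
#' sections.  The report is a pure function of its inputs, so it
#' regenerates deterministically from the JSON artifacts alone.
#'
#' @param effects named list of serialized effect estimates (the
#'   `effects.json` content).
#' @param path output file.
#' @param sensitivity,attrition optional serialized sensitivity/attrition
#'   lists.
#' @return `path`, invisibly.
#' @export
write_report <- function(effects, path, sensitivity = NULL, attrition = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) cat(..., file = con, sep = "")
  w("# Trial analysis report\n\n")
  w("## Primary outcome (standardized composite change score)\n\n")
  w("| Model | Cohen d | 95% CI | t (df) | p |\n|---|---|---|---|---|\n")
  for (key in intersect(c("mi-unadjusted", "mi-adjusted", "per-protocol"),
                        names(effects)))
    w(fmt_est_row(key, effects[[key]]))
  beh <- grep("^per-protocol-", names(effects), value = TRUE)
  if (length(beh)) {
    w("\n## Separate behaviors (per-protocol, unadjusted)\n\n")
    w("| Behavior | Cohen d | 95% CI | t (df) | p |\n|---|---|---|---|---|\n")
    for (key in beh) w(fmt_est_row(sub("per-protocol-", "", key), effects[[key]]))
  }
  if (!is.null(sensitivity)) {
    w("\n## Sensitivity scenarios (primary outcome)\n\n")
    w("| Scenario | Cohen d | 95% CI | t (df) | p |\n|---|---|---|---|---|\n")
    for (key in names(sensitivity)) w(fmt_est_row(key, sensitivity[[key]]))
  }
  if (!is.null(attrition)) {
    w("\n## Attrition\n\n| Predictor | OR | 95% CI | p |\n|---|---|---|---|\n")
    for (o in attrition)
      w(sprintf("| %s | %.2f | %.3f to %.3f | %.3g |\n",
                o$predictor, o$or, o$ci_low, o$ci_high, o$p))
  }
  invisible(path)
}
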