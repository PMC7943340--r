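# Questionnaire scoring: SQUASH MET-minutes, FFQ snack kilocalories, and
# ProMAS medication-adherence sums.
#
# MET values per activity and kilocalories per snack portion are
# configuration data, not code: the package ships documented default tables
# under inst/extdata and every run should log which tables it used.

.table_cache <- new.env(parent = emptyenv())

#' Read a MET table
#'
#' A MET table maps SQUASH activity categories to metabolic-equivalent
#' values.  CSV columns: `activity_id`, optional `label`, `met` (> 0).
#'
#' @param path CSV file path.
#' @return a data.frame of class `met_table`.
#' @export
read_met_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("activity_id", "met") %in% names(tab)))
    stop("MET table needs columns activity_id and met", call. = FALSE)
  if (any(!is.finite(tab$met)) || any(tab$met <= 0))
    stop("all MET values must be > 0", call. = FALSE)
  if (anyDuplicated(tab$activity_id)) stop("duplicate activity_id", call. = FALSE)
  class(tab) <- c("met_table", "data.frame")
  tab
}

#' Read a kilocalorie table
#'
#' Maps FFQ snack items to kilocalories per portion.  CSV columns:
#' `snack_id`, optional `label`, `kcal` (> 0).
#'
#' @param path CSV file path.
#' @return a data.frame of class `kcal_table`.
#' @export
read_kcal_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("snack_id", "kcal") %in% names(tab)))
    stop("kcal table needs columns snack_id and kcal", call. = FALSE)
  if (any(!is.finite(tab$kcal)) || any(tab$kcal <= 0))
    stop("all kcal values must be > 0", call. = FALSE)
  if (anyDuplicated(tab$snack_id)) stop("duplicate snack_id", call. = FALSE)
  class(tab) <- c("kcal_table", "data.frame")
  tab
}

#' @rdname read_met_table
#' @export
default_met_table <- function() {
  if (is.null(.table_cache$met))
    .table_cache$met <- read_met_table(
      system.file("extdata", "met_table.csv", package = "compadhere"))
  .table_cache$met
}

#' @rdname read_kcal_table
#' @export
default_kcal_table <- function() {
  if (is.null(.table_cache$kcal))
    .table_cache$kcal <- read_kcal_table(
      system.file("extdata", "kcal_table.csv", package = "compadhere"))
  .table_cache$kcal
}

#' Score SQUASH activity entries into weekly PA minutes
#'
#' Sums `days_per_week * daily_minutes` over entries whose activity has a
#' MET value at or above the moderate-intensity threshold; lighter
#' activities are excluded.  The threshold comparison is inclusive
#' (`MET >= 3` counts as at least moderate).
#'
#' @param entries data.frame with columns `activity_id`, `days_per_week`
#'   (0-7) and `daily_minutes` (>= 0).  Durations reported as hours must be
#'   normalized to minutes before scoring.
#' @param met a MET table ([default_met_table()] by default).
#' @param threshold minimum MET value for an activity to count; default 3.
#' @return weekly physical-activity minutes (scalar, >= 0).
#' @export
score_squash <- function(entries, met = default_met_table(), threshold = 3) {
  if (nrow(entries) == 0) return(0)
  if (any(entries$days_per_week < 0 | entries$days_per_week > 7))
    stop("days_per_week must lie in [0, 7]", call. = FALSE)
  if (any(!is.finite(entries$daily_minutes)) || any(entries$daily_minutes < 0))
    stop("daily_minutes must be finite and >= 0", call. = FALSE)
  mv <- met$met[match(entries$activity_id, met$activity_id)]
  if (anyNA(mv))
    stop("unknown activity_id: ",
         paste(unique(entries$activity_id[is.na(mv)]), collapse = ", "),
         call. = FALSE)
  keep <- mv >= threshold
  sum(entries$days_per_week[keep] * entries$daily_minutes[keep])
}

#' Score FFQ snack entries into weekly kilocalories
#'
#' @param entries data.frame with columns `snack_id` and `weekly_frequency`
#'   (portions per week, >= 0; fractional frequencies such as a portion
#'   every other week are allowed).
#' @param kcal a kilocalorie table ([default_kcal_table()] by default).
#' @return weekly kilocalorie intake from the listed snacks (scalar, >= 0).
#' @export
score_ffq <- function(entries, kcal = default_kcal_table()) {
  if (nrow(entries) == 0) return(0)
  if (any(!is.finite(entries$weekly_frequency)) || any(entries$weekly_frequency < 0))
    stop("weekly_frequency must be finite and >= 0", call. = FALSE)
  kc <- kcal$kcal[match(entries$snack_id, kcal$snack_id)]
  if (anyNA(kc))
    stop("unknown snack_id: ",
         paste(unique(entries$snack_id[is.na(kc)]), collapse = ", "),
         call. = FALSE)
  sum(entries$weekly_frequency * kc)
}

promas_sum <- function(responses, n_items, max_missing) {
  if (length(responses) != n_items)
    stop(sprintf("expected %d ProMAS responses, got %d", n_items,
                 length(responses)), call. = FALSE)
  if (!all(responses %in% c(0, 1, NA)))
    stop("ProMAS responses must be 0 (non-adherent), 1 (adherent) or NA",
         call. = FALSE)
  n_miss <- sum(is.na(responses))
  if (n_miss > max_missing)
    return(list(score = NA_integer_, flagged = FALSE, n_missing = n_miss))
  # missing items scored as non-adherent (conservative), record flagged
  list(score = as.integer(sum(responses, na.rm = TRUE)),
       flagged = n_miss > 0, n_missing = n_miss)
}

#' Score the 18-item ProMAS oral-medication adherence scale
#'
#' Counts adherent responses; higher is better adherence (0-18).  If at most
#' `max_missing` items are missing they are scored as non-adherent and the
#' record is flagged; with more missing items the score is missing.
#'
#' @param responses 18 binary indicators (1 adherent, 0 non-adherent, NA).
#' @param max_missing maximum number of missing items tolerated; default 2.
#' @return list with `score`, `flagged`, `n_missing`.
#' @export
score_promas <- function(responses, max_missing = 2) {
  promas_sum(responses, 18L, max_missing)
}

#' Score the 9-item insulin-therapy adaptation of ProMAS
#'
#' As [score_promas()] with 9 items (score range 0-9) and at most
#' `max_missing = 1` missing item tolerated.
#'
#' @param responses 9 binary indicators.
#' @param max_missing default 1.
#' @return list with `score`, `flagged`, `n_missing`.
#' @export
score_promas_insulin <- function(responses, max_missing = 1) {
  promas_sum(responses, 9L, max_missing)
}

#' Score all item-level responses of a trial dataset
#'
#' Vectorized application of the four instrument scoring rules to a long
#' item table (`participant_id`, `wave`, `instrument`, `item_id`, `value`).
#' SQUASH rows encode activity entries as `<activity>.days` /
#' `<activity>.min` item pairs.  ProMAS scores are only reported for
#' participants whose medication type makes the instrument applicable.
#'
#' @param cohort a `trial_cohort`, or a list with `items` and
#'   `participants` data.frames.
#' @param met,kcal scoring tables.
#' @param threshold SQUASH MET threshold.
#' @return data.frame: `participant_id`, `wave`, `pa_min`, `snack_kcal`,
#'   `oha`, `insulin`, `oha_flagged`, `insulin_flagged`.
#' @export
score_trial <- function(cohort, met = default_met_table(),
                        kcal = default_kcal_table(), threshold = 3) {
  items <- cohort$items
  if (is.null(items)) stop("cohort has no item-level responses", call. = FALSE)
  pt <- cohort$participants
  key <- unique(pt[, c("participant_id", "wave", "medication_type")])
  out <- key[order(key$participant_id, key$wave), c("participant_id", "wave")]
  med <- key$medication_type[match(paste(out$participant_id, out$wave),
                                   paste(key$participant_id, key$wave))]
  kid <- paste(out$participant_id, out$wave)

  sq <- items[items$instrument == "squash", ]
  if (nrow(sq)) {
    act <- sub("\\.(days|min)$", "", sq$item_id)
    fld <- sub("^.*\\.", "", sq$item_id)
    mv <- met$met[match(act, met$activity_id)]
    if (anyNA(mv))
      stop("unknown activity_id: ", paste(unique(act[is.na(mv)]), collapse = ", "),
           call. = FALSE)
    k <- paste(sq$participant_id, sq$wave, act)
    days <- sq$value[fld == "days"][match(k[fld == "min"], k[fld == "days"])]
    mins <- sq$value[fld == "min"]
    qual <- mv[fld == "min"] >= threshold
    contrib <- days * mins * qual
    pa <- rowsum(contrib, paste(sq$participant_id, sq$wave)[fld == "min"])
    out$pa_min <- pa[match(kid, rownames(pa)), 1]
  } else out$pa_min <- NA_real_

  ff <- items[items$instrument == "ffq", ]
  if (nrow(ff)) {
    kc <- kcal$kcal[match(ff$item_id, kcal$snack_id)]
    if (anyNA(kc))
      stop("unknown snack_id: ", paste(unique(ff$item_id[is.na(kc)]), collapse = ", "),
           call. = FALSE)
    sn <- rowsum(ff$value * kc, paste(ff$participant_id, ff$wave))
    out$snack_kcal <- sn[match(kid, rownames(sn)), 1]
  } else out$snack_kcal <- NA_real_

  score_promas_block <- function(instr, n_items, max_missing, uses) {
    px <- items[items$instrument == instr, ]
    score <- rep(NA_real_, nrow(out)); flag <- rep(FALSE, nrow(out))
    if (nrow(px)) {
      k <- paste(px$participant_id, px$wave)
      ssum <- rowsum(px$value, k, na.rm = TRUE)
      nmiss <- n_items - rowsum(as.numeric(!is.na(px$value)), k)
      idx <- match(kid, rownames(ssum))
      score <- ssum[idx, 1]
      nm <- nmiss[idx, 1]
      score[!is.na(nm) & nm > max_missing] <- NA
      flag <- !is.na(nm) & nm > 0 & nm <= max_missing
    }
    score[!uses] <- NA
    list(score = score, flag = flag & uses)
  }
  uses_oha <- med %in% c("oha_only", "both")
  uses_ins <- med %in% c("insulin_only", "both")
  ob <- score_promas_block("promas_oha", 18L, 2L, uses_oha)
  ib <- score_promas_block("promas_insulin", 9L, 1L, uses_ins)
  out$oha <- ob$score; out$insulin <- ib$score
  out$oha_flagged <- ob$flag; out$insulin_flagged <- ib$flag
  rownames(out) <- NULL
  out
}
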