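# Per-participant performance/confidence summaries, cohort calibration
# curves, and discrimination (confidence in correct vs incorrect answers).
#
# All confidence means are kept on the raw 0-100 scale internally; the
# 50-100 probability mapping is applied only when a curve or table is
# meant for presentation, via to_probability_scale().

#' Summarize one participant's scored responses
#'
#' @param scored data.frame of scored responses for a single participant,
#'   as produced by [score_responses()] (columns `confidence`, `correct`).
#' @param participant_id optional id to stamp on the summary; defaults to
#'   the (single) id found in `scored`.
#' @return a one-row data.frame with `participant_id`, `n_answered`,
#'   `n_correct`, `mean_confidence`, `mean_conf_correct`,
#'   `mean_conf_incorrect` and `discrimination` (the difference in mean
#'   confidence between correct and incorrect answers; `NA` when the
#'   participant has no correct or no incorrect answers).
#' @export
summarize_participant <- function(scored, participant_id = NULL) {
  .require_columns(scored, c("confidence", "correct"), "scored")
  if (nrow(scored) == 0) stop("no scored responses for participant", call. = FALSE)
  if (is.null(participant_id)) {
    ids <- unique(scored$participant_id)
    if (length(ids) > 1) {
      stop("scored responses span multiple participants; use summarize_participants()",
           call. = FALSE)
    }
    participant_id <- if (length(ids)) ids else NA
  }
  # rows with correct = NA are x = 0 responses under the 'excluded'
  # policy: they still count as answered but are excluded entirely from
  # accuracy and confidence aggregation
  n_answered <- nrow(scored)
  keep <- !is.na(scored$correct)
  n_correct <- sum(scored$correct[keep] == 1L)
  conf_correct <- scored$confidence[keep & scored$correct == 1L]
  conf_incorrect <- scored$confidence[keep & scored$correct == -1L]
  mc_corr <- if (length(conf_correct)) mean(conf_correct) else NA_real_
  mc_inc <- if (length(conf_incorrect)) mean(conf_incorrect) else NA_real_
  data.frame(
    participant_id = participant_id,
    n_answered = n_answered,
    n_correct = n_correct,
    mean_confidence = if (any(keep)) mean(scored$confidence[keep]) else NA_real_,
    mean_conf_correct = mc_corr,
    mean_conf_incorrect = mc_inc,
    discrimination = mc_corr - mc_inc
  )
}

#' Summarize all participants in a scored response table
#'
#' @param scored data.frame from [score_responses()].
#' @param demographics optional data.frame keyed by `participant_id`
#'   whose remaining columns (e.g. `profile`, `advanced_stats`) are
#'   joined onto the summaries.
#' @return data.frame with one row per participant (see
#'   [summarize_participant()]).
#' @export
summarize_participants <- function(scored, demographics = NULL) {
  .require_columns(scored, c("participant_id", "confidence", "correct"), "scored")
  pieces <- lapply(split(scored, scored$participant_id, drop = TRUE),
                   summarize_participant)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  if (!is.null(demographics)) {
    .require_columns(demographics, "participant_id", "demographics")
    j <- match(out$participant_id, demographics$participant_id)
    extra <- demographics[j, setdiff(names(demographics), "participant_id"), drop = FALSE]
    out <- cbind(out, extra)
    rownames(out) <- NULL
  }
  out
}

#' Cohort calibration curve: confidence as a function of performance
#'
#' Groups participants by their number of correct answers and reports,
#' per level, the mean and SEM of per-participant mean confidence mapped
#' onto the 50-100 probability scale. Performance levels with no
#' participants are reported with `n = 0` and `NA` means so the curve
#' always spans 0..`n_claims`.
#'
#' @param summaries data.frame from [summarize_participants()].
#' @param n_claims number of claims defining the performance range
#'   (default 12, i.e. two exercises of six claims).
#' @return data.frame with columns `n_correct`, `mean_confidence`
#'   (probability scale), `sem`, `n_participants`.
#' @export
calibration_curve <- function(summaries, n_claims = 12) {
  .require_columns(summaries, c("n_correct", "mean_confidence"), "summaries")
  if (nrow(summaries) == 0) stop("no participant summaries", call. = FALSE)
  levels_k <- 0:n_claims
  conf_p <- to_probability_scale(summaries$mean_confidence)
  grp <- factor(summaries$n_correct, levels = levels_k)
  n <- as.integer(table(grp))
  mean_k <- tapply(conf_p, grp, mean)
  sem_k <- tapply(conf_p, grp, function(v) {
    if (length(v) < 2) return(NA_real_)
    stats::sd(v) / sqrt(length(v))
  })
  data.frame(
    n_correct = levels_k,
    mean_confidence = as.numeric(mean_k),
    sem = as.numeric(sem_k),
    n_participants = n
  )
}

#' Discrimination by group
#'
#' Averages, within groups, each participant's mean confidence in correct
#' and in incorrect answers and their difference (discrimination).
#' Participants with undefined discrimination (no correct or no incorrect
#' answers) are excluded from the aggregation; groups with no eligible
#' participant are omitted with a message.
#'
#' @param summaries data.frame from [summarize_participants()].
#' @param by name of the grouping column, typically `"profile"` or
#'   `"n_correct"`.
#' @return data.frame with columns `group`, `mean_conf_correct`,
#'   `mean_conf_incorrect`, `delta`, `n`.
#' @export
discrimination_by_group <- function(summaries, by = "profile") {
  .require_columns(summaries, c(by, "mean_conf_correct", "mean_conf_incorrect",
                                "discrimination"), "summaries")
  eligible <- !is.na(summaries$discrimination)
  dropped_groups <- setdiff(unique(summaries[[by]]), unique(summaries[[by]][eligible]))
  if (length(dropped_groups)) {
    message("discrimination_by_group: no eligible participants in group(s): ",
            paste(dropped_groups, collapse = ", "))
  }
  s <- summaries[eligible, , drop = FALSE]
  if (nrow(s) == 0) stop("no participant has defined discrimination", call. = FALSE)
  grp <- factor(s[[by]])
  agg <- function(v) as.numeric(tapply(v, grp, mean))
  data.frame(
    group = levels(grp),
    mean_conf_correct = agg(s$mean_conf_correct),
    mean_conf_incorrect = agg(s$mean_conf_incorrect),
    delta = agg(s$discrimination),
    n = as.integer(table(grp))
  )
}

#' Flag participants with a plausibly advanced level in statistics
#'
#' A participant counts as advanced if they hold a bachelor/master degree
#' in mathematics, hold a PhD, or spend at least 20% of their time on
#' research.
#'
#' @param math_degree,phd logical vectors.
#' @param research_fraction numeric vector in \[0, 1\].
#' @return logical vector; missing fields yield `FALSE` with a warning.
#' @export
classify_advanced <- function(math_degree, phd, research_fraction) {
  n <- max(length(math_degree), length(phd), length(research_fraction))
  math_degree <- rep_len(as.logical(math_degree), n)
  phd <- rep_len(as.logical(phd), n)
  research_fraction <- rep_len(as.numeric(research_fraction), n)
  out <- math_degree | phd | (research_fraction >= 0.20)
  if (anyNA(out)) {
    warning(sprintf("classify_advanced: %d record(s) with missing fields treated as not advanced",
                    sum(is.na(out))), call. = FALSE)
    out[is.na(out)] <- FALSE
  }
  out
}

#' Variance-stabilising confidence transform
#'
#' `y = sqrt(100 - x)`: monotone decreasing, spreading out the mass of
#' near-ceiling confidence judgments so residuals of linear models on
#' confidence better meet normality/homoscedasticity assumptions.
#'
#' @param confidence numeric vector in \[0, 100\].
#' @return numeric vector in \[0, 10\].
#' @export
sqrt_conf_transform <- function(confidence) {
  .check_range(confidence, 0, 100, "confidence")
  sqrt(100 - confidence)
}

#' Long-format export for external mixed-model fitting
#'
#' Produces one row per (participant, claim) with correctness, raw
#' confidence and any demographic covariates — the layout expected by
#' mixed-effects packages (participant as random intercept). No model is
#' fitted here.
#'
#' @param scored data.frame from [score_responses()].
#' @param demographics optional covariates keyed by `participant_id`.
#' @return data.frame with columns `participant_id`, `exercise_id`,
#'   `claim_id`, `correct`, `confidence`, `d`, plus demographics.
#' @export
export_long <- function(scored, demographics = NULL) {
  .require_columns(scored, c("participant_id", "exercise_id", "claim_id",
                             "correct", "confidence", "d"), "scored")
  out <- scored[, c("participant_id", "exercise_id", "claim_id",
                    "correct", "confidence", "d")]
  if (!is.null(demographics)) {
    .require_columns(demographics, "participant_id", "demographics")
    j <- match(out$participant_id, demographics$participant_id)
    out <- cbind(out, demographics[j, setdiff(names(demographics), "participant_id"),
                                   drop = FALSE])
  }
  rownames(out) <- NULL
  out
}
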