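# Orchestration: validation -> scoring -> classification -> summaries ->
# statistics, plus the simulate/analyze/report command-line interface.

#' Analysis configuration
#'
#' @param unknown_policy how VAS = 0 responses enter accuracy counts
#'   (see [response_correctness()]).
#' @param classifier a [classifier_config()] for the PPV task.
#' @param n_claims performance range for the calibration curve.
#' @param continuity_correction default for 2x2 chi-square tests.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(unknown_policy = c("incorrect", "excluded"),
                            classifier = classifier_config(),
                            n_claims = 12,
                            continuity_correction = TRUE) {
  unknown_policy <- match.arg(unknown_policy)
  stopifnot(inherits(classifier, "classifier_config"))
  structure(list(unknown_policy = unknown_policy, classifier = classifier,
                 n_claims = n_claims,
                 continuity_correction = continuity_correction),
            class = "analysis_config")
}

#' Validate pipeline input tables
#'
#' Schema-checks the response tables, drops rows with missing VAS values
#' (logging each), rejects out-of-range values and unknown claim ids with
#' record coordinates, and excludes participants from any exercise in
#' which they answered nothing.
#'
#' @param responses long claim-response table (`participant_id`,
#'   `exercise_id`, `claim_id`, `vas_value`).
#' @param claim_key claim key (`exercise_id`, `claim_id`, `truth`).
#' @param ppv_task optional PPV-task table (`participant_id`, `framing`,
#'   `estimate`, `confidence`).
#' @return list with `responses` (clean), `ppv_task`, and `issues`
#'   (data.frame: `table`, `row`, `participant_id`, `issue`).
#' @export
validate_inputs <- function(responses, claim_key, ppv_task = NULL) {
  .require_columns(responses, c("participant_id", "exercise_id", "claim_id", "vas_value"),
                   "responses")
  .require_columns(claim_key, c("exercise_id", "claim_id", "truth"), "claim_key")
  issues <- list()
  log_issue <- function(table, row, pid, what) {
    issues[[length(issues) + 1]] <<- data.frame(
      table = table, row = row, participant_id = pid, issue = what)
  }

  if (!is.numeric(responses$vas_value)) {
    stop("responses$vas_value must be numeric", call. = FALSE)
  }
  bad <- which(!is.na(responses$vas_value) &
                 (responses$vas_value < -100 | responses$vas_value > 100))
  if (length(bad)) {
    stop(sprintf("responses row %d: vas_value %g outside [-100, 100]",
                 bad[1], responses$vas_value[bad[1]]), call. = FALSE)
  }
  known <- paste(claim_key$exercise_id, claim_key$claim_id, sep = "\r")
  ref <- paste(responses$exercise_id, responses$claim_id, sep = "\r")
  unknown <- which(!ref %in% known)
  if (length(unknown)) {
    stop(sprintf("responses row %d references unknown claim (exercise '%s', claim '%s')",
                 unknown[1], responses$exercise_id[unknown[1]],
                 responses$claim_id[unknown[1]]), call. = FALSE)
  }

  missing_rows <- which(is.na(responses$vas_value))
  for (r in missing_rows) {
    log_issue("responses", r, responses$participant_id[r], "missing vas_value (dropped)")
  }
  clean <- responses[setdiff(seq_len(nrow(responses)), missing_rows), , drop = FALSE]

  # exclude participants with no remaining response in an exercise they
  # appeared in
  appeared <- unique(responses[, c("participant_id", "exercise_id")])
  remaining <- unique(clean[, c("participant_id", "exercise_id")])
  app_id <- paste(appeared$participant_id, appeared$exercise_id, sep = "\r")
  rem_id <- paste(remaining$participant_id, remaining$exercise_id, sep = "\r")
  gone <- appeared[!app_id %in% rem_id, , drop = FALSE]
  for (g in seq_len(nrow(gone))) {
    log_issue("responses", NA_integer_, gone$participant_id[g],
              sprintf("no responses in exercise '%s' (participant excluded from it)",
                      gone$exercise_id[g]))
  }

  if (!is.null(ppv_task)) {
    .require_columns(ppv_task, c("participant_id", "framing", "estimate", "confidence"),
                     "ppv_task")
    for (col in c("estimate", "confidence")) {
      bad <- which(!is.na(ppv_task[[col]]) &
                     (ppv_task[[col]] < 0 | ppv_task[[col]] > 100))
      if (length(bad)) {
        stop(sprintf("ppv_task row %d: %s %g outside [0, 100]",
                     bad[1], col, ppv_task[[col]][bad[1]]), call. = FALSE)
      }
    }
    badf <- which(!ppv_task$framing %in% c("CP", "NF"))
    if (length(badf)) {
      stop(sprintf("ppv_task row %d: framing '%s' not in {CP, NF}",
                   badf[1], ppv_task$framing[badf[1]]), call. = FALSE)
    }
    drop <- which(is.na(ppv_task$estimate) | is.na(ppv_task$confidence))
    for (r in drop) {
      log_issue("ppv_task", r, ppv_task$participant_id[r],
                "missing estimate/confidence (dropped)")
    }
    ppv_task <- ppv_task[setdiff(seq_len(nrow(ppv_task)), drop), , drop = FALSE]
  }

  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(table = character(), row = integer(),
               participant_id = character(), issue = character())
  list(responses = clean, ppv_task = ppv_task, issues = issues)
}

#' Run the full analysis
#'
#' Scores the claim responses, summarises participants, builds the
#' calibration curve and discrimination tables, classifies PPV-task
#' answers, and computes the framing comparison (correct-answer ratio
#' NF/CP with a 95% CI and a Yates-corrected chi-square). Fully
#' deterministic for fixed inputs.
#'
#' @param responses,claim_key,ppv_task as in [validate_inputs()];
#'   validation is applied first.
#' @param demographics optional covariates keyed by `participant_id`
#'   (e.g. `profile`).
#' @param config an [analysis_config()].
#' @return an object of class `analysis_report`: list with elements
#'   `scored`, `claim_accuracy`, `d_summary`, `summaries`,
#'   `calibration`, `discrimination_by_performance` (and `_by_profile`
#'   when profiles are supplied), `ppv` (classified table, counts,
#'   framing comparison), `statistics`, `issues`.
#' @export
run_analysis <- function(responses, claim_key, ppv_task = NULL,
                         demographics = NULL, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  val <- validate_inputs(responses, claim_key, ppv_task)
  scored <- score_responses(val$responses, claim_key,
                            unknown_policy = config$unknown_policy)

  acc <- tapply(scored$correct == 1L, scored$claim_id, mean, na.rm = TRUE)
  claim_accuracy <- data.frame(claim_id = names(acc),
                               accuracy = as.numeric(acc),
                               n = as.integer(table(scored$claim_id)[names(acc)]))
  rownames(claim_accuracy) <- NULL

  d_summary <- do.call(rbind, lapply(split(scored$d, scored$exercise_id), function(d) {
    data.frame(n = length(d), mean_d = mean(d), median_d = stats::median(d),
               q1 = unname(stats::quantile(d, 0.25)), q3 = unname(stats::quantile(d, 0.75)))
  }))
  d_summary <- cbind(exercise_id = rownames(d_summary), d_summary)
  rownames(d_summary) <- NULL

  summaries <- summarize_participants(scored, demographics)
  calib <- calibration_curve(summaries, n_claims = config$n_claims)
  disc_perf <- suppressMessages(discrimination_by_group(summaries, by = "n_correct"))
  disc_prof <- if (!is.null(demographics) && "profile" %in% names(summaries)) {
    suppressMessages(discrimination_by_group(summaries, by = "profile"))
  }

  stats_list <- list()
  ppv_out <- NULL
  if (!is.null(val$ppv_task) && nrow(val$ppv_task)) {
    classified <- tabulate_ppv_answers(val$ppv_task, config$classifier)
    counts <- attr(classified, "counts")
    correct_by_framing <- data.frame(
      framing = rownames(counts),
      n_correct = as.integer(counts[, "correct"]),
      n = as.integer(rowSums(counts))
    )
    framing_comparison <- NULL
    if (all(c("CP", "NF") %in% correct_by_framing$framing) &&
        all(correct_by_framing$n_correct > 0) &&
        all(correct_by_framing$n > correct_by_framing$n_correct)) {
      nf <- correct_by_framing[correct_by_framing$framing == "NF", ]
      cp <- correct_by_framing[correct_by_framing$framing == "CP", ]
      ratio <- (nf$n_correct / nf$n) / (cp$n_correct / cp$n)
      se_log <- sqrt(1 / nf$n_correct - 1 / nf$n + 1 / cp$n_correct - 1 / cp$n)
      tab2 <- rbind(c(nf$n_correct, nf$n - nf$n_correct),
                    c(cp$n_correct, cp$n - cp$n_correct))
      chi <- suppressWarnings(
        chi2_contingency(tab2, continuity_correction = config$continuity_correction))
      stats_list$framing_x_correct <- chi
      framing_comparison <- data.frame(
        ratio = ratio,
        ci_lower = exp(log(ratio) - 1.96 * se_log),
        ci_upper = exp(log(ratio) + 1.96 * se_log),
        chi2 = chi$statistic, df = chi$df, p_value = chi$p_value
      )
    }
    ppv_out <- list(classified = classified, counts = counts,
                    n_noninformative = sum(classified$noninformative),
                    framing_comparison = framing_comparison)
  }
  statistics <- if (length(stats_list)) do.call(statistics_report, stats_list) else NULL

  structure(
    list(scored = scored, claim_accuracy = claim_accuracy, d_summary = d_summary,
         summaries = summaries, calibration = calib,
         discrimination_by_performance = disc_perf,
         discrimination_by_profile = disc_prof,
         ppv = ppv_out, statistics = statistics, issues = val$issues,
         config = config),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(report_text(x), sep = "\n")
  invisible(x)
}

#' Plain-text summary of an analysis report
#'
#' @param report an `analysis_report`.
#' @return character vector of lines.
#' @export
report_text <- function(report) {
  stopifnot(inherits(report, "analysis_report"))
  lines <- c(
    "# Analysis report",
    sprintf("Participants summarized: %d", nrow(report$summaries)),
    sprintf("Claim accuracy range: %.1f%% - %.1f%%",
            100 * min(report$claim_accuracy$accuracy),
            100 * max(report$claim_accuracy$accuracy)),
    sprintf("Validation issues logged: %d", nrow(report$issues))
  )
  if (!is.null(report$ppv)) {
    counts <- report$ppv$counts
    total <- sum(counts)
    lines <- c(lines,
      sprintf("PPV task responses: %d (%d non-informative, kept)",
              total, report$ppv$n_noninformative),
      sprintf("PPV categories: correct %d, confusion_sensitivity %d, confusion_specificity %d, other %d",
              sum(counts[, "correct"]), sum(counts[, "confusion_sensitivity"]),
              sum(counts[, "confusion_specificity"]), sum(counts[, "other_incorrect"])))
    fc <- report$ppv$framing_comparison
    if (!is.null(fc)) {
      lines <- c(lines, sprintf(
        "NF/CP correct-answer ratio: %.2f (95%% CI %.2f-%.2f), chi2 = %.1f, df = %g, p = %.2g",
        fc$ratio, fc$ci_lower, fc$ci_upper, fc$chi2, fc$df, fc$p_value))
    }
  }
  lines
}

#' Write an analysis report to a directory of CSV files
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  emit <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  emit(report$scored, "scored_responses.csv")
  emit(report$claim_accuracy, "claim_accuracy.csv")
  emit(report$d_summary, "d_summary.csv")
  emit(report$summaries, "participant_summaries.csv")
  emit(report$calibration, "calibration_curve.csv")
  emit(report$discrimination_by_performance, "discrimination_by_performance.csv")
  if (!is.null(report$discrimination_by_profile)) {
    emit(report$discrimination_by_profile, "discrimination_by_profile.csv")
  }
  if (!is.null(report$ppv)) {
    emit(report$ppv$classified, "ppv_classified.csv")
    emit(as.data.frame(report$ppv$counts), "ppv_counts.csv")
    if (!is.null(report$ppv$framing_comparison)) {
      emit(report$ppv$framing_comparison, "framing_comparison.csv")
    }
  }
  if (!is.null(report$statistics)) emit(report$statistics, "statistics.csv")
  emit(report$issues, "issues.csv")
  emit(export_long(report$scored,
                   if ("profile" %in% names(report$summaries))
                     report$summaries[, c("participant_id", "profile")]),
       "mixed_model_export.csv")
  writeLines(report_text(report), file.path(dir, "report.md"))
  invisible(c(paths, file.path(dir, "report.md")))
}

# ---- command-line interface ----

.cli_read_config <- function(path) {
  if (is.null(path)) return(list())
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

.cli_sim_config <- function(cfg, seed = NULL) {
  args <- list()
  if (!is.null(cfg$n_per_profile)) args$n_per_profile <- unlist(cfg$n_per_profile)
  for (f in c("ability_sd", "baseline_discriminability", "metacognitive_noise",
              "confidence_bias", "nf_correct_multiplier", "seed")) {
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  }
  if (!is.null(cfg$ppv_mixture)) args$ppv_mixture <- unlist(cfg$ppv_mixture)
  if (!is.null(cfg$claims)) args$claims <- as.data.frame(cfg$claims)
  if (!is.null(seed)) args$seed <- seed
  do.call(simulation_config, args)
}

.cli_analysis_config <- function(cfg) {
  cls <- do.call(classifier_config, cfg$classifier %||% list())
  analysis_config(
    unknown_policy = cfg$unknown_policy %||% "incorrect",
    classifier = cls,
    n_claims = cfg$n_claims %||% 12,
    continuity_correction = cfg$continuity_correction %||% TRUE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_csv_commented <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_lines), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Command-line entry point
#'
#' Subcommands: `simulate --config cfg.json --out dir/ [--seed n]`
#' generates a synthetic cohort (visible CSVs plus hidden-truth CSVs,
#' with the configuration echoed in `#` header comments);
#' `analyze --responses r.csv --claims k.csv [--ppv p.csv]
#' [--demographics d.csv] [--config cfg.json] --out dir/` runs the full
#' pipeline; `report --in dir/` prints the text summary of a previous
#' analyze run.
#'
#' @param args character vector of command-line arguments (defaults to
#'   the actual command line).
#' @return integer exit status, invisibly: 0 ok, 1 validation failure,
#'   2 internal error. A wrapper script should pass this to `quit()`.
#' @export
vasmeta_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) {
      cat("usage: vasmeta <simulate|analyze|report> [options]\n")
      return(invisible(1L))
    }
    cmd <- args[1]
    rest <- args[-1]
    switch(cmd,
      simulate = .cli_simulate(rest),
      analyze = .cli_analyze(rest),
      report = .cli_report(rest),
      {
        message(sprintf("unknown subcommand '%s'", cmd))
        1L
      }
    )
  },
  vasmeta_validation = function(e) { message("validation error: ", conditionMessage(e)); 1L },
  error = function(e) { message("error: ", conditionMessage(e)); 2L })
  invisible(status)
}

.cli_simulate <- function(args) {
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--out", type = "character"),
    optparse::make_option("--seed", type = "integer", default = NULL)
  ))
  opts <- optparse::parse_args(parser, args = args)
  if (is.null(opts$out)) stop("simulate: --out is required", call. = FALSE)
  cfg <- .cli_sim_config(.cli_read_config(opts$config), seed = opts$seed)
  sim <- simulate_claim_responses(cfg)
  psim <- simulate_ppv_task(cfg)
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  echo <- sprintf("generated by vasmeta simulate; seed=%d", cfg$seed)
  .write_csv_commented(sim$responses, file.path(opts$out, "responses.csv"), echo)
  .write_csv_commented(sim$claim_key, file.path(opts$out, "claim_key.csv"), echo)
  .write_csv_commented(sim$demographics, file.path(opts$out, "demographics.csv"), echo)
  .write_csv_commented(psim$responses, file.path(opts$out, "ppv_task.csv"), echo)
  .write_csv_commented(sim$hidden, file.path(opts$out, "hidden_claims.csv"),
                       c(echo, "hidden ground truth: not an analysis input"))
  .write_csv_commented(psim$hidden, file.path(opts$out, "hidden_ppv.csv"),
                       c(echo, "hidden ground truth: not an analysis input"))
  message(sprintf("simulate: wrote cohort of %d participants to %s",
                  nrow(sim$demographics), opts$out))
  0L
}

.cli_read_csv <- function(path, what) {
  if (is.null(path)) return(NULL)
  if (!file.exists(path)) {
    stop(structure(class = c("vasmeta_validation", "error", "condition"),
                   list(message = sprintf("%s file not found: %s", what, path),
                        call = NULL)))
  }
  utils::read.csv(path, comment.char = "#")
}

.cli_analyze <- function(args) {
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--responses", type = "character"),
    optparse::make_option("--claims", type = "character"),
    optparse::make_option("--ppv", type = "character", default = NULL),
    optparse::make_option("--demographics", type = "character", default = NULL),
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--out", type = "character")
  ))
  opts <- optparse::parse_args(parser, args = args)
  if (is.null(opts$responses) || is.null(opts$claims) || is.null(opts$out)) {
    stop("analyze: --responses, --claims and --out are required", call. = FALSE)
  }
  responses <- .cli_read_csv(opts$responses, "responses")
  claim_key <- .cli_read_csv(opts$claims, "claim key")
  claim_key$truth <- as.logical(claim_key$truth)
  ppv_task <- .cli_read_csv(opts$ppv, "ppv task")
  demographics <- .cli_read_csv(opts$demographics, "demographics")
  config <- .cli_analysis_config(.cli_read_config(opts$config))
  report <- tryCatch(
    run_analysis(responses, claim_key, ppv_task, demographics, config),
    error = function(e) {
      stop(structure(class = c("vasmeta_validation", "error", "condition"),
                     list(message = conditionMessage(e), call = NULL)))
    })
  write_report(report, opts$out)
  message(sprintf("analyze: report written to %s", opts$out))
  0L
}

.cli_report <- function(args) {
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--in", type = "character", dest = "indir")
  ))
  opts <- optparse::parse_args(parser, args = args)
  if (is.null(opts$indir)) stop("report: --in is required", call. = FALSE)
  path <- file.path(opts$indir, "report.md")
  if (!file.exists(path)) {
    stop(structure(class = c("vasmeta_validation", "error", "condition"),
                   list(message = sprintf("no report.md under %s", opts$indir),
                        call = NULL)))
  }
  cat(readLines(path), sep = "\n")
  0L
}
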