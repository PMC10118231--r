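# Bayesian predictive values for diagnostic screening, conversion between
# conditional-probability and natural-frequency framings, and the
# classification of PPV-task answers into correct / confusion categories.

#' Diagnostic test parameters
#'
#' @param sensitivity P(test positive | diseased), in \[0, 1\].
#' @param specificity P(test negative | healthy), in \[0, 1\].
#' @param prevalence pre-test probability of disease, in \[0, 1\].
#' @return an object of class `test_parameters`.
#' @examples
#' test_parameters(0.90, 0.99, 0.0039)
#' @export
test_parameters <- function(sensitivity, specificity, prevalence) {
  for (v in c("sensitivity", "specificity", "prevalence")) {
    val <- get(v)
    if (!is.numeric(val) || length(val) != 1 || is.na(val) || val < 0 || val > 1) {
      stop(sprintf("%s must be a single probability in [0, 1]", v), call. = FALSE)
    }
  }
  structure(
    list(sensitivity = sensitivity, specificity = specificity, prevalence = prevalence),
    class = "test_parameters"
  )
}

#' @export
print.test_parameters <- function(x, ...) {
  cat(sprintf("Diagnostic test: sensitivity %.4g, specificity %.4g, prevalence %.4g\n",
              x$sensitivity, x$specificity, x$prevalence))
  invisible(x)
}

#' Positive predictive value
#'
#' `PPV = se * p / (se * p + (1 - sp) * (1 - p))` with se = sensitivity,
#' sp = specificity, p = prevalence.
#'
#' @param params a [test_parameters()] object.
#' @return probability that a positive test indicates disease.
#' @export
ppv <- function(params) {
  stopifnot(inherits(params, "test_parameters"))
  num <- params$sensitivity * params$prevalence
  den <- num + (1 - params$specificity) * (1 - params$prevalence)
  if (den <= 0) {
    stop("PPV undefined: the probability of a positive test is zero", call. = FALSE)
  }
  num / den
}

#' Negative predictive value
#'
#' `NPV = sp * (1 - p) / (sp * (1 - p) + (1 - se) * p)`.
#'
#' @inheritParams ppv
#' @return probability that a negative test indicates absence of disease.
#' @export
npv <- function(params) {
  stopifnot(inherits(params, "test_parameters"))
  num <- params$specificity * (1 - params$prevalence)
  den <- num + (1 - params$sensitivity) * params$prevalence
  if (den <= 0) {
    stop("NPV undefined: the probability of a negative test is zero", call. = FALSE)
  }
  num / den
}

#' Render conditional probabilities as a natural-frequency table
#'
#' Natural frequencies express the same information as counts in a
#' reference population: out of `n_total` persons, `n_diseased` have the
#' disease, of whom `n_true_positive` test positive, while
#' `n_false_positive` of the healthy test positive.
#'
#' @inheritParams ppv
#' @param n_total reference population size (>= 1).
#' @param rounding `"nearest"` (integer counts, the way worked examples
#'   are printed), `"floor"`, or `"none"` (exact fractional counts, for
#'   which [nf_to_ppv()] recovers [ppv()] exactly).
#' @return an object of class `nf_table` with fields `n_total`,
#'   `n_diseased`, `n_true_positive`, `n_false_positive`.
#' @examples
#' cp_to_nf(test_parameters(0.90, 0.91, 0.01), 1000)
#' @export
cp_to_nf <- function(params, n_total, rounding = c("nearest", "none", "floor")) {
  stopifnot(inherits(params, "test_parameters"))
  rounding <- match.arg(rounding)
  if (!is.numeric(n_total) || length(n_total) != 1 || n_total < 1) {
    stop("n_total must be a single count >= 1", call. = FALSE)
  }
  rnd <- switch(rounding, nearest = round, floor = floor, none = identity)
  n_diseased <- rnd(params$prevalence * n_total)
  n_healthy <- n_total - n_diseased
  n_true_positive <- rnd(params$sensitivity * n_diseased)
  n_true_negative <- rnd(params$specificity * n_healthy)
  n_false_positive <- n_healthy - n_true_negative
  nf_table(n_total, n_diseased, n_true_positive, n_false_positive,
           .allow_fractional = (rounding == "none"))
}

#' Construct a natural-frequency table
#'
#' @param n_total,n_diseased,n_true_positive,n_false_positive nonnegative
#'   counts with `n_diseased <= n_total`, `n_true_positive <= n_diseased`
#'   and `n_false_positive <= n_total - n_diseased`.
#' @param .allow_fractional internal; permits non-integer counts as
#'   produced by [cp_to_nf()] with `rounding = "none"`.
#' @return an object of class `nf_table`.
#' @export
nf_table <- function(n_total, n_diseased, n_true_positive, n_false_positive,
                     .allow_fractional = FALSE) {
  counts <- c(n_total = n_total, n_diseased = n_diseased,
              n_true_positive = n_true_positive, n_false_positive = n_false_positive)
  if (any(counts < 0)) stop("natural-frequency counts must be nonnegative", call. = FALSE)
  if (!.allow_fractional && any(abs(counts - round(counts)) > 1e-9)) {
    stop("natural-frequency counts must be integers (use rounding = 'none' for exact tables)",
         call. = FALSE)
  }
  if (n_diseased > n_total) stop("n_diseased exceeds n_total", call. = FALSE)
  if (n_true_positive > n_diseased) stop("n_true_positive exceeds n_diseased", call. = FALSE)
  if (n_false_positive > n_total - n_diseased) {
    stop("n_false_positive exceeds the healthy count", call. = FALSE)
  }
  structure(as.list(counts), class = "nf_table")
}

#' @export
print.nf_table <- function(x, ...) {
  cat(sprintf(paste0(
    "Of %g persons, %g have the disease; %g of the diseased test positive\n",
    "and %g of the %g healthy test positive.\n"),
    x$n_total, x$n_diseased, x$n_true_positive, x$n_false_positive,
    x$n_total - x$n_diseased))
  invisible(x)
}

#' PPV read directly off a natural-frequency table
#'
#' With counts in hand the PPV "appears intuitively" as the fraction of
#' positives that are true positives.
#'
#' @param table an [nf_table()].
#' @return `n_true_positive / (n_true_positive + n_false_positive)`.
#' @export
nf_to_ppv <- function(table) {
  stopifnot(inherits(table, "nf_table"))
  den <- table$n_true_positive + table$n_false_positive
  if (den <= 0) stop("PPV undefined: the table has no positive tests", call. = FALSE)
  table$n_true_positive / den
}

#' Classifier windows for PPV-task answers
#'
#' Defaults encode a task whose correct PPV is 26% (accepted within
#' +/- 5 points) and whose instructions state a sensitivity of 90% and a
#' specificity of 99%; answers within +/- 1 point of those anchors are
#' treated as confusion with the respective parameter. Sliders barely
#' moved from their 50% default (both within +/- 5) are flagged
#' non-informative but kept.
#'
#' @param correct_center,correct_halfwidth window of accepted answers (%).
#' @param sens_anchor,spec_anchor stated sensitivity and specificity (%).
#' @param confusion_halfwidth half-width of each confusion window (%).
#' @param noninfo_halfwidth half-width of the untouched-slider zone around
#'   50 (%).
#' @return an object of class `classifier_config`.
#' @export
classifier_config <- function(correct_center = 26, correct_halfwidth = 5,
                              sens_anchor = 90, spec_anchor = 99,
                              confusion_halfwidth = 1, noninfo_halfwidth = 5) {
  cfg <- list(correct_center = correct_center, correct_halfwidth = correct_halfwidth,
              sens_anchor = sens_anchor, spec_anchor = spec_anchor,
              confusion_halfwidth = confusion_halfwidth,
              noninfo_halfwidth = noninfo_halfwidth)
  if (any(vapply(cfg, function(v) !is.numeric(v) || length(v) != 1 || is.na(v), TRUE))) {
    stop("classifier_config fields must be single numbers", call. = FALSE)
  }
  if (cfg$correct_halfwidth <= 0 || cfg$confusion_halfwidth <= 0 || cfg$noninfo_halfwidth <= 0) {
    stop("classifier halfwidths must be > 0", call. = FALSE)
  }
  structure(cfg, class = "classifier_config")
}

#' Classify a PPV estimate into answer categories
#'
#' Windows are closed on both sides. When user-supplied windows overlap,
#' precedence is correct > confusion_sensitivity > confusion_specificity,
#' so correctness always dominates.
#'
#' @param estimate numeric vector of PPV estimates in \[0, 100\].
#' @param config a [classifier_config()].
#' @return factor with levels `correct`, `confusion_sensitivity`,
#'   `confusion_specificity`, `other_incorrect`.
#' @examples
#' classify_estimate(c(26, 31, 90.5, 99, 50))
#' @export
classify_estimate <- function(estimate, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  .check_range(estimate, 0, 100, "estimate")
  out <- rep(NA_character_, length(estimate))
  out[abs(estimate - config$spec_anchor) <= config$confusion_halfwidth] <- "confusion_specificity"
  out[abs(estimate - config$sens_anchor) <= config$confusion_halfwidth] <- "confusion_sensitivity"
  out[abs(estimate - config$correct_center) <= config$correct_halfwidth] <- "correct"
  out[is.na(out) & !is.na(estimate)] <- "other_incorrect"
  factor(out, levels = c("correct", "confusion_sensitivity",
                         "confusion_specificity", "other_incorrect"))
}

#' Flag answers where both sliders barely moved from their defaults
#'
#' Both sliders start at 50; a record with estimate and confidence both
#' within the +/- `noninfo_halfwidth` zone around 50 is likely a
#' non-engaged response. Flagged records are retained in analyses.
#'
#' @param estimate,confidence numeric vectors in \[0, 100\].
#' @param config a [classifier_config()].
#' @return logical vector.
#' @export
flag_noninformative <- function(estimate, confidence, config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  .check_range(estimate, 0, 100, "estimate")
  .check_range(confidence, 0, 100, "confidence")
  hw <- config$noninfo_halfwidth
  abs(estimate - 50) <= hw & abs(confidence - 50) <= hw
}

#' Width of the uncertainty zone around a PPV estimate
#'
#' The paired-VAS response widget displays a blue zone of uncertainty
#' around the estimate whose width follows `0.02 * setting^2` for the
#' second slider's setting. Whether that slider encodes confidence
#' (literal formula) or uncertainty (wider zone for lower confidence) is
#' ambiguous in the original widget description, so the coding is an
#' explicit argument rather than a guess.
#'
#' @param confidence_setting numeric vector in \[0, 100\].
#' @param slider_encodes `"confidence"` applies the formula to the setting
#'   itself; `"uncertainty"` applies it to `100 - setting`.
#' @param clip clip the width to the displayable \[0, 100\] axis (the
#'   stored value is the raw formula output by default).
#' @return numeric widths.
#' @export
blue_zone_width <- function(confidence_setting,
                            slider_encodes = c("confidence", "uncertainty"),
                            clip = FALSE) {
  slider_encodes <- match.arg(slider_encodes)
  .check_range(confidence_setting, 0, 100, "confidence_setting")
  s <- if (slider_encodes == "confidence") confidence_setting else 100 - confidence_setting
  w <- 0.02 * s^2
  if (clip) w <- pmin(w, 100)
  w
}

#' Classify a PPV-task response table
#'
#' @param ppv_task data.frame with columns `participant_id`, `framing`
#'   (`"CP"` or `"NF"`), `estimate`, `confidence`.
#' @param config a [classifier_config()].
#' @return the input with `category` and `noninformative` columns
#'   appended, plus a `counts` attribute holding the framing x category
#'   contingency table.
#' @export
tabulate_ppv_answers <- function(ppv_task, config = classifier_config()) {
  .require_columns(ppv_task, c("participant_id", "framing", "estimate", "confidence"),
                   "ppv_task")
  bad <- which(!ppv_task$framing %in% c("CP", "NF"))
  if (length(bad)) {
    stop(sprintf("ppv_task row %d has framing '%s'; expected 'CP' or 'NF'",
                 bad[1], ppv_task$framing[bad[1]]), call. = FALSE)
  }
  ppv_task$category <- classify_estimate(ppv_task$estimate, config)
  ppv_task$noninformative <- flag_noninformative(ppv_task$estimate,
                                                ppv_task$confidence, config)
  attr(ppv_task, "counts") <- table(framing = ppv_task$framing,
                                    category = ppv_task$category)
  ppv_task
}

#' Load a PPV-task configuration from JSON
#'
#' Reads test parameters, reference-population size and classifier
#' windows. The package ships an example at
#' `system.file("extdata", "covid_ppv_config.json", package = "vasmeta")`
#' describing a COVID-19 antigen-test task (sensitivity 90%, specificity
#' 99%, prevalence 0.39%, correct PPV about 26%).
#'
#' @param path path to a JSON config file.
#' @return list with `params` ([test_parameters()]), `n_total` and
#'   `classifier` ([classifier_config()]).
#' @export
load_ppv_config <- function(path = system.file("extdata", "covid_ppv_config.json",
                                               package = "vasmeta")) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("sensitivity", "specificity", "prevalence")) {
    if (is.null(cfg[[f]])) stop(sprintf("PPV config is missing '%s'", f), call. = FALSE)
  }
  classifier <- if (is.null(cfg$classifier)) classifier_config() else
    do.call(classifier_config, as.list(cfg$classifier))
  list(
    params = test_parameters(cfg$sensitivity, cfg$specificity, cfg$prevalence),
    n_total = if (is.null(cfg$nf_population)) 1000 else cfg$nf_population,
    classifier = classifier
  )
}
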