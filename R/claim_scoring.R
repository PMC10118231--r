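# Double-sided VAS decoding and the distance-to-correct-answer score.
#
# A double-sided visual analog scale records one number x in [-100, +100]:
# the sign carries the participant's verdict on a claim ("true" for x > 0,
# "false" for x < 0, "I do not know" at exactly 0) and the magnitude |x|
# carries their confidence on a 0-100 scale.

#' Decode double-sided VAS responses into verdict and confidence
#'
#' A double-sided VAS spans "surely false" (-100) through "I do not know"
#' (0) to "surely true" (+100). The sign encodes the verdict and the
#' magnitude encodes confidence.
#'
#' @param x numeric vector of raw VAS positions in \[-100, 100\]. `NA`
#'   entries (missing responses) are propagated.
#' @return a data.frame with columns `verdict` (factor with levels
#'   `asserts_true`, `asserts_false`, `unknown`) and `confidence`
#'   (numeric, `abs(x)`).
#' @examples
#' decode_vas(c(100, 0, -63))
#' @export
decode_vas <- function(x) {
  .check_vas_range(x, "vas_value")
  verdict <- ifelse(is.na(x), NA_character_,
             ifelse(x > 0, "asserts_true",
             ifelse(x < 0, "asserts_false", "unknown")))
  data.frame(
    verdict = factor(verdict, levels = c("asserts_true", "asserts_false", "unknown")),
    confidence = abs(x)
  )
}

#' Correctness of a decoded response against the claim key
#'
#' @param verdict character or factor vector of verdicts as produced by
#'   [decode_vas()].
#' @param truth logical vector: is the claim factually true?
#' @param unknown_policy how `unknown` (VAS exactly 0) verdicts enter
#'   accuracy counts: `"incorrect"` scores them as c = -1, `"excluded"`
#'   returns `NA` so they drop out of counts.
#' @return integer vector in \{+1, -1\} (`NA` for missing or excluded).
#' @export
response_correctness <- function(verdict, truth,
                                 unknown_policy = c("incorrect", "excluded")) {
  unknown_policy <- match.arg(unknown_policy)
  verdict <- as.character(verdict)
  stopifnot(is.logical(truth))
  truth <- rep_len(truth, length(verdict))
  out <- ifelse(
    is.na(verdict), NA_integer_,
    ifelse(verdict == "unknown",
           if (unknown_policy == "incorrect") -1L else NA_integer_,
           ifelse((verdict == "asserts_true") == truth, 1L, -1L))
  )
  as.integer(out)
}

#' Distance to the correct answer
#'
#' Combines correctness and confidence into one 0-100 score:
#' `d = |c * sign(x) * 100 - x| / 2`, where c = +1 for a correct verdict
#' and -1 for an incorrect one. d = 0 is a maximally confident correct
#' answer, d = 100 a maximally confident error, and d = 50 is "I do not
#' know" (defined by convention at x = 0, where the literal formula would
#' be discontinuous).
#'
#' @param x numeric vector of raw VAS positions in \[-100, 100\].
#' @param truth logical vector of claim truth values.
#' @return numeric vector of d scores in \[0, 100\]; `NA` for missing x.
#' @examples
#' distance_score(c(100, -100, 0, 60), truth = TRUE)
#' @export
distance_score <- function(x, truth) {
  .check_vas_range(x, "vas_value")
  stopifnot(is.logical(truth))
  truth <- rep_len(truth, length(x))
  verdict <- decode_vas(x)$verdict
  cc <- response_correctness(verdict, truth, unknown_policy = "incorrect")
  d <- abs(cc * sign(x) * 100 - x) / 2
  # x = 0: the formula collapses to 0, but the scale's center means
  # "I do not know", which sits midway between confident-correct and
  # confident-wrong.
  d[!is.na(x) & x == 0] <- 50
  d
}

#' Map 0-100 confidence onto the 50-100 probability scale
#'
#' A confidence of 0 means "I answered randomly", i.e. a subjective
#' probability of being correct of 50%; a confidence of 100 means
#' certainty. The map is `confidence / 2 + 50`.
#'
#' @param confidence numeric vector in \[0, 100\].
#' @return numeric vector in \[50, 100\].
#' @seealso [from_probability_scale()] for the inverse.
#' @export
to_probability_scale <- function(confidence) {
  .check_range(confidence, 0, 100, "confidence")
  confidence / 2 + 50
}

#' Inverse of [to_probability_scale()]
#'
#' @param p numeric vector in \[50, 100\].
#' @return numeric confidence in \[0, 100\].
#' @export
from_probability_scale <- function(p) {
  .check_range(p, 50, 100, "probability-scale confidence")
  (p - 50) * 2
}

#' Score a long table of VAS responses against a claim key
#'
#' Joins responses to the claim key, decodes each VAS value and appends
#' `verdict`, `confidence`, `correct` (+1/-1, `NA` under the excluded
#' policy for x = 0) and the distance score `d`. Rows with a missing
#' `vas_value` are dropped; a participant is retained in an exercise as
#' long as they answered at least one of its claims.
#'
#' @param responses data.frame with columns `participant_id`,
#'   `exercise_id`, `claim_id`, `vas_value`.
#' @param claim_key data.frame with columns `exercise_id`, `claim_id`,
#'   `truth` (logical).
#' @param unknown_policy passed to [response_correctness()].
#' @return the responses data.frame with scoring columns appended and
#'   missing responses removed.
#' @export
score_responses <- function(responses, claim_key,
                            unknown_policy = c("incorrect", "excluded")) {
  unknown_policy <- match.arg(unknown_policy)
  .require_columns(responses, c("participant_id", "exercise_id", "claim_id", "vas_value"),
                   "responses")
  .require_columns(claim_key, c("exercise_id", "claim_id", "truth"), "claim_key")
  if (!is.logical(claim_key$truth)) {
    stop("claim_key$truth must be logical (TRUE/FALSE)", call. = FALSE)
  }
  key_id <- interaction(claim_key$exercise_id, claim_key$claim_id, drop = TRUE)
  if (anyDuplicated(key_id)) {
    stop("claim_key contains duplicated (exercise_id, claim_id) pairs", call. = FALSE)
  }
  idx <- match(paste(responses$exercise_id, responses$claim_id, sep = "\r"),
               paste(claim_key$exercise_id, claim_key$claim_id, sep = "\r"))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("response row %d references unknown claim (exercise '%s', claim '%s')",
                 bad, responses$exercise_id[bad], responses$claim_id[bad]),
         call. = FALSE)
  }
  out <- responses[!is.na(responses$vas_value), , drop = FALSE]
  idx <- idx[!is.na(responses$vas_value)]
  truth <- claim_key$truth[idx]
  dec <- decode_vas(out$vas_value)
  out$truth <- truth
  out$verdict <- dec$verdict
  out$confidence <- dec$confidence
  out$correct <- response_correctness(dec$verdict, truth, unknown_policy)
  out$d <- distance_score(out$vas_value, truth)
  rownames(out) <- NULL
  out
}

# ---- internal validators ----

.check_vas_range <- function(x, what) {
  if (!is.numeric(x)) stop(sprintf("%s must be numeric", what), call. = FALSE)
  bad <- which(!is.na(x) & (x < -100 | x > 100))
  if (length(bad)) {
    stop(sprintf("%s out of [-100, 100] at position %d (value %g)",
                 what, bad[1], x[bad[1]]), call. = FALSE)
  }
  invisible(x)
}

.check_range <- function(x, lo, hi, what) {
  if (!is.numeric(x)) stop(sprintf("%s must be numeric", what), call. = FALSE)
  bad <- which(!is.na(x) & (x < lo | x > hi))
  if (length(bad)) {
    stop(sprintf("%s out of [%g, %g] at position %d (value %g)",
                 what, lo, hi, bad[1], x[bad[1]]), call. = FALSE)
  }
  invisible(x)
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
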