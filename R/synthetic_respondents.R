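# Synthetic respondent generator.
#
# The claim exercises are simulated with an equal-variance Gaussian
# signal-detection model with post-decision metacognitive noise:
#
#   ability        theta_i ~ Normal(0, ability_sd^2)
#   discriminability d_ij  = max(0, delta0 + theta_i - b_j)   (b_j: claim difficulty)
#   stimulus       t_j     = +1 if the claim is true, else -1
#   evidence       e_ij    ~ Normal(t_j * d_ij / 2, 1)
#   verdict        sign(e_ij);   P(correct) = Phi(d_ij / 2)
#   confidence     clamp(100 * beta * (2 * Phi(|e_ij + eta_ij|) - 1), 0, 100)
#                  with metacognitive noise eta_ij ~ Normal(0, sigma_m^2)
#   VAS response   x_ij = verdict * confidence
#
# beta > 1 yields overconfidence (confidence rising faster than
# accuracy); sigma_m > 0 degrades discrimination without touching
# first-order accuracy. The PPV calculation task is simulated as a
# four-component mixture over answer categories (correct / confusion with
# sensitivity / confusion with specificity / other), with the
# natural-frequency framing multiplying the probability of a correct
# answer.

#' Configuration for the synthetic respondent generator
#'
#' Defaults describe a cohort shaped like a large clinician survey:
#' 522 students, 151 residents, 22 foreign students/residents and
#' 203 physicians answering 12 claims (two exercises of six), with
#' overconfidence (`confidence_bias` > 1), moderate metacognitive noise,
#' and a PPV-task answer mixture whose conditional-probability weights
#' match the error structure such surveys report (few correct answers,
#' a large confusion-with-sensitivity cluster, a smaller
#' confusion-with-specificity cluster); natural-frequency framing doubles
#' the probability of a correct answer.
#'
#' @param n_per_profile named integer vector of cohort sizes by profile.
#' @param claims data.frame with columns `exercise_id`, `claim_id`,
#'   `truth` (logical), `difficulty` (real, higher = harder).
#' @param ability_sd sd of the participant ability distribution (> 0).
#' @param baseline_discriminability baseline evidence strength delta0.
#' @param metacognitive_noise sigma_m >= 0, sd of post-decision noise on
#'   the evidence feeding confidence.
#' @param confidence_bias beta > 0 scaling confidence; > 1 produces
#'   overconfidence.
#' @param ppv_mixture numeric vector of 4 nonnegative weights summing to
#'   1, named `correct`, `confusion_sensitivity`, `confusion_specificity`,
#'   `other_incorrect`, applying to the CP framing.
#' @param nf_correct_multiplier factor (>= 1) applied to the correct
#'   weight under NF framing before renormalisation.
#' @param ppv_confidence list of `c(shape1, shape2)` Beta parameters per
#'   category; confidence is drawn as 100 * Beta. Defaults give high
#'   confidence in confusion answers (similar to or higher than for
#'   correct answers) and lower confidence in other errors.
#' @param classifier a [classifier_config()] providing the anchors and
#'   windows estimates are drawn around.
#' @param seed integer master seed; per-participant substreams are derived
#'   by stable hashing so partial regeneration is reproducible.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_per_profile = c(student = 522, resident = 151, foreign = 22, physician = 203),
    claims = default_claims(),
    ability_sd = 0.8,
    baseline_discriminability = 0.8,
    metacognitive_noise = 1.0,
    confidence_bias = 1.3,
    ppv_mixture = c(correct = 0.08, confusion_sensitivity = 0.41,
                    confusion_specificity = 0.12, other_incorrect = 0.39),
    nf_correct_multiplier = 2,
    ppv_confidence = list(correct = c(12, 2), confusion_sensitivity = c(10, 2),
                          confusion_specificity = c(14, 1), other_incorrect = c(5, 2)),
    classifier = classifier_config(),
    seed = 20210802L) {
  problems <- character()
  if (!length(n_per_profile) || is.null(names(n_per_profile)) ||
      any(n_per_profile < 0) || any(n_per_profile != round(n_per_profile))) {
    problems <- c(problems, "n_per_profile must be named nonnegative integers")
  }
  cl_cols <- c("exercise_id", "claim_id", "truth", "difficulty")
  if (!is.data.frame(claims) || !all(cl_cols %in% names(claims)) ||
      !is.logical(claims$truth)) {
    problems <- c(problems, "claims must be a data.frame with exercise_id, claim_id, truth (logical), difficulty")
  }
  if (!is.numeric(ability_sd) || ability_sd <= 0) {
    problems <- c(problems, "ability_sd must be > 0")
  }
  if (!is.numeric(metacognitive_noise) || metacognitive_noise < 0) {
    problems <- c(problems, "metacognitive_noise must be >= 0")
  }
  if (!is.numeric(confidence_bias) || confidence_bias <= 0) {
    problems <- c(problems, "confidence_bias must be > 0")
  }
  mix_names <- c("correct", "confusion_sensitivity", "confusion_specificity",
                 "other_incorrect")
  if (length(ppv_mixture) != 4 || !setequal(names(ppv_mixture), mix_names) ||
      any(ppv_mixture < 0) || abs(sum(ppv_mixture) - 1) > 1e-8) {
    problems <- c(problems, "ppv_mixture must be 4 named nonnegative weights summing to 1")
  }
  if (!is.numeric(nf_correct_multiplier) || nf_correct_multiplier < 1) {
    problems <- c(problems, "nf_correct_multiplier must be >= 1")
  }
  if (length(problems)) {
    stop("invalid simulation config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(
    list(n_per_profile = n_per_profile, claims = claims, ability_sd = ability_sd,
         baseline_discriminability = baseline_discriminability,
         metacognitive_noise = metacognitive_noise,
         confidence_bias = confidence_bias,
         ppv_mixture = ppv_mixture[mix_names],
         nf_correct_multiplier = nf_correct_multiplier,
         ppv_confidence = ppv_confidence, classifier = classifier,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Default claim set: two exercises of six claims
#'
#' Difficulties span an easy-to-hard gradient so per-claim accuracy
#' spreads widely, as observed in real cohorts.
#'
#' @return data.frame with `exercise_id`, `claim_id`, `truth`,
#'   `difficulty`.
#' @export
default_claims <- function() {
  data.frame(
    exercise_id = rep(c("vaccine_efficacy", "p_value"), each = 6),
    claim_id = c(paste0("vac", 1:6), paste0("pval", 1:6)),
    truth = rep(c(TRUE, FALSE), 6),
    difficulty = seq(-1.2, 1.4, length.out = 12)
  )
}

# stable 31-bit string hash for per-participant substreams
.stable_hash <- function(s) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

.substream_seed <- function(seed, id, tag) {
  as.integer((as.double(seed) + .stable_hash(paste0(tag, ":", id))) %% 2147483647)
}

.participant_frame <- function(config) {
  profiles <- rep(names(config$n_per_profile), config$n_per_profile)
  data.frame(
    participant_id = sprintf("P%04d", seq_along(profiles)),
    profile = profiles
  )
}

#' Simulate double-sided VAS responses to the claim exercises
#'
#' See the model sketch in the package vignette: ability and claim
#' difficulty set per-cell discriminability, an evidence sample sets the
#' verdict, and a noisy readout of the same evidence sets confidence.
#' Identical config (including seed) gives identical output.
#'
#' @param config a [simulation_config()].
#' @return an object of class `synthetic_claims`: a list with
#'   `responses` (visible long table: `participant_id`, `exercise_id`,
#'   `claim_id`, `vas_value`), `claim_key`, `demographics`
#'   (`participant_id`, `profile`, `gender`, `math_degree`, `phd`,
#'   `research_fraction`) and `hidden` (ground truth per cell: `theta`,
#'   `d_ij`, `evidence`, `p_correct`), kept separate so analysis code
#'   never sees it.
#' @export
simulate_claim_responses <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  participants <- .participant_frame(config)
  claims <- config$claims
  nc <- nrow(claims)
  t_j <- ifelse(claims$truth, 1, -1)

  # gender proportions by profile emulate the strong profile gradient of
  # real clinician cohorts (women majorities among students/residents)
  p_woman <- c(student = 0.71, resident = 0.67, foreign = 0.64, physician = 0.43)

  res <- vector("list", nrow(participants))
  hid <- vector("list", nrow(participants))
  demo <- vector("list", nrow(participants))
  for (i in seq_len(nrow(participants))) {
    pid <- participants$participant_id[i]
    set.seed(.substream_seed(config$seed, pid, "claims"))
    theta <- stats::rnorm(1, 0, config$ability_sd)
    d_ij <- pmax(0, config$baseline_discriminability + theta - claims$difficulty)
    e <- stats::rnorm(nc, t_j * d_ij / 2, 1)
    eta <- stats::rnorm(nc, 0, config$metacognitive_noise)
    confidence <- pmin(pmax(100 * config$confidence_bias *
                              (2 * stats::pnorm(abs(e + eta)) - 1), 0), 100)
    verdict <- sign(e)
    res[[i]] <- data.frame(
      participant_id = pid,
      exercise_id = claims$exercise_id,
      claim_id = claims$claim_id,
      vas_value = verdict * confidence
    )
    hid[[i]] <- data.frame(
      participant_id = pid, claim_id = claims$claim_id,
      theta = theta, d_ij = d_ij, evidence = e,
      p_correct = stats::pnorm(d_ij / 2)
    )
    demo[[i]] <- data.frame(
      participant_id = pid,
      profile = participants$profile[i],
      gender = ifelse(stats::runif(1) < p_woman[[participants$profile[i]]],
                      "woman", "man"),
      math_degree = stats::runif(1) < 0.03,
      phd = stats::runif(1) < 0.05,
      research_fraction = sample(c(0, 0.05, 0.1, 0.25, 0.5), 1,
                                 prob = c(0.55, 0.15, 0.15, 0.1, 0.05))
    )
  }
  structure(
    list(responses = do.call(rbind, res),
         claim_key = claims[, c("exercise_id", "claim_id", "truth")],
         demographics = do.call(rbind, demo),
         hidden = do.call(rbind, hid),
         config = config),
    class = "synthetic_claims"
  )
}

#' Simulate the PPV calculation task
#'
#' Each participant is assigned the conditional-probability (CP) or
#' natural-frequency (NF) framing with equal probability, draws an answer
#' category from the framing's mixture (NF scales the correct weight by
#' `nf_correct_multiplier`, then renormalises), and produces an estimate
#' inside the drawn category's window — uniform over the window for the
#' anchored categories, uniform over \[0, 100\] excluding all three
#' windows for `other_incorrect` — with confidence drawn from the
#' category's Beta distribution.
#'
#' @param config a [simulation_config()].
#' @return an object of class `synthetic_ppv`: list with `responses`
#'   (visible: `participant_id`, `framing`, `estimate`, `confidence`) and
#'   `hidden` (`category_drawn`), plus the mixture actually used per
#'   framing in `mixtures`.
#' @export
simulate_ppv_task <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  participants <- .participant_frame(config)
  cfg_cls <- config$classifier
  mix_cp <- config$ppv_mixture
  mix_nf <- mix_cp
  mix_nf["correct"] <- mix_nf["correct"] * config$nf_correct_multiplier
  mix_nf <- mix_nf / sum(mix_nf)
  cats <- names(mix_cp)

  windows <- rbind(
    c(cfg_cls$correct_center - cfg_cls$correct_halfwidth,
      cfg_cls$correct_center + cfg_cls$correct_halfwidth),
    c(cfg_cls$sens_anchor - cfg_cls$confusion_halfwidth,
      cfg_cls$sens_anchor + cfg_cls$confusion_halfwidth),
    c(cfg_cls$spec_anchor - cfg_cls$confusion_halfwidth,
      cfg_cls$spec_anchor + cfg_cls$confusion_halfwidth)
  )
  draw_other <- function() {
    repeat {
      u <- stats::runif(1, 0, 100)
      inside <- any(u >= windows[, 1] & u <= windows[, 2])
      if (!inside) return(u)
    }
  }
  centers <- c(correct = cfg_cls$correct_center,
               confusion_sensitivity = cfg_cls$sens_anchor,
               confusion_specificity = cfg_cls$spec_anchor)
  halfw <- c(correct = cfg_cls$correct_halfwidth,
             confusion_sensitivity = cfg_cls$confusion_halfwidth,
             confusion_specificity = cfg_cls$confusion_halfwidth)

  n <- nrow(participants)
  framing <- character(n); category <- character(n)
  estimate <- numeric(n); confidence <- numeric(n)
  for (i in seq_len(n)) {
    pid <- participants$participant_id[i]
    set.seed(.substream_seed(config$seed, pid, "ppv"))
    framing[i] <- if (stats::runif(1) < 0.5) "CP" else "NF"
    mix <- if (framing[i] == "NF") mix_nf else mix_cp
    category[i] <- sample(cats, 1, prob = mix)
    estimate[i] <- if (category[i] == "other_incorrect") {
      draw_other()
    } else {
      ctr <- centers[[category[i]]]
      hw <- halfw[[category[i]]]
      min(100, max(0, ctr + stats::runif(1, -hw, hw)))
    }
    bp <- config$ppv_confidence[[category[i]]]
    confidence[i] <- 100 * stats::rbeta(1, bp[1], bp[2])
  }
  structure(
    list(responses = data.frame(participant_id = participants$participant_id,
                                framing = framing, estimate = estimate,
                                confidence = confidence),
         hidden = data.frame(participant_id = participants$participant_id,
                             category_drawn = category),
         mixtures = list(CP = mix_cp, NF = mix_nf),
         config = config),
    class = "synthetic_ppv"
  )
}

#' Parameter-recovery report for a synthetic cohort
#'
#' Compares what the analysis pipeline estimates from the visible tables
#' with the generator's hidden ground truth: per-claim accuracy against
#' the model-implied mean Phi(d_ij / 2) (with 95% binomial CI coverage),
#' and — when a PPV simulation is supplied — classified category
#' proportions per framing against the generating mixture.
#'
#' @param sim a `synthetic_claims` object.
#' @param ppv_sim optional `synthetic_ppv` object from the same config.
#' @return a list with `claim_accuracy` (per-claim observed vs expected
#'   accuracy, CI bounds, `covered`), `coverage` (fraction of claims whose
#'   expected accuracy lies in the observed 95% CI) and, if `ppv_sim` is
#'   given, `ppv_mixture` (per framing: estimated vs true weights and
#'   max absolute error).
#' @export
recovery_report <- function(sim, ppv_sim = NULL) {
  stopifnot(inherits(sim, "synthetic_claims"))
  scored <- score_responses(sim$responses, sim$claim_key)
  obs <- tapply(scored$correct == 1L, scored$claim_id, mean)
  n_obs <- tapply(scored$correct, scored$claim_id, length)
  expd <- tapply(sim$hidden$p_correct, sim$hidden$claim_id, mean)
  ids <- names(obs)
  ci <- t(vapply(ids, function(id) {
    k <- round(obs[[id]] * n_obs[[id]])
    as.numeric(stats::binom.test(k, n_obs[[id]])$conf.int)
  }, numeric(2)))
  claim_accuracy <- data.frame(
    claim_id = ids,
    observed = as.numeric(obs[ids]),
    expected = as.numeric(expd[ids]),
    ci_lower = ci[, 1], ci_upper = ci[, 2],
    covered = expd[ids] >= ci[, 1] & expd[ids] <= ci[, 2]
  )
  rownames(claim_accuracy) <- NULL
  out <- list(claim_accuracy = claim_accuracy,
              coverage = mean(claim_accuracy$covered))
  if (!is.null(ppv_sim)) {
    stopifnot(inherits(ppv_sim, "synthetic_ppv"))
    tab <- tabulate_ppv_answers(ppv_sim$responses, ppv_sim$config$classifier)
    counts <- attr(tab, "counts")
    est <- sweep(counts, 1, rowSums(counts), "/")
    truth <- rbind(CP = ppv_sim$mixtures$CP, NF = ppv_sim$mixtures$NF)
    out$ppv_mixture <- list(
      estimated = est, true = truth[rownames(est), colnames(est)],
      max_abs_error = max(abs(est - truth[rownames(est), colnames(est)]))
    )
  }
  out
}
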