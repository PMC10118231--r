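test_that("summarize_participant computes counts, means and discrimination", {
  sc <- data.frame(participant_id = "p",
                   confidence = c(80, 90, 100, 40, 60),
                   correct = c(1L, 1L, 1L, -1L, -1L))
  s <- summarize_participant(sc)
  expect_equal(s$n_answered, 5)
  expect_equal(s$n_correct, 3)
  expect_equal(s$mean_conf_correct, 90)
  expect_equal(s$mean_conf_incorrect, 50)
  expect_equal(s$discrimination, 40)

  # all correct: discrimination undefined
  allc <- data.frame(participant_id = "p", confidence = rep(100, 12),
                     correct = rep(1L, 12))
  s2 <- summarize_participant(allc)
  expect_equal(s2$n_correct, 12)
  expect_equal(s2$mean_confidence, 100)
  expect_true(is.na(s2$discrimination))

  # equal confidence, mixed correctness: discrimination zero
  eq <- data.frame(participant_id = "p", confidence = rep(70, 4),
                   correct = c(1L, -1L, 1L, -1L))
  expect_equal(summarize_participant(eq)$discrimination, 0)

  expect_error(summarize_participant(allc[0, ]), "no scored responses")
})

test_that("summarize_participants joins demographics and respects policy NAs", {
  scored <- scored_fixture()
  demo <- data.frame(participant_id = c("p1", "p2", "p3"),
                     profile = c("student", "resident", "physician"))
  s <- summarize_participants(scored, demo)
  expect_equal(nrow(s), 3)
  expect_equal(s$profile, c("student", "resident", "physician"))
  expect_equal(s$n_correct[s$participant_id == "p1"], 4)
  # p3's x = 0 response counts as incorrect with confidence 0
  p3 <- s[s$participant_id == "p3", ]
  expect_equal(p3$mean_conf_incorrect, 0)
  expect_equal(p3$discrimination, 85)
})

test_that("calibration_curve groups on the probability scale with SEM", {
  one <- data.frame(n_correct = 5, mean_confidence = 60)
  curve <- calibration_curve(one, n_claims = 12)
  expect_equal(nrow(curve), 13)
  expect_equal(curve$mean_confidence[curve$n_correct == 5], 80)
  expect_equal(curve$n_participants[curve$n_correct == 5], 1)
  expect_equal(sum(curve$n_participants), 1)

  two <- data.frame(n_correct = c(4, 4), mean_confidence = c(70, 70))
  c2 <- calibration_curve(two)
  expect_equal(c2$sem[c2$n_correct == 4], 0)
  expect_equal(sum(c2$n_participants), nrow(two))
})

test_that("confidence independent of correctness gives a flat calibration curve", {
  set.seed(11)
  n <- 4000
  summaries <- data.frame(
    n_correct = rbinom(n, 12, 0.55),
    mean_confidence = runif(n, 40, 80)  # independent of performance
  )
  curve <- calibration_curve(summaries)
  mid <- curve[curve$n_participants >= 50, ]
  expect_lt(max(mid$mean_confidence) - min(mid$mean_confidence), 2)
})

test_that("discrimination_by_group averages eligible participants per group", {
  s <- data.frame(profile = c("a", "a", "b", "b"),
                  mean_conf_correct = c(90, 80, 70, NA),
                  mean_conf_incorrect = c(50, 60, 70, 20),
                  discrimination = c(40, 20, 0, NA))
  out <- discrimination_by_group(s, by = "profile")
  expect_equal(out$delta[out$group == "a"], 30)
  expect_equal(out$delta[out$group == "b"], 0)
  expect_equal(out$n, c(2L, 1L))

  s$discrimination[3] <- NA
  expect_message(discrimination_by_group(s, by = "profile"), "group\\(s\\): b")
})

test_that("permuting confidence within participant destroys discrimination", {
  set.seed(7)
  sim <- simulate_claim_responses(small_sim_config(metacognitive_noise = 0))
  scored <- score_responses(sim$responses, sim$claim_key)
  base <- summarize_participants(scored)
  expect_gt(mean(base$discrimination, na.rm = TRUE), 10)

  scored_ord <- scored[order(scored$participant_id), ]
  deltas <- replicate(20, {
    shuffled <- scored_ord
    shuffled$confidence <- unlist(
      lapply(split(scored_ord$confidence, scored_ord$participant_id), sample),
      use.names = FALSE)
    mean(summarize_participants(shuffled)$discrimination, na.rm = TRUE)
  })
  expect_lt(abs(mean(deltas)), 3)
})

test_that("classify_advanced applies the degree/PhD/research-time rule", {
  expect_equal(classify_advanced(c(FALSE, FALSE, TRUE, FALSE),
                                 c(FALSE, FALSE, FALSE, TRUE),
                                 c(0.25, 0.19, 0, 0)),
               c(TRUE, FALSE, TRUE, TRUE))
  expect_warning(out <- classify_advanced(NA, FALSE, 0.1), "missing")
  expect_false(out)
})

test_that("sqrt_conf_transform is the stated decreasing map", {
  expect_equal(sqrt_conf_transform(c(100, 0, 75)), c(0, 10, 5))
  conf <- seq(0, 100, by = 5)
  expect_true(all(diff(sqrt_conf_transform(conf)) < 0))
  expect_error(sqrt_conf_transform(101), "out of")
})

test_that("export_long produces a per-response covariate table", {
  scored <- scored_fixture()
  demo <- data.frame(participant_id = c("p1", "p2", "p3"),
                     profile = c("student", "resident", "physician"))
  long <- export_long(scored, demo)
  expect_equal(nrow(long), nrow(scored))
  expect_true(all(c("correct", "confidence", "d", "profile") %in% names(long)))
  expect_equal(unique(long$profile[long$participant_id == "p2"]), "resident")
})
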