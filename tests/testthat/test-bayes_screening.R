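test_that("ppv and npv evaluate the Bayes formulas", {
  p <- test_parameters(0.9, 0.91, 0.01)
  expect_equal(ppv(p), 0.9 * 0.01 / (0.9 * 0.01 + 0.09 * 0.99))
  expect_equal(ppv(p), 0.09174312, tolerance = 1e-7)
  expect_equal(npv(p), 0.91 * 0.99 / (0.91 * 0.99 + 0.1 * 0.01))
  expect_equal(npv(p), 0.9988907, tolerance = 1e-6)
  expect_equal(ppv(test_parameters(0.7, 1, 0.3)), 1)
  expect_equal(npv(test_parameters(1, 0.6, 0.5)), 1)
  expect_equal(npv(test_parameters(0.9, 0.99, 0)), 1)
  expect_error(ppv(test_parameters(0.9, 1, 0)), "undefined")
  expect_error(test_parameters(1.2, 0.5, 0.5), "probability")
})

test_that("ppv rises and npv falls with prevalence", {
  prev <- seq(0.01, 0.99, by = 0.02)
  for (se in c(0.7, 0.9)) for (sp in c(0.8, 0.99)) {
    ppvs <- vapply(prev, function(q) ppv(test_parameters(se, sp, q)), 0)
    npvs <- vapply(prev, function(q) npv(test_parameters(se, sp, q)), 0)
    expect_true(all(diff(ppvs) > 0))
    expect_true(all(diff(npvs) < 0))
  }
})

test_that("cp_to_nf reproduces printed worked examples", {
  # 1% prevalence, 90/91 test in a population of 1000:
  # 10 diseased, 9 true positives, 89 false positives
  tab <- cp_to_nf(test_parameters(0.9, 0.91, 0.01), 1000)
  expect_equal(unclass(tab)[c("n_total", "n_diseased", "n_true_positive", "n_false_positive")],
               list(n_total = 1000, n_diseased = 10, n_true_positive = 9,
                    n_false_positive = 89))
  expect_equal(nf_to_ppv(tab), 9 / 98)

  # sensitivity 90% rendered over 40 diseased gives 36 true positives
  tab40 <- cp_to_nf(test_parameters(0.9, 0.99, 40 / 10256), 10256)
  expect_equal(tab40$n_diseased, 40)
  expect_equal(tab40$n_true_positive, 36)

  expect_equal(unlist(unclass(cp_to_nf(test_parameters(1, 1, 0.5), 10))[-1]),
               c(n_diseased = 5, n_true_positive = 5, n_false_positive = 0))
})

test_that("rounding = 'none' makes nf_to_ppv an exact inverse of ppv", {
  grid <- expand.grid(se = c(0.5, 0.9, 0.99), sp = c(0.6, 0.91, 0.99),
                      prev = c(0.0039, 0.01, 0.3), N = c(37, 1000))
  for (i in seq_len(nrow(grid))) {
    p <- test_parameters(grid$se[i], grid$sp[i], grid$prev[i])
    expect_equal(nf_to_ppv(cp_to_nf(p, grid$N[i], rounding = "none")), ppv(p),
                 tolerance = 1e-12)
  }
})

test_that("nf_table enforces its count invariants", {
  expect_error(nf_table(100, 101, 0, 0), "exceeds n_total")
  expect_error(nf_table(100, 10, 11, 0), "exceeds n_diseased")
  expect_error(nf_table(100, 10, 9, 91), "healthy")
  expect_error(nf_table(100, 10, 9.5, 10), "integers")
  expect_error(nf_to_ppv(nf_table(100, 0, 0, 0)), "no positive tests")
})

test_that("classify_estimate applies closed windows with stated precedence", {
  expect_equal(as.character(classify_estimate(c(26, 31, 21, 90.5, 89, 91, 99, 98, 100, 50, 0))),
               c("correct", "correct", "correct",
                 "confusion_sensitivity", "confusion_sensitivity", "confusion_sensitivity",
                 "confusion_specificity", "confusion_specificity", "confusion_specificity",
                 "other_incorrect", "other_incorrect"))
  expect_error(classify_estimate(101), "out of")

  # every estimate maps to exactly one category under the default windows
  grid <- seq(0, 100, by = 0.25)
  cats <- classify_estimate(grid)
  expect_false(anyNA(cats))
  in_correct <- abs(grid - 26) <= 5
  in_sens <- abs(grid - 90) <= 1
  in_spec <- abs(grid - 99) <= 1
  expect_equal(cats == "correct", in_correct)
  expect_equal(cats == "confusion_sensitivity", in_sens)
  expect_equal(cats == "confusion_specificity", in_spec)
  expect_equal(cats == "other_incorrect", !(in_correct | in_sens | in_spec))

  # overlapping user windows: correct dominates, then sensitivity
  overlap <- classifier_config(correct_center = 88, correct_halfwidth = 3,
                               sens_anchor = 90, spec_anchor = 91,
                               confusion_halfwidth = 2)
  expect_equal(as.character(classify_estimate(c(90, 92, 93), overlap)),
               c("correct", "confusion_sensitivity", "confusion_specificity"))
})

test_that("flag_noninformative is the closed box around the slider defaults", {
  expect_true(flag_noninformative(50, 50))
  expect_true(flag_noninformative(45, 55))
  expect_false(flag_noninformative(26, 95))
  expect_false(flag_noninformative(44.9, 50))
  expect_false(flag_noninformative(50, 55.1))
})

test_that("blue_zone_width follows the quadratic widget formula", {
  expect_equal(blue_zone_width(c(0, 50, 100)), c(0, 50, 200))
  expect_equal(blue_zone_width(100, clip = TRUE), 100)
  # uncertainty coding: low confidence setting -> wide zone
  expect_equal(blue_zone_width(c(0, 100), slider_encodes = "uncertainty"), c(200, 0))
})

test_that("tabulate_ppv_answers classifies and counts by framing", {
  df <- data.frame(
    participant_id = paste0("p", 1:6),
    framing = c("CP", "CP", "NF", "NF", "NF", "CP"),
    estimate = c(26, 90, 99, 50, 28, 51),
    confidence = c(90, 80, 95, 52, 70, 49)
  )
  out <- tabulate_ppv_answers(df)
  expect_equal(as.character(out$category),
               c("correct", "confusion_sensitivity", "confusion_specificity",
                 "other_incorrect", "correct", "other_incorrect"))
  expect_equal(out$noninformative, c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE))
  counts <- attr(out, "counts")
  expect_equal(as.integer(counts["NF", c("correct", "confusion_specificity")]), c(1L, 1L))
  expect_error(tabulate_ppv_answers(transform(df, framing = "nf")), "framing")
})

test_that("the shipped task config yields the stated PPV and frequency rendering", {
  cfg <- load_ppv_config()
  expect_equal(ppv(cfg$params), 0.2605597, tolerance = 1e-6)
  tab <- cp_to_nf(cfg$params, cfg$n_total)
  expect_equal(tab$n_diseased, 40)
  expect_equal(tab$n_true_positive, 36)
  expect_equal(round(100 * ppv(cfg$params)), cfg$classifier$correct_center)
})
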