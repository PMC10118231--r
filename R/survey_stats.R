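# Classical test statistics with the conventions under which the printed
# values of clinician-survey reports reproduce: Yates continuity
# correction on by default for 2x2 contingency and one-sample proportion
# chi-squares, two-sided p values throughout.

#' Construct a test result
#'
#' Light container used by all tests in this module.
#'
#' @param test name of the test.
#' @param statistic test statistic.
#' @param df degrees of freedom (`NA` where not applicable).
#' @param p_value two-sided p value.
#' @param estimate optional point estimate (e.g. Pearson r).
#' @return an object of class `vasmeta_test`.
#' @keywords internal
new_test_result <- function(test, statistic, df = NA_real_, p_value, estimate = NULL) {
  structure(
    list(test = test, statistic = unname(statistic), df = unname(df),
         p_value = unname(p_value), estimate = unname(estimate)),
    class = "vasmeta_test"
  )
}

#' @export
print.vasmeta_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.3g\n", x$test, x$statistic,
              if (is.na(x$df)) "" else sprintf(", df = %.4g", x$df), x$p_value))
  invisible(x)
}

#' @export
as.data.frame.vasmeta_test <- function(x, ...) {
  data.frame(test = x$test, statistic = x$statistic, df = x$df,
             p_value = x$p_value,
             estimate = if (is.null(x$estimate)) NA_real_ else x$estimate)
}

#' Pearson chi-square test on a contingency table
#'
#' For 2x2 tables the Yates continuity correction (|O - E| reduced by
#' 0.5, floored at 0) is applied by default; larger tables use the plain
#' Pearson statistic with df = (r-1)(c-1).
#'
#' @param counts matrix (or table) of nonnegative counts, at least 2x2.
#' @param continuity_correction apply Yates' correction (2x2 only;
#'   default `TRUE` for 2x2, ignored with a message otherwise).
#' @return a `vasmeta_test`.
#' @examples
#' chi2_contingency(matrix(c(72, 271, 30, 308), 2, byrow = TRUE))
#' @export
chi2_contingency <- function(counts, continuity_correction = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("contingency table must be at least 2x2", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("contingency table must contain nonnegative integer counts", call. = FALSE)
  }
  is2x2 <- nrow(counts) == 2 && ncol(counts) == 2
  if (is.null(continuity_correction)) continuity_correction <- is2x2
  if (continuity_correction && !is2x2) {
    message("continuity correction only applies to 2x2 tables; ignored")
    continuity_correction <- FALSE
  }
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0)) stop(sprintf("row %d of the table is all zero", which(rs == 0)[1]),
                         call. = FALSE)
  if (any(cs == 0)) stop(sprintf("column %d of the table is all zero", which(cs == 0)[1]),
                         call. = FALSE)
  expected <- outer(rs, cs) / sum(counts)
  if (any(expected < 5)) {
    warning("some expected cell counts are below 5; the chi-square approximation may be poor",
            call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = continuity_correction))
  new_test_result("chi-square (contingency)", res$statistic,
                  res$parameter, res$p.value)
}

#' One-sample chi-square test of a proportion
#'
#' Tests `successes / n` against a reference proportion `p0` with df = 1,
#' applying Yates' continuity correction by default (the convention under
#' which published comparisons against registry proportions reproduce).
#'
#' @param successes,n observed successes out of n.
#' @param p0 reference proportion, strictly inside (0, 1).
#' @param continuity_correction apply |O - E| - 0.5 (floored at 0).
#' @return a `vasmeta_test`.
#' @export
chi2_gof_proportion <- function(successes, n, p0, continuity_correction = TRUE) {
  stopifnot(length(successes) == 1, length(n) == 1, length(p0) == 1)
  if (successes < 0 || successes > n) stop("successes must be in [0, n]", call. = FALSE)
  if (p0 <= 0 || p0 >= 1) stop("p0 must be strictly between 0 and 1", call. = FALSE)
  observed <- c(successes, n - successes)
  expected <- c(n * p0, n * (1 - p0))
  dev <- abs(observed - expected)
  if (continuity_correction) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  new_test_result("chi-square (proportion)", stat, 1,
                  stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Welch's two-sample t test
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @return a `vasmeta_test` with the Welch statistic and
#'   Welch-Satterthwaite df.
#' @export
welch_t <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    stop("both samples have zero variance", call. = FALSE)
  }
  res <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  new_test_result("Welch t", res$statistic, res$parameter, res$p.value,
                  estimate = unname(res$estimate[1] - res$estimate[2]))
}

#' Pearson correlation with two-sided p value
#'
#' @param xs,ys numeric vectors of equal length >= 3 with nonzero
#'   variance.
#' @return a `vasmeta_test`; `estimate` holds r.
#' @export
pearson_r <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("xs and ys must have equal length", call. = FALSE)
  if (length(xs) < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::var(xs) == 0 || stats::var(ys) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  res <- stats::cor.test(xs, ys, method = "pearson")
  new_test_result("Pearson r", res$statistic, res$parameter, res$p.value,
                  estimate = res$estimate)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Uses the normal approximation with tie correction and continuity
#' correction (exact enumeration for tiny samples is left to callers that
#' need it; tests in this package use brute-force enumeration as an
#' independent oracle).
#'
#' @param sample_a,sample_b nonempty numeric vectors.
#' @return a `vasmeta_test`; `statistic` is the Mann-Whitney U of
#'   `sample_a`.
#' @export
mann_whitney <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  res <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, exact = FALSE, correct = TRUE)
  )
  new_test_result("Mann-Whitney U", res$statistic, NA_real_, res$p.value)
}

#' Hypergeometric test for over-representation
#'
#' Upper-tail probability `P(X >= k)` for X ~ Hypergeometric drawing `n`
#' from a population of `N` containing `K` marked items.
#'
#' @param k observed overlap.
#' @param K number of marked items in the population.
#' @param n sample size drawn.
#' @param N population size.
#' @return the upper-tail p value.
#' @export
hypergeom_over_representation <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (K > N || n > N || k > min(K, n) || any(c(k, K, n, N) < 0)) {
    stop("inconsistent hypergeometric counts: need k <= min(K, n), K <= N, n <= N",
         call. = FALSE)
  }
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Bind test results into a statistics report
#'
#' @param ... named `vasmeta_test` objects (names become the `label`
#'   column).
#' @return data.frame with one row per test.
#' @export
statistics_report <- function(...) {
  tests <- list(...)
  if (is.null(names(tests)) || any(names(tests) == "")) {
    stop("all test results must be named", call. = FALSE)
  }
  rows <- Map(function(label, t) cbind(label = label, as.data.frame(t)),
              names(tests), tests)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
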