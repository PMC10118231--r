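# independent oracles kept deliberately naive: direct formula evaluation
# and exhaustive enumeration on tiny inputs

pearson_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df)
}

# exact two-sided Mann-Whitney p by enumerating all rank assignments
mw_exact_oracle <- function(a, b) {
  u_stat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- u_stat(a, b)
  pool <- c(a, b)
  na <- length(a)
  idx <- utils::combn(length(pool), na)
  us <- apply(idx, 2, function(ii) u_stat(pool[ii], pool[-ii]))
  mu <- na * length(b) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

test_that("chi2_contingency matches the brute-force Pearson oracle", {
  set.seed(42)
  for (i in 1:25) {
    r <- sample(2:4, 1); cc <- sample(2:4, 1)
    tab <- matrix(rpois(r * cc, 30) + 1, r, cc)
    res <- suppressWarnings(chi2_contingency(tab, continuity_correction = FALSE))
    expect_equal(res$statistic, pearson_oracle(tab), tolerance = 1e-10)
    expect_equal(res$df, (r - 1) * (cc - 1))
    expect_gte(res$p_value, 0)
    expect_lte(res$p_value, 1)
    # invariance under simultaneous row and column permutation
    perm <- suppressWarnings(chi2_contingency(tab[sample(r), sample(cc)],
                                              continuity_correction = FALSE))
    expect_equal(perm$statistic, res$statistic, tolerance = 1e-10)
  }
})

test_that("Yates correction never increases the 2x2 statistic", {
  set.seed(1)
  for (i in 1:30) {
    tab <- matrix(rpois(4, 20) + 1, 2, 2)
    corr <- suppressWarnings(chi2_contingency(tab, continuity_correction = TRUE))
    plain <- suppressWarnings(chi2_contingency(tab, continuity_correction = FALSE))
    expect_lte(corr$statistic, plain$statistic + 1e-12)
  }
})

test_that("chi2_contingency rejects degenerate tables and warns on small cells", {
  expect_error(chi2_contingency(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), "row 1")
  expect_error(chi2_contingency(matrix(c(0, 3, 0, 4), 2, byrow = TRUE)), "column 1")
  expect_error(chi2_contingency(matrix(1:3, 1)), "at least 2x2")
  expect_warning(chi2_contingency(matrix(c(1, 2, 3, 4), 2), continuity_correction = FALSE),
                 "below 5")
  expect_equal(suppressWarnings(
    chi2_contingency(matrix(c(7, 9, 7, 9), 2, byrow = TRUE),
                     continuity_correction = FALSE))$statistic, 0)
})

test_that("chi2_gof_proportion matches its 1x2 expected construction", {
  gof_oracle <- function(s, n, p0, correct) {
    O <- c(s, n - s); E <- c(n * p0, n * (1 - p0))
    dev <- abs(O - E); if (correct) dev <- pmax(dev - 0.5, 0)
    sum(dev^2 / E)
  }
  set.seed(3)
  for (i in 1:20) {
    n <- sample(20:300, 1); s <- sample(0:n, 1); p0 <- runif(1, 0.05, 0.95)
    for (corr in c(TRUE, FALSE)) {
      res <- chi2_gof_proportion(s, n, p0, continuity_correction = corr)
      expect_equal(res$statistic, gof_oracle(s, n, p0, corr), tolerance = 1e-12)
      expect_equal(res$df, 1)
    }
  }
  expect_lt(chi2_gof_proportion(round(100 * 0.3), 100, 0.3,
                                continuity_correction = FALSE)$statistic, 1e-12)
  expect_error(chi2_gof_proportion(5, 10, 1), "strictly between")
  expect_error(chi2_gof_proportion(11, 10, 0.5), "\\[0, n\\]")
})

test_that("welch_t matches the textbook formula and is antisymmetric", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- welch_t(a, b)
  ora <- welch_oracle(a, b)
  expect_equal(res$statistic, ora$t, tolerance = 1e-12)
  expect_equal(res$df, ora$df, tolerance = 1e-12)

  swapped <- welch_t(b, a)
  expect_equal(swapped$statistic, -res$statistic)
  expect_equal(swapped$p_value, res$p_value)

  same <- welch_t(c(5, 6, 7, 9), c(5, 6, 7, 9))
  expect_equal(same$statistic, 0)
  expect_error(welch_t(1, c(2, 3)), "at least 2")
  expect_error(welch_t(c(2, 2), c(2, 2)), "zero variance")
})

test_that("pearson_r recovers exact and hand-computed correlations", {
  x <- c(1, 4, 9, 13)
  expect_equal(pearson_r(x, 2 * x + 1)$estimate, 1)
  expect_equal(pearson_r(x, -x)$estimate, -1)
  xs <- c(1, 2, 4); ys <- c(1, 3, 4)
  r_hand <- sum((xs - mean(xs)) * (ys - mean(ys))) /
    sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
  expect_equal(pearson_r(xs, ys)$estimate, r_hand, tolerance = 1e-12)
  expect_error(pearson_r(c(1, 1, 1), ys), "constant")
  expect_error(pearson_r(1:4, 1:5), "equal length")
})

test_that("mann_whitney agrees with exhaustive enumeration on tiny samples", {
  cases <- list(
    list(a = c(1.2, 5.1, 7.4), b = c(2.3, 3.1, 9.2, 11.5)),
    list(a = c(10, 20, 30, 40), b = c(5, 15, 25)),
    list(a = c(1, 2), b = c(3, 4, 5, 6))
  )
  u_brute <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  for (cs in cases) {
    res <- mann_whitney(cs$a, cs$b)
    expect_equal(res$statistic, u_brute(cs$a, cs$b))
    expect_lt(abs(res$p_value - mw_exact_oracle(cs$a, cs$b)), 0.06)
  }
  # full dominance: U = n_a * n_b
  expect_equal(mann_whitney(c(10, 11, 12), c(1, 2))$statistic, 6)
  expect_gt(mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))$p_value, 0.9)
  expect_error(mann_whitney(numeric(0), 1), "nonempty")
})

test_that("hypergeometric over-representation matches tail enumeration", {
  expect_equal(hypergeom_over_representation(0, 4, 3, 10), 1)
  expect_equal(hypergeom_over_representation(4, 4, 4, 4), 1)
  # N = 10, K = 4, n = 3: P(X >= 2) = (C(4,2) C(6,1) + C(4,3)) / C(10,3) = 1/3
  expect_equal(hypergeom_over_representation(2, 4, 3, 10), 1 / 3, tolerance = 1e-12)
  pmf_sum <- sum(vapply(2:3, function(k)
    choose(4, k) * choose(6, 3 - k) / choose(10, 3), 0))
  expect_equal(hypergeom_over_representation(2, 4, 3, 10), pmf_sum, tolerance = 1e-12)
  expect_error(hypergeom_over_representation(5, 4, 3, 10), "inconsistent")
})

test_that("statistics_report binds labelled results", {
  rep <- statistics_report(
    framing = chi2_contingency(matrix(c(72, 271, 30, 308), 2, byrow = TRUE)),
    residents = chi2_gof_proportion(99, 148, 0.612)
  )
  expect_equal(rep$label, c("framing", "residents"))
  expect_equal(round(rep$statistic, 1), c(18.7, 1.8))
  expect_error(statistics_report(chi2_gof_proportion(99, 148, 0.612)), "named")
})
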