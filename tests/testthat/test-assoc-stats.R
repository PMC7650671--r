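# Published 2x2 / 2x3 tables used throughout (counts as printed):
# co-occurrence pairs among the five most mutated loci, and the
# clinico-biological group tables.
T3 <- list(
  gpr_plek  = matrix(c(45, 11, 28, 19), 2),  # plain chi2, p 0.021
  adm_plek  = matrix(c(70, 3, 21, 9), 2),    # Yates,      p 0.0007
  adm_chr15 = matrix(c(88, 3, 7, 5), 2),     # Fisher,     p 0.0004
  c15_gpr   = matrix(c(55, 1, 40, 7), 2),    # Yates,      p 0.035
  c15_plek  = matrix(c(70, 3, 25, 5), 2))    # Fisher,     p 0.045

test_that("expected counts match hand arithmetic", {
  E <- expected_counts(T3$adm_plek)
  expect_equal(min(E), 12 * 30 / 103, tolerance = 1e-12)  # ~3.50
  expect_equal(E[1, 1], 91 * 73 / 103, tolerance = 1e-12)
  expect_equal(expected_counts(matrix(10, 2, 2)), matrix(10, 2, 2))
  expect_error(expected_counts(matrix(c(0, 5, 0, 5), 2)), "margin")
  expect_error(expected_counts(matrix(c(-1, 5, 2, 5), 2)), "non-negative")
})

test_that("chi-square statistics agree with the closed-form oracle", {
  set.seed(42)
  for (i in 1:20) {
    m <- matrix(rpois(4, 20) + 1, 2)
    plain <- chi_square_test(m)
    yates <- chi_square_test(m, yates = TRUE)
    expect_equal(plain$statistic, oracle_chi2_stat(m), tolerance = 1e-10)
    expect_equal(yates$statistic, oracle_chi2_stat(m, yates = TRUE),
                 tolerance = 1e-10)
    expect_equal(plain$df, 1)
    # the correction can only shrink the statistic, so p_plain <= p_yates
    expect_gte(plain$statistic, yates$statistic)
    expect_lte(plain$p_value, yates$p_value)
    expect_true(plain$p_value >= 0 && plain$p_value <= 1)
  }
})

test_that("chi-square handles independence, r x c, and degenerate input", {
  res <- chi_square_test(matrix(10, 2, 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  r23 <- chi_square_test(matrix(c(10, 20, 30, 12, 25, 28), 2))
  expect_equal(r23$df, 2)
  expect_error(chi_square_test(matrix(c(10, 20, 30, 12, 25, 28), 2),
                               yates = TRUE), "2x2")
})

test_that("two-sided Fisher matches exhaustive enumeration", {
  expect_equal(fisher_exact_two_sided(matrix(c(2, 0, 0, 2), 2))$p_value,
               1 / 3, tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(matrix(c(0, 5, 5, 0), 2))$p_value,
               2 / 252, tolerance = 1e-12)
  set.seed(7)
  for (i in 1:25) {
    m <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact_two_sided(m)$p_value, oracle_fisher2x2(m),
                 tolerance = 1e-9)
  }
})

test_that("Fisher flags zero-margin tables as degenerate with p = 1", {
  res <- fisher_exact_two_sided(matrix(c(0, 0, 3, 4), 2))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
})

test_that("the selection rule reproduces the published test choices", {
  res <- select_and_run_test(T3$gpr_plek)
  expect_equal(res$test_used, "chi2")
  expect_equal(round(res$p_value, 3), 0.021)

  res <- select_and_run_test(T3$adm_plek)
  expect_equal(res$test_used, "chi2_yates")
  expect_equal(round(res$p_value, 4), 0.0007)

  res <- select_and_run_test(T3$adm_chr15)
  expect_equal(res$test_used, "fisher")
  expect_equal(round(res$p_value, 4), 0.0004)

  res <- select_and_run_test(T3$c15_gpr)
  expect_equal(res$test_used, "chi2_yates")
  expect_equal(round(res$p_value, 3), 0.035)

  res <- select_and_run_test(T3$c15_plek)
  expect_equal(res$test_used, "fisher")
  expect_lt(abs(res$p_value - 0.045), 0.001)
})

test_that("selection thresholds are configurable", {
  # forcing low thresholds turns the Yates case into a plain chi-square
  res <- select_and_run_test(T3$adm_plek, thresholds = c(plain = 1, yates = 0))
  expect_equal(res$test_used, "chi2")
  res <- select_and_run_test(T3$gpr_plek, thresholds = c(plain = 99, yates = 99))
  expect_equal(res$test_used, "fisher")
})

test_that("tests are invariant under row/column permutation", {
  for (m in T3) {
    for (perm in list(m[2:1, ], m[, 2:1], m[2:1, 2:1], t(m))) {
      expect_equal(select_and_run_test(perm)$p_value,
                   select_and_run_test(m)$p_value, tolerance = 1e-9)
    }
  }
})

test_that("pairwise co-occurrence reproduces each published pair end-to-end", {
  # rebuild each pair's 103-sample binary matrix from the printed joints
  cases <- list(
    list(m = T3$gpr_plek, test = "chi2", p = 0.021, digits = 3),
    list(m = T3$adm_plek, test = "chi2_yates", p = 0.0007, digits = 4),
    list(m = T3$adm_chr15, test = "fisher", p = 0.0004, digits = 4),
    list(m = T3$c15_gpr, test = "chi2_yates", p = 0.035, digits = 3))
  for (cs in cases) {
    counts <- as.vector(cs$m)  # wt/wt, m/wt, wt/m, m/m for locus B rows
    a <- rep(c(0, 1, 0, 1), counts)
    b <- rep(c(0, 0, 1, 1), counts)
    mat <- cbind(A = a, B = b)
    res <- pairwise_cooccurrence(mat)
    expect_equal(nrow(res), 1L)
    expect_equal(res$test_used, cs$test)
    expect_equal(round(res$p_value, cs$digits), cs$p)
    expect_equal(res$a_wt_b_wt, cs$m[1, 1])
    expect_equal(res$a_m_b_m, cs$m[2, 2])
  }
})

test_that("pairwise co-occurrence flags constant loci untestable", {
  mat <- cbind(A = c(0, 1, 0, 1), B = c(0, 0, 0, 0))
  res <- pairwise_cooccurrence(mat)
  expect_true(res$untestable)
  expect_true(is.na(res$p_value))
  expect_error(pairwise_cooccurrence(mat[, 1, drop = FALSE]), "at least 2")
})

test_that("group-by-covariate tables reproduce the published associations", {
  g <- fixture_groups()
  sex <- fixture_covariate(c(3, 6, 8), c("female", "male"))
  res <- categorical_association(g, sex)
  expect_equal(res$test_used, "chi2")
  expect_equal(res$df, 2)
  expect_equal(round(res$p_value, 4), 0.0017)

  hist <- fixture_covariate(c(12, 26, 6), c("yes", "no"))
  expect_equal(round(categorical_association(g, hist)$p_value, 3), 0.039)

  fgfr3 <- fixture_covariate(c(6, 19, 3), c("mutated", "not_mutated"))
  expect_equal(round(categorical_association(g, fgfr3)$p_value, 3), 0.015)
})

test_that("missing covariates are excluded per test (pairwise deletion)", {
  g <- fixture_groups()
  # TERT status known for 102 of 103 samples: mutated 25/38/16 by group
  tert <- fixture_covariate(c(25, 38, 16), c("mutated", "not_mutated"))
  tert[39] <- NA  # the one G1 sample without a TERT call
  res <- categorical_association(g, tert)
  expect_equal(sum(!is.na(tert)), 102)
  expect_equal(round(res$p_value, 3), 0.082)
})

test_that("degenerate covariates are rejected", {
  g <- fixture_groups()
  expect_error(categorical_association(g, rep("x", length(g))),
               "fewer than 2")
})

test_that("chi-square p at df = 2 obeys the closed form exp(-x/2)", {
  g <- fixture_groups()
  sex <- fixture_covariate(c(3, 6, 8), c("female", "male"))
  res <- categorical_association(g, sex)
  expect_equal(res$p_value, exp(-res$statistic / 2), tolerance = 1e-12)
})

test_that("rank_group_test picks Mann-Whitney or Kruskal-Wallis by arity", {
  set.seed(9)
  x <- rnorm(60)
  g2 <- rep(c("a", "b"), 30)
  g3 <- rep(c("a", "b", "c"), 20)
  r2 <- rank_group_test(x, g2)
  expect_equal(r2$method, "mann_whitney")
  expect_equal(r2$p_value,
               wilcox.test(x ~ g2, exact = FALSE)$p.value, tolerance = 1e-12)
  r3 <- rank_group_test(x, g3)
  expect_equal(r3$method, "kruskal_wallis")
  expect_equal(r3$p_value, kruskal.test(x, factor(g3))$p.value,
               tolerance = 1e-12)
  expect_error(rank_group_test(x, rep("a", 60)), "2 non-empty")
})

test_that("constant values across groups are degenerate with p = 1", {
  res <- rank_group_test(rep(5, 30), rep(c("a", "b", "c"), 10))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
})
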