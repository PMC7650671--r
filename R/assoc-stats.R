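# Contingency statistics with explicit test selection.
#
# The bladder-cohort analyses report plain chi-square, Yates-corrected
# chi-square and two-sided Fisher exact p-values for 2x2 tables without
# stating which rule picked the test.  The rule implemented here — plain
# chi-square when every expected count is at least `plain`, Yates when every
# expected count is at least `yates` but some are below `plain`, Fisher
# otherwise — is the unique simple minimum-expected-count rule consistent
# with all the verifiable published p-values; both thresholds are arguments.

.new_contingency_result <- function(test_used, statistic, df, p_value,
                                    min_expected, degenerate = FALSE) {
  structure(list(test_used = test_used, statistic = statistic, df = df,
                 p_value = p_value, min_expected = min_expected,
                 degenerate = degenerate),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("<contingency_result> ", x$test_used,
      if (!is.na(x$statistic)) sprintf(", statistic = %.4g", x$statistic),
      if (!is.na(x$df)) sprintf(", df = %d", as.integer(x$df)),
      sprintf(", p = %.4f", x$p_value),
      if (x$degenerate) " [degenerate]", "\n", sep = "")
  invisible(x)
}

.check_table <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("contingency table must hold non-negative integers", call. = FALSE)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table must be at least 2x2", call. = FALSE)
  storage.mode(counts) <- "double"
  counts
}

#' Expected counts under independence
#'
#' `E[i,j] = rowsum_i * colsum_j / N`, the quantities the test-selection
#' rule inspects. Tables with a zero row or column margin are rejected:
#' they carry no information about association.
#'
#' @param counts Non-negative integer matrix, at least 2x2.
#' @return Real matrix of expected counts.
#' @examples
#' expected_counts(matrix(c(70, 3, 21, 9), 2))  # min expected 3.50
#' @export
expected_counts <- function(counts) {
  counts <- .check_table(counts)
  if (sum(counts) == 0) stop("empty table", call. = FALSE)
  rs <- rowSums(counts); cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0))
    stop("zero row/column margin: table not testable", call. = FALSE)
  outer(rs, cs) / sum(counts)
}

#' Pearson chi-square test (optionally Yates-corrected)
#'
#' Plain Pearson chi-square on an r x c table, or the continuity-corrected
#' version for 2x2 tables. The Yates term is floored so a corrected
#' deviation can never overshoot zero (the behaviour of
#' [stats::chisq.test()], which performs the computation). The p-value is
#' the upper chi-square tail with `(r-1)(c-1)` degrees of freedom.
#'
#' @param counts Contingency table (matrix).
#' @param yates Apply the continuity correction (2x2 tables only).
#' @return A `contingency_result`.
#' @examples
#' chi_square_test(matrix(c(45, 11, 28, 19), 2))               # p ~ 0.021
#' chi_square_test(matrix(c(70, 3, 21, 9), 2), yates = TRUE)   # p ~ 0.0007
#' @export
chi_square_test <- function(counts, yates = FALSE) {
  counts <- .check_table(counts)
  if (yates && !all(dim(counts) == 2L))
    stop("Yates correction applies to 2x2 tables only", call. = FALSE)
  E <- expected_counts(counts)
  if (any(E == 0))
    stop("zero expected count: chi-square undefined, use the Fisher test",
         call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(counts, correct = yates))
  .new_contingency_result(
    test_used = if (yates) "chi2_yates" else "chi2",
    statistic = unname(res$statistic), df = unname(res$parameter),
    p_value = res$p.value, min_expected = min(E))
}

#' Two-sided Fisher exact test for 2x2 tables
#'
#' Exact two-sided p-value by the point-probability rule: the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table
#' (the definition used by [stats::fisher.test()], which performs the
#' computation). A table with a zero margin is degenerate: p = 1 by
#' convention, flagged.
#'
#' @param counts 2x2 matrix of counts.
#' @return A `contingency_result` (no statistic or df).
#' @examples
#' fisher_exact_two_sided(matrix(c(88, 3, 7, 5), 2))  # p ~ 0.0004
#' fisher_exact_two_sided(matrix(c(2, 0, 0, 2), 2))   # p = 1/3
#' @export
fisher_exact_two_sided <- function(counts) {
  counts <- .check_table(counts)
  if (!all(dim(counts) == 2L))
    stop("Fisher exact test implemented for 2x2 tables", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    return(.new_contingency_result("fisher", NA_real_, NA_real_, 1,
                                   min_expected = NA_real_,
                                   degenerate = TRUE))
  p <- stats::fisher.test(counts)$p.value
  .new_contingency_result("fisher", NA_real_, NA_real_, min(p, 1),
                          min_expected = min(expected_counts(counts)))
}

#' Select and run the appropriate 2x2 test
#'
#' Applies the minimum-expected-count selection rule: plain chi-square when
#' every expected count is at least `thresholds["plain"]` (default 5), the
#' Yates-corrected chi-square when every expected count is at least
#' `thresholds["yates"]` (default 3) but some fall below `plain`, and the
#' two-sided Fisher exact test otherwise. The result records which test ran.
#'
#' @param counts 2x2 matrix of counts.
#' @param thresholds Named numeric vector with elements `plain` and `yates`.
#' @return A `contingency_result`.
#' @examples
#' select_and_run_test(matrix(c(45, 11, 28, 19), 2))  # chi2,   p ~ 0.021
#' select_and_run_test(matrix(c(55, 1, 40, 7), 2))    # Yates,  p ~ 0.035
#' select_and_run_test(matrix(c(70, 3, 25, 5), 2))    # Fisher, p ~ 0.045
#' @export
select_and_run_test <- function(counts, thresholds = c(plain = 5, yates = 3)) {
  counts <- .check_table(counts)
  if (!all(dim(counts) == 2L))
    stop("test selection applies to 2x2 tables", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    return(fisher_exact_two_sided(counts))
  minE <- min(expected_counts(counts))
  if (minE >= thresholds[["plain"]]) chi_square_test(counts, yates = FALSE)
  else if (minE >= thresholds[["yates"]]) chi_square_test(counts, yates = TRUE)
  else fisher_exact_two_sided(counts)
}

#' Pairwise co-occurrence tests between loci
#'
#' For every unordered pair of loci, builds the WT/mutated x WT/mutated 2x2
#' table across samples and applies [select_and_run_test()]. Pairs involving
#' a constant column (all samples WT, or all mutated) are flagged
#' untestable. A Bonferroni-adjusted p-value column is reported for
#' reference; significance calls in the published analysis use raw p-values.
#'
#' @param cm A `cohort_matrix`, or a plain binary samples x loci matrix.
#' @param loci Locus ids (column names) to test; default all columns.
#' @param thresholds Selection thresholds, see [select_and_run_test()].
#' @return Tidy data frame, one row per pair: counts (`a_wt_b_wt`,
#'   `a_wt_b_m`, `a_m_b_wt`, `a_m_b_m`), `test_used`, `statistic`, `df`,
#'   `p_value`, `p_bonferroni`, `odds_ratio`, `untestable`.
#' @export
pairwise_cooccurrence <- function(cm, loci = NULL,
                                  thresholds = c(plain = 5, yates = 3)) {
  calls <- if (inherits(cm, "cohort_matrix")) cm$calls else as.matrix(cm)
  if (is.null(loci)) loci <- colnames(calls)
  if (length(loci) < 2L) stop("need at least 2 loci", call. = FALSE)
  missing <- setdiff(loci, colnames(calls))
  if (length(missing))
    stop("unknown loci: ", paste(missing, collapse = ", "), call. = FALSE)

  pairs <- utils::combn(loci, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- calls[, pairs[1L, j]]; b <- calls[, pairs[2L, j]]
    tab <- table(factor(a, levels = 0:1), factor(b, levels = 0:1))
    cnt <- as.vector(tab)  # wt/wt, m/wt, wt/m, m/m (column-major)
    untestable <- length(unique(a)) < 2L || length(unique(b)) < 2L
    if (untestable) {
      res <- .new_contingency_result("none", NA_real_, NA_real_, NA_real_,
                                     NA_real_, degenerate = TRUE)
    } else {
      res <- select_and_run_test(unclass(tab), thresholds)
    }
    data.frame(locus_a = pairs[1L, j], locus_b = pairs[2L, j],
               a_wt_b_wt = cnt[1L], a_m_b_wt = cnt[2L],
               a_wt_b_m = cnt[3L], a_m_b_m = cnt[4L],
               test_used = res$test_used, statistic = res$statistic,
               df = res$df, p_value = res$p_value,
               odds_ratio = (cnt[1L] * cnt[4L]) / (cnt[2L] * cnt[3L]),
               untestable = untestable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_value * sum(!out$untestable))
  out
}

#' Association between signature groups and a categorical covariate
#'
#' Plain chi-square on the covariate x group (r x 3) table. Samples with a
#' missing covariate are excluded from this test only (pairwise deletion).
#' Covariate levels absent from the data are dropped with a warning.
#'
#' @param groups Factor of signature groups (`G1`/`G2`/`G3`), one per sample.
#' @param covariate Factor or character covariate, `NA` allowed.
#' @return A `contingency_result`.
#' @examples
#' # sex by group counts: males 36/40/10, females 3/6/8 -> p ~ 0.0017
#' g <- rep(c("G1", "G2", "G3"), c(39, 46, 18))
#' sex <- c(rep(c("M", "F"), c(36, 3)), rep(c("M", "F"), c(40, 6)),
#'          rep(c("M", "F"), c(10, 8)))
#' categorical_association(factor(g), sex)
#' @export
categorical_association <- function(groups, covariate) {
  stopifnot(length(groups) == length(covariate))
  keep <- !is.na(covariate) & !is.na(groups)
  groups <- factor(groups[keep])
  covariate <- factor(covariate[keep])
  empty <- levels(covariate)[table(covariate) == 0L]
  if (length(empty)) {
    warning("dropping empty covariate levels: ",
            paste(empty, collapse = ", "))
    covariate <- droplevels(covariate)
  }
  if (nlevels(covariate) < 2L)
    stop("covariate has fewer than 2 observed levels", call. = FALSE)
  tab <- table(covariate, groups)
  chi_square_test(unclass(tab), yates = FALSE)
}

#' Rank-based group comparison (Kruskal-Wallis / Mann-Whitney)
#'
#' Two groups: two-sided Mann-Whitney U (normal approximation with tie and
#' continuity correction). Three or more groups: tie-corrected
#' Kruskal-Wallis with the chi-square approximation. Constant values across
#' all groups are degenerate: p = 1, flagged.
#'
#' @param values Numeric vector.
#' @param groups Factor (2 or more levels present in the data).
#' @return List with `statistic`, `p_value`, `method`, `degenerate`.
#' @export
rank_group_test <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  if (nlevels(groups) < 2L || any(table(groups) == 0L))
    stop("need at least 2 non-empty groups", call. = FALSE)
  if (length(unique(values)) == 1L)
    return(list(statistic = NA_real_, p_value = 1,
                method = "degenerate", degenerate = TRUE))
  if (nlevels(groups) == 2L) {
    res <- stats::wilcox.test(values ~ groups, exact = FALSE, correct = TRUE)
    list(statistic = unname(res$statistic), p_value = res$p.value,
         method = "mann_whitney", degenerate = FALSE)
  } else {
    res <- stats::kruskal.test(values, groups)
    list(statistic = unname(res$statistic), p_value = res$p.value,
         method = "kruskal_wallis", degenerate = FALSE)
  }
}
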