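# Independent oracles and fixtures shared across the suite.

# complement table local to the oracles (kept separate from the package's)
.ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(x) {
  ch <- rev(strsplit(toupper(x), "", fixed = TRUE)[[1L]])
  paste(.ORACLE_COMP[ch], collapse = "")
}

# Quadratic brute-force scanner: every position x every arm depth, by
# substring comparison (no incremental extension).  Returns start / strand /
# arm_length for loci with min_arm <= arm <= max_arm.
oracle_scan <- function(seq, core, min_arm, max_arm = Inf) {
  up <- toupper(seq)
  n <- nchar(up)
  core <- toupper(core)
  len <- nchar(core)
  core_rc <- oracle_revcomp(core)
  rows <- list()
  if (n >= len) for (p in 1:(n - len + 1L)) {
    w <- substr(up, p, p + len - 1L)
    strands <- character(0)
    if (w == core) strands <- "+"
    if (w == core_rc && !(core == core_rc)) strands <- c(strands, "-")
    if (length(strands) == 0L) next
    if (length(strands) == 2L) strands <- strands[1L]  # same interval
    arm <- 0L
    kmax <- min(p - 1L, n - p - len + 1L)
    k <- 1L
    while (k <= kmax) {
      L <- substr(up, p - k, p - 1L)
      R <- substr(up, p + len, p + len + k - 1L)
      if (grepl("N", L, fixed = TRUE) || grepl("N", R, fixed = TRUE)) break
      if (L != oracle_revcomp(R)) break
      arm <- k
      k <- k + 1L
    }
    if (arm >= min_arm && arm <= max_arm)
      rows[[length(rows) + 1L]] <- data.frame(
        start = p, strand = strands, arm_length = arm,
        stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(0), strand = character(0),
                      arm_length = integer(0)))
  do.call(rbind, rows)
}

# Exhaustive two-sided Fisher p-value by hypergeometric enumeration with the
# point-probability rule.
oracle_fisher2x2 <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- sum(m)
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson chi-square statistic with optional (floored) Yates correction.
oracle_chi2_stat <- function(m, yates = FALSE) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  d <- abs(m - E)
  if (yates) d <- pmax(d - 0.5, 0)
  sum(d^2 / E)
}

random_dna_string <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Cohort fixture built to the published marginals: 103 samples; GPR126 47,
# PLEKHS1 30, Intron ADM 12, Chr7:11 10, Chr15:96 8, GABRG3 7, CLVS2 1,
# Chr3:82 1, RAD51B 5; the union of TGAACA-mutated samples is exactly
# samples 1..64 (62.1% positivity), and the 5 RAD51B samples are nested
# within them.
fixture_cohort <- function() {
  reg <- default_registry()
  assign <- list(
    "GPR126" = 1:47, "PLEKHS1" = 18:47, "Intron ADM" = 53:64,
    "Chr7:11" = 48:57, "Chr15:96" = 57:64, "GABRG3" = 58:64,
    "CLVS2" = 64, "Chr3:82" = 64, "RAD51B" = 60:64)
  ids <- sprintf("S%03d", 1:103)
  rows <- lapply(names(assign), function(lid) {
    r <- reg[reg$locus_id == lid, ]
    data.frame(sample_id = ids[assign[[lid]]], chrom = r$chrom,
               pos = r$pos1, ref = "G", alt = "A",
               stringsAsFactors = FALSE)
  })
  build_matrix(do.call(rbind, rows), reg, ids)
}

# Signature groups at the published sizes 39 / 46 / 18.
fixture_groups <- function() {
  factor(rep(c("G1", "G2", "G3"), c(39, 46, 18)),
         levels = c("G1", "G2", "G3"))
}

# Expand per-group counts of a binary covariate into per-sample vectors
# aligned with fixture_groups(): counts is c(level1 in G1, G2, G3) and
# totals the group sizes.
fixture_covariate <- function(level1_counts, levels = c("yes", "no"),
                              sizes = c(39, 46, 18)) {
  unlist(mapply(function(k, n) rep(levels, c(k, n - k)),
                level1_counts, sizes, SIMPLIFY = FALSE))
}
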