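# Locus registry and sample x locus mutation matrix.

#' Build a locus registry
#'
#' The registry names each recurrently mutated core-motif locus and carries
#' its two mutable genomic positions (1-based, forward strand) and core
#' sequence. For the TGAACA and AGATCA cores the two mutable bases (the
#' internal G and C) sit exactly 3 bp apart, so `pos2 = pos1 + 3`.
#'
#' @param entries Data frame with columns `locus_id`, `chrom`, `pos1`,
#'   `pos2` (may be `NA` for loci with a single assayed position), `core`.
#' @return A `data.frame` of class `locus_registry`.
#' @seealso [default_registry()]
#' @export
locus_registry <- function(entries) {
  need <- c("locus_id", "chrom", "pos1", "pos2", "core")
  if (!all(need %in% names(entries)))
    stop("registry needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(entries$locus_id))
    stop("duplicate locus_id in registry", call. = FALSE)
  ok <- is.na(entries$pos2) | (entries$pos2 - entries$pos1 == 3L)
  if (!all(ok))
    stop("pos2 must equal pos1 + 3 for two-position loci (mutable core ",
         "offsets 1 and 4); offending: ",
         paste(entries$locus_id[!ok], collapse = ", "), call. = FALSE)
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  class(entries) <- c("locus_registry", "data.frame")
  entries
}

#' Default bladder-cancer locus registry
#'
#' The 18 TGAACA-core loci forming the palindromic mutation signature, plus
#' the AGATCA-core locus in intron 10 of RAD51B. Published coordinates are
#' used where available (Chr3:82 at chr3:82807069, Intron ADM at
#' chr11:10331381/10331384, CLVS2 at chr6:123442661, GABRG3 at
#' chr15:27617168/27617171). The remaining loci carry clearly synthetic
#' placeholder coordinates on their nominal chromosomes (the published
#' appendix with full positions is not machine-readable); supply a registry
#' of true coordinates via [locus_registry()] for real-data analyses.
#' Placeholder loci `TGAACA_L09` ... `TGAACA_L18` stand in for the unnamed
#' members of the 18-locus panel.
#'
#' @return A `locus_registry` data frame with 19 rows.
#' @export
default_registry <- function() {
  entries <- data.frame(
    locus_id = c("GPR126", "PLEKHS1", "Intron ADM", "Chr7:11", "Chr15:96",
                 "GABRG3", "CLVS2", "Chr3:82",
                 paste0("TGAACA_L", formatC(9:18, width = 2, flag = "0")),
                 "RAD51B"),
    chrom = c("chr6", "chr10", "chr11", "chr7", "chr15",
              "chr15", "chr6", "chr3",
              paste0("chr", c(1, 2, 4, 5, 8, 9, 12, 13, 16, 17)), "chr14"),
    pos1 = c(142500001, 115500001, 10331381, 11000001, 96000001,
             27617168, 123442661, 82807069,
             rep(50000001, 10), 68500001),
    stringsAsFactors = FALSE)
  entries$pos2 <- entries$pos1 + 3L
  entries$core <- c(rep("TGAACA", 18L), "AGATCA")
  # synthetic placeholder flag: TRUE where the coordinate is not published
  entries$synthetic_coord <- !(entries$locus_id %in%
    c("Intron ADM", "CLVS2", "Chr3:82", "GABRG3"))
  locus_registry(entries)
}

#' TGAACA signature loci of a registry
#'
#' Convenience accessor: the locus ids whose core is TGAACA (the 18-locus
#' signature panel in the default registry).
#'
#' @param registry A `locus_registry`.
#' @return Character vector of locus ids.
#' @export
signature_loci <- function(registry) {
  registry$locus_id[registry$core == "TGAACA"]
}

#' Build the binary sample x locus mutation matrix
#'
#' Each mutation record is matched against the registry's mutable positions;
#' a sample scores 1 for a locus if it carries a call at either of the
#' locus's two mutable positions (calls at both still score 1). Records at
#' positions absent from the registry are an error (never silently dropped),
#' as are samples missing from the sample table. Duplicate
#' (sample, position, alt) rows are collapsed with a warning.
#'
#' @param mutations Data frame with columns `sample_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`.
#' @param registry A [locus_registry()].
#' @param samples Character vector of sample ids, or a data frame of
#'   per-sample covariates containing a `sample_id` column (kept on the
#'   returned object).
#' @return An object of class `cohort_matrix`: a list with `calls` (binary
#'   samples x loci matrix), `registry`, `samples` (covariate data frame),
#'   and `detail` (per-call table with locus id and core offset, used for
#'   context classification).
#' @export
build_matrix <- function(mutations, registry, samples) {
  if (is.character(samples))
    samples <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(samples), "sample_id" %in% names(samples))
  need <- c("sample_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(mutations)))
    stop("mutation table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)

  if (nrow(mutations) > 0L) {
    key <- paste(mutations$sample_id, mutations$chrom, mutations$pos,
                 mutations$alt)
    if (anyDuplicated(key)) {
      warning("removed ", sum(duplicated(key)),
              " duplicate (sample, position, alt) mutation rows")
      mutations <- mutations[!duplicated(key), , drop = FALSE]
    }
    unknown_samples <- setdiff(mutations$sample_id, samples$sample_id)
    if (length(unknown_samples))
      stop("mutation table contains samples absent from the sample list: ",
           paste(unknown_samples, collapse = ", "), call. = FALSE)

    reg_long <- rbind(
      data.frame(locus_id = registry$locus_id, chrom = registry$chrom,
                 pos = registry$pos1, offset = 1L, stringsAsFactors = FALSE),
      data.frame(locus_id = registry$locus_id[!is.na(registry$pos2)],
                 chrom = registry$chrom[!is.na(registry$pos2)],
                 pos = registry$pos2[!is.na(registry$pos2)], offset = 4L,
                 stringsAsFactors = FALSE))
    idx <- match(paste(mutations$chrom, mutations$pos),
                 paste(reg_long$chrom, reg_long$pos))
    if (anyNA(idx)) {
      bad <- unique(paste0(mutations$chrom, ":", mutations$pos)[is.na(idx)])
      stop("mutation positions not in registry: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    mutations$locus_id <- reg_long$locus_id[idx]
    mutations$core_offset <- reg_long$offset[idx]
  } else {
    mutations$locus_id <- character(0)
    mutations$core_offset <- integer(0)
  }

  calls <- matrix(0L, nrow = nrow(samples), ncol = nrow(registry),
                  dimnames = list(samples$sample_id, registry$locus_id))
  if (nrow(mutations) > 0L) {
    ij <- cbind(match(mutations$sample_id, samples$sample_id),
                match(mutations$locus_id, registry$locus_id))
    calls[ij] <- 1L
  }
  structure(list(calls = calls, registry = registry, samples = samples,
                 detail = mutations),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat("<cohort_matrix> ", nrow(x$calls), " samples x ", ncol(x$calls),
      " loci; ", sum(x$calls), " calls\n", sep = "")
  invisible(x)
}

#' Per-sample mutation burden
#'
#' Number of mutated loci per sample, optionally restricted to a locus
#' subset (by default the TGAACA signature panel of the registry).
#'
#' @param cm A `cohort_matrix`.
#' @param loci Character vector of locus ids, or `NULL` for the TGAACA panel.
#' @return Named integer vector (one burden per sample).
#' @export
sample_burden <- function(cm, loci = NULL) {
  if (is.null(loci)) loci <- signature_loci(cm$registry)
  missing <- setdiff(loci, colnames(cm$calls))
  if (length(missing))
    stop("unknown loci: ", paste(missing, collapse = ", "), call. = FALSE)
  rowSums(cm$calls[, loci, drop = FALSE])
}

#' Signature group from mutation burden
#'
#' The cohort stratification by TGAACA-locus burden: `G1` for 0 mutated
#' loci, `G2` for 1-2, `G3` for 3 or more.
#'
#' @param burden Non-negative integer vector of per-sample burdens.
#' @return Factor with levels `G1`, `G2`, `G3`.
#' @examples
#' assign_signature_group(c(0, 2, 8))  # G1 G2 G3
#' @export
assign_signature_group <- function(burden) {
  if (any(burden < 0)) stop("burden must be >= 0", call. = FALSE)
  factor(ifelse(burden == 0, "G1", ifelse(burden <= 2, "G2", "G3")),
         levels = c("G1", "G2", "G3"))
}

#' Per-locus mutation frequency
#'
#' @param cm A `cohort_matrix`.
#' @param locus_id A single locus id, or `NULL` for all loci.
#' @return Data frame with `locus_id`, `count`, `n`, `fraction`.
#' @export
locus_frequency <- function(cm, locus_id = NULL) {
  ids <- if (is.null(locus_id)) colnames(cm$calls) else locus_id
  missing <- setdiff(ids, colnames(cm$calls))
  if (length(missing))
    stop("unknown locus: ", paste(missing, collapse = ", "), call. = FALSE)
  counts <- colSums(cm$calls[, ids, drop = FALSE])
  data.frame(locus_id = ids, count = as.integer(counts),
             n = nrow(cm$calls), fraction = counts / nrow(cm$calls),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of signature-positive samples
#'
#' Fraction of samples mutated at one or more loci of the subset (burden
#' >= 1). For a single-locus subset this equals [locus_frequency()].
#'
#' @param cm A `cohort_matrix`.
#' @param loci Locus-id subset, or `NULL` for the TGAACA panel.
#' @return A single numeric fraction.
#' @export
signature_positive_fraction <- function(cm, loci = NULL) {
  mean(sample_burden(cm, loci) >= 1L)
}

#' Nesting report for a secondary core motif
#'
#' Checks whether every sample mutated at `inner_locus` (e.g. the AGATCA
#' locus of RAD51B) is also positive for the TGAACA signature panel, the
#' containment observed in the bladder cohort.
#'
#' @param cm A `cohort_matrix`.
#' @param inner_locus Locus id to test.
#' @param panel Locus subset defining positivity (`NULL` = TGAACA panel).
#' @return List with `nested` (logical), `n_inner`, `n_overlap`.
#' @export
nesting_report <- function(cm, inner_locus = "RAD51B", panel = NULL) {
  inner <- cm$calls[, inner_locus] == 1L
  positive <- sample_burden(cm, panel) >= 1L
  list(nested = all(positive[inner]),
       n_inner = sum(inner),
       n_overlap = sum(inner & positive))
}
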