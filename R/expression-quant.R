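# qPCR relative quantification (delta-Ct, base 2).

#' Relative expression from mean Ct values
#'
#' N-fold expression of a target gene relative to the endogenous reference
#' gene: `2 ^ (ct_ref - ct_gene)`. Amplification efficiency is assumed to be
#' 100% (exact doubling per cycle); replicate Ct values should be averaged
#' before calling this.
#'
#' @param ct_gene Mean Ct of the target gene (cycles).
#' @param ct_ref Mean Ct of the reference gene for the same sample.
#' @return Numeric vector of unnormalized N-fold values.
#' @examples
#' relative_expression(30, 30)      # 1
#' relative_expression(28, 30)      # 4
#' relative_expression(33.32, 30)   # ~0.1
#' @export
relative_expression <- function(ct_gene, ct_ref) {
  stopifnot(is.numeric(ct_gene), is.numeric(ct_ref))
  if (any(!is.finite(ct_gene)) || any(!is.finite(ct_ref)))
    stop("Ct values must be finite", call. = FALSE)
  2 ^ (ct_ref - ct_gene)
}

#' Normalize N-fold values to a reference cohort
#'
#' Divides every value by the median over the designated normal-tissue
#' samples, so that the normal median equals exactly 1 (Table-4 convention).
#' Even-sized medians use the usual midpoint.
#'
#' @param values Numeric N-fold values, named by sample id (or supply
#'   `sample_ids`).
#' @param normal_ids Character vector of normal-tissue sample ids.
#' @param sample_ids Optional sample ids aligned with `values`.
#' @return Numeric vector of normalized values (names preserved).
#' @export
normalize_to_reference_cohort <- function(values, normal_ids,
                                          sample_ids = names(values)) {
  stopifnot(is.numeric(values))
  if (is.null(sample_ids))
    stop("values must be named by sample id (or pass sample_ids)",
         call. = FALSE)
  idx <- sample_ids %in% normal_ids
  ref <- values[idx & !is.na(values)]
  if (length(ref) == 0L)
    stop("no normal sample with a value: cannot normalize", call. = FALSE)
  scale <- stats::median(ref)
  if (scale <= 0) stop("normal median is not positive", call. = FALSE)
  values / scale
}

#' Full qPCR quantification pipeline for a Ct table
#'
#' Averages replicate Ct values per (sample, gene), computes the N-fold
#' value of each target gene against the reference gene
#' ([relative_expression()]), and rescales each gene so the median over
#' the normal samples is 1 ([normalize_to_reference_cohort()]). Samples
#' missing the reference gene are skipped with a warning; a missing
#' (sample, gene) pair stays missing rather than becoming zero.
#'
#' @param ct_table Data frame with columns `sample_id`, `gene`, `ct`
#'   (one row per replicate).
#' @param reference_gene Endogenous control gene name (default `"TBP"`).
#' @param normal_ids Sample ids of the normal-tissue reference cohort.
#' @return Data frame `sample_id`, `gene`, `nfold` (normalized).
#' @export
quantify_expression <- function(ct_table, reference_gene = "TBP",
                                normal_ids) {
  need <- c("sample_id", "gene", "ct")
  if (!all(need %in% names(ct_table)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(ct_table$ct) | ct_table$ct <= 0))
    stop("Ct values must be finite and positive", call. = FALSE)

  mean_ct <- stats::aggregate(ct ~ sample_id + gene, data = ct_table,
                              FUN = mean)
  ref <- mean_ct[mean_ct$gene == reference_gene, c("sample_id", "ct")]
  if (nrow(ref) == 0L)
    stop("reference gene '", reference_gene, "' absent from Ct table",
         call. = FALSE)
  tgt <- mean_ct[mean_ct$gene != reference_gene, , drop = FALSE]
  ct_ref <- ref$ct[match(tgt$sample_id, ref$sample_id)]
  no_ref <- is.na(ct_ref)
  if (any(no_ref)) {
    warning("skipping ", sum(no_ref), " sample-gene pairs lacking a ",
            reference_gene, " measurement: ",
            paste(unique(tgt$sample_id[no_ref]), collapse = ", "))
    tgt <- tgt[!no_ref, , drop = FALSE]
    ct_ref <- ct_ref[!no_ref]
  }
  tgt$nfold <- relative_expression(tgt$ct, ct_ref)
  out <- do.call(rbind, lapply(split(tgt, tgt$gene), function(d) {
    d$nfold <- normalize_to_reference_cohort(d$nfold, normal_ids,
                                             sample_ids = d$sample_id)
    d
  }))
  rownames(out) <- NULL
  out[order(out$gene, out$sample_id), c("sample_id", "gene", "nfold")]
}
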