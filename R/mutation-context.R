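# Pyrimidine-normalized trinucleotide context and APOBEC classification.
#
# APOBEC3 cytidine deaminases act on TCN (optimally TCA) in single-stranded
# DNA, producing C>T / C>G substitutions; read on the opposite strand these
# appear as G>A at TGA.  Contexts are therefore normalized so the mutated
# base is reported as a pyrimidine: a purine ref flips both alleles to their
# complements and reverse-complements the trinucleotide.

.comp_base <- function(b) unname(.DNA_COMP[toupper(b)])

.classify_apobec <- function(substitution, trinucleotide) {
  if (is.na(trinucleotide)) return(NA_character_)
  if (substitution %in% c("C>T", "C>G") &&
      substr(trinucleotide, 1L, 1L) == "T") {
    if (trinucleotide == "TCA") "TCA_optimal" else "TCN_canonical"
  } else "other"
}

#' Pyrimidine-normalized substitution context
#'
#' For each substitution, extracts the trinucleotide centred on the mutated
#' base and normalizes to the strand on which the mutated base is a
#' pyrimidine (C or T). The APOBEC class is `TCA_optimal` for C>T/C>G at
#' TCA, `TCN_canonical` for C>T/C>G at other TCN, and `other` otherwise.
#' Sites at the first or last base of a sequence have no complete
#' trinucleotide: context and class are `NA` (excluded from summaries).
#'
#' @param seqs Named character vector of reference sequences (or a single
#'   string), as from [read_fasta()].
#' @param chrom,pos,ref,alt Vectors describing the substitutions (1-based
#'   positions; `ref` must match the reference base, case-insensitively).
#' @return Data frame with `chrom`, `pos`, `ref`, `alt`, `strand` (`+` if
#'   the ref base was already a pyrimidine, `-` if flipped), `trinucleotide`,
#'   `substitution` (pyrimidine-normalized, e.g. `"C>T"`), `apobec_class`.
#' @examples
#' s <- c(chrA = "CCTGAACAGG")
#' # G>A at the core G (forward context TGA) -> C>T at TCA, APOBEC-optimal
#' pyrimidine_context(s, "chrA", 4, "G", "A")
#' @export
pyrimidine_context <- function(seqs, chrom, pos, ref, alt) {
  seqs <- .as_seqs(seqs)
  n <- length(pos)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n)
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  if (any(nchar(ref) != 1L | nchar(alt) != 1L))
    stop("ref and alt must be single bases", call. = FALSE)

  out <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    strand = NA_character_, trinucleotide = NA_character_,
                    substitution = NA_character_,
                    apobec_class = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (!chrom[i] %in% names(seqs))
      stop("unknown sequence: ", chrom[i], call. = FALSE)
    s <- seqs[[chrom[i]]]
    base <- toupper(substr(s, pos[i], pos[i]))
    if (base != ref[i])
      stop(sprintf("ref mismatch at %s:%d: reference has %s, record says %s",
                   chrom[i], pos[i], base, ref[i]), call. = FALSE)
    at_edge <- pos[i] <= 1L || pos[i] >= nchar(s)
    tri <- if (at_edge) NA_character_
           else toupper(substr(s, pos[i] - 1L, pos[i] + 1L))
    if (ref[i] %in% c("A", "G")) {  # purine: flip to pyrimidine strand
      out$strand[i] <- "-"
      r <- .comp_base(ref[i]); a <- .comp_base(alt[i])
      if (!is.na(tri)) tri <- reverse_complement(tri)
    } else {
      out$strand[i] <- "+"
      r <- ref[i]; a <- alt[i]
    }
    out$trinucleotide[i] <- tri
    out$substitution[i] <- paste0(r, ">", a)
    out$apobec_class[i] <- .classify_apobec(out$substitution[i], tri)
  }
  out
}

#' Classify every mutation of a cohort and summarize
#'
#' Runs [pyrimidine_context()] on the per-call detail table of a
#' `cohort_matrix` (or any mutation table) and reports summary fractions:
#' the fraction of calls that are G>A or C>T as recorded on the forward
#' strand, and the fraction whose context is APOBEC-compatible
#' (`TCN_canonical` or `TCA_optimal`). Edge sites with unknown context are
#' excluded from the APOBEC fraction.
#'
#' @param mutations A `cohort_matrix` (its `detail` table is used) or a
#'   data frame with `sample_id`, `chrom`, `pos`, `ref`, `alt`.
#' @param seqs Named character vector of reference sequences.
#' @return List with `table` (per-mutation context data frame, sample ids
#'   retained) and `summary` (`n`, `fraction_ga_ct`, `fraction_apobec`,
#'   `fraction_tca_optimal`).
#' @export
classify_cohort <- function(mutations, seqs) {
  if (inherits(mutations, "cohort_matrix")) mutations <- mutations$detail
  ctx <- pyrimidine_context(seqs, mutations$chrom, mutations$pos,
                            mutations$ref, mutations$alt)
  ctx <- cbind(sample_id = mutations$sample_id, ctx)
  known <- !is.na(ctx$apobec_class)
  list(
    table = ctx,
    summary = list(
      n = nrow(ctx),
      fraction_ga_ct = mean((ctx$ref == "G" & ctx$alt == "A") |
                            (ctx$ref == "C" & ctx$alt == "T")),
      fraction_apobec = mean(ctx$apobec_class[known] %in%
                             c("TCN_canonical", "TCA_optimal")),
      fraction_tca_optimal = mean(ctx$apobec_class[known] == "TCA_optimal")))
}
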