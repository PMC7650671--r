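# File formats: FASTA (soft-masked, optionally gzipped), BED6 locus output,
# and the tab-separated tables the pipeline exchanges.  All tabular output is
# headered, UTF-8, tab-separated; "chr"-prefixed sequence names are tolerated
# and preserved.  R-side coordinates are 1-based; BED is written 0-based
# half-open at this boundary.

#' Read a (soft-masked) FASTA file
#'
#' Reads a multi-record FASTA, preserving case so soft-masking survives
#' (lowercase = repeat-annotated). Gzipped input is handled transparently.
#' Record names are truncated at the first whitespace. Sequences are
#' validated against the DNA alphabet `A,C,G,T,N` (either case).
#'
#' @param path Path to a FASTA or FASTA.gz file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (length(set) == 0L)
    stop("empty FASTA: ", path, call. = FALSE)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  for (i in seq_along(out))
    .check_dna(out[[i]], what = paste0("record '", names(out)[i], "'"))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- .as_seqs(seqs)
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write scanned loci as BED6
#'
#' One line per locus over the core interval, 0-based half-open: `chrom`,
#' `start`, `end`, `name` (`<core>|arm=<k>`), `score` (arm length),
#' `strand` (orientation of the matched core).
#'
#' @param loci A `palin_loci` data frame from [scan_core_motif()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(loci, path) {
  if (nrow(loci) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(
    chrom = loci$seqname,
    start = loci$start - 1L,           # 0-based half-open
    end = loci$end,
    name = paste0(loci$core, "|arm=", loci$arm_length),
    score = loci$arm_length,
    strand = loci$strand,
    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file of scanned loci
#'
#' Inverse of [write_bed()]: restores 1-based inclusive coordinates and
#' splits the name field back into core and arm length.
#'
#' @param path Path to a BED6 file.
#' @return Data frame with `seqname`, `start`, `end`, `strand`, `core`,
#'   `arm_length`.
#' @export
read_bed <- function(path) {
  if (file.size(path) == 0L)
    return(data.frame(seqname = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      core = character(0), arm_length = integer(0)))
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  data.frame(seqname = bed$chrom,
             start = bed$start + 1L,
             end = bed$end,
             strand = bed$strand,
             core = sub("\\|arm=.*$", "", bed$name),
             arm_length = as.integer(bed$score),
             stringsAsFactors = FALSE)
}

.read_tsv <- function(path, required) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("'", path, "' lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  x
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read / write the pipeline's TSV tables
#'
#' Thin validated wrappers around tab-separated files: the per-sample
#' mutation table (`sample_id`, `chrom`, `pos`, `ref`, `alt`), the covariate
#' table (`sample_id` plus arbitrary columns; empty fields become `NA`), and
#' the qPCR Ct table (`sample_id`, `gene`, `ct`, one row per replicate).
#'
#' @param path File path.
#' @param x Data frame to write.
#' @return The data frame (readers) or `path` invisibly (writers).
#' @name pipeline_tables
#' @export
read_mutations <- function(path) {
  x <- .read_tsv(path, c("sample_id", "chrom", "pos", "ref", "alt"))
  x$pos <- as.integer(x$pos)
  x
}

#' @rdname pipeline_tables
#' @export
write_mutations <- function(x, path) .write_tsv(
  x[, c("sample_id", "chrom", "pos", "ref", "alt")], path)

#' @rdname pipeline_tables
#' @export
read_covariates <- function(path) {
  x <- .read_tsv(path, "sample_id")
  x[x == ""] <- NA
  x
}

#' @rdname pipeline_tables
#' @export
write_covariates <- function(x, path) .write_tsv(x, path)

#' @rdname pipeline_tables
#' @export
read_ct_table <- function(path) {
  x <- .read_tsv(path, c("sample_id", "gene", "ct"))
  x$ct <- as.numeric(x$ct)
  x
}

#' @rdname pipeline_tables
#' @export
write_ct_table <- function(x, path) .write_tsv(
  x[, c("sample_id", "gene", "ct")], path)

#' Export / import a cohort call matrix as TSV
#'
#' Samples as rows, loci as columns, a leading `sample_id` column.
#'
#' @param cm A `cohort_matrix`.
#' @param path File path.
#' @return `path` invisibly (writer); a binary matrix with sample rownames
#'   (reader).
#' @export
write_matrix <- function(cm, path) {
  d <- data.frame(sample_id = rownames(cm$calls), cm$calls,
                  check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(d, path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  d <- .read_tsv(path, "sample_id")
  m <- as.matrix(d[, setdiff(names(d), "sample_id"), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- d$sample_id
  m
}
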