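# Core-motif / palindromic-arm scanner.
#
# A locus is an occurrence of a short core motif (5-8 bp) whose flanks form a
# perfect inverted repeat: the k bases immediately left of the core equal the
# reverse complement of the k bases immediately right of it.  The core itself
# is excluded from the palindrome (TGAACA is not self-complementary; the core
# sits in the loop of the hairpin the arms can fold into).  All coordinates in
# R objects are 1-based inclusive; BED output converts to 0-based half-open.

.DNA_ALPHABET <- "ACGTNacgtn"
.DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
               a = "t", c = "g", g = "c", t = "a", n = "n")

.check_dna <- function(x, what = "sequence") {
  bad <- regexpr(sprintf("[^%s]", .DNA_ALPHABET), x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("non-DNA character '%s' in %s at position %d",
                 substr(x[i], bad[i], bad[i]), what, bad[i]), call. = FALSE)
  }
  invisible(x)
}

#' Reverse complement of DNA strings
#'
#' Watson-Crick complement, reversed. Case is preserved (soft-masking
#' survives the operation) and `N` maps to `N`.
#'
#' @param x Character vector of DNA strings over `A,C,G,T,N` (either case).
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("TGAACA")   # "TGTTCA"
#' reverse_complement("AGATCA")   # "TGATCT"
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x))
  .check_dna(x)
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Maximal palindromic arm length around a core interval
#'
#' Returns the largest `k >= 0` such that the `k` bases immediately before
#' the core equal the reverse complement of the `k` bases immediately after
#' it. Comparison is case-insensitive; any `N` stops extension; the arm is
#' bounded by the sequence ends.
#'
#' @param seq A single DNA string (the reference sequence).
#' @param core_start 1-based position of the first core base.
#' @param core_len Core length in bases.
#' @return Integer arm length.
#' @examples
#' s <- paste0("AAAA", "CATTGGCGA", "TGAACA", "TCGCCAATG", "AAAA")
#' max_arm_length(s, core_start = 14, core_len = 6)  # 9
#' @export
max_arm_length <- function(seq, core_start, core_len) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  if (core_start < 1L || core_len < 1L || core_start + core_len - 1L > n)
    stop("core interval [", core_start, ", ", core_start + core_len - 1L,
         "] out of sequence bounds [1, ", n, "]", call. = FALSE)
  up <- toupper(seq)
  k <- 0L
  repeat {
    l <- core_start - k - 1L
    r <- core_start + core_len + k
    if (l < 1L || r > n) break
    lb <- substr(up, l, l)
    rb <- substr(up, r, r)
    if (lb == "N" || rb == "N") break
    if (.DNA_COMP[[lb]] != rb) break
    k <- k + 1L
  }
  k
}

#' Construct a core motif
#'
#' A core motif is an uppercase DNA word of length 5-8 together with the
#' 0-based offsets of its recurrently mutable bases. For the bladder-cancer
#' TGAACA core the mutable bases are the internal G and C at offsets 1 and 4,
#' i.e. genomic positions exactly 3 bp apart; the AGATCA core shares the same
#' offsets.
#'
#' @param sequence Uppercase DNA string, length 5 to 8, no `N`.
#' @param mutable_offsets Integer vector of 0-based offsets within the core.
#' @return An object of class `core_motif`.
#' @examples
#' core_motif("TGAACA")           # offsets 1 and 4 by default
#' core_motif("AGATCA", c(1, 4))
#' @export
core_motif <- function(sequence, mutable_offsets = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence))
    stop("core motif must be over A,C,G,T", call. = FALSE)
  len <- nchar(sequence)
  if (len < 5L || len > 8L)
    stop("core motif length must be between 5 and 8 bp, got ", len,
         call. = FALSE)
  if (is.null(mutable_offsets)) {
    # default: the G and C of the TGAACA-style core (offsets 1 and 4)
    mutable_offsets <- if (sequence %in% c("TGAACA", "AGATCA")) c(1L, 4L)
                       else integer(0)
  }
  mutable_offsets <- as.integer(mutable_offsets)
  if (any(mutable_offsets < 0L | mutable_offsets >= len))
    stop("mutable_offsets must lie within [0, core length)", call. = FALSE)
  structure(list(sequence = sequence, mutable_offsets = mutable_offsets),
            class = "core_motif")
}

#' @export
print.core_motif <- function(x, ...) {
  cat("<core_motif> ", x$sequence,
      " (mutable offsets: ", paste(x$mutable_offsets, collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

.as_core <- function(core) {
  if (inherits(core, "core_motif")) core else core_motif(core)
}

# named character vector of sequences from string / named vector / XStringSet
.as_seqs <- function(seqs) {
  if (methods::is(seqs, "XStringSet")) {
    out <- as.character(seqs)
    names(out) <- sub("\\s.*$", "", names(seqs))
    return(out)
  }
  stopifnot(is.character(seqs))
  if (is.null(names(seqs)))
    names(seqs) <- if (length(seqs) == 1L) "seq1"
                   else paste0("seq", seq_along(seqs))
  seqs
}

.masked_fraction <- function(seq, start, end) {
  region <- substr(seq, max(1L, start), min(nchar(seq), end))
  chars <- strsplit(region, "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L) return(0)
  mean(chars %in% c("a", "c", "g", "t", "n"))
}

.is_homopolymer_string <- function(x) {
  nzchar(x) && length(unique(strsplit(toupper(x), "", fixed = TRUE)[[1L]])) == 1L
}

# all match starts (1-based) of `pattern` in `subject`, overlapping allowed;
# N in the subject never matches (pattern is N-free)
.match_starts <- function(subject_upper, pattern) {
  m <- Biostrings::matchPattern(pattern,
                                Biostrings::DNAString(subject_upper),
                                fixed = TRUE)
  BiocGenerics::start(m)
}

#' Scan reference sequences for core-motif loci with palindromic arms
#'
#' Finds every forward-strand occurrence of `core` and of its reverse
#' complement, measures the maximal perfect palindromic arm at each, and
#' keeps loci whose arm length falls in `[min_arm, max_arm]`. Occurrences
#' where both orientations describe the same interval (self-complementary
#' cores) are de-duplicated. Output is sorted by sequence name and start.
#'
#' Soft-masked (lowercase) bases participate in matching and arm measurement;
#' the lowercase fraction of each locus footprint (arms + core) is reported
#' as `masked_fraction` so repeat-overlapping loci can be filtered with
#' [passes_repeat_filter()]. Windows containing `N` never match.
#'
#' @param seqs Named character vector of DNA strings, a single string, or a
#'   `Biostrings::BStringSet`/`DNAStringSet`.
#' @param core A [core_motif()] or a plain DNA string.
#' @param min_arm Minimum arm length (>= 1).
#' @param max_arm Maximum arm length, or `Inf` for unbounded.
#' @param homopolymer_filter Drop loci where either arm is a single repeated
#'   base (default `TRUE`).
#' @param max_masked_fraction If non-`NULL`, drop loci whose
#'   `masked_fraction` exceeds this threshold (use `0` to require fully
#'   unmasked loci).
#' @return A `data.frame` of class `palin_loci` with columns `seqname`,
#'   `start`, `end` (1-based inclusive core interval), `strand` (`+` if the
#'   core matched as given, `-` if its reverse complement matched), `core`
#'   (the motif as it reads on the forward strand), `arm_length`,
#'   `left_arm`, `right_arm`, `masked_fraction`, `arm_homopolymer`.
#' @examples
#' arm <- "CATTGGCGA"
#' s <- paste0("ACGT", arm, "TGAACA", reverse_complement(arm), "ACGT")
#' scan_core_motif(s, "TGAACA", min_arm = 9)
#' @export
scan_core_motif <- function(seqs, core, min_arm = 9L, max_arm = Inf,
                            homopolymer_filter = TRUE,
                            max_masked_fraction = NULL) {
  stopifnot(min_arm >= 1L)
  core <- .as_core(core)
  seqs <- .as_seqs(seqs)
  len <- nchar(core$sequence)
  rc <- reverse_complement(core$sequence)

  rows <- list()
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    if (!nzchar(s)) next
    .check_dna(s, what = paste0("sequence '", nm, "'"))
    up <- toupper(s)
    starts_fwd <- .match_starts(up, core$sequence)
    starts_rev <- if (rc == core$sequence) integer(0)
                  else .match_starts(up, rc)
    starts <- c(starts_fwd, starts_rev)
    strand <- rep(c("+", "-"), c(length(starts_fwd), length(starts_rev)))
    if (length(starts) == 0L) next
    o <- order(starts, strand)
    starts <- starts[o]; strand <- strand[o]
    # identical intervals from both orientations collapse to one record
    dup <- duplicated(starts)
    starts <- starts[dup == FALSE]; strand <- strand[dup == FALSE]

    for (i in seq_along(starts)) {
      st <- starts[i]
      k <- max_arm_length(s, st, len)
      if (k < min_arm || k > max_arm) next
      left <- substr(s, st - k, st - 1L)
      right <- substr(s, st + len, st + len + k - 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        seqname = nm, start = st, end = st + len - 1L,
        strand = strand[i],
        core = substr(up, st, st + len - 1L),
        arm_length = k,
        left_arm = left, right_arm = right,
        masked_fraction = .masked_fraction(s, st - k, st + len + k - 1L),
        arm_homopolymer = k > 0L && (.is_homopolymer_string(left) ||
                                     .is_homopolymer_string(right)),
        stringsAsFactors = FALSE)
    }
  }

  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    seqname = character(0), start = integer(0), end = integer(0),
    strand = character(0), core = character(0), arm_length = integer(0),
    left_arm = character(0), right_arm = character(0),
    masked_fraction = numeric(0), arm_homopolymer = logical(0),
    stringsAsFactors = FALSE)
  if (homopolymer_filter) out <- out[!out$arm_homopolymer, , drop = FALSE]
  if (!is.null(max_masked_fraction))
    out <- out[out$masked_fraction <= max_masked_fraction, , drop = FALSE]
  out <- out[order(out$seqname, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "core_motif") <- core
  class(out) <- c("palin_loci", "data.frame")
  out
}

#' Mutable genomic positions of scanned loci
#'
#' Maps the core motif's mutable offsets onto genomic coordinates for each
#' locus, taking orientation into account: for a locus matched on the `-`
#' strand, offset `o` maps to forward-strand position
#' `start + (core_len - 1 - o)`.
#'
#' @param loci A `palin_loci` data frame from [scan_core_motif()].
#' @param core Optional [core_motif()]; defaults to the one stored on `loci`.
#' @return A data frame with `seqname`, `locus_start`, `offset`, `pos`.
#' @export
mutable_positions <- function(loci, core = NULL) {
  if (is.null(core)) core <- attr(loci, "core_motif")
  core <- .as_core(core)
  len <- nchar(core$sequence)
  offs <- core$mutable_offsets
  if (nrow(loci) == 0L || length(offs) == 0L)
    return(data.frame(seqname = character(0), locus_start = integer(0),
                      offset = integer(0), pos = integer(0)))
  do.call(rbind, lapply(seq_len(nrow(loci)), function(i) {
    o <- if (loci$strand[i] == "+") offs else (len - 1L - offs)
    data.frame(seqname = loci$seqname[i], locus_start = loci$start[i],
               offset = sort(o), pos = loci$start[i] + sort(o))
  }))
}

#' Variant-window discovery of palindromic core patterns
#'
#' Discovery mode around a called SNV: within a window centred on the variant
#' (alternate allele already substituted in), every sub-pattern of length
#' `core_len_range[1]` to `core_len_range[2]` containing the variant position
#' is enumerated, and those flanked by maximal palindromic arms of at least
#' `min_arm` bases on each side are reported. Candidates whose pattern or
#' either arm is a homopolymer are discarded.
#'
#' @param window A single DNA string (typically 61 bp: the variant +/- 30).
#' @param variant_pos 1-based position of the variant within the window
#'   (default: the centre).
#' @param core_len_range Two integers, smallest and largest pattern length.
#' @param min_arm Minimum arm length on each side (default 8, i.e. arms
#'   strictly longer than 7 bp).
#' @return Data frame with `core_start` (1-based within the window),
#'   `core_len`, `core`, `arm_length`.
#' @examples
#' arm <- "GCATTGCGA"
#' w <- paste0("ACGTGA", arm, "TGAACA", reverse_complement(arm), "CTGACT")
#' scan_variant_window(w, variant_pos = 17, min_arm = 8)
#' @export
scan_variant_window <- function(window, variant_pos = (nchar(window) + 1L) %/% 2L,
                                core_len_range = c(5L, 8L), min_arm = 8L) {
  stopifnot(is.character(window), length(window) == 1L)
  .check_dna(window)
  n <- nchar(window)
  empty <- data.frame(core_start = integer(0), core_len = integer(0),
                      core = character(0), arm_length = integer(0),
                      stringsAsFactors = FALSE)
  if (variant_pos < 1L || variant_pos > n)
    stop("variant_pos outside window", call. = FALSE)
  if (n < 2L * min_arm + core_len_range[1L]) {
    warning("window too short for any pattern with ", min_arm,
            "-bp arms; returning no candidates")
    return(empty)
  }
  up <- toupper(window)
  rows <- list()
  for (len in seq(core_len_range[1L], core_len_range[2L])) {
    for (st in seq(max(1L, variant_pos - len + 1L),
                   min(variant_pos, n - len + 1L))) {
      pat <- substr(up, st, st + len - 1L)
      if (grepl("N", pat, fixed = TRUE)) next
      k <- max_arm_length(window, st, len)
      if (k < min_arm) next
      left <- substr(up, st - k, st - 1L)
      right <- substr(up, st + len, st + len + k - 1L)
      if (.is_homopolymer_string(pat) || .is_homopolymer_string(left) ||
          .is_homopolymer_string(right)) next
      rows[[length(rows) + 1L]] <- data.frame(
        core_start = st, core_len = len, core = pat, arm_length = k,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Homopolymer-arm flag for scanned loci
#'
#' `TRUE` for loci where either palindromic arm consists of a single repeated
#' base. A zero-length arm is vacuously not a homopolymer.
#'
#' @param loci A `palin_loci` data frame (uses its stored arm strings).
#' @return Logical vector, one value per locus.
#' @export
is_arm_homopolymer <- function(loci) {
  if (nrow(loci) == 0L) return(logical(0))
  vapply(seq_len(nrow(loci)), function(i) {
    loci$arm_length[i] > 0L &&
      (.is_homopolymer_string(loci$left_arm[i]) ||
       .is_homopolymer_string(loci$right_arm[i]))
  }, logical(1L))
}

#' Soft-masked repeat filter
#'
#' `TRUE` for loci whose lowercase (soft-masked) fraction over the full
#' footprint (arms + core) does not exceed `max_masked_fraction`. The default
#' of 0 keeps only loci entirely outside repeat-annotated sequence.
#'
#' @param loci A `palin_loci` data frame.
#' @param max_masked_fraction Highest tolerated lowercase fraction.
#' @return Logical vector, one value per locus.
#' @export
passes_repeat_filter <- function(loci, max_masked_fraction = 0) {
  loci$masked_fraction <= max_masked_fraction
}
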