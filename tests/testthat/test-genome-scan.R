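test_that("reverse_complement handles canonical cores and preserves case", {
  expect_equal(reverse_complement("TGAACA"), "TGTTCA")
  expect_equal(reverse_complement("AGATCA"), "TGATCT")
  expect_equal(reverse_complement("acgTN"), "NAcgt")
  expect_equal(reverse_complement(c("A", "CG")), c("T", "CG"))
})

test_that("reverse_complement is an involution on random DNA", {
  set.seed(11)
  for (i in 1:20) {
    x <- random_dna_string(sample(1:80, 1), c("A", "C", "G", "T", "N"))
    expect_identical(reverse_complement(reverse_complement(x)), x)
    expect_identical(reverse_complement(x), oracle_revcomp(x))
  }
})

test_that("reverse_complement rejects non-DNA input naming the position", {
  expect_error(reverse_complement("ACGU"), "position 4")
  expect_error(reverse_complement("AC-GT"), "position 3")
})

test_that("max_arm_length measures the maximal perfect arm", {
  s <- paste0("AAAA", "CATTGGCGA", "TGAACA", "TCGCCAATG", "AAAA")
  expect_equal(max_arm_length(s, 14, 6), 9)        # flanking A/A pair breaks k = 10
  expect_equal(max_arm_length("TTTTTGAACATTTT", 5, 6), 0)  # T cannot pair with T
  expect_equal(max_arm_length("TGAACAGGGG", 1, 6), 0)      # no left flank
  expect_error(max_arm_length("ACGT", 3, 6), "out of sequence bounds")
})

test_that("max_arm_length is case-insensitive and stops at N", {
  arm <- "GATTACAGG"
  s <- paste0("T", tolower(arm), "TGAACA", reverse_complement(arm), "T")
  expect_equal(max_arm_length(s, 11, 6), 9)
  sN <- paste0("T", sub("G", "N", arm), "TGAACA", reverse_complement(arm), "T")
  expect_lt(max_arm_length(sN, 11, 6), 9)
})

test_that("scan recovers an implanted locus and ignores a bare core", {
  arm <- "CATTGGCGA"
  s <- paste0("CCGT", arm, "TGAACA", reverse_complement(arm),
              "GGCCA", "TGAACA", "GGCCA")
  hits <- scan_core_motif(s, "TGAACA", min_arm = 9)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 14L)
  expect_equal(hits$arm_length, 9L)
  expect_equal(hits$left_arm, arm)
})

test_that("scanning the reverse-complemented sequence mirrors the loci", {
  set.seed(21)
  for (i in 1:10) {
    g <- simulate_genome(seq_length = 3000, implant_arms = sample(8:12, 3),
                         seed = 100 + i)
    s <- unname(g$sequences[1])
    n <- nchar(s)
    fwd <- scan_core_motif(s, "TGAACA", min_arm = 8)
    rev <- scan_core_motif(reverse_complement(s), "TGAACA", min_arm = 8)
    expect_equal(nrow(fwd), nrow(rev))
    mirrored <- sort(n - fwd$end + 1L)
    expect_equal(sort(rev$start), mirrored)
    expect_equal(rev$arm_length[order(rev$start)],
                 fwd$arm_length[order(-fwd$start)])
  }
})

test_that("scan agrees exactly with the quadratic brute-force oracle", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(200:5000, 1)
    s <- random_dna_string(n, c("A", "C", "G", "T", if (i %% 5 == 0) "N"))
    # plant a couple of constructs so matches actually occur
    g <- simulate_genome(seq_length = n, implant_arms = sample(2:6, 2),
                         n_bare = 2, seed = 400 + i)
    for (seqstr in c(s, unname(g$sequences))) {
      got <- scan_core_motif(seqstr, "TGAACA", min_arm = 2,
                             homopolymer_filter = FALSE)
      want <- oracle_scan(seqstr, "TGAACA", min_arm = 2)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want)) {
        expect_equal(got$start, want$start)
        expect_equal(got$arm_length, want$arm_length)
        expect_equal(got$strand, want$strand)
      }
    }
  }
})

test_that("emitted arms are maximal: one more base breaks complementarity", {
  g <- simulate_genome(seq_length = 8000, implant_arms = c(8, 9, 10, 11, 12),
                       seed = 7)
  s <- g$sequences[1]
  hits <- scan_core_motif(s, "TGAACA", min_arm = 8)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nrow(hits))) {
    k <- hits$arm_length[i] + 1L
    l <- hits$start[i] - k
    r <- hits$end[i] + k
    if (l >= 1 && r <= nchar(s)) {
      lb <- toupper(substr(s, l, l)); rb <- toupper(substr(s, r, r))
      expect_false(identical(unname(comp[lb]), rb))
    }
  }
})

test_that("self-complementary cores are reported once per interval", {
  arm <- "CGGATCCGT"
  s <- paste0("TT", arm, "GAATTC", reverse_complement(arm), "TT")
  hits <- scan_core_motif(s, core_motif("GAATTC", integer(0)), min_arm = 9)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "+")
})

test_that("variant-window discovery reports an implanted construct", {
  set.seed(5)
  arm <- "GCATTGCGA"  # 9 bp, not a homopolymer
  # A/A flanks so the measured arm is exactly 9
  left <- paste0(random_dna_string(9), "A")
  w <- paste0(left, arm, "TGAACA", reverse_complement(arm), "A",
              random_dna_string(9))
  # variant at the core G: window position 10 + 9 + 2
  cand <- scan_variant_window(w, variant_pos = 21, min_arm = 8)
  expect_true(any(cand$core_start == 20 & cand$core_len == 6 &
                  cand$core == "TGAACA" & cand$arm_length == 9))
})

test_that("variant-window filters: homopolymers, short arms, short windows", {
  expect_equal(nrow(scan_variant_window(strrep("A", 61), variant_pos = 31)), 0)
  arm7 <- "GCATTGC"
  # A/A flanks stop extension at exactly 7, below the >7 bp requirement
  w <- paste0("ACGTGTGTAA", arm7, "TGAACA", reverse_complement(arm7),
              "ATACGTACGT")
  expect_equal(nrow(scan_variant_window(w, variant_pos = 19, min_arm = 8)), 0)
  expect_warning(out <- scan_variant_window("ACGTACGTA", variant_pos = 5),
                 "too short")
  expect_equal(nrow(out), 0)
})

test_that("homopolymer and repeat filters behave per locus", {
  arm <- "CATTGGCGA"
  # A/A flanks around each construct so arms measure exactly 9
  s <- paste0("CTA", strrep("A", 9), "TGAACA", strrep("T", 9), "A",
              "CTA", arm, "TGAACA", reverse_complement(arm), "ACT")
  all_hits <- scan_core_motif(s, "TGAACA", min_arm = 9,
                              homopolymer_filter = FALSE)
  expect_equal(nrow(all_hits), 2L)
  expect_equal(is_arm_homopolymer(all_hits), c(TRUE, FALSE))
  filtered <- scan_core_motif(s, "TGAACA", min_arm = 9)
  expect_equal(nrow(filtered), 1L)
  expect_false(any(is_arm_homopolymer(filtered)))

  masked <- paste0("CA", tolower(arm), "TGAACA",
                   tolower(reverse_complement(arm)), "AG")
  hits <- scan_core_motif(masked, "TGAACA", min_arm = 9)
  expect_equal(nrow(hits), 1L)
  expect_false(passes_repeat_filter(hits, 0))
  expect_true(passes_repeat_filter(hits, 0.8))
  clean <- scan_core_motif(toupper(masked), "TGAACA", min_arm = 9)
  expect_true(passes_repeat_filter(clean, 0))
})

test_that("mutable positions sit 3 bases apart for TGAACA-family cores", {
  arm <- "CATTGGCGA"
  s <- paste0("GG", arm, "TGAACA", reverse_complement(arm), "GG")
  for (core in c("TGAACA", "AGATCA")) {
    s2 <- paste0("GG", arm, core, reverse_complement(arm), "GG")
    hits <- scan_core_motif(s2, core, min_arm = 9)
    mp <- mutable_positions(hits)
    expect_equal(diff(mp$pos), 3L)
  }
  # reverse-strand match: offsets mirror within the window
  srev <- reverse_complement(s)
  hits <- scan_core_motif(srev, "TGAACA", min_arm = 9)
  expect_equal(hits$strand, "-")
  mp <- mutable_positions(hits)
  expect_equal(diff(mp$pos), 3L)
})

test_that("core_motif validates its invariants", {
  expect_error(core_motif("TGAA"), "between 5 and 8")
  expect_error(core_motif("TGAACATGG"), "between 5 and 8")
  expect_error(core_motif("TGAACA", c(1, 6)), "within")
  expect_equal(core_motif("TGAACA")$mutable_offsets, c(1L, 4L))
})
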