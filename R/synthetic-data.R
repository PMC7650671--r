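# Synthetic-data generators with ground-truth records.
#
# Three generators cover the pipeline's inputs: reference sequences with
# implanted palindromic core-motif loci (plus decoy classes exercising each
# filter), cohort mutation matrices with realistic marginals and positive
# pairwise dependence induced by a single latent instability factor, and
# qPCR Ct tables with a group expression effect.  Every generator is fully
# deterministic under its seed and returns the truth needed to score the
# downstream stage.

.random_dna <- function(n, base_probs = c(A = .25, C = .25, G = .25, T = .25)) {
  sample(names(base_probs), n, replace = TRUE, prob = base_probs)
}

# random non-homopolymer arm free of the core in either orientation
.random_arm <- function(k, core, base_probs) {
  rc <- reverse_complement(core)
  repeat {
    arm <- paste(.random_dna(k, base_probs), collapse = "")
    if (k >= 2L && .is_homopolymer_string(arm)) next
    if (k >= nchar(core) &&
        (grepl(core, arm, fixed = TRUE) || grepl(rc, arm, fixed = TRUE))) next
    return(arm)
  }
}

#' Simulate reference sequences with implanted palindromic loci
#'
#' Generates random DNA and implants, at recorded non-overlapping positions,
#' constructs of the form `arm + core + reverse_complement(arm)`, flanked on
#' both sides by an `A` so the measured arm is exactly the implanted length
#' (an A/A pair cannot extend the palindrome). Decoy classes exercise the
#' scanner's filters: `bare` cores with zero-length arms, `homopolymer`
#' constructs with poly-A/poly-T arms, and `masked` constructs written in
#' lowercase (soft-masked repeat).
#'
#' @param n_sequences Number of sequences.
#' @param seq_length Length of each sequence (bases).
#' @param implant_arms Integer vector: one implant per element, with that
#'   arm length (e.g. `c(9, 10, 11)`).
#' @param core Core motif string (default `"TGAACA"`).
#' @param n_bare,n_homopolymer,n_masked Number of decoys of each class.
#' @param decoy_arm Arm length used for homopolymer and masked decoys.
#' @param base_probs Background base composition.
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @return List with `sequences` (named character vector), `truth` (data
#'   frame `seqname`, `start`, `core`, `arm_length`, `class`) and `params`
#'   (the generating parameters).
#' @examples
#' g <- simulate_genome(seq_length = 4000, implant_arms = c(9, 10, 11),
#'                      n_bare = 2, seed = 1)
#' scan_core_motif(g$sequences, "TGAACA", min_arm = 9)
#' @export
simulate_genome <- function(n_sequences = 1L, seq_length = 10000L,
                            implant_arms = c(9L, 10L, 11L),
                            core = "TGAACA",
                            n_bare = 0L, n_homopolymer = 0L, n_masked = 0L,
                            decoy_arm = 9L,
                            base_probs = c(A = .25, C = .25, G = .25, T = .25),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  core <- toupper(core)
  clen <- nchar(core)

  constructs <- data.frame(
    class = c(rep("implant", length(implant_arms)),
              rep("bare", n_bare),
              rep("homopolymer", n_homopolymer),
              rep("masked", n_masked)),
    arm = c(as.integer(implant_arms), rep(0L, n_bare),
            rep(decoy_arm, n_homopolymer), rep(decoy_arm, n_masked)),
    stringsAsFactors = FALSE)
  n_con <- nrow(constructs)
  constructs$seq_idx <- rep_len(seq_len(n_sequences), n_con)

  seqs <- character(n_sequences)
  names(seqs) <- paste0("synth", seq_len(n_sequences))
  truth <- list()
  for (si in seq_len(n_sequences)) {
    chars <- .random_dna(seq_length, base_probs)
    mine <- constructs[constructs$seq_idx == si, , drop = FALSE]
    if (nrow(mine) > 0L) {
      footprints <- 2L * mine$arm + clen + 2L
      block <- seq_length %/% nrow(mine)
      if (any(footprints + 4L > block))
        stop("infeasible packing: constructs do not fit the sequence length",
             call. = FALSE)
      for (j in seq_len(nrow(mine))) {
        arm_len <- mine$arm[j]
        left <- if (arm_len > 0L) .random_arm(arm_len, core, base_probs) else ""
        if (mine$class[j] == "homopolymer") left <- strrep("A", arm_len)
        right <- if (arm_len > 0L) reverse_complement(left) else ""
        body <- paste0("A", left, core, right, "A")
        if (mine$class[j] == "masked") body <- tolower(body)
        at <- (j - 1L) * block + 3L  # 1-based start of the flank base
        chars[seq(at, at + nchar(body) - 1L)] <-
          strsplit(body, "", fixed = TRUE)[[1L]]
        truth[[length(truth) + 1L]] <- data.frame(
          seqname = names(seqs)[si],
          start = at + 1L + arm_len,   # core start
          core = core, arm_length = arm_len, class = mine$class[j],
          stringsAsFactors = FALSE)
      }
    }
    seqs[si] <- paste(chars, collapse = "")
  }
  truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
    seqname = character(0), start = integer(0), core = character(0),
    arm_length = integer(0), class = character(0))
  truth <- truth[order(truth$seqname, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(sequences = seqs, truth = truth,
       params = list(n_sequences = n_sequences, seq_length = seq_length,
                   implant_arms = implant_arms, core = core,
                   n_bare = n_bare, n_homopolymer = n_homopolymer,
                   n_masked = n_masked, decoy_arm = decoy_arm,
                   base_probs = base_probs, seed = seed))
}

# --- latent-factor dependence calibration ------------------------------------

.marginal_given_alpha <- function(alpha, sigma) {
  stats::integrate(function(z) stats::plogis(alpha + sigma * z) *
                     stats::dnorm(z), -8, 8)$value
}

.calibrate_alpha <- function(p, sigma) {
  stats::uniroot(function(a) .marginal_given_alpha(a, sigma) - p,
                 interval = c(-30, 30), tol = 1e-9)$root
}

.implied_or <- function(sigma, p_a, p_b) {
  a <- .calibrate_alpha(p_a, sigma)
  b <- .calibrate_alpha(p_b, sigma)
  p11 <- stats::integrate(function(z)
    stats::plogis(a + sigma * z) * stats::plogis(b + sigma * z) *
      stats::dnorm(z), -8, 8)$value
  p10 <- p_a - p11; p01 <- p_b - p11; p00 <- 1 - p_a - p_b + p11
  (p11 * p00) / (p10 * p01)
}

#' Calibrate the latent-factor scale to a target odds ratio
#'
#' The cohort generator induces positive dependence between loci through a
#' single per-sample latent "instability" factor `z ~ N(0,1)` acting on the
#' log-odds of every locus: `logit P(call) = alpha_j + sigma * z`. This
#' solves for the `sigma` at which the model-implied odds ratio between two
#' loci with marginals `p_a` and `p_b` equals `target_or` (1-D root finding;
#' the implied OR is monotone increasing in `sigma`).
#'
#' @param target_or Target pairwise odds ratio (> 1).
#' @param p_a,p_b Marginal mutation probabilities of the two loci.
#' @return The calibrated `sigma`.
#' @export
calibrate_dependence <- function(target_or, p_a, p_b) {
  stopifnot(target_or >= 1)
  if (target_or == 1) return(0)
  stats::uniroot(function(s) log(.implied_or(s, p_a, p_b)) - log(target_or),
                 interval = c(1e-3, 8), tol = 1e-7)$root
}

#' Default per-locus mutation marginals for the simulated cohort
#'
#' Observed cohort frequencies for the named loci (GPR126 45.6%, PLEKHS1
#' 29.1%, Intron ADM 11.7%, Chr7:11 9.7%, Chr15:96 7.8%, GABRG3 6.8%,
#' CLVS2 1%, Chr3:82 1%); the ten unnamed panel loci default to 2%, the
#' order of magnitude of the rarer assayed loci.
#'
#' @return Named numeric vector over the default registry's TGAACA loci.
#' @export
default_cohort_marginals <- function() {
  c("GPR126" = 0.456, "PLEKHS1" = 0.291, "Intron ADM" = 0.117,
    "Chr7:11" = 0.097, "Chr15:96" = 0.078, "GABRG3" = 0.068,
    "CLVS2" = 0.01, "Chr3:82" = 0.01,
    stats::setNames(rep(0.02, 10),
                    paste0("TGAACA_L", formatC(9:18, width = 2, flag = "0"))))
}

.group_probs_default <- function() list(
  female = c(G1 = 3 / 39, G2 = 6 / 46, G3 = 8 / 18),
  history_yes = c(G1 = 12 / 39, G2 = 26 / 46, G3 = 6 / 18),
  fgfr3_mut = c(G1 = 6 / 39, G2 = 19 / 46, G3 = 3 / 18),
  pik3ca_mut = c(G1 = 2 / 39, G2 = 7 / 46, G3 = 4 / 18),
  tert_mut = c(G1 = 25 / 38, G2 = 38 / 46, G3 = 16 / 18),
  age_ge60 = c(G1 = 29 / 39, G2 = 34 / 46, G3 = 14 / 18),
  smoker = c(G1 = 29 / 35, G2 = 28 / 44, G3 = 12 / 18),
  stage = rbind(G1 = c(1, 11, 5, 8, 14) / 39,
                G2 = c(0, 17, 6, 8, 15) / 46,
                G3 = c(0, 2, 4, 3, 9) / 18))

#' Simulate a cohort mutation table with covariates
#'
#' Per sample, a latent instability factor `z ~ N(0,1)` scales the log-odds
#' of every TGAACA locus (`logit p_ij = alpha_j + sigma * z_i`); `alpha_j`
#' is calibrated so each locus hits its target marginal, and `sigma` so the
#' implied odds ratio between `or_pair` equals `target_or` (see
#' [calibrate_dependence()]). Each call is assigned to one of the two
#' mutable core positions: offset 1 (the core G, emitted as G>A) with
#' probability `offset_mix`, otherwise offset 4 (the core C, emitted as
#' C>T). The AGATCA locus of RAD51B is drawn conditionally on TGAACA
#' signature positivity, reproducing the observed nesting. Covariates are
#' drawn per signature group from the observed cohort proportions (sex,
#' age, smoking, NMIBC history, stage, FGFR3/PIK3CA/TERT status); outcome
#' fields are carried but not modelled.
#'
#' @param n_samples Cohort size (default 103).
#' @param marginals Named per-locus marginal probabilities (TGAACA loci).
#' @param target_or,or_pair Calibration target for the pairwise odds ratio.
#' @param sigma Latent scale; overrides calibration when supplied.
#' @param registry Locus registry supplying genomic coordinates.
#' @param offset_mix Probability a call lands on core offset 1.
#' @param rad51b_marginal Target marginal for the RAD51B AGATCA locus.
#' @param rad51b_conditional Draw RAD51B only among signature-positive
#'   samples (default `TRUE`).
#' @param seed Integer seed.
#' @return List with `mutations` (sample_id, chrom, pos, ref, alt),
#'   `covariates` (one row per sample), `truth` (generating parameters:
#'   marginals, sigma, alphas, group probabilities, seed) and `registry`.
#' @export
simulate_cohort <- function(n_samples = 103L,
                            marginals = default_cohort_marginals(),
                            target_or = 10, or_pair = c("Intron ADM", "PLEKHS1"),
                            sigma = NULL,
                            registry = default_registry(),
                            offset_mix = 0.5,
                            rad51b_marginal = 0.049,
                            rad51b_conditional = TRUE,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(marginals > 0 & marginals < 1))
  loci <- names(marginals)
  missing <- setdiff(loci, registry$locus_id)
  if (length(missing))
    stop("marginals name loci absent from the registry: ",
         paste(missing, collapse = ", "), call. = FALSE)

  if (is.null(sigma))
    sigma <- calibrate_dependence(target_or, marginals[[or_pair[1L]]],
                                  marginals[[or_pair[2L]]])
  alphas <- vapply(marginals, .calibrate_alpha, numeric(1L), sigma = sigma)

  z <- stats::rnorm(n_samples)
  eta <- outer(sigma * z, rep(1, length(loci))) +
    matrix(alphas, n_samples, length(loci), byrow = TRUE)
  calls <- matrix(stats::runif(length(eta)) < stats::plogis(eta),
                  n_samples, length(loci),
                  dimnames = list(sprintf("S%03d", seq_len(n_samples)), loci))

  burden <- rowSums(calls)
  group <- assign_signature_group(burden)

  # RAD51B nested within signature-positive samples
  rad <- rep(FALSE, n_samples)
  positive <- burden >= 1L
  if (rad51b_conditional) {
    if (any(positive)) {
      p_cond <- min(1, rad51b_marginal * n_samples / sum(positive))
      rad[positive] <- stats::runif(sum(positive)) < p_cond
    }
  } else {
    rad <- stats::runif(n_samples) < rad51b_marginal
  }

  sample_ids <- rownames(calls)
  all_calls <- cbind(calls, RAD51B = rad)

  mut_rows <- which(all_calls, arr.ind = TRUE)
  mutations <- if (nrow(mut_rows)) {
    lid <- colnames(all_calls)[mut_rows[, 2L]]
    ri <- match(lid, registry$locus_id)
    use1 <- stats::runif(nrow(mut_rows)) < offset_mix
    use1[is.na(registry$pos2[ri])] <- TRUE
    data.frame(
      sample_id = sample_ids[mut_rows[, 1L]],
      chrom = registry$chrom[ri],
      pos = ifelse(use1, registry$pos1[ri], registry$pos2[ri]),
      ref = ifelse(use1, "G", "C"),
      alt = ifelse(use1, "A", "T"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = character(0), chrom = character(0),
               pos = integer(0), ref = character(0), alt = character(0))
  }
  mutations <- mutations[order(mutations$sample_id, mutations$chrom,
                               mutations$pos), , drop = FALSE]
  rownames(mutations) <- NULL

  gp <- .group_probs_default()
  gi <- as.integer(group)
  draw <- function(p) stats::runif(n_samples) < p[gi]
  stage_levels <- c("Cis", "Ta", "T1", "T2", ">=T3")
  stage <- vapply(gi, function(g)
    sample(stage_levels, 1L, prob = gp$stage[g, ]), character(1L))
  nmibc <- stage %in% c("Cis", "Ta", "T1")
  smoking <- ifelse(draw(gp$smoker), "smoker", "non_smoker")
  smoking[sample.int(n_samples, min(6L, n_samples))] <- NA
  tert <- ifelse(draw(gp$tert_mut), "mutated", "not_mutated")
  tert[sample.int(n_samples, 1L)] <- NA

  covariates <- data.frame(
    sample_id = sample_ids,
    sex = ifelse(draw(gp$female), "female", "male"),
    age_group = ifelse(draw(gp$age_ge60), ">=60", "<60"),
    smoking = smoking,
    history_nmibc = ifelse(draw(gp$history_yes), "yes", "no"),
    stage = stage,
    grade = ifelse(stage == "Ta" & stats::runif(n_samples) < 2 / 3,
                   "low", "high"),
    cohort = ifelse(nmibc, "NMIBC", "MIBC"),
    fgfr3 = ifelse(draw(gp$fgfr3_mut), "mutated", "not_mutated"),
    pik3ca = ifelse(draw(gp$pik3ca_mut), "mutated", "not_mutated"),
    tert = tert,
    recurrence = ifelse(nmibc, stats::runif(n_samples) < 0.5, NA),
    progression = ifelse(nmibc, stats::runif(n_samples) < 0.18, NA),
    death = ifelse(!nmibc, stats::runif(n_samples) < 0.576, NA),
    stringsAsFactors = FALSE)

  list(mutations = mutations, covariates = covariates,
       truth = list(marginals = marginals, sigma = sigma, alphas = alphas,
                    target_or = target_or, or_pair = or_pair,
                    rad51b_marginal = rad51b_marginal,
                    rad51b_conditional = rad51b_conditional,
                    offset_mix = offset_mix,
                    group_probs = gp, seed = seed),
       registry = registry)
}

#' Simulate a qPCR Ct table with a group expression effect
#'
#' Log-normal expression on the log2 scale: groups 1 and 2 share a common
#' tumor baseline, group 3 is shifted by `fold` (default 2), and the normal
#' reference tissues sit at level 1. Ct values are generated by inversion
#' (`Ct_gene = Ct_ref - log2(expression)`), so [relative_expression()]
#' recovers the generated expression exactly.
#'
#' @param groups Factor of signature groups for the tumor samples, named by
#'   sample id (unnamed vectors get `T001`, `T002`, ...).
#' @param gene Target gene name (default `"APOBEC3B"`).
#' @param fold Expression fold change of group 3 versus the tumor baseline.
#' @param baseline Tumor baseline expression relative to normal tissue.
#' @param sd_log2 Biological scatter (standard deviation on log2 scale).
#' @param reference_gene Reference gene name (default `"TBP"`).
#' @param ct_ref_mean,ct_ref_sd Per-sample reference-gene Ct distribution.
#' @param n_normals Number of normal-tissue samples appended (`N01`, ...).
#' @param seed Integer seed.
#' @return List with `ct_table` (`sample_id`, `gene`, `ct`), `normal_ids`,
#'   and `truth` (per-sample generated expression and parameters).
#' @export
simulate_expression <- function(groups, gene = "APOBEC3B", fold = 2,
                                baseline = 10, sd_log2 = 1,
                                reference_gene = "TBP",
                                ct_ref_mean = 30, ct_ref_sd = 0.5,
                                n_normals = 20L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- factor(groups)
  ids <- names(groups)
  if (is.null(ids)) ids <- sprintf("T%03d", seq_along(groups))

  level <- c(rep(1, n_normals),
             ifelse(groups == "G3", baseline * fold, baseline))
  all_ids <- c(sprintf("N%02d", seq_len(n_normals)), ids)
  log2e <- log2(level) + stats::rnorm(length(level), 0, sd_log2)
  ct_ref <- stats::rnorm(length(level), ct_ref_mean, ct_ref_sd)
  ct_gene <- ct_ref - log2e

  ct_table <- rbind(
    data.frame(sample_id = all_ids, gene = gene, ct = ct_gene,
               stringsAsFactors = FALSE),
    data.frame(sample_id = all_ids, gene = reference_gene, ct = ct_ref,
               stringsAsFactors = FALSE))
  list(ct_table = ct_table,
       normal_ids = sprintf("N%02d", seq_len(n_normals)),
       truth = list(
         expression = data.frame(
           sample_id = all_ids,
           group = c(rep("normal", n_normals), as.character(groups)),
           expression = 2 ^ log2e, stringsAsFactors = FALSE),
         fold = fold, baseline = baseline, sd_log2 = sd_log2, seed = seed))
}
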