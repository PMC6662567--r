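# Tetranucleotide composition: canonical tetramer classes, per-contig
# frequency vectors, and the raw TNF similarity score.

revcomp_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical tetramers
#'
#' The 256 tetramers collapse into 136 strand-independent classes: a tetramer
#' and its reverse complement share one representative (the lexicographically
#' smaller of the two; 16 tetramers are their own reverse complement).
#'
#' @return Sorted character vector of the 136 canonical representatives.
#' @export
canonical_tetramers <- function() {
  all4 <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 4L)
  rc <- revcomp_str(all4)
  sort(unique(pmin(all4, rc)))
}

# 256-long map: tetramer (mkAllStrings order) -> canonical representative.
tetramer_fold_map <- function() {
  all4 <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), 4L)
  rc <- revcomp_str(all4)
  structure(pmin(all4, rc), names = all4)
}

#' Tetranucleotide frequency vectors
#'
#' Counts every 4-bp window (step 1) that contains only A/C/G/T, accumulates
#' counts on canonical (strand-collapsed) tetramers, and normalizes to
#' frequencies.  Windows containing N are skipped.
#'
#' @param seqs A [Biostrings::DNAStringSet] (or single character string).
#' @return A matrix with one row per sequence and 136 canonical-tetramer
#'   columns; rows sum to 1 where any valid window exists, and are all zero
#'   otherwise.  Attribute `n_kmers` holds the per-sequence count of valid
#'   windows.
#' @export
compute_tnf <- function(seqs) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  canon <- canonical_tetramers()
  fold <- tetramer_fold_map()
  counts <- Biostrings::oligonucleotideFrequency(seqs, width = 4L)
  folded <- t(rowsum(t(counts), group = fold[colnames(counts)]))
  folded <- folded[, canon, drop = FALSE]
  n_kmers <- stats::setNames(rowSums(folded), names(seqs))
  freq <- folded / ifelse(n_kmers > 0, n_kmers, 1)
  rownames(freq) <- names(seqs)
  attr(freq, "n_kmers") <- n_kmers
  freq
}

# Logistic coefficients mapping (Euclidean TNF distance, pair length scale)
# to the probability that two contigs come from the same genome.  Frozen
# output of calibrate_tnf_logistic(seed = 7) -- see that function for the
# procedure; rerunning it reproduces these values.
.tnf_logistic <- c(intercept = 14.4344996, dist = -1484.2623191,
                   lenscale = 1160.0360415)

#' Raw TNF similarity score
#'
#' A calibrated logistic in the Euclidean distance between two canonical
#' tetramer frequency vectors, with a length-dependent midpoint that absorbs
#' the sampling noise of short contigs (frequency estimates from L bp have
#' standard error ~ 1/sqrt(L)).  The logistic is rescaled so that distance 0
#' maps to exactly 1; scores decay towards 0 for distant compositions.
#'
#' @param a,b Frequency vectors (rows of [compute_tnf()] output), or `a` may
#'   be a full frequency matrix and `b` `NULL` to get the all-pairs matrix.
#' @param len_a,len_b Contig lengths in bp (vector of all lengths when `b`
#'   is `NULL`).
#' @return Score(s) in \[0, 1\]; symmetric in the two contigs.
#' @export
tnf_raw_score <- function(a, b = NULL, len_a, len_b = NULL) {
  if (is.null(b)) {
    nk <- pmax(len_a - 3, 1)
    d2 <- outer(rowSums(a^2), rowSums(a^2), "+") - 2 * tcrossprod(a)
    d <- sqrt(pmax(d2, 0))
    srt <- sqrt(outer(1 / nk, 1 / nk, "+"))
  } else {
    if (sum(a) == 0 || sum(b) == 0)
      return(NA_real_)
    d <- sqrt(sum((a - b)^2))
    srt <- sqrt(1 / max(len_a - 3, 1) + 1 / max(len_b - 3, 1))
  }
  score <- tnf_raw_from_distance(d, srt = srt)
  if (is.matrix(score)) diag(score) <- 1
  score
}

# Calibrated logistic score from a Euclidean TNF distance and the pair
# length scale srt = sqrt(1/nA + 1/nB) (window counts nA, nB), rescaled so
# that distance 0 scores exactly 1.
tnf_raw_from_distance <- function(d, len_a = NULL, len_b = NULL, srt = NULL) {
  if (is.null(srt))
    srt <- sqrt(1 / max(len_a - 3, 1) + 1 / max(len_b - 3, 1))
  eta0 <- .tnf_logistic[["intercept"]] + .tnf_logistic[["lenscale"]] * srt
  eta <- eta0 + .tnf_logistic[["dist"]] * d
  pmin(stats::plogis(eta) / stats::plogis(eta0), 1)
}

#' Calibrate the TNF logistic score
#'
#' Simulates communities of Markov-chain genomes, fragments them at lengths
#' spanning 1-50 kb, and fits a logistic regression of the same-genome
#' indicator on the Euclidean TNF distance and the pair length scale
#' sqrt(1/nA + 1/nB).  The fitted coefficients are the ones frozen in the
#' package source; the procedure is deterministic given `seed`.
#'
#' @param n_genomes,genome_length,n_reps Size of the calibration simulation.
#' @param seed RNG seed.
#' @return Named coefficient vector (intercept, dist, lenscale).
#' @export
calibrate_tnf_logistic <- function(n_genomes = 12, genome_length = 3e5,
                                   n_reps = 3, seed = 7) {
  with_seed(seed, {
    d <- numeric(0); srt <- numeric(0); same <- logical(0)
    for (rep in seq_len(n_reps)) {
      com <- generate_community(community_spec(
        n_genomes = n_genomes, genome_length = genome_length,
        n_samples = 1, seed = seed + rep))
      tnf <- compute_tnf(com$contigs)
      len <- Biostrings::width(com$contigs)
      keep <- len >= 1000
      tnf <- tnf[keep, , drop = FALSE]; len <- len[keep]
      gen <- com$truth$genome_id[keep]
      n <- nrow(tnf)
      pairs <- cbind(sample.int(n, 4000L, replace = TRUE),
                     sample.int(n, 4000L, replace = TRUE))
      pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
      dd <- sqrt(rowSums((tnf[pairs[, 1], ] - tnf[pairs[, 2], ])^2))
      ss <- sqrt(1 / (len[pairs[, 1]] - 3) + 1 / (len[pairs[, 2]] - 3))
      d <- c(d, dd); srt <- c(srt, ss)
      same <- c(same, gen[pairs[, 1]] == gen[pairs[, 2]])
    }
    fit <- stats::glm(same ~ d + srt, family = stats::binomial())
    stats::setNames(stats::coef(fit), c("intercept", "dist", "lenscale"))
  })
}
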