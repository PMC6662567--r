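# Shared fixtures, built in code at test time.

# A small, fast community for module-level tests.
tiny_community <- function(n_genomes = 4, genome_length = 3e5, n_samples = 3,
                           seed = 3, ...) {
  generate_community(community_spec(n_genomes = n_genomes,
                                    genome_length = genome_length,
                                    n_samples = n_samples, seed = seed, ...))
}

# Random TNF-like frequency vector on the 136 canonical classes.
random_freq <- function() {
  x <- runif(136)
  x / sum(x)
}

# Reverse complement of a plain character DNA string.
rc <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Random DNA string.
random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Closed-form chi-square survival for even degrees of freedom 2m:
#   P(X > x) = exp(-x/2) * sum_{i=0}^{m-1} (x/2)^i / i!
# Independent of pchisq; used as the Fisher's-method oracle.
chisq_sf_even <- function(x, m) {
  h <- x / 2
  terms <- vapply(0:(m - 1), function(i) exp(-h + i * log(h) - lfactorial(i)),
                  numeric(1))
  sum(terms)
}

# Brute-force dense per-node top-k from a symmetric score matrix:
# for node i, the k best-scoring partners (ties to the lexicographically
# smaller id).
dense_topk <- function(scores, k) {
  nodes <- rownames(scores)
  lapply(stats::setNames(seq_along(nodes), nodes), function(i) {
    s <- scores[i, ]
    s[i] <- NA
    cand <- which(!is.na(s))
    cand <- cand[order(-s[cand], nodes[cand])]
    nodes[cand[seq_len(min(k, length(cand)))]]
  })
}
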