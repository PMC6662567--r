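# Synthetic multi-sample community simulator with ground truth, plus the
# completeness/precision evaluator used to score binning results.

#' Specify a synthetic community
#'
#' Each genome is sampled from its own order-3 Markov chain whose transition
#' logits are perturbed around uniform by `markov_bias` (larger values give
#' more distinguishable tetramer composition; the default is chosen so that
#' between-genome TNF distances resemble the 0.02-0.1 range typical of
#' distinct microbial species).  Genomes are fragmented into contigs; a
#' fraction `frac_small` of fragments falls below 2.5 kb (uniform 1-2.5 kb)
#' and the rest are uniform 2.5-50 kb.  Per-genome per-sample coverage is
#' lognormal; per-contig mean depth wobbles around it with relative sd
#' `depth_noise`, and the reported depth variance is `dispersion` times the
#' mean (overdispersed-Poisson read depth).
#'
#' @param n_genomes Number of genomes.
#' @param genome_length Genome length in bp.
#' @param n_samples Number of samples.
#' @param markov_bias Sd of the per-genome transition-logit perturbation.
#' @param coverage_meanlog,coverage_sdlog Lognormal parameters of the
#'   genome-by-sample coverage draw.
#' @param frac_small Fraction of fragments drawn from the 1-2.5 kb range.
#' @param small_range,large_range Fragment length ranges (bp).
#' @param depth_noise Relative sd of per-contig depth around the
#'   genome-sample coverage.
#' @param dispersion Depth variance = `dispersion` * mean depth.
#' @param bias_groups Optional integer vector (length `n_genomes`): genomes
#'   sharing a group share one Markov chain, i.e. identical tetramer bias.
#' @param coverage Optional explicit genome-by-sample coverage matrix
#'   overriding the lognormal draw.
#' @param seed RNG seed; the whole community is deterministic given it.
#' @return A `community_spec` list.
#' @export
community_spec <- function(n_genomes = 20, genome_length = 2e6,
                           n_samples = 3, markov_bias = 0.3,
                           coverage_meanlog = log(25), coverage_sdlog = 0.8,
                           frac_small = 0.15, small_range = c(1000, 2500),
                           large_range = c(2500, 50000), depth_noise = 0.1,
                           dispersion = 2, bias_groups = NULL,
                           coverage = NULL, seed = 1) {
  stopifnot(n_genomes >= 1, genome_length >= large_range[[2L]],
            n_samples >= 1, frac_small >= 0, frac_small <= 1,
            markov_bias >= 0, depth_noise >= 0, dispersion > 0)
  if (is.null(bias_groups)) bias_groups <- seq_len(n_genomes)
  stopifnot(length(bias_groups) == n_genomes)
  if (!is.null(coverage))
    stopifnot(nrow(coverage) == n_genomes, ncol(coverage) == n_samples)
  structure(list(n_genomes = n_genomes, genome_length = genome_length,
                 n_samples = n_samples, markov_bias = markov_bias,
                 coverage_meanlog = coverage_meanlog,
                 coverage_sdlog = coverage_sdlog, frac_small = frac_small,
                 small_range = small_range, large_range = large_range,
                 depth_noise = depth_noise, dispersion = dispersion,
                 bias_groups = bias_groups, coverage = coverage,
                 seed = seed),
            class = "community_spec")
}

# Order-3 transition matrix (64 x 4): softmax of uniform logits perturbed by
# N(0, bias) per (state, base).
markov_transitions <- function(bias) {
  logits <- matrix(rnorm(64 * 4, sd = bias), 64, 4)
  p <- exp(logits)
  p / rowSums(p)
}

# Fragment a genome of length L into contig lengths per the mixture law.
fragment_lengths <- function(L, spec) {
  out <- numeric(0)
  pos <- 0
  while (pos < L) {
    len <- if (runif(1) < spec$frac_small)
      round(runif(1, spec$small_range[[1L]], spec$small_range[[2L]]))
    else
      round(runif(1, spec$large_range[[1L]], spec$large_range[[2L]]))
    len <- min(len, L - pos)
    out <- c(out, len)
    pos <- pos + len
  }
  # drop a trailing sliver shorter than the smallest simulated contig
  if (length(out) > 1L && out[[length(out)]] < spec$small_range[[1L]])
    out <- out[-length(out)]
  out
}

#' Generate a synthetic community with ground truth
#'
#' @param spec A [community_spec()].
#' @param out_dir Optional directory; when given, writes `contigs.fa`,
#'   `depth.tsv` and `truth.tsv` there.
#' @return List with `contigs` ([Biostrings::DNAStringSet]), `coverage`
#'   (a `coverage_table`), `truth` (data frame `contig_id`, `genome_id`,
#'   `contig_bp`), `genome_coverage` (genome x sample matrix), and `paths`
#'   (when `out_dir` is given).
#' @export
generate_community <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "community_spec"))
  with_seed(spec$seed, {
    groups <- spec$bias_groups
    trans <- vector("list", max(groups))
    for (g in sort(unique(groups))) trans[[g]] <- markov_transitions(spec$markov_bias)
    cov <- spec$coverage
    if (is.null(cov))
      cov <- matrix(rlnorm(spec$n_genomes * spec$n_samples,
                           spec$coverage_meanlog, spec$coverage_sdlog),
                    spec$n_genomes, spec$n_samples)
    rownames(cov) <- sprintf("genome_%02d", seq_len(spec$n_genomes))
    colnames(cov) <- sprintf("sample_%d", seq_len(spec$n_samples))

    seqs <- character(0); ids <- character(0)
    genome_of <- character(0)
    for (g in seq_len(spec$n_genomes)) {
      genome <- markov_sequence(spec$genome_length, trans[[groups[[g]]]],
                                runif(spec$genome_length))
      lens <- fragment_lengths(spec$genome_length, spec)
      ends <- cumsum(lens)
      starts <- ends - lens + 1
      frag <- substring(genome, starts, ends)
      cid <- sprintf("g%02d_c%04d", g, seq_along(frag))
      seqs <- c(seqs, frag); ids <- c(ids, cid)
      genome_of <- c(genome_of, rep(rownames(cov)[[g]], length(frag)))
    }
    contigs <- Biostrings::DNAStringSet(seqs)
    names(contigs) <- ids
    lens <- Biostrings::width(contigs)
    gidx <- match(genome_of, rownames(cov))
    noise <- matrix(1 + rnorm(length(ids) * spec$n_samples,
                              sd = spec$depth_noise),
                    length(ids), spec$n_samples)
    mean_depth <- pmax(cov[gidx, , drop = FALSE] * noise, 0.01)
    depth_variance <- spec$dispersion * mean_depth
    dimnames(mean_depth) <- dimnames(depth_variance) <-
      list(ids, colnames(cov))
    coverage <- structure(list(
      contig_ids = ids, n_samples = spec$n_samples,
      sample_names = colnames(cov), mean_depth = mean_depth,
      depth_variance = depth_variance,
      total_avg_depth = stats::setNames(rowSums(mean_depth), ids),
      lengths = stats::setNames(as.numeric(lens), ids),
      unmatched = character(0)), class = "coverage_table")
    truth <- data.frame(contig_id = ids, genome_id = genome_of,
                        contig_bp = as.integer(lens),
                        stringsAsFactors = FALSE)
    out <- list(contigs = contigs, coverage = coverage, truth = truth,
                genome_coverage = cov)
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      paths <- list(fasta = file.path(out_dir, "contigs.fa"),
                    depth = file.path(out_dir, "depth.tsv"),
                    truth = file.path(out_dir, "truth.tsv"))
      Biostrings::writeXStringSet(contigs, paths$fasta, width = 80L)
      write_depth_table(coverage, paths$depth)
      utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      out$paths <- paths
    }
    out
  })
}

#' Write a coverage table in the depth-summarizer dialect
#'
#' @param coverage A `coverage_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(coverage, path) {
  stopifnot(inherits(coverage, "coverage_table"))
  n <- length(coverage$contig_ids)
  s <- coverage$n_samples
  cols <- list(contigName = coverage$contig_ids,
               contigLen = as.integer(coverage$lengths),
               totalAvgDepth = signif(coverage$total_avg_depth, 8))
  for (j in seq_len(s)) {
    nm <- coverage$sample_names[[j]]
    cols[[nm]] <- signif(coverage$mean_depth[, j], 8)
    cols[[paste0(nm, "-var")]] <- signif(coverage$depth_variance[, j], 8)
  }
  tab <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth table
#'
#' @param path Truth TSV (`contig_id`, `genome_id`, `contig_bp`).
#' @return Data frame.
#' @export
read_truth <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Evaluate bins against ground truth
#'
#' Bin precision is the bp share of the bin's majority genome; genome
#' completeness is the bp of the genome inside the single bin holding most
#' of it, over the genome's total bp across contigs (binned or not).  A
#' genome counts as recovered at thresholds (c, p) iff its best bin has
#' precision >= p and the genome's completeness in that bin is >= c.
#'
#' @param bins A `bin_set`.
#' @param truth Data frame (`contig_id`, `genome_id`, `contig_bp`) or named
#'   character vector contig -> genome (then `lengths` is required).
#' @param lengths Named contig lengths, required when `truth` is a vector.
#' @return An `eval_report`: list with `per_bin`, `per_genome`, and `counts`
#'   (5 completeness x 2 precision matrix of recovered-genome counts).
#' @export
evaluate_bins <- function(bins, truth, lengths = NULL) {
  stopifnot(inherits(bins, "bin_set"))
  if (is.data.frame(truth)) {
    lengths <- stats::setNames(as.numeric(truth$contig_bp), truth$contig_id)
    truth <- stats::setNames(truth$genome_id, truth$contig_id)
  }
  stopifnot(!is.null(lengths))
  binned <- unlist(bins$bins, use.names = FALSE)
  missing <- setdiff(binned, names(truth))
  if (length(missing)) stop("binned contig absent from truth: ", missing[[1L]])
  genomes <- sort(unique(unname(truth)))
  genome_bp <- vapply(genomes, function(g)
    sum(lengths[names(truth)[truth == g]]), numeric(1))

  per_bin <- data.frame(bin = character(0), bp = numeric(0),
                        majority_genome = character(0), precision = numeric(0),
                        stringsAsFactors = FALSE)
  # bp of each genome inside each bin
  in_bin <- matrix(0, length(genomes), length(bins$bins),
                   dimnames = list(genomes, names(bins$bins)))
  for (b in names(bins$bins)) {
    m <- bins$bins[[b]]
    bp <- tapply(lengths[m], truth[m], sum)
    in_bin[names(bp), b] <- bp
    maj <- names(bp)[order(-bp, names(bp))][[1L]]
    per_bin <- rbind(per_bin, data.frame(
      bin = b, bp = sum(bp), majority_genome = maj,
      precision = bp[[maj]] / sum(bp), stringsAsFactors = FALSE))
  }
  cvals <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  pvals <- c(0.9, 0.95)
  counts <- matrix(0L, length(cvals), length(pvals),
                   dimnames = list(paste0("c", cvals * 100),
                                   paste0("p", pvals * 100)))
  per_genome <- data.frame(genome = genomes, bp = unname(genome_bp),
                           best_bin = NA_character_,
                           completeness = 0, best_bin_precision = NA_real_,
                           stringsAsFactors = FALSE)
  if (ncol(in_bin) > 0L) {
    for (i in seq_along(genomes)) {
      row <- stats::setNames(in_bin[i, ], colnames(in_bin))
      if (all(row == 0)) next
      best <- names(row)[order(-row, names(row))][[1L]]
      per_genome$best_bin[i] <- best
      per_genome$completeness[i] <- row[[best]] / genome_bp[[i]]
      per_genome$best_bin_precision[i] <-
        per_bin$precision[per_bin$bin == best]
    }
    for (ci in seq_along(cvals)) for (pi in seq_along(pvals))
      counts[ci, pi] <- sum(per_genome$completeness >= cvals[[ci]] &
                              !is.na(per_genome$best_bin_precision) &
                              per_genome$best_bin_precision >= pvals[[pi]])
  }
  structure(list(per_bin = per_bin, per_genome = per_genome, counts = counts),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report:", nrow(x$per_bin), "bins,", nrow(x$per_genome),
      "genomes\nrecovered-genome counts (completeness x precision):\n")
  print(x$counts)
  invisible(x)
}
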