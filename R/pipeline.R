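# End-to-end binning pipeline: features -> score normalization -> two-stage
# graph partitioning -> small-contig/bin recruiting -> outputs.

#' Binning parameters
#'
#' @param min_contig Minimum contig length (bp) used for clustering
#'   (default 2500).
#' @param max_p Percentile (0-100] locating the strong-score admission
#'   cutoffs; higher admits more edges and gives more sensitivity
#'   (default 95).
#' @param min_s Minimum edge score kept for binning, on a 0-100 scale;
#'   higher gives more specificity (default 60).
#' @param max_edges Maximum number of edges per node (default 200); smaller
#'   values favor specificity over sensitivity.
#' @param min_cls_size Minimum bin size in bp (default 200000).
#' @param min_cv Effective-coverage threshold: a sample counts towards nABD
#'   when either contig's mean depth exceeds it (default 1).
#' @param min_contig_recruit Minimum length of small contigs considered for
#'   recruiting (default 1000; recruiting covers lengths from here up to
#'   `min_contig`).
#' @param schedule_steps Number of equal threshold steps in the iterative
#'   admission schedule (default 10).
#' @param max_lpa_iters Sweep cap per label-propagation fixed point
#'   (default 50).
#' @param geodesic_mean_3 Use the cube root in the three-factor composite
#'   score instead of the square root (default FALSE).
#' @param seed RNG seed controlling pair sampling and recruiting subsamples
#'   (default 1).
#' @return A `binning_params` list.
#' @export
binning_params <- function(min_contig = 2500, max_p = 95, min_s = 60,
                           max_edges = 200, min_cls_size = 200000,
                           min_cv = 1, min_contig_recruit = 1000,
                           schedule_steps = 10, max_lpa_iters = 50,
                           geodesic_mean_3 = FALSE, seed = 1) {
  stopifnot(max_p > 0, max_p <= 100, min_s >= 0, min_s < 100,
            max_edges >= 1, min_contig >= 1, min_cls_size >= 0,
            schedule_steps >= 1)
  structure(list(min_contig = min_contig, max_p = max_p, min_s = min_s,
                 max_edges = max_edges, min_cls_size = min_cls_size,
                 min_cv = min_cv, min_contig_recruit = min_contig_recruit,
                 schedule_steps = schedule_steps,
                 max_lpa_iters = max_lpa_iters,
                 geodesic_mean_3 = geodesic_mean_3, seed = seed),
            class = "binning_params")
}

# Compute raw evidence on a sampled set of pairs; used to fit normalizers
# and to locate percentile cutoffs.
sampled_pair_evidence <- function(tnf_scores, abd, nABD, cor_mat, seed) {
  n <- nrow(tnf_scores)
  pairs <- with_seed(seed, sample_pair_indices(n))
  ii <- cbind(pairs[, 1], pairs[, 2])
  data.frame(tnf_raw = tnf_scores[ii], abd = abd[ii], nABD = nABD[ii],
             cor = if (is.null(cor_mat)) NA_real_ else cor_mat[ii])
}

#' Run the full binning pipeline
#'
#' Reads contigs and depths (paths or in-memory objects), clusters contigs
#' at least `min_contig` bp long on the composite-score graph, drops or
#' dissolves bins under `min_cls_size`, recruits small contigs and freed
#' members by coverage correlation when three or more samples are present,
#' and (optionally) writes per-bin FASTA files plus a membership table.
#'
#' @param fasta Path to the contig FASTA, or a named
#'   [Biostrings::DNAStringSet].
#' @param depth Path to the depth table, or a `coverage_table`.
#' @param out_prefix Output prefix for [write_bins()], or `NULL` to skip
#'   writing.
#' @param params A [binning_params()] list.
#' @param quiet Suppress the summary log.
#' @return A list with `bins` (a `bin_set`), `membership` (data frame of
#'   contig_id/bin_id over all contigs), `labels`, `recruit` decisions (or
#'   `NULL`), `files` written, and a `summary` list (contig counts, admitted
#'   edges per iteration, bin count, binned bp, parameters).
#' @export
run_binning <- function(fasta, depth, out_prefix = NULL,
                        params = binning_params(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  contigs <- if (is.character(fasta)) read_fasta(fasta) else fasta
  coverage <- if (is.character(depth))
    read_depth_table(depth, contig_ids = names(contigs)) else depth
  stopifnot(inherits(coverage, "coverage_table"))
  lengths <- stats::setNames(as.numeric(Biostrings::width(contigs)),
                             names(contigs))
  n_samples <- coverage$n_samples
  if (n_samples < 2L)
    say("NOTE: ", n_samples, " sample(s) only; binning accuracy is much ",
        "lower without coverage information from multiple samples")
  say("contigs: ", length(contigs), " (", format(sum(lengths), big.mark = ","),
      " bp), samples: ", n_samples)

  node_ids <- names(contigs)[lengths >= params$min_contig]
  say("clustering ", length(node_ids), " contigs >= ", params$min_contig, " bp")
  labels <- integer(0)
  bins <- bin_set(list(), lengths)
  admitted <- integer(0)
  if (length(node_ids) >= 2L) {
    tnf <- compute_tnf(contigs[node_ids])
    tnf_scores <- tnf_raw_score(tnf, len_a = lengths[node_ids])
    zerok <- attr(tnf, "n_kmers") == 0
    if (any(zerok)) {
      tnf_scores[zerok, ] <- NA_real_
      tnf_scores[, zerok] <- NA_real_
    }
    am <- abd_matrix(coverage$mean_depth[node_ids, , drop = FALSE],
                     coverage$depth_variance[node_ids, , drop = FALSE],
                     min_cv = params$min_cv)
    cm <- cor_matrix(coverage$mean_depth[node_ids, , drop = FALSE])
    ev <- sampled_pair_evidence(tnf_scores, am$abd, am$nABD, cm, params$seed)
    norms <- fit_normalizers(ev)
    tnf_n <- normalize_scores(norms, tnf_scores, "tnf")
    cor_n <- if (!is.null(cm) && length(norms$cor_sample) >= 2L)
      normalize_scores(norms, cm, "cor") else NULL
    s_matrix <- composite_score(tnf_n, am$abd, am$nABD, cor_n,
                                params$geodesic_mean_3)
    s_sample <- composite_score(
      normalize_scores(norms, ev$tnf_raw, "tnf"), ev$abd, ev$nABD,
      if (is.null(cor_n)) NULL else normalize_scores(norms, ev$cor, "cor"),
      params$geodesic_mean_3)
    seed_g <- build_seed_graph(tnf_scores, params, tnf_sample = ev$tnf_raw)
    say("seed graph: ", n_edges(seed_g), " TNF edges")
    labels <- iterative_partition(s_matrix, seed_g, params,
                                  s_sample = s_sample,
                                  tnf_scores = tnf_scores)
    admitted <- attr(labels, "admitted")
    say("admitted edges per iteration: ", paste(admitted, collapse = " "))
    groups <- split(node_ids, as.integer(labels))
    groups <- groups[order(-vapply(groups, function(m) sum(lengths[m]),
                                   numeric(1)),
                           vapply(groups, min, character(1)))]
    names(groups) <- paste0("bin.", seq_along(groups))
    bins <- bin_set(groups, lengths)
  }

  recruit_dec <- NULL
  if (n_samples >= 3L) {
    dis <- dissolve_small_bins(bins, lengths, params$min_cls_size, n_samples)
    small_ids <- names(contigs)[lengths >= params$min_contig_recruit &
                                  lengths < params$min_contig]
    free <- union(dis$freed, small_ids)
    say("recruiting: ", length(free), " free contigs (",
        length(dis$freed), " from dissolved bins, ",
        length(small_ids), " small) into ", length(dis$bins$bins), " bins")
    rec <- with_seed(params$seed + 1L,
                     recruit_free_contigs(dis$bins, free, coverage, lengths))
    bins <- rec$bins
    recruit_dec <- rec$decisions
  } else {
    keep <- names(bins$bin_bp)[bins$bin_bp >= params$min_cls_size]
    bins <- bin_set(bins$bins[keep], lengths)
  }

  assign_to <- rep("unbinned", length(contigs))
  names(assign_to) <- names(contigs)
  for (b in names(bins$bins)) assign_to[bins$bins[[b]]] <- b
  membership <- data.frame(contig_id = names(contigs),
                           bin_id = unname(assign_to),
                           stringsAsFactors = FALSE)
  files <- character(0)
  if (!is.null(out_prefix))
    files <- write_bins(bins, contigs, out_prefix)
  say("bins: ", length(bins$bins), ", binned bp: ",
      format(sum(bins$bin_bp), big.mark = ","), " / ",
      format(sum(lengths), big.mark = ","))
  list(bins = bins, membership = membership, labels = labels,
       recruit = recruit_dec, files = files,
       summary = list(n_contigs = length(contigs),
                      n_clustered = length(node_ids),
                      n_samples = n_samples, admitted_edges = admitted,
                      n_bins = length(bins$bins),
                      binned_bp = sum(bins$bin_bp),
                      total_bp = sum(lengths), params = unclass(params)))
}
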