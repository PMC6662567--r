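# Sparse capped-degree similarity graph and its partitioning by a
# deterministic, edge-strength-ordered label propagation algorithm (LPA)
# with Fisher's-method membership decisions.

#' Create an empty top-k link store
#'
#' Each node retains at most the `k` highest-scoring links offered to it
#' (ties broken towards the lexicographically smaller neighbor id), keeping
#' memory linear in the node count instead of quadratic.
#'
#' @param nodes Character vector of node ids.
#' @param k Maximum links retained per node.
#' @return A `topk_store`.
#' @export
topk_store <- function(nodes, k) {
  stopifnot(k >= 1L, !anyDuplicated(nodes))
  structure(list(nodes = nodes, k = as.integer(k),
                 links = stats::setNames(vector("list", length(nodes)), nodes)),
            class = "topk_store")
}

#' Offer a scored link to both endpoints of a pair
#'
#' The offer is recorded independently on each endpoint's top-k list; the
#' final retained set per node is therefore the best k offers it ever
#' received, independent of insertion order.  [finalize_graph()] then keeps
#' an edge only when both endpoints retained it, which makes the adjacency
#' symmetric.
#'
#' @param store A `topk_store`.
#' @param u,v Distinct node ids.
#' @param s Score in \[0, 1\].
#' @return The updated store.
#' @export
topk_insert <- function(store, u, v, s) {
  stopifnot(u != v)
  for (end in list(c(u, v), c(v, u))) {
    cur <- store$links[[end[[1L]]]]
    cur <- c(cur, stats::setNames(s, end[[2L]]))
    if (length(cur) > store$k) {
      keep <- order(-cur, names(cur))[seq_len(store$k)]
      cur <- cur[keep]
    }
    store$links[[end[[1L]]]] <- cur
  }
  store
}

#' Finalize a top-k store into a symmetric sparse graph
#'
#' @param store A `topk_store`.
#' @return A `sparse_graph` (see [build_capped_graph()]); an edge survives
#'   iff it sits in the top-k lists of both endpoints, so per-node degree
#'   never exceeds k.
#' @export
finalize_graph <- function(store) {
  nodes <- store$nodes
  idx <- stats::setNames(seq_along(nodes), nodes)
  nbr <- vector("list", length(nodes))
  sc <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    ln <- store$links[[i]]
    if (is.null(ln) || length(ln) == 0L) {
      nbr[[i]] <- integer(0); sc[[i]] <- numeric(0); next
    }
    mutual <- vapply(names(ln), function(v) nodes[[i]] %in% names(store$links[[v]]),
                     logical(1))
    ln <- ln[mutual]
    o <- order(-ln, names(ln))
    nbr[[i]] <- unname(idx[names(ln)[o]])
    sc[[i]] <- unname(ln[o])
  }
  structure(list(nodes = nodes, k = store$k, nbr = nbr, s = sc),
            class = "sparse_graph")
}

# Build a capped mutual-top-k graph from a dense symmetric score matrix.
# Edges with score below `cutoff` or with NA score are not offered.
build_capped_graph <- function(scores, k, cutoff = -Inf) {
  nodes <- rownames(scores)
  n <- nrow(scores)
  stopifnot(!is.null(nodes), n == ncol(scores))
  topk <- vector("list", n)
  for (i in seq_len(n)) {
    s <- scores[i, ]
    s[i] <- NA_real_
    cand <- which(!is.na(s) & s >= cutoff)
    if (length(cand) > k) {
      o <- cand[order(-s[cand], nodes[cand])][seq_len(k)]
    } else {
      o <- cand[order(-s[cand], nodes[cand])]
    }
    topk[[i]] <- o
  }
  nbr <- vector("list", n)
  sc <- vector("list", n)
  for (i in seq_len(n)) {
    js <- topk[[i]]
    mutual <- js[vapply(js, function(j) i %in% topk[[j]], logical(1))]
    nbr[[i]] <- unname(mutual)
    sc[[i]] <- unname(scores[i, mutual])
  }
  structure(list(nodes = nodes, k = as.integer(k), nbr = nbr, s = sc),
            class = "sparse_graph")
}

#' @export
print.sparse_graph <- function(x, ...) {
  cat("sparse_graph:", length(x$nodes), "nodes,",
      sum(lengths(x$nbr)) / 2, "edges, cap", x$k, "\n")
  invisible(x)
}

n_edges <- function(graph) sum(lengths(graph$nbr)) / 2

#' Fisher's-method membership decision
#'
#' Treats `1 - S` of each incident edge as a p-value for the hypothesis that
#' the node does *not* belong with that neighbor, and combines the edges
#' supporting each candidate label with Fisher's statistic
#' `X = -2 * sum(log(1 - S))` (with `1 - S` floored at 1e-12), referred to a
#' chi-square with `2m` degrees of freedom.  The label with the smallest
#' combined p-value wins; exact ties keep the node's current label when it
#' is among them, otherwise the lexicographically smallest label.  Combining
#' evidence this way compares neighborhoods of different sizes fairly.
#'
#' @param neighbor_scores Named list mapping candidate label to the numeric
#'   vector of edge scores supporting it.
#' @param current The node's current label (optional, used for ties).
#' @return The winning label; attribute `p` holds its combined p-value.
#' @export
fisher_membership <- function(neighbor_scores, current = NULL) {
  stopifnot(length(neighbor_scores) >= 1L)
  p <- vapply(neighbor_scores, function(s) {
    x <- -2 * sum(log(pmax(1 - s, 1e-12)))
    pchisq(x, df = 2 * length(s), lower.tail = FALSE)
  }, numeric(1))
  best <- names(p)[p == min(p)]
  win <- if (!is.null(current) && as.character(current) %in% best)
    as.character(current) else min(best)
  structure(win, p = unname(p[[win]]))
}

# Fast integer-label fisher decision used inside LPA sweeps.  The combined
# p-value is compared on the log scale: strong neighborhoods underflow
# double precision (p == 0), and log-scale comparison keeps them ordered
# instead of spuriously tied.
fisher_pick <- function(nbr_labels, scores, current) {
  ll <- -2 * log(pmax(1 - scores, 1e-12))
  x <- rowsum(ll, nbr_labels)
  m <- rowsum(rep(1, length(ll)), nbr_labels)
  logp <- pchisq(x, df = 2 * m, lower.tail = FALSE, log.p = TRUE)
  labs <- as.integer(rownames(x))
  best <- labs[logp == min(logp)]
  if (current %in% best) current else min(best)
}

#' One deterministic label propagation sweep
#'
#' Nodes are visited in decreasing order of their strongest incident edge
#' (ties towards the lexicographically smaller node id); each visited node
#' immediately adopts the label chosen by [fisher_membership()] over its
#' neighbors' current labels.  Identical inputs yield identical outputs.
#'
#' @param graph A `sparse_graph`.
#' @param labels Integer label vector aligned with `graph$nodes`.
#' @return Updated label vector; attribute `n_changed` counts relabelings.
#' @export
lpa_round <- function(graph, labels) {
  stopifnot(length(labels) == length(graph$nodes))
  strongest <- vapply(graph$s, function(s) if (length(s)) s[[1L]] else -Inf,
                      numeric(1))
  visit <- order(-strongest, graph$nodes)
  changed <- 0L
  for (i in visit) {
    js <- graph$nbr[[i]]
    if (length(js) == 0L) next
    new <- fisher_pick(labels[js], graph$s[[i]], labels[[i]])
    if (new != labels[[i]]) {
      labels[[i]] <- new
      changed <- changed + 1L
    }
  }
  attr(labels, "n_changed") <- changed
  labels
}

# Run lpa_round to a fixed point (no label changes in a full sweep).
# Asynchronous propagation can enter a stable 2-cycle on symmetric
# structures; when a sweep reproduces the state of two sweeps ago the
# oscillation is accepted as terminal (the two states are equivalent
# partitions up to the alternating nodes) and the current labels returned.
lpa_fixed_point <- function(graph, labels, max_iters = 50L, quiet = TRUE) {
  prev <- NULL
  for (it in seq_len(max_iters)) {
    older <- prev
    prev <- as.integer(labels)
    labels <- lpa_round(graph, labels)
    if (attr(labels, "n_changed") == 0L ||
        identical(as.integer(labels), older)) {
      attr(labels, "iterations") <- it
      return(labels)
    }
  }
  warning("label propagation did not reach a fixed point in ", max_iters,
          " sweeps; using current labels")
  attr(labels, "iterations") <- max_iters
  labels
}

#' Build the TNF seed graph
#'
#' First-stage graph over contigs using raw TNF scores only: a link is
#' offered when its TNF score clears the strong-score cutoff (the
#' `max_p`-th percentile of the sampled TNF score distribution), and each
#' node is capped at `max_edges` links.
#'
#' @param tnf_scores Dense symmetric raw TNF score matrix (row/col names are
#'   contig ids).
#' @param params A [binning_params()] list.
#' @param tnf_sample Sampled raw TNF scores used to locate the percentile
#'   cutoff (defaults to the full matrix's upper triangle).
#' @return A `sparse_graph`.
#' @export
build_seed_graph <- function(tnf_scores, params, tnf_sample = NULL) {
  if (nrow(tnf_scores) == 0L)
    return(structure(list(nodes = character(0), k = params$max_edges,
                          nbr = list(), s = list()), class = "sparse_graph"))
  if (is.null(tnf_sample)) tnf_sample <- tnf_scores[upper.tri(tnf_scores)]
  tnf_sample <- tnf_sample[!is.na(tnf_sample)]
  cutoff <- unname(quantile(tnf_sample, params$max_p / 100, names = FALSE))
  g <- build_capped_graph(tnf_scores, params$max_edges, cutoff)
  if (n_edges(g) == 0L)
    warning("seed graph has no edges above the TNF cutoff (",
            signif(cutoff, 4), "); all contigs start as singletons")
  g
}

#' Two-stage iterative graph partitioning
#'
#' Stage 1 partitions the TNF seed graph from singleton labels with its raw
#' TNF weights — composition evidence is saturated for same-genome pairs,
#' which consolidates whole-genome clusters robustly.  Stage 2 then lowers
#' the composite-score admission threshold from the top of the sampled S
#' distribution to `min_s / 100` over `schedule_steps` equal steps,
#' rebuilding the capped graph from all pairs with S at or above the
#' threshold and running label propagation to a fixed point warm-started
#' from the previous labels.  Finally, labels are refined by the connected
#' components of the last (most permissive) S graph, augmented with the
#' composition-only seed edges of pairs whose S is undefined: a bin must be
#' connected in the surviving evidence graph, so genomes that composition
#' alone cannot distinguish split apart when no coverage-backed edge above
#' `min_s` joins them.
#'
#' @param s_matrix Dense symmetric composite score matrix (NA where S is
#'   undefined).
#' @param seed_graph The TNF seed graph from [build_seed_graph()].
#' @param params A [binning_params()] list.
#' @param s_sample Sampled S values locating the starting percentile
#'   (defaults to the matrix upper triangle).
#' @param tnf_scores Optional raw TNF score matrix backing stage-1 weights
#'   for pairs with undefined S.
#' @return Integer labels aligned with `rownames(s_matrix)`; attribute
#'   `admitted` records the edge count at each threshold step.
#' @export
iterative_partition <- function(s_matrix, seed_graph, params,
                                s_sample = NULL, tnf_scores = NULL) {
  nodes <- seed_graph$nodes
  labels <- seq_along(nodes)
  if (length(nodes) == 0L) return(labels)

  # stage 1: cluster on the seed graph's saturated TNF weights
  labels <- lpa_fixed_point(seed_graph, labels, params$max_lpa_iters)

  if (is.null(s_sample)) s_sample <- s_matrix[upper.tri(s_matrix)]
  s_sample <- s_sample[!is.na(s_sample)]
  lo <- params$min_s / 100
  if (length(s_sample) == 0L) {
    attr(labels, "admitted") <- integer(0)
    return(labels)
  }
  # strongest edges first: descend from the top of the S distribution
  hi <- max(s_sample)
  thresholds <- if (hi <= lo) lo else seq(hi, lo, length.out = params$schedule_steps)
  admitted <- integer(0)
  g <- NULL
  for (t in thresholds) {
    g <- build_capped_graph(s_matrix, params$max_edges, cutoff = t)
    admitted <- c(admitted, n_edges(g))
    labels <- lpa_fixed_point(g, as.integer(labels), params$max_lpa_iters)
  }
  # component refinement on the final evidence graph (S >= min_s edges plus
  # composition-only seed edges whose S is undefined)
  labels <- split_by_components(as.integer(labels), g, seed_graph, s_matrix)
  attr(labels, "admitted") <- admitted
  labels
}

# A label spanning several connected components of the final evidence graph
# has no evidence holding it together; give each (label, component) group
# its own label.  Seed edges with undefined S still count as connectivity
# (composition-only evidence for zero-coverage contigs).
split_by_components <- function(labels, final_graph, seed_graph, s_matrix) {
  n <- length(labels)
  adj <- final_graph$nbr
  for (i in seq_len(n)) {
    js <- seed_graph$nbr[[i]]
    und <- js[is.na(s_matrix[i, js])]
    if (length(und)) adj[[i]] <- union(adj[[i]], und)
  }
  comp <- integer(n)            # 0 = unvisited
  cid <- 0L
  for (start in seq_len(n)) {
    if (comp[[start]] != 0L) next
    cid <- cid + 1L
    queue <- start
    comp[[start]] <- cid
    while (length(queue)) {
      u <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      for (v in adj[[u]]) if (comp[[v]] == 0L) {
        comp[[v]] <- cid
        queue <- c(queue, v)
      }
    }
  }
  grp <- match(paste(labels, comp), unique(paste(labels, comp)))
  # stable relabeling: each group takes its smallest member index
  as.integer(ave(seq_len(n), grp, FUN = min))
}
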