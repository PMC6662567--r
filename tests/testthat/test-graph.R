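test_that("top-k store keeps the best k offers per node, ties lexicographic", {
  st <- topk_store(c("u", "a", "b", "c"), k = 2)
  st <- topk_insert(st, "u", "a", 0.5)
  st <- topk_insert(st, "u", "b", 0.9)
  st <- topk_insert(st, "u", "c", 0.7)
  expect_equal(sort(unname(st$links[["u"]]), decreasing = TRUE), c(0.9, 0.7))
  expect_setequal(names(st$links[["u"]]), c("b", "c"))
  # equal scores: lexicographically smaller neighbor wins
  st1 <- topk_store(c("u", "a", "b"), k = 1)
  st1 <- topk_insert(st1, "u", "b", 0.8)
  st1 <- topk_insert(st1, "u", "a", 0.8)
  expect_equal(names(st1$links[["u"]]), "a")
})

test_that("capped adjacency equals dense brute-force top-k on random instances", {
  set.seed(17)
  for (rep in 1:10) {
    n <- 50
    ids <- sprintf("n%02d", seq_len(n))
    sc <- matrix(runif(n * n), n, n, dimnames = list(ids, ids))
    sc <- (sc + t(sc)) / 2
    diag(sc) <- NA
    k <- sample(c(1, 3, 5, 10), 1)
    oracle <- dense_topk(sc, k)
    # streaming insertion in random order
    st <- topk_store(ids, k)
    pairs <- which(upper.tri(sc), arr.ind = TRUE)
    pairs <- pairs[sample(nrow(pairs)), , drop = FALSE]
    for (r in seq_len(nrow(pairs)))
      st <- topk_insert(st, ids[pairs[r, 1]], ids[pairs[r, 2]],
                        sc[pairs[r, 1], pairs[r, 2]])
    for (u in ids)
      expect_setequal(names(st$links[[u]]), oracle[[u]])
    # finalized symmetric graph: mutual top-k, degree never exceeds k
    g <- finalize_graph(st)
    expect_true(all(lengths(g$nbr) <= k))
    gm <- build_capped_graph(sc, k)
    expect_identical(g$nbr, gm$nbr)
    for (i in seq_len(n)) for (jx in seq_along(g$nbr[[i]])) {
      j <- g$nbr[[i]][jx]
      expect_true(ids[i] %in% oracle[[ids[j]]] && ids[j] %in% oracle[[ids[i]]])
      expect_true(i %in% g$nbr[[j]])  # symmetric storage
    }
  }
})

test_that("Fisher membership agrees with the closed-form chi-square survival oracle", {
  # spec-style cases
  one <- fisher_membership(list(A = 0))
  expect_equal(as.character(one), "A")
  expect_equal(attr(one, "p"), 1.0)
  a2 <- fisher_membership(list(A = c(0.95, 0.95), B = 0.95))
  expect_equal(as.character(a2), "A")
  x <- -2 * 2 * log(0.05)
  expect_equal(attr(a2, "p"), chisq_sf_even(x, 2), tolerance = 1e-12)
  many <- fisher_membership(list(A = rep(0.5, 10), B = 0.99))
  pa <- chisq_sf_even(-2 * 10 * log(0.5), 10)
  pb <- chisq_sf_even(-2 * log(0.01), 1)
  expect_equal(as.character(many), c("A", "B")[which.min(c(pa, pb))])

  set.seed(41)
  for (i in 1:1000) {
    m <- sample(1:8, 1)
    s <- runif(m, 0, 0.999)
    got <- attr(fisher_membership(list(L = s)), "p")
    oracle <- chisq_sf_even(-2 * sum(log(1 - s)), m)
    expect_equal(got, oracle, tolerance = 1e-9)
  }
})

test_that("Fisher membership tie rules favor the current label, then lexicographic", {
  tie <- fisher_membership(list(A = 0.9, B = 0.9), current = "B")
  expect_equal(as.character(tie), "B")
  tie2 <- fisher_membership(list(C = 0.9, B = 0.9), current = "Z")
  expect_equal(as.character(tie2), "B")
})

test_that("one LPA round merges a connected pair and keeps components apart", {
  ids <- c("a", "b")
  sc <- matrix(c(NA, 0.9, 0.9, NA), 2, dimnames = list(ids, ids))
  g <- build_capped_graph(sc, k = 5)
  lab <- lpa_round(g, 1:2)
  expect_equal(lab[[1]], lab[[2]])

  # two disconnected triangles -> exactly two labels survive
  ids <- letters[1:6]
  sc <- matrix(NA_real_, 6, 6, dimnames = list(ids, ids))
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6)))
    sc[p[1], p[2]] <- sc[p[2], p[1]] <- 0.8
  g <- build_capped_graph(sc, k = 5)
  lab <- metabin:::lpa_fixed_point(g, 1:6)
  expect_equal(length(unique(as.integer(lab))), 2L)
  expect_equal(length(unique(as.integer(lab)[1:3])), 1L)
  expect_equal(length(unique(as.integer(lab)[4:6])), 1L)
})

test_that("LPA is deterministic: identical inputs give identical labelings", {
  set.seed(55)
  n <- 40
  ids <- sprintf("n%02d", 1:n)
  sc <- matrix(runif(n * n, 0.3, 0.99), n, n, dimnames = list(ids, ids))
  sc <- (sc + t(sc)) / 2
  sc[sc < 0.6] <- NA
  g <- build_capped_graph(sc, k = 6)
  l1 <- metabin:::lpa_fixed_point(g, seq_len(n))
  l2 <- metabin:::lpa_fixed_point(g, seq_len(n))
  expect_identical(as.integer(l1), as.integer(l2))
})

test_that("seed graph admits only strong TNF links under the per-node cap", {
  com <- tiny_community(n_genomes = 3, genome_length = 2e5, seed = 19)
  keep <- Biostrings::width(com$contigs) >= 2500
  tnf <- compute_tnf(com$contigs[keep])
  len <- Biostrings::width(com$contigs[keep])
  sc <- tnf_raw_score(tnf, len_a = len)
  g1 <- build_seed_graph(sc, binning_params(max_edges = 1))
  expect_true(all(lengths(g1$nbr) <= 1L))
  g <- build_seed_graph(sc, binning_params())
  cutoff <- quantile(sc[upper.tri(sc)], 0.95)
  for (i in seq_along(g$nbr))
    if (length(g$nbr[[i]])) expect_true(all(g$s[[i]] >= cutoff))
  # empty node set
  g0 <- build_seed_graph(matrix(numeric(0), 0, 0), binning_params())
  expect_length(g0$nodes, 0L)
})

test_that("seed graph separates identical-composition contigs from an outlier", {
  set.seed(23)
  base <- random_dna(6000)
  other <- random_dna(6000, alphabet = c("A", "A", "C", "G", "T", "T"))
  seqs <- Biostrings::DNAStringSet(c(t1 = substr(base, 1, 3000),
                                     t2 = substr(base, 3001, 6000),
                                     out = other))
  tnf <- compute_tnf(seqs)
  sc <- tnf_raw_score(tnf, len_a = Biostrings::width(seqs))
  g <- build_seed_graph(sc, binning_params(max_p = 60))
  i <- function(id) match(id, g$nodes)
  expect_true(i("t2") %in% g$nbr[[i("t1")]])
  expect_false(i("out") %in% g$nbr[[i("t1")]])
  expect_false(i("out") %in% g$nbr[[i("t2")]])
})

test_that("planted cliques partition into exactly their communities", {
  ids <- sprintf("n%02d", 1:9)
  sc <- matrix(NA_real_, 9, 9, dimnames = list(ids, ids))
  for (grp in list(1:3, 4:6, 7:9))
    for (i in grp) for (j in grp) if (i != j) sc[i, j] <- 0.9
  # weak inter-community edges below min_s
  sc[3, 4] <- sc[4, 3] <- 0.3
  sc[6, 7] <- sc[7, 6] <- 0.3
  g_seed <- structure(list(nodes = ids, k = 10L,
                           nbr = rep(list(integer(0)), 9),
                           s = rep(list(numeric(0)), 9)),
                      class = "sparse_graph")
  lab <- iterative_partition(sc, g_seed, binning_params(min_s = 60))
  expect_equal(length(unique(as.integer(lab))), 3L)
  for (grp in list(1:3, 4:6, 7:9))
    expect_equal(length(unique(as.integer(lab)[grp])), 1L)
})

test_that("label count is non-increasing as the admission floor drops", {
  set.seed(61)
  n <- 30
  ids <- sprintf("n%02d", 1:n)
  sc <- matrix(runif(n * n, 0.2, 1), n, n, dimnames = list(ids, ids))
  sc <- (sc + t(sc)) / 2
  g_seed <- build_capped_graph(sc, k = 10, cutoff = 0.99)
  labs_strict <- iterative_partition(sc, g_seed, binning_params(min_s = 99))
  labs_loose <- iterative_partition(sc, g_seed, binning_params(min_s = 1))
  expect_gte(length(unique(as.integer(labs_strict))),
             length(unique(as.integer(labs_loose))))
})

test_that("warm start reaches the same fixed point as a cold start", {
  set.seed(67)
  for (rep in 1:5) {
    n <- 25
    ids <- sprintf("n%02d", 1:n)
    sc <- matrix(runif(n * n, 0.4, 0.99), n, n, dimnames = list(ids, ids))
    sc <- (sc + t(sc)) / 2
    sc[sc < 0.7] <- NA
    g <- build_capped_graph(sc, k = 5)
    cold <- metabin:::lpa_fixed_point(g, seq_len(n))
    warm <- metabin:::lpa_fixed_point(g, as.integer(cold))
    expect_identical(as.integer(warm), as.integer(cold))
  }
})
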