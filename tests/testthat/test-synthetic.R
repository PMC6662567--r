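test_that("community generation is byte-deterministic given the seed", {
  spec <- community_spec(n_genomes = 3, genome_length = 1e5, seed = 77)
  d1 <- file.path(withr::local_tempdir(), "a")
  d2 <- file.path(withr::local_tempdir(), "b")
  c1 <- generate_community(spec, out_dir = d1)
  c2 <- generate_community(spec, out_dir = d2)
  for (f in c("fasta", "depth", "truth"))
    expect_identical(readLines(c1$paths[[f]]), readLines(c2$paths[[f]]))
  expect_identical(as.character(c1$contigs), as.character(c2$contigs))
})

test_that("same-genome contigs are compositionally closer than between-genome", {
  com <- tiny_community(n_genomes = 6, genome_length = 2e5, seed = 83)
  keep <- Biostrings::width(com$contigs) >= 2500
  tnf <- compute_tnf(com$contigs[keep])
  gen <- com$truth$genome_id[keep]
  d2 <- outer(rowSums(tnf^2), rowSums(tnf^2), "+") - 2 * tcrossprod(tnf)
  d <- sqrt(pmax(d2, 0))
  ut <- upper.tri(d)
  same <- outer(gen, gen, "==") & ut
  betw <- (!outer(gen, gen, "==")) & ut
  expect_lt(median(d[same]), median(d[betw]))
  # typical same-genome distance sits below the between-genome median
  expect_lt(mean(d[same] < median(d[betw])), 1.01)
  expect_gt(mean(d[same] < median(d[betw])), 0.9)
})

test_that("depth table shape follows the sample count", {
  com <- tiny_community(n_genomes = 2, genome_length = 1e5, n_samples = 1,
                        seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_depth_table(com$coverage, f)
  header <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_length(header, 5L)  # 3 fixed + one mean/var pair
  expect_equal(header[4:5], c("sample_1", "sample_1-var"))
})

test_that("contig lengths respect the fragmentation law", {
  com <- tiny_community(n_genomes = 5, genome_length = 3e5, seed = 31)
  lens <- Biostrings::width(com$contigs)
  expect_true(all(lens >= 1000 & lens <= 50000))
  expect_gt(sum(lens < 2500), 0)
  expect_equal(sum(com$truth$contig_bp), sum(lens))
  # per-genome bp never exceeds the genome length
  bp <- tapply(com$truth$contig_bp, com$truth$genome_id, sum)
  expect_true(all(bp <= 3e5))
})

test_that("evaluation: perfect binning recovers every genome everywhere", {
  com <- tiny_community(n_genomes = 5, genome_length = 1e5, seed = 37)
  lens <- stats::setNames(as.numeric(com$truth$contig_bp),
                          com$truth$contig_id)
  truth_bins <- split(com$truth$contig_id, com$truth$genome_id)
  rep_ <- evaluate_bins(bin_set(truth_bins, lens), com$truth)
  expect_true(all(rep_$counts == 5L))
  expect_true(all(rep_$per_bin$precision == 1))
  expect_true(all(rep_$per_genome$completeness == 1))
})

test_that("evaluation: merging two equal genomes halves precision", {
  lens <- c(a1 = 1000, a2 = 1000, b1 = 1000, b2 = 1000)
  truth <- data.frame(contig_id = names(lens),
                      genome_id = c("A", "A", "B", "B"),
                      contig_bp = unname(lens))
  merged <- bin_set(list(bin.1 = names(lens)), lens)
  rep_ <- evaluate_bins(merged, truth)
  expect_equal(rep_$per_bin$precision, 0.5)
  expect_true(all(rep_$counts[, "p90"] == 0L))
  expect_true(all(rep_$counts[, "p95"] == 0L))
  # empty bin set: all counts zero
  rep0 <- evaluate_bins(bin_set(list(), lens), truth)
  expect_true(all(rep0$counts == 0L))
})

test_that("random assignment yields the permutation-oracle precision", {
  set.seed(91)
  n_contigs <- 200; n_genomes <- 10
  ids <- sprintf("c%03d", 1:n_contigs)
  lens <- stats::setNames(rep(1000, n_contigs), ids)
  truth <- data.frame(contig_id = ids,
                      genome_id = sprintf("g%02d", rep(1:n_genomes, each = 20)),
                      contig_bp = 1000)
  precisions <- replicate(20, {
    shuffled <- split(sample(ids), rep(1:10, each = 20))
    names(shuffled) <- paste0("bin.", 1:10)
    mean(evaluate_bins(bin_set(shuffled, lens), truth)$per_bin$precision)
  })
  # oracle: a random bin's precision is max multinomial count / bin size,
  # simulated directly without the evaluator
  oracle <- mean(replicate(2000, {
    max(table(sample(rep(1:n_genomes, each = 20), 20))) / 20
  }))
  expect_lt(abs(mean(precisions) - oracle), 0.02)
  expect_gt(mean(precisions), 1 / n_genomes)  # majority share exceeds 1/k
})

test_that("recovered-genome counts are monotone along both threshold axes", {
  com <- tiny_community(n_genomes = 4, genome_length = 2e5, seed = 41)
  res <- run_binning(com$contigs, com$coverage, quiet = TRUE)
  cnt <- evaluate_bins(res$bins, com$truth)$counts
  for (j in seq_len(ncol(cnt))) expect_true(all(diff(cnt[, j]) <= 0))
  for (i in seq_len(nrow(cnt))) expect_true(all(diff(cnt[i, ]) <= 0))
})

test_that("truth table round-trips through disk", {
  d <- withr::local_tempdir()
  com <- generate_community(community_spec(n_genomes = 2,
                                           genome_length = 1e5, seed = 53),
                            out_dir = d)
  back <- read_truth(com$paths$truth)
  expect_equal(back, com$truth)
})
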