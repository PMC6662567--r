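# Brute-force rank/quantile oracle for quantile normalization: the value at
# the interpolated empirical rank of t in the raw sample, read off the
# ABD-sample quantile function.
qn_oracle <- function(t, raw_sample, abd_sample) {
  rs <- sort(raw_sample)
  p <- approx(rs, seq(0, 1, length.out = length(rs)), xout = t, rule = 2)$y
  unname(quantile(sort(abd_sample), probs = p, type = 7))
}

test_that("quantile normalization maps ranks to ABD quantiles", {
  norms <- fit_normalizers(data.frame(tnf_raw = c(0.1, 0.5, 0.9),
                                      abd = c(0.2, 0.6, 0.8),
                                      cor = NA_real_))
  expect_equal(normalize_scores(norms, 0.5, "tnf"), 0.6)
  expect_equal(normalize_scores(norms, c(0.1, 0.9), "tnf"), c(0.2, 0.8))
  # clamping outside the fitted range
  expect_equal(normalize_scores(norms, c(-1, 2), "tnf"), c(0.2, 0.8))

  set.seed(31)
  raw <- runif(200); abd <- rbeta(200, 2, 1)
  norms2 <- fit_normalizers(data.frame(tnf_raw = raw, abd = abd,
                                       cor = NA_real_))
  q <- runif(50)
  expect_equal(normalize_scores(norms2, q, "tnf"), qn_oracle(q, raw, abd),
               tolerance = 1e-9)
})

test_that("normalized raw-sample distribution matches the ABD distribution", {
  set.seed(32)
  raw <- rbeta(500, 5, 2); abd <- rbeta(500, 1, 3)
  norms <- fit_normalizers(data.frame(tnf_raw = raw, abd = abd,
                                      cor = NA_real_))
  mapped <- normalize_scores(norms, raw, "tnf")
  gaps <- abs(sort(mapped) - sort(abd))
  expect_lt(max(gaps), 0.02)  # interpolation error only
})

test_that("normalization mapping is monotone over random queries", {
  set.seed(33)
  norms <- fit_normalizers(data.frame(tnf_raw = runif(300),
                                      abd = rbeta(300, 2, 2),
                                      cor = runif(300, -1, 1)))
  q <- sort(runif(1000, -0.2, 1.2))
  expect_true(!is.unsorted(normalize_scores(norms, q, "tnf")))
  qc <- sort(runif(1000, -1.2, 1.2))
  expect_true(!is.unsorted(normalize_scores(norms, qc, "cor")))
})

test_that("identical raw and ABD samples normalize to the identity", {
  s <- sort(runif(50))
  norms <- fit_normalizers(data.frame(tnf_raw = s, abd = s, cor = NA_real_))
  expect_equal(normalize_scores(norms, s, "tnf"), s, tolerance = 1e-12)
})

test_that("normalizer fitting fails without defined ABD scores", {
  expect_error(fit_normalizers(data.frame(tnf_raw = c(0.1, 0.2),
                                          abd = c(NA_real_, NA_real_),
                                          cor = NA_real_)),
               "coverage")
})

test_that("composite score algebra: weights, fixed points, hand case", {
  # w = nABD / (nABD + 1): recover the implied weight from S on known inputs
  for (n in c(1L, 3L)) {
    s <- composite_score(tnf_n = 0.25, abd = 1, nABD = n)
    expect_equal(log(s) / log(0.25), 1 - n / (n + 1), tolerance = 1e-12)
  }
  expect_equal(composite_score(tnf_n = 0.64, abd = 0.81, nABD = 1), 0.72)
  expect_equal(composite_score(1, 1, 5, cor_n = 1), 1)
  expect_equal(composite_score(1, 1, 5, cor_n = 1, geodesic_mean_3 = TRUE), 1)
  # one sample reduces to the plain geometric mean
  expect_equal(composite_score(0.49, 0.81, 1), sqrt(0.49 * 0.81))
  # undefined ABD stays undefined even though w = 0
  expect_true(is.na(composite_score(0.8, NA_real_, 0)))
  # three-factor form as printed: sqrt of the product
  expect_equal(composite_score(0.64, 0.81, 1, cor_n = 0.5),
               sqrt(0.64^0.5 * 0.81^0.5 * 0.5))
  # cube-root alternative
  expect_equal(composite_score(0.64, 0.81, 1, cor_n = 0.5,
                               geodesic_mean_3 = TRUE),
               (0.64^0.5 * 0.81^0.5 * 0.5)^(1 / 3))
})

test_that("composite score is monotone in each factor and in nABD weight", {
  base <- composite_score(0.5, 0.9, 2)
  expect_gt(composite_score(0.6, 0.9, 2), base)
  expect_gt(composite_score(0.5, 0.95, 2), base)
  expect_gt(composite_score(0.5, 0.9, 2, cor_n = 0.9),
            composite_score(0.5, 0.9, 2, cor_n = 0.5))
  # with ABD > TNF, more effective samples shift weight towards ABD
  s_by_n <- vapply(1:8, function(n) composite_score(0.5, 0.9, n), numeric(1))
  expect_true(all(diff(s_by_n) > 0))
  w <- (1:8) / (2:9)
  expect_true(all(diff(w) > 0) && all(w >= 0 & w < 1))
})

test_that("pair sampling is deterministic and within bounds", {
  p1 <- metabin:::sample_pair_indices
  a <- {set.seed(5); p1(100, pairs_per_item = 5)}
  b <- {set.seed(5); p1(100, pairs_per_item = 5)}
  expect_identical(a, b)
  expect_true(all(a[, "i"] < a[, "j"]))
  # small n enumerates all pairs
  all10 <- {set.seed(1); p1(10)}
  expect_equal(nrow(all10), 45L)
})
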