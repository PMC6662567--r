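# Score normalization and the composite score S.
#
# TNF and COR raw scores live on scales of their own; both are mapped onto
# the ABD score distribution by quantile normalization (rank in the raw
# sample -> same quantile of the ABD sample), so that all three kinds of
# evidence fall within the same range before being combined.

#' Fit quantile normalizers from sampled pair evidence
#'
#' @param pairs Data frame of sampled pair evidence with columns `tnf_raw`,
#'   `abd`, `cor` (the `cor` column may be absent or all `NA` when fewer
#'   than three samples are available).
#' @return A `score_normalizers` object holding the sorted score samples.
#' @export
fit_normalizers <- function(pairs) {
  abd <- sort(pairs$abd[!is.na(pairs$abd)])
  if (length(abd) < 2L)
    stop("fewer than 2 pairs with a defined ABD score; check that contigs ",
         "have coverage above the effective threshold in at least one sample")
  tnf <- sort(pairs$tnf_raw[!is.na(pairs$tnf_raw)])
  cor <- if (!is.null(pairs$cor)) sort(pairs$cor[!is.na(pairs$cor)]) else numeric(0)
  structure(list(abd_sample = abd, tnf_sample = tnf, cor_sample = cor),
            class = "score_normalizers")
}

#' Quantile-normalize raw scores onto the ABD scale
#'
#' Maps raw values through rank-in-source-sample -> ABD-sample quantile,
#' with linear interpolation between order statistics and clamping outside
#' the fitted range.  Tied raw values take the maximum rank of their tied
#' block (ECDF semantics): raw scores often saturate at their ceiling, and
#' a block of maximal raw evidence must map to the top of the ABD scale,
#' not to the block's mid-rank.  Works for vectors and matrices; the
#' mapping is non-decreasing by construction.
#'
#' @param norms A `score_normalizers` object from [fit_normalizers()].
#' @param values Raw TNF or COR score(s); `NA` passes through.
#' @param which Which fitted sample the values are ranked in.
#' @return Normalized score(s), same shape as `values`.
#' @export
normalize_scores <- function(norms, values, which = c("tnf", "cor")) {
  which <- match.arg(which)
  src <- switch(which, tnf = norms$tnf_sample, cor = norms$cor_sample)
  if (length(src) < 2L)
    stop("no fitted sample for '", which, "' normalization")
  dst <- norms$abd_sample
  shape <- dim(values)
  v <- as.numeric(values)
  n <- length(src)
  xu <- unique(src)                      # src is sorted
  if (length(xu) < 2L) {
    p <- as.numeric(v >= xu[[1L]])       # degenerate one-value sample
  } else {
    max_rank <- cumsum(tabulate(match(src, xu), nbins = length(xu)))
    p <- approx(x = xu, y = (max_rank - 1) / (n - 1),
                xout = v, rule = 2)$y
  }
  out <- approx(x = seq(0, 1, length.out = length(dst)), y = dst,
                xout = p, rule = 2)$y
  out[is.na(v)] <- NA_real_
  if (!is.null(shape)) {
    dim(out) <- shape
    dimnames(out) <- dimnames(values)
  } else {
    names(out) <- names(values)
  }
  out
}

#' Composite similarity score S
#'
#' With `w = nABD / (nABD + 1)`, the composite score is
#' `S = TNFn^(1-w) * ABD^w`, where TNFn is the quantile-normalized TNF
#' score.  When a normalized correlation score is available (three or more
#' samples), `S = sqrt(TNFn^(1-w) * ABD^w * CORn)`.  As the number of
#' effective samples grows, weight shifts from composition to coverage.
#'
#' @param tnf_n Normalized TNF score(s).
#' @param abd ABD score(s); `NA` yields `NA` (such pairs carry TNF-only
#'   evidence usable in the seed graph only).
#' @param nABD Effective-sample count(s).
#' @param cor_n Normalized COR score(s) or `NA`/`NULL` where undefined.
#' @param geodesic_mean_3 If `TRUE` use the cube root (true geometric mean
#'   of three factors) instead of the square root in the three-factor form.
#' @return S in \[0, 1\] (`NA` where ABD is undefined); same shape as input.
#' @export
composite_score <- function(tnf_n, abd, nABD, cor_n = NULL,
                            geodesic_mean_3 = FALSE) {
  w <- nABD / (nABD + 1)
  s <- tnf_n^(1 - w) * abd^w
  s[is.na(abd)] <- NA_real_  # NA^0 is 1 in R; undefined ABD must stay undefined
  if (!is.null(cor_n)) {
    root <- if (geodesic_mean_3) 1 / 3 else 1 / 2
    s3 <- (s * pmax(cor_n, 0))^root
    s <- ifelse(is.na(cor_n), s, s3)
  }
  pmin(pmax(s, 0), 1)
}

# Uniformly sample distinct index pairs (i < j) among n items; deterministic
# given the RNG state.  Samples min(pairs_per_item * n, max_pairs) draws
# (with replacement across draws) or enumerates all pairs when few.
sample_pair_indices <- function(n, pairs_per_item = 500, max_pairs = 2e6) {
  total <- n * (n - 1) / 2
  target <- min(pairs_per_item * n, max_pairs)
  if (total <= target) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    return(cbind(i = idx[, 1], j = idx[, 2]))
  }
  i <- sample.int(n, target, replace = TRUE)
  j <- sample.int(n - 1L, target, replace = TRUE)
  j <- ifelse(j >= i, j + 1L, j)
  cbind(i = pmin(i, j), j = pmax(i, j))
}
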