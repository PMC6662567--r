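# Coverage-based pairwise evidence: abundance (ABD) score from the overlap
# of per-sample depth distributions, and the across-sample depth
# correlation (COR) score.

# Elementwise overlap coefficient of N(m1, v1) and N(m2, v2).  Variances are
# floored at `eps` to guard zero-variance rows.  For unequal variances the
# two density intersection points are found analytically and the shared area
# is the sum of the narrow density's tail masses plus the wide density's
# mass between the roots.
normal_overlap <- function(m1, v1, m2, v2, eps = 1e-4) {
  v1 <- pmax(v1, eps)
  v2 <- pmax(v2, eps)
  # order so that component 1 is the narrower density
  swap <- v2 < v1
  if (any(swap)) {
    tm <- m1; tv <- v1
    m1 <- ifelse(swap, m2, m1); v1 <- ifelse(swap, v2, v1)
    m2 <- ifelse(swap, tm, m2); v2 <- ifelse(swap, tv, v2)
  }
  s1 <- sqrt(v1); s2 <- sqrt(v2)
  equal <- abs(v1 - v2) < 1e-12
  out <- 2 * pnorm(-abs(m1 - m2) / (2 * s1))   # equal-variance branch
  if (!all(equal)) {
    a <- 1 / v1 - 1 / v2
    b <- -2 * (m1 / v1 - m2 / v2)
    cc <- m1^2 / v1 - m2^2 / v2 - log(v2 / v1)
    disc <- sqrt(pmax(b^2 - 4 * a * cc, 0))
    x1 <- (-b - disc) / (2 * a)
    x2 <- (-b + disc) / (2 * a)
    lo <- pmin(x1, x2); hi <- pmax(x1, x2)
    # narrow density dominates between the roots, so min(f,g) integrates to
    # narrow tails + wide middle
    ovl <- pnorm((lo - m1) / s1) + (1 - pnorm((hi - m1) / s1)) +
      (pnorm((hi - m2) / s2) - pnorm((lo - m2) / s2))
    out <- ifelse(equal, out, ovl)
  }
  pmin(pmax(out, 0), 1)
}

#' Abundance (ABD) score for one contig pair
#'
#' Each sample where at least one of the two contigs has mean depth above
#' `min_cv` (default > 1) is *effective*.  Per effective sample the score is
#' the overlap coefficient of the two depth distributions modeled as normals
#' N(mean, variance); scores are combined across effective samples by their
#' geometric mean.
#'
#' @param mean_a,var_a,mean_b,var_b Per-sample depth means and variances.
#' @param min_cv Effective-coverage threshold (a sample counts when either
#'   mean exceeds it).
#' @return List with `score` (in \[0, 1\], or `NA` when no sample is
#'   effective) and `nABD` (number of effective samples).
#' @export
abd_score <- function(mean_a, var_a, mean_b, var_b, min_cv = 1) {
  if (length(mean_a) != length(mean_b))
    stop("mismatched sample counts: ", length(mean_a), " vs ", length(mean_b))
  eff <- mean_a > min_cv | mean_b > min_cv
  n <- sum(eff)
  if (n == 0L) return(list(score = NA_real_, nABD = 0L))
  ovl <- normal_overlap(mean_a[eff], var_a[eff], mean_b[eff], var_b[eff])
  list(score = exp(mean(log(pmax(ovl, 1e-300)))), nABD = as.integer(n))
}

# All-pairs ABD: returns list(abd = n x n score matrix with NA where no
# effective sample, nABD = n x n effective-sample counts).
abd_matrix <- function(mean_depth, depth_variance, min_cv = 1) {
  n <- nrow(mean_depth)
  s <- ncol(mean_depth)
  logsum <- matrix(0, n, n)
  nabd <- matrix(0L, n, n)
  one <- rep(1, n)
  for (j in seq_len(s)) {
    m <- mean_depth[, j]; v <- depth_variance[, j]
    eff <- outer(m > min_cv, m > min_cv, "|")
    ovl <- normal_overlap(outer(m, one), outer(v, one),
                          outer(one, m), outer(one, v))
    logsum <- logsum + ifelse(eff, log(pmax(ovl, 1e-300)), 0)
    nabd <- nabd + eff
  }
  abd <- exp(logsum / ifelse(nabd > 0L, nabd, 1L))
  abd[nabd == 0L] <- NA_real_
  diag(abd) <- ifelse(diag(nabd) > 0L, 1, NA_real_)
  dimnames(abd) <- dimnames(nabd) <- list(rownames(mean_depth), rownames(mean_depth))
  list(abd = abd, nABD = nabd)
}

#' Coverage correlation (COR) score
#'
#' Pearson correlation of two contigs' mean-depth profiles across samples.
#' Undefined (`NA`) with fewer than three samples or when either profile has
#' zero variance.
#'
#' @param mean_a,mean_b Per-sample mean depths.
#' @return Correlation in \[-1, 1\], or `NA` when undefined.
#' @export
cor_score <- function(mean_a, mean_b) {
  if (length(mean_a) != length(mean_b))
    stop("mismatched sample counts: ", length(mean_a), " vs ", length(mean_b))
  if (length(mean_a) < 3L) return(NA_real_)
  if (stats::sd(mean_a) == 0 || stats::sd(mean_b) == 0) return(NA_real_)
  cor(mean_a, mean_b)
}

# All-pairs COR (NA where undefined); NULL with < 3 samples.
cor_matrix <- function(mean_depth) {
  if (ncol(mean_depth) < 3L) return(NULL)
  suppressWarnings(cor(t(mean_depth)))
}
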