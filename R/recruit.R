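# Post-clustering recruiting: dissolve undersized bins and re-assign their
# members, together with small contigs (1-2.5 kb by default), to bins whose
# members they track in coverage across samples.  Requires >= 3 samples;
# with fewer the whole module is a no-op.

#' Dissolve bins below the minimum bin size
#'
#' @param bins A `bin_set`.
#' @param lengths Named contig lengths (bp).
#' @param min_cls_size Minimum bin size in bp (default 200 kb).
#' @param n_samples Number of samples; with fewer than 3 the operation is
#'   skipped and nothing is freed.
#' @return List with `bins` (surviving `bin_set`) and `freed` (character
#'   vector of contig ids from dissolved bins).
#' @export
dissolve_small_bins <- function(bins, lengths, min_cls_size = 200000,
                                n_samples = 3) {
  if (n_samples < 3L)
    return(list(bins = bins, freed = character(0)))
  small <- names(bins$bin_bp)[bins$bin_bp < min_cls_size]
  freed <- unlist(bins$bins[small], use.names = FALSE)
  keep <- setdiff(names(bins$bins), small)
  list(bins = bin_set(bins$bins[keep], lengths),
       freed = if (is.null(freed)) character(0) else freed)
}

# Mean pairwise Pearson correlation of member depth profiles within a bin,
# over a capped random subsample of members for large bins.  NA when the
# bin has fewer than 2 members or no defined correlations.
within_bin_correlation <- function(member_ids, mean_depth, cap = 50L) {
  if (length(member_ids) < 2L) return(NA_real_)
  if (length(member_ids) > cap) member_ids <- sort(sample(member_ids, cap))
  cc <- suppressWarnings(cor(t(mean_depth[member_ids, , drop = FALSE])))
  vals <- cc[upper.tri(cc)]
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

#' Recruit free contigs into bins by coverage correlation
#'
#' A free contig joins the bin maximizing its mean Pearson correlation to
#' the bin's member depth profiles, provided that correlation exceeds the
#' bin's own mean pairwise member correlation.  All decisions are taken
#' against the pre-recruitment bin state, so the outcome is independent of
#' the order of the free list.  Bins with a single member never recruit.
#'
#' @param bins A `bin_set` (post-dissolution state).
#' @param free Character vector of free contig ids (small contigs plus
#'   members of dissolved bins).
#' @param coverage A `coverage_table` covering members and free contigs.
#' @param lengths Named contig lengths (bp).
#' @param within_cap Member subsample cap for the within-bin correlation.
#' @return List with `bins` (updated `bin_set`) and `decisions` (data frame
#'   with one row per free contig: `contig_id`, `target_bin`,
#'   `free_to_bin_corr`, `within_bin_corr`).
#' @export
recruit_free_contigs <- function(bins, free, coverage, lengths,
                                 within_cap = 50L) {
  if (coverage$n_samples < 3L || length(free) == 0L ||
      length(bins$bins) == 0L) {
    dec <- data.frame(contig_id = character(0), target_bin = character(0),
                      free_to_bin_corr = numeric(0),
                      within_bin_corr = numeric(0), stringsAsFactors = FALSE)
    return(list(bins = bins, decisions = dec))
  }
  md <- coverage$mean_depth
  free <- sort(intersect(free, rownames(md)))
  bin_ids <- sort(names(bins$bins))
  within <- vapply(bin_ids, function(b)
    within_bin_correlation(bins$bins[[b]], md, within_cap), numeric(1))
  eligible <- bin_ids[!is.na(within)]
  skipped <- setdiff(bin_ids, eligible)
  if (length(skipped))
    message(length(skipped), " bin(s) with undefined within-bin correlation ",
            "(single member) never recruit")
  # correlation of every free contig profile to every member profile
  member_ids <- unlist(bins$bins[eligible], use.names = FALSE)
  decisions <- data.frame(contig_id = free, target_bin = NA_character_,
                          free_to_bin_corr = NA_real_,
                          within_bin_corr = NA_real_, stringsAsFactors = FALSE)
  if (length(eligible) && length(free)) {
    cc <- suppressWarnings(cor(t(md[free, , drop = FALSE]),
                               t(md[member_ids, , drop = FALSE])))
    grp <- rep(eligible, lengths(bins$bins[eligible]))
    for (fi in seq_along(free)) {
      r <- cc[fi, ]
      mean_r <- tapply(r, grp, mean, na.rm = TRUE)
      mean_r[is.nan(mean_r)] <- NA_real_
      if (all(is.na(mean_r))) next
      # the candidate is the argmax over all bins; it recruits the contig
      # only if the contig out-correlates that bin's own members
      ok <- names(mean_r)[!is.na(mean_r)]
      best <- ok[order(-mean_r[ok], ok)][[1L]]
      if (mean_r[[best]] <= within[[best]]) next
      decisions$target_bin[fi] <- best
      decisions$free_to_bin_corr[fi] <- mean_r[[best]]
      decisions$within_bin_corr[fi] <- within[[best]]
    }
  }
  new_bins <- bins$bins
  got <- decisions[!is.na(decisions$target_bin), , drop = FALSE]
  for (b in unique(got$target_bin))
    new_bins[[b]] <- c(new_bins[[b]], got$contig_id[got$target_bin == b])
  list(bins = bin_set(new_bins, lengths), decisions = decisions)
}
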