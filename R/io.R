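#' Read assembled contigs from a FASTA file
#'
#' Sequences are uppercased and any character outside A/C/G/T is mapped to N,
#' so that ambiguity handling is localized to tetramer counting (windows
#' containing N are skipped there).
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by contig id, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate contig id in FASTA: ", dup[[1L]])
  names(seqs) <- ids
  raw <- toupper(as.character(seqs))
  raw <- gsub("[^ACGT]", "N", raw)
  out <- Biostrings::DNAStringSet(raw)
  names(out) <- ids
  out
}

#' Read a per-contig depth table
#'
#' Accepts the depth-summarizer dialect: a TSV with header columns
#' \code{contigName}, \code{contigLen}, \code{totalAvgDepth} followed by one
#' \code{<sample>} / \code{<sample>-var} column pair per sample.  A mean-only
#' variant (no \code{-var} columns) is also accepted; there the variance
#' defaults to the mean (Poisson-like), and a message says so.
#'
#' @param path Path to the TSV.
#' @param contig_ids Optional character vector of contig ids (e.g. from the
#'   FASTA).  Rows are aligned to this order; contigs missing from the table
#'   get zero coverage in all samples with a warning, and table rows absent
#'   from `contig_ids` are reported in the `unmatched` field.
#' @return A `coverage_table`: list with `contig_ids`, `n_samples`,
#'   `sample_names`, `mean_depth` and `depth_variance` (contigs x samples
#'   matrices), `total_avg_depth`, `lengths`, and `unmatched`.
#' @export
read_depth_table <- function(path, contig_ids = NULL) {
  if (!file.exists(path)) stop("depth table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("depth table needs at least 3 columns, got ", ncol(tab))
  extra <- names(tab)[-(1:3)]
  n_extra <- length(extra)
  is_var <- grepl("-var$", extra)
  if (any(is_var)) {
    if (n_extra %% 2L != 0L)
      stop("odd number of per-sample columns (", n_extra, ") in ", path)
    if (!all(is_var == rep(c(FALSE, TRUE), n_extra / 2L)))
      stop("per-sample columns must alternate <sample>, <sample>-var in ", path)
    n_samples <- n_extra %/% 2L
    mean_idx <- 3L + seq(1L, n_extra, by = 2L)
    var_idx <- mean_idx + 1L
    sample_names <- extra[seq(1L, n_extra, by = 2L)]
    mean_depth <- as.matrix(tab[, mean_idx, drop = FALSE])
    depth_variance <- as.matrix(tab[, var_idx, drop = FALSE])
  } else {
    n_samples <- n_extra
    sample_names <- extra
    mean_depth <- as.matrix(tab[, -(1:3), drop = FALSE])
    depth_variance <- mean_depth
    if (n_samples > 0L)
      message("depth table has no -var columns; assuming variance = mean ",
              "(Poisson-like) for ", n_samples, " sample(s)")
  }
  if (any(depth_variance < 0)) stop("negative depth variance in ", path)
  if (any(mean_depth < 0)) stop("negative mean depth in ", path)
  ids <- as.character(tab[[1L]])
  rownames(mean_depth) <- rownames(depth_variance) <- ids
  colnames(mean_depth) <- colnames(depth_variance) <- sample_names
  lengths <- as.numeric(tab[[2L]])
  names(lengths) <- ids
  total <- as.numeric(tab[[3L]])
  names(total) <- ids

  unmatched <- character(0)
  if (!is.null(contig_ids)) {
    unmatched <- setdiff(ids, contig_ids)
    if (length(unmatched))
      warning(length(unmatched), " depth-table contig(s) absent from the assembly, ",
              "e.g. ", unmatched[[1L]])
    missing <- setdiff(contig_ids, ids)
    if (length(missing))
      warning(length(missing), " contig(s) missing from the depth table get zero ",
              "coverage, e.g. ", missing[[1L]])
    md <- matrix(0, length(contig_ids), max(n_samples, 0L),
                 dimnames = list(contig_ids, sample_names))
    dv <- md
    keep <- intersect(contig_ids, ids)
    md[keep, ] <- mean_depth[keep, , drop = FALSE]
    dv[keep, ] <- depth_variance[keep, , drop = FALSE]
    mean_depth <- md
    depth_variance <- dv
    lengths <- lengths[match(contig_ids, ids)]
    total <- total[match(contig_ids, ids)]
    names(lengths) <- names(total) <- contig_ids
    ids <- contig_ids
  }
  structure(list(contig_ids = ids, n_samples = n_samples,
                 sample_names = sample_names, mean_depth = mean_depth,
                 depth_variance = depth_variance, total_avg_depth = total,
                 lengths = lengths, unmatched = unmatched),
            class = "coverage_table")
}

#' Construct a bin set
#'
#' @param bins Named list mapping bin id to a character vector of contig ids.
#' @param lengths Named numeric vector of contig lengths (bp).
#' @return A `bin_set`: list with `bins` and `bin_bp`.
#' @export
bin_set <- function(bins, lengths) {
  bins <- bins[lengths(bins) > 0L]
  members <- unlist(bins, use.names = FALSE)
  dup <- members[duplicated(members)]
  if (length(dup)) stop("contig assigned to two bins: ", dup[[1L]])
  bad <- setdiff(members, names(lengths))
  if (length(bad)) stop("bin member without a known length: ", bad[[1L]])
  bin_bp <- vapply(bins, function(m) sum(lengths[m]), numeric(1))
  structure(list(bins = bins, bin_bp = bin_bp), class = "bin_set")
}

#' @export
print.bin_set <- function(x, ...) {
  cat("bin_set:", length(x$bins), "bins,",
      sum(lengths(x$bins)), "contigs,",
      format(sum(x$bin_bp), big.mark = ","), "bp\n")
  invisible(x)
}

#' Write bins to per-bin FASTA files and a membership table
#'
#' Writes one FASTA per bin, `<prefix>.<bin-id>.fa`, plus a two-column TSV
#' `<prefix>.membership.tsv` (header `contig_id`, `bin_id`) covering every
#' contig; contigs in no bin get bin id `unbinned`.
#'
#' @param bins A `bin_set`.
#' @param contigs [Biostrings::DNAStringSet] of all contigs.
#' @param out_prefix Output path prefix.
#' @return Invisibly, the character vector of files written.
#' @export
write_bins <- function(bins, contigs, out_prefix) {
  stopifnot(inherits(bins, "bin_set"))
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  members <- unlist(bins$bins, use.names = FALSE)
  bad <- setdiff(members, names(contigs))
  if (length(bad)) stop("bin member not among contigs: ", bad[[1L]])
  files <- character(0)
  for (b in names(bins$bins)) {
    f <- paste0(out_prefix, ".", b, ".fa")
    Biostrings::writeXStringSet(contigs[bins$bins[[b]]], f, width = 80L)
    files <- c(files, f)
  }
  assign_to <- rep("unbinned", length(contigs))
  names(assign_to) <- names(contigs)
  for (b in names(bins$bins)) assign_to[bins$bins[[b]]] <- b
  mem <- data.frame(contig_id = names(contigs), bin_id = unname(assign_to),
                    stringsAsFactors = FALSE)
  mf <- paste0(out_prefix, ".membership.tsv")
  utils::write.table(mem, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(files, mf))
}

#' Read a membership TSV back into a bin set
#'
#' @param path Membership TSV written by [write_bins()].
#' @param lengths Named numeric vector of contig lengths.
#' @return A `bin_set` (unbinned contigs excluded).
#' @export
read_membership <- function(path, lengths) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab <- tab[tab$bin_id != "unbinned", , drop = FALSE]
  bin_set(split(tab$contig_id, tab$bin_id), lengths)
}
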