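#' Downsample a fragment set without replacement
#'
#' Selects exactly `n` fragments uniformly at random without replacement,
#' deterministically for a given seed. Used to equalize library sizes before
#' peak-level QC (the study design downsamples all libraries to a common
#' fragment count).
#'
#' @param frags Fragment `GRanges`.
#' @param n Number of fragments to keep (`n <= length(frags)`).
#' @param seed Integer seed.
#' @return Fragment `GRanges` of length `n`.
#' @export
downsample_fragments <- function(frags, n, seed = 1) {
  if (n > length(frags)) stop("n exceeds library size")
  if (n == length(frags)) return(frags)
  set.seed(seed)
  frags[sort(sample.int(length(frags), n))]
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values factors for a replicate count matrix, computed
#' with edgeR: the reference sample is the one whose upper quartile is
#' closest to the mean upper quartile; M-values are trimmed by
#' `trim_M`/`trim_A` and weighted by inverse asymptotic binomial variance;
#' factors are rescaled to geometric mean 1.
#'
#' @param cm A [count_matrix()].
#' @param trim_M Trim fraction on log-ratios (M).
#' @param trim_A Trim fraction on absolute intensities (A).
#' @param lib_sizes Optional named library sizes; defaults to column sums.
#' @return Named numeric vector of factors, geometric mean 1.
#' @export
tmm_factors <- function(cm, trim_M = 0.30, trim_A = 0.05, lib_sizes = NULL) {
  counts <- cm$counts
  if (ncol(counts) < 2) stop("TMM needs >= 2 samples")
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  f <- edgeR::calcNormFactors(counts, lib.size = lib_sizes[colnames(counts)],
                              method = "TMM",
                              logratioTrim = trim_M, sumTrim = trim_A)
  setNames(f, colnames(counts))
}

#' TMM-minus-control accessibility scores
#'
#' Per-sample score for each feature:
#' `max(0, count / (libsize * factor) - control / control_libsize) * 1e6`,
#' i.e. effective-library-size CPM with genomic-control CPM subtracted and
#' floored at zero. Class-level scores are arithmetic means over replicates.
#' Without a control the subtraction is skipped and the result tagged `CPM`.
#'
#' @param cm A [count_matrix()] of fragment counts.
#' @param factors TMM factors from [tmm_factors()] (defaults to all 1).
#' @param control Optional numeric vector of genomic-control counts per
#'   feature (same order as `rownames(cm$counts)`).
#' @param control_lib_size Control library size (defaults to `sum(control)`).
#' @param lib_sizes Optional named library sizes; defaults to column sums.
#' @return A `score_matrix`: list with `scores` (feature x sample),
#'   `class_scores` (feature x class) and `normalization` tag.
#' @export
tmm_score <- function(cm, factors = NULL, control = NULL,
                      control_lib_size = NULL, lib_sizes = NULL) {
  counts <- cm$counts
  if (is.null(factors)) factors <- setNames(rep(1, ncol(counts)), colnames(counts))
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  eff <- lib_sizes[colnames(counts)] * factors[colnames(counts)]
  cpm <- sweep(counts, 2, eff, "/") * 1e6
  tag <- "CPM"
  if (!is.null(control)) {
    if (is.null(control_lib_size)) control_lib_size <- sum(control)
    ctrl_cpm <- if (control_lib_size > 0) {
      control / control_lib_size * 1e6
    } else rep(0, nrow(cpm))
    cpm <- pmax(cpm - ctrl_cpm, 0)
    tag <- "TMM_minus_control"
  }
  cls <- cm$sample_class
  class_levels <- unique(unname(cls))
  class_scores <- vapply(class_levels, function(k) {
    rowMeans(cpm[, names(cls)[cls == k], drop = FALSE])
  }, numeric(nrow(cpm)))
  structure(list(scores = cpm, class_scores = class_scores,
                 normalization = tag),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix (%s): %d features, %d samples, %d classes\n",
              x$normalization, nrow(x$scores), ncol(x$scores),
              ncol(x$class_scores)))
  invisible(x)
}

#' Fraction of fragments in peaks (FRiP)
#'
#' Signal-to-noise QC statistic: the fraction of fragments overlapping at
#' least one peak by at least one base.
#'
#' @param frags Fragment `GRanges`.
#' @param peaks Peak `GRanges`.
#' @return Fraction in `[0, 1]`.
#' @export
frip <- function(frags, peaks) {
  if (!length(frags)) stop("empty fragment set")
  hits <- GenomicRanges::countOverlaps(frags, peaks, minoverlap = 1L,
                                       ignore.strand = TRUE)
  mean(hits > 0)
}

#' Insert-size histogram of a fragment set
#'
#' Exact counts of fragment lengths. ATAC-seq libraries show sub-nucleosomal
#' (< ~100 bp) and mono-/di-/tri-nucleosomal modes; [histogram_modes()]
#' reports the local maxima.
#'
#' @param frags Fragment `GRanges`.
#' @return Named integer vector (length in bp -> count).
#' @export
insert_size_histogram <- function(frags) {
  if (!length(frags)) return(integer(0))
  tab <- table(GenomicRanges::width(frags))
  setNames(as.integer(tab), names(tab))
}

#' Local maxima of an insert-size histogram
#'
#' Smooths the counts with a running mean and returns lengths at local
#' maxima separated by at least `min_sep` bp.
#'
#' @param hist Named counts from [insert_size_histogram()].
#' @param smooth Half-width (bp) of the running-mean window.
#' @param min_sep Minimum separation between reported modes.
#' @param min_frac Height floor: maxima below this fraction of the largest
#'   smoothed count are ignored.
#' @param min_prominence A maximum must exceed the valley separating it
#'   from the nearest taller retained peak by this factor.
#' @return Integer vector of mode positions (bp).
#' @export
histogram_modes <- function(hist, smooth = 15, min_sep = 50,
                            min_frac = 0.005, min_prominence = 1.2) {
  if (!length(hist)) return(integer(0))
  lens <- as.integer(names(hist))
  full <- numeric(max(lens))
  full[lens] <- as.numeric(hist)
  k <- 2 * smooth + 1
  sm <- stats::filter(full, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- 0
  is_max <- which(diff(sign(diff(sm))) == -2) + 1L
  is_max <- is_max[sm[is_max] > min_frac * max(sm)]
  if (!length(is_max)) return(integer(0))
  is_max <- is_max[order(-sm[is_max])]
  keep <- integer(0)
  for (m in is_max) {
    if (!length(keep)) {
      keep <- m
      next
    }
    if (any(abs(keep - m) < min_sep)) next
    nearest <- keep[which.min(abs(keep - m))]
    valley <- min(sm[min(m, nearest):max(m, nearest)])
    if (sm[m] >= min_prominence * max(valley, .Machine$double.eps)) {
      keep <- c(keep, m)
    }
  }
  sort(keep)
}
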