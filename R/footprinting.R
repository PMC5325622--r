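#' Aggregate Tn5 insertion profile around motif occurrences
#'
#' For each motif hit, counts Tn5 insertion events (fragment cut sites) at
#' every base offset from the motif center, oriented by the hit strand so
#' that motif logos align, sums over hits and normalizes to insertions per
#' million library fragments. By default both fragment ends count as
#' insertion events (tagmentation cuts at both ends of a fragment); the
#' `ends = "five_prime"` mode counts only the 5' end of each fragment.
#'
#' @param frags Fragment `GRanges` from one class/replicate.
#' @param hits Motif hits ([scan_sequences()]), typically one motif family.
#' @param peaks Peak `GRanges` (to place hit offsets on the genome).
#' @param window Half-window width in bp (default 250).
#' @param ends `"both"` or `"five_prime"`.
#' @param library_size Library fragment count (defaults to `length(frags)`).
#' @return Object of class `footprint_profile`: `offsets` (-window..window),
#'   `values` (insertions per million), `motif_span`, `n_hits`,
#'   `library_size`.
#' @export
insertion_profile <- function(frags, hits, peaks, window = 250,
                              ends = c("both", "five_prime"),
                              library_size = NULL) {
  ends <- match.arg(ends)
  if (!nrow(hits)) stop("no motif hits supplied")
  if (is.null(library_size)) library_size <- length(frags)
  peak_chr <- as.character(GenomicRanges::seqnames(peaks))
  peak_start0 <- GenomicRanges::start(peaks) - 1L
  idx <- match(hits$peak_id, names(peaks))
  if (anyNA(idx)) stop("hits reference peaks absent from the peak set")
  # 0-based genomic motif center
  center0 <- peak_start0[idx] + hits$offset + hits$width %/% 2L
  flip <- hits$strand == "-"

  # insertion positions (0-based): fragment start and/or end-1
  start0 <- GenomicRanges::start(frags) - 1L
  end0m1 <- GenomicRanges::end(frags) - 1L
  frag_strand <- as.character(GenomicRanges::strand(frags))
  if (ends == "both") {
    ins_pos <- c(start0, end0m1)
    ins_chr <- rep(as.character(GenomicRanges::seqnames(frags)), 2)
  } else {
    five <- ifelse(frag_strand == "-", end0m1, start0)
    ins_pos <- five
    ins_chr <- as.character(GenomicRanges::seqnames(frags))
  }
  ins <- GenomicRanges::GRanges(ins_chr, IRanges::IRanges(ins_pos + 1L,
                                                          ins_pos + 1L))
  win <- GenomicRanges::GRanges(
    peak_chr[idx],
    IRanges::IRanges(pmax(center0 - window, 0L) + 1L, center0 + window + 1L))
  ov <- GenomicRanges::findOverlaps(ins, win, ignore.strand = TRUE)
  rel <- ins_pos[S4Vectors::queryHits(ov)] -
    center0[S4Vectors::subjectHits(ov)]
  rel <- ifelse(flip[S4Vectors::subjectHits(ov)], -rel, rel)
  rel <- rel[abs(rel) <= window]
  offsets <- seq(-window, window)
  counts <- tabulate(rel + window + 1L, nbins = 2L * window + 1L)
  structure(list(
    offsets = offsets,
    values = counts / (library_size / 1e6),
    motif_span = max(hits$width),
    n_hits = nrow(hits),
    library_size = library_size), class = "footprint_profile")
}

#' @export
print.footprint_profile <- function(x, ...) {
  cat(sprintf("footprint_profile: %d hits, window +/-%d bp, depth ratio %.3f\n",
              x$n_hits, max(x$offsets), footprint_depth(x)))
  invisible(x)
}

#' Footprint depth ratio of an insertion profile
#'
#' Mean insertion rate over the central motif span divided by the mean rate
#' over the flanks beyond +/-`flank_from` bp. A flat profile gives 1;
#' protection at a bound motif gives values below 1.
#'
#' @param profile A `footprint_profile`.
#' @param flank_from Offset (bp) beyond which positions count as flank.
#' @return Depth ratio, or `NA` when the flank signal is zero.
#' @export
footprint_depth <- function(profile, flank_from = 50) {
  half_span <- profile$motif_span %/% 2
  central <- abs(profile$offsets) <= half_span
  flank <- abs(profile$offsets) > flank_from
  flank_mean <- mean(profile$values[flank])
  if (!is.finite(flank_mean) || flank_mean == 0) return(NA_real_)
  mean(profile$values[central]) / flank_mean
}
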