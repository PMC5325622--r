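#' Bin a signed peak-TSS distance into the six distance categories
#'
#' Distances are signed relative to the gene strand (negative = upstream of
#' the TSS). The six categories are: distal upstream (-3, beyond 2 kb),
#' upstream (-2, 200 bp to 2 kb), proximal upstream (-1, within 200 bp),
#' and the mirrored downstream bins +1, +2, +3. Boundary conventions:
#' exactly 200 or 2000 bp falls in the +/-2 bin; distance 0 is +1.
#'
#' @param d Signed distances in bp (vectorized).
#' @return Integer bins in `{-3,-2,-1,1,2,3}`.
#' @export
bin_distance <- function(d) {
  ifelse(d < -2000, -3L,
  ifelse(d <= -200, -2L,
  ifelse(d < 0, -1L,
  ifelse(d < 200, 1L,
  ifelse(d <= 2000, 2L, 3L)))))
}

#' Assign each peak to its nearest TSS
#'
#' The peak anchor is its interval midpoint (floored for odd widths); the
#' assigned gene is the owner of the TSS minimizing `|midpoint - pos|` over
#' all isoform TSSs. Equidistant ties prefer the downstream side (relative
#' to the gene strand), then the lexicographically smaller gene id. Peaks on
#' chromosomes without any TSS are dropped with a message.
#'
#' @param peaks Peak `GRanges`.
#' @param tss TSS data.frame (see [read_tss_table()]).
#' @return Data.frame with columns `peak_id`, `gene_id`, `signed_distance`,
#'   `bin`, `proximal` (`|distance| < 2000`).
#' @export
assign_nearest_tss <- function(peaks, tss) {
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  start0 <- GenomicRanges::start(peaks) - 1L
  end0 <- GenomicRanges::end(peaks)
  mid <- (start0 + end0) %/% 2L
  ids <- names(peaks)

  res <- vector("list", length(unique(chrom)))
  no_tss <- setdiff(unique(chrom), unique(tss$chrom))
  if (length(no_tss)) {
    message("dropping peaks on chromosomes without TSS: ",
            paste(no_tss, collapse = ", "))
  }
  out <- data.frame(peak_id = character(0), gene_id = character(0),
                    signed_distance = integer(0), bin = integer(0),
                    proximal = logical(0))
  for (chr in intersect(unique(chrom), unique(tss$chrom))) {
    t <- tss[tss$chrom == chr, , drop = FALSE]
    t <- t[order(t$pos, t$gene_id), , drop = FALSE]
    pos <- t$pos
    sel <- which(chrom == chr)
    m <- mid[sel]
    # nearest position via sorted lookup on either side
    idx <- findInterval(m, pos)
    left <- pmax(idx, 1L)
    right <- pmin(idx + 1L, length(pos))
    dl <- abs(m - pos[left])
    dr <- abs(m - pos[right])
    dl[idx < 1L] <- .Machine$integer.max
    dmin <- pmin(dl, dr)
    assigned <- integer(length(sel))
    for (i in seq_along(sel)) {
      # all TSS records at the minimal distance (handles duplicates and
      # equidistant up/downstream candidates)
      cand_pos <- unique(c(m[i] - dmin[i], m[i] + dmin[i]))
      cand <- which(pos %in% cand_pos)
      if (length(cand) > 1L) {
        d_signed <- ifelse(t$strand[cand] == "+",
                           m[i] - pos[cand], pos[cand] - m[i])
        down <- d_signed >= 0
        if (any(down)) cand <- cand[down]
        cand <- cand[order(t$gene_id[cand])]
      }
      assigned[i] <- cand[1]
    }
    d_signed <- ifelse(t$strand[assigned] == "+",
                       m - pos[assigned], pos[assigned] - m)
    out <- rbind(out, data.frame(
      peak_id = ids[sel],
      gene_id = t$gene_id[assigned],
      signed_distance = as.integer(d_signed),
      bin = bin_distance(d_signed),
      proximal = abs(d_signed) < 2000))
  }
  rownames(out) <- NULL
  out[match(ids[ids %in% out$peak_id], out$peak_id), , drop = FALSE]
}

#' Fraction of query peaks overlapping a reference peak set
#'
#' Overall fraction of query peaks overlapping at least one reference peak
#' by at least one base; optionally stratified by distance bin.
#'
#' @param query Query peak `GRanges`.
#' @param reference Reference peak `GRanges`.
#' @param by_bin Optional named vector of distance bins (names = query peak
#'   ids) for stratified fractions.
#' @return If `by_bin` is `NULL`, a single fraction; otherwise a list with
#'   `overall` and `per_bin`.
#' @export
overlap_fraction <- function(query, reference, by_bin = NULL) {
  if (!length(query)) stop("empty query peak set")
  hit <- GenomicRanges::countOverlaps(query, reference, minoverlap = 1L,
                                      ignore.strand = TRUE) > 0
  overall <- mean(hit)
  if (is.null(by_bin)) return(overall)
  bins <- by_bin[names(query)]
  per_bin <- tapply(hit, bins, mean)
  list(overall = overall, per_bin = per_bin)
}

#' Presence/absence pattern counts of merged peaks across classes
#'
#' A merged peak is called present in a class when it overlaps peaks called
#' in all replicates of that class; each merged peak then contributes to one
#' presence/absence pattern (UpSet-style).
#'
#' @param per_class_peaksets Named list (class -> list of replicate peak
#'   `GRanges`).
#' @param merged Merged peak `GRanges`.
#' @return Named integer vector: pattern (classes joined by `+`, empty
#'   pattern `"none"`) -> count. Counts sum to `length(merged)`.
#' @export
intersection_pattern_counts <- function(per_class_peaksets, merged) {
  classes <- names(per_class_peaksets)
  present <- vapply(classes, function(k) {
    reps <- per_class_peaksets[[k]]
    in_all <- rep(TRUE, length(merged))
    for (r in reps) {
      in_all <- in_all & (GenomicRanges::countOverlaps(
        merged, r, minoverlap = 1L, ignore.strand = TRUE) > 0)
    }
    in_all
  }, logical(length(merged)))
  pattern <- apply(present, 1, function(p) {
    if (!any(p)) "none" else paste(classes[p], collapse = "+")
  })
  tab <- table(pattern)
  setNames(as.integer(tab), names(tab))
}
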