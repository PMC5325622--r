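#' Log-odds score matrix of a PWM
#'
#' Per-cell scores `log2((p + eps * b) / b)` in bits, where `b` is the
#' background frequency of the letter and `eps` a small background
#' admixture that keeps zero-probability cells finite.
#'
#' @param p A [pwm()] object.
#' @param epsilon Background admixture weight.
#' @return Numeric matrix (length x 4) of scores in bits.
#' @export
pwm_log_odds <- function(p, epsilon = 0.001) {
  if (any(p$background <= 0)) stop("zero background frequency")
  b <- matrix(p$background, nrow(p$probs), 4, byrow = TRUE)
  lo <- log2((p$probs + epsilon * b) / b)
  colnames(lo) <- c("A", "C", "G", "T")
  lo
}

# integer-discretized score matrix and the exact null (background) score
# distribution by dynamic-programming convolution; tail[i] = P(S >= min+i-1)
pwm_score_dp <- function(p, granularity = 1e-3, epsilon = 0.001) {
  s_int <- round(pwm_log_odds(p, epsilon) / granularity)
  lo_min <- sum(apply(s_int, 1, min))
  lo_max <- sum(apply(s_int, 1, max))
  dist <- 1 # probability vector over scores lo..; starts at "sum = 0"
  offset <- 0 # dist[i] = P(S = offset + i - 1)
  for (j in seq_len(nrow(s_int))) {
    row <- s_int[j, ]
    new_offset <- offset + min(row)
    new_len <- length(dist) + (max(row) - min(row))
    new_dist <- numeric(new_len)
    for (l in 1:4) {
      shift <- row[l] - min(row)
      idx <- seq_along(dist) + shift
      new_dist[idx] <- new_dist[idx] + dist * p$background[l]
    }
    dist <- new_dist
    offset <- new_offset
  }
  tail <- rev(cumsum(rev(dist)))
  list(scores_int = s_int, min_score = offset, tail = tail,
       granularity = granularity)
}

# tail probability P(S >= s_int) for integer grid scores (vectorized)
dp_tail_at <- function(dp, s_int) {
  i <- s_int - dp$min_score + 1
  out <- numeric(length(i))
  out[i <= 1] <- 1
  inside <- i >= 1 & i <= length(dp$tail)
  out[inside] <- dp$tail[i[inside]]
  out[i > length(dp$tail)] <- 0
  out
}

#' Exact p-value of a PWM score threshold
#'
#' The probability that a random background sequence of the motif's length
#' scores at or above `score_threshold`, computed exactly on an
#' integer-discretized score grid by dynamic-programming convolution over
#' positions.
#'
#' @param p A [pwm()] object.
#' @param score_threshold Score in bits.
#' @param granularity Discretization step (bits).
#' @return Tail probability in `[0, 1]`.
#' @export
pwm_pvalue <- function(p, score_threshold, granularity = 1e-3) {
  dp <- pwm_score_dp(p, granularity)
  dp_tail_at(dp, round(score_threshold / granularity))
}

# smallest integer grid score whose tail probability is <= p_threshold
pwm_hit_cutoff <- function(dp, p_threshold) {
  idx <- which(dp$tail <= p_threshold)
  if (!length(idx)) return(Inf)
  dp$min_score + idx[1] - 1
}

# reverse complement of a pwm (reverse positions, swap A<->T and C<->G)
pwm_revcomp <- function(p) {
  probs <- p$probs[rev(seq_len(nrow(p$probs))), c(4, 3, 2, 1), drop = FALSE]
  colnames(probs) <- c("A", "C", "G", "T")
  pwm(p$motif_id, probs, p$background[c(4, 3, 2, 1)], p$pseudocount)
}

# encode sequences as integer codes A=1 C=2 G=3 T=4, 0 otherwise
encode_dna <- function(seqs) {
  if (inherits(seqs, "DNAStringSet")) {
    seqs <- as.character(seqs)
  }
  lapply(seqs, function(s) {
    code <- match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T"))
    code[is.na(code)] <- 0L
    code
  })
}

# sliding integer window scores of one integer score matrix over one coded
# sequence; windows containing non-ACGT positions are NA
slide_scores <- function(code, s_int) {
  L <- nrow(s_int)
  n <- length(code)
  if (n < L) return(numeric(0))
  nw <- n - L + 1
  total <- numeric(nw)
  valid <- rep(TRUE, nw)
  for (j in seq_len(L)) {
    cj <- code[j:(j + nw - 1)]
    bad <- cj == 0L
    valid <- valid & !bad
    cj[bad] <- 1L
    total <- total + s_int[j, cj]
  }
  total[!valid] <- NA
  total
}

#' Scan sequences for PWM occurrences
#'
#' FIMO-style scan of both strands: for every window the integer-grid
#' log-odds score is compared against the exact background distribution
#' ([pwm_pvalue()]); windows with tail probability at or below `p_threshold`
#' are reported as hits. Overlapping hits of the same motif on opposite
#' strands are both retained; windows containing non-ACGT characters are
#' skipped.
#'
#' @param pwms List of [pwm()] objects.
#' @param seqs Named `DNAStringSet` or named character vector (names are
#'   peak ids).
#' @param p_threshold Per-position p-value threshold (default 1e-4).
#' @param granularity Score discretization (bits).
#' @return Data.frame `motif_id`, `peak_id`, `offset` (0-based from peak
#'   start), `strand`, `width`, `score` (bits), `p`.
#' @export
scan_sequences <- function(pwms, seqs, p_threshold = 1e-4,
                           granularity = 1e-3) {
  empty <- data.frame(motif_id = character(0), peak_id = character(0),
                      offset = integer(0), strand = character(0),
                      width = integer(0), score = numeric(0), p = numeric(0))
  if (!length(seqs)) return(empty)
  codes <- encode_dna(seqs)
  ids <- names(seqs)
  out <- list(empty)
  for (p in pwms) {
    dp_f <- pwm_score_dp(p, granularity)
    cutoff <- pwm_hit_cutoff(dp_f, p_threshold)
    if (!is.finite(cutoff)) next
    rc <- pwm_revcomp(p)
    s_rc <- round(pwm_log_odds(rc) / granularity)
    L <- nrow(p$probs)
    for (i in seq_along(codes)) {
      for (strand in c("+", "-")) {
        s_int <- if (strand == "+") dp_f$scores_int else s_rc
        sc <- slide_scores(codes[[i]], s_int)
        hit <- which(!is.na(sc) & sc >= cutoff)
        if (length(hit)) {
          out[[length(out) + 1]] <- data.frame(
            motif_id = p$motif_id, peak_id = ids[i],
            offset = hit - 1L, strand = strand, width = L,
            score = sc[hit] * granularity,
            p = dp_tail_at(dp_f, sc[hit]))
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Background module set for motif enrichment
#'
#' For a foreground module, the background consists of all other modules
#' whose binary center is low (< 0.5) in every cell class where the
#' foreground center is high (> 0.5) - modules that do not share the
#' foreground's accessibility pattern in any glutamatergic class.
#'
#' @param foreground Foreground module label.
#' @param patterns Binary module x class pattern matrix (e.g.
#'   [default_module_patterns()] or binarized final centers).
#' @return Character vector of background module labels.
#' @export
select_background <- function(foreground, patterns = default_module_patterns()) {
  if (!foreground %in% rownames(patterns)) stop("unknown module: ", foreground)
  high <- patterns[foreground, ] > 0.5
  if (!any(!high)) stop("foreground module is high in every class; empty background")
  others <- setdiff(rownames(patterns), foreground)
  bg <- others[vapply(others, function(m) all(patterns[m, high] < 0.5), TRUE)]
  if (!length(bg)) stop("empty background for module ", foreground)
  bg
}

#' Module-level motif enrichment against dissimilar-module backgrounds
#'
#' AME-style per-module test: peaks wider than `width_max` are excluded;
#' for each module the foreground is its member peaks and the background
#' the peaks of its dissimilar modules ([select_background()]). Per motif a
#' one-sided Fisher exact test on per-peak hit presence (at least one hit)
#' tests enrichment; depletion swaps the foreground and background sets.
#' BH adjustment is applied across motifs within each module and direction.
#'
#' @param hits Scan results ([scan_sequences()]).
#' @param module_set Peak `module_set` ([kmeans_seeded()]).
#' @param peak_widths Named vector of peak widths (bp).
#' @param direction `"enriched"`, `"depleted"` or `"both"`.
#' @param width_max Peak width cutoff (bp).
#' @param patterns Binary patterns used for the background rule; defaults
#'   to the binarized final centers.
#' @return Data.frame `motif_id`, `module`, `direction`, counts `a`-`d`,
#'   `odds_ratio`, `p`, `adj_p`.
#' @export
motif_module_enrichment <- function(hits, module_set, peak_widths,
                                    direction = c("both", "enriched", "depleted"),
                                    width_max = 400,
                                    patterns = NULL) {
  direction <- match.arg(direction)
  directions <- if (direction == "both") c("enriched", "depleted") else direction
  if (is.null(patterns)) patterns <- binarize_centers(module_set$centers)
  membership <- module_set$membership
  keep <- names(membership)[peak_widths[names(membership)] <= width_max]
  motifs <- sort(unique(hits$motif_id))
  out <- list()
  for (m in module_set$labels) {
    fg <- keep[membership[keep] == m]
    if (!length(fg)) stop("empty foreground after width filter: module ", m)
    bg_modules <- select_background(m, patterns)
    bg <- keep[membership[keep] %in% bg_modules]
    for (mot in motifs) {
      with_hit <- unique(hits$peak_id[hits$motif_id == mot])
      a <- sum(fg %in% with_hit); b <- length(fg) - a
      cc <- sum(bg %in% with_hit); d <- length(bg) - cc
      for (dir in directions) {
        # depletion swaps foreground and background; the stored counts are
        # the table actually tested
        tab <- if (dir == "enriched") rbind(c(a, b), c(cc, d)) else
          rbind(c(cc, d), c(a, b))
        ft <- fisher_exact_2x2(tab, alternative = "greater")
        out[[length(out) + 1]] <- data.frame(
          motif_id = mot, module = m, direction = dir,
          a = tab[1, 1], b = tab[1, 2], c = tab[2, 1], d = tab[2, 2],
          odds_ratio = ft$odds_ratio, p = ft$p)
      }
    }
  }
  res <- do.call(rbind, out)
  res$adj_p <- NA_real_
  for (m in unique(res$module)) {
    for (dir in directions) {
      sel <- res$module == m & res$direction == dir
      res$adj_p[sel] <- adjust_pvalues(res$p[sel], "BH")
    }
  }
  rownames(res) <- NULL
  res
}

#' Aggregate motif enrichment to family level
#'
#' Motif families (a curated grouping of member motif ids) are summarized
#' by the best member p-value per module and direction.
#'
#' @param enrichment [motif_module_enrichment()] result.
#' @param families Named character vector: motif id -> family label.
#' @return Data.frame like `enrichment` aggregated per family.
#' @export
family_enrichment <- function(enrichment, families) {
  enrichment$family <- families[enrichment$motif_id]
  enrichment <- enrichment[!is.na(enrichment$family), , drop = FALSE]
  keys <- unique(enrichment[c("family", "module", "direction")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- enrichment$family == keys$family[i] &
      enrichment$module == keys$module[i] &
      enrichment$direction == keys$direction[i]
    sub <- enrichment[sel, , drop = FALSE]
    best <- which.min(sub$p)
    data.frame(keys[i, ], motif_id = sub$motif_id[best],
               odds_ratio = sub$odds_ratio[best],
               p = sub$p[best], adj_p = sub$adj_p[best])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
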