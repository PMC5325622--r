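#' Fisher's exact test for a 2x2 table
#'
#' Conditional hypergeometric exact test (two-sided, via
#' [stats::fisher.test()]) with the sample odds ratio `ad/bc`. Conventions:
#' `OR = Inf` when `bc = 0` with `a, d > 0`; degenerate tables with an empty
#' margin have `OR = 1` and `p = 1`.
#'
#' @param table 2x2 matrix of non-negative counts
#'   (`rbind(c(a, b), c(c, d))`).
#' @param alternative Passed to `fisher.test` (`"two.sided"`, `"greater"`,
#'   `"less"`).
#' @return List with `odds_ratio` and `p`.
#' @export
fisher_exact_2x2 <- function(table, alternative = "two.sided") {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0)) stop("counts must be non-negative")
  a <- table[1, 1]; b <- table[1, 2]; cc <- table[2, 1]; d <- table[2, 2]
  if (b * cc == 0) {
    or <- if (a * d > 0) Inf else 1
  } else {
    or <- (a * d) / (b * cc)
  }
  if (sum(table) == 0 || any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(list(odds_ratio = or, p = 1))
  }
  p <- fisher.test(table, alternative = alternative)$p.value
  list(odds_ratio = or, p = min(1, p))
}

#' Fisher association between peak modules and gene modules
#'
#' For each (peak module i, gene module j) pair, counts how often peaks in
#' module i are positionally associated with genes in module j, and tests
#' enrichment/depletion with a two-sided Fisher exact test. The universe is
#' all module peaks that carry a gene assignment; peaks whose assigned gene
#' belongs to no gene module count against the pair (columns b/d). BH
#' adjustment is applied across all pairs.
#'
#' @param peak_modules Named membership vector (peak id -> module label).
#' @param gene_modules Named membership vector (gene id -> module label).
#' @param assignments Peak-gene assignments ([assign_nearest_tss()]).
#' @return Data.frame with one row per module pair: counts `a`-`d`,
#'   `odds_ratio`, `p`, `adj_p`, `direction` (enriched/depleted).
#' @export
module_module_fisher <- function(peak_modules, gene_modules, assignments) {
  asn <- assignments[assignments$peak_id %in% names(peak_modules), , drop = FALSE]
  pk_mod <- peak_modules[asn$peak_id]
  gn_mod <- unname(gene_modules[asn$gene_id])
  peak_labels <- sort(unique(unname(peak_modules)))
  gene_labels <- sort(unique(unname(gene_modules)))
  grid <- expand.grid(peak_module = peak_labels, gene_module = gene_labels,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    in_i <- pk_mod == grid$peak_module[i]
    in_j <- !is.na(gn_mod) & gn_mod == grid$gene_module[i]
    a <- sum(in_i & in_j); b <- sum(in_i & !in_j)
    cc <- sum(!in_i & in_j); d <- sum(!in_i & !in_j)
    ft <- fisher_exact_2x2(rbind(c(a, b), c(cc, d)))
    data.frame(grid[i, ], a = a, b = b, c = cc, d = d,
               odds_ratio = ft$odds_ratio, p = ft$p)
  })
  out <- do.call(rbind, res)
  out$adj_p <- adjust_pvalues(out$p, "BH")
  out$direction <- ifelse(out$odds_ratio > 1, "enriched",
                          ifelse(out$odds_ratio < 1, "depleted", "none"))
  rownames(out) <- NULL
  out
}

#' Peak-gene expression correlation over cell classes
#'
#' Pearson correlation between each assigned peak's scaled class
#' accessibility profile and its gene's scaled class expression profile.
#' Pairs with a constant profile on either side are dropped with a message.
#'
#' @param peak_scaled Peak x class scaled score matrix ([scale_rows()]).
#' @param gene_scaled Gene x class scaled expression matrix.
#' @param assignments Peak-gene assignments.
#' @return Data.frame `peak_id`, `gene_id`, `r`.
#' @export
peak_gene_correlation <- function(peak_scaled, gene_scaled, assignments) {
  asn <- assignments[assignments$peak_id %in% rownames(peak_scaled) &
                     assignments$gene_id %in% rownames(gene_scaled), ,
                     drop = FALSE]
  pk <- peak_scaled[asn$peak_id, , drop = FALSE]
  gn <- gene_scaled[asn$gene_id, , drop = FALSE]
  r <- row_cor(pk, gn)
  drop <- is.na(r)
  if (any(drop)) message(sum(drop), " constant pairs dropped from correlation")
  data.frame(peak_id = asn$peak_id[!drop], gene_id = asn$gene_id[!drop],
             r = r[!drop], row.names = NULL)
}

# rowwise Pearson correlation of two equal-shaped matrices
row_cor <- function(x, y) {
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  den <- sqrt(rowSums(xc^2) * rowSums(yc^2))
  r <- rowSums(xc * yc) / den
  r[den == 0] <- NA
  r
}

#' Permutation control for peak-gene correlations
#'
#' Randomly permutes the peak-to-gene assignment, recomputes the
#' correlations, and compares the observed correlation distribution with
#' each permuted set by a two-sample Kolmogorov-Smirnov test. Deterministic
#' for a given seed.
#'
#' @param peak_scaled,gene_scaled,assignments As in
#'   [peak_gene_correlation()].
#' @param n_perms Number of permutations (default 10).
#' @param seed Integer seed.
#' @return List with `observed` (correlation data.frame) and `permutations`
#'   (data.frame `perm`, `ks_stat`, `p`).
#' @export
permutation_ks <- function(peak_scaled, gene_scaled, assignments,
                           n_perms = 10, seed = 1) {
  if (n_perms < 1) stop("n_perms must be >= 1")
  observed <- peak_gene_correlation(peak_scaled, gene_scaled, assignments)
  set.seed(seed)
  perms <- lapply(seq_len(n_perms), function(b) {
    shuffled <- assignments
    shuffled$gene_id <- sample(shuffled$gene_id)
    perm_r <- suppressMessages(
      peak_gene_correlation(peak_scaled, gene_scaled, shuffled))
    ks <- suppressWarnings(ks.test(observed$r, perm_r$r))
    data.frame(perm = b, ks_stat = unname(ks$statistic), p = ks$p.value)
  })
  list(observed = observed, permutations = do.call(rbind, perms))
}
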