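#' The eight default binary module patterns
#'
#' Binary high/low accessibility (or expression) patterns over the four
#' glutamatergic classes that define the module seeds: one selective-high
#' pattern per class, Upper+ (high L2/3 and L4), Lower+ (high L5 and L6),
#' L4- (low in L4 only) and L6- (low in L6 only).
#'
#' @param classes Class labels (column order).
#' @return 8 x 4 binary matrix, rownames the module labels.
#' @export
default_module_patterns <- function(classes = c("L2/3", "L4", "L5", "L6")) {
  m <- rbind(
    "L2/3+"  = c(1, 0, 0, 0),
    "L4+"    = c(0, 1, 0, 0),
    "L5+"    = c(0, 0, 1, 0),
    "L6+"    = c(0, 0, 0, 1),
    "Upper+" = c(1, 1, 0, 0),
    "Lower+" = c(0, 0, 1, 1),
    "L4-"    = c(1, 0, 1, 1),
    "L6-"    = c(1, 1, 1, 0))
  colnames(m) <- classes
  m
}

#' Select features for module clustering
#'
#' Joint filter applied per pairwise glutamatergic contrast: a feature
#' qualifies when, in at least one contrast, it is significantly
#' differential and shows at least the required fold difference in
#' class-mean normalized score. Defaults follow the two feature kinds:
#' peaks require adjusted p < 0.01 and > 4-fold difference in average TMM
#' score; genes require p < 0.05 and > 2-fold change.
#'
#' @param diff_list List of per-contrast differential results
#'   ([nb_differential_all_pairs()]); only contrasts between columns of
#'   `class_scores` are used.
#' @param class_scores Feature x class score matrix (class-level means).
#' @param kind `"peak"` or `"gene"` (sets default thresholds).
#' @param p_threshold,fc_threshold Override thresholds.
#' @param use_adjusted Whether the p filter applies to `adj_p` (peaks) or
#'   raw `p` (genes).
#' @return Character vector of qualifying feature ids.
#' @export
select_module_features <- function(diff_list, class_scores,
                                   kind = c("peak", "gene"),
                                   p_threshold = NULL, fc_threshold = NULL,
                                   use_adjusted = NULL) {
  kind <- match.arg(kind)
  if (is.null(p_threshold)) p_threshold <- if (kind == "peak") 0.01 else 0.05
  if (is.null(fc_threshold)) fc_threshold <- if (kind == "peak") 4 else 2
  if (is.null(use_adjusted)) use_adjusted <- kind == "peak"
  classes <- colnames(class_scores)
  selected <- character(0)
  for (d in diff_list) {
    if (!nrow(d)) next
    if (!(d$class_a[1] %in% classes && d$class_b[1] %in% classes)) next
    pv <- if (use_adjusted) d$adj_p else d$p
    sa <- class_scores[match(d$feature_id, rownames(class_scores)), d$class_a[1]]
    sb <- class_scores[match(d$feature_id, rownames(class_scores)), d$class_b[1]]
    fc <- (pmax(sa, sb) + 0.5) / (pmin(sa, sb) + 0.5)
    pass <- !is.na(pv) & pv < p_threshold & fc > fc_threshold
    selected <- union(selected, d$feature_id[pass])
  }
  selected
}

#' Scale feature profiles to the unit interval
#'
#' Per feature: subtract the minimum over the glutamatergic classes, then
#' divide by the resulting maximum, so each row spans exactly `[0, 1]`.
#' Constant rows (zero range) are excluded with a message.
#'
#' @param scores Feature x class numeric matrix.
#' @return Matrix of scaled profiles (possibly fewer rows).
#' @export
scale_rows <- function(scores) {
  rng <- apply(scores, 1, function(x) diff(range(x)))
  constant <- rng == 0 | !is.finite(rng)
  if (any(constant)) {
    message(sum(constant), " constant rows excluded from scaling")
    scores <- scores[!constant, , drop = FALSE]
    rng <- rng[!constant]
  }
  mins <- apply(scores, 1, min)
  (scores - mins) / rng
}

# Lloyd's algorithm with fixed initial centers; an empty cluster keeps its
# (seed) center rather than being dropped or re-seeded.
lloyd_kmeans <- function(x, centers, iter_max = 100) {
  k <- nrow(centers)
  assign_old <- rep(-1L, nrow(x))
  for (it in seq_len(iter_max)) {
    d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * x %*% t(centers)
    assignment <- max.col(-d2, ties.method = "first")
    if (all(assignment == assign_old)) break
    assign_old <- assignment
    for (j in seq_len(k)) {
      members <- assignment == j
      if (any(members)) centers[j, ] <- colMeans(x[members, , drop = FALSE])
    }
  }
  inertia <- sum((x - centers[assignment, , drop = FALSE])^2)
  list(centers = centers, cluster = assignment, inertia = inertia,
       iterations = it)
}

# k-means++ seeding
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1, ] <- x[sample.int(n, 1, prob = probs), ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j + 1, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' Exploratory k-means clustering of scaled profiles
#'
#' Lloyd's algorithm with k-means++ initialization, best of `restarts`
#' runs by within-cluster sum of squares; deterministic for a given seed.
#' This is the diagnostic first round used to see which binary patterns the
#' data support; module construction itself uses [kmeans_seeded()].
#'
#' @param profiles Scaled profile matrix ([scale_rows()]).
#' @param k Number of clusters.
#' @param restarts Number of initializations.
#' @param seed Integer seed.
#' @return List with `centers`, `cluster` (named by feature), `inertia`.
#' @export
kmeans_explore <- function(profiles, k = 15, restarts = 10, seed = 1) {
  if (k > nrow(profiles)) stop("k exceeds the number of features")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- lloyd_kmeans(profiles, kmeanspp_init(profiles, k))
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  best$cluster <- setNames(best$cluster, rownames(profiles))
  best
}

#' Binarize cluster centers
#'
#' Elementwise threshold at 0.5: values above (or exactly at) 0.5 become 1,
#' values below become 0.
#'
#' @param centers Numeric matrix of cluster centers.
#' @return Binary matrix of the same shape.
#' @export
binarize_centers <- function(centers) {
  (centers >= 0.5) * 1
}

#' Seeded k-means module construction
#'
#' Second clustering round: Lloyd's algorithm started from the eight fixed
#' binary patterns (no restarts, no randomness). A cluster that loses all
#' members keeps its seed center. The result is the final module set.
#'
#' @param profiles Scaled profile matrix.
#' @param seed_centers Binary seed matrix (default
#'   [default_module_patterns()]); rownames are the module labels.
#' @param feature_kind `"peak"` or `"gene"`.
#' @return Object of class `module_set`: `labels`, `centers`,
#'   `seed_centers`, `membership` (named by feature), `feature_kind`,
#'   `sizes`, `inertia`.
#' @export
kmeans_seeded <- function(profiles, seed_centers = default_module_patterns(),
                          feature_kind = "peak") {
  stopifnot(ncol(profiles) == ncol(seed_centers))
  fit <- lloyd_kmeans(profiles, seed_centers)
  labels <- rownames(seed_centers)
  membership <- setNames(labels[fit$cluster], rownames(profiles))
  structure(list(
    labels = labels,
    centers = structure(fit$centers, dimnames = dimnames(seed_centers)),
    seed_centers = seed_centers,
    membership = membership,
    feature_kind = feature_kind,
    sizes = setNames(as.integer(table(factor(membership, levels = labels))),
                     labels),
    inertia = fit$inertia), class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set (%s): %d features in %d modules\n",
              x$feature_kind, length(x$membership), length(x$labels)))
  print(x$sizes)
  invisible(x)
}

#' Assign a module to each gene by correlation with module centers
#'
#' For genes not clustered directly (e.g. TF candidates), the module whose
#' center has the highest Pearson correlation with the gene's class-mean
#' expression profile is assigned. Constant expression vectors are
#' unassigned (`NA`) since the correlation is undefined.
#'
#' @param expr_means Gene x class expression matrix (class-level means over
#'   the glutamatergic classes).
#' @param centers Module x class center matrix.
#' @return Data.frame `gene_id`, `module`, `r`.
#' @export
assign_gene_module_by_correlation <- function(expr_means, centers) {
  out <- data.frame(gene_id = rownames(expr_means),
                    module = NA_character_, r = NA_real_)
  keep <- apply(expr_means, 1, function(x) stats::sd(x) > 0)
  if (any(keep)) {
    r_mat <- cor(t(expr_means[keep, , drop = FALSE]), t(centers))
    best <- max.col(r_mat, ties.method = "first")
    out$module[keep] <- rownames(centers)[best]
    out$r[keep] <- r_mat[cbind(seq_len(nrow(r_mat)), best)]
  }
  out
}

#' Hierarchical clustering of samples over top differential peaks
#'
#' Complete-linkage agglomeration on `1 - Pearson` distance between sample
#' score columns, restricted to the `top_n` most differential peaks (ranked
#' by the supplied adjusted p-values).
#'
#' @param scores Feature x sample score matrix.
#' @param peak_rank_p Named vector of (adjusted) p-values used for ranking;
#'   missing features rank last.
#' @param top_n Number of peaks to use (default 7500); when more than
#'   available, all are used with a warning.
#' @return An `hclust` object.
#' @export
hclust_samples <- function(scores, peak_rank_p = NULL, top_n = 7500) {
  if (is.null(peak_rank_p)) {
    peak_rank_p <- setNames(rep(0, nrow(scores)), rownames(scores))
  }
  if (top_n > nrow(scores)) {
    warning("top_n exceeds available peaks; using all ", nrow(scores))
    top_n <- nrow(scores)
  }
  pv <- peak_rank_p[rownames(scores)]
  pv[is.na(pv)] <- Inf
  keep <- rownames(scores)[order(pv)][seq_len(top_n)]
  sub <- scores[keep, , drop = FALSE]
  d <- stats::as.dist(1 - cor(sub))
  hclust(d, method = "complete")
}

#' Export a dendrogram in Newick format
#' @param hc An `hclust` object.
#' @param path Output path.
#' @export
dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
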