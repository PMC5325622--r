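#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up (with enforced monotonicity) or Bonferroni
#' (`min(1, m * p)`), via [stats::p.adjust()].
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}

#' Negative-binomial Wald test for differential accessibility/expression
#'
#' A two-group Wald test on effective-library-size-normalized counts
#' (CPM scale) under an NB variance model `Var = mu + phi * mu^2`.
#' Per-feature dispersion is a method-of-moments estimate (floored at 0)
#' shrunk 50% toward a trended mean-dispersion fit across all features.
#' The statistic is `z = log2fc / SE` with `log2fc` computed on class-mean
#' normalized counts with a pseudocount of 0.5, and the standard error from
#' the delta method.
#'
#' Two-sided p-values use a finite-sample null calibration of `z`: with
#' three replicates per class the plug-in dispersion makes the naive normal
#' reference anticonservative, so the null law of `z` is estimated by a
#' parametric bootstrap on a grid of abundance bins (NB draws at the
#' trended dispersion, pushed through the identical estimator). The bulk of
#' the distribution is calibrated empirically; beyond the resolution of the
#' bootstrap the tail continues as a continuity-matched scaled normal, so
#' very small p-values remain available to the downstream gates. The
#' bootstrap uses a fixed internal seed and restores the caller's RNG
#' state, keeping results deterministic. `null_calibration = FALSE` gives
#' plain normal p-values.
#'
#' @param cm A [count_matrix()].
#' @param contrast Character vector `c(class_A, class_B)`; the fold change
#'   is A over B.
#' @param factors Optional TMM factors (defaults to 1).
#' @param lib_sizes Optional library sizes (defaults to column sums over all
#'   samples in `cm`).
#' @param null_calibration Calibrate p-values against the bootstrap null
#'   law of `z` (default) instead of the standard normal.
#' @return Data.frame with `feature_id`, `class_a`, `class_b`, `mean_a`,
#'   `mean_b` (CPM), `log2fc`, `dispersion`, `p`, `adj_p`, `method`.
#' @export
nb_differential <- function(cm, contrast, factors = NULL, lib_sizes = NULL,
                            null_calibration = TRUE) {
  stopifnot(length(contrast) == 2)
  cls <- cm$sample_class
  a_samples <- names(cls)[cls == contrast[1]]
  b_samples <- names(cls)[cls == contrast[2]]
  if (length(a_samples) < 2 || length(b_samples) < 2) {
    stop("need >= 2 replicates per class in the contrast")
  }
  counts <- cm$counts
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (is.null(names(lib_sizes))) names(lib_sizes) <- colnames(counts)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  if (is.null(names(factors))) names(factors) <- colnames(counts)
  sel <- c(a_samples, b_samples)
  eff <- lib_sizes[sel] * factors[sel]
  q <- sweep(counts[, sel, drop = FALSE], 2, eff, "/") * 1e6
  qa <- q[, a_samples, drop = FALSE]
  qb <- q[, b_samples, drop = FALSE]
  na <- length(a_samples); nb <- length(b_samples)
  ma <- rowMeans(qa); mb <- rowMeans(qb)

  # method-of-moments dispersion, pooled over the two classes, with the
  # Poisson (counting) component removed on the CPM scale
  scale_a <- mean(1e6 / eff[a_samples]); scale_b <- mean(1e6 / eff[b_samples])
  va <- apply(qa, 1, var); vb <- apply(qb, 1, var)
  phi_a <- (va - ma * scale_a) / ma^2
  phi_b <- (vb - mb * scale_b) / mb^2
  phi_a[!is.finite(phi_a)] <- NA
  phi_b[!is.finite(phi_b)] <- NA
  phi_raw <- pmax(0, rowMeans(cbind(phi_a, phi_b), na.rm = TRUE))
  phi_raw[is.na(phi_raw)] <- 0

  # trended fit of dispersion on mean abundance, then 50% shrinkage
  mu <- (ma * na + mb * nb) / (na + nb)
  ok <- mu > 0
  trend <- rep(0, length(mu))
  if (sum(ok) >= 10) {
    lw <- lowess(log(mu[ok]), phi_raw[ok], f = 2 / 3)
    trend[ok] <- approx(lw$x, lw$y, xout = log(mu[ok]), rule = 2,
                        ties = "ordered")$y
  } else if (any(ok)) {
    trend[ok] <- mean(phi_raw[ok])
  }
  trend <- pmax(trend, 0)
  phi <- pmax(0.5 * phi_raw + 0.5 * trend, 1e-8)

  log2fc <- log2((ma + 0.5) / (mb + 0.5))
  var_ma <- (ma * scale_a + phi * ma^2) / na
  var_mb <- (mb * scale_b + phi * mb^2) / nb
  se2 <- var_ma / ((ma + 0.5)^2) + var_mb / ((mb + 0.5)^2)
  se <- sqrt(se2) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  # the bootstrap correction matters only for few replicates; with larger
  # groups the dispersion estimate has enough degrees of freedom that the
  # normal reference is accurate
  if (null_calibration && min(na, nb) < 8) {
    p <- nb_null_calibrated_p(z, mu, trend, phi_raw, scale_a, scale_b,
                              na, nb)
  } else {
    p <- 2 * pnorm(-abs(z))
  }
  both_zero <- ma == 0 & mb == 0
  p[both_zero] <- 1
  log2fc[both_zero] <- 0
  data.frame(
    feature_id = rownames(counts),
    class_a = contrast[1], class_b = contrast[2],
    mean_a = ma, mean_b = mb,
    log2fc = log2fc, dispersion = phi,
    p = p, adj_p = adjust_pvalues(p, "BH"),
    method = "nb_wald",
    row.names = NULL)
}

#' NB differential tests for all pairwise class contrasts
#'
#' @param cm A [count_matrix()].
#' @param classes Classes to contrast (defaults to all classes in `cm`).
#' @inheritParams nb_differential
#' @return Named list of [nb_differential()] results, one per unordered
#'   pair, named `"A|B"`.
#' @export
nb_differential_all_pairs <- function(cm, classes = NULL, factors = NULL,
                                      lib_sizes = NULL) {
  if (is.null(classes)) classes <- count_matrix_classes(cm)
  pairs <- combn(classes, 2, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    nb_differential(cm, pr, factors = factors, lib_sizes = lib_sizes)
  })
  names(res) <- vapply(pairs, paste, "", collapse = "|")
  res
}

# Finite-sample null calibration of the NB Wald z. Features are binned by
# pooled CPM abundance; for each bin the null law of z is estimated by a
# parametric bootstrap (NB draws at the trended dispersion pushed through
# the identical moment estimator). Observed |z| in the bulk get empirical
# two-sided p-values; beyond the bootstrap resolution the tail continues
# as a continuity-matched scaled normal. Fixed internal seed; caller RNG
# state restored.
nb_null_calibrated_p <- function(z, mu, trend, phi_raw_obs,
                                 scale_a, scale_b, na, nb,
                                 n_bins = 25, B = 20000) {
  p <- 2 * pnorm(-abs(z))
  ok <- which(mu > 0)
  if (!length(ok)) return(p)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(710710L)
  lmu <- log(mu[ok])
  brks <- seq(min(lmu), max(lmu), length.out = n_bins + 1)
  brks[1] <- brks[1] - 1e-9; brks[n_bins + 1] <- brks[n_bins + 1] + 1e-9
  bin <- findInterval(lmu, brks, all.inside = TRUE)
  row_var <- function(m) {
    rowSums((m - rowMeans(m))^2) / (ncol(m) - 1)
  }
  boot_z <- function(mu0, phi_sim, phi_target) {
    qa <- matrix(rnbinom(B * na, mu = mu0 / scale_a, size = 1 / phi_sim),
                 B, na) * scale_a
    qb <- matrix(rnbinom(B * nb, mu = mu0 / scale_b, size = 1 / phi_sim),
                 B, nb) * scale_b
    ma <- rowMeans(qa); mb <- rowMeans(qb)
    phi_a <- (row_var(qa) - ma * scale_a) / ma^2
    phi_b <- (row_var(qb) - mb * scale_b) / mb^2
    phi_a[!is.finite(phi_a)] <- NA; phi_b[!is.finite(phi_b)] <- NA
    phi_raw <- pmax(0, rowMeans(cbind(phi_a, phi_b), na.rm = TRUE))
    phi_raw[is.na(phi_raw)] <- 0
    phis <- pmax(0.5 * phi_raw + 0.5 * phi_target, 1e-8)
    lfc_b <- log2((ma + 0.5) / (mb + 0.5))
    se2_b <- (ma * scale_a + phis * ma^2) / na / (ma + 0.5)^2 +
      (mb * scale_b + phis * mb^2) / nb / (mb + 0.5)^2
    list(z = abs(lfc_b / (sqrt(se2_b) / log(2))), phi_raw = phi_raw)
  }
  for (b in unique(bin)) {
    idx <- ok[bin == b]
    mu0 <- exp(mean(range(lmu[bin == b])))
    # the shrinkage target the real estimator used for this bin
    target0 <- max(stats::median(trend[idx]), 1e-8)
    # the moment estimator is biased at n = 3; correct the simulation
    # dispersion so its mean moment estimate matches the observed one
    pilot <- boot_z(mu0, target0, target0)
    beta <- mean(pilot$phi_raw) / target0
    obs_phi <- mean(phi_raw_obs[idx])
    phi_sim <- max(if (is.finite(beta) && beta > 0) obs_phi / beta else
      target0, 1e-8)
    zb <- boot_z(mu0, phi_sim, target0)$z
    zb <- zb[is.finite(zb)]
    zb_sorted <- sort(zb)
    nB <- length(zb_sorted)
    tail_k <- 200L
    z_cut <- zb_sorted[nB - tail_k]
    p_cut <- (1 + tail_k) / (nB + 1)
    c_tail <- if (z_cut > 0) qnorm(1 - p_cut / 2) / z_cut else 1
    zo <- abs(z[idx])
    # empirical two-sided p: fraction of bootstrap |z| at or above observed
    ge <- nB - findInterval(zo - 1e-12, zb_sorted)
    p_emp <- (1 + ge) / (nB + 1)
    in_tail <- zo > z_cut
    p_emp[in_tail] <- 2 * pnorm(-zo[in_tail] * c_tail)
    p[idx] <- pmin(p_emp, 1)
  }
  p
}

# exact null distribution of the rank-sum statistic by enumeration of all
# C(nA+nB, nA) group assignments of the pooled (midrank) values
mw_enumerate <- function(pooled_ranks, n_a) {
  n <- length(pooled_ranks)
  idx <- combn(n, n_a)
  colSums(matrix(pooled_ranks[idx], nrow = n_a)) - n_a * (n_a + 1) / 2
}

#' Mann-Whitney U test for two sets of peak accessibility scores
#'
#' Computes U with midrank ties. For small groups (both sizes at most
#' `exact_max`) the p-value is exact, by full enumeration of all
#' `choose(nA+nB, nA)` group assignments of the pooled values; otherwise the
#' normal approximation with tie and continuity correction is used.
#'
#' @param scores_a,scores_b Numeric score vectors (both non-empty).
#' @param exact_max Enumeration threshold on each group size.
#' @param label Optional gene-set label carried into the result.
#' @return List of class `mw_test` with `U`, `p` (two-sided), `p_less`,
#'   `p_greater` (one-sided: A below / above B), `n_a`, `n_b`, `exact`,
#'   `label`.
#' @export
mw_gene_set_test <- function(scores_a, scores_b, exact_max = 8, label = NA) {
  n_a <- length(scores_a); n_b <- length(scores_b)
  if (n_a == 0 || n_b == 0) stop("empty group in Mann-Whitney test")
  pooled <- c(scores_a, scores_b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  if (n_a <= exact_max && n_b <= exact_max) {
    null_u <- mw_enumerate(r, n_a)
    p_less <- mean(null_u <= u)
    p_greater <- mean(null_u >= u)
    p <- min(1, 2 * min(p_less, p_greater))
    exact <- TRUE
  } else {
    n <- n_a + n_b
    ties <- table(pooled)
    mu <- n_a * n_b / 2
    sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    cc <- 0.5
    p_less <- pnorm((u - mu + cc) / sigma)
    p_greater <- pnorm((u - mu - cc) / sigma, lower.tail = FALSE)
    p <- min(1, 2 * min(p_less, p_greater))
    exact <- FALSE
  }
  structure(list(U = u, p = p, p_less = p_less, p_greater = p_greater,
                 n_a = n_a, n_b = n_b, exact = exact, label = label),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n = %d vs %d), two-sided p = %.4g (%s)\n",
              x$U, x$n_a, x$n_b, x$p, if (x$exact) "exact" else "normal approx."))
  invisible(x)
}

#' Pairwise gene-set accessibility comparison
#'
#' For one class contrast: split differentially expressed genes (adjusted
#' p below `gene_p`) by the class with higher expression, collect the
#' class-level accessibility scores of all peaks positionally associated
#' with each gene set, and compare the two classes' score distributions per
#' gene set with a Mann-Whitney U test, Bonferroni-corrected across the
#' tests performed.
#'
#' @param peak_class_scores Feature x class score matrix (class-level).
#' @param diff_genes [nb_differential()] result for the gene contrast.
#' @param assignments Peak-gene assignments ([assign_nearest_tss()]).
#' @param contrast `c(class_A, class_B)`.
#' @param gene_p Adjusted-p threshold for differential expression.
#' @return Data.frame with one row per gene set (`higher_in`), U, p, adj_p
#'   (Bonferroni) and group sizes.
#' @export
pairwise_gene_set_mw <- function(peak_class_scores, diff_genes, assignments,
                                 contrast, gene_p = 0.001) {
  de <- diff_genes[diff_genes$adj_p < gene_p, , drop = FALSE]
  sets <- list(de$feature_id[de$log2fc > 0], de$feature_id[de$log2fc < 0])
  names(sets) <- contrast
  out <- lapply(names(sets), function(k) {
    pk <- assignments$peak_id[assignments$gene_id %in% sets[[k]]]
    pk <- intersect(pk, rownames(peak_class_scores))
    if (!length(pk)) return(NULL)
    res <- mw_gene_set_test(peak_class_scores[pk, contrast[1]],
                            peak_class_scores[pk, contrast[2]],
                            label = k)
    data.frame(higher_in = k, n_peaks = length(pk), U = res$U, p = res$p,
               n_a = res$n_a, n_b = res$n_b)
  })
  out <- do.call(rbind, out)
  if (!is.null(out)) out$adj_p <- adjust_pvalues(out$p, "bonferroni")
  out
}

#' Volcano table of peaks near differentially expressed genes
#'
#' Restricts a peak differential result to peaks whose assigned gene is
#' differentially expressed (adjusted p below `gene_filter_p`) in the same
#' contrast, and marks whether peak and gene fold changes agree in sign
#' (positively correlated).
#'
#' @param diff_peaks [nb_differential()] result for peaks.
#' @param diff_genes [nb_differential()] result for genes (same contrast).
#' @param assignments Peak-gene assignments.
#' @param gene_filter_p Adjusted-p threshold on the gene.
#' @return Data.frame with `peak_id`, `gene_id`, `log2fc`, `neg_log10_p`,
#'   `gene_log2fc`, `positively_correlated`.
#' @export
volcano_table <- function(diff_peaks, diff_genes, assignments,
                          gene_filter_p = 1e-6) {
  de <- diff_genes[diff_genes$adj_p < gene_filter_p, , drop = FALSE]
  asn <- assignments[assignments$gene_id %in% de$feature_id, , drop = FALSE]
  rows <- diff_peaks[match(asn$peak_id, diff_peaks$feature_id), , drop = FALSE]
  keep <- !is.na(rows$feature_id)
  asn <- asn[keep, , drop = FALSE]; rows <- rows[keep, , drop = FALSE]
  gene_lfc <- de$log2fc[match(asn$gene_id, de$feature_id)]
  data.frame(
    peak_id = rows$feature_id,
    gene_id = asn$gene_id,
    log2fc = rows$log2fc,
    neg_log10_p = -log10(pmax(rows$p, .Machine$double.xmin)),
    gene_log2fc = gene_lfc,
    positively_correlated = sign(rows$log2fc) == sign(gene_lfc),
    row.names = NULL)
}
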