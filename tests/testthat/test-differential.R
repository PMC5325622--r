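make_cm <- function(counts, classes) {
  dimnames(counts) <- list(sprintf("f%04d", seq_len(nrow(counts))),
                           sprintf("s%d", seq_len(ncol(counts))))
  count_matrix(counts, setNames(classes, colnames(counts)))
}

test_that("degenerate features are handled: identical groups, all-zero", {
  counts <- rbind(rep(c(10, 20, 30), 2), rep(0, 6), c(5, 6, 7, 50, 60, 70))
  counts <- counts[rep(1:3, 20), ]  # enough features for the trend fit
  cm <- make_cm(counts, rep(c("A", "B"), each = 3))
  res <- nb_differential(cm, c("A", "B"), lib_sizes = rep(1e6, 6),
                         null_calibration = FALSE)
  expect_equal(res$log2fc[1], 0)
  expect_equal(res$p[1], 1)
  expect_equal(res$log2fc[2], 0)
  expect_equal(res$p[2], 1)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$adj_p >= res$p - 1e-12))
})

test_that("null NB counts give calibrated p-values", {
  set.seed(7)
  n <- 5000
  mu <- exp(runif(n, log(50), log(2000)))
  counts <- sapply(1:6, function(i) rnbinom(n, mu = mu, size = 10))
  cm <- make_cm(counts, rep(c("A", "B"), each = 3))
  res <- nb_differential(cm, c("A", "B"))
  expect_lt(abs(mean(res$p < 0.05) - 0.05), 0.015)
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted 6-fold features are detected with high power", {
  set.seed(5)
  n <- 2000; n_de <- 200
  mu2 <- rep(500, n) * ifelse(seq_len(n) <= n_de, 6, 1)
  counts <- cbind(sapply(1:3, function(i) rnbinom(n, mu = mu2, size = 10)),
                  sapply(1:3, function(i) rnbinom(n, mu = 500, size = 10)))
  cm <- make_cm(counts, rep(c("A", "B"), each = 3))
  res <- nb_differential(cm, c("A", "B"), factors = tmm_factors(cm))
  expect_gte(mean(res$adj_p[1:n_de] < 0.01), 0.95)
  expect_lte(mean(res$adj_p[(n_de + 1):n] < 0.01), 0.02)
  expect_gte(mean(res$log2fc[1:n_de] > 2), 0.9)
})

test_that("nb_differential is deterministic and leaves the RNG state alone", {
  set.seed(3)
  counts <- sapply(1:6, function(i) rnbinom(500, mu = 300, size = 10))
  cm <- make_cm(counts, rep(c("A", "B"), each = 3))
  set.seed(99); r1 <- nb_differential(cm, c("A", "B"))
  after1 <- runif(1)
  set.seed(99); r2 <- nb_differential(cm, c("A", "B"))
  after2 <- runif(1)
  expect_identical(r1, r2)
  expect_identical(after1, after2)
})

test_that("Mann-Whitney exact path matches frozen and enumerated values", {
  res <- mw_gene_set_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_less, 1 / 20)  # full enumeration of C(6,3) splits
  expect_equal(res$p, 2 / 20)
  expect_true(res$exact)

  # identical multisets: symmetric, two-sided p = 1
  same <- mw_gene_set_test(c(1, 2, 2), c(2, 1, 2))
  expect_equal(same$p, 1)
  expect_error(mw_gene_set_test(numeric(0), 1:3), "empty")
})

test_that("exact Mann-Whitney agrees with an independent pair-counting oracle", {
  set.seed(17)
  for (rep in 1:25) {
    n_a <- sample(2:6, 1); n_b <- sample(2:6, 1)
    vals <- sample(1:5, n_a + n_b, replace = TRUE)  # ties likely
    a <- vals[seq_len(n_a)]; b <- vals[-seq_len(n_a)]
    res <- mw_gene_set_test(a, b)
    # oracle: U by counting pairs, null by enumerating all group splits
    u_of <- function(x, y) {
      sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    }
    expect_equal(res$U, u_of(a, b))
    splits <- combn(n_a + n_b, n_a)
    null_u <- apply(splits, 2, function(ii) u_of(vals[ii], vals[-ii]))
    expect_equal(res$p_less, mean(null_u <= res$U))
    expect_equal(res$p_greater, mean(null_u >= res$U))
    expect_equal(res$p, min(1, 2 * min(res$p_less, res$p_greater)))
  }
})

test_that("tie-free exact null matches the Wilcoxon distribution", {
  set.seed(2)
  for (rep in 1:10) {
    n_a <- sample(3:6, 1); n_b <- sample(3:6, 1)
    vals <- sample(1:1000, n_a + n_b)
    res <- mw_gene_set_test(vals[seq_len(n_a)], vals[-seq_len(n_a)])
    expect_equal(res$p_less, pwilcox(res$U, n_a, n_b))
  }
})

test_that("normal approximation tracks the exact p at moderate sizes", {
  set.seed(13)
  a <- rnorm(8); b <- rnorm(8, 1)
  exact <- mw_gene_set_test(a, b, exact_max = 8)
  approx <- mw_gene_set_test(a, b, exact_max = 7)
  expect_false(approx$exact)
  expect_lt(abs(approx$p - exact$p) / exact$p, 0.10)
})

test_that("p-value adjustment follows BH step-up and Bonferroni", {
  expect_equal(adjust_pvalues(0.01, "BH"), 0.01)
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  expect_equal(adjust_pvalues(c(0.4, 0.6), "bonferroni"), c(0.8, 1.0))
  expect_error(adjust_pvalues(c(0.5, 1.2), "BH"), "0, 1")

  set.seed(4)
  p <- runif(100)
  adj <- adjust_pvalues(p, "BH")
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj >= p))
})

test_that("volcano table keeps peaks of strongly differential genes only", {
  diff_genes <- data.frame(feature_id = c("g1", "g2"),
                           class_a = "A", class_b = "B",
                           log2fc = c(3, -2), p = c(1e-10, 0.5),
                           adj_p = c(1e-9, 0.6))
  diff_peaks <- data.frame(feature_id = c("p1", "p2", "p3"),
                           class_a = "A", class_b = "B",
                           log2fc = c(2, -1, 1), p = c(1e-5, 1e-4, 0.2),
                           adj_p = c(1e-4, 1e-3, 0.3))
  asn <- data.frame(peak_id = c("p1", "p2", "p3"),
                    gene_id = c("g1", "g1", "g2"))
  v <- volcano_table(diff_peaks, diff_genes, asn, gene_filter_p = 1e-6)
  expect_setequal(v$peak_id, c("p1", "p2"))
  # positive correlation iff peak and gene fold changes agree in sign
  expect_true(v$positively_correlated[v$peak_id == "p1"])
  expect_false(v$positively_correlated[v$peak_id == "p2"])

  none <- volcano_table(diff_peaks,
                        transform(diff_genes, adj_p = c(0.5, 0.6)), asn)
  expect_equal(nrow(none), 0)
})

test_that("coupled synthetic peaks are mostly positively correlated", {
  ds <- shared_dataset()
  res <- shared_pipeline()
  v <- volcano_table(res$diff_peaks[["L4|L6"]], res$diff_genes[["L4|L6"]],
                     res$assignments, gene_filter_p = 1e-6)
  expect_gt(nrow(v), 50)
  # restrict to clearly differential peaks, as in the study's summaries
  strong <- v[v$neg_log10_p > 3, ]
  expect_gte(mean(strong$positively_correlated), 0.9)
})

test_that("pairwise gene-set comparison separates direction groups", {
  res <- shared_pipeline()
  mw <- pairwise_gene_set_mw(res$peak_class_scores,
                             res$diff_genes[["L4|L6"]],
                             res$assignments, c("L4", "L6"))
  expect_equal(nrow(mw), 2)
  expect_true(all(mw$adj_p < 0.05))
  # peaks of L4-high genes are more accessible in L4, and vice versa
  u_norm <- mw$U / (mw$n_a * mw$n_b)
  expect_gt(u_norm[mw$higher_in == "L4"], 0.5)
  expect_lt(u_norm[mw$higher_in == "L6"], 0.5)
})
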