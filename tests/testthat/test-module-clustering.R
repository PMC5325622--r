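test_that("default module patterns are the eight binary layer patterns", {
  pat <- default_module_patterns()
  expect_equal(dim(pat), c(8, 4))
  expect_equal(unname(pat["Upper+", ]), c(1, 1, 0, 0))
  expect_equal(unname(pat["L4-", ]), c(1, 0, 1, 1))
  expect_equal(rownames(pat),
               c("L2/3+", "L4+", "L5+", "L6+", "Upper+", "Lower+",
                 "L4-", "L6-"))
})

test_that("row scaling follows the min-max formula and drops constants", {
  m <- rbind(a = c(2, 4, 6, 10), b = c(5, 5, 5, 5), c = c(0, 1, 0.5, 0.25))
  expect_message(sc <- scale_rows(m), "constant")
  expect_equal(unname(sc["a", ]), c(0, 0.25, 0.5, 1))
  expect_false("b" %in% rownames(sc))
  # idempotent on already-scaled rows
  expect_equal(scale_rows(sc), sc)
})

test_that("module feature selection applies the joint p and fold filters", {
  scores <- rbind(hit = c(100, 100, 10, 10), weak = c(30, 30, 10, 10),
                  ns = c(100, 100, 10, 10))
  colnames(scores) <- c("L2/3", "L4", "L5", "L6")
  d <- data.frame(feature_id = c("hit", "weak", "ns"),
                  class_a = "L2/3", class_b = "L5",
                  log2fc = c(3.3, 1.6, 3.3), p = c(1e-8, 1e-8, 0.5),
                  adj_p = c(1e-7, 1e-7, 0.6))
  sel <- select_module_features(list(d), scores, "peak")
  expect_equal(sel, "hit")  # "weak" fails 4-fold, "ns" fails adj p
  # gene thresholds: raw p < 0.05 and 2-fold
  sel_g <- select_module_features(list(d), scores, "gene")
  expect_setequal(sel_g, c("hit", "weak"))
  expect_length(select_module_features(list(), scores, "peak"), 0)
})

test_that("binarization thresholds at 0.5 with the declared tie rule", {
  expect_equal(binarize_centers(matrix(c(0.6, 0.4, 0.5, 0))),
               matrix(c(1, 0, 1, 0)))
})

test_that("exploratory k-means: degenerate k, planted patterns, determinism", {
  set.seed(33)
  pat <- default_module_patterns()
  x <- pat[rep(1:8, each = 30), ] + matrix(rnorm(8 * 30 * 4, 0, 0.08),
                                           240, 4)
  x <- pmin(pmax(x, 0), 1)
  rownames(x) <- sprintf("f%03d", 1:240)

  few <- x[1:10, ]
  fit_n <- kmeans_explore(few, k = 10, seed = 2)
  expect_equal(fit_n$inertia, 0, tolerance = 1e-12)
  expect_error(kmeans_explore(few, k = 11), "exceeds")

  fit <- kmeans_explore(x, k = 15, restarts = 10, seed = 4)
  expect_identical(fit$cluster,
                   kmeans_explore(x, k = 15, restarts = 10, seed = 4)$cluster)
  bin_pats <- unique(apply(binarize_centers(fit$centers), 1, paste,
                           collapse = ""))
  expect_gte(length(bin_pats), 8)

  # sanity: our Lloyd inertia is no worse than stats::kmeans on this data
  ref <- stats::kmeans(x, 15, nstart = 10, iter.max = 100)
  expect_lt(fit$inertia, ref$tot.withinss * 1.2)
})

test_that("seeded k-means is a fixpoint on the seed patterns themselves", {
  pat <- default_module_patterns()
  profiles <- pat[rep(1:8, 3), ]
  rownames(profiles) <- sprintf("f%02d", 1:24)
  ms <- kmeans_seeded(profiles)
  expect_equal(unname(ms$membership), rep(rownames(pat), 3))
  expect_equal(ms$centers, pat)
  expect_identical(ms$membership, kmeans_seeded(profiles)$membership)
  # every member is closest to its own center at convergence
  d2 <- as.matrix(stats::dist(rbind(profiles, ms$centers)))
  d2 <- d2[1:24, 25:32]
  expect_equal(colnames(d2)[max.col(-d2, ties.method = "first")],
               unname(ms$membership))
})

test_that("an empty cluster keeps its seed center", {
  pat <- default_module_patterns()
  profiles <- pat[rep(1:4, each = 5), ] # no members near the last 4 seeds
  rownames(profiles) <- sprintf("f%02d", 1:20)
  ms <- kmeans_seeded(profiles)
  expect_equal(ms$sizes[["Lower+"]], 0L)
  expect_equal(ms$centers["Lower+", ], pat["Lower+", ])
})

test_that("planted modules are recovered from the synthetic dataset", {
  ds <- shared_dataset()
  res <- shared_pipeline()
  sel <- names(res$peak_modules$membership)
  ari <- adjusted_rand_index(res$peak_modules$membership,
                             truth_labels(ds$truth$peak_module_of, sel))
  expect_gte(ari, 0.9)
  gsel <- names(res$gene_modules$membership)
  ari_g <- adjusted_rand_index(res$gene_modules$membership,
                               truth_labels(ds$truth$gene_module_of, gsel))
  expect_gte(ari_g, 0.85)
})

test_that("selection filters behave on null and planted features", {
  ds <- shared_dataset()
  res <- shared_pipeline()
  truth <- ds$truth$peak_module_of
  sel <- names(res$peak_modules$membership)
  null_ids <- names(truth)[is.na(truth)]
  expect_lte(mean(null_ids %in% sel), 0.02)
  module_ids <- names(truth)[!is.na(truth)]
  expect_gte(mean(module_ids %in% sel), 0.95)
})

test_that("gene-module assignment by correlation handles all cases", {
  centers <- default_module_patterns()
  expr <- rbind(match = c(10, 1, 1, 1),    # L2/3+ shape
                anti = c(1, 10, 10, 10),   # complement of L2/3+
                flat = c(5, 5, 5, 5))
  colnames(expr) <- colnames(centers)
  asn <- assign_gene_module_by_correlation(expr, centers)
  expect_equal(asn$module[1], "L2/3+")
  expect_equal(asn$r[1], 1)
  # anti-pattern lands on the best-correlated complementary pattern
  r_all <- cor(expr["anti", ], t(centers))[1, ]
  expect_equal(asn$module[2], names(which.max(r_all)))
  expect_true(is.na(asn$module[3]))
})

test_that("sample clustering groups replicates of the same class", {
  res <- shared_pipeline()
  sc <- res$scores$scores
  pv <- res$diff_peaks[[1]]$adj_p
  names(pv) <- res$diff_peaks[[1]]$feature_id
  expect_warning(hc <- hclust_samples(sc, pv, top_n = 7500), "top_n")
  expect_true(all(diff(hc$height) >= -1e-9))
  cl <- cutree(hc, k = length(unique(sub("_rep.*", "", colnames(sc)))))
  expect_equal(length(unique(paste(cl, sub("_rep.*", "", colnames(sc))))),
               length(unique(cl)))

  # duplicated sample columns merge first at height 0
  dup <- cbind(sc[, 1, drop = FALSE], sc)
  colnames(dup)[1] <- "copy"
  hc2 <- hclust_samples(dup, pv, top_n = nrow(dup))
  expect_equal(min(hc2$height), 0, tolerance = 1e-12)

  f <- withr::local_tempfile()
  dendrogram_newick(hc, f)
  tree <- ape::read.tree(f)
  expect_setequal(tree$tip.label, colnames(sc))
})
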