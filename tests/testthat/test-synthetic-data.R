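test_that("configuration enforces the planted-effect constraints", {
  expect_error(simulation_config(fold_change = 3), "exceed 4")
  expect_error(simulation_config(frac_null = 1), "frac_null")
  cfg <- simulation_config()
  expect_equal(cfg$fold_change, 6)
  expect_equal(cfg$nb_dispersion, 0.1)
  expect_equal(cfg$classes, c("L2/3", "L4", "L5", "L6"))
})

test_that("annotation places peaks resolvable by the nearest-TSS rule", {
  cfg <- simulation_config(seed = 3, n_genes = 60, n_peaks = 300)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$tss), 60)
  expect_gte(length(ann$peaks), 60)
  expect_equal(length(ann$peaks), 300)

  # brute-force nearest TSS equals the intended gene for every peak
  mids <- ann$peaks$midpoint0
  for (i in seq_along(ann$peaks)) {
    d <- abs(mids[i] - ann$tss$pos)
    expect_equal(ann$tss$gene_id[which.min(d)], ann$peaks$gene_of[i])
  }
  # all six distance bins populated at this size
  expect_setequal(unique(ann$peaks$planted_bin), c(-3, -2, -1, 1, 2, 3))
})

test_that("counts are reproducible and carry the planted fold change", {
  ds <- shared_dataset()
  cfg <- ds$config
  truth <- list(peaks = ds$peaks, gene_table = NULL)
  # identical seed reproduces identical matrices
  ds2_counts <- local({
    gt <- data.frame(gene_id = rownames(ds$truth$class_means$genes))
    gt$module <- unname(ds$truth$gene_module_of[gt$gene_id])
    generate_counts(cfg, list(peaks = ds$peaks, gene_table = gt,
                              edges = ds$truth$network_edges))
  })
  expect_identical(ds2_counts$peak_counts$counts, ds$peak_counts$counts)

  # planted L4+ peaks: empirical mean ratio L4 over L2/3 within [5, 7]
  l4 <- names(ds$truth$peak_module_of)[
    !is.na(ds$truth$peak_module_of) & ds$truth$peak_module_of == "L4+"]
  cls <- ds$peak_counts$sample_class
  m_l4 <- rowMeans(ds$peak_counts$counts[l4, cls == "L4", drop = FALSE])
  m_l23 <- rowMeans(ds$peak_counts$counts[l4, cls == "L2/3", drop = FALSE])
  ratio <- mean(m_l4) / mean(m_l23)
  expect_gt(ratio, 5); expect_lt(ratio, 7)
})

test_that("an all-null simulation yields almost no differential calls", {
  cfg <- simulation_config(seed = 44, frac_null = 0.999, n_genes = 200,
                           n_peaks = 1200, include_gaba = FALSE)
  ann <- generate_annotation(cfg)
  planted <- layerreg:::plant_peak_structure(cfg, ann)
  planted$peaks$module <- NA_character_  # ignore forced edge hosts
  counts <- generate_counts(cfg, list(peaks = planted$peaks,
                                      gene_table = ann$gene_table))
  d <- nb_differential(counts$peak_counts, c("L4", "L6"),
                       factors = tmm_factors(counts$peak_counts))
  expect_lte(mean(d$adj_p < 0.01), 0.02)
})

test_that("sequences carry exactly the recorded motif placements", {
  ds <- shared_dataset()
  hits <- shared_pipeline()$hits
  pl <- ds$truth$motif_placements
  key <- function(df) paste(df$motif_id, df$peak_id, df$offset, df$strand)
  expect_setequal(key(hits), key(pl))
  # placement rate ratio, target module vs background, near the planted 5x
  egr <- pl[pl$motif_id == "M_EGR", ]
  mod <- ds$truth$peak_module_of
  in_mod <- names(mod)[!is.na(mod) & mod == "L2/3+"]
  tf_genes <- ds$tf_table$gene_id
  bg_univ <- setdiff(names(ds$peaks)[!(ds$peaks$gene_of %in% tf_genes)],
                     in_mod)
  fg_univ <- setdiff(in_mod, names(ds$peaks)[ds$peaks$gene_of %in% tf_genes])
  rate_fg <- length(intersect(egr$peak_id, fg_univ)) / length(fg_univ)
  rate_bg <- length(intersect(egr$peak_id, bg_univ)) / length(bg_univ)
  expect_gt(rate_fg / rate_bg, 3)
  expect_lt(rate_fg / rate_bg, 8)
})

test_that("background base composition matches the configured GC", {
  ds <- shared_dataset()
  freq <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(ds$sequences))[, c("A", "C", "G", "T")])
  freq <- freq / sum(freq)
  expect_true(all(abs(freq - 0.25) < 0.01))
})

test_that("fragment sets show FRiP and nucleosomal length structure", {
  ds <- shared_dataset()
  fr <- ds$fragments[["L2/3"]]
  expect_equal(length(fr), ds$config$fragments_per_class)
  f <- frip(fr, ds$peaks)
  expect_gt(f, 0.18); expect_lt(f, 0.45)
  modes <- histogram_modes(insert_size_histogram(fr))
  expect_gte(length(modes), 3)
})

test_that("a depletion-free generator leaves flat footprints", {
  cfg <- simulation_config(seed = 15, footprint_depletion = 0,
                           n_genes = 80, n_peaks = 400,
                           fragments_per_class = 150000,
                           include_gaba = FALSE, scrub_sequences = FALSE)
  ann <- generate_annotation(cfg)
  planted <- layerreg:::plant_peak_structure(cfg, ann)
  truth <- list(peaks = planted$peaks, edges = planted$edges,
                gene_table = ann$gene_table)
  counts <- generate_counts(cfg, truth)
  pwms <- random_pwms(paste0("M_", c("EGR", "FOS")), length = 10)
  sq <- generate_sequences_and_hits(cfg, truth, pwms)
  frags <- generate_fragments(cfg, c(truth, list(
    placements = sq$placements, pwms = pwms,
    peak_units = counts$peak_units)))
  pl <- utils::head(sq$placements[sq$placements$motif_id == "M_EGR", ], 30)
  hits <- data.frame(motif_id = pl$motif_id, peak_id = pl$peak_id,
                     offset = pl$offset, strand = pl$strand, width = 10,
                     score = 1, p = 1e-5)
  prof <- insertion_profile(frags[["L2/3"]], hits, planted$peaks)
  expect_lt(abs(footprint_depth(prof) - 1), 0.15)
})

test_that("the written dataset round-trips through the file formats", {
  ds <- shared_dataset()
  out <- withr::local_tempdir()
  write_synthetic_dataset(ds, out)
  pk <- read_peaks_bed(file.path(out, "peaks.bed"))
  expect_equal(length(pk), length(ds$peaks))
  expect_equal(GenomicRanges::ranges(pk), GenomicRanges::ranges(ds$peaks))
  cm <- read_count_matrix(file.path(out, "peak_counts.tsv"),
                          file.path(out, "peak_sample_classes.tsv"))
  expect_equal(cm$counts, ds$peak_counts$counts)
  seqs <- read_peak_fasta(file.path(out, "peak_sequences.fa"))
  expect_equal(as.character(seqs), unname(ds$sequences),
               ignore_attr = TRUE)
  motifs <- read_meme_motifs(file.path(out, "motifs.meme"))
  expect_length(motifs, length(ds$pwms))
  truth <- jsonlite::read_json(file.path(out, "truth.json"))
  expect_named(truth, c("peak_module_of", "gene_module_of",
                        "motif_placements", "network_edges",
                        "class_means", "params"), ignore.order = TRUE)
})
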