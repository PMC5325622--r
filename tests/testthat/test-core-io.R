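test_that("BED peaks read with field mapping, auto ids, and validation", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t250\tp1", "chr2\t0\t50\tp2"), f)
  pk <- read_peaks_bed(f)
  expect_equal(names(pk), c("p1", "p2"))
  expect_equal(GenomicRanges::start(pk), c(101L, 1L))
  expect_equal(GenomicRanges::end(pk), c(250L, 50L))

  writeLines(c("chr1\t100\t250", "chr1\t300\t400"), f)
  pk3 <- read_peaks_bed(f)
  expect_equal(names(pk3), c("peak_000001", "peak_000002"))

  writeLines("chr1\t250\t100", f)
  expect_error(read_peaks_bed(f), "end <= start")
  writeLines(c("chr1\t100\t250\tok", "chr1\t500"), f)
  expect_error(read_peaks_bed(f), "line 2")
})

test_that("BED write/read round trip is byte-identical for canonical BED4", {
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  lines <- c("chr1\t100\t250\tp1", "chr1\t300\t420\tp2", "chr2\t5\t80\tp3")
  writeLines(lines, f1)
  write_peaks_bed(read_peaks_bed(f1), f2)
  expect_identical(readLines(f2), lines)
})

test_that("TSS table reading keeps isoform duplicates and validates strand", {
  f <- withr::local_tempfile()
  write.table(data.frame(gene_id = c("g1", "g1", "g2"), chrom = "chr1",
                         pos = c(5000, 5200, 9000),
                         strand = c("+", "+", "-")),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  tss <- read_tss_table(f)
  expect_equal(nrow(tss), 3)
  expect_equal(sum(tss$gene_id == "g1"), 2)

  write.table(data.frame(gene_id = "g1", chrom = "chr1", pos = 5,
                         strand = "."),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_tss_table(f), "strand")
})

test_that("MEME minimal parser: blocks, background default, consensus", {
  f <- withr::local_tempfile()
  writeLines(c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    "MOTIF m1",
    "letter-probability matrix: alength= 4 w= 2 nsites= 20 E= 0",
    " 1.0 0.0 0.0 0.0", " 0.0 1.0 0.0 0.0",
    "",
    "MOTIF m2",
    "letter-probability matrix: alength= 4 w= 3 nsites= 20 E= 0",
    " 0.25 0.25 0.25 0.25", " 0.1 0.2 0.3 0.4", " 0.0 0.0 0.0 1.0"), f)
  pwms <- read_meme_motifs(f)
  expect_length(pwms, 2)
  expect_equal(pwm_consensus(pwms[[1]]), "AC")
  expect_equal(pwms[[1]]$background, rep(0.25, 4))

  # explicit background is picked up
  writeLines(c(
    "MEME version 4", "", "Background letter frequencies",
    "A 0.3 C 0.2 G 0.2 T 0.3", "",
    "MOTIF m1",
    "letter-probability matrix: alength= 4 w= 1 nsites= 20 E= 0",
    " 0.5 0.5 0.0 0.0"), f)
  expect_equal(read_meme_motifs(f)[[1]]$background, c(0.3, 0.2, 0.2, 0.3))
})

test_that("MEME parser warns on drifting rows and rejects other alphabets", {
  f <- withr::local_tempfile()
  writeLines(c(
    "MEME version 4", "",
    "MOTIF bad",
    "letter-probability matrix: alength= 4 w= 1 nsites= 20 E= 0",
    " 0.5 0.4 0.0 0.0"), f)
  expect_warning(read_meme_motifs(f), "deviate")

  writeLines(c("MEME version 4", "", "ALPHABET= ACGU", ""), f)
  expect_error(read_meme_motifs(f), "ACGT")
})

test_that("MEME write/read round trip preserves probabilities", {
  f <- withr::local_tempfile()
  pwms <- random_pwms(c("a", "b"), length = 6)
  write_meme_motifs(pwms, f)
  back <- read_meme_motifs(f)
  expect_equal(back[[1]]$probs, pwms[[1]]$probs, tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(vapply(back, function(p) p$motif_id, ""), c("a", "b"))
})

test_that("merging takes outer boundaries of strict overlaps only", {
  a <- make_peaks(c(10, 40), c(50, 80), ids = c("a1", "a2"))
  m <- merge_overlapping_peaks(list(a))
  expect_length(m, 1)
  expect_equal(GenomicRanges::start(m) - 1L, 10)
  expect_equal(GenomicRanges::end(m), 80)
  expect_setequal(m$source_peaks[[1]], c("a1", "a2"))

  # abutting half-open intervals do not merge
  b <- make_peaks(c(10, 50), c(50, 80))
  expect_length(merge_overlapping_peaks(list(b)), 2)
})

test_that("merging matches a brute-force union oracle and is idempotent", {
  set.seed(31)
  starts <- sample(1:5000, 300)
  ends <- starts + sample(10:200, 300, replace = TRUE)
  pk <- make_peaks(starts, ends)
  m <- merge_overlapping_peaks(list(pk))

  # independent sweep oracle over sorted 0-based half-open intervals
  o <- order(starts, ends)
  s <- starts[o]; e <- ends[o]
  merged <- list(); cs <- s[1]; ce <- e[1]
  for (i in 2:length(s)) {
    if (s[i] < ce) ce <- max(ce, e[i]) else {
      merged[[length(merged) + 1]] <- c(cs, ce); cs <- s[i]; ce <- e[i]
    }
  }
  merged[[length(merged) + 1]] <- c(cs, ce)
  oracle <- do.call(rbind, merged)
  expect_equal(GenomicRanges::start(m) - 1L, oracle[, 1])
  expect_equal(GenomicRanges::end(m), oracle[, 2])

  # idempotent and order-invariant over input sets
  m2 <- merge_overlapping_peaks(list(m))
  expect_equal(GenomicRanges::ranges(m2), GenomicRanges::ranges(m))
  half <- sample(300, 150)
  m3 <- merge_overlapping_peaks(list(pk[half], pk[-half]))
  expect_equal(GenomicRanges::ranges(m3), GenomicRanges::ranges(m))
})

test_that("count matrix validates and survives a TSV round trip", {
  counts <- matrix(rpois(12, 50), 4, 3,
                   dimnames = list(paste0("f", 1:4), paste0("s", 1:3)))
  cls <- setNames(c("A", "A", "B"), paste0("s", 1:3))
  cm <- count_matrix(counts, cls)
  expect_equal(count_matrix_classes(cm), c("A", "B"))
  expect_error(count_matrix(counts - 100, cls), "non-negative")
  expect_error(count_matrix(counts, cls[1:2]), "class")

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_count_matrix(cm, f1, f2)
  back <- read_count_matrix(f1, f2)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$sample_class, cm$sample_class)
})

test_that("fragment BED round trip preserves coordinates and samples", {
  gr <- GenomicRanges::GRanges("chrS", IRanges::IRanges(c(11, 51), c(110, 95)),
                               strand = c("+", "-"))
  gr$sample_id <- c("L4_rep1", "L4_rep1")
  f <- withr::local_tempfile()
  write_fragments_bed(gr, f)
  back <- read_fragments_bed(f)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_equal(back$sample_id, gr$sample_id)
})
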