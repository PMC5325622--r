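#' @import methods
#' @importFrom stats cor dist hclust ks.test p.adjust pnorm rnbinom runif
#'   setNames var lowess approx fisher.test rlnorm cutree
#' @importFrom utils read.delim write.table head combn
NULL

# Internal coordinate convention: BED-style 0-based half-open on disk,
# GRanges (1-based closed) in memory. start1 = start0 + 1, end1 = end0.

#' Construct a peak GRanges from 0-based half-open coordinates
#'
#' Peaks are represented throughout the package as a
#' [GenomicRanges::GRanges] whose `names` are unique peak identifiers.
#'
#' @param chrom Chromosome names.
#' @param start 0-based start positions.
#' @param end End positions (half-open; must satisfy `end > start`).
#' @param id Peak identifiers; auto-generated (`peak_000001`, ...) when `NULL`.
#' @return A `GRanges` with one range per peak, names set to the peak ids.
#' @export
peaks_from_bed_coords <- function(chrom, start, end, id = NULL) {
  if (any(start < 0)) stop("peak start positions must be >= 0")
  if (any(end <= start)) {
    bad <- which(end <= start)[1]
    stop(sprintf("peak %d has end <= start (%d <= %d)", bad, end[bad], start[bad]))
  }
  if (any(!nzchar(chrom))) stop("chrom must be non-empty")
  if (is.null(id)) id <- sprintf("peak_%06d", seq_along(chrom))
  if (anyDuplicated(id)) stop("peak ids must be unique")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  names(gr) <- id
  gr
}

#' Read peaks from a BED3/BED4 file
#'
#' Parses a tab-separated BED file into a peak `GRanges`. Coordinates are
#' 0-based half-open as in BED; ids come from column 4 when present and are
#' auto-generated otherwise.
#'
#' @param path Path to a BED file with at least 3 tab-separated columns.
#' @return A `GRanges` of peaks (see [peaks_from_bed_coords()]).
#' @export
read_peaks_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("malformed BED line %d: fewer than 3 tab-separated columns",
                 which(nf < 3)[1]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("malformed BED line %d: non-integer coordinates",
                 which(is.na(start) | is.na(end))[1]))
  }
  if (any(end <= start)) {
    stop(sprintf("invalid interval at line %d: end <= start",
                 which(end <= start)[1]))
  }
  id <- if (all(nf >= 4)) vapply(fields, `[[`, "", 4L) else NULL
  peaks_from_bed_coords(chrom, start, end, id)
}

#' Write peaks to a 4-column BED file
#'
#' Inverse of [read_peaks_bed()]; the round trip is byte-identical for
#' canonical 4-column BED input.
#'
#' @param peaks Peak `GRanges`.
#' @param path Output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  lines <- sprintf("%s\t%d\t%d\t%s",
                   as.character(GenomicRanges::seqnames(peaks)),
                   GenomicRanges::start(peaks) - 1L,
                   GenomicRanges::end(peaks),
                   names(peaks))
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Expects a tab-separated file with header columns `gene_id`, `chrom`,
#' `pos` (0-based TSS position) and `strand`. One gene may appear on several
#' rows (isoform TSSs); duplicates are retained.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `gene_id`, `chrom`, `pos`, `strand`.
#' @export
read_tss_table <- function(path) {
  tss <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "chrom", "pos", "strand")
  missing <- setdiff(required, names(tss))
  if (length(missing)) stop("TSS table lacks columns: ", paste(missing, collapse = ", "))
  tss <- tss[required]
  if (!all(tss$strand %in% c("+", "-"))) {
    stop("TSS strand must be '+' or '-'")
  }
  if (any(tss$pos < 0)) stop("TSS positions must be >= 0")
  tss
}

#' Write a TSS annotation table
#' @param tss Data.frame as returned by [read_tss_table()].
#' @param path Output path.
#' @export
write_tss_table <- function(tss, path) {
  write.table(tss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a replicate-level count matrix
#'
#' The container used for both peak fragment counts and gene expression
#' counts: an integer matrix (features x samples) plus a sample-to-class map.
#'
#' @param counts Non-negative integer matrix with feature ids as rownames and
#'   sample ids as colnames.
#' @param sample_class Named character vector mapping every sample id to a
#'   cell-class label.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, sample_class) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have feature rownames and sample colnames")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (!all(colnames(counts) %in% names(sample_class))) {
    stop("every sample must be mapped to a class")
  }
  structure(
    list(counts = counts,
         sample_class = sample_class[colnames(counts)]),
    class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples (%d classes)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$sample_class))))
  invisible(x)
}

#' Classes of a count matrix in first-appearance order
#' @param cm A `count_matrix`.
#' @return Character vector of class labels.
#' @export
count_matrix_classes <- function(cm) unique(unname(cm$sample_class))

#' Write / read a count matrix as TSV
#'
#' The matrix is written as `feature_id` plus one column per sample; the
#' sample-to-class map goes to a companion two-column TSV.
#'
#' @param cm A `count_matrix`.
#' @param path Matrix TSV path.
#' @param class_path Sample-class TSV path.
#' @export
write_count_matrix <- function(cm, path, class_path) {
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = names(cm$sample_class),
                         class = unname(cm$sample_class)),
              class_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path, class_path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  cls <- read.delim(class_path, stringsAsFactors = FALSE)
  count_matrix(counts, setNames(cls$class, cls$sample_id))
}

#' Read fragments from a BED file
#'
#' Fragments are sequenced ATAC-seq read pairs: each BED row is one fragment
#' (0-based half-open), column 4 the sample id, column 6 the strand when
#' present. Returned as a `GRanges` with a `sample_id` metadata column; the
#' library size of a fragment set is its length.
#'
#' @param path BED path.
#' @return `GRanges` of fragments.
#' @export
read_fragments_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("fragment BED needs >= 4 columns (chrom,start,end,sample)")
  strand <- if (ncol(df) >= 6) df[[6]] else "*"
  gr <- GenomicRanges::GRanges(df[[1]], IRanges::IRanges(df[[2]] + 1L, df[[3]]),
                               strand = strand)
  gr$sample_id <- df[[4]]
  gr
}

#' Write fragments to BED
#' @param frags Fragment `GRanges` with `sample_id` metadata column.
#' @param path Output path.
#' @export
write_fragments_bed <- function(frags, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   as.character(GenomicRanges::seqnames(frags)),
                   GenomicRanges::start(frags) - 1L,
                   GenomicRanges::end(frags),
                   frags$sample_id,
                   as.character(GenomicRanges::strand(frags)))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a position weight matrix object
#'
#' @param motif_id Motif identifier.
#' @param probs Numeric matrix (length x 4), columns A, C, G, T; each row a
#'   probability distribution.
#' @param background Background nucleotide distribution (length 4, sums to 1).
#' @param pseudocount Pseudocount already applied during normalization
#'   (recorded for provenance).
#' @return An object of class `pwm`.
#' @export
pwm <- function(motif_id, probs, background = rep(0.25, 4), pseudocount = 0) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) stop("pwm probs must have 4 columns (A,C,G,T)")
  if (nrow(probs) < 1) stop("pwm must have length >= 1")
  colnames(probs) <- c("A", "C", "G", "T")
  if (any(abs(rowSums(probs) - 1) > 1e-9)) stop("pwm rows must sum to 1")
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  structure(list(motif_id = motif_id, probs = probs,
                 background = background, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cons <- paste(c("A", "C", "G", "T")[max.col(x$probs)], collapse = "")
  cat(sprintf("pwm %s (length %d, consensus %s)\n", x$motif_id,
              nrow(x$probs), cons))
  invisible(x)
}

#' Read motifs in MEME minimal format
#'
#' Parses letter-probability matrices from a MEME minimal-format file. Rows
#' are renormalized after adding `pseudocount * background`; the background
#' distribution is taken from the file's "Background letter frequencies"
#' block and defaults to uniform when absent. Only the ACGT alphabet is
#' supported.
#'
#' @param path MEME file path.
#' @param pseudocount Pseudocount weight added (times background) to each
#'   probability before renormalization.
#' @return List of [pwm()] objects.
#' @export
read_meme_motifs <- function(path, pseudocount = 0) {
  lines <- readLines(path)
  alpha_line <- grep("^ALPHABET", lines, value = TRUE)
  if (length(alpha_line) && !grepl("ACGT", gsub("[ =]", "", alpha_line[1]))) {
    stop("only the ACGT alphabet is supported")
  }
  background <- rep(0.25, 4)
  bg_at <- grep("^Background letter frequencies", lines)
  if (length(bg_at)) {
    bg_toks <- strsplit(trimws(lines[bg_at[1] + 1]), "\\s+")[[1]]
    freq <- as.numeric(bg_toks[seq(2, length(bg_toks), by = 2)])
    names(freq) <- bg_toks[seq(1, length(bg_toks), by = 2)]
    if (!all(c("A", "C", "G", "T") %in% names(freq))) {
      stop("malformed background line")
    }
    background <- unname(freq[c("A", "C", "G", "T")])
  }
  motif_at <- grep("^MOTIF", lines)
  out <- vector("list", length(motif_at))
  bounds <- c(motif_at, length(lines) + 1L)
  for (i in seq_along(motif_at)) {
    block <- lines[motif_at[i]:(bounds[i + 1] - 1L)]
    motif_id <- strsplit(trimws(block[1]), "\\s+")[[1]][2]
    lp <- grep("^letter-probability matrix", block)
    if (!length(lp)) stop("MOTIF block without letter-probability matrix: ", motif_id)
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", block[lp[1]]))
    rows <- block[(lp[1] + 1):(lp[1] + w)]
    probs <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }))
    if (ncol(probs) != 4) stop("motif ", motif_id, " is not over a 4-letter alphabet")
    bad <- abs(rowSums(probs) - 1) > 1e-3
    if (any(bad)) {
      warning(sprintf("motif %s: %d rows deviate from sum 1 by > 1e-3 before normalization",
                      motif_id, sum(bad)))
    }
    probs <- probs + pseudocount * matrix(background, nrow(probs), 4, byrow = TRUE)
    probs <- probs / rowSums(probs)
    out[[i]] <- pwm(motif_id, probs, background, pseudocount)
  }
  out
}

#' Write motifs in MEME minimal format
#' @param pwms List of [pwm()] objects (sharing one background).
#' @param path Output path.
#' @export
write_meme_motifs <- function(pwms, path) {
  bg <- pwms[[1]]$background
  lines <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
             "Background letter frequencies",
             sprintf("A %.6f C %.6f G %.6f T %.6f", bg[1], bg[2], bg[3], bg[4]),
             "")
  for (p in pwms) {
    lines <- c(lines,
               paste("MOTIF", p$motif_id),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       nrow(p$probs)),
               apply(p$probs, 1, function(r) sprintf(" %.6f %.6f %.6f %.6f",
                                                     r[1], r[2], r[3], r[4])),
               "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Consensus sequence of a PWM
#' @param p A [pwm()] object.
#' @return Character string of most probable bases.
#' @export
pwm_consensus <- function(p) {
  paste(c("A", "C", "G", "T")[max.col(p$probs, ties.method = "first")],
        collapse = "")
}

#' Merge overlapping peaks across peak sets
#'
#' Takes one or more peak sets and forms maximal union intervals from all
#' strictly overlapping peaks (outer boundaries). Abutting half-open
#' intervals (`end == start`) do not merge. Each merged peak records the ids
#' of its contributing source peaks in the `source_peaks` metadata column.
#'
#' @param peak_sets A list of peak `GRanges` (or a single `GRanges`).
#' @return Sorted merged peak `GRanges` with ids `merged_000001`, ...
#' @export
merge_overlapping_peaks <- function(peak_sets) {
  if (inherits(peak_sets, "GRanges")) peak_sets <- list(peak_sets)
  if (!length(peak_sets)) stop("need at least one peak set")
  all_ids <- unlist(lapply(peak_sets, names), use.names = FALSE)
  pooled <- suppressWarnings(do.call(c, lapply(peak_sets, function(g) {
    GenomicRanges::granges(g, use.names = FALSE)
  })))
  if (is.null(all_ids)) all_ids <- sprintf("input_%06d", seq_along(pooled))
  merged <- GenomicRanges::reduce(pooled, min.gapwidth = 0L, with.revmap = TRUE)
  merged <- GenomicRanges::sort(merged)
  src <- lapply(merged$revmap, function(ii) all_ids[ii])
  merged$revmap <- NULL
  merged$source_peaks <- S4Vectors::SimpleList(src)
  names(merged) <- sprintf("merged_%06d", seq_along(merged))
  merged
}

#' Read / write peak sequences (FASTA)
#'
#' Thin wrappers over Biostrings keeping peak ids as sequence names.
#' @param path FASTA path.
#' @return A `DNAStringSet` named by peak id.
#' @export
read_peak_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname read_peak_fasta
#' @param seqs Named `DNAStringSet` or named character vector.
#' @export
write_peak_fasta <- function(seqs, path) {
  if (!inherits(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
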