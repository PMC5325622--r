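#' Simulation configuration for the synthetic cortex dataset
#'
#' Defines the study conditions the generator emulates: four glutamatergic
#' layer classes (plus an optional GABAergic class) with three replicates
#' each, negative-binomial fragment counts with planted binary-pattern
#' modules at a high/low ratio of `fold_change`, class-patterned gene
#' expression, PWM instances embedded in peak sequences at module-biased
#' rates, Tn5 insertion tracks with protection at bound motifs, and a known
#' activator/repressor TF-to-target network.
#'
#' @param n_peaks Number of peaks (distributed 1-8 per gene).
#' @param n_genes Number of genes.
#' @param n_null_motifs Motifs with no module bias and no owning TF,
#'   appended to the 12 TF-family motifs.
#' @param frac_null Fraction of genes with no class effect.
#' @param fold_change Planted high/low mean ratio (must exceed 4).
#' @param nb_dispersion NB dispersion `phi` (`Var = mu + phi mu^2`).
#' @param lib_size_mean Mean fragment-library size per replicate.
#' @param seed Integer seed; all randomness flows from it.
#' @param footprint_depletion Fractional loss of Tn5 insertions within the
#'   central 20 bp of a bound motif.
#' @param motif_enrichment_rate Planted placement-rate ratio, target module
#'   vs background peaks.
#' @param background_hit_rate Per-peak placement probability outside the
#'   target module.
#' @param coupling Probability that a peak of a module gene shares the
#'   gene's module.
#' @param replicates Replicates per class.
#' @param include_gaba Include a pan-GABAergic class (flat profiles).
#' @param gc Background GC content of peak sequences.
#' @param frip_target Fraction of fragments placed in (padded) peaks.
#' @param fragments_per_class Fragments per class fragment set.
#' @param gene_spacing Distance between consecutive TSSs (bp).
#' @param motif_length PWM length (bp).
#' @param expr_low,expr_high Low/high class-mean expression counts for
#'   module genes (`expr_high = expr_low * fold_change` when `NULL`).
#' @param n_cells_per_class Cells per class for the per-cell expression
#'   draws (the expression side emulates depth-equalized single-cell
#'   profiles whose class means feed the downstream analysis).
#' @param expr_dispersion NB dispersion of per-cell expression counts.
#' @param scrub_sequences Regenerate background sequence around unintended
#'   motif matches so the scan hit structure equals the recorded truth.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_peaks = 2000, n_genes = 400,
                              n_null_motifs = 4, frac_null = 0.4,
                              fold_change = 6, nb_dispersion = 0.1,
                              lib_size_mean = 1e6, seed = 1,
                              footprint_depletion = 0.8,
                              motif_enrichment_rate = 5,
                              background_hit_rate = 0.08,
                              coupling = 0.7, replicates = 3,
                              include_gaba = TRUE, gc = 0.5,
                              frip_target = 0.3,
                              fragments_per_class = 3e5,
                              gene_spacing = 20000, motif_length = 10,
                              expr_low = 50, expr_high = NULL,
                              n_cells_per_class = 60,
                              expr_dispersion = 0.35,
                              scrub_sequences = TRUE) {
  if (fold_change <= 4) stop("fold_change must exceed 4")
  if (frac_null < 0 || frac_null >= 1) stop("frac_null must lie in [0, 1)")
  if (replicates < 1) stop("need >= 1 replicate per class")
  if (n_peaks < n_genes || n_peaks > 8 * n_genes) {
    stop("n_peaks must lie in [n_genes, 8 * n_genes] (1-8 peaks per gene)")
  }
  if (is.null(expr_high)) expr_high <- expr_low * fold_change
  cfg <- as.list(environment())
  cfg$classes <- c("L2/3", "L4", "L5", "L6")
  class(cfg) <- "simulation_config"
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("simulation_config: %d peaks, %d genes, fold change %g, ",
                     "dispersion %g, seed %d\n"),
              x$n_peaks, x$n_genes, x$fold_change, x$nb_dispersion, x$seed))
  invisible(x)
}

# the complement pattern of a module label within the default 8 patterns
# (only defined for patterns whose bitwise complement is also a default)
module_complement <- function(label) {
  switch(label,
         "Upper+" = "Lower+", "Lower+" = "Upper+",
         "L4+" = "L4-", "L4-" = "L4+",
         "L6+" = "L6-", "L6-" = "L6+",
         stop("module ", label, " has no complement among the default patterns"))
}

# planted TF genes: the 12 key regulators with curated roles and modules,
# additional TF-family genes usable as network targets, non-differential
# TF-list decoys, and low-expression candidate decoys
synthetic_tf_table <- function() {
  key <- data.frame(
    gene_id = c("Egr1", "Fos", "Mef2c", "Nfia", "Neurod6", "Pou3f2",
                "Rfx3", "Rorb", "Meis2", "Tbr1", "Foxp2", "Cux1"),
    motif_family = c("EGR", "FOS", "MEF2", "NFIA", "NEUROD", "POU3F",
                     "RFX", "RORB", "MEIS", "TBR", "FOXP", "CUX"),
    role = c(rep("activator", 10), rep("repressor", 2)),
    module = c("L2/3+", "L5+", "Upper+", "L6+", "L4+", "L2/3+",
               "Upper+", "L4+", "Lower+", "Lower+", "L6+", "Upper+"),
    is_key = TRUE, is_candidate = TRUE, in_tf_list = TRUE)
  extra <- data.frame(
    gene_id = c("Cux2", "Foxp1", "Nfib", "Sox5", "Fezf2", "Bcl11b",
                "Pou6f2", "Zfpm2", "Satb2", "Rfx7", "Neurod1", "Etv1",
                "Wfs1", "Calb1"),
    motif_family = NA_character_, role = NA_character_,
    module = c("Upper+", "Upper+", "Lower+", "Lower+", "L5+", "L5+",
               "L6+", "L6+", "L6-", "L6-", "L4+", "L4+",
               "L2/3+", "L2/3+"),
    is_key = FALSE, is_candidate = FALSE, in_tf_list = TRUE)
  nulls <- data.frame(
    gene_id = sprintf("Tfnull%d", 1:8),
    motif_family = NA_character_, role = NA_character_,
    module = NA_character_,
    is_key = FALSE, is_candidate = FALSE, in_tf_list = TRUE)
  lowexpr <- data.frame(
    gene_id = c("Declow1", "Declow2"),
    motif_family = c("NFIA", "RFX"), role = "activator",
    module = NA_character_,
    is_key = FALSE, is_candidate = TRUE, in_tf_list = TRUE)
  rbind(key, extra, nulls, lowexpr)
}

#' Random informative PWMs
#'
#' One sharply informative PWM per motif id: a random consensus with the
#' dominant base at probability `dominant` and the remainder spread evenly.
#'
#' @param motif_ids Motif identifiers.
#' @param length Motif length.
#' @param dominant Consensus base probability.
#' @param background Background distribution.
#' @return List of [pwm()] objects.
#' @export
random_pwms <- function(motif_ids, length = 10, dominant = 0.97,
                        background = rep(0.25, 4)) {
  lapply(motif_ids, function(id) {
    cons <- sample.int(4, length, replace = TRUE)
    probs <- matrix((1 - dominant) / 3, length, 4)
    probs[cbind(seq_len(length), cons)] <- dominant
    pwm(id, probs, background)
  })
}

# gene table with module assignments; TF genes keep their planted modules,
# generic genes are split into nulls and round-robin module members
synthetic_gene_table <- function(cfg) {
  tf <- synthetic_tf_table()
  n_generic <- cfg$n_genes - nrow(tf)
  if (n_generic < 8) stop("n_genes too small for the planted TF set")
  generic <- data.frame(
    gene_id = sprintf("gene_%04d", seq_len(n_generic)),
    motif_family = NA_character_, role = NA_character_,
    module = NA_character_,
    is_key = FALSE, is_candidate = FALSE, in_tf_list = FALSE)
  n_null_target <- max(0, round(cfg$frac_null * cfg$n_genes) -
                         sum(is.na(tf$module)))
  n_module <- max(0, n_generic - n_null_target)
  labels <- rownames(default_module_patterns())
  if (n_module > 0) {
    mods <- rep(labels, length.out = n_module)
    generic$module[seq_len(n_module)] <- sample(mods)
  }
  genes <- rbind(tf, generic)
  # shuffle genomic order so modules are not positionally clustered
  genes[sample.int(nrow(genes)), , drop = FALSE]
}

#' Generate the synthetic TSS annotation and peak set
#'
#' Genes are evenly spaced along one synthetic chromosome and each receives
#' 1-8 peaks whose midpoints are placed at signed TSS distances covering
#' all six distance bins, close enough to their own TSS that the
#' nearest-TSS rule assigns them unambiguously.
#'
#' @param cfg A [simulation_config()].
#' @param gene_table Optional gene table (generated when `NULL`).
#' @return List with `tss` (data.frame), `peaks` (`GRanges` with `gene_of`
#'   and planted-bin metadata), `gene_table`.
#' @export
generate_annotation <- function(cfg, gene_table = NULL) {
  set.seed(cfg$seed + 1L)
  if (is.null(gene_table)) gene_table <- synthetic_gene_table(cfg)
  n_genes <- nrow(gene_table)
  pos <- as.integer(seq_len(n_genes) * cfg$gene_spacing - cfg$gene_spacing / 2)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  tss <- data.frame(gene_id = gene_table$gene_id, chrom = "chrS",
                    pos = pos, strand = strand)

  # distribute n_peaks over genes, 1..8 each
  ppg <- sample(1:8, n_genes, replace = TRUE,
                prob = c(.05, .1, .15, .2, .2, .15, .1, .05))
  while (sum(ppg) != cfg$n_peaks) {
    i <- sample.int(n_genes, 1)
    if (sum(ppg) > cfg$n_peaks && ppg[i] > 1) ppg[i] <- ppg[i] - 1L
    if (sum(ppg) < cfg$n_peaks && ppg[i] < 8) ppg[i] <- ppg[i] + 1L
  }
  gene_idx <- rep(seq_len(n_genes), ppg)
  n <- length(gene_idx)
  bins <- sample(c(-3L, -2L, -1L, 1L, 2L, 3L), n, replace = TRUE,
                 prob = c(.12, .18, .2, .2, .18, .12))
  mag <- integer(n)
  mag[abs(bins) == 1] <- sample(0:199, sum(abs(bins) == 1), replace = TRUE)
  mag[abs(bins) == 2] <- sample(200:2000, sum(abs(bins) == 2), replace = TRUE)
  mag[abs(bins) == 3] <- sample(2001:8000, sum(abs(bins) == 3), replace = TRUE)
  d <- ifelse(bins < 0, -mag, mag)
  d[bins == -1 & mag == 0] <- -1L  # bin -1 excludes distance 0
  genomic_offset <- ifelse(strand[gene_idx] == "+", d, -d)
  mid <- pos[gene_idx] + genomic_offset
  peaks <- peaks_from_bed_coords(rep("chrS", n), pmax(mid - 75L, 0L),
                                 mid + 75L,
                                 sprintf("peak_%06d", seq_len(n)))
  peaks$gene_of <- gene_table$gene_id[gene_idx]
  peaks$planted_bin <- ifelse(d == 0, 1L, bins)
  peaks$midpoint0 <- mid
  list(tss = tss, peaks = peaks, gene_table = gene_table)
}

# assign peak modules (coupled to the host gene's module), plant the edge
# host peaks, then set final peak widths (module peaks <= 400 bp)
plant_peak_structure <- function(cfg, ann) {
  set.seed(cfg$seed + 2L)
  gene_table <- ann$gene_table
  peaks <- ann$peaks
  gene_module <- setNames(gene_table$module, gene_table$gene_id)
  pk_gene <- peaks$gene_of
  pk_module <- rep(NA_character_, length(peaks))
  has_mod <- !is.na(gene_module[pk_gene])
  coupled <- has_mod & runif(length(peaks)) < cfg$coupling
  pk_module[coupled] <- gene_module[pk_gene[coupled]]

  # planted regulatory edges: 2-3 targets per key TF from TF-list genes in
  # the required module (own module for activators, complement for
  # repressors); each edge gets 1-3 host peaks carrying the motif
  tf <- gene_table[gene_table$is_key %in% TRUE, , drop = FALSE]
  pool <- gene_table[gene_table$in_tf_list & !is.na(gene_table$module), ,
                     drop = FALSE]
  edges <- list()
  for (i in seq_len(nrow(tf))) {
    required <- if (tf$role[i] == "activator") tf$module[i] else
      module_complement(tf$module[i])
    eligible <- setdiff(pool$gene_id[pool$module == required], tf$gene_id[i])
    if (!length(eligible)) next
    n_t <- min(length(eligible), sample(2:3, 1))
    targets <- sample(eligible, n_t)
    for (g in targets) {
      g_peaks <- which(pk_gene == g)
      hosts <- g_peaks[!is.na(pk_module[g_peaks]) &
                         pk_module[g_peaks] == required]
      n_inst <- sample(1:3, 1)
      if (length(hosts) < n_inst) {
        # convert spare peaks of the target gene into the required module
        spare <- g_peaks[!(g_peaks %in% hosts)]
        take <- utils::head(spare, n_inst - length(hosts))
        pk_module[take] <- required
        hosts <- c(hosts, take)
      }
      hosts <- hosts[seq_len(min(n_inst, length(hosts)))]
      edges[[length(edges) + 1]] <- data.frame(
        source_tf = tf$gene_id[i], motif_id = paste0("M_", tf$motif_family[i]),
        motif_family = tf$motif_family[i],
        target_gene = g, role = tf$role[i],
        host_peak = names(peaks)[hosts])
    }
  }
  edges <- do.call(rbind, edges)

  # widths: module peaks 150-350 bp, null peaks 150-550 bp
  n <- length(peaks)
  w <- integer(n)
  is_mod <- !is.na(pk_module)
  w[is_mod] <- sample(150:350, sum(is_mod), replace = TRUE)
  w[!is_mod] <- sample(150:550, sum(!is_mod), replace = TRUE)
  start0 <- pmax(peaks$midpoint0 - w %/% 2L, 0L)
  out <- peaks_from_bed_coords(rep("chrS", n), start0, start0 + w,
                               names(peaks))
  out$gene_of <- peaks$gene_of
  out$planted_bin <- peaks$planted_bin
  out$module <- pk_module
  list(peaks = out, edges = edges)
}

#' Generate replicate-level NB counts for peaks and genes
#'
#' Counts follow `NB(mean = libsize * pi_class, dispersion = phi)`: module
#' features have class means following their binary pattern at ratio
#' `fold_change`, null features have identical means in every class.
#' Expression is emitted both as replicate counts and as the planted
#' class-mean matrix. A genomic-control library with uniform (width-
#' proportional) coverage accompanies the peak counts.
#'
#' @param cfg A [simulation_config()].
#' @param truth Planted structure (from [simulate_dataset()] internals):
#'   needs `peaks` with `module` metadata and `gene_table`.
#' @return List with `peak_counts` ([count_matrix()]), `gene_counts`,
#'   `control` (vector), `control_lib_size`, `peak_units`, `gene_units`
#'   (planted class-mean matrices).
#' @export
generate_counts <- function(cfg, truth) {
  set.seed(cfg$seed + 3L)
  classes <- cfg$classes
  all_classes <- if (cfg$include_gaba) c(classes, "GABA") else classes
  patterns <- default_module_patterns(classes)
  peaks <- truth$peaks
  n <- length(peaks)

  # per-class accessibility units
  peak_units <- matrix(2, n, length(all_classes),
                       dimnames = list(names(peaks), all_classes))
  is_mod <- !is.na(peaks$module)
  pat <- patterns[peaks$module[is_mod], , drop = FALSE]
  peak_units[is_mod, classes] <- 1 + (cfg$fold_change - 1) * pat
  size_mult <- rlnorm(n, 0, 0.25)
  peak_units <- peak_units * size_mult
  if (cfg$include_gaba) {
    # GABAergic class: broadly different accessibility, unrelated to the
    # glutamatergic layer patterns
    peak_units[, "GABA"] <- 2 * size_mult * rlnorm(n, 0, 0.5)
  }

  gene_table <- truth$gene_table
  gene_units <- matrix(cfg$expr_low, nrow(gene_table), length(all_classes),
                       dimnames = list(gene_table$gene_id, all_classes))
  gmod <- !is.na(gene_table$module)
  gpat <- patterns[gene_table$module[gmod], , drop = FALSE]
  gene_units[gmod, classes] <- cfg$expr_low +
    (cfg$expr_high - cfg$expr_low) * gpat
  gene_units[gene_table$gene_id %in% c("Declow1", "Declow2"), ] <- 2
  if (cfg$include_gaba) gene_units[, "GABA"] <- cfg$expr_low

  sample_ids <- as.vector(t(outer(all_classes, seq_len(cfg$replicates),
                                  function(k, r) paste0(k, "_rep", r))))
  sample_class <- setNames(rep(all_classes, each = cfg$replicates), sample_ids)
  counts <- matrix(0L, nrow(peak_units), length(sample_ids),
                   dimnames = list(rownames(peak_units), sample_ids))
  for (s in sample_ids) {
    k <- sample_class[s]
    lib <- round(cfg$lib_size_mean * runif(1, 0.9, 1.1))
    mu <- lib * peak_units[, k] / sum(peak_units[, k])
    counts[, s] <- rnbinom(nrow(peak_units), mu = mu,
                           size = 1 / cfg$nb_dispersion)
  }
  peak_cm <- count_matrix(counts, sample_class)

  # expression: depth-equalized per-cell NB draws whose class means are the
  # downstream "average gene expression counts"
  n_cells <- cfg$n_cells_per_class
  cell_ids <- as.vector(t(outer(all_classes, seq_len(n_cells),
                                function(k, i) sprintf("%s_cell%03d", k, i))))
  cell_class <- setNames(rep(all_classes, each = n_cells), cell_ids)
  gcounts <- matrix(0L, nrow(gene_units), length(cell_ids),
                    dimnames = list(rownames(gene_units), cell_ids))
  for (s in cell_ids) {
    gcounts[, s] <- rnbinom(nrow(gene_units), mu = gene_units[, cell_class[s]],
                            size = 1 / cfg$expr_dispersion)
  }
  gene_cm <- count_matrix(gcounts, cell_class)

  control_lib <- cfg$lib_size_mean
  w <- GenomicRanges::width(peaks)
  control <- rnbinom(n, mu = 0.05 * control_lib * w / sum(w),
                     size = 1 / cfg$nb_dispersion)
  list(peak_counts = peak_cm, gene_counts = gene_cm,
       control = setNames(control, names(peaks)),
       control_lib_size = control_lib,
       peak_units = peak_units, gene_units = gene_units)
}

# placement plan for one motif over all peaks; returns peak name vector
place_motif <- function(cfg, peaks, motif, tf_row, edges) {
  modules <- peaks$module
  tfgene_peaks <- peaks$gene_of %in% edges$tf_list_genes
  fg_rate <- min(1, cfg$background_hit_rate * cfg$motif_enrichment_rate)
  rate <- rep(cfg$background_hit_rate, length(peaks))
  rate[tfgene_peaks] <- 0 # no accidental placements near TF-list genes
  if (!is.null(tf_row)) {
    target_module <- if (tf_row$role == "activator") tf_row$module else
      module_complement(tf_row$module)
    in_target <- !is.na(modules) & modules == target_module
    rate[in_target & !tfgene_peaks] <- fg_rate
    # a repressor keeps its own module's motif-bearing peaks closed: those
    # peaks are absent from the accessible peak set, so the placement rate
    # in the repressor's own module is zero
    if (tf_row$role == "repressor") {
      own <- !is.na(modules) & modules == tf_row$module
      rate[own] <- 0
    }
  }
  names(peaks)[runif(length(peaks)) < rate]
}

#' Generate peak sequences with embedded motif instances
#'
#' Peak sequences are iid background at the configured GC content. Each TF
#' motif is planted in its target-module peaks at
#' `motif_enrichment_rate x background_hit_rate` and elsewhere at the
#' background rate (never in peaks of TF-list genes, except the planted
#' edge host peaks, which always carry their edge's motif); repressor
#' motifs are absent from the repressor's own module. Null motifs have no
#' module bias. When `scrub_sequences` is set, background sequence that
#' happens to contain an unintended motif match is redrawn, and embedded
#' instances that a scan would miss are replaced by the consensus, so the
#' scan hit structure equals the recorded placements.
#'
#' @param cfg A [simulation_config()].
#' @param truth List with `peaks` (module/gene metadata) and `edges`.
#' @param pwms List of [pwm()] objects (TF motifs named `M_<family>`, plus
#'   null motifs).
#' @return List with `sequences` (named character) and `placements`
#'   (data.frame `motif_id`, `peak_id`, `offset`, `strand`).
#' @export
generate_sequences_and_hits <- function(cfg, truth, pwms) {
  set.seed(cfg$seed + 4L)
  peaks <- truth$peaks
  widths <- GenomicRanges::width(peaks)
  names(widths) <- names(peaks)
  tf_table <- truth$gene_table[truth$gene_table$is_key %in% TRUE, ,
                               drop = FALSE]
  tf_list_genes <- truth$gene_table$gene_id[truth$gene_table$in_tf_list]
  edges <- truth$edges

  # choose placements per motif
  placements <- list()
  for (p in pwms) {
    fam <- sub("^M_", "", p$motif_id)
    tf_row <- tf_table[match(fam, tf_table$motif_family), , drop = FALSE]
    tf_row <- if (nrow(tf_row) && !is.na(tf_row$gene_id[1])) tf_row[1, ] else NULL
    chosen <- place_motif(cfg, peaks, p$motif_id, tf_row,
                          list(tf_list_genes = tf_list_genes))
    forced <- if (!is.null(edges)) {
      unique(edges$host_peak[edges$motif_id == p$motif_id])
    } else character(0)
    chosen <- union(chosen, forced)
    if (length(chosen)) {
      L <- nrow(p$probs)
      ok <- widths[chosen] >= L
      if (any(!ok)) warning("motif longer than peak: ",
                            sum(!ok), " placements skipped")
      chosen <- chosen[ok]
      placements[[length(placements) + 1]] <- data.frame(
        motif_id = p$motif_id, peak_id = chosen,
        offset = NA_integer_,
        strand = sample(c("+", "-"), length(chosen), replace = TRUE))
    }
  }
  placements <- do.call(rbind, placements)

  # non-overlapping offsets within each peak
  by_peak <- split(seq_len(nrow(placements)), placements$peak_id)
  L_of <- setNames(vapply(pwms, function(p) nrow(p$probs), 1L),
                   vapply(pwms, function(p) p$motif_id, ""))
  for (pk in names(by_peak)) {
    rows <- by_peak[[pk]]
    w <- widths[pk]
    taken <- integer(0)
    for (ri in rows) {
      L <- L_of[placements$motif_id[ri]]
      for (try in 1:50) {
        off <- sample.int(w - L + 1, 1) - 1L
        clash <- FALSE
        if (length(taken)) {
          prev <- placements[rows[seq_along(taken)], , drop = FALSE]
          clash <- any(off < prev$offset + L_of[prev$motif_id] &
                         off + L > prev$offset)
        }
        if (!clash) break
      }
      placements$offset[ri] <- off
      taken <- c(taken, off)
    }
  }

  base_probs <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
  letters4 <- c("A", "C", "G", "T")
  draw_bg <- function(w) {
    paste(sample(letters4, w, replace = TRUE, prob = base_probs),
          collapse = "")
  }
  sample_instance <- function(p) {
    idx <- apply(p$probs, 1, function(pr) sample.int(4, 1, prob = pr))
    paste(letters4[idx], collapse = "")
  }
  embed <- function(seq_str, pl) {
    if (is.null(pl) || !nrow(pl)) return(seq_str)
    s <- strsplit(seq_str, "")[[1]]
    for (i in seq_len(nrow(pl))) {
      p <- pwms[[match(pl$motif_id[i], names(L_of))]]
      inst <- sample_instance(p)
      if (pl$strand[i] == "-") {
        inst <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(inst)))
      }
      s[(pl$offset[i] + 1):(pl$offset[i] + nchar(inst))] <-
        strsplit(inst, "")[[1]]
    }
    paste(s, collapse = "")
  }

  pl_by_peak <- split(placements, placements$peak_id)
  seqs <- setNames(vapply(names(peaks), function(pk) {
    embed(draw_bg(widths[pk]), pl_by_peak[[pk]])
  }, ""), names(peaks))

  if (cfg$scrub_sequences) {
    seqs <- scrub_sequences(cfg, seqs, placements, pwms, pl_by_peak,
                            draw_bg, embed)
  }
  list(sequences = seqs, placements = placements)
}

# redraw background sequence around unintended motif matches and replace
# undetectable planted instances by the consensus
scrub_sequences <- function(cfg, seqs, placements, pwms, pl_by_peak,
                            draw_bg, embed, p_threshold = 1e-4,
                            max_rounds = 30) {
  key <- function(m, pk, off, st) paste(m, pk, off, st, sep = "|")
  planted_keys <- with(placements, key(motif_id, peak_id, offset, strand))
  dirty <- names(seqs)
  for (round in seq_len(max_rounds)) {
    hits <- scan_sequences(pwms, seqs[dirty], p_threshold = p_threshold)
    hit_keys <- if (nrow(hits)) {
      with(hits, key(motif_id, peak_id, offset, strand))
    } else character(0)
    extra <- hits[!(hit_keys %in% planted_keys), , drop = FALSE]
    pl_dirty <- placements[placements$peak_id %in% dirty, , drop = FALSE]
    missed <- pl_dirty[!(with(pl_dirty, key(motif_id, peak_id, offset, strand))
                         %in% hit_keys), , drop = FALSE]
    # undetected planted instances: force the consensus
    if (nrow(missed)) {
      for (i in seq_len(nrow(missed))) {
        p <- pwms[[match(missed$motif_id[i],
                         vapply(pwms, function(q) q$motif_id, ""))]]
        cons <- pwm_consensus(p)
        if (missed$strand[i] == "-") {
          cons <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(cons)))
        }
        s <- strsplit(seqs[[missed$peak_id[i]]], "")[[1]]
        s[(missed$offset[i] + 1):(missed$offset[i] + nchar(cons))] <-
          strsplit(cons, "")[[1]]
        seqs[[missed$peak_id[i]]] <- paste(s, collapse = "")
      }
    }
    dirty <- unique(extra$peak_id)
    if (!length(dirty) && !nrow(missed)) break
    dirty <- unique(c(dirty, missed$peak_id))
    # regenerate the background of offending peaks, keeping placements
    for (pk in unique(extra$peak_id)) {
      seqs[[pk]] <- embed(draw_bg(nchar(seqs[[pk]])), pl_by_peak[[pk]])
    }
  }
  seqs
}

# fragment length mixture emulating sub-nucleosomal and nucleosomal modes
sample_fragment_lengths <- function(n, modes = c(75, 200, 400, 600),
                                    weights = c(.45, .3, .15, .1),
                                    sdlog = 0.18) {
  comp <- sample.int(length(modes), n, replace = TRUE, prob = weights)
  len <- round(rlnorm(n, meanlog = log(modes)[comp] + sdlog^2, sdlog = sdlog))
  pmax(len, 20L)
}

#' Generate per-class Tn5 fragment sets
#'
#' Fragments are placed with both cut sites drawn from a class-specific
#' insertion track: uniform across (shoulder-padded) peaks weighted by the
#' class accessibility, with the insertion probability multiplied by
#' `1 - footprint_depletion` within the central 20 bp of planted motifs
#' whose owning TF is expressed in that class. The remaining
#' `1 - frip_target` of fragments fall uniformly on the chromosome.
#' Fragment lengths follow a mixture with modes near 75/200/400/600 bp.
#'
#' @param cfg A [simulation_config()].
#' @param truth List with `peaks`, `placements`, `gene_table`, `peak_units`.
#' @return Named list (class -> fragment `GRanges` with `sample_id`).
#' @export
generate_fragments <- function(cfg, truth) {
  set.seed(cfg$seed + 5L)
  peaks <- truth$peaks
  classes <- cfg$classes
  all_classes <- if (cfg$include_gaba) c(classes, "GABA") else classes
  patterns <- default_module_patterns(classes)
  pad <- 260L
  start0 <- GenomicRanges::start(peaks) - 1L - pad
  end0 <- GenomicRanges::end(peaks) + pad
  reg_w <- end0 - start0
  chrom_len <- nrow(truth$gene_table) * cfg$gene_spacing

  # genomic depleted windows per motif placement (center +/- 10 bp)
  pl <- truth$placements
  L_of <- setNames(vapply(truth$pwms, function(p) nrow(p$probs), 1L),
                   vapply(truth$pwms, function(p) p$motif_id, ""))
  pk_idx <- match(pl$peak_id, names(peaks))
  center0 <- (GenomicRanges::start(peaks)[pk_idx] - 1L) + pl$offset +
    L_of[pl$motif_id] %/% 2L
  fam <- sub("^M_", "", pl$motif_id)
  tf_table <- truth$gene_table[truth$gene_table$is_key %in% TRUE, ,
                               drop = FALSE]
  tf_module <- setNames(tf_table$module, tf_table$motif_family)

  out <- list()
  for (k in all_classes) {
    expressed <- rep(FALSE, length(fam))
    if (k %in% classes) {
      has_tf <- !is.na(tf_module[fam])
      expressed[has_tf] <- patterns[tf_module[fam[has_tf]], k] == 1
    }
    dep_lo <- center0[expressed] - 10L
    dep_hi <- center0[expressed] + 10L
    dep <- if (length(dep_lo)) {
      GenomicRanges::reduce(GenomicRanges::GRanges(
        "chrS", IRanges::IRanges(dep_lo + 1L, dep_hi + 1L)))
    } else GenomicRanges::GRanges()
    in_dep <- function(pos0) {
      if (!length(dep)) return(rep(FALSE, length(pos0)))
      GenomicRanges::countOverlaps(
        GenomicRanges::GRanges("chrS", IRanges::IRanges(pos0 + 1L, pos0 + 1L)),
        dep) > 0
    }
    units_k <- truth$peak_units[, k]
    w_peak <- units_k * reg_w
    n_in <- round(cfg$frip_target * cfg$fragments_per_class)
    accepted1 <- integer(0)
    while (length(accepted1) < n_in) {
      m <- ceiling((n_in - length(accepted1)) * 1.3)
      pk <- sample.int(length(peaks), m, replace = TRUE, prob = w_peak)
      pos0 <- start0[pk] + floor(runif(m) * reg_w[pk])
      drop <- in_dep(pos0) & runif(m) < cfg$footprint_depletion
      accepted1 <- c(accepted1, pos0[!drop])
    }
    end1 <- accepted1[seq_len(n_in)]
    # second cut site: length mixture, then thinning by the end-2 weight
    end2 <- integer(0); keep1 <- integer(0)
    remaining <- seq_len(n_in)
    while (length(remaining)) {
      len <- sample_fragment_lengths(length(remaining))
      dir <- sample(c(-1L, 1L), length(remaining), replace = TRUE)
      cand2 <- end1[remaining] + dir * len
      drop <- in_dep(cand2) & runif(length(cand2)) < cfg$footprint_depletion
      keep1 <- c(keep1, remaining[!drop]); end2 <- c(end2, cand2[!drop])
      remaining <- remaining[drop]
    }
    a <- pmin(end1[keep1], end2); b <- pmax(end1[keep1], end2)
    a <- pmax(a, 0L)
    n_bg <- cfg$fragments_per_class - n_in
    bg1 <- as.integer(floor(runif(n_bg) * (chrom_len - 700))) + 1L
    bg_len <- sample_fragment_lengths(n_bg)
    gr <- GenomicRanges::GRanges(
      "chrS", IRanges::IRanges(c(a, bg1) + 1L, c(b, bg1 + bg_len) + 1L))
    gr$sample_id <- paste0(k, "_rep1")
    out[[k]] <- gr
  }
  out
}

#' Simulate the full synthetic dataset
#'
#' Runs every generator stage from one seed and returns the dataset plus
#' the planted ground truth. With `outdir`, writes all pipeline input
#' files (BED/TSV/FASTA/MEME) plus `truth.json`.
#'
#' @param cfg A [simulation_config()].
#' @param outdir Optional output directory.
#' @return List of class `synthetic_dataset` with elements `config`,
#'   `tss`, `peaks`, `peak_counts`, `gene_counts`, `control`,
#'   `control_lib_size`, `pwms`, `sequences`, `fragments`, `tf_table`,
#'   `truth`.
#' @export
simulate_dataset <- function(cfg = simulation_config(), outdir = NULL) {
  set.seed(cfg$seed)
  ann <- generate_annotation(cfg)
  planted <- plant_peak_structure(cfg, ann)
  truth_core <- list(peaks = planted$peaks, edges = planted$edges,
                     gene_table = ann$gene_table)
  counts <- generate_counts(cfg, truth_core)
  set.seed(cfg$seed + 6L)
  motif_ids <- c(paste0("M_", unique(synthetic_tf_table()$motif_family[
    synthetic_tf_table()$is_key])),
    sprintf("M_NULL%d", seq_len(cfg$n_null_motifs)))
  pwms <- random_pwms(motif_ids, length = cfg$motif_length)
  seq_out <- generate_sequences_and_hits(cfg, truth_core, pwms)
  frag_in <- c(truth_core, list(placements = seq_out$placements,
                                pwms = pwms, peak_units = counts$peak_units))
  frags <- generate_fragments(cfg, frag_in)

  tf_table <- ann$gene_table[ann$gene_table$in_tf_list, , drop = FALSE]
  truth <- list(
    peak_module_of = setNames(planted$peaks$module, names(planted$peaks)),
    gene_module_of = setNames(ann$gene_table$module, ann$gene_table$gene_id),
    motif_placements = seq_out$placements,
    network_edges = planted$edges,
    class_means = list(peaks = counts$peak_units, genes = counts$gene_units),
    params = cfg)
  ds <- structure(list(
    config = cfg, tss = ann$tss, peaks = planted$peaks,
    peak_counts = counts$peak_counts, gene_counts = counts$gene_counts,
    control = counts$control, control_lib_size = counts$control_lib_size,
    pwms = pwms, sequences = seq_out$sequences, fragments = frags,
    tf_table = tf_table, truth = truth), class = "synthetic_dataset")
  if (!is.null(outdir)) write_synthetic_dataset(ds, outdir)
  ds
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("synthetic_dataset: %d peaks, %d genes, %d motifs, ",
                     "%d planted edges (seed %d)\n"),
              length(x$peaks), nrow(x$tss), length(x$pwms),
              nrow(x$truth$network_edges), x$config$seed))
  invisible(x)
}

#' Write a synthetic dataset to pipeline input files
#' @param ds A `synthetic_dataset`.
#' @param outdir Output directory (created if needed).
#' @export
write_synthetic_dataset <- function(ds, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  f <- function(x) file.path(outdir, x)
  write_peaks_bed(ds$peaks, f("peaks.bed"))
  write_tss_table(ds$tss, f("tss.tsv"))
  write_count_matrix(ds$peak_counts, f("peak_counts.tsv"),
                     f("peak_sample_classes.tsv"))
  write_count_matrix(ds$gene_counts, f("gene_counts.tsv"),
                     f("gene_sample_classes.tsv"))
  write.table(data.frame(peak_id = names(ds$control),
                         control_count = unname(ds$control)),
              f("control_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_peak_fasta(ds$sequences, f("peak_sequences.fa"))
  write_meme_motifs(ds$pwms, f("motifs.meme"))
  for (k in names(ds$fragments)) {
    write_fragments_bed(ds$fragments[[k]],
                        f(sprintf("fragments_%s.bed", gsub("/", "", k))))
  }
  write.table(ds$tf_table, f("tf_table.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- ds$truth
  truth$params <- unclass(truth$params)
  jsonlite::write_json(truth, f("truth.json"), auto_unbox = TRUE,
                       na = "null", digits = NA)
  invisible(outdir)
}
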