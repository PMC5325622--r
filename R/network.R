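#' Curated activator/repressor roles of the key layer TFs
#'
#' The default activator/repressor designations shipped with the package:
#' activators Egr1, Fos, Mef2c, Nfia, Neurod6, Pou3f2, Rfx3, Rorb, Meis2
#' and Tbr1; repressors Foxp2 and Cux1. Roles are a curated input (derived
#' from the literature), not inferred by the pipeline.
#'
#' @return Data.frame `gene_id`, `role`.
#' @export
tf_roles_default <- function() {
  data.frame(
    gene_id = c("Egr1", "Fos", "Mef2c", "Nfia", "Neurod6", "Pou3f2",
                "Rfx3", "Rorb", "Meis2", "Tbr1", "Foxp2", "Cux1"),
    role = c(rep("activator", 10), rep("repressor", 2)))
}

#' Select key TF source nodes
#'
#' Implements the node-selection flowchart: candidates (TF genes with a
#' motif family and curated role) are filtered for a maximum class-mean
#' expression above `min_expression`; each is assigned the gene module
#' whose center best correlates with its expression profile; an activator
#' is retained when its motif family is enriched (adjusted p below
#' `enrich_p`) in the matching peak module, a repressor when its family is
#' depleted there. Per (motif family, role) the highest-expressed passer
#' becomes the key TF node.
#'
#' @param candidates Data.frame `gene_id`, `motif_family`, `role`.
#' @param expr_means Gene x class expression matrix (glutamatergic class
#'   means).
#' @param gene_centers Gene-module center matrix (modules x classes).
#' @param enrichment [motif_module_enrichment()] result (motif level).
#' @param families Named vector motif id -> family.
#' @param min_expression Expression floor (class-mean counts).
#' @param enrich_p Adjusted-p threshold on enrichment/depletion.
#' @return Data.frame of selected nodes: `gene_id`, `motif_family`, `role`,
#'   `assigned_module`, `assignment_r`, `max_expression`.
#' @export
select_key_tfs <- function(candidates, expr_means, gene_centers, enrichment,
                           families, min_expression = 5, enrich_p = 0.01) {
  cand <- candidates[candidates$gene_id %in% rownames(expr_means), ,
                     drop = FALSE]
  cand$max_expression <- apply(expr_means[cand$gene_id, , drop = FALSE],
                               1, max)
  cand <- cand[cand$max_expression > min_expression, , drop = FALSE]
  if (!nrow(cand)) return(cand)
  asn <- assign_gene_module_by_correlation(
    expr_means[cand$gene_id, , drop = FALSE], gene_centers)
  cand$assigned_module <- asn$module
  cand$assignment_r <- asn$r
  enrichment$family <- families[enrichment$motif_id]
  pass <- vapply(seq_len(nrow(cand)), function(i) {
    want <- if (cand$role[i] == "activator") "enriched" else "depleted"
    any(enrichment$family == cand$motif_family[i] &
          enrichment$module == cand$assigned_module[i] &
          enrichment$direction == want &
          enrichment$adj_p < enrich_p, na.rm = TRUE)
  }, TRUE)
  cand <- cand[pass & !is.na(cand$assigned_module), , drop = FALSE]
  if (!nrow(cand)) return(cand)
  keys <- unique(cand[c("motif_family", "role")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- cand[cand$motif_family == keys$motif_family[i] &
                  cand$role == keys$role[i], , drop = FALSE]
    sub[which.max(sub$max_expression), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("gene_id", "motif_family", "role", "assigned_module",
        "assignment_r", "max_expression")]
}

#' Filter motif instances into regulatory edges
#'
#' Implements the edge-selection flowchart. A motif instance survives when
#' all six gates pass: (1) its family is Fisher-associated (p below
#' `assoc_p`) with at least one peak module; (2) the instance's host-peak
#' module is among those associated modules and is positively associated
#' (p below `assoc_p`, OR above 1) with at least one gene module; (3) the
#' host peak is differentially accessible (p below `peak_p`) in at least
#' one glutamatergic contrast; (4) the host peak's assigned gene is
#' differentially expressed (p below `gene_p`); (5) that gene is in the TF
#' gene list; (6) the Pearson correlation between the host peak's scaled
#' class profile and the source TF's scaled expression profile exceeds
#' `cor_threshold` for an activator (falls below its negative for a
#' repressor). Passing instances are aggregated into directed edges
#' (source TF -> target gene) weighted by instance count.
#'
#' @param hits Motif hits ([scan_sequences()]).
#' @param key_tfs Selected nodes ([select_key_tfs()]).
#' @param families Named vector motif id -> family.
#' @param enrichment [motif_module_enrichment()] result.
#' @param module_assoc [module_module_fisher()] result.
#' @param peak_modules Named membership vector (peak -> module).
#' @param diff_peaks,diff_genes Lists of per-contrast differential results
#'   (glutamatergic contrasts).
#' @param assignments Peak-gene assignments.
#' @param tf_list Character vector of TF gene ids (the allowed targets).
#' @param peak_scaled,expr_scaled Scaled class profiles for peaks and genes.
#' @param assoc_p,peak_p,gene_p,cor_threshold Gate thresholds.
#' @return List with `edges` (data.frame `source_tf`, `motif_family`,
#'   `target_gene`, `role`, `n_motif_instances`, `supporting_peaks`,
#'   `correlation_r`) and `audit` (per-instance gate table).
#' @export
filter_edges <- function(hits, key_tfs, families, enrichment, module_assoc,
                         peak_modules, diff_peaks, diff_genes, assignments,
                         tf_list, peak_scaled, expr_scaled,
                         assoc_p = 0.01, peak_p = 0.001, gene_p = 1e-5,
                         cor_threshold = 0.3) {
  enrichment$family <- families[enrichment$motif_id]
  # gate 1/2 precomputation: per family, peak modules the family is
  # associated with that are positively associated with a gene module
  pos_modules <- unique(module_assoc$peak_module[
    module_assoc$p < assoc_p & module_assoc$odds_ratio > 1])
  family_modules <- lapply(split(enrichment, enrichment$family), function(e) {
    intersect(unique(e$module[e$p < assoc_p]), pos_modules)
  })
  # per-feature minimum p across glutamatergic contrasts
  min_p <- function(lst) {
    ids <- unique(unlist(lapply(lst, `[[`, "feature_id")))
    m <- rep(Inf, length(ids)); names(m) <- ids
    for (d in lst) m[d$feature_id] <- pmin(m[d$feature_id], d$p)
    m
  }
  peak_min_p <- min_p(diff_peaks)
  gene_min_p <- min_p(diff_genes)

  inst <- hits[families[hits$motif_id] %in% key_tfs$motif_family, ,
               drop = FALSE]
  inst$family <- families[inst$motif_id]
  src_idx <- match(inst$family, key_tfs$motif_family)
  inst$source_tf <- key_tfs$gene_id[src_idx]
  inst$role <- key_tfs$role[src_idx]
  inst$gene_id <- assignments$gene_id[match(inst$peak_id, assignments$peak_id)]
  inst$module <- unname(peak_modules[inst$peak_id])

  g1 <- vapply(inst$family, function(f) length(family_modules[[f]]) > 0, TRUE)
  g2 <- mapply(function(f, m) !is.na(m) && m %in% family_modules[[f]],
               inst$family, inst$module)
  g3 <- !is.na(peak_min_p[inst$peak_id]) & peak_min_p[inst$peak_id] < peak_p
  g4 <- !is.na(inst$gene_id) & !is.na(gene_min_p[inst$gene_id]) &
    gene_min_p[inst$gene_id] < gene_p
  g5 <- !is.na(inst$gene_id) & inst$gene_id %in% tf_list
  r <- rep(NA_real_, nrow(inst))
  ok_r <- inst$peak_id %in% rownames(peak_scaled) &
    inst$source_tf %in% rownames(expr_scaled)
  if (any(ok_r)) {
    r[ok_r] <- row_cor(peak_scaled[inst$peak_id[ok_r], , drop = FALSE],
                       expr_scaled[inst$source_tf[ok_r], , drop = FALSE])
  }
  g6 <- !is.na(r) & ifelse(inst$role == "activator",
                           r > cor_threshold, r < -cor_threshold)
  audit <- data.frame(inst[c("motif_id", "family", "peak_id", "offset",
                             "strand", "source_tf", "role", "gene_id",
                             "module")],
                      correlation_r = r,
                      gate1 = g1, gate2 = unname(g2), gate3 = unname(g3),
                      gate4 = unname(g4), gate5 = g5, gate6 = g6)
  audit$pass <- with(audit, gate1 & gate2 & gate3 & gate4 & gate5 & gate6)
  passed <- audit[audit$pass, , drop = FALSE]
  if (!nrow(passed)) {
    edges <- data.frame(source_tf = character(0), motif_family = character(0),
                        target_gene = character(0), role = character(0),
                        n_motif_instances = integer(0),
                        supporting_peaks = character(0),
                        correlation_r = numeric(0))
    return(list(edges = edges, audit = audit))
  }
  key <- paste(passed$source_tf, passed$gene_id, sep = "->")
  agg <- split(passed, key)
  edges <- do.call(rbind, lapply(agg, function(s) data.frame(
    source_tf = s$source_tf[1], motif_family = s$family[1],
    target_gene = s$gene_id[1], role = s$role[1],
    n_motif_instances = nrow(s),
    supporting_peaks = paste(unique(s$peak_id), collapse = ","),
    correlation_r = mean(s$correlation_r))))
  rownames(edges) <- NULL
  list(edges = edges, audit = audit)
}

#' Assemble and export a regulatory network
#'
#' Builds a directed igraph from key-TF nodes and filtered edges, and
#' writes GraphML plus a TSV edge list. Node attributes carry role, module
#' and expression; edge attributes carry weight, motif family and
#' correlation.
#'
#' @param key_tfs Node table ([select_key_tfs()]).
#' @param edges Edge table ([filter_edges()]`$edges`).
#' @param graphml_path,tsv_path Optional output paths.
#' @return The igraph object (invisibly when writing).
#' @export
export_network <- function(key_tfs, edges, graphml_path = NULL,
                           tsv_path = NULL) {
  nodes <- unique(c(key_tfs$gene_id, edges$target_gene))
  if (nrow(edges) && !all(edges$source_tf %in% key_tfs$gene_id)) {
    stop("dangling edge: source TF not among nodes")
  }
  vert <- data.frame(name = nodes,
                     role = key_tfs$role[match(nodes, key_tfs$gene_id)],
                     module = key_tfs$assigned_module[
                       match(nodes, key_tfs$gene_id)],
                     expression = key_tfs$max_expression[
                       match(nodes, key_tfs$gene_id)])
  vert[is.na(vert)] <- ""
  g <- igraph::graph_from_data_frame(
    edges[, c("source_tf", "target_gene", "motif_family", "role",
              "n_motif_instances", "correlation_r"), drop = FALSE],
    directed = TRUE, vertices = vert)
  if (!is.null(graphml_path)) {
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(tsv_path)) {
    write.table(edges, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(g)
}

#' Read a network edge list written by [export_network()]
#' @param tsv_path Path to the TSV edge list.
#' @return Edge data.frame.
#' @export
read_network_tsv <- function(tsv_path) {
  read.delim(tsv_path, stringsAsFactors = FALSE)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items
#' (used for module-recovery evaluation).
#'
#' @param a,b Label vectors of equal length.
#' @return ARI in `[-1, 1]` (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

#' Compare a recovered network with the planted truth
#'
#' @param edges Recovered edge table.
#' @param truth_edges Planted edge table (`source_tf`, `target_gene`).
#' @return List with `precision`, `recall`, `n_recovered`, `n_true`,
#'   `false_edges`, `missed_edges`.
#' @export
evaluate_network <- function(edges, truth_edges) {
  got <- unique(paste(edges$source_tf, edges$target_gene, sep = "->"))
  want <- unique(paste(truth_edges$source_tf, truth_edges$target_gene,
                       sep = "->"))
  tp <- sum(got %in% want)
  list(precision = if (length(got)) tp / length(got) else NA_real_,
       recall = if (length(want)) tp / length(want) else NA_real_,
       n_recovered = length(got), n_true = length(want),
       false_edges = setdiff(got, want), missed_edges = setdiff(want, got))
}

#' Run the full integrative pipeline on a dataset
#'
#' Orchestrates every stage in order: TMM normalization and scoring ->
#' pairwise NB differential tests (peaks and genes) -> nearest-TSS
#' annotation -> module feature selection, scaling and seeded k-means ->
#' module-module Fisher association -> motif scanning and module
#' enrichment -> key-TF selection and edge filtering -> network assembly.
#' All stochastic stages derive from the dataset's seed; rerunning on the
#' same dataset yields identical outputs.
#'
#' @param ds A `synthetic_dataset` (or a list with the same elements built
#'   from files).
#' @param outdir Optional directory for stage outputs (TSV/GraphML).
#' @param scan_p Motif scan per-position p-value threshold.
#' @return List of class `pipeline_result` with all stage outputs.
#' @export
run_pipeline <- function(ds, outdir = NULL, scan_p = 1e-4) {
  cfg <- ds$config
  glut <- cfg$classes

  factors <- tmm_factors(ds$peak_counts)
  scores <- tmm_score(ds$peak_counts, factors, control = ds$control,
                      control_lib_size = ds$control_lib_size)
  diff_peaks <- nb_differential_all_pairs(ds$peak_counts, classes = glut,
                                          factors = factors)
  # expression profiles are depth-equalized, so differential expression
  # runs on the counts themselves (constant library size)
  gene_libs <- setNames(rep(1e6, ncol(ds$gene_counts$counts)),
                        colnames(ds$gene_counts$counts))
  diff_genes <- nb_differential_all_pairs(ds$gene_counts, classes = glut,
                                          lib_sizes = gene_libs)

  assignments <- assign_nearest_tss(ds$peaks, ds$tss)

  peak_class <- scores$class_scores[, glut, drop = FALSE]
  expr_class <- local({
    cm <- ds$gene_counts
    out <- vapply(glut, function(k) {
      rowMeans(cm$counts[, names(cm$sample_class)[cm$sample_class == k],
                         drop = FALSE])
    }, numeric(nrow(cm$counts)))
    out
  })

  peak_sel <- select_module_features(diff_peaks, peak_class, "peak")
  gene_sel <- select_module_features(diff_genes, expr_class, "gene")
  peak_scaled <- suppressMessages(
    scale_rows(peak_class[peak_sel, , drop = FALSE]))
  gene_scaled <- suppressMessages(
    scale_rows(expr_class[gene_sel, , drop = FALSE]))
  peak_modules <- kmeans_seeded(peak_scaled, feature_kind = "peak")
  gene_modules <- kmeans_seeded(gene_scaled, feature_kind = "gene")

  module_assoc <- module_module_fisher(peak_modules$membership,
                                       gene_modules$membership, assignments)

  hits <- scan_sequences(ds$pwms, ds$sequences, p_threshold = scan_p)
  widths <- setNames(GenomicRanges::width(ds$peaks), names(ds$peaks))
  enrichment <- motif_module_enrichment(hits, peak_modules, widths)
  families <- setNames(sub("^M_", "", vapply(ds$pwms, function(p) p$motif_id,
                                             "")),
                       vapply(ds$pwms, function(p) p$motif_id, ""))

  candidates <- ds$tf_table[!is.na(ds$tf_table$motif_family) &
                              nzchar(ds$tf_table$motif_family), ,
                            drop = FALSE]
  key_tfs <- select_key_tfs(candidates[c("gene_id", "motif_family", "role")],
                            expr_class, gene_modules$centers, enrichment,
                            families)
  expr_scaled_all <- suppressMessages(scale_rows(expr_class))
  peak_scaled_all <- suppressMessages(scale_rows(peak_class))
  net <- filter_edges(hits, key_tfs, families, enrichment, module_assoc,
                      peak_modules$membership, diff_peaks, diff_genes,
                      assignments, ds$tf_table$gene_id,
                      peak_scaled_all, expr_scaled_all)

  result <- structure(list(
    factors = factors, scores = scores,
    diff_peaks = diff_peaks, diff_genes = diff_genes,
    assignments = assignments,
    peak_class_scores = peak_class, expr_class_means = expr_class,
    peak_modules = peak_modules, gene_modules = gene_modules,
    module_assoc = module_assoc,
    hits = hits, enrichment = enrichment, families = families,
    key_tfs = key_tfs, edges = net$edges, audit = net$audit),
    class = "pipeline_result")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    f <- function(x) file.path(outdir, x)
    write.table(assignments, f("peak_gene_assignments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(feature = names(peak_modules$membership),
                           module = unname(peak_modules$membership)),
                f("peak_modules.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(feature = names(gene_modules$membership),
                           module = unname(gene_modules$membership)),
                f("gene_modules.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(module_assoc, f("module_associations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(enrichment, f("motif_enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(hits, f("motif_hits.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    export_network(key_tfs, net$edges, f("network.graphml"),
                   f("network_edges.tsv"))
    write.table(key_tfs, f("network_nodes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0("pipeline_result: %d peak / %d gene module features, ",
                     "%d motif hits, %d key TFs, %d edges\n"),
              length(x$peak_modules$membership),
              length(x$gene_modules$membership),
              nrow(x$hits), nrow(x$key_tfs), nrow(x$edges)))
  invisible(x)
}
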