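#' Run the full synthetic-study pipeline
#'
#' Simulates every input, then runs the complete analysis chain --
#' differential expression per RNA class, target-table intersection and
#' negative co-expression filtering, ceRNA pair screening and triplet
#' assembly per sponge class, back-splice circRNA calling, and the assay
#' computations -- writing every declared output table under `outdir`.
#' Identical configs (including the seed) produce byte-identical output
#' trees.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created).
#' @param min_shared,p_threshold,fdr_threshold,pcc_threshold,scc_threshold
#'   screening thresholds, passed through to [screen_pairs()] and
#'   [negative_coexpression_filter()].
#' @param min_reads junction-read support threshold for circRNA calls.
#' @return invisibly, a list with the intermediate objects (`sim`, `de`,
#'   `interactions`, `pairs`, `triplets`, `circ_calls`, `assays`) and a
#'   `summary` data.frame of stage tallies.
#' @export
run_pipeline <- function(config, outdir,
                         min_shared = 4L, p_threshold = 0.05,
                         fdr_threshold = 0.05, pcc_threshold = 0.8,
                         scc_threshold = -0.7, min_reads = 2L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim_dir <- file.path(outdir, "sim")

  ## ---- simulate ----------------------------------------------------------
  sim <- simulate_counts(config)
  write_sim_counts(sim, sim_dir)
  tables <- simulate_target_tables(config, sim)
  utils::write.table(tables$table_a, file.path(sim_dir, "targets_toolA.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tables$table_b, file.path(sim_dir, "targets_toolB.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bs <- simulate_backsplice_reads(config)
  write_backsplice_sim(bs, sim_dir)
  assay_sim <- simulate_assay_tables(config)
  utils::write.table(assay_sim$ct, file.path(sim_dir, "qpcr_ct.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(assay_sim$standards,
                     file.path(sim_dir, "melanin_standards.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- differential expression per class ---------------------------------
  de <- lapply(sim$counts, de_test, groups = sim$groups)
  for (cls in names(de)) {
    utils::write.table(cbind(class = cls, de[[cls]]),
                       file.path(outdir, paste0("de_", cls, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  de_ids <- lapply(de, function(d) d$feature_id[d$significant])

  ## normalized expression used by every correlation downstream
  norm <- lapply(sim$counts, function(m) sweep(m, 2, size_factors(m), "/"))
  target_expr <- rbind(
    fpkm(sim$counts$mrna, sim$annotation,
         mapped = colSums(sim$counts$mrna) + colSums(sim$counts$lncrna)),
    norm$lncrna, norm$circrna)

  ## ---- interactions -------------------------------------------------------
  interactions <- intersect_predictions(tables$table_a, tables$table_b)
  de_targets <- c(de_ids$mrna, de_ids$lncrna, de_ids$circrna)
  scc_mrna <- negative_coexpression_filter(
    interactions[interactions$target_id %in% rownames(sim$counts$mrna), ],
    norm$mirna, target_expr, threshold = scc_threshold,
    de_mirnas = de_ids$mirna, de_targets = de_ids$mrna)
  utils::write.table(scc_mrna, file.path(outdir, "interactions_filtered.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## ---- ceRNA screen -------------------------------------------------------
  sets <- interaction_sets(interactions)
  sponge_ids <- intersect(names(sets$by_target),
                          c(de_ids$lncrna, de_ids$circrna))
  mrna_ids <- intersect(names(sets$by_target), de_ids$mrna)
  sponge_class <- stats::setNames(
    ifelse(sponge_ids %in% rownames(sim$counts$lncrna), "lncrna", "circrna"),
    sponge_ids)
  sponge_expr <- rbind(norm$lncrna, norm$circrna)
  pairs <- screen_pairs(
    sets$by_target[sponge_ids], sets$by_target[mrna_ids],
    sponge_expr, target_expr,
    sponge_class = sponge_class, min_shared = min_shared,
    p_threshold = p_threshold, fdr_threshold = fdr_threshold,
    pcc_threshold = pcc_threshold)
  utils::write.table(pairs, file.path(outdir, "cerna_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  triplets <- assemble_triplets(pairs, sets$by_target[sponge_ids],
                                sets$by_target[mrna_ids], scc_mrna)
  utils::write.table(triplets, file.path(outdir, "cerna_triplets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  export_network(triplets, file.path(outdir, "cerna_network.sif"), "sif")
  export_network(triplets, file.path(outdir, "cerna_network.graphml"), "graphml")
  export_network(triplets, file.path(outdir, "cerna_network_edges.tsv"), "edgelist")

  ## ---- back-splice calls --------------------------------------------------
  ann <- read_exon_annotation(file.path(sim_dir, "annotation.gtf"))
  circ_calls <- call_backsplice(file.path(sim_dir, "reads.sam"), bs$genome,
                                gtf = ann, min_reads = min_reads)
  utils::write.table(circ_calls, file.path(outdir, "circ_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_circ_bed(circ_calls, file.path(outdir, "circ_calls.bed"))

  ## ---- assays -------------------------------------------------------------
  rel <- ddct(assay_sim$ct, calibrator_group = "A")
  utils::write.table(rel, file.path(outdir, "qpcr_relative_expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  curve <- melanin_fit(assay_sim$standards$conc, assay_sim$standards$absorbance)
  utils::write.table(
    data.frame(slope = curve$slope, intercept = curve$intercept, r2 = curve$r2),
    file.path(outdir, "melanin_curve.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  summary <- data.frame(
    stage = c(paste0("de_", names(de)), "interactions", "cerna_pairs",
              "cerna_triplets", "circ_calls"),
    n = c(vapply(de, function(d) sum(d$significant), integer(1)),
          nrow(interactions), nrow(pairs), nrow(triplets), nrow(circ_calls)),
    row.names = NULL)
  utils::write.table(summary, file.path(outdir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(sim = sim, tables = tables, backsplice_sim = bs,
                 assay_sim = assay_sim, de = de, interactions = interactions,
                 scc_mrna = scc_mrna, pairs = pairs, triplets = triplets,
                 circ_calls = circ_calls,
                 assays = list(relative_expression = rel, curve = curve),
                 summary = summary))
}

#' Compare pipeline output with the planted truth
#'
#' @param result list returned by [run_pipeline()].
#' @return list with triplet recall/precision, back-splice junction recall,
#'   and the count of circRNA calls not matching any planted junction.
#' @export
evaluate_recovery <- function(result) {
  truth <- result$sim$truth
  tkey <- function(d) paste(d$sponge_id, d$mirna_id, d$mrna_id, sep = "\r")
  found <- tkey(result$triplets)
  planted <- tkey(truth$triplets)
  triplet_recall <- if (length(planted)) mean(planted %in% found) else NA_real_
  triplet_precision <- if (length(found)) mean(found %in% planted) else NA_real_

  bkey <- function(d) paste(d$chrom, d$start, d$end, sep = "\r")
  calls <- bkey(result$circ_calls)
  bsj <- bkey(result$backsplice_sim$bsj_truth)
  list(
    triplet_recall = triplet_recall,
    triplet_precision = triplet_precision,
    bsj_recall = if (length(bsj)) mean(bsj %in% calls) else NA_real_,
    bsj_false_calls = sum(!(calls %in% bsj))
  )
}
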