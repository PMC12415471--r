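#!/usr/bin/env Rscript
# Stage 3: high-confidence miRNA-target interactions.
#
# The two predictor tables are intersected (only pairs called by both tools
# survive), then miRNA-mRNA pairs are filtered to negatively co-expressed
# DE pairs: Spearman rank correlation < -0.7 on log2(normalized + 1)
# expression across all six libraries, restricted to DE miRNAs and DE mRNAs.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                 value = TRUE))), "common.R"))

tab_a <- read_target_table(file.path(SIM_DIR, "targets_toolA.tsv"))
tab_b <- read_target_table(file.path(SIM_DIR, "targets_toolB.tsv"))
inter <- intersect_predictions(tab_a, tab_b)
cat(sprintf("tool A: %d rows, tool B: %d rows, intersection: %d pairs\n",
            nrow(tab_a), nrow(tab_b), nrow(inter)))
utils::write.table(inter, file.path(RESULTS, "interactions_highconf.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

## expression for co-expression filtering
groups <- read_design_tsv(file.path(SIM_DIR, "design.tsv"))
counts <- lapply(c(mrna = "mrna", lncrna = "lncrna", circrna = "circrna",
                   mirna = "mirna"), function(cls)
  read_counts_tsv(file.path(SIM_DIR, paste0("counts_", cls, ".tsv"))))
norm <- lapply(counts, function(m) sweep(m, 2, size_factors(m), "/"))
ann <- utils::read.delim(file.path(SIM_DIR, "feature_annotation.tsv"))
mrna_expr <- fpkm(counts$mrna, ann,
                  mapped = colSums(counts$mrna) + colSums(counts$lncrna))

de_ids <- lapply(c(mrna = "mrna", mirna = "mirna"), function(cls) {
  d <- utils::read.delim(file.path(RESULTS, paste0("de_", cls, ".tsv")))
  d$feature_id[d$significant]
})

scc <- negative_coexpression_filter(
  inter[inter$target_id %in% rownames(counts$mrna), ],
  norm$mirna, mrna_expr,
  de_mirnas = de_ids$mirna, de_targets = de_ids$mrna)
utils::write.table(scc, file.path(RESULTS, "interactions_filtered.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("negatively co-expressed DE miRNA-mRNA pairs (SCC < -0.7): %d\n",
            nrow(scc)))
cat(sprintf("median SCC among retained pairs: %.3f\n", median(scc$scc)))
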