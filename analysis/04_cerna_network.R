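#!/usr/bin/env Rscript
# Stage 4: ceRNA pair screening and sponge-miRNA-mRNA triplet assembly.
#
# Candidates are all (DE sponge, DE mRNA) pairs whose members hold nonempty
# high-confidence miRNA sets. Selection: shared miRNAs > 3, hypergeometric
# p < 0.05, BH FDR < 0.05 (lncRNA and circRNA networks adjusted separately),
# and Pearson correlation > 0.8 on log2 expression. Each retained pair
# contributes one triplet per shared miRNA that survived the SCC < -0.7
# miRNA-mRNA filter. Networks are exported in SIF / GraphML / edge-list form.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                 value = TRUE))), "common.R"))

inter <- utils::read.delim(file.path(RESULTS, "interactions_highconf.tsv"))
scc <- utils::read.delim(file.path(RESULTS, "interactions_filtered.tsv"))
sets <- interaction_sets(inter)

counts <- lapply(c(mrna = "mrna", lncrna = "lncrna", circrna = "circrna"),
                 function(cls)
  read_counts_tsv(file.path(SIM_DIR, paste0("counts_", cls, ".tsv"))))
norm <- lapply(counts, function(m) sweep(m, 2, size_factors(m), "/"))
ann <- utils::read.delim(file.path(SIM_DIR, "feature_annotation.tsv"))
mrna_expr <- fpkm(counts$mrna, ann,
                  mapped = colSums(counts$mrna) + colSums(counts$lncrna))

de_ids <- lapply(c(mrna = "mrna", lncrna = "lncrna", circrna = "circrna"),
                 function(cls) {
  d <- utils::read.delim(file.path(RESULTS, paste0("de_", cls, ".tsv")))
  d$feature_id[d$significant]
})

sponges <- intersect(names(sets$by_target), c(de_ids$lncrna, de_ids$circrna))
mrnas <- intersect(names(sets$by_target), de_ids$mrna)
sponge_class <- stats::setNames(
  ifelse(sponges %in% rownames(counts$lncrna), "lncrna", "circrna"), sponges)
cat(sprintf("candidates: %d DE sponges x %d DE mRNAs with target sets\n",
            length(sponges), length(mrnas)))

pairs <- screen_pairs(sets$by_target[sponges], sets$by_target[mrnas],
                      rbind(norm$lncrna, norm$circrna), mrna_expr,
                      sponge_class = sponge_class)
utils::write.table(pairs, file.path(RESULTS, "cerna_pairs.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("retained ceRNA pairs: %d (%d lncRNA-mRNA, %d circRNA-mRNA)\n",
            nrow(pairs), sum(pairs$sponge_class == "lncrna"),
            sum(pairs$sponge_class == "circrna")))

triplets <- assemble_triplets(pairs, sets$by_target[sponges],
                              sets$by_target[mrnas], scc)
utils::write.table(triplets, file.path(RESULTS, "cerna_triplets.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
g <- export_network(triplets, file.path(RESULTS, "cerna_network.sif"), "sif")
export_network(triplets, file.path(RESULTS, "cerna_network.graphml"), "graphml")
export_network(triplets, file.path(RESULTS, "cerna_network_edges.tsv"), "edgelist")
cat(sprintf("network: %d nodes, %d edges from %d triplets\n",
            igraph::vcount(g), igraph::ecount(g), nrow(triplets)))

## recall / precision against the planted truth
truth <- utils::read.delim(file.path(SIM_DIR, "truth_triplets.tsv"))
key <- function(d) paste(d$sponge_id, d$mirna_id, d$mrna_id)
recall <- mean(key(truth) %in% key(triplets))
precision <- if (nrow(triplets)) mean(key(triplets) %in% key(truth)) else NA
cat(sprintf("planted-triplet recall %.3f, precision %.3f\n", recall, precision))
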