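#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-breed skin study.
#
# Emulates the design of the real experiment -- two groups ("A" and "B",
# standing in for the two breeds) x three libraries, four RNA classes -- with
# planted differential expression, 10 sponge-miRNA-mRNA triplet groups
# (5 shared miRNAs each), two target-prediction tables, a toy genome with 50
# back-spliced circles, and the qPCR / melanin assay tables. Everything
# downstream reads these files, so the whole analysis is reproducible
# offline from one seed.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                 value = TRUE))), "common.R"))

cfg <- analysis_config()
print(cfg)

sim <- simulate_counts(cfg)
write_sim_counts(sim, SIM_DIR)
utils::write.table(sim$annotation, file.path(SIM_DIR, "feature_annotation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(sim$truth$de_features, file.path(SIM_DIR, "truth_de.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(sim$truth$triplets, file.path(SIM_DIR, "truth_triplets.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

tb <- simulate_target_tables(cfg, sim)
utils::write.table(tb$table_a, file.path(SIM_DIR, "targets_toolA.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(tb$table_b, file.path(SIM_DIR, "targets_toolB.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(tb$true_pairs, file.path(SIM_DIR, "truth_interactions.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

bs <- simulate_backsplice_reads(cfg)
write_backsplice_sim(bs, SIM_DIR)

assays <- simulate_assay_tables(cfg)
utils::write.table(assays$ct, file.path(SIM_DIR, "qpcr_ct.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(assays$standards, file.path(SIM_DIR, "melanin_standards.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "simulated %d mRNA / %d lncRNA / %d circRNA / %d miRNA features over %d libraries\n",
  cfg$n_mrna, cfg$n_lncrna, cfg$n_circrna, cfg$n_mirna,
  2L * cfg$samples_per_group))
cat(sprintf("planted: %d DE features, %d triplets, %d back-splice circles\n",
            nrow(sim$truth$de_features), nrow(sim$truth$triplets),
            nrow(bs$bsj_truth)))
cat("inputs written under", SIM_DIR, "\n")
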