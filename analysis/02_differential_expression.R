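#!/usr/bin/env Rscript
# Stage 2: negative-binomial differential expression, one test per RNA class.
#
# Counts are normalized by median-of-ratios size factors; each feature gets a
# moderated method-of-moments NB dispersion, a Wald log2-fold-change test and
# a Benjamini-Hochberg adjusted p-value (significant: padj < 0.05).

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                 value = TRUE))), "common.R"))

groups <- read_design_tsv(file.path(SIM_DIR, "design.tsv"))
classes <- c("mrna", "lncrna", "circrna", "mirna")

for (cls in classes) {
  counts <- read_counts_tsv(file.path(SIM_DIR, paste0("counts_", cls, ".tsv")))
  de <- de_test(counts, groups)
  utils::write.table(cbind(class = cls, de),
                     file.path(RESULTS, paste0("de_", cls, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%-8s %5d features, %4d significant (%d up / %d down in group B)\n",
              cls, nrow(de), sum(de$significant),
              sum(de$significant & de$direction == "up"),
              sum(de$significant & de$direction == "down")))
}

# recovery check against the planted truth
truth <- utils::read.delim(file.path(SIM_DIR, "truth_de.tsv"))
for (cls in classes) {
  de <- utils::read.delim(file.path(RESULTS, paste0("de_", cls, ".tsv")))
  t_cls <- truth[truth$class == cls, ]
  hit <- de$significant[match(t_cls$feature_id, de$feature_id)]
  cat(sprintf("%-8s planted recovery: %.2f (%d / %d)\n",
              cls, mean(hit), sum(hit), nrow(t_cls)))
}
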