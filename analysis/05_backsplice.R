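#!/usr/bin/env Rscript
# Stage 5: back-splice circRNA junction calling from the simulated SAM.
#
# Clip-signature scan (xS yM / xM yS / xS yM zS CIGARs), chiastic re-match of
# the clipped segment, paired-end mate containment, GT-AG / AT-AC splice
# signal check, exon-boundary annotation filter, and grouping by junction
# with a >= 2 distinct-read support threshold.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                 value = TRUE))), "common.R"))

calls <- call_backsplice(file.path(SIM_DIR, "reads.sam"),
                         file.path(SIM_DIR, "genome.fa"),
                         gtf = file.path(SIM_DIR, "annotation.gtf"),
                         min_reads = 2L)
utils::write.table(calls, file.path(RESULTS, "circ_calls.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_circ_bed(calls, file.path(RESULTS, "circ_calls.bed"))

truth <- jsonlite::read_json(file.path(SIM_DIR, "bsj_truth.json"),
                             simplifyVector = TRUE)
key <- function(d) paste(d$chrom, d$start, d$end)
cat(sprintf("called %d junctions; planted %d\n", nrow(calls), nrow(truth)))
cat(sprintf("recall %.3f, false calls %d\n",
            mean(key(truth) %in% key(calls)),
            sum(!(key(calls) %in% key(truth)))))
cat(sprintf("splice signals: %s\n",
            paste(names(table(calls$signal)), table(calls$signal),
                  collapse = ", ", sep = "=")))
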