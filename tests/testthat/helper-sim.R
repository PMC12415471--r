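# small, fast configurations used across the unit tests

small_config <- function(seed = 42L, ...) {
  args <- list(
    seed = seed,
    n_mrna = 200L, n_lncrna = 60L, n_circrna = 60L, n_mirna = 60L,
    n_triplets = 4L, k_shared = 5L, n_decoy_sponges = 20L,
    circle_count = 5L, reads_per_junction = 6L,
    n_background_reads = 200L, chrom_length = 60000L
  )
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# one-record alignment data.frame for detector unit tests
aln_row <- function(qname, chrom, pos, cigar, seq, flag = 0L,
                    mate_chrom = NA_character_, mate_pos = NA_integer_) {
  data.frame(qname = qname, flag = flag, chrom = chrom, pos = pos,
             cigar = cigar, seq = seq, mate_chrom = mate_chrom,
             mate_pos = mate_pos, stringsAsFactors = FALSE)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
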