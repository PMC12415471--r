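test_that("classify_cigar recognizes the clip-signature grammar", {
  expect_equal(classify_cigar("100M")$category, "none")
  l <- classify_cigar("30S70M")
  expect_equal(l[c("category", "x", "y")],
               list(category = "left_clip", x = 30L, y = 70L))
  expect_equal(classify_cigar("30H70M")$category, "left_clip")
  r <- classify_cigar("70M30S")
  expect_equal(r[c("category", "x", "y")],
               list(category = "right_clip", x = 70L, y = 30L))
  d <- classify_cigar("20S60M20S")
  expect_equal(d[c("category", "x", "y", "z")],
               list(category = "double_clip", x = 20L, y = 60L, z = 20L))
  expect_equal(classify_cigar("20H60M20S")$category, "double_clip")
  # indel/spliced alignments carry no back-splice signature
  expect_equal(classify_cigar("40M2I58M")$category, "none")
  expect_equal(classify_cigar("10S40M2D50M")$category, "none")
  expect_equal(classify_cigar("50M1000N50M")$category, "none")
  expect_error(classify_cigar("12M3Q"), "malformed CIGAR.*offset 4")
  expect_error(parse_cigar("*"), "empty")
})

test_that("classify_cigar round-trips randomly generated valid CIGARs", {
  set.seed(31)
  print_cigar <- function(lens, ops) paste0(lens, ops, collapse = "")
  for (r in 1:100) {
    form <- sample(c("left", "right", "double", "none"), 1)
    lens <- sample(5:90, 3)
    cg <- switch(form,
      left = print_cigar(lens[1:2], c(sample(c("S", "H"), 1), "M")),
      right = print_cigar(lens[1:2], c("M", sample(c("S", "H"), 1))),
      double = print_cigar(lens, c(sample(c("S", "H"), 1), "M",
                                   sample(c("S", "H"), 1))),
      none = print_cigar(lens[1], "M"))
    got <- classify_cigar(cg)
    expect_equal(got$category,
                 c(left = "left_clip", right = "right_clip",
                   double = "double_clip", none = "none")[[form]])
    if (form != "none") expect_equal(got$x, lens[1])
  }
})

# hand-built micro-genome with one circle at [101, 260]
micro_fixture <- function() {
  set.seed(77)
  g <- random_dna(600)
  circle <- c(101L, 260L)
  genome <- c(chrZ = g)
  # junction read: 40-base tail + 60-base head
  tail_seq <- substr(g, 221, 260)
  head_seq <- substr(g, 101, 160)
  list(genome = genome, circle = circle,
       junction_seq = paste0(tail_seq, head_seq),
       head_at = 101L, tail_at = 221L)
}

test_that("chiastic clipped reads yield the planted junction; colinear ones do not", {
  fx <- micro_fixture()
  # left clip: head anchored at circle start, tail clipped
  a1 <- aln_row("r1", "chrZ", fx$head_at, "40S60M", fx$junction_seq)
  c1 <- detect_junction_candidates(a1, fx$genome, window = 500)
  expect_equal(nrow(c1), 1L)
  expect_equal(c(c1$start, c1$end), fx$circle)

  # right clip: tail anchored at the circle end, head clipped
  a2 <- aln_row("r2", "chrZ", fx$tail_at, "40M60S", fx$junction_seq)
  c2 <- detect_junction_candidates(a2, fx$genome, window = 500)
  expect_equal(nrow(c2), 1L)
  expect_equal(c(c2$start, c2$end), fx$circle)

  # linear read: no candidate
  a3 <- aln_row("r3", "chrZ", 301L, "100M", substr(fx$genome, 301, 400))
  expect_equal(nrow(detect_junction_candidates(a3, fx$genome)), 0L)

  # colinear clip (forward splice): clipped prefix matches upstream -> none
  g <- fx$genome[["chrZ"]]
  splice_read <- paste0(substr(g, 61, 100), substr(g, 301, 360))
  a4 <- aln_row("r4", "chrZ", 301L, "40S60M", splice_read)
  expect_equal(nrow(detect_junction_candidates(a4, fx$genome, window = 500)), 0L)

  # clips below the minimum re-match length are skipped
  a5 <- aln_row("r5", "chrZ", fx$head_at, "5S95M",
                paste0(substr(g, 256, 260), substr(g, 101, 195)))
  expect_equal(nrow(detect_junction_candidates(a5, fx$genome)), 0L)

  expect_error(detect_junction_candidates(
    aln_row("r", "chrMissing", 1L, "100M", strrep("A", 100)), fx$genome),
    "absent from genome")
})

test_that("double-clipped single-exon reads resolve to one interval", {
  set.seed(78)
  g <- random_dna(600)
  genome <- c(chrZ = g)
  # single-exon circle [101, 160] shorter than the read: the read wraps,
  # giving 25S (circle tail) + 60M (full circle) + 15S (circle head again)
  seqd <- paste0(substr(g, 136, 160), substr(g, 101, 160), substr(g, 101, 115))
  a <- aln_row("rd", "chrZ", 101L, "25S60M15S", seqd)
  cand <- detect_junction_candidates(a, genome, window = 400)
  expect_equal(nrow(cand), 1L)
  expect_equal(c(cand$start, cand$end), c(101L, 160L))
})

test_that("ambiguous clip re-matches are discarded and tallied", {
  rep20 <- strrep("AC", 10)
  g <- paste0(random_dna(200), rep20, random_dna(100), rep20, random_dna(100))
  genome <- c(chrA = g)
  anchor <- substr(g, 1, 60)
  a <- aln_row("ra", "chrA", 1L, "20S60M", paste0(rep20, anchor))
  cand <- detect_junction_candidates(a, genome, window = 600)
  expect_equal(nrow(cand), 0L)
  expect_gte(attr(cand, "ambiguous"), 1L)
})

test_that("mate constraint keeps contained mates and passes unpaired reads", {
  cand <- data.frame(qname = c("p1", "p2", "p3", "u1"), chrom = "chr1",
                     start = 100L, end = 400L, stringsAsFactors = FALSE)
  aln <- rbind(
    aln_row("p1", "chr1", 100L, "40S60M", strrep("A", 100), flag = 65L,
            mate_chrom = "chr1", mate_pos = 250L),   # inside
    aln_row("p2", "chr1", 100L, "40S60M", strrep("A", 100), flag = 65L,
            mate_chrom = "chr1", mate_pos = 900L),   # outside
    aln_row("p3", "chr1", 100L, "40S60M", strrep("A", 100), flag = 65L,
            mate_chrom = "chr2", mate_pos = 250L),   # other chromosome
    aln_row("u1", "chr1", 100L, "40S60M", strrep("A", 100), flag = 0L))
  out <- mate_constraint(cand, aln)
  expect_setequal(out$qname, c("p1", "u1"))
})

test_that("splice signals are classified strand-aware", {
  #           acceptor v         v donor
  g <- paste0("AAAA", "AG", "CCCCGGGCCC", "GT", "AAAA")
  genome <- c(c1 = g)
  s <- splice_signal_check(genome, "c1", 7L, 16L)
  expect_equal(s, list(signal = "GT-AG", strand = "+"))

  # minus strand: genomic AC before start, CT after end
  gm <- paste0("AAAA", "AC", "CCCCGGGCCC", "CT", "AAAA")
  sm <- splice_signal_check(c(c1 = gm), "c1", 7L, 16L)
  expect_equal(sm, list(signal = "GT-AG", strand = "-"))

  # weak AT-AC signal
  gw <- paste0("AAAA", "AC", "CCCCGGGCCC", "AT", "AAAA")
  sw <- splice_signal_check(c(c1 = gw), "c1", 7L, 16L)
  expect_equal(sw, list(signal = "AT-AC", strand = "+"))

  # no signal
  gn <- paste0("AAAA", "AA", "CCCCGGGCCC", "TT", "AAAA")
  expect_equal(splice_signal_check(c(c1 = gn), "c1", 7L, 16L)$signal, "none")

  # too close to the chromosome edge to read a signal
  expect_equal(splice_signal_check(genome, "c1", 2L, 16L)$signal, "none")
  expect_equal(splice_signal_check(genome, "c1", 7L, nchar(g) - 1L)$signal,
               "none")
})

test_that("annotation filter enforces exon boundaries within tolerance", {
  ann <- list(
    exons = data.frame(chrom = "chr1", start = c(100L, 300L),
                       end = c(200L, 400L), gene_id = "G",
                       stringsAsFactors = FALSE),
    genes = data.frame(gene_id = "G", chrom = "chr1", start = 100L,
                       end = 400L, stringsAsFactors = FALSE))
  exact <- data.frame(qname = "q", chrom = "chr1", start = 100L, end = 400L)
  off1 <- data.frame(qname = "q", chrom = "chr1", start = 101L, end = 400L)
  inside <- data.frame(qname = "q", chrom = "chr1", start = 150L, end = 400L)

  kept <- annotation_filter(exact, ann)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$source_gene, "G")
  expect_equal(nrow(annotation_filter(off1, ann)), 0L)
  expect_equal(nrow(annotation_filter(off1, ann, tolerance = 2L)), 1L)
  expect_equal(nrow(annotation_filter(inside, ann)), 0L)
  # unannotated chromosome: dropped unless keep_intergenic
  interg <- data.frame(qname = "q", chrom = "chr2", start = 10L, end = 90L)
  expect_equal(nrow(annotation_filter(interg, ann)), 0L)
  kept2 <- annotation_filter(interg, ann, keep_intergenic = TRUE)
  expect_equal(nrow(kept2), 1L)
  expect_true(is.na(kept2$source_gene))
})

test_that("call grouping counts distinct query names and applies min_reads", {
  cand <- data.frame(
    qname = c("a", "a", "b", "c", "d"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(10L, 10L, 10L, 10L, 5L),
    end = c(90L, 90L, 90L, 90L, 50L), stringsAsFactors = FALSE)
  calls <- call_circles(cand, min_reads = 2L)
  expect_equal(nrow(calls), 1L)      # chr2 junction has 1 read only
  expect_equal(calls$junction_reads, 3L)  # qname "a" counted once
  expect_equal(nrow(call_circles(cand, min_reads = 1L)), 2L)
  expect_true(all(calls$start < calls$end))
})

test_that("the full caller recovers planted circles from a simulated SAM", {
  cfg <- small_config(seed = 13L, circle_count = 4L, reads_per_junction = 5L,
                      n_background_reads = 300L)
  bs <- simulate_backsplice_reads(cfg)
  sam <- tempfile(fileext = ".sam")
  gtf <- tempfile(fileext = ".gtf")
  writeLines(bs$sam, sam)
  writeLines(bs$gtf, gtf)

  calls <- call_backsplice(sam, bs$genome, gtf = gtf, min_reads = 2L)
  key <- function(d) paste(d$chrom, d$start, d$end)
  expect_setequal(key(calls), key(bs$bsj_truth))
  expect_true(all(calls$junction_reads == 5L))
  expect_true(all(calls$signal == "GT-AG"))
  expect_equal(calls$strand,
               bs$bsj_truth$strand[match(key(calls), key(bs$bsj_truth))])
  expect_equal(calls$source_gene,
               bs$bsj_truth$gene_id[match(key(calls), key(bs$bsj_truth))])

  # output is invariant to record order
  recs <- bs$sam[!startsWith(bs$sam, "@")]
  set.seed(1)
  shuffled <- c(bs$sam[startsWith(bs$sam, "@")], sample(recs))
  sam2 <- tempfile(fileext = ".sam")
  writeLines(shuffled, sam2)
  calls2 <- call_backsplice(sam2, bs$genome, gtf = gtf, min_reads = 2L)
  expect_equal(calls, calls2)

  # BED export is 0-based half-open with junction-read scores
  bed <- tempfile(fileext = ".bed")
  write_circ_bed(calls, bed)
  b <- utils::read.delim(bed, header = FALSE)
  expect_equal(b$V2, calls$start - 1L)
  expect_equal(b$V3, calls$end)
  expect_equal(b$V5, calls$junction_reads)
})
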