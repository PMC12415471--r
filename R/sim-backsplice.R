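#' Simulate a toy genome, annotation, and back-spliced read alignments
#'
#' Builds a random multi-chromosome genome populated with multi-exon genes,
#' writes canonical splice dinucleotides at every exon boundary (GT donor /
#' AG acceptor on the plus strand, their reverse complements for minus-strand
#' genes), and plants `circle_count` circles whose back-splice junctions sit
#' exactly on exon boundaries. For each circle, `reads_per_junction` read
#' pairs are synthesized: read 1 spans the back-splice point (its sequence is
#' circle tail followed by circle head) and is emitted as a clipped alignment
#' whose CIGAR is `xS yM` (anchor at the circle start, clipped tail) or
#' `xM yS` (anchor at the circle end, clipped head) -- the chiastic clip
#' signature a back-splice produces -- while read 2 maps fully inside the
#' circle interval with a plain full-match CIGAR. Linear background read
#' pairs with full-match CIGARs are added for specificity testing.
#'
#' The junction split point is drawn uniformly so that both the clipped and
#' the matched segment are at least 20 bases, keeping every clip long enough
#' for unambiguous re-matching.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector of chromosome
#'   sequences), `genes` (data.frame of exons: gene_id, chrom, strand,
#'   exon_number, start, end; 1-based inclusive), `gtf` (character vector of
#'   GTF lines), `sam` (character vector of SAM lines, header included) and
#'   `bsj_truth` (data.frame: circ_id, chrom, start, end, strand, gene_id).
#' @export
simulate_backsplice_reads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  L <- config$read_length
  chroms <- paste0("chr", seq_len(config$n_chroms))
  genome <- lapply(chroms, function(ch)
    sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE))
  names(genome) <- chroms

  ## ---- gene models -------------------------------------------------------
  exons <- list()
  gi <- 0L
  for (ch in chroms) {
    pos <- 2000L
    repeat {
      n_ex <- sample(3:6, 1)
      ex_len <- sample(150:400, n_ex, replace = TRUE)
      in_len <- sample(200:800, max(n_ex - 1, 0), replace = TRUE)
      span <- sum(ex_len) + sum(in_len)
      if (pos + span > config$chrom_length - 2000L) break
      gi <- gi + 1L
      strand <- sample(c("+", "-"), 1)
      starts <- pos + cumsum(c(0L, ex_len[-n_ex] + in_len))
      ends <- starts + ex_len - 1L
      exons[[gi]] <- data.frame(
        gene_id = sprintf("gene_%03d", gi), chrom = ch, strand = strand,
        exon_number = seq_len(n_ex), start = starts, end = ends,
        stringsAsFactors = FALSE)
      pos <- pos + span + sample(500:1500, 1)
    }
  }
  genes <- do.call(rbind, exons)

  ## plant splice dinucleotides at every exon boundary
  for (i in seq_len(nrow(genes))) {
    ch <- genes$chrom[i]; s <- genes$start[i]; e <- genes$end[i]
    if (genes$strand[i] == "+") {
      genome[[ch]][(e + 1):(e + 2)] <- c("G", "T")   # donor
      genome[[ch]][(s - 2):(s - 1)] <- c("A", "G")   # acceptor
    } else {
      genome[[ch]][(s - 2):(s - 1)] <- c("A", "C")   # revcomp -> GT donor
      genome[[ch]][(e + 1):(e + 2)] <- c("C", "T")   # revcomp -> AG acceptor
    }
  }

  ## ---- choose circles on exon boundaries --------------------------------
  gene_ids <- unique(genes$gene_id)
  order_genes <- sample(gene_ids)
  circles <- list()
  ci <- 0L
  for (g in rep(order_genes, 2)) {       # at most two circles per gene
    if (ci >= config$circle_count) break
    gx <- genes[genes$gene_id == g, , drop = FALSE]
    combos <- expand.grid(i = seq_len(nrow(gx)), j = seq_len(nrow(gx)))
    combos <- combos[combos$i <= combos$j, , drop = FALSE]
    combos <- combos[sample.int(nrow(combos)), , drop = FALSE]
    for (r in seq_len(nrow(combos))) {
      s <- gx$start[combos$i[r]]; e <- gx$end[combos$j[r]]
      if (e - s + 1 <= L + 40) next
      dup <- any(vapply(circles, function(cc)
        cc$chrom == gx$chrom[1] && cc$start == s && cc$end == e, logical(1)))
      if (dup) next
      ci <- ci + 1L
      circles[[ci]] <- list(circ_id = sprintf("circle_%03d", ci),
                            chrom = gx$chrom[1], start = s, end = e,
                            strand = gx$strand[1], gene_id = g)
      break
    }
  }
  if (ci < config$circle_count) {
    stop("simulate_backsplice_reads: could not place ", config$circle_count,
         " circles; enlarge the genome", call. = FALSE)
  }

  ## ---- emit reads --------------------------------------------------------
  sub <- function(ch, a, b) paste(genome[[ch]][a:b], collapse = "")
  recs <- character(0)
  add_rec <- function(qname, flag, ch, pos, cigar, rnext, pnext, seq) {
    recs[[length(recs) + 1L]] <<- paste(qname, flag, ch, pos, 60L, cigar,
                                        rnext, pnext, 0L, seq, "*",
                                        sep = "\t")
  }
  for (cc in circles) {
    span <- cc$end - cc$start + 1
    for (r in seq_len(config$reads_per_junction)) {
      split <- sample(20:(L - 20), 1)          # clipped tail length
      head_len <- L - split
      tail_seq <- sub(cc$chrom, cc$end - split + 1, cc$end)
      head_seq <- sub(cc$chrom, cc$start, cc$start + head_len - 1)
      seq1 <- paste0(tail_seq, head_seq)
      qname <- paste0(cc$circ_id, "_r", r)
      mate_pos <- sample(cc$start:(cc$end - L + 1), 1)
      mate_seq <- sub(cc$chrom, mate_pos, mate_pos + L - 1)
      if (head_len >= split) {
        ## anchor the head at the circle start, clip the tail prefix
        add_rec(qname, 65L, cc$chrom, cc$start,
                paste0(split, "S", head_len, "M"),
                "=", mate_pos, seq1)
      } else {
        ## anchor the tail at the circle end, clip the head suffix
        add_rec(qname, 65L, cc$chrom, cc$end - split + 1,
                paste0(split, "M", head_len, "S"),
                "=", mate_pos, seq1)
      }
      add_rec(qname, 129L, cc$chrom, mate_pos, paste0(L, "M"),
              "=", if (head_len >= split) cc$start else cc$end - split + 1,
              mate_seq)
    }
  }

  ## linear background read pairs
  n_bg <- config$n_background_reads
  bi <- 0L
  while (bi < n_bg) {
    ch <- sample(chroms, 1)
    p1 <- sample(1000:(config$chrom_length - 1500), 1)
    p2 <- p1 + sample(150:400, 1)
    qn <- sprintf("bg_%05d", bi %/% 2 + 1L)
    add_rec(qn, 65L, ch, p1, paste0(L, "M"), "=", p2, sub(ch, p1, p1 + L - 1))
    bi <- bi + 1L
    if (bi >= n_bg) break
    add_rec(qn, 129L, ch, p2, paste0(L, "M"), "=", p1, sub(ch, p2, p2 + L - 1))
    bi <- bi + 1L
  }

  header <- c("@HD\tVN:1.6\tSO:unsorted",
              paste0("@SQ\tSN:", chroms, "\tLN:", config$chrom_length))

  ## ---- GTF lines (ensembl dialect) --------------------------------------
  gtf <- character(0)
  for (g in gene_ids) {
    gx <- genes[genes$gene_id == g, , drop = FALSE]
    attr_g <- sprintf('gene_id "%s";', g)
    attr_t <- sprintf('gene_id "%s"; transcript_id "%s.t1";', g, g)
    gtf <- c(gtf,
      paste(gx$chrom[1], "toysim", "gene", min(gx$start), max(gx$end), ".",
            gx$strand[1], ".", attr_g, sep = "\t"),
      paste(gx$chrom[1], "toysim", "transcript", min(gx$start), max(gx$end),
            ".", gx$strand[1], ".", attr_t, sep = "\t"),
      vapply(seq_len(nrow(gx)), function(i)
        paste(gx$chrom[i], "toysim", "exon", gx$start[i], gx$end[i], ".",
              gx$strand[i], ".",
              sprintf('%s exon_number "%d";', attr_t, gx$exon_number[i]),
              sep = "\t"), character(1)))
  }

  bsj <- if (length(circles)) {
    do.call(rbind, lapply(circles, function(cc)
      data.frame(circ_id = cc$circ_id, chrom = cc$chrom, start = cc$start,
                 end = cc$end, strand = cc$strand, gene_id = cc$gene_id,
                 stringsAsFactors = FALSE)))
  } else {
    data.frame(circ_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               gene_id = character(0), stringsAsFactors = FALSE)
  }
  bsj <- bsj[order(bsj$chrom, bsj$start, bsj$end), , drop = FALSE]
  rownames(bsj) <- NULL

  list(genome = vapply(genome, paste, character(1), collapse = ""),
       genes = genes, gtf = gtf, sam = c(header, unlist(recs)),
       bsj_truth = bsj)
}

#' Write a back-splice simulation to disk
#'
#' Emits `genome.fa` (via Biostrings), `annotation.gtf`, `reads.sam` and
#' `bsj_truth.json`.
#'
#' @param bs result of [simulate_backsplice_reads()].
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_backsplice_sim <- function(bs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(bs$genome), fa)
  gtf <- file.path(dir, "annotation.gtf")
  writeLines(bs$gtf, gtf)
  sam <- file.path(dir, "reads.sam")
  writeLines(bs$sam, sam)
  truth <- file.path(dir, "bsj_truth.json")
  jsonlite::write_json(bs$bsj_truth, truth, dataframe = "rows")
  invisible(c(fa, gtf, sam, truth))
}
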