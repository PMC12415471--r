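#' Classify a CIGAR string by its terminal-clip signature
#'
#' Back-splice junction reads align with a characteristic clipped CIGAR:
#' `xS yM` / `xH yM` (left clip), `xM yS` / `xM yH` (right clip), or
#' `xS yM zS` with either clip kind on both ends (the single-exon /
#' long-short-long case). Anything else -- pure matches, internal indels,
#' spliced `N` alignments -- carries no back-splice signature.
#'
#' @param cigar a CIGAR string.
#' @return list with `category` ("left_clip", "right_clip", "double_clip" or
#'   "none") and clip/match lengths `x`, `y`, `z` (NA where not applicable).
#' @export
classify_cigar <- function(cigar) {
  ops <- parse_cigar(cigar)
  none <- list(category = "none", x = NA_integer_, y = NA_integer_, z = NA_integer_)
  is_clip <- ops$op %in% c("S", "H")
  n <- nrow(ops)
  if (n == 2L && is_clip[1] && ops$op[2] == "M") {
    list(category = "left_clip", x = ops$len[1], y = ops$len[2], z = NA_integer_)
  } else if (n == 2L && ops$op[1] == "M" && is_clip[2]) {
    list(category = "right_clip", x = ops$len[1], y = ops$len[2], z = NA_integer_)
  } else if (n == 3L && is_clip[1] && ops$op[2] == "M" && is_clip[3]) {
    list(category = "double_clip", x = ops$len[1], y = ops$len[2], z = ops$len[3])
  } else {
    none
  }
}

#' Parse a CIGAR string into operations
#'
#' @param cigar CIGAR string.
#' @return data.frame with `len` (integer) and `op` (character) columns.
#' @export
parse_cigar <- function(cigar) {
  if (is.na(cigar) || !nzchar(cigar) || cigar == "*") {
    stop("parse_cigar: empty CIGAR", call. = FALSE)
  }
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (sum(nchar(toks)) != nchar(cigar)) {
    consumed <- sum(nchar(toks))
    stop("parse_cigar: malformed CIGAR '", cigar, "' at offset ", consumed + 1,
         call. = FALSE)
  }
  data.frame(len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
             op = sub("^[0-9]+", "", toks), stringsAsFactors = FALSE)
}

#' Read alignment records from a SAM file
#'
#' Converts through BAM (Rsamtools) and returns the fields the back-splice
#' scan needs. The SAM header with `@SQ` lines is required.
#'
#' @param sam_path path to a SAM file.
#' @return data.frame: qname, flag, chrom, pos, cigar, seq, mate_chrom,
#'   mate_pos.
#' @export
read_alignments <- function(sam_path) {
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "mrnm", "mpos")))[[1]]
  data.frame(qname = res$qname, flag = res$flag,
             chrom = as.character(res$rname), pos = res$pos,
             cigar = res$cigar, seq = as.character(res$seq),
             mate_chrom = as.character(res$mrnm), mate_pos = res$mpos,
             stringsAsFactors = FALSE)
}

#' Read a genome FASTA as named character strings
#'
#' @param fa_path path to a FASTA file.
#' @return named character vector, one element per sequence.
#' @export
read_genome <- function(fa_path) {
  seqs <- Biostrings::readDNAStringSet(fa_path)
  stats::setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
}

#' Scan clipped alignments for chiastic back-splice junction candidates
#'
#' For every record with a terminal-clip signature, the clipped query
#' segment is re-matched exactly against the reference within `window` bases
#' of the anchor match. A candidate junction is emitted only in the chiastic
#' configuration: a left clip whose clipped prefix matches *downstream* of
#' the anchor block (the anchor start is the junction acceptor, the clip
#' match end the donor), or a right clip whose clipped suffix matches
#' *upstream* (mirror case). Colinear matches -- ordinary forward splices --
#' produce no candidate. Double-clip records are resolved as the single-exon
#' case: both clips must re-match on opposite ends of one interval. Clips
#' shorter than `min_clip` and clips matching at more than one window
#' position are skipped (ambiguous evidence is never guessed); the number of
#' ambiguous skips is attached as the `ambiguous` attribute.
#'
#' @param aln alignment data.frame from [read_alignments()].
#' @param genome named character vector of chromosome sequences.
#' @param window search half-width around the anchor (bases).
#' @param min_clip minimum clip length to attempt a re-match.
#' @return data.frame: qname, chrom, start, end (1-based inclusive BSJ
#'   coordinates) with an `ambiguous` attribute.
#' @export
detect_junction_candidates <- function(aln, genome, window = 100000L,
                                       min_clip = 10L) {
  missing_chrom <- setdiff(unique(aln$chrom), c(names(genome), NA))
  if (length(missing_chrom)) {
    stop("detect_junction_candidates: chromosome(s) absent from genome: ",
         paste(missing_chrom, collapse = ", "), call. = FALSE)
  }
  ambiguous <- 0L
  rows <- list()
  dna <- lapply(genome, Biostrings::DNAString)

  rematch <- function(chrom, pattern, lo, hi) {
    ## returns unique genomic start of an exact match in [lo, hi], or NA
    lo <- max(1L, lo); hi <- min(nchar(genome[[chrom]]), hi)
    if (hi - lo + 1 < nchar(pattern)) return(NA_integer_)
    m <- Biostrings::matchPattern(pattern,
                                  Biostrings::subseq(dna[[chrom]], lo, hi))
    if (length(m) != 1L) {
      if (length(m) > 1L) ambiguous <<- ambiguous + 1L
      return(NA_integer_)
    }
    lo + Biostrings::start(m)[1] - 1L
  }

  for (i in seq_len(nrow(aln))) {
    cg <- aln$cigar[i]
    if (is.na(cg)) next
    sig <- classify_cigar(cg)
    if (sig$category == "none") next
    chrom <- aln$chrom[i]; pos <- aln$pos[i]; seq <- aln$seq[i]
    if (sig$category == "left_clip") {
      x <- sig$x; y <- sig$y
      if (x < min_clip) next
      clip <- substr(seq, 1L, x)
      q <- rematch(chrom, clip, pos, pos + window)
      ## chiastic: clipped prefix maps beyond the anchor block
      if (!is.na(q) && q >= pos + y) {
        rows[[length(rows) + 1L]] <- data.frame(
          qname = aln$qname[i], chrom = chrom, start = pos, end = q + x - 1L,
          stringsAsFactors = FALSE)
      }
    } else if (sig$category == "right_clip") {
      x <- sig$x; y <- sig$y
      if (y < min_clip) next
      clip <- substr(seq, x + 1L, x + y)
      q <- rematch(chrom, clip, pos - window, pos - 1L)
      ## chiastic: clipped suffix maps before the anchor block
      if (!is.na(q) && q + y - 1L < pos) {
        rows[[length(rows) + 1L]] <- data.frame(
          qname = aln$qname[i], chrom = chrom, start = q, end = pos + x - 1L,
          stringsAsFactors = FALSE)
      }
    } else { # double_clip: clips match opposite ends of one circle interval
      x <- sig$x; y <- sig$y; z <- sig$z
      if (x < min_clip || z < min_clip) next
      pre <- substr(seq, 1L, x)
      suf <- substr(seq, x + y + 1L, x + y + z)
      q_end <- rematch(chrom, pre, pos - window, pos + window)
      q_start <- rematch(chrom, suf, pos - window, pos + window)
      ## the candidate interval must contain the anchor block: the prefix
      ## clip carries the interval end, the suffix clip its start (the read
      ## wraps past the back-splice point on both sides)
      if (!is.na(q_end) && !is.na(q_start) &&
          q_start <= pos && q_end + x - 1L >= pos + y - 1L &&
          q_start < q_end + x - 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          qname = aln$qname[i], chrom = chrom, start = q_start,
          end = q_end + x - 1L, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(qname = character(0), chrom = character(0),
               start = integer(0), end = integer(0), stringsAsFactors = FALSE)
  attr(out, "ambiguous") <- ambiguous
  out
}

#' Paired-end containment constraint on junction candidates
#'
#' A paired junction read supports a circle only if its mate maps inside the
#' candidate circle interval on the same chromosome. Unpaired records bypass
#' the filter.
#'
#' @param candidates data.frame from [detect_junction_candidates()].
#' @param aln alignment data.frame (used for flag and mate fields).
#' @return filtered candidate data.frame.
#' @export
mate_constraint <- function(candidates, aln) {
  if (nrow(candidates) == 0L) return(candidates)
  ## first record per qname carrying a clip signature provides mate info
  idx <- match(candidates$qname, aln$qname)
  flag <- aln$flag[idx]
  paired <- bitwAnd(flag, 1L) == 1L
  mchrom <- aln$mate_chrom[idx]
  mpos <- aln$mate_pos[idx]
  same <- !is.na(mchrom) & (mchrom == candidates$chrom | mchrom == "=")
  inside <- same & !is.na(mpos) & mpos >= candidates$start & mpos <= candidates$end
  keep <- !paired | inside
  out <- candidates[keep, , drop = FALSE]
  attr(out, "ambiguous") <- attr(candidates, "ambiguous")
  out
}

#' Splice-signal classification at a candidate back-splice junction
#'
#' Reads the donor dinucleotide immediately downstream of the junction donor
#' end and the acceptor dinucleotide immediately upstream of the acceptor
#' start. On the plus strand these are `genome[end+1..end+2]` and
#' `genome[start-2..start-1]`; on the minus strand the two flanks swap roles
#' and are reverse-complemented. Returns the canonical GT-AG class, the weak
#' AT-AC class, or none; the strand achieving a signal is reported.
#'
#' @param genome named character vector of chromosome sequences.
#' @param chrom,start,end candidate coordinates (1-based inclusive).
#' @return list with `signal` ("GT-AG", "AT-AC", "none") and `strand`.
#' @export
splice_signal_check <- function(genome, chrom, start, end) {
  n <- nchar(genome[[chrom]])
  if (start - 2L < 1L || end + 2L > n) {
    return(list(signal = "none", strand = "+"))
  }
  up <- substr(genome[[chrom]], start - 2L, start - 1L)   # before acceptor
  down <- substr(genome[[chrom]], end + 1L, end + 2L)     # after donor
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  if (down == "GT" && up == "AG") return(list(signal = "GT-AG", strand = "+"))
  if (rc(up) == "GT" && rc(down) == "AG") {
    return(list(signal = "GT-AG", strand = "-"))
  }
  if (down == "AT" && up == "AC") return(list(signal = "AT-AC", strand = "+"))
  if (rc(up) == "AT" && rc(down) == "AC") {
    return(list(signal = "AT-AC", strand = "-"))
  }
  list(signal = "none", strand = "+")
}

#' Parse exon boundaries and gene ranges from a GTF file
#'
#' @param gtf_path path to a GTF/GFF file readable by rtracklayer.
#' @return list with `exons` (data.frame: chrom, start, end, gene_id) and
#'   `genes` (data.frame: gene_id, chrom, start, end).
#' @export
read_exon_annotation <- function(gtf_path) {
  gr <- as.data.frame(rtracklayer::import(gtf_path))
  ex <- gr[gr$type == "exon", , drop = FALSE]
  exons <- data.frame(chrom = as.character(ex$seqnames),
                      start = ex$start, end = ex$end,
                      gene_id = ex$gene_id, stringsAsFactors = FALSE)
  genes <- do.call(rbind, lapply(split(exons, exons$gene_id), function(d)
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end),
               stringsAsFactors = FALSE)))
  rownames(genes) <- NULL
  list(exons = exons, genes = genes)
}

#' Exon-boundary annotation filter for junction candidates
#'
#' Keeps candidates whose start lies within `tolerance` of an annotated exon
#' start and whose end lies within `tolerance` of an annotated exon end, and
#' assigns the source gene containing the candidate interval. Candidates in
#' unannotated regions are dropped unless `keep_intergenic` is set (those
#' keep `source_gene = NA`).
#'
#' @param candidates data.frame with chrom, start, end columns.
#' @param annotation result of [read_exon_annotation()] (or a GTF path).
#' @param tolerance maximum distance (bases) from an exon boundary.
#' @param keep_intergenic keep candidates failing the boundary test.
#' @return candidates with a `source_gene` column, filtered.
#' @export
annotation_filter <- function(candidates, annotation, tolerance = 0L,
                              keep_intergenic = FALSE) {
  if (is.character(annotation)) annotation <- read_exon_annotation(annotation)
  if (nrow(candidates) == 0L) {
    candidates$source_gene <- character(0)
    return(candidates)
  }
  ex <- annotation$exons
  gn <- annotation$genes
  ok <- logical(nrow(candidates))
  gene <- rep(NA_character_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    e <- ex[ex$chrom == candidates$chrom[i], , drop = FALSE]
    ok[i] <- any(abs(e$start - candidates$start[i]) <= tolerance) &&
      any(abs(e$end - candidates$end[i]) <= tolerance)
    g <- gn[gn$chrom == candidates$chrom[i] &
              gn$start <= candidates$start[i] &
              gn$end >= candidates$end[i], , drop = FALSE]
    if (nrow(g)) gene[i] <- g$gene_id[1]
  }
  candidates$source_gene <- gene
  keep <- ok | (keep_intergenic & is.na(gene))
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group junction candidates into circRNA calls
#'
#' Candidates are grouped by identical (chrom, start, end); junction-read
#' support counts *distinct query names*, so a read pair whose both mates
#' clip is counted once. Calls with support below `min_reads` are dropped;
#' output is sorted by chromosome then start.
#'
#' @param candidates data.frame with qname, chrom, start, end (and
#'   optionally strand, signal, source_gene from earlier stages).
#' @param min_reads minimum distinct supporting query names.
#' @return data.frame: chrom, start, end, junction_reads plus any carried
#'   strand/signal/source_gene columns.
#' @export
call_circles <- function(candidates, min_reads = 2L) {
  if (nrow(candidates) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), junction_reads = integer(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(candidates$chrom, candidates$start, candidates$end, sep = "\r")
  sp <- split(candidates, key)
  out <- do.call(rbind, lapply(sp, function(d) {
    r <- d[1, setdiff(names(d), "qname"), drop = FALSE]
    r$junction_reads <- length(unique(d$qname))
    r
  }))
  out <- out[out$junction_reads >= min_reads, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full back-splice circRNA calling pipeline
#'
#' Runs the clip-signature scan, paired-end mate constraint, splice-signal
#' classification, optional exon-boundary annotation filter, and read-support
#' grouping, in that order.
#'
#' @param sam path to a SAM file, or a data.frame from [read_alignments()].
#' @param genome path to a FASTA file, or a named character vector.
#' @param gtf optional GTF path (or [read_exon_annotation()] result); when
#'   supplied, the annotation filter runs.
#' @param min_reads minimum distinct junction reads per call.
#' @param window re-match search half-width.
#' @param min_clip minimum clip length to attempt a re-match.
#' @param require_gt_ag drop calls without the canonical GT-AG signal.
#' @param tolerance exon-boundary tolerance for the annotation filter.
#' @param keep_intergenic keep unannotated candidates.
#' @return data.frame: chrom, start, end, strand, signal, junction_reads,
#'   source_gene.
#' @export
call_backsplice <- function(sam, genome, gtf = NULL, min_reads = 2L,
                            window = 100000L, min_clip = 10L,
                            require_gt_ag = FALSE, tolerance = 0L,
                            keep_intergenic = FALSE) {
  aln <- if (is.character(sam)) read_alignments(sam) else sam
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_genome(genome)
  }
  cand <- detect_junction_candidates(aln, genome, window = window,
                                     min_clip = min_clip)
  cand <- mate_constraint(cand, aln)
  if (nrow(cand)) {
    sig <- lapply(seq_len(nrow(cand)), function(i)
      splice_signal_check(genome, cand$chrom[i], cand$start[i], cand$end[i]))
    cand$strand <- vapply(sig, `[[`, character(1), "strand")
    cand$signal <- vapply(sig, `[[`, character(1), "signal")
  } else {
    cand$strand <- character(0)
    cand$signal <- character(0)
  }
  if (!is.null(gtf)) {
    cand <- annotation_filter(cand, gtf, tolerance = tolerance,
                              keep_intergenic = keep_intergenic)
  } else {
    cand$source_gene <- rep(NA_character_, nrow(cand))
  }
  calls <- call_circles(cand, min_reads = min_reads)
  if (require_gt_ag && nrow(calls)) {
    calls <- calls[calls$signal == "GT-AG", , drop = FALSE]
    rownames(calls) <- NULL
  }
  cols <- c("chrom", "start", "end", "strand", "signal", "junction_reads",
            "source_gene")
  calls[intersect(cols, names(calls))]
}

#' Write circRNA calls as BED6
#'
#' BED is 0-based half-open: `start - 1` becomes the BED start. The score
#' column carries the junction-read count.
#'
#' @param calls data.frame from [call_backsplice()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_circ_bed <- function(calls, path) {
  name <- sprintf("circ|%s:%d-%d", calls$chrom, calls$start, calls$end)
  bed <- data.frame(chrom = calls$chrom, start = calls$start - 1L,
                    end = calls$end, name = name,
                    score = calls$junction_reads,
                    strand = if (nrow(calls)) calls$strand else character(0),
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
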