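#' Median-of-ratios size factors
#'
#' Per-sample normalization factors in the style RNA-seq count models use:
#' each feature's geometric mean across samples is the reference, features
#' containing any zero are excluded, and a sample's factor is the median of
#' its count-to-reference ratios. Factors are rescaled to geometric mean 1.
#'
#' @param counts nonnegative numeric matrix, features x samples.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("size_factors: negative counts", call. = FALSE)
  log_geo <- rowMeans(log(counts))
  usable <- is.finite(log_geo)          # any zero count gives -Inf
  if (!any(usable)) stop("no usable features", call. = FALSE)
  sf <- apply(counts[usable, , drop = FALSE], 2, function(col)
    stats::median(col / exp(log_geo[usable])))
  if (any(!is.finite(sf) | sf <= 0)) stop("no usable features", call. = FALSE)
  sf / exp(mean(log(sf)))
}

#' FPKM from counts and feature lengths
#'
#' Fragments per kilobase of exon per million mapped fragments:
#' `count / (length/1000) / (mapped/1e6)` with per-sample mapped totals.
#'
#' @param counts feature x sample count matrix.
#' @param lengths named numeric vector or annotation data.frame
#'   (feature_id, length); every feature must be covered.
#' @param mapped per-sample mapped fragment totals; defaults to the column
#'   sums of `counts`.
#' @return numeric matrix of FPKM values, same shape as `counts`.
#' @export
fpkm <- function(counts, lengths, mapped = colSums(counts)) {
  counts <- as.matrix(counts)
  if (is.data.frame(lengths)) {
    lengths <- stats::setNames(lengths$length, lengths$feature_id)
  }
  len <- lengths[rownames(counts)]
  if (any(is.na(len))) {
    stop("fpkm: missing length for feature(s): ",
         paste(rownames(counts)[is.na(len)], collapse = ", "), call. = FALSE)
  }
  sweep(counts / (len / 1000), 2, mapped / 1e6, "/")
}

#' Gene-level FPKM by summing transcript FPKM
#'
#' @param tx_fpkm transcript-level FPKM matrix (transcripts x samples).
#' @param tx2gene named character vector mapping transcript id -> gene id.
#' @return gene x sample FPKM matrix.
#' @export
gene_fpkm <- function(tx_fpkm, tx2gene) {
  g <- tx2gene[rownames(tx_fpkm)]
  if (any(is.na(g))) {
    stop("gene_fpkm: unmapped transcript(s): ",
         paste(rownames(tx_fpkm)[is.na(g)], collapse = ", "), call. = FALSE)
  }
  rowsum(tx_fpkm, group = g)
}

#' Small-RNA read-length filter
#'
#' Retains reads between 18 and 30 nucleotides inclusive, the conventional
#' bounds for miRNA-sized small RNAs.
#'
#' @param read_lengths integer vector of read lengths.
#' @param min,max inclusive bounds.
#' @return integer indices of retained reads.
#' @export
filter_srna_reads <- function(read_lengths, min = 18L, max = 30L) {
  if (any(read_lengths < 0)) {
    stop("filter_srna_reads: negative lengths", call. = FALSE)
  }
  which(read_lengths >= min & read_lengths <= max)
}

#' lncRNA candidate filter
#'
#' Retains candidates strictly longer than 200 bp with at least `min_exons`
#' exons. The exon cutoff is a configuration choice (no universal
#' convention exists); the default of 2 drops mono-exonic candidates.
#'
#' @param ann data.frame with feature_id, length, exon_count.
#' @param min_length strict lower bound on length (bp).
#' @param min_exons minimum exon count (inclusive).
#' @return character vector of retained feature ids.
#' @export
filter_lncrna_candidates <- function(ann, min_length = 200L, min_exons = 2L) {
  stopifnot(all(c("feature_id", "length", "exon_count") %in% names(ann)))
  ann$feature_id[ann$length > min_length & ann$exon_count >= min_exons]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; delegates to [stats::p.adjust()] after validating
#' the input range.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("bh_adjust: p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Negative-binomial Wald differential expression test
#'
#' A compact two-group NB pipeline: median-of-ratios normalization,
#' method-of-moments gene-wise dispersion moderated by a binned-median trend,
#' log2 fold change with a pseudocount, delta-method Wald statistic and a
#' two-sided normal p-value, then Benjamini-Hochberg adjustment.
#'
#' Dispersion: for each gene the moments estimate
#' `(s2 - mu) / mu^2` (pooled within-group variance of normalized counts) is
#' floored at 1e-8 and then at the median estimate of its mean-expression
#' bin. The trend floor stabilizes the handful of genes whose six-sample
#' variance estimate collapses by chance, which would otherwise inflate the
#' Wald statistic and break null calibration.
#'
#' @param counts feature x sample count matrix.
#' @param groups character/factor vector (or named vector over colnames) with
#'   two levels; the fold change is second level over first ("B" over "A").
#' @param alpha significance threshold applied to adjusted (default) or raw
#'   p-values.
#' @param pseudocount added to group means inside the log2 ratio.
#' @param use_adjusted if FALSE, `significant` is called on raw p-values.
#' @param dispersion_bins number of mean-rank bins for the dispersion trend.
#' @return data.frame: feature_id, base_mean, log2fc, stat, p, padj,
#'   significant, direction ("up"/"down", NA at log2fc = 0).
#' @export
de_test <- function(counts, groups, alpha = 0.05, pseudocount = 0.5,
                    use_adjusted = TRUE, dispersion_bins = 10L) {
  counts <- as.matrix(counts)
  if (!is.null(names(groups))) groups <- groups[colnames(counts)]
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2L) stop("de_test: exactly two groups required", call. = FALSE)
  if (any(table(groups) < 2L)) stop("de_test: >=2 samples per group required", call. = FALSE)
  A <- groups == levels(groups)[1]
  B <- !A
  nA <- sum(A); nB <- sum(B)

  sf <- size_factors(counts)
  nc <- sweep(counts, 2, sf, "/")
  muA <- rowMeans(nc[, A, drop = FALSE])
  muB <- rowMeans(nc[, B, drop = FALSE])
  mu <- rowMeans(nc)
  vA <- apply(nc[, A, drop = FALSE], 1, stats::var)
  vB <- apply(nc[, B, drop = FALSE], 1, stats::var)
  s2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  phi <- pmax((s2 - mu) / mu^2, 1e-8)
  phi[!is.finite(phi)] <- 1e-8                     # all-zero features
  bins <- cut(rank(mu, ties.method = "first"), breaks = dispersion_bins)
  phi <- pmax(phi, stats::ave(phi, bins, FUN = stats::median))

  lfc <- log2((muB + pseudocount) / (muA + pseudocount))
  se2 <- ((muA + phi * muA^2) / (nA * (muA + pseudocount)^2) +
          (muB + phi * muB^2) / (nB * (muB + pseudocount)^2)) / log(2)^2
  stat <- ifelse(muA == muB, 0, lfc / sqrt(se2))
  p <- 2 * stats::pnorm(-abs(stat))
  padj <- bh_adjust(p)
  sig <- if (use_adjusted) padj < alpha else p < alpha
  data.frame(
    feature_id = rownames(counts),
    base_mean = mu,
    log2fc = lfc,
    stat = stat,
    p = p,
    padj = padj,
    significant = sig,
    direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", NA_character_)),
    row.names = NULL, stringsAsFactors = FALSE)
}
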