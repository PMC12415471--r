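#' Shared-miRNA over-representation test
#'
#' For two ceRNA candidates with miRNA interaction sets `t_a` and `t_b`
#' inside a common miRNA universe, tests whether they share more miRNAs than
#' expected by chance: with `k = |t_a intersect t_b|`, the p-value is the
#' upper tail `P(X >= k)` of a hypergeometric draw of `|t_b|` miRNAs from a
#' universe of size `M` containing `|t_a|` successes.
#'
#' @param t_a,t_b character vectors of miRNA ids.
#' @param universe character vector containing both sets.
#' @return list with `k` (shared count) and `p` (one-sided p-value).
#' @export
shared_mirna_test <- function(t_a, t_b, universe) {
  t_a <- unique(t_a); t_b <- unique(t_b); universe <- unique(universe)
  if (length(universe) == 0L) stop("shared_mirna_test: empty universe", call. = FALSE)
  if (!all(t_a %in% universe) || !all(t_b %in% universe)) {
    stop("shared_mirna_test: sets must be contained in the universe", call. = FALSE)
  }
  k <- length(intersect(t_a, t_b))
  p <- stats::phyper(k - 1, length(t_a), length(universe) - length(t_a),
                     length(t_b), lower.tail = FALSE)
  list(k = k, p = p)
}

#' Screen sponge-mRNA candidate pairs for ceRNA relationships
#'
#' Every (sponge, mRNA) candidate with nonempty miRNA sets is scored:
#' shared-miRNA count `k`, hypergeometric p, BH FDR (adjusted within each
#' sponge class, since lncRNA and circRNA networks are built separately) and
#' the Pearson correlation of the two members' `log2(x + 1)` expression. A
#' pair is retained when `k >= min_shared`, `p < p_threshold`,
#' `fdr < fdr_threshold` and `pcc > pcc_threshold` (the inequality on k is
#' the literal reading of "shared more than 3 miRNAs": k > 3, i.e. k >= 4).
#'
#' @param sponge_sets named list: sponge id -> character vector of miRNAs.
#' @param mrna_sets named list: mRNA id -> character vector of miRNAs.
#' @param sponge_expr,mrna_expr normalized expression matrices covering the
#'   candidates (features x samples, same sample order).
#' @param universe miRNA universe for the hypergeometric test; defaults to
#'   all miRNAs appearing in the supplied interaction sets.
#' @param sponge_class optional named character vector (sponge id -> class)
#'   controlling the FDR stratification; one stratum when omitted.
#' @param min_shared minimum shared-miRNA count (inclusive).
#' @param p_threshold,fdr_threshold,pcc_threshold strict thresholds.
#' @param keep_all return all scored pairs with a `retained` flag instead of
#'   only the retained ones.
#' @return data.frame: sponge_id, mrna_id, sponge_class, shared_k, p_hyper,
#'   fdr, pcc (and `retained` when `keep_all = TRUE`).
#' @export
screen_pairs <- function(sponge_sets, mrna_sets, sponge_expr, mrna_expr,
                         universe = NULL, sponge_class = NULL,
                         min_shared = 4L, p_threshold = 0.05,
                         fdr_threshold = 0.05, pcc_threshold = 0.8,
                         keep_all = FALSE) {
  sponge_sets <- sponge_sets[lengths(sponge_sets) > 0]
  mrna_sets <- mrna_sets[lengths(mrna_sets) > 0]
  empty <- data.frame(sponge_id = character(0), mrna_id = character(0),
                      sponge_class = character(0), shared_k = integer(0),
                      p_hyper = numeric(0), fdr = numeric(0), pcc = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(sponge_sets) == 0L || length(mrna_sets) == 0L) return(empty)
  if (is.null(universe)) {
    universe <- unique(c(unlist(sponge_sets), unlist(mrna_sets)))
  }
  if (is.null(sponge_class)) {
    sponge_class <- stats::setNames(rep("sponge", length(sponge_sets)),
                                    names(sponge_sets))
  }

  ## incidence matrices over the universe give all pairwise shared counts
  inc <- function(sets) {
    m <- matrix(0L, nrow = length(universe), ncol = length(sets),
                dimnames = list(universe, names(sets)))
    for (j in seq_along(sets)) m[match(sets[[j]], universe), j] <- 1L
    m
  }
  Ms <- inc(sponge_sets)
  Mm <- inc(mrna_sets)
  K <- crossprod(Ms, Mm)               # shared counts, sponges x mrnas

  sponge_id <- rep(rownames(K), times = ncol(K))
  mrna_id <- rep(colnames(K), each = nrow(K))
  k <- as.vector(K)
  sizes_s <- colSums(Ms)[sponge_id]
  sizes_m <- colSums(Mm)[mrna_id]
  M <- length(universe)
  p <- stats::phyper(k - 1, sizes_s, M - sizes_s, sizes_m, lower.tail = FALSE)

  cls <- unname(sponge_class[sponge_id])
  fdr <- stats::ave(p, cls, FUN = function(v) stats::p.adjust(v, "BH"))

  miss <- c(setdiff(unique(sponge_id), rownames(sponge_expr)),
            setdiff(unique(mrna_id), rownames(mrna_expr)))
  if (length(miss)) {
    stop("screen_pairs: missing expression for: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ls_ <- log_expr(sponge_expr[unique(sponge_id), , drop = FALSE])
  lm_ <- log_expr(mrna_expr[unique(mrna_id), , drop = FALSE])
  pcc_mat <- suppressWarnings(stats::cor(t(ls_), t(lm_)))
  pcc <- pcc_mat[cbind(sponge_id, mrna_id)]

  out <- data.frame(sponge_id = sponge_id, mrna_id = mrna_id,
                    sponge_class = cls, shared_k = k, p_hyper = p,
                    fdr = fdr, pcc = pcc, stringsAsFactors = FALSE)
  retained <- out$shared_k >= min_shared & out$p_hyper < p_threshold &
    out$fdr < fdr_threshold & !is.na(out$pcc) & out$pcc > pcc_threshold
  if (keep_all) {
    out$retained <- retained
  } else {
    out <- out[retained, , drop = FALSE]
  }
  out <- out[order(out$sponge_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble sponge-miRNA-mRNA triplets from screened pairs
#'
#' One triplet per (retained pair, shared miRNA) where the miRNA--mRNA edge
#' survived the negative co-expression filter. The miRNA--sponge correlation
#' is recorded when a sponge SCC table is supplied and can optionally be
#' used as an additional filter.
#'
#' @param pairs retained pairs from [screen_pairs()].
#' @param sponge_sets,mrna_sets interaction sets as in [screen_pairs()].
#' @param scc_mrna data.frame (mirna_id, target_id, scc) of miRNA--mRNA
#'   pairs that survived [negative_coexpression_filter()].
#' @param scc_sponge optional data.frame (mirna_id, target_id, scc) of
#'   miRNA--sponge correlations (unfiltered).
#' @param filter_sponge_scc when TRUE, triplets additionally require the
#'   miRNA--sponge SCC to fall below `sponge_scc_threshold`.
#' @param sponge_scc_threshold strict threshold for the optional sponge-side
#'   filter.
#' @return data.frame: sponge_id, mirna_id, mrna_id, sponge_class, shared_k,
#'   p_hyper, fdr, pcc, scc_mirna_mrna, scc_mirna_sponge.
#' @export
assemble_triplets <- function(pairs, sponge_sets, mrna_sets, scc_mrna,
                              scc_sponge = NULL, filter_sponge_scc = FALSE,
                              sponge_scc_threshold = -0.7) {
  empty <- data.frame(sponge_id = character(0), mirna_id = character(0),
                      mrna_id = character(0), sponge_class = character(0),
                      shared_k = integer(0), p_hyper = numeric(0),
                      fdr = numeric(0), pcc = numeric(0),
                      scc_mirna_mrna = numeric(0),
                      scc_mirna_sponge = numeric(0), stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) return(empty)
  if (filter_sponge_scc && is.null(scc_sponge)) {
    stop("assemble_triplets: filter_sponge_scc requires scc_sponge", call. = FALSE)
  }
  mkey <- paste(scc_mrna$mirna_id, scc_mrna$target_id, sep = "\r")
  skey <- if (!is.null(scc_sponge)) {
    stats::setNames(scc_sponge$scc,
                    paste(scc_sponge$mirna_id, scc_sponge$target_id, sep = "\r"))
  }
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    sp <- pairs$sponge_id[i]; mr <- pairs$mrna_id[i]
    shared <- intersect(sponge_sets[[sp]], mrna_sets[[mr]])
    ok <- shared[paste(shared, mr, sep = "\r") %in% mkey]
    if (length(ok) == 0L) next
    scc_mm <- stats::setNames(scc_mrna$scc, mkey)[paste(ok, mr, sep = "\r")]
    scc_ms <- if (!is.null(scc_sponge)) {
      unname(skey[paste(ok, sp, sep = "\r")])
    } else rep(NA_real_, length(ok))
    if (filter_sponge_scc) {
      keep <- !is.na(scc_ms) & scc_ms < sponge_scc_threshold
      ok <- ok[keep]; scc_mm <- scc_mm[keep]; scc_ms <- scc_ms[keep]
      if (length(ok) == 0L) next
    }
    rows[[i]] <- data.frame(
      sponge_id = sp, mirna_id = ok, mrna_id = mr,
      sponge_class = pairs$sponge_class[i], shared_k = pairs$shared_k[i],
      p_hyper = pairs$p_hyper[i], fdr = pairs$fdr[i], pcc = pairs$pcc[i],
      scc_mirna_mrna = unname(scc_mm), scc_mirna_sponge = scc_ms,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$sponge_id, out$mrna_id, out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a ceRNA network
#'
#' Nodes are typed (sponge class, `mirna`, `mrna`); edges run sponge--miRNA
#' (`sponges`) and miRNA--mRNA (`targets`). Supported formats: `sif`
#' (Cytoscape simple interaction file), `graphml`, `edgelist` (TSV). The
#' three writers produce isomorphic graphs.
#'
#' @param triplets data.frame from [assemble_triplets()].
#' @param path output file.
#' @param format one of "sif", "graphml", "edgelist".
#' @return invisibly, the igraph object that was exported.
#' @export
export_network <- function(triplets, path, format = c("sif", "graphml", "edgelist")) {
  if (length(format) == 1L && !format %in% c("sif", "graphml", "edgelist")) {
    stop("export_network: unknown format '", format,
         "'; supported: sif, graphml, edgelist", call. = FALSE)
  }
  format <- match.arg(format)
  g <- cerna_graph(triplets)
  edges <- igraph::as_data_frame(g, what = "edges")
  if (format == "sif") {
    writeLines(paste(edges$from, edges$relation, edges$to), path)
  } else if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.table(edges[c("from", "relation", "to")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(g)
}

#' Build the igraph object for a triplet table
#'
#' @param triplets data.frame with sponge_id, mirna_id, mrna_id (and
#'   optionally sponge_class).
#' @return an igraph graph with a `type` vertex attribute and a `relation`
#'   edge attribute.
#' @export
cerna_graph <- function(triplets) {
  scls <- if ("sponge_class" %in% names(triplets)) triplets$sponge_class else
    rep("sponge", nrow(triplets))
  nodes <- unique(rbind(
    data.frame(name = triplets$sponge_id, type = scls, stringsAsFactors = FALSE),
    data.frame(name = triplets$mirna_id, type = "mirna", stringsAsFactors = FALSE),
    data.frame(name = triplets$mrna_id, type = "mrna", stringsAsFactors = FALSE)))
  edges <- unique(rbind(
    data.frame(from = triplets$sponge_id, to = triplets$mirna_id,
               relation = "sponges", stringsAsFactors = FALSE),
    data.frame(from = triplets$mirna_id, to = triplets$mrna_id,
               relation = "targets", stringsAsFactors = FALSE)))
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}
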