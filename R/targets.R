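#' Intersect two miRNA-target prediction tables
#'
#' High-confidence interactions are the (miRNA, target) pairs predicted by
#' both tools; the tool and score columns are dropped.
#'
#' @param table_a,table_b data.frames with columns mirna_id, target_id (extra
#'   columns ignored).
#' @return data.frame (mirna_id, target_id) of the shared pairs, sorted for
#'   reproducibility. Warns (and returns an empty set) when the intersection
#'   is empty.
#' @export
intersect_predictions <- function(table_a, table_b) {
  for (t in list(table_a, table_b)) {
    stopifnot(all(c("mirna_id", "target_id") %in% names(t)))
  }
  a <- unique(table_a[c("mirna_id", "target_id")])
  b <- unique(table_b[c("mirna_id", "target_id")])
  key <- function(d) paste(d$mirna_id, d$target_id, sep = "\r")
  out <- a[key(a) %in% key(b), , drop = FALSE]
  out <- out[order(out$mirna_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("intersect_predictions: empty intersection")
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranked values. Vectors must have equal length
#' of at least 3; a constant vector has no defined rank correlation and is
#' rejected.
#'
#' @param x,y numeric vectors.
#' @return rho in \[-1, 1\].
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("spearman_cor: vectors must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation", call. = FALSE)
  }
  stats::cor(x, y, method = "spearman")
}

#' Pearson correlation with the same validation contract as [spearman_cor()]
#'
#' @param x,y numeric vectors.
#' @return r in \[-1, 1\].
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("pearson_cor: vectors must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation", call. = FALSE)
  }
  stats::cor(x, y)
}

#' log2(x + 1) expression transform used for all co-expression statistics
#'
#' @param expr numeric matrix of normalized expression (features x samples).
#' @return log2-transformed matrix.
#' @export
log_expr <- function(expr) log2(expr + 1)

#' Negative co-expression filter on miRNA-target interactions
#'
#' Computes the Spearman rank correlation between each interacting miRNA and
#' target across samples (on `log2(x + 1)`-transformed expression) and keeps
#' pairs strictly below the threshold. When DE feature sets are supplied the
#' filter is restricted to DE-miRNA / DE-target pairs first, mirroring the
#' workflow in which only differentially expressed RNAs enter the network.
#'
#' @param interactions data.frame (mirna_id, target_id), e.g. from
#'   [intersect_predictions()].
#' @param mirna_expr,target_expr normalized expression matrices (features x
#'   samples, same sample order) covering every id in `interactions`.
#' @param threshold strict upper bound on the SCC (default -0.7).
#' @param de_mirnas,de_targets optional character vectors; when given, only
#'   pairs with both members differentially expressed are considered.
#' @return data.frame (mirna_id, target_id, scc) of retained pairs.
#' @export
negative_coexpression_filter <- function(interactions, mirna_expr, target_expr,
                                         threshold = -0.7,
                                         de_mirnas = NULL, de_targets = NULL) {
  stopifnot(all(c("mirna_id", "target_id") %in% names(interactions)))
  pairs <- interactions[c("mirna_id", "target_id")]
  if (!is.null(de_mirnas)) pairs <- pairs[pairs$mirna_id %in% de_mirnas, ]
  if (!is.null(de_targets)) pairs <- pairs[pairs$target_id %in% de_targets, ]
  if (nrow(pairs) == 0L) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      scc = numeric(0)))
  }
  miss_m <- setdiff(unique(pairs$mirna_id), rownames(mirna_expr))
  miss_t <- setdiff(unique(pairs$target_id), rownames(target_expr))
  if (length(miss_m) || length(miss_t)) {
    stop("negative_coexpression_filter: missing expression for: ",
         paste(c(miss_m, miss_t), collapse = ", "), call. = FALSE)
  }
  lm_ <- log_expr(mirna_expr[unique(pairs$mirna_id), , drop = FALSE])
  lt_ <- log_expr(target_expr[unique(pairs$target_id), , drop = FALSE])
  scc <- vapply(seq_len(nrow(pairs)), function(i)
    suppressWarnings(stats::cor(lm_[pairs$mirna_id[i], ],
                                lt_[pairs$target_id[i], ],
                                method = "spearman")),
    numeric(1))
  pairs$scc <- scc
  keep <- !is.na(scc) & scc < threshold
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Forward/inverse interaction maps
#'
#' @param interactions data.frame (mirna_id, target_id).
#' @return list with `by_target` (target_id -> character vector of miRNAs)
#'   and `by_mirna` (the inverse).
#' @export
interaction_sets <- function(interactions) {
  list(
    by_target = lapply(split(interactions$mirna_id, interactions$target_id), unique),
    by_mirna = lapply(split(interactions$target_id, interactions$mirna_id), unique)
  )
}
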