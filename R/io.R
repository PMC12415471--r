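#' Read a count-matrix TSV
#'
#' Expects the layout written by [write_sim_counts()]: `feature_id`, `class`,
#' then one column per sample.
#'
#' @param path TSV file.
#' @return integer matrix (features x samples) with a `rna_class` attribute.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("feature_id", "class") %in% names(df)))
  m <- as.matrix(df[, setdiff(names(df), c("feature_id", "class")), drop = FALSE])
  rownames(m) <- df$feature_id
  attr(m, "rna_class") <- df$class
  m
}

#' Read a sample design TSV (sample_id, group)
#'
#' @param path TSV file.
#' @return named character vector sample -> group.
#' @export
read_design_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "group") %in% names(df)))
  stats::setNames(df$group, df$sample_id)
}

#' Read a miRNA-target prediction TSV (mirna_id, target_id, score, tool)
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_target_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("mirna_id", "target_id") %in% names(df)))
  df
}
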