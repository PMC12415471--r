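#' Simulate two miRNA-target prediction tables
#'
#' Emulates running two independent target predictors whose intersection
#' defines the high-confidence interaction set. Every planted interaction --
#' the miRNA--sponge and miRNA--mRNA edges of each planted triplet, plus a
#' random `decoy_targets_per_feature`-sized miRNA set for every decoy sponge
#' and every ordinary DE mRNA -- appears in *both* tables. On top of these
#' shared rows, each table receives rows unique to itself so that a
#' `decoy_target_fraction` of its rows are tool-specific (and are therefore
#' removed by [intersect_predictions()]).
#'
#' @param config a [sim_config()].
#' @param sim result of [simulate_counts()] under the same config.
#' @return list with `table_a`, `table_b` (data.frames: mirna_id, target_id,
#'   score, tool) and `true_pairs` (the shared interaction set, the exact
#'   expected result of intersecting the two tables).
#' @export
simulate_target_tables <- function(config, sim) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  truth <- sim$truth
  mirna_ids <- rownames(sim$counts$mirna)

  ## planted triplet edges (miRNA -> sponge and miRNA -> mRNA)
  edges <- rbind(
    data.frame(mirna_id = truth$triplets$mirna_id,
               target_id = truth$triplets$sponge_id, stringsAsFactors = FALSE),
    data.frame(mirna_id = truth$triplets$mirna_id,
               target_id = truth$triplets$mrna_id, stringsAsFactors = FALSE)
  )

  ## decoy target sets: decoy sponges and ordinary DE mRNAs
  de <- truth$de_features
  decoy_targets <- c(truth$decoy_sponges,
                     de$feature_id[de$class == "mrna" & de$planted_as == "de"])
  npt <- config$decoy_targets_per_feature
  if (length(decoy_targets) > 0 && npt > 0) {
    dec <- data.frame(
      mirna_id = unlist(lapply(decoy_targets, function(t)
        sample(mirna_ids, npt))),
      target_id = rep(decoy_targets, each = npt),
      stringsAsFactors = FALSE)
    edges <- rbind(edges, dec)
  }
  edges <- unique(edges)

  ## tool-unique decoy rows: fraction f of each table must be unique to it
  f <- config$decoy_target_fraction
  n_true <- nrow(edges)
  n_unique <- if (f > 0) round(f / (1 - f) * n_true) else 0L
  all_targets <- unlist(lapply(sim$counts[c("mrna", "lncrna", "circrna")],
                               rownames), use.names = FALSE)
  key <- function(d) paste(d$mirna_id, d$target_id, sep = "\r")
  sample_unique_rows <- function(n, forbidden) {
    out <- data.frame(mirna_id = character(0), target_id = character(0),
                      stringsAsFactors = FALSE)
    while (nrow(out) < n) {
      m <- n - nrow(out)
      cand <- data.frame(mirna_id = sample(mirna_ids, m, replace = TRUE),
                         target_id = sample(all_targets, m, replace = TRUE),
                         stringsAsFactors = FALSE)
      cand <- cand[!(key(cand) %in% forbidden), , drop = FALSE]
      out <- unique(rbind(out, cand))
    }
    out[seq_len(n), , drop = FALSE]
  }
  forbidden <- key(edges)
  uniq_a <- sample_unique_rows(n_unique, forbidden)
  uniq_b <- sample_unique_rows(n_unique, c(forbidden, key(uniq_a)))

  finish <- function(shared, uniq, tool) {
    d <- rbind(shared, uniq)
    d$score <- round(stats::runif(nrow(d)), 4)
    d$tool <- tool
    d[sample.int(nrow(d)), , drop = FALSE] # shuffle row order per tool
  }
  table_a <- finish(edges, uniq_a, "toolA")
  table_b <- finish(edges, uniq_b, "toolB")
  rownames(table_a) <- rownames(table_b) <- NULL

  list(table_a = table_a, table_b = table_b, true_pairs = edges)
}
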