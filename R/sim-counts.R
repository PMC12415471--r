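#' Simulate negative-binomial count matrices with planted truth
#'
#' Draws one count matrix per RNA class (mRNA, lncRNA, circRNA, miRNA) over
#' two groups of `samples_per_group` libraries. Counts follow a negative
#' binomial with per-feature base means on a log10-uniform grid. Three kinds
#' of structure are planted and recorded in the returned truth object:
#'
#' * ordinary DE features: a `de_fraction` of each class has its group-B mean
#'   multiplied by `2^(+-de_log2fc)`;
#' * decoy sponges: `n_decoy_sponges` lncRNA/circRNA features forced DE so
#'   they enter the ceRNA candidate screen (their random target sets are
#'   attached by [simulate_target_tables()]);
#' * triplet members: for each of `n_triplets` planted sponge--miRNA--mRNA
#'   groups, sponge and mRNA share an upward group shift and a common
#'   per-sample latent factor while each of the `k_shared` miRNAs moves in
#'   the opposite direction, yielding positively correlated sponge/mRNA and
#'   anticorrelated miRNA/target expression across all libraries.
#'
#' A feature-annotation table (length, exon count, biotype) is generated for
#' mRNA and lncRNA features so FPKM and the lncRNA candidate filter can run
#' on simulated data.
#'
#' @param config a [sim_config()].
#' @return a list with elements
#'   `counts` (named list of integer matrices, one per class, features x
#'   samples), `groups` (named character vector, sample -> "A"/"B"),
#'   `annotation` (data.frame: feature_id, length, exon_count, biotype) and
#'   `truth` (list: `de_features` data.frame with the planted signed log2
#'   fold changes, `triplets` data.frame of planted
#'   (sponge_id, mirna_id, mrna_id), `decoy_sponges`, `triplet_pairs`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_s <- config$samples_per_group
  samples <- c(paste0("A", seq_len(n_s)), paste0("B", seq_len(n_s)))
  groups <- stats::setNames(rep(c("A", "B"), each = n_s), samples)
  shift <- as.numeric(groups == "B")

  ids <- list(
    mrna   = sprintf("mRNA_%04d", seq_len(config$n_mrna)),
    lncrna = sprintf("lnc_%04d",  seq_len(config$n_lncrna)),
    circrna = sprintf("circ_%04d", seq_len(config$n_circrna)),
    mirna  = sprintf("mir_%04d",  seq_len(config$n_mirna))
  )

  ## --- choose planted triplet members ------------------------------------
  nT <- config$n_triplets
  k <- config$k_shared
  sponge_class <- rep(c("lncrna", "circrna"), length.out = nT)
  trip_sponge <- character(nT)
  n_lnc_trip <- sum(sponge_class == "lncrna")
  trip_sponge[sponge_class == "lncrna"] <- ids$lncrna[seq_len(n_lnc_trip)]
  trip_sponge[sponge_class == "circrna"] <- ids$circrna[seq_len(nT - n_lnc_trip)]
  trip_mrna <- ids$mrna[seq_len(nT)]
  trip_mirna <- if (nT > 0) {
    matrix(ids$mirna[seq_len(nT * k)], nrow = nT, byrow = TRUE)
  } else {
    matrix(character(0), nrow = 0, ncol = k)
  }

  ## --- decoy sponges (forced DE, random target sets added later) ---------
  n_dec <- config$n_decoy_sponges
  dec_lnc <- ceiling(n_dec / 2)
  dec_circ <- n_dec - dec_lnc
  avail_lnc <- setdiff(ids$lncrna, trip_sponge)
  avail_circ <- setdiff(ids$circrna, trip_sponge)
  if (dec_lnc > length(avail_lnc) || dec_circ > length(avail_circ)) {
    stop("simulate_counts: not enough sponge features for n_decoy_sponges",
         call. = FALSE)
  }
  decoy_sponges <- c(avail_lnc[seq_len(dec_lnc)], avail_circ[seq_len(dec_circ)])

  ## shared latent factor per triplet and sample (ln scale)
  Z <- matrix(stats::rnorm(nT * length(samples)), nrow = max(nT, 0))

  de_rows <- list()
  counts <- list()
  for (cls in names(ids)) {
    fid <- ids[[cls]]
    n <- length(fid)
    mu0 <- 10^stats::runif(n, config$nb_mean_log_range[1], config$nb_mean_log_range[2])
    lfc <- rep(0, n)
    phi <- rep(config$nb_dispersion, n)
    lat_amp <- rep(0, n)          # signed latent amplitude per feature
    lat_idx <- rep(NA_integer_, n) # which triplet's latent factor

    trip_members <- switch(cls,
      mrna = stats::setNames(seq_len(nT), trip_mrna)[fid],
      lncrna = ,
      circrna = stats::setNames(seq_along(trip_sponge), trip_sponge)[fid],
      mirna = {
        m <- stats::setNames(rep(seq_len(nT), each = k), as.vector(t(trip_mirna)))
        m[fid]
      })
    trip_members <- unname(trip_members)
    is_trip <- !is.na(trip_members)
    sgn <- if (cls == "mirna") -1 else +1
    if (any(is_trip)) {
      mu0[is_trip] <- 10^stats::runif(sum(is_trip),
                                      config$triplet_mean_log_range[1],
                                      config$triplet_mean_log_range[2])
      lfc[is_trip] <- sgn * config$triplet_log2fc
      phi[is_trip] <- config$triplet_dispersion
      lat_amp[is_trip] <- sgn * config$triplet_latent_sd
      lat_idx[is_trip] <- trip_members[is_trip]
    }

    ## decoy sponges: forced DE, random direction
    is_dec <- fid %in% decoy_sponges
    if (any(is_dec)) {
      lfc[is_dec] <- sample(c(-1, 1), sum(is_dec), replace = TRUE) * config$de_log2fc
    }

    ## ordinary planted DE among the remaining features
    free <- which(!is_trip & !is_dec)
    n_de <- floor(config$de_fraction * n)
    de_pick <- if (n_de > 0 && length(free) > 0) {
      free[sample.int(length(free), min(n_de, length(free)))]
    } else integer(0)
    lfc[de_pick] <- sample(c(-1, 1), length(de_pick), replace = TRUE) * config$de_log2fc

    ## assemble mean matrix and draw counts
    M <- matrix(0L, n, length(samples), dimnames = list(fid, samples))
    for (s in seq_along(samples)) {
      mu <- mu0 * 2^(lfc * shift[s])
      has_lat <- !is.na(lat_idx)
      if (any(has_lat)) {
        mu[has_lat] <- mu[has_lat] * exp(lat_amp[has_lat] * Z[lat_idx[has_lat], s])
      }
      M[, s] <- stats::rnbinom(n, mu = mu, size = 1 / phi)
    }
    counts[[cls]] <- M

    planted <- lfc != 0
    if (any(planted)) {
      de_rows[[cls]] <- data.frame(
        feature_id = fid[planted], class = cls, log2fc = lfc[planted],
        planted_as = ifelse(is_trip[planted], "triplet",
                            ifelse(is_dec[planted], "decoy_sponge", "de")),
        stringsAsFactors = FALSE)
    }
  }

  triplets <- if (nT > 0) {
    data.frame(
      sponge_id = rep(trip_sponge, each = k),
      mirna_id = as.vector(t(trip_mirna)),
      mrna_id = rep(trip_mrna, each = k),
      pair = rep(seq_len(nT), each = k),
      stringsAsFactors = FALSE)
  } else {
    data.frame(sponge_id = character(0), mirna_id = character(0),
               mrna_id = character(0), pair = integer(0))
  }

  ## feature annotation for FPKM / lncRNA filtering demos
  ann <- rbind(
    data.frame(feature_id = ids$mrna,
               length = round(10^stats::runif(config$n_mrna, 2.9, 3.6)),
               exon_count = sample(2:12, config$n_mrna, replace = TRUE),
               biotype = "protein_coding", stringsAsFactors = FALSE),
    data.frame(feature_id = ids$lncrna,
               length = round(10^stats::runif(config$n_lncrna, 2.0, 3.4)),
               exon_count = sample(1:6, config$n_lncrna, replace = TRUE),
               biotype = "lncRNA", stringsAsFactors = FALSE)
  )

  list(
    counts = counts,
    groups = groups,
    annotation = ann,
    truth = list(
      de_features = if (length(de_rows)) do.call(rbind, unname(de_rows)) else
        data.frame(feature_id = character(0), class = character(0),
                   log2fc = numeric(0), planted_as = character(0)),
      triplets = triplets,
      triplet_pairs = unique(triplets[c("sponge_id", "mrna_id", "pair")]),
      decoy_sponges = decoy_sponges
    )
  )
}

#' Write simulated count matrices as TSV files
#'
#' One file per RNA class, columns `feature_id`, `class`, then one column per
#' sample, matching the real-data entry format of the expression module.
#'
#' @param sim result of [simulate_counts()].
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
write_sim_counts <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (cls in names(sim$counts)) {
    M <- sim$counts[[cls]]
    df <- data.frame(feature_id = rownames(M), class = cls, M,
                     check.names = FALSE, stringsAsFactors = FALSE)
    p <- file.path(dir, paste0("counts_", cls, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  grp <- data.frame(sample_id = names(sim$groups), group = unname(sim$groups))
  p <- file.path(dir, "design.tsv")
  utils::write.table(grp, p, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, p))
}
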