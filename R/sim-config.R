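#' Simulation configuration for the synthetic whole-transcriptome study
#'
#' Bundles every knob of the synthetic-data generators into one validated
#' object. The defaults emulate the two-breed, three-libraries-per-breed
#' skin study design the package re-implements: four RNA classes with
#' negative-binomial counts, planted differential expression, planted
#' sponge--miRNA--mRNA triplets recoverable by the ceRNA screen, a toy
#' two-chromosome genome carrying back-spliced circRNA junction reads, and
#' small qPCR / melanin assay tables.
#'
#' Planted triplet members form the "easy regime" of the generator: their
#' counts are drawn with a tighter dispersion (`triplet_dispersion`), a larger
#' group fold change (`triplet_log2fc`) and high base means
#' (`triplet_mean_log_range`), plus a shared per-sample latent factor of
#' amplitude `triplet_latent_sd` that raises sponge and mRNA together while
#' lowering the miRNA, so that the planted coupling is recoverable through
#' the full differential-expression + correlation + hypergeometric screen.
#'
#' @param seed integer seed; identical configs reproduce byte-identical output.
#' @param n_mrna,n_lncrna,n_circrna,n_mirna features per RNA class.
#' @param samples_per_group libraries per group (two groups, "A" and "B").
#' @param nb_mean_log_range log10 range the NB base means are drawn from.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param de_fraction fraction of features per class given a planted group
#'   effect of size `de_log2fc` (random sign).
#' @param de_log2fc absolute log2 fold change of ordinary planted DE features.
#' @param n_triplets number of planted sponge--miRNA--mRNA triplet groups;
#'   sponges alternate between lncRNA and circRNA.
#' @param k_shared miRNAs shared by each planted sponge--mRNA pair.
#' @param triplet_log2fc,triplet_dispersion,triplet_latent_sd,triplet_mean_log_range
#'   easy-regime parameters of planted triplet members (see Details).
#' @param n_decoy_sponges DE sponges (half lncRNA, half circRNA) with random
#'   miRNA target sets; these enter the ceRNA screen as realistic negatives.
#' @param decoy_targets_per_feature miRNAs in each decoy feature's target set.
#' @param decoy_target_fraction fraction of each predictor table's rows that
#'   are unique to that table (and therefore removed by intersection).
#' @param circle_count planted back-splice circles.
#' @param reads_per_junction junction-spanning read pairs per circle.
#' @param read_length read length (bases) of simulated alignments.
#' @param n_background_reads linear full-match background reads in the SAM.
#' @param n_chroms,chrom_length toy genome shape.
#' @param assay_fold_change planted target-gene fold change (group B over A)
#'   in the simulated CT table.
#' @param assay_ct_sd Gaussian noise (cycles) on simulated CT values.
#' @param assay_noise_sd Gaussian noise on simulated standard absorbances.
#' @param assay_slope,assay_intercept planted melanin working-curve line.
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(seed = 1L,
                       n_mrna = 2000L, n_lncrna = 400L, n_circrna = 400L,
                       n_mirna = 200L,
                       samples_per_group = 3L,
                       nb_mean_log_range = c(1, 3),
                       nb_dispersion = 0.1,
                       de_fraction = 0.1,
                       de_log2fc = 2,
                       n_triplets = 10L,
                       k_shared = 5L,
                       triplet_log2fc = 3,
                       triplet_dispersion = 0.01,
                       triplet_latent_sd = 0.25,
                       triplet_mean_log_range = c(2.5, 3.2),
                       n_decoy_sponges = 200L,
                       decoy_targets_per_feature = 5L,
                       decoy_target_fraction = 0.5,
                       circle_count = 50L,
                       reads_per_junction = 10L,
                       read_length = 100L,
                       n_background_reads = 5000L,
                       n_chroms = 2L,
                       chrom_length = 100000L,
                       assay_fold_change = 4,
                       assay_ct_sd = 0.05,
                       assay_noise_sd = 0.002,
                       assay_slope = 1.5,
                       assay_intercept = 0.05) {
  cfg <- list(
    seed = as.integer(seed),
    n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
    n_circrna = as.integer(n_circrna), n_mirna = as.integer(n_mirna),
    samples_per_group = as.integer(samples_per_group),
    nb_mean_log_range = as.numeric(nb_mean_log_range),
    nb_dispersion = as.numeric(nb_dispersion),
    de_fraction = as.numeric(de_fraction),
    de_log2fc = as.numeric(de_log2fc),
    n_triplets = as.integer(n_triplets),
    k_shared = as.integer(k_shared),
    triplet_log2fc = as.numeric(triplet_log2fc),
    triplet_dispersion = as.numeric(triplet_dispersion),
    triplet_latent_sd = as.numeric(triplet_latent_sd),
    triplet_mean_log_range = as.numeric(triplet_mean_log_range),
    n_decoy_sponges = as.integer(n_decoy_sponges),
    decoy_targets_per_feature = as.integer(decoy_targets_per_feature),
    decoy_target_fraction = as.numeric(decoy_target_fraction),
    circle_count = as.integer(circle_count),
    reads_per_junction = as.integer(reads_per_junction),
    read_length = as.integer(read_length),
    n_background_reads = as.integer(n_background_reads),
    n_chroms = as.integer(n_chroms),
    chrom_length = as.integer(chrom_length),
    assay_fold_change = as.numeric(assay_fold_change),
    assay_ct_sd = as.numeric(assay_ct_sd),
    assay_noise_sd = as.numeric(assay_noise_sd),
    assay_slope = as.numeric(assay_slope),
    assay_intercept = as.numeric(assay_intercept)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  num <- unlist(cfg[vapply(cfg, is.numeric, logical(1))])
  if (any(!is.finite(num))) {
    stop("sim_config: all parameters must be finite", call. = FALSE)
  }
  counts <- c("n_mrna", "n_lncrna", "n_circrna", "n_mirna")
  for (f in counts) {
    if (cfg[[f]] < 1L) stop("sim_config: ", f, " must be >= 1", call. = FALSE)
  }
  if (cfg$samples_per_group < 2L) {
    stop("sim_config: samples_per_group must be >= 2", call. = FALSE)
  }
  if (cfg$nb_dispersion <= 0 || cfg$triplet_dispersion <= 0) {
    stop("sim_config: dispersions must be > 0", call. = FALSE)
  }
  for (f in c("de_fraction", "decoy_target_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("sim_config: ", f, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$de_log2fc < 0) stop("sim_config: de_log2fc must be >= 0", call. = FALSE)
  if (length(cfg$nb_mean_log_range) != 2L ||
      diff(cfg$nb_mean_log_range) < 0) {
    stop("sim_config: nb_mean_log_range must be an increasing pair", call. = FALSE)
  }
  need_mirna <- cfg$n_triplets * cfg$k_shared
  if (need_mirna > cfg$n_mirna) {
    stop("sim_config: n_triplets * k_shared exceeds n_mirna", call. = FALSE)
  }
  if (cfg$n_triplets > min(cfg$n_mrna, cfg$n_lncrna + cfg$n_circrna)) {
    stop("sim_config: not enough features to host the planted triplets", call. = FALSE)
  }
  if (cfg$read_length < 40L) {
    stop("sim_config: read_length must be >= 40 (junction reads need 20 bases on each side)",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config (seed ", x$seed, "): ",
      x$n_mrna, " mRNA / ", x$n_lncrna, " lncRNA / ",
      x$n_circrna, " circRNA / ", x$n_mirna, " miRNA, ",
      2L * x$samples_per_group, " libraries, ",
      x$n_triplets, " planted triplets, ",
      x$circle_count, " planted circles\n", sep = "")
  invisible(x)
}
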