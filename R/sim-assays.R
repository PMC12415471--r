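#' Simulate qPCR CT and melanin-standard absorbance tables
#'
#' The CT table carries one target gene and one reference gene
#' (a beta-actin-like internal control) per sample over the two groups, with
#' a planted group-B fold change of `assay_fold_change` on the target: the
#' target CT in group B is lowered by `log2(assay_fold_change)` cycles while
#' the reference stays flat, so the expected recovered relative expression
#' under the ddCt method equals the planted fold change. The absorbance
#' table follows the standard melanin working-curve grid (0 to 0.6 mg/mL)
#' from a planted linear slope/intercept with Gaussian noise.
#'
#' @param config a [sim_config()].
#' @return list with `ct` (data.frame: sample_id, group, gene_id, role, ct),
#'   `standards` (data.frame: conc, absorbance) and `truth` (planted
#'   fold_change, slope, intercept).
#' @export
simulate_assay_tables <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  n_s <- config$samples_per_group
  samples <- c(paste0("A", seq_len(n_s)), paste0("B", seq_len(n_s)))
  groups <- rep(c("A", "B"), each = n_s)

  ref_base <- 18
  dct_base <- 6                       # target CT sits above the reference
  shift <- log2(config$assay_fold_change) * (groups == "B")
  ref_ct <- ref_base + stats::rnorm(length(samples), 0, config$assay_ct_sd)
  tgt_ct <- ref_ct + dct_base - shift +
    stats::rnorm(length(samples), 0, config$assay_ct_sd)
  ct <- rbind(
    data.frame(sample_id = samples, group = groups, gene_id = "TARGET1",
               role = "target", ct = tgt_ct, stringsAsFactors = FALSE),
    data.frame(sample_id = samples, group = groups, gene_id = "ACTB",
               role = "reference", ct = ref_ct, stringsAsFactors = FALSE))
  rownames(ct) <- NULL

  conc <- melanin_standard_grid()
  absorbance <- config$assay_intercept + config$assay_slope * conc +
    stats::rnorm(length(conc), 0, config$assay_noise_sd)
  standards <- data.frame(conc = conc, absorbance = absorbance)

  list(ct = ct, standards = standards,
       truth = list(fold_change = config$assay_fold_change,
                    slope = config$assay_slope,
                    intercept = config$assay_intercept))
}

#' Standard melanin concentration grid (mg/mL)
#'
#' The 14-point concentration series used to establish the melanin working
#' curve.
#'
#' @return numeric vector of concentrations in mg/mL.
#' @export
melanin_standard_grid <- function() {
  c(0, 0.02, 0.04, 0.06, 0.08, 0.1, 0.12, 0.14, 0.16, 0.2, 0.3, 0.4, 0.5, 0.6)
}
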