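#' Relative expression by the 2^-ddCt method
#'
#' Per sample, the target CT is normalized by the reference-gene CT
#' (`dCt = CT_target - CT_reference`), then by the mean dCt of the
#' calibrator group (`ddCt = dCt - mean(dCt[calibrator])`); relative
#' expression is `2^-ddCt`. Multiple target or reference wells per sample
#' are averaged first.
#'
#' @param ct data.frame with columns sample_id, group, gene_id, role
#'   ("target"/"reference"), ct.
#' @param calibrator_group group whose mean dCt defines the baseline.
#' @return data.frame: sample_id, group, dct, ddct, rel_expr.
#' @export
ddct <- function(ct, calibrator_group = "A") {
  stopifnot(all(c("sample_id", "group", "role", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("ddct: CT values must be positive", call. = FALSE)
  samples <- unique(ct[c("sample_id", "group")])
  if (!calibrator_group %in% samples$group) {
    stop("ddct: calibrator group '", calibrator_group, "' has no samples",
         call. = FALSE)
  }
  dct <- vapply(samples$sample_id, function(s) {
    rows <- ct[ct$sample_id == s, , drop = FALSE]
    tgt <- rows$ct[rows$role == "target"]
    ref <- rows$ct[rows$role == "reference"]
    if (length(ref) == 0L) {
      stop("ddct: sample '", s, "' has no reference CT", call. = FALSE)
    }
    if (length(tgt) == 0L) {
      stop("ddct: sample '", s, "' has no target CT", call. = FALSE)
    }
    mean(tgt) - mean(ref)
  }, numeric(1))
  baseline <- mean(dct[samples$group == calibrator_group])
  ddct_v <- dct - baseline
  data.frame(sample_id = samples$sample_id, group = samples$group,
             dct = unname(dct), ddct = unname(ddct_v),
             rel_expr = 2^(-unname(ddct_v)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit a melanin working curve
#'
#' Ordinary least squares of absorbance on standard concentration, with R^2
#' from the residual sum of squares.
#'
#' @param conc standard concentrations (mg/mL), at least 3 distinct values.
#' @param absorbance measured absorbances, same length.
#' @return object of class `standard_curve`: list(slope, intercept, r2, n).
#' @export
melanin_fit <- function(conc, absorbance) {
  if (length(conc) != length(absorbance)) {
    stop("melanin_fit: conc and absorbance lengths differ", call. = FALSE)
  }
  if (length(unique(conc)) < 3L) {
    stop("melanin_fit: need >= 3 distinct concentrations", call. = FALSE)
  }
  fit <- stats::lm(absorbance ~ conc)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((absorbance - mean(absorbance))^2)
  out <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
              n = length(conc))
  class(out) <- "standard_curve"
  out
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("melanin working curve: A = %.4f x conc + %.4f (R^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Melanin content of a fiber sample from its absorbance
#'
#' Inverts the working curve (`conc = (A - intercept) / slope`, floored at
#' zero) and scales by extraction volume and fiber mass:
#' `content = conc * volume / (mass/1000)` in mg melanin per g fiber.
#'
#' @param curve a `standard_curve` from [melanin_fit()].
#' @param absorbance measured absorbance of the extract.
#' @param fiber_mass_mg fiber sample mass in mg (typically 15--30 mg).
#' @param volume_ml extraction volume in mL.
#' @return melanin content, mg per g fiber.
#' @export
melanin_content <- function(curve, absorbance, fiber_mass_mg, volume_ml = 1.0) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) stop("melanin_content: zero-slope curve", call. = FALSE)
  if (any(fiber_mass_mg <= 0)) {
    stop("melanin_content: fiber mass must be positive", call. = FALSE)
  }
  conc <- (absorbance - curve$intercept) / curve$slope
  if (any(conc < -1e-9)) {   # below blank beyond numerical noise
    warning("melanin_content: absorbance below intercept; concentration floored at 0")
  }
  conc <- pmax(conc, 0)
  conc * volume_ml / (fiber_mass_mg / 1000)
}

#' Hair follicle density from a marked section image
#'
#' @param marked_count follicles marked on the image.
#' @param area_mm2 imaged area; defaults to the 9.26 mm^2 standard field.
#' @return follicles per mm^2.
#' @export
follicle_density <- function(marked_count, area_mm2 = 9.26) {
  if (any(marked_count < 0)) {
    stop("follicle_density: negative count", call. = FALSE)
  }
  if (any(area_mm2 <= 0)) {
    stop("follicle_density: area must be positive", call. = FALSE)
  }
  marked_count / area_mm2
}

#' Independent two-group t-test with summary statistics
#'
#' Student's pooled-variance two-sample t-test (two-sided) by default,
#' matching a workflow in which variance homogeneity is verified beforehand;
#' `welch = TRUE` switches to the Welch test. Groups with zero pooled
#' variance and equal means return t = 0, p = 1. Significance stars follow
#' the usual convention (* p < 0.05, ** p < 0.01).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use the Welch (unequal-variance) test.
#' @return list: t, df, p, mean_a, sd_a, mean_b, sd_b, stars.
#' @export
two_group_test <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("two_group_test: each group needs >= 2 observations", call. = FALSE)
  }
  res <- tryCatch(
    stats::t.test(a, b, var.equal = !welch),
    error = function(e) NULL)
  if (is.null(res)) {  # degenerate: zero variance
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      tt <- 0; df <- length(a) + length(b) - 2; p <- 1
    } else {
      tt <- sign(mean(a) - mean(b)) * Inf
      df <- length(a) + length(b) - 2; p <- 0
    }
  } else {
    tt <- unname(res$statistic); df <- unname(res$parameter); p <- res$p.value
  }
  stars <- if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  list(t = tt, df = df, p = p,
       mean_a = mean(a), sd_a = stats::sd(a),
       mean_b = mean(b), sd_b = stats::sd(b),
       stars = stars)
}
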