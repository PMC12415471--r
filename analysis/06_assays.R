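#!/usr/bin/env Rscript
# Stage 6: validation-assay computations.
#
# 2^-ddCt relative expression from the qPCR CT table (group A as the
# calibrator), melanin working curve from the 14-point standard series with
# content inversion for example fleece samples, follicle density from marked
# counts on the 9.26 mm^2 standard field, and the pooled-variance two-group
# t-test used for all phenotype comparisons.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(FALSE),
                                                 value = TRUE))), "common.R"))

ct <- utils::read.delim(file.path(SIM_DIR, "qpcr_ct.tsv"))
rel <- ddct(ct, calibrator_group = "A")
utils::write.table(rel, file.path(RESULTS, "qpcr_relative_expression.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("2^-ddCt: group A mean %.3f, group B mean %.3f\n",
            mean(rel$rel_expr[rel$group == "A"]),
            mean(rel$rel_expr[rel$group == "B"])))

std <- utils::read.delim(file.path(SIM_DIR, "melanin_standards.tsv"))
curve <- melanin_fit(std$conc, std$absorbance)
print(curve)
utils::write.table(
  data.frame(slope = curve$slope, intercept = curve$intercept, r2 = curve$r2),
  file.path(RESULTS, "melanin_curve.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

## example fleece measurements run through the curve (20 mg fiber, 1 mL NaOH)
example_abs <- c(0.18, 0.32, 0.55)
content <- melanin_content(curve, example_abs, fiber_mass_mg = 20)
cat("melanin content (mg/g fiber) for absorbances",
    paste(example_abs, collapse = ", "), "->",
    paste(round(content, 2), collapse = ", "), "\n")

## follicle density on the standard 9.26 mm^2 field
marked <- c(groupA = 420L, groupB = 610L)
cat("follicle densities (per mm^2):",
    paste(names(marked), round(follicle_density(marked), 1),
          sep = "=", collapse = ", "), "\n")

## two-group comparison of the relative expression values
tt <- two_group_test(rel$rel_expr[rel$group == "A"],
                     rel$rel_expr[rel$group == "B"])
cat(sprintf(
  "t-test A vs B: t = %.3f (df %.1f), p = %.4g %s; A %.2f+/-%.2f, B %.2f+/-%.2f\n",
  tt$t, tt$df, tt$p, tt$stars, tt$mean_a, tt$sd_a, tt$mean_b, tt$sd_b))
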