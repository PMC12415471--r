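# cernaflow

Competing-endogenous-RNA (ceRNA) network inference from two-group
whole-transcriptome data, built as a tested R package plus a numbered
analysis workflow.

## The problem

Skin transcriptome studies comparing two animal populations (here: two goat
breeds differing in coat colour and cashmere traits) profile four RNA
classes — mRNA, lncRNA, circRNA, miRNA — across a handful of libraries per
group, and ask which regulatory couplings distinguish the phenotypes. The
analysis chain is long: negative-binomial differential expression,
miRNA-target prediction with tool intersection, co-expression filtering,
hypergeometric shared-miRNA testing to nominate sponge–miRNA–mRNA triplets,
and circRNA discovery from back-spliced read alignments. Each step has
sharp, testable contracts, but published pipelines rarely ship them in
runnable form. `cernaflow` implements the whole chain with a synthetic-data
generator that plants recoverable truth, so every stage is verifiable
offline.

## The statistics at the core

* **Differential expression** — counts modelled as NB($\mu$, $\mu+\phi\mu^2$);
  median-of-ratios size factors; gene-wise method-of-moments dispersion
  floored at a binned-median trend; Wald test on
  $\log_2 FC = \log_2\frac{\bar\mu_B + c}{\bar\mu_A + c}$ with
  Benjamini–Hochberg adjustment.
* **ceRNA screen** — for sponge and mRNA target sets $T_A, T_B$ in a miRNA
  universe of size $M$: $k = |T_A \cap T_B|$ with hypergeometric
  $p = P(X \ge k)$; retain pairs with $k > 3$, $p < 0.05$, FDR $< 0.05$,
  and Pearson $r > 0.8$ between sponge and mRNA log2 expression; triplets
  require the miRNA–mRNA Spearman correlation $< -0.7$.
* **Back-splice calling** — chiastic clip signatures (`xS yM`, `xM yS`,
  `xS yM zS`) re-matched against the genome, paired-end mate containment,
  strand-aware GT–AG / AT–AC splice signals, exon-boundary filtering, and a
  ≥ 2 distinct-read support threshold.
* **Assays** — 2^−ΔΔCt relative expression, OLS melanin working curve with
  inversion to mg/g fiber, follicle density per mm², pooled-variance
  t-test.

## Worked example

The numbered scripts under `analysis/` run the full study on synthetic data
(seed fixed in `analysis/common.R`), writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_differential_expression.R
Rscript analysis/03_target_links.R
Rscript analysis/04_cerna_network.R
Rscript analysis/05_backsplice.R
Rscript analysis/06_assays.R
```

Output of the ceRNA stage:

```
candidates: 202 DE sponges x 188 DE mRNAs with target sets
retained ceRNA pairs: 10 (5 lncRNA-mRNA, 5 circRNA-mRNA)
network: 68 nodes, 96 edges from 48 triplets
planted-triplet recall 0.960, precision 1.000
```

The generator planted 10 sponge–mRNA pairs each sharing 5 miRNAs; the
screen retains exactly those 10 pairs out of ~38,000 candidates, and 48 of
the 50 planted (sponge, miRNA, mRNA) triplets survive the full chain (two
miRNA–mRNA edges fall short of the strict −0.7 rank-correlation cutoff at
n = 6 — the expected price of a strict threshold on six samples). The
back-splice stage reports:

```
called 50 junctions; planted 50
recall 1.000, false calls 0
splice signals: GT-AG=50
```

and the assay stage recovers the planted 4-fold qPCR effect and the melanin
curve:

```
2^-ddCt: group A mean 1.000, group B mean 4.092
melanin working curve: A = 1.4987 x conc + 0.0497 (R^2 = 1.0000, n = 14)
follicle densities (per mm^2): groupA=45.4, groupB=65.9
```

The same machinery is available programmatically:

```r
library(cernaflow)
cfg <- sim_config(seed = 7)
res <- run_pipeline(cfg, "run1")
evaluate_recovery(res)
#> $triplet_recall   [1] 0.98
#> $triplet_precision [1] 1
#> $bsj_recall       [1] 1
#> $bsj_false_calls  [1] 0
```

Real data enter through the same file formats the simulator writes: count
TSVs (`feature_id`, `class`, one column per sample), prediction TSVs
(`mirna_id`, `target_id`, `score`, `tool`), FASTA + GTF + SAM for the
circRNA caller, and CT / standards TSVs for the assays.

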