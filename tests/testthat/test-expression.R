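test_that("size factors satisfy the median-of-ratios contract", {
  # identical columns: all factors 1
  m <- matrix(rep(c(10, 100, 7), 3), ncol = 3)
  expect_equal(size_factors(m), rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)

  # hand-computed toy: second column doubled -> factor ratio 2
  toy <- matrix(c(10, 100, 1, 20, 200, 2), ncol = 2)
  sf <- size_factors(toy)
  expect_equal(sf[2] / sf[1], 2, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)

  # scale equivariance: multiplying one column scales its factor
  set.seed(1)
  m <- matrix(rpois(60, 50) + 1, ncol = 4)
  m2 <- m; m2[, 3] <- m2[, 3] * 5
  expect_equal(size_factors(m2)[3] / size_factors(m2)[1],
               5 * size_factors(m)[3] / size_factors(m)[1],
               tolerance = 1e-12)

  # permutation invariance over features
  expect_equal(size_factors(m[sample(nrow(m)), ]), size_factors(m))

  expect_error(size_factors(matrix(0, 3, 2)), "no usable features")
})

test_that("size factors agree with the DESeq2 estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(2)
  # odd feature count: the linear-space and log-space median conventions
  # pick the same element, so the two estimators agree exactly
  m <- matrix(rnbinom(101 * 6, mu = 100, size = 5), ncol = 6)
  m <- m[rowSums(m == 0) == 0, , drop = FALSE]
  if (nrow(m) %% 2 == 0) m <- m[-1, , drop = FALSE]
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ours <- size_factors(m)
  # same up to the geometric-mean-1 rescaling convention
  expect_equal(ours / ours[1], unname(ref / ref[1]), tolerance = 1e-10)
})

test_that("fpkm computes the length- and depth-normalized value", {
  m <- matrix(c(0, 1000), ncol = 1, dimnames = list(c("t0", "t1"), "s1"))
  v <- fpkm(m, c(t0 = 500, t1 = 1000), mapped = 1e6)
  expect_equal(v["t0", 1], 0)
  expect_equal(v["t1", 1], 1000)  # 1000 / (1 kb * 1 M)
  expect_error(fpkm(m, c(t1 = 1000)), "missing length.*t0")

  # gene FPKM = sum of transcript FPKM
  tx <- matrix(c(2, 3), ncol = 1, dimnames = list(c("tA", "tB"), "s1"))
  g <- gene_fpkm(tx, c(tA = "g1", tB = "g1"))
  expect_equal(g["g1", 1], 5)
})

test_that("small-RNA length filter keeps [18, 30] inclusive", {
  lens <- c(17, 18, 19, 30, 31, 25, 0)
  kept <- filter_srna_reads(lens)
  expect_equal(lens[kept], c(18, 19, 30, 25))
  expect_error(filter_srna_reads(c(-1, 20)), "negative")
})

test_that("lncRNA candidate filter applies strict length and exon cutoffs", {
  ann <- data.frame(feature_id = c("a", "b", "c", "d"),
                    length = c(200, 201, 5000, 1000),
                    exon_count = c(3, 2, 1, 4))
  expect_equal(filter_lncrna_candidates(ann), c("b", "d"))  # 200 bp excluded
  expect_equal(filter_lncrna_candidates(ann, min_exons = 1), c("b", "c", "d"))
})

test_that("bh_adjust reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("bh_adjust matches a brute-force step-up oracle on random vectors", {
  brute_bh <- function(p) {
    m <- length(p)
    cnt <- rank(p, ties.method = "max")       # |{j : p_j <= p_i}|
    vals <- p * m / cnt
    vapply(seq_len(m), function(i) min(1, min(vals[p >= p[i]])), numeric(1))
  }
  set.seed(7)
  for (r in 1:50) {
    p <- round(runif(sample(1:60, 1)), sample(1:4, 1))  # ties likely
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("de_test handles degenerate features and reports directions", {
  # balanced libraries (identical columns): a flat feature gives lfc 0, p 1
  set.seed(3)
  base <- rnbinom(50, mu = 50, size = 10) + 1
  flat <- matrix(rep(c(base, 0), 6), ncol = 6,
                 dimnames = list(sprintf("g%03d", 1:51), paste0("s", 1:6)))
  grp <- setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  de0 <- de_test(flat, grp)
  expect_equal(de0$log2fc, rep(0, 51))
  expect_equal(de0$p, rep(1, 51))       # includes the all-zero feature

  m <- matrix(rnbinom(200 * 6, mu = 50, size = 10), ncol = 6,
              dimnames = list(sprintf("g%03d", 1:200), paste0("s", 1:6)))
  de <- de_test(m, grp)
  expect_false(any(is.na(de$p)))
  expect_true(all(de$padj >= de$p))
  expect_true(all(de$p >= 0 & de$p <= 1))
  expect_true(all(de$direction[de$log2fc > 0] == "up"))
  expect_true(all(de$direction[de$log2fc < 0] == "down"))
})

test_that("de_test log2fc sign follows the group mean difference", {
  set.seed(4)
  m <- matrix(rnbinom(100 * 6, mu = 80, size = 5), ncol = 6,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  grp <- setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6))
  de <- de_test(m, grp)
  sf <- size_factors(m)
  nc <- sweep(m, 2, sf, "/")
  dif <- rowMeans(nc[, 4:6]) - rowMeans(nc[, 1:3])
  nz <- dif != 0
  expect_equal(sign(de$log2fc[nz]), sign(dif[nz]), ignore_attr = TRUE)
})

test_that("de_test flags strong planted effects and not their mirror", {
  cfg <- small_config(seed = 12L, n_mrna = 600L, de_fraction = 0.1,
                      de_log2fc = 2, nb_mean_log_range = c(2, 3),
                      n_triplets = 0L, n_decoy_sponges = 0L)
  sim <- simulate_counts(cfg)
  de <- de_test(sim$counts$mrna, sim$groups)
  truth <- subset(sim$truth$de_features, class == "mrna")
  hit <- de[match(truth$feature_id, de$feature_id), ]
  expect_gt(mean(hit$significant), 0.8)
  flagged <- hit[hit$significant, ]
  expect_true(all(sign(flagged$log2fc) ==
                    sign(truth$log2fc[match(flagged$feature_id,
                                            truth$feature_id)])))
})
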