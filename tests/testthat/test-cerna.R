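test_that("shared-miRNA hypergeometric test matches closed-form cases", {
  U <- paste0("m", 1:10)
  # no overlap: P(X >= 0) = 1
  r0 <- shared_mirna_test(U[1:3], U[4:6], U)
  expect_equal(r0$k, 0L)
  expect_equal(r0$p, 1)
  # both sets equal the universe: overlap is certain
  r1 <- shared_mirna_test(U, U, U)
  expect_equal(r1$p, 1)
  # M=10, |tA|=5, |tB|=4, k=3: p = 55/210 by enumeration of all C(10,4) draws
  r2 <- shared_mirna_test(U[1:5], c(U[1:3], U[6]), U)
  expect_equal(r2$k, 3L)
  expect_equal(r2$p, 55 / 210, tolerance = 1e-12)

  expect_error(shared_mirna_test(c("x"), U[1:2], U), "contained")
  expect_error(shared_mirna_test(U[1], U[2], character(0)), "empty universe")
})

test_that("hypergeometric p equals subset enumeration on small universes", {
  # literal enumeration over every draw of t_b, universes up to M = 8
  for (M in 2:8) {
    U <- paste0("m", seq_len(M))
    for (K in 1:M) {
      for (n in 1:M) {
        draws <- utils::combn(M, n)
        overlap <- colSums(draws <= K)
        for (k in 0:min(K, n)) {
          if (n - k > M - K) next
          tB <- c(seq_len(k), K + seq_len(n - k))
          r <- shared_mirna_test(U[seq_len(K)], U[tB], U)
          expect_equal(r$k, k)
          expect_equal(r$p, mean(overlap >= k), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("hypergeometric p is monotone non-increasing in the overlap", {
  U <- paste0("m", 1:20)
  p <- vapply(0:6, function(k) {
    tB <- c(U[seq_len(k)], U[8 + seq_len(6 - k)])
    shared_mirna_test(U[1:8], tB, U)$p
  }, numeric(1))
  expect_true(all(diff(p) <= 1e-15))
})

mk_screen_fixture <- function() {
  U <- paste0("m", 1:40)
  sam <- paste0("s", 1:6)
  base <- 2^c(1, 1.1, 0.9, 5, 5.2, 4.9)          # strongly group-separated
  sponge_sets <- list(L1 = U[1:5],                 # shares 5 with G1
                      L2 = U[c(1:3, 11)],          # shares 3 with G1
                      L3 = U[21:25])               # shares 5 with G2
  mrna_sets <- list(G1 = U[1:5], G2 = U[21:25])
  se <- rbind(L1 = base, L2 = base, L3 = base * 2)
  me <- rbind(G1 = base * 1.5, G2 = base)          # all share the group pattern
  colnames(se) <- colnames(me) <- sam
  list(U = U, sponge_sets = sponge_sets, mrna_sets = mrna_sets,
       se = se, me = me)
}

test_that("pair screening applies every threshold strictly", {
  fx <- mk_screen_fixture()
  all_pairs <- screen_pairs(fx$sponge_sets, fx$mrna_sets, fx$se, fx$me,
                            universe = fx$U, keep_all = TRUE)
  expect_equal(nrow(all_pairs), 6L)  # 3 sponges x 2 mRNAs

  got <- screen_pairs(fx$sponge_sets, fx$mrna_sets, fx$se, fx$me,
                      universe = fx$U)
  # L2-G1 shares exactly 3 miRNAs: rejected under the strict "more than 3"
  expect_false(any(got$sponge_id == "L2"))
  # L1-G1 and L3-G2 share 5 and are strongly co-expressed
  expect_true(all(c("L1", "L3") %in% got$sponge_id))
  expect_true(all(got$shared_k >= 4))
  expect_true(all(got$p_hyper < 0.05 & got$fdr < 0.05 & got$pcc > 0.8))

  # k = 3 passes when min_shared is lowered to 3
  low <- screen_pairs(fx$sponge_sets, fx$mrna_sets, fx$se, fx$me,
                      universe = fx$U, min_shared = 3L)
  expect_true(any(low$sponge_id == "L2" & low$mrna_id == "G1"))
})

test_that("a pair at pcc exactly 0.8 is rejected", {
  U <- paste0("m", 1:10)
  sets_s <- list(S = U[1:5]); sets_m <- list(G = U[1:5])
  sam <- paste0("s", 1:6)
  se <- matrix(2^c(1, 2, 3, 4, 5, 6) - 1, 1, 6, dimnames = list("S", sam))
  me <- matrix(c(5, 80, 20, 160, 40, 640), 1, 6, dimnames = list("G", sam))
  # threshold set to the pair's own PCC: the strict inequality must reject it
  pcc <- cor(log2(se + 1)[1, ], log2(me + 1)[1, ])
  res <- screen_pairs(sets_s, sets_m, se, me, universe = U,
                      pcc_threshold = pcc, keep_all = TRUE)
  expect_false(res$retained[1])  # strict inequality at the boundary
})

test_that("relaxing any single screening threshold never shrinks the pair set", {
  cfg <- small_config(seed = 21L)
  sim <- simulate_counts(cfg)
  tb <- simulate_target_tables(cfg, sim)
  inter <- intersect_predictions(tb$table_a, tb$table_b)
  sets <- interaction_sets(inter)
  sponges <- intersect(names(sets$by_target),
                       c(rownames(sim$counts$lncrna), rownames(sim$counts$circrna)))
  mrnas <- intersect(names(sets$by_target), rownames(sim$counts$mrna))
  se <- rbind(sim$counts$lncrna, sim$counts$circrna)
  me <- sim$counts$mrna
  base <- function(...) screen_pairs(sets$by_target[sponges],
                                     sets$by_target[mrnas], se, me, ...)
  key <- function(d) paste(d$sponge_id, d$mrna_id)
  strict <- base()
  for (relax in list(list(min_shared = 3L), list(p_threshold = 0.2),
                     list(fdr_threshold = 0.2), list(pcc_threshold = 0.5))) {
    relaxed <- do.call(base, relax)
    expect_true(all(key(strict) %in% key(relaxed)))
  }
})

test_that("triplet assembly emits one triplet per surviving shared miRNA", {
  pairs <- data.frame(sponge_id = "L1", mrna_id = "G1", sponge_class = "lncrna",
                      shared_k = 2L, p_hyper = 0.001, fdr = 0.004, pcc = 0.95,
                      stringsAsFactors = FALSE)
  sets_s <- list(L1 = c("m1", "m2", "m3"))
  sets_m <- list(G1 = c("m1", "m2"))
  scc <- data.frame(mirna_id = "m1", target_id = "G1", scc = -0.9)
  tr <- assemble_triplets(pairs, sets_s, sets_m, scc)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$mirna_id, "m1")
  expect_equal(tr$scc_mirna_mrna, -0.9)

  # no surviving miRNA: the pair contributes nothing
  none <- assemble_triplets(pairs, sets_s, sets_m,
                            data.frame(mirna_id = character(0),
                                       target_id = character(0),
                                       scc = numeric(0)))
  expect_equal(nrow(none), 0L)

  # optional sponge-side filter
  scc2 <- data.frame(mirna_id = c("m1", "m2"), target_id = "G1",
                     scc = c(-0.9, -0.8))
  scc_sp <- data.frame(mirna_id = c("m1", "m2"), target_id = "L1",
                       scc = c(-0.95, -0.2))
  both <- assemble_triplets(pairs, sets_s, sets_m, scc2, scc_sponge = scc_sp)
  expect_equal(nrow(both), 2L)
  filt <- assemble_triplets(pairs, sets_s, sets_m, scc2, scc_sponge = scc_sp,
                            filter_sponge_scc = TRUE)
  expect_equal(filt$mirna_id, "m1")
})

test_that("network export writes isomorphic SIF/GraphML/edge-list graphs", {
  tr <- data.frame(
    sponge_id = c("L1", "L1", "C1"), mirna_id = c("m1", "m2", "m1"),
    mrna_id = c("G1", "G1", "G2"),
    sponge_class = c("lncrna", "lncrna", "circrna"),
    stringsAsFactors = FALSE)
  sif <- tempfile(fileext = ".sif")
  gml <- tempfile(fileext = ".graphml")
  edg <- tempfile(fileext = ".tsv")
  g <- export_network(tr, sif, "sif")
  export_network(tr, gml, "graphml")
  export_network(tr, edg, "edgelist")

  # miRNA m1 appears once as a node despite supporting two triplets
  expect_equal(sum(igraph::V(g)$name == "m1"), 1L)
  expect_equal(igraph::vcount(g), 6L)   # L1, C1, m1, m2, G1, G2
  expect_equal(igraph::ecount(g), 6L)

  sif_lines <- readLines(sif)
  expect_length(sif_lines, 6L)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_true(igraph::isomorphic(g, g2))
  edges2 <- utils::read.delim(edg)
  expect_setequal(paste(edges2$from, edges2$to),
                  paste(igraph::as_data_frame(g)$from,
                        igraph::as_data_frame(g)$to))

  # single triplet: 3 nodes, 2 edges
  g1 <- export_network(tr[1, ], tempfile(fileext = ".sif"), "sif")
  expect_equal(igraph::vcount(g1), 3L)
  expect_equal(igraph::ecount(g1), 2L)

  expect_error(export_network(tr, tempfile(), "dot"), "sif, graphml, edgelist")
})
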