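test_that("correlation records hit the closed-form anchors", {
  expect_equal(spearman_cor(c(1, 2, 3), c(6, 4, 2))$value, -1)  # anti-monotone
  expect_equal(pearson_cor(1:5, 1:5)$value, 1)
  r <- spearman_cor(c(3, 3, 3), c(1, 2, 3))
  expect_false(r$defined)
  expect_true(is.na(r$value))
  expect_error(spearman_cor(1:3, 1:4), "equal length")
  expect_error(pearson_cor(1:2, 1:2), "3 samples")
})

test_that("correlations match naive rank/moment recomputation", {
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(20); y <- rnorm(20)
    expect_equal(spearman_cor(x, y)$value, naive_spearman(x, y), tolerance = 1e-12)
    expect_equal(pearson_cor(x, y)$value, naive_pearson(x, y), tolerance = 1e-12)
  }
  # ties handled by mid-ranks
  x <- c(1, 1, 2, 3, 3, 4); y <- c(2, 5, 5, 1, 4, 4)
  expect_equal(spearman_cor(x, y)$value, naive_spearman(x, y), tolerance = 1e-12)
})

test_that("miRNA screening requires a table hit and strictly negative SCC", {
  groups <- rep(c("A-ED", "NC"), each = 2)
  cm <- rbind(m1 = c(10, 20, 30, 40), m2 = c(40, 30, 20, 10),
              fill = c(50, 50, 50, 50))
  ct <- rbind(t1 = c(30, 10, 40, 20), t2 = c(10, 20, 30, 40),
              fill = c(60, 70, 30, 40))
  colnames(cm) <- colnames(ct) <- sprintf("s%d", 1:4)
  mir <- expression_matrix(cm, groups, "miRNA")
  tgt <- expression_matrix(ct, groups, "mRNA")
  targets <- data.frame(
    mirna = c("m1", "m2"), target = c("t1", "t2"),
    target_class = "mRNA", stringsAsFactors = FALSE
  )
  # m1 x t1 has SCC exactly 0 on the rank pattern (1,2,3,4) vs (3,1,4,2)
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(3, 1, 4, 2))$value, 0)
  out <- screen_mirna_pairs(mir, tgt, targets)
  expect_false(any(out$mirna == "m1"))        # SCC = 0 is not < 0
  expect_true(any(out$mirna == "m2" & out$target == "t2"))  # SCC = -1
  # strongly anti-correlated pair absent from the table is never screened in
  targets2 <- targets[targets$mirna == "m1", , drop = FALSE]
  out2 <- screen_mirna_pairs(mir, tgt, targets2)
  expect_equal(nrow(out2), 0)
})

test_that("lncRNA-mRNA screening drops PCC at the boundary and unshared pairs", {
  cfg <- sim_config(seed = 13, n_lnc = 10, n_mir = 9, n_mrna = 20,
                    n_planted_triplets = 3, target_density = 0)
  sim <- simulate_counts(cfg)
  tt <- simulate_target_table(cfg, sim$truth)
  mir_pairs <- rbind(
    screen_mirna_pairs(sim$miRNA, sim$lncRNA, tt),
    screen_mirna_pairs(sim$miRNA, sim$mRNA, tt)
  )
  pairs <- screen_lnc_mrna_pairs(sim$lncRNA, sim$mRNA, mir_pairs, pcc_min = 0.5)
  expect_true(all(pairs$pcc > 0.5))
  expect_true(all(pairs$x >= 1))
  if (nrow(pairs) > 0) {
    # raising the threshold to an observed PCC drops that pair: strict
    at <- screen_lnc_mrna_pairs(sim$lncRNA, sim$mRNA, mir_pairs,
                                pcc_min = max(pairs$pcc))
    expect_lt(nrow(at), nrow(pairs))
  }
})

test_that("sponge test matches enumeration and rejects inconsistent counts", {
  expect_equal(sponge_test(3, K = 4, n = 5, N = 10), 66 / 252)
  expect_equal(sponge_test(0, 4, 5, 10), 1)
  expect_equal(sponge_test(4, 4, 4, 4), 1)
  expect_error(sponge_test(5, 4, 5, 10), "min")
  expect_error(sponge_test(3, 12, 5, 10), "universe")
})

test_that("network assembly is invariant to pair order and prunes dead miRNAs", {
  pairs <- data.frame(
    lncrna = c("L1", "L1", "L2"), mrna = c("G1", "G2", "G1"),
    pcc = c(0.9, 0.8, 0.7),
    shared_mirnas = c("M1;M2", "M1", "M3"), x = c(2L, 1L, 1L),
    retained = TRUE, stringsAsFactors = FALSE
  )
  mir_pairs <- data.frame(
    mirna = c("M1", "M2", "M1", "M2", "M3", "M3", "M1"),
    target = c("L1", "L1", "G1", "G1", "L2", "G1", "G2"),
    target_class = c("lncRNA", "lncRNA", "mRNA", "mRNA", "lncRNA", "mRNA", "mRNA"),
    scc = -c(0.5, 0.6, 0.7, 0.8, 0.9, 0.4, 0.3),
    stringsAsFactors = FALSE
  )
  dirs <- setNames(rep("up", 6), c("L1", "L2", "G1", "G2", "M1", "M2"))
  dirs <- c(dirs, M3 = "down")
  n1 <- assemble_network(pairs, mir_pairs, dirs)
  n2 <- assemble_network(pairs[c(3, 1, 2), ], mir_pairs, dirs)
  expect_identical(igraph::as_data_frame(n1$graph, "edges"),
                   igraph::as_data_frame(n2$graph, "edges"))
  expect_identical(igraph::as_data_frame(n1$graph, "vertices"),
                   igraph::as_data_frame(n2$graph, "vertices"))
  # tripartite: no edge joins two nodes of the same class or lncRNA-mRNA
  cls <- setNames(igraph::V(n1$graph)$class, igraph::V(n1$graph)$name)
  el <- igraph::as_data_frame(n1$graph, "edges")
  kinds <- paste(pmin(cls[el$from], cls[el$to]), pmax(cls[el$from], cls[el$to]))
  expect_true(all(kinds %in% c("lncRNA miRNA", "mRNA miRNA")))
  # M2 shared on pair L1-G1 only; every miRNA lies on a full path
  for (m in igraph::V(n1$graph)$name[cls == "miRNA"]) {
    nb <- igraph::neighbors(n1$graph, m)$name
    expect_true(any(cls[nb] == "lncRNA") && any(cls[nb] == "mRNA"))
  }
  expect_error(assemble_network(pairs, mir_pairs, dirs[-1]), "L1")
})

test_that("directions missing for a network node are reported by name", {
  lnc_mir <- data.frame(lncrna = "L1", mirna = "M1", stringsAsFactors = FALSE)
  mir_mrna <- data.frame(mirna = "M1", mrna = "G1", stringsAsFactors = FALSE)
  expect_error(
    cerna_network_from_edges(lnc_mir, mir_mrna, c(L1 = "up", M1 = "down")),
    "G1"
  )
})

test_that("pipeline recovers planted pairs on the default design", {
  cfg <- sim_config(seed = 1)
  sim <- simulate_counts(cfg)
  tt <- simulate_target_table(cfg, sim$truth)
  res <- run_cerna_pipeline(sim$lncRNA, sim$miRNA, sim$mRNA, tt)
  expect_gt(pair_f1(res, sim$truth), 0.7)
  expect_true(all(res$pairs$p_sponge[res$pairs$retained] < 0.05))
  expect_true(all(res$pairs$x <= pmin(res$pairs$K, res$pairs$n_mrna_mirnas)))
  # network nodes carry class and direction for export
  v <- igraph::as_data_frame(res$network$graph, "vertices")
  expect_true(all(v$class %in% c("lncRNA", "miRNA", "mRNA")))
  expect_true(all(v$direction %in% c("up", "down")))
})

test_that("published worked-example network reproduces the reported axes", {
  net <- aed_example_network()
  ax <- axis_summary(net, "ENSRNOT00000029245")
  counts <- setNames(ax$axes$n_exclusive, ax$axes$mirna)
  expect_equal(unname(counts["miR484x"]), 23L)
  expect_equal(unname(counts["rno-miR-653-5p"]), 14L)
  expect_true("Il6r" %in% ax$mrnas[["miR484x"]])
  expect_true("Il6r" %in% ax$mrnas[["rno-miR-653-5p"]])
})
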