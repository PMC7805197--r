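test_that("ranked list sorts by absolute significance with -log10 weights", {
  de <- de_table(c("g1", "g2", "g3"), c(2, -1, 0.1), c(0.001, 0.1, 0.9))
  rl <- build_ranked_list(de, omega = 1)
  expect_equal(rl$genes, c("G1", "G2", "G3"))
  # expected weights recomputed per gene: -log10 of each significance
  expect_equal(rl$weights, c(3, 1, 0.04575749), tolerance = 1e-7)
  expect_equal(rl$disease_dirs, c(1, -1, 1))
  expect_equal(rl$rank_stat, c(3, -1, 0.04575749), tolerance = 1e-7)

  # omega = 0: every weight is 1 whatever the significance
  rl0 <- build_ranked_list(de, omega = 0)
  expect_equal(rl0$weights, rep(1, 3))

  # signed-statistic ranking uses the effect column directly
  rls <- build_ranked_list(de, omega = 1, rank_stat_kind = "signed_stat")
  expect_equal(rls$rank_stat, c(2, -1, 0.1))
})

test_that("ties in |T| break lexicographically and flat lists warn", {
  de <- de_table(c("gB", "gA", "gC"), c(1, 1, 1), c(0.05, 0.05, 0.01))
  rl <- build_ranked_list(de)
  expect_equal(rl$genes, c("GC", "GA", "GB"))
  flat <- de_table(c("g1", "g2"), c(1, -1), c(0.5, 0.5))
  expect_warning(build_ranked_list(flat), "tie-dominated")
})

test_that("directional hits respect mode and disease sign", {
  de <- de_table(c("g1", "g2", "g3"), c(2, 1, -1), c(0.001, 0.5, 0.1))
  rl <- build_ranked_list(de)
  pm <- proto_matrix("dA", "g1", "up", 1)
  # drug pushes g1 up, disease has g1 up: no antagonist hit, one agonist hit
  hv_ant <- directional_hits(rl, pm, "dA", mode = "antagonist")
  expect_equal(hv_ant$gamma, 0L)
  hv_ago <- directional_hits(rl, pm, "dA", mode = "agonist")
  expect_equal(hv_ago$gamma, 1L)
  expect_true(hv_ago$hit_flags[which(rl$genes == "G1")])
  expect_error(directional_hits(rl, pm, "nosuch"), "not present")
})

test_that("signature genes absent from the DE table are ignored", {
  de <- de_table(c("g1", "g2"), c(-2, 1), c(0.01, 0.2))
  rl <- build_ranked_list(de)
  pm <- proto_matrix(rep("dA", 3), c("g1", "g2", "gX"),
                     c("up", "down", "up"), 1:3)
  hv <- directional_hits(rl, pm, "dA", mode = "antagonist")
  # oracle: enumerate signature genes and compare signs
  # g1: drug up, disease down -> antagonist hit; g2: drug down, disease up -> hit
  expect_equal(hv$gamma, 2L)
  expect_equal(sum(hv$hit_flags), 2L)
  expect_equal(rl$p, 2L)  # gX never enters the list
})

test_that("a zero disease direction never matches", {
  de <- de_table(c("g1", "g2"), c(0, 1), c(0.01, 0.2))
  rl <- build_ranked_list(de)
  pm <- proto_matrix(c("d", "d"), c("g1", "g2"), c("down", "down"), 1:2)
  hv <- directional_hits(rl, pm, "d", mode = "antagonist")
  expect_false(hv$hit_flags[which(rl$genes == "G1")])
  expect_equal(hv$gamma, 1L)
})

test_that("running sum matches hand-computed values", {
  # p = 5, single hit at rank 1, omega = 0: straight descent to 0
  rl <- make_ranked_list(c(5, 4, 3, 2, 1), omega = 0)
  hv <- make_hits(5, 1)
  expect_equal(running_sum(rl, hv), c(1, 0.75, 0.5, 0.25, 0))

  # p = 10 worked example, hits at ranks 1 and 4, omega = 1
  abs_t <- c(5, 4, 3, 2.5, 2, 1.5, 1, 0.5, 0.2, 0.1)
  rl10 <- make_ranked_list(abs_t, omega = 1)
  hv10 <- make_hits(10, c(1, 4))
  v <- running_sum(rl10, hv10)
  expect_equal(v[1], 5 / 7.5, tolerance = 1e-12)
  expect_equal(v[4], 0.75, tolerance = 1e-12)
  expect_equal(v[10], 0, tolerance = 1e-12)
  expect_equal(v, oracle_v(abs_t, hv10$hit_flags, 1), tolerance = 1e-12)
})

test_that("worked example yields the expected ES, TCS and leading edge", {
  abs_t <- c(5, 4, 3, 2.5, 2, 1.5, 1, 0.5, 0.2, 0.1)
  rl <- make_ranked_list(abs_t, omega = 1)
  hv <- make_hits(10, c(1, 4))
  sc <- enrichment_scores(rl, hv)
  expect_equal(sc$es, 0.75, tolerance = 1e-12)
  expect_equal(sc$l_max, 4L)
  expect_equal(sc$l_min, 10L)
  expect_equal(sc$tcs_raw, 6L)
  expect_equal(sc$tcs, 6 / 9, tolerance = 1e-12)
  expect_equal(sc$leading_edge, rl$genes[c(1, 4)])
})

test_that("degenerate hit structures are handled with warnings", {
  rl <- make_ranked_list(c(3, 2, 1), omega = 1)
  all_hits <- make_hits(3, 1:3)
  expect_warning(v <- running_sum(rl, all_hits), "every gene is a hit")
  expect_equal(v, cumsum(c(3, 2, 1)) / 6)

  # all hit weights zero: unweighted hit fraction takes over
  rlz <- make_ranked_list(c(2, 1, 0, 0), omega = 1)
  hvz <- make_hits(4, c(3, 4))
  expect_warning(vz <- running_sum(rlz, hvz), "zero")
  expect_equal(vz[4], 0)
  expect_error(running_sum(rl, make_hits(3, integer(0))), "gamma")
})

test_that("vectorized scores agree with the double-loop oracle", {
  set.seed(421)
  for (i in 1:150) {
    omega <- sample(c(0, 0.5, 1, 2), 1)
    p <- sample(5:50, 1)
    gamma <- sample(seq_len(min(10, p - 1)), 1)
    inst <- random_instance(p, gamma, omega)
    sc <- enrichment_scores(inst$rl, inst$hv)
    orc <- oracle_scores(inst$abs_t, inst$hv$hit_flags, omega)
    expect_lt(abs(sc$es - orc$es), 1e-12)
    expect_equal(sc$l_max, orc$l_max)
    expect_equal(sc$tcs, orc$tcs, tolerance = 1e-12)
    expect_lt(abs(running_sum(inst$rl, inst$hv)[p]), 1e-12)
  }
})

test_that("scores are invariant to relabeling non-hit genes", {
  set.seed(7)
  inst <- random_instance(30, 5, 1)
  sc1 <- enrichment_scores(inst$rl, inst$hv)
  rl2 <- inst$rl
  non <- which(!inst$hv$hit_flags)
  rl2$genes[non] <- rl2$genes[sample(non)]
  sc2 <- enrichment_scores(rl2, inst$hv)
  expect_identical(sc1$es, sc2$es)
  expect_identical(sc1$tcs, sc2$tcs)
})

test_that("scores stay in [0, 1] with a non-empty leading edge", {
  set.seed(99)
  for (i in 1:50) {
    p <- sample(5:40, 1)
    inst <- random_instance(p, sample(seq_len(min(8, p - 1)), 1),
                            sample(c(0, 1), 1))
    sc <- enrichment_scores(inst$rl, inst$hv)
    expect_gte(sc$es, 0); expect_lte(sc$es, 1)
    expect_gte(sc$tcs, 0); expect_lte(sc$tcs, 1)
    expect_gt(length(sc$leading_edge), 0L)
  }
})

test_that("the weighted statistic matches an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(55)
  for (i in 1:25) {
    p <- sample(20:60, 1)
    inst <- random_instance(p, sample(3:8, 1), omega = 1)
    stats <- stats::setNames(inst$abs_t, inst$rl$genes)
    ref <- abs(fgsea::calcGseaStat(stats, selectedStats = inst$idx,
                                   gseaParam = 1))
    sc <- enrichment_scores(inst$rl, inst$hv)
    expect_equal(sc$es, ref, tolerance = 1e-10)
  }
})
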