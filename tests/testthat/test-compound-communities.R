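# build a shared-target interaction fixture: each compound's target list
# becomes aggregated strong-binding interactions
strong_ints <- function(targets_of, classes) {
  do.call(rbind, lapply(names(targets_of), function(cpd) {
    data.frame(compound_id = cpd, target_id = targets_of[[cpd]],
               max_level = "III", best_exact_value_nM = 10, n_evidence = 1L,
               class = classes[[cpd]], stringsAsFactors = FALSE)
  }))
}

test_that("compound graph weights equal shared-target counts", {
  tof <- list(c1 = c("T1", "T2"), c2 = c("T2", "T3"), c3 = c("T9"),
              c4 = c("T1", "T2"))
  cg <- build_compound_graph(strong_ints(tof, list(c1 = "NP", c2 = "NP",
                                                   c3 = "CT", c4 = "CT")))
  e <- cg$edges
  expect_equal(e$weight[e$c1 == "c1" & e$c2 == "c2"], 1)
  expect_equal(e$weight[e$c1 == "c1" & e$c2 == "c4"], 2)
  expect_equal(nrow(e[e$c1 == "c3" | e$c2 == "c3", ]), 0)  # disjoint: no edge
  expect_equal(igraph::vcount(cg$graph), 4)
  # brute-force check on a random fixture of 20 compounds
  set.seed(33)
  tof2 <- setNames(lapply(1:20, function(i) {
    sample(paste0("T", 1:15), sample(1:5, 1))
  }), paste0("c", 1:20))
  cg2 <- build_compound_graph(strong_ints(tof2, as.list(setNames(
    rep(c("NP", "CT"), 10), paste0("c", 1:20)))))
  for (i in 1:19) for (j in (i + 1):20) {
    a <- paste0("c", i); b <- paste0("c", j)
    w <- length(intersect(tof2[[i]], tof2[[j]]))
    row <- cg2$edges[(cg2$edges$c1 == a & cg2$edges$c2 == b) |
                       (cg2$edges$c1 == b & cg2$edges$c2 == a), ]
    expect_equal(nrow(row), as.integer(w > 0))
    if (w > 0) expect_equal(row$weight, w)
  }
})

test_that("community detection separates disconnected blocks and respects seeds", {
  # two disjoint triangles -> exactly 2 communities
  tof <- list(a1 = c("X1", "X2"), a2 = c("X2", "X3"), a3 = c("X1", "X3"),
              b1 = c("Y1", "Y2"), b2 = c("Y2", "Y3"), b3 = c("Y1", "Y3"))
  cls <- as.list(setNames(rep("NP", 6), names(tof)))
  cg <- build_compound_graph(strong_ints(tof, cls))
  part <- detect_communities(cg$graph, seed = 1)
  expect_equal(part$n_communities, 2)
  memb <- setNames(part$membership$community_id, part$membership$compound_id)
  expect_length(unique(memb[c("a1", "a2", "a3")]), 1)
  expect_length(unique(memb[c("b1", "b2", "b3")]), 1)
  # single clique -> one community
  tof2 <- list(k1 = "T", k2 = "T", k3 = "T", k4 = "T")
  cg2 <- build_compound_graph(strong_ints(tof2, as.list(setNames(
    rep("NP", 4), names(tof2)))))
  expect_equal(detect_communities(cg2$graph, seed = 1)$n_communities, 1)
  # determinism under fixed seed
  p1 <- detect_communities(cg$graph, seed = 9)
  p2 <- detect_communities(cg$graph, seed = 9)
  expect_identical(p1$membership, p2$membership)
})

test_that("returned partitions beat the trivial partitions on modularity", {
  set.seed(44)
  tof <- c(setNames(lapply(1:10, function(i) {
    sample(paste0("A", 1:6), 3)
  }), paste0("np", 1:10)),
  setNames(lapply(1:10, function(i) {
    sample(paste0("B", 1:6), 3)
  }), paste0("ct", 1:10)))
  cls <- as.list(setNames(rep(c("NP", "CT"), each = 10), names(tof)))
  cg <- build_compound_graph(strong_ints(tof, cls))
  part <- detect_communities(cg$graph, seed = 2)
  w <- igraph::E(cg$graph)$weight
  m_single <- igraph::modularity(cg$graph,
                                 rep(1, igraph::vcount(cg$graph)), weights = w)
  m_singletons <- igraph::modularity(cg$graph,
                                     seq_len(igraph::vcount(cg$graph)),
                                     weights = w)
  expect_gte(part$modularity, m_single)
  expect_gte(part$modularity, m_singletons)
})

test_that("community composition reports class enrichment and family counts", {
  tof <- c(setNames(lapply(1:5, function(i) c("A1", "A2")), paste0("np", 1:5)),
           setNames(lapply(1:5, function(i) c("B1", "B2")), paste0("ct", 1:5)))
  cls <- setNames(rep(c("NP", "CT"), each = 5), names(tof))
  membership <- data.frame(compound_id = names(tof),
                           community_id = rep(1:2, each = 5))
  fams <- data.frame(target_id = c("A1", "A2", "B1"),
                     family = c("kinase", "kinase", "GPCR"))
  comp <- community_composition(membership, cls, tof, fams)
  c1 <- comp$communities[comp$communities$community_id == 1, ]
  expect_equal(c(c1$n_np, c1$n_ct), c(5, 0))
  # Fisher 2x2 on (5,0;0,5)
  expect_equal(c1$p_value, fisher.test(matrix(c(5, 0, 0, 5), 2))$p.value)
  expect_equal(c1$p_value, 2 / choose(10, 5))
  f1 <- comp$families[comp$families$community_id == 1, ]
  expect_equal(f1$family, "kinase")
  expect_equal(f1$n_targets, 2)
  # unclassified targets fall into their own bucket
  f2 <- comp$families[comp$families$community_id == 2, ]
  expect_setequal(f2$family, c("GPCR", "unclassified"))
  # all compounds in one community: enrichment p = 1
  memb_one <- data.frame(compound_id = names(tof), community_id = 1)
  comp_one <- community_composition(memb_one, cls, tof, fams)
  expect_equal(comp_one$communities$p_value, 1)
})

test_that("a planted two-block compound partition is recovered with high ARI", {
  skip_if_not_installed("mclust")
  aris <- vapply(1:10, function(seed) {
    set.seed(seed + 100)
    # 15 compounds per block sharing a dense within-block target pool
    tof <- c(setNames(lapply(1:15, function(i) {
      sample(paste0("A", 1:10), 6)
    }), paste0("np", 1:15)),
    setNames(lapply(1:15, function(i) {
      c(sample(paste0("B", 1:10), 6),
        if (i == 1) "A1" else character(0))  # one weak bridge
    }), paste0("ct", 1:15)))
    cls <- as.list(setNames(rep(c("NP", "CT"), each = 15), names(tof)))
    cg <- build_compound_graph(strong_ints(tof, cls))
    part <- detect_communities(cg$graph, seed = seed)
    memb <- setNames(part$membership$community_id,
                     part$membership$compound_id)
    truth <- rep(1:2, each = 15)
    mclust::adjustedRandIndex(unname(memb[names(tof)]), truth)
  }, 1.0)
  expect_gte(mean(aris >= 0.8), 1)
})
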