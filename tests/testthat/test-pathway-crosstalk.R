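test_that("pathway graph edges are exactly the positive shared-gene pairs", {
  pg <- build_pathway_graph(list(P1 = c("A", "B"), P2 = c("B", "C"),
                                 P3 = c("D")))
  expect_equal(nrow(pg$edges), 1)
  expect_equal(pg$edges$shared_gene_count, 1)
  expect_equal(sort(c(pg$edges$p1, pg$edges$p2)), c("P1", "P2"))
  expect_equal(igraph::vcount(pg$graph), 3)  # isolated P3 retained

  expect_error(build_pathway_graph(setNames(list(c("A"), c("B")),
                                            c("P", "P"))),
               "unique")

  # brute-force double loop on random sets
  set.seed(52)
  sets <- setNames(lapply(1:10, function(i) {
    sample(LETTERS, sample(3:8, 1))
  }), paste0("pw", 1:10))
  pg2 <- build_pathway_graph(sets)
  for (i in 1:9) {
    for (j in (i + 1):10) {
      a <- paste0("pw", i); b <- paste0("pw", j)
      w <- length(intersect(sets[[i]], sets[[j]]))
      row <- pg2$edges[(pg2$edges$p1 == a & pg2$edges$p2 == b) |
                         (pg2$edges$p1 == b & pg2$edges$p2 == a), ]
      if (w == 0) {
        expect_equal(nrow(row), 0)
      } else {
        expect_equal(row$shared_gene_count, w)
      }
    }
  }
})

test_that("set distances match a BFS oracle, are symmetric, and exclude cross-component pairs", {
  # 8 pathways: chain pw1..pw6 plus disconnected pair pw7-pw8
  genes <- function(...) c(...)
  sets <- list(pw1 = c("a1", "s12"), pw2 = c("s12", "s23"),
               pw3 = c("s23", "s34"), pw4 = c("s34", "s45"),
               pw5 = c("s45", "s56"), pw6 = c("s56", "b6"),
               pw7 = c("q1", "q2"), pw8 = c("q2", "q3"))
  pg <- build_pathway_graph(sets)
  one <- set_distance(pg$graph, "pw1", "pw2")
  expect_equal(one$mean_distance, 1)
  # oracle: BFS on the 8-node pathway adjacency
  ids <- names(sets)
  adj <- matrix(0L, 8, 8, dimnames = list(ids, ids))
  for (i in 1:7) for (j in (i + 1):8) {
    if (length(intersect(sets[[i]], sets[[j]])) > 0) {
      adj[i, j] <- adj[j, i] <- 1L
    }
  }
  d_oracle <- oracle_bfs(adj)
  A <- c("pw1", "pw7")
  B <- c("pw4", "pw8")
  res <- set_distance(pg$graph, A, B)
  # pairs: (pw1,pw4)=3, (pw1,pw8)=Inf excluded, (pw7,pw4)=Inf excluded,
  # (pw7,pw8)=1
  expect_equal(d_oracle[1, 4], 3)  # pw1 -> pw4
  expect_equal(res$mean_distance, mean(c(3, 1)))
  expect_equal(res$n_excluded, 2)
  # symmetry
  res_ba <- set_distance(pg$graph, B, A)
  expect_equal(res$mean_distance, res_ba$mean_distance)
  # A = B = single pathway: no a != b pair
  same <- set_distance(pg$graph, "pw1", "pw1")
  expect_false(same$defined)
})

test_that("control distances are seeded and produce sane empirical p-values", {
  set.seed(61)
  sets <- setNames(lapply(1:12, function(i) sample(letters, 6)),
                   paste0("pw", 1:12))
  pg <- build_pathway_graph(sets)
  c1 <- control_distance(pg$graph, 3, 3, n_reps = 50, seed = 5)
  c2 <- control_distance(pg$graph, 3, 3, n_reps = 50, seed = 5)
  expect_equal(c1$distances, c2$distances)
  ctrl <- c1$distances[!is.na(c1$distances)]
  expect_equal(empirical_p(min(ctrl) - 1, ctrl), 1 / (length(ctrl) + 1))
  expect_equal(empirical_p(stats::median(ctrl), ctrl), 0.5, tolerance = 0.15)
})

test_that("synergy candidates are NP-only pathways adjacent to enriched CT/BOTH pathways", {
  sets <- list(npw = c("n1", "shared"), epw = c("shared", "c1"),
               other = c("n2", "zz"))
  pg <- build_pathway_graph(sets)
  labels <- data.frame(entity_id = c("npw", "epw", "other"),
                       label = c("NP_ONLY", "BOTH", "NP_ONLY"))
  cand <- neighbor_synergy_candidates(pg, labels, enriched_ids = "epw",
                                      pathways = sets,
                                      np_targets = c("n1", "shared"),
                                      ct_targets = "c1")
  expect_equal(nrow(cand), 1)
  expect_equal(cand$np_pathway, "npw")
  expect_equal(cand$enriched_pathway, "epw")
  expect_equal(cand$shared_genes, "shared")
  # two NP_ONLY neighbors yield no candidate
  labels2 <- labels
  labels2$label <- "NP_ONLY"
  cand2 <- neighbor_synergy_candidates(pg, labels2, "epw", sets,
                                       c("n1", "shared"), "c1")
  expect_equal(nrow(cand2), 0)
})

test_that("every candidate is a graph edge satisfying the labeling rule", {
  d <- withr::local_tempdir()
  generate_scenario(small_scenario_config(seed = 71), d)
  sc <- load_scenario(d)
  ints <- aggregate_interactions(sc$evidence)
  entity_ids <- sc$hierarchy$pathway_id[sc$hierarchy$entity_level]
  sets <- sc$pathways[entity_ids]
  pg <- build_pathway_graph(sets)
  enr <- aberrational_pathways(sc$pathways, unique(sc$drivers$gene))
  enriched_entity <- intersect(enr$enriched_ids, entity_ids)
  edge_keys <- paste(pmin(pg$edges$p1, pg$edges$p2),
                     pmax(pg$edges$p1, pg$edges$p2))
  for (thr in c(100, 1000)) {
    strong <- filter_by_affinity(ints, thr)
    np <- unique(strong$target_id[strong$class == "NP"])
    ct <- unique(strong$target_id[strong$class == "CT"])
    labels <- classify_entities(np, ct, sets)
    lab <- setNames(labels$label, labels$entity_id)
    cand <- neighbor_synergy_candidates(pg, labels, enriched_entity, sets,
                                        np, ct)
    if (nrow(cand) == 0) next
    # candidates are a subset of the edge set
    ck <- paste(pmin(cand$np_pathway, cand$enriched_pathway),
                pmax(cand$np_pathway, cand$enriched_pathway))
    expect_true(all(ck %in% edge_keys))
    # and satisfy the labeling rule on both endpoints
    expect_true(all(lab[cand$np_pathway] == "NP_ONLY"))
    expect_true(all(cand$enriched_pathway %in% enriched_entity))
    expect_true(all(lab[cand$enriched_pathway] %in% c("CT_ONLY", "BOTH")))
  }
})
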