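test_that("network loading deduplicates edges and drops self-loops", {
  d <- withr::local_tempdir()
  path <- file.path(d, "net.tsv")
  writeLines(c("A\tB", "B\tA", "A\tA", "B\tC"), path)
  g <- load_network(path)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_equal(igraph::graph_attr(g, "n_self_loops_dropped"), 1)
  expect_equal(igraph::graph_attr(g, "n_duplicate_edges_dropped"), 1)

  sif <- file.path(d, "net.sif")
  writeLines(c("A\tpp\tB", "B\tpp\tC"), sif)
  g2 <- load_network(sif)
  expect_equal(igraph::ecount(g2), 2)

  empty <- file.path(d, "empty.tsv")
  writeLines(character(0), empty)
  expect_warning(g3 <- load_network(empty), "empty")
  expect_equal(igraph::vcount(g3), 0)

  bad <- file.path(d, "bad.tsv")
  writeLines(c("A\tB", "loneToken"), bad)
  expect_error(load_network(bad), "line")
})

test_that("centralities on canonical small graphs match first principles", {
  d <- withr::local_tempdir()
  path <- file.path(d, "pathgraph.tsv")
  writeLines(c("A\tB", "B\tC"), path)  # path graph A-B-C
  prof <- compute_centralities(load_network(path))
  btw <- setNames(prof$betweenness, prof$node_id)
  expect_equal(unname(btw["B"]), 1)
  expect_equal(unname(btw["A"]), 0)

  star <- file.path(d, "star.tsv")
  writeLines(c("c\tl1", "c\tl2", "c\tl3"), star)
  prof2 <- compute_centralities(load_network(star))
  expect_equal(prof2$betweenness[prof2$node_id == "c"], 3)  # C(3,2) leaf pairs

  cyc <- file.path(d, "cycle.tsv")
  writeLines(c("a\tb", "b\tc", "c\td", "d\te", "e\ta"), cyc)
  prof3 <- compute_centralities(load_network(cyc))
  expect_equal(prof3$eigenvector, rep(1, 5))  # symmetry
})

test_that("degree, betweenness and eigenvector match brute-force oracles on random graphs", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(3:7, 1)
    adj <- random_connected_adj(n)
    g <- adj_to_graph(adj)
    prof <- compute_centralities(g)
    ord <- match(paste0("n", seq_len(n)), prof$node_id)
    expect_equal(prof$degree[ord], rowSums(adj))
    expect_equal(prof$betweenness[ord], oracle_betweenness(adj),
                 tolerance = 1e-9)
    expect_equal(prof$eigenvector[ord], oracle_eigen(adj), tolerance = 1e-6)
    # conservation: sum of betweenness = sum over pairs of (d(s,t) - 1)
    dd <- oracle_bfs(adj)
    expect_equal(sum(prof$betweenness),
                 sum(dd[upper.tri(dd)][is.finite(dd[upper.tri(dd)])] - 1),
                 tolerance = 1e-9)
  }
})

test_that("mean distance to drivers excludes self and is NA when unreachable", {
  d <- withr::local_tempdir()
  path <- file.path(d, "two_comp.tsv")
  writeLines(c("A\tB", "B\tC", "X\tY"), path)
  g <- load_network(path)
  md <- mean_distance_to_drivers(g, c("C"))
  expect_equal(unname(md["A"]), 2)
  expect_true(is.na(md["X"]))  # no driver reachable from the X-Y component
  # driver with drivers {itself, neighbor}: self excluded
  md2 <- mean_distance_to_drivers(g, c("A", "B"))
  expect_equal(unname(md2["A"]), 1)
})

test_that("group comparisons detect separation and respect seeding", {
  prof <- data.frame(
    node_id = paste0("n", 1:30),
    degree = c(10:19, 100:109, rep(5, 10)),
    betweenness = 0, eigenvector = 0,
    mean_dist_to_drivers = c(runif(10, 1, 2), runif(10, 1, 2),
                             runif(10, 3, 4)),
    group = rep(c("NP_ONLY", "CT_ONLY", "UNTARGETED"), each = 10),
    is_driver = FALSE, stringsAsFactors = FALSE)
  cmp <- compare_groups(prof, "degree", n_controls = 50, seed = 4)
  row <- cmp$pairwise[cmp$pairwise$group_a == "CT_ONLY" &
                        cmp$pairwise$group_b == "NP_ONLY", ]
  expect_lt(row$p_value, 0.05)
  # identical groups: no significance
  prof2 <- prof
  prof2$degree <- rep(1:10, 3)
  cmp2 <- compare_groups(prof2, "degree", n_controls = 50, seed = 4)
  expect_true(all(cmp2$pairwise$p_value > 0.9))
  # distance controls: empirical p reproducible under the same seed
  c1 <- compare_groups(prof, "mean_dist_to_drivers", n_controls = 100,
                       seed = 7)
  c2 <- compare_groups(prof, "mean_dist_to_drivers", n_controls = 100,
                       seed = 7)
  expect_equal(c1$controls$empirical_p, c2$controls$empirical_p)
  # undersized groups are skipped with a warning
  prof3 <- prof[c(1:10, 11), ]
  expect_warning(compare_groups(prof3, "degree", n_controls = 10, seed = 1),
                 "skipped")
})

test_that("top-node reports rank by value with lexicographic tie-break", {
  prof <- data.frame(node_id = c("zeta", "alpha", "mid"),
                     degree = c(5, 5, 9), betweenness = 1:3,
                     eigenvector = c(0.2, 0.1, 1),
                     mean_dist_to_drivers = 1,
                     group = "NP_ONLY", is_driver = c(TRUE, FALSE, FALSE),
                     stringsAsFactors = FALSE)
  top <- top_nodes_report(prof, k = 3, measures = "degree")
  expect_equal(top$node_id, c("mid", "alpha", "zeta"))
  expect_equal(top$rank, 1:3)
})

test_that("planted high-degree driver nodes are detected as significantly higher", {
  d <- withr::local_tempdir()
  tr <- generate_scenario(small_scenario_config(seed = 41), d)
  sc <- load_scenario(d)
  g <- load_network(sc$ppi_path)
  prof <- compute_centralities(g, driver_genes = tr$planted_driver_set)
  drv <- prof$degree[prof$is_driver]
  non <- prof$degree[!prof$is_driver]
  expect_gt(median(drv), median(non))
  wt <- suppressWarnings(wilcox.test(drv, non, exact = FALSE))
  expect_lt(wt$p.value, 0.05)
})
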