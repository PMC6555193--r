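test_that("entity classification follows the at-least-one-target rule", {
  membership <- list(p1 = c("A", "B"), p2 = c("A", "B"), p3 = c("A", "B"),
                     p4 = c("C"))
  cls <- classify_entities(np_targets = "A", ct_targets = character(0),
                           membership["p1"])
  expect_equal(cls$label, "NP_ONLY")
  cls2 <- classify_entities("A", "B", membership)
  lab <- setNames(cls2$label, cls2$entity_id)
  expect_equal(unname(lab["p1"]), "BOTH")  # BOTH without a shared target
  expect_equal(unname(lab["p4"]), "NEITHER")
  # labels partition the universe
  expect_equal(sum(table(cls2$label)), length(membership))
  expect_warning(classify_entities("A", "B", list(px = character(0))),
                 "empty membership")
})

test_that("relative increase reproduces published arithmetic and is scale-invariant", {
  expect_equal(round(relative_increase(725, 0, 1196)), 61)
  expect_equal(round(relative_increase(218, 266, 495)), 29)
  expect_equal(relative_increase(0, 3, 7), 0)
  expect_equal(relative_increase(10, 5, 5), relative_increase(30, 15, 15))
  expect_error(relative_increase(5, 0, 0), "division by zero")
})

test_that("coverage percentages round to two decimals of the universe share", {
  # construct strata-free check through classify + manual count instead of
  # asserting constants: 218 of 1944 and 59 of 533
  expect_equal(round(100 * 218 / 1944, 2), 11.21)
  expect_equal(round(100 * 59 / 533, 2), 11.07)
  ev <- rbind(make_evidence("np1", "A", "NP", ref = TRUE, value = 10),
              make_evidence("ct1", "B", "CT", ref = TRUE, value = 20))
  ints <- aggregate_interactions(ev)
  pw <- list(p1 = c("A", "X"), p2 = c("B", "Y"), p3 = c("A", "B"),
             p4 = c("Z"))
  tab <- coverage_table(ints, pw)
  expect_equal(tab$n_pathways_np_only, rep(1, 4))
  expect_equal(tab$n_pathways_both, rep(1, 4))
  expect_equal(tab$pct_np_only, rep(25, 4))
  # no interactions: all zero
  tab0 <- coverage_table(ints[0, ], pw)
  expect_true(all(tab0$n_pathways_np_only == 0 & tab0$pct_both == 0))
})

test_that("coverage strata are monotone: tighter strata target fewer pathways", {
  d <- withr::local_tempdir()
  generate_scenario(small_scenario_config(seed = 21), d)
  sc <- load_scenario(d)
  ints <- aggregate_interactions(sc$evidence)
  covered <- function(levels, thr = NULL) {
    sub <- ints[ints$max_level %in% levels, , drop = FALSE]
    if (!is.null(thr)) sub <- filter_by_affinity(sub, thr)
    cls <- classify_entities(unique(sub$target_id[sub$class == "NP"]),
                             unique(sub$target_id[sub$class == "CT"]),
                             sc$pathways)
    cls$entity_id[cls$label != "NEITHER"]
  }
  s1 <- covered(c("I", "II", "III"))
  s2 <- covered(c("II", "III"))
  s3 <- covered("III")
  s4 <- covered("III", 100)
  expect_true(all(s4 %in% s3))
  expect_true(all(s3 %in% s2))
  expect_true(all(s2 %in% s1))
})

test_that("within-BOTH-pathway NP-only share counts (pathway, target) pairs", {
  pw <- list(p1 = c("A", "B"), p2 = c("C", "D"), p3 = c("A", "C", "E"))
  targets <- c("A", "B", "C", "D", "E")
  # A np-only, B ct-only, C both, D ct-only, E uncovered
  t_lab <- classify_entities(c("A", "C"), c("B", "C", "D"), targets)
  p_lab <- classify_entities(c("A", "C"), c("B", "C", "D"), pw)
  share <- within_pathway_interaction_share(p_lab, t_lab, pw)
  # BOTH pathways: p1 (A, B covered; 1 NP_ONLY of 2), p2 (C, D; 0 of 2),
  # p3 (A, C; 1 of 2) -> 2/6
  expect_equal(share, 2 / 6)
  # extreme: every covered target NP-only
  t2 <- classify_entities(c("A", "B"), character(0), c("A", "B"))
  p2 <- data.frame(entity_id = "p1", label = "BOTH")
  expect_equal(within_pathway_interaction_share(p2, t2, list(p1 = c("A", "B"))),
               1.0)
})

test_that("driver coverage per tumor type counts classes and flags NP-improved types", {
  drivers <- data.frame(gene = c("D1", "D2", "D1", "D3"),
                        tumor_type = c("melanoma", "melanoma", "lung", "lung"))
  ev <- rbind(make_evidence("np1", "D1", "NP", ref = TRUE, value = 50),
              make_evidence("ct1", "D3", "CT", ref = TRUE, value = 5))
  ints <- aggregate_interactions(ev)
  tab <- driver_tumor_coverage(drivers, ints, 100)
  mel <- tab[tab$tumor_type == "melanoma", ]
  expect_equal(mel$np_only, 1)
  expect_equal(mel$ct_only, 0)
  expect_equal(mel$total_drivers, 2)
  expect_true(mel$np_improved)
  lung <- tab[tab$tumor_type == "lung", ]
  expect_equal(lung$np_only, 1)
  expect_equal(lung$ct_only, 1)
  # nothing passes an impossible threshold
  tab0 <- driver_tumor_coverage(drivers, ints, 1e-6)
  expect_true(all(tab0$np_only == 0 & tab0$ct_only == 0 & tab0$both == 0))
  expect_false(any(tab0$np_improved))
})

test_that("KS comparisons match a double-loop ECDF oracle and flag extremes", {
  ev <- do.call(rbind, c(
    lapply(1:3, function(i) {
      do.call(rbind, lapply(seq_len(i), function(j) {
        make_evidence(paste0("np", i), paste0("t", i, "_", j), "NP",
                      ref = TRUE, value = 10)
      }))
    }),
    lapply(4:6, function(i) {
      do.call(rbind, lapply(seq_len(i), function(j) {
        make_evidence(paste0("ct", i), paste0("u", i, "_", j), "CT",
                      ref = TRUE, value = 10)
      }))
    }))
  )
  pw <- list(p = unique(ev$target_id))
  drv <- data.frame(gene = "none", tumor_type = "tt")
  res <- suppressWarnings(per_compound_distributions(
    aggregate_interactions(ev), pw, drv, thresholds = 100))
  tg <- res$tests[res$tests$type == "targets", ]
  # NP counts {1,2,3} vs CT counts {4,5,6}: completely separated
  expect_equal(tg$D, 1)
  expect_equal(tg$D, oracle_ks_D(1:3, 4:6))

  set.seed(9)
  for (rep in 1:10) {
    x <- sample(0:12, sample(5:50, 1), replace = TRUE)
    y <- sample(0:12, sample(5:50, 1), replace = TRUE)
    D_pkg <- suppressWarnings(stats::ks.test(x, y, exact = FALSE)$statistic)
    expect_equal(unname(D_pkg), oracle_ks_D(x, y))
  }
  # identical samples: D = 0, p = 1
  ks0 <- suppressWarnings(stats::ks.test(c(1, 2, 3), c(1, 2, 3),
                                         exact = FALSE))
  expect_equal(unname(ks0$statistic), 0)
  expect_equal(ks0$p.value, 1)
})
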