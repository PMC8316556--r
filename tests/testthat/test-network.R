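test_that("the global average NPMI is the arithmetic mean of records", {
  rec <- records_fixture(gene = c("A", "B"), concept_id = c("P1", "P2"),
                         npmi = c(0.2, 0.4))
  expect_equal(global_average_npmi(rec), 0.3)
  expect_equal(global_average_npmi(rec[1, ]), 0.2)
  seven <- records_fixture(gene = paste0("G", 1:7),
                           concept_id = paste0("P", 1:7),
                           npmi = c(0.1, -0.2, 0.5, 0.3, 0, 0.6, 0.4))
  expect_equal(global_average_npmi(seven), sum(seven$npmi) / 7)
  expect_equal(global_average_npmi(seven, positive_only = TRUE),
               mean(c(0.1, 0.5, 0.3, 0.6, 0.4)))
  expect_error(global_average_npmi(seven[0, ]), "no association")
})

test_that("edges require both genes to qualify and compress into weights", {
  rec <- records_fixture(
    gene = c("A", "B", "A", "B", "A", "B", "C", "A"),
    concept_id = c("P1", "P1", "P2", "P2", "P3", "P3", "P4", "P4"),
    npmi = c(0.9, 0.8, 0.7, 0.6, 0.9, 0.9, 0.9, 0.2))
  g <- build_graph(rec, threshold = 0.5)
  # A and B share three qualifying phenotypes -> one edge of weight 3
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$weight, 3)
  # P4 qualifies for C only (A is below threshold) -> no edge for C
  expect_true("C" %in% igraph::V(g)$name)
  expect_equal(unname(igraph::degree(g)["C"]), 0)
  # three genes sharing one phenotype form a triangle of unit weights
  tri <- records_fixture(gene = c("X", "Y", "Z"),
                         concept_id = rep("P9", 3), npmi = rep(0.9, 3))
  gt <- build_graph(tri, threshold = 0.5)
  expect_equal(igraph::ecount(gt), 3L)
  expect_equal(igraph::E(gt)$weight, c(1, 1, 1))
})

test_that("graph construction is order-independent and self-loop-free", {
  rec <- records_fixture(
    gene = c("A", "B", "C", "A", "C", "B"),
    concept_id = c("P1", "P1", "P1", "P2", "P2", "P3"),
    npmi = rep(0.9, 6))
  g1 <- build_graph(rec, threshold = 0.1)
  g2 <- build_graph(rec[rev(seq_len(nrow(rec))), ], threshold = 0.1)
  e1 <- igraph::as_data_frame(g1); e2 <- igraph::as_data_frame(g2)
  expect_equal(e1, e2)
  expect_false(any(igraph::which_loop(g1)))
  expect_true(all(igraph::E(g1)$weight >= 1))
})

test_that("betweenness matches hand-enumerated path structure", {
  path3 <- records_fixture(gene = c("a", "b", "b", "c"),
                           concept_id = c("P1", "P1", "P2", "P2"),
                           npmi = rep(0.9, 4))
  g <- build_graph(path3, threshold = 0.5)
  cb <- betweenness_centrality(g, weighted = FALSE)
  expect_equal(unname(cb[c("a", "b", "c")]), c(0, 1, 0))
  # star with three leaves: every leaf pair routes through the center
  star <- records_fixture(gene = c("hub", "l1", "hub", "l2", "hub", "l3"),
                          concept_id = c("P1", "P1", "P2", "P2", "P3", "P3"),
                          npmi = rep(0.9, 6))
  gs <- build_graph(star, threshold = 0.5)
  cbs <- betweenness_centrality(gs, weighted = FALSE)
  expect_equal(unname(cbs["hub"]), 3)
  expect_equal(unname(cbs[c("l1", "l2", "l3")]), c(0, 0, 0))
  # complete graph: all direct edges, all scores 0
  k4 <- records_fixture(gene = rep(c("w", "x", "y", "z"), 3),
                        concept_id = rep(c("P1", "P2", "P3"), each = 4),
                        npmi = rep(0.9, 12))
  gk <- build_graph(k4, threshold = 0.5)
  expect_equal(unname(betweenness_centrality(gk, weighted = FALSE)),
               rep(0, 4))
})

test_that("betweenness equals the path-enumeration oracle on random graphs", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(6:12, 1)
    nodes <- paste0("g", seq_len(n))
    pairs <- t(utils::combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.35
    if (sum(keep) < 2) keep[1:2] <- TRUE
    edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                        weight = sample(1:4, sum(keep), replace = TRUE),
                        stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = nodes))
    # unweighted: every edge has unit length
    cb_u <- betweenness_centrality(g, weighted = FALSE)
    oracle_u <- betweenness_oracle(nodes, transform(edges, length = 1))
    expect_equal(cb_u[nodes], oracle_u[nodes], tolerance = 1e-9,
                 info = paste("unweighted seed", seed))
    # weighted: length = 1/weight
    cb_w <- betweenness_centrality(g, weighted = TRUE)
    oracle_w <- betweenness_oracle(nodes,
                                   transform(edges, length = 1 / weight))
    expect_equal(cb_w[nodes], oracle_w[nodes], tolerance = 1e-9,
                 info = paste("weighted seed", seed))
  }
})

test_that("top-fraction selection takes the ceiling and reports cut ties", {
  scores <- stats::setNames(c(5, 4, 3, 3, 1), paste0("g", 1:5))
  sel <- top_fraction(scores, 0.4)
  expect_equal(length(sel), 2L)
  expect_equal(sel[1], "g1")
  sel3 <- top_fraction(scores, 0.6)
  expect_equal(length(sel3), 3L)
  expect_true(all(c("g3", "g4") %in% attr(sel3, "ties_at_cut")))
  expect_equal(sort(top_fraction(scores, 1.0)), sort(names(scores)))
  # 600 genes at 10% -> 60 selected, matching the sort-oracle head
  set.seed(11)
  big <- stats::setNames(runif(600), sprintf("g%03d", 1:600))
  sel60 <- top_fraction(big, 0.10)
  expect_length(sel60, 60L)
  expect_equal(unname(sel60), names(sort(big, decreasing = TRUE))[1:60],
               ignore_attr = TRUE)
})

test_that("keyword subsetting filters preferred names case-insensitively", {
  rec <- records_fixture(
    gene = c("A", "B", "C", "D", "E"),
    concept_id = paste0("P", 1:5),
    preferred_name = c("Language impairment", "Specific Language Disorder",
                       "Seizure", "Delayed speech and language development",
                       "Hypotonia"),
    npmi = c(0.5, 0.6, 0.7, 0.55, 0.4))
  out <- subset_by_phenotype_keyword(rec, "language", threshold = 0.1)
  expect_equal(nrow(out$records), 3L)
  expect_true(all(grepl("language", out$records$preferred_name,
                        ignore.case = TRUE)))
  expect_setequal(igraph::V(out$graph)$name, c("A", "B", "D"))
  expect_warning(none <- subset_by_phenotype_keyword(rec, "zebra",
                                                     threshold = 0.1),
                 "no phenotype matched")
  expect_equal(nrow(none$records), 0L)
  expect_error(subset_by_phenotype_keyword(rec, character(0)), "non-empty")
})
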