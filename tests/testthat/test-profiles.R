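test_that("the binary matrix keys on strictly positive NPMI", {
  rec <- records_fixture(gene = c("G1", "G1", "G2", "G2", "G3"),
                         concept_id = c("P1", "P2", "P1", "P2", "P1"),
                         npmi = c(0.4, 0, -0.2, 0.1, 0.6))
  m <- build_matrix(rec)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(sum(m), 3L)            # three positive records
  expect_equal(m["G1", "P2"], 0L)     # npmi = 0 -> 0 (strict >)
  expect_equal(m["G2", "P1"], 0L)
  # order-independence / idempotence
  set.seed(1)
  m2 <- build_matrix(rec[sample(nrow(rec)), ])
  expect_identical(m, m2)
})

test_that("gene labels come from the top-NPMI phenotype, dropping NA categories", {
  rec <- records_fixture(
    gene = c("G1", "G1", "G2", "G3", "G3"),
    concept_id = c("P1", "P2", "P3", "P4", "P5"),
    npmi = c(0.9, 0.5, 0.7, 0.3, 0.3),
    n_GP = c(10L, 10L, 10L, 12L, 9L),
    category = c("Neoplasm", "Abnormality of the eye", "NA",
                 "Growth abnormality", "Neoplasm"))
  lab <- label_by_top_category(rec)
  expect_equal(lab[["G1"]], "Neoplasm")
  expect_false("G2" %in% names(lab))       # top phenotype unmapped -> dropped
  # G3 tie on npmi broken by n_GP (P4 wins)
  expect_equal(lab[["G3"]], "Growth abnormality")
})

test_that("embedding is deterministic and separates identical-profile blocks", {
  set.seed(9)
  block <- rbind(matrix(rep(c(1L, 1L, 0L, 0L, 0L, 0L), 5), nrow = 5,
                        byrow = TRUE),
                 matrix(rep(c(0L, 0L, 0L, 0L, 1L, 1L), 5), nrow = 5,
                        byrow = TRUE))
  rownames(block) <- paste0("G", 1:10)
  colnames(block) <- paste0("P", 1:6)
  c1 <- embed_2d(block, seed = 4, perplexity = 2)
  c2 <- embed_2d(block, seed = 4, perplexity = 2)
  expect_identical(c1, c2)
  expect_true(all(is.finite(c1)))
  # within-block distances smaller than between-block distances
  d <- as.matrix(dist(c1))
  within <- c(d[1:5, 1:5][upper.tri(diag(5))], d[6:10, 6:10][upper.tri(diag(5))])
  between <- d[1:5, 6:10]
  expect_lt(max(within), min(between))
  expect_error(embed_2d(block[1:2, , drop = FALSE]), "at least 3")
  expect_error(embed_2d(block, perplexity = 50), "perplexity")
})

test_that("k-means on separable blobs recovers blob membership deterministically", {
  set.seed(2)
  pts <- rbind(cbind(rnorm(10, 0, 0.1), rnorm(10, 0, 0.1)),
               cbind(rnorm(10, 10, 0.1), rnorm(10, 10, 0.1)))
  rownames(pts) <- paste0("G", 1:20)
  k1 <- kmeans_cluster(pts, k = 2, seed = 7)
  k2 <- kmeans_cluster(pts, k = 7, seed = 7)
  expect_identical(kmeans_cluster(pts, k = 2, seed = 7), k1)
  expect_length(unique(k1[1:10]), 1L)
  expect_length(unique(k1[11:20]), 1L)
  expect_false(k1[[1]] == k1[[20]])
  # k = n gives singletons
  ks <- kmeans_cluster(pts, k = 20, seed = 3)
  expect_equal(length(unique(ks)), 20L)
  expect_error(kmeans_cluster(pts, k = 1, seed = 1), "invalid k")
  expect_error(kmeans_cluster(pts, k = 21, seed = 1), "invalid k")
})

test_that("identical partitions score 1 on all four concordance metrics", {
  a <- c(1, 1, 2, 2, 3, 3)
  s <- concordance_scores(a, a)
  expect_identical(s$adjusted_rand, 1)
  expect_identical(s$jaccard, 1)
  expect_identical(s$nmi, 1)
  expect_identical(s$purity, 1)
  # relabeled but identical structure also scores 1
  b <- c("x", "x", "y", "y", "z", "z")
  s2 <- concordance_scores(a, b)
  expect_equal(unlist(s2), c(adjusted_rand = 1, jaccard = 1, nmi = 1,
                             purity = 1))
})

test_that("the worked purity example evaluates to 0.75", {
  expect_equal(purity(c("A", "A", "B", "B"), c("x", "y", "y", "y")), 0.75)
})

test_that("all four metrics agree with the pair-enumeration oracle", {
  for (seed in 1:8) {
    n <- sample(c(10, 20, 30), 1)
    a <- random_partition(n, sample(2:5, 1), seed)
    b <- random_partition(n, sample(2:5, 1), seed + 100)
    expect_equal(adjusted_rand_index(a, b), ari_oracle(a, b),
                 tolerance = 1e-12, info = paste("seed", seed))
    expect_equal(jaccard_index(a, b), jaccard_oracle(a, b),
                 tolerance = 1e-12)
    expect_equal(normalized_mutual_information(a, b), nmi_oracle(a, b),
                 tolerance = 1e-10)
    expect_equal(purity(a, b), purity_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("metrics are invariant under cluster relabeling and handle direction", {
  a <- random_partition(24, 3, 42)
  b <- random_partition(24, 4, 43)
  relab <- c(7, 9, 8)[a]
  expect_equal(normalized_mutual_information(relab, b),
               normalized_mutual_information(a, b))
  expect_equal(purity(relab, b), purity(a, b))
  expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
  expect_equal(jaccard_index(a, b), jaccard_index(b, a))
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("ARI of random labels against structure centers on zero", {
  ref <- rep(1:5, each = 10)
  aris <- vapply(1:100, function(s)
    adjusted_rand_index(random_partition(50, 5, s), ref), numeric(1))
  expect_lt(abs(mean(aris)), 0.1)
})
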