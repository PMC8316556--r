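test_that("NPMI evaluates the formula exactly with boundary conventions", {
  # always co-occurring
  expect_identical(npmi(10, 10, 10, 100), 1)
  # independent: joint frequency equals product of marginals
  expect_equal(npmi(20, 10, 2, 100), 0, tolerance = 1e-12)
  # never co-occurring
  expect_identical(npmi(10, 10, 0, 100), -1)
  # full-corpus co-occurrence limit
  expect_identical(npmi(100, 100, 100, 100), 1)
  # worked value: ln 5 / -ln 0.05
  expect_equal(npmi(10, 10, 5, 100), log(5) / (-log(0.05)),
               tolerance = 1e-12)
  expect_equal(round(npmi(10, 10, 5, 100), 4), 0.5372)
  # count corruption is fatal
  expect_error(npmi(3, 10, 5, 100), "corruption")
  expect_error(npmi(10, 10, 5, 0), "positive")
})

test_that("NPMI is bounded, symmetric, and increasing in the joint count", {
  grid <- expand.grid(n_G = c(1, 5, 20, 80), n_P = c(1, 5, 20, 80),
                      n_GP = 0:5, n_tot = 100)
  grid <- grid[grid$n_GP <= pmin(grid$n_G, grid$n_P), ]
  vals <- npmi(grid$n_G, grid$n_P, grid$n_GP, grid$n_tot)
  expect_true(all(vals >= -1 & vals <= 1))
  sym <- npmi(grid$n_P, grid$n_G, grid$n_GP, grid$n_tot)
  expect_equal(vals, sym)
  for (ng in c(10, 40)) {
    v <- npmi(rep(ng, ng), rep(ng, ng), seq_len(ng), 100)
    expect_true(all(diff(v) > 0))
  }
})

test_that("occurrence counting deduplicates within a sentence", {
  v <- fixture_vocab()
  sents <- sentences_from_text(c(
    "FMR1 and FMR1 were tied to seizure and seizure again",
    "Background sentence with nothing",
    "FMR1 alone in this sentence"))
  mn <- mine_corpus(sents, v$genes, v$index)
  std <- standardize_corpus(mn, v$lexicon, v$hierarchy)
  counts <- count_occurrences(mn, std)
  expect_equal(counts$n_tot, 3L)
  expect_equal(unname(counts$n_G[["FMR1"]]), 2L)
  expect_equal(unname(counts$n_P[["C0036572"]]), 1L)
  expect_equal(counts$pairs$n_GP, 1L)
  expect_equal(unname(counts$papers_G[["FMR1"]]), 1L)
})

test_that("empty corpora yield all-zero counts", {
  v <- fixture_vocab()
  mn <- mine_corpus(sentences_from_text(character(0))[0, ], v$genes, v$index)
  std <- standardize_corpus(mn, v$lexicon, v$hierarchy)
  counts <- count_occurrences(mn, std)
  expect_equal(counts$n_tot, 0L)
  expect_length(counts$n_G, 0L)
  expect_equal(nrow(counts$pairs), 0L)
})

test_that("association filtering applies strict thresholds", {
  rec <- records_fixture(gene = paste0("G", 1:10),
                         concept_id = paste0("P", 1:10),
                         npmi = c(0.3, 0.3, -0.1, 0.5, 0, 0.2, 0.9, 0.1,
                                  0.4, 0.6),
                         n_GP = c(6L, 5L, 10L, 7L, 9L, 3L, 6L, 6L, 2L, 8L))
  kept <- filter_associations(rec)
  # hand filter: npmi > 0 AND n_GP > 5
  expect_equal(sort(kept$gene), sort(c("G1", "G4", "G7", "G8", "G10")))
  # boundary: npmi=0.3 with n_GP=5 is dropped (strict >)
  expect_false("G2" %in% kept$gene)
  expect_false("G5" %in% kept$gene)  # npmi = 0 dropped
})

test_that("per-gene ranking orders by NPMI with documented tie-breaks", {
  rec <- records_fixture(gene = rep("G1", 5),
                         concept_id = paste0("P", 1:5),
                         npmi = c(0.5, 0.9, 0.7, 0.9, 0.1),
                         n_GP = c(10L, 8L, 10L, 9L, 10L))
  top <- rank_phenotypes_for_gene(rec, "G1", k = 3)
  # full-sort oracle: by npmi desc, then n_GP desc, then concept id
  ord <- rec[order(-rec$npmi, -rec$n_GP, rec$concept_id), ]
  expect_equal(top$concept_id, head(ord$concept_id, 3))
  expect_equal(top$concept_id[1], "P4")  # tie on npmi, higher n_GP first
  expect_equal(nrow(rank_phenotypes_for_gene(rec, "ABSENT")), 0L)
  two <- records_fixture(gene = c("G2", "G2"), concept_id = c("A", "B"),
                         npmi = c(0.2, 0.3))
  expect_equal(nrow(rank_phenotypes_for_gene(two, "G2", k = 3)), 2L)
})

test_that("frequency summaries report class shares and top lists", {
  v <- fixture_vocab()
  rec <- records_fixture(gene = c("MECP2", "FMR1", "DRD2", "TP53", "STAT3",
                                  "UNKNOWN1", "UNKNOWN2", "UNKNOWN3",
                                  "UNKNOWN4", "UNKNOWN5"),
                         concept_id = paste0("P", 1:10),
                         npmi = runif(10, 0.1, 0.9))
  counts <- structure(list(
    n_tot = 100L,
    n_G = stats::setNames(rep(5L, 10), rec$gene),
    n_P = stats::setNames(rep(4L, 10), rec$concept_id),
    papers_G = stats::setNames(10:1, rec$gene),
    pairs = rec[, c("gene", "concept_id", "n_GP")]),
    class = "corpus_counts")
  s <- summarize_frequencies(counts, rec, v$genes, top_n = 3)
  # MECP2 and FMR1 are the two class-1 genes of ten -> 20%
  expect_equal(s$gene_class_share$pct_genes[
    s$gene_class_share$risk_class == "1"], 20)
  expect_equal(sum(s$gene_class_share$n_genes), 10L)
  expect_equal(s$top_genes$gene[1], "MECP2")  # highest papers_G
  expect_equal(nrow(s$top_genes), 3L)
  expect_equal(nrow(s$top_phenotypes), 3L)
})

test_that("count invariants hold on a planted corpus", {
  v <- fixture_vocab()
  d <- withr::local_tempdir()
  spec <- planting_spec(n_articles = 4, sentences_per_article = 40)
  truth <- generate_corpus(spec, d, seed = 5)
  sents <- corpus_sentences(read_corpus(d))
  mn <- mine_corpus(sents, v$genes, v$index)
  std <- standardize_corpus(mn, v$lexicon, v$hierarchy)
  counts <- count_occurrences(mn, std)
  rec <- build_associations(counts, std)
  expect_true(all(rec$n_GP <= pmin(rec$n_G, rec$n_P)))
  expect_true(all(pmin(rec$n_G, rec$n_P) <= rec$n_tot))
  expect_true(all(rec$npmi >= -1 & rec$npmi <= 1))
  expect_equal(unique(rec$n_tot), truth$n_sentences)
})
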