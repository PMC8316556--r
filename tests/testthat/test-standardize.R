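test_that("priority resolution picks the highest-priority source", {
  v <- fixture_vocab()
  # HPO beats MSH for the shared seizure concept
  cand <- data.frame(concept_id = c("C0036572", "C0036572"),
                     source = c("MSH", "HPO"), stringsAsFactors = FALSE)
  win <- standardize_mention(cand, v$lexicon)
  expect_equal(win$source, "HPO")
  expect_equal(win$preferred_name, "Seizure")
  expect_equal(win$hpo_id, "HP:0001250")
  # single candidate wins trivially
  one <- standardize_mention(cand[1, ], v$lexicon)
  expect_equal(one$source, "MSH")
  # OMIM (rank 3) beats SNOMEDCT_US (rank 5)
  cand2 <- data.frame(concept_id = c("C0011570", "C0016667"),
                      source = c("SNOMEDCT_US", "OMIM"),
                      stringsAsFactors = FALSE)
  expect_equal(standardize_mention(cand2, v$lexicon)$source, "OMIM")
  expect_error(standardize_mention(cand[0, ], v$lexicon), "no candidate")
})

test_that("priority resolution is invariant under candidate permutation", {
  v <- fixture_vocab()
  cand <- data.frame(concept_id = c("C0036572", "C0036572", "C0011570"),
                     source = c("MSH", "HPO", "SNOMEDCT_US"),
                     stringsAsFactors = FALSE)
  base <- standardize_mention(cand, v$lexicon)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
    expect_equal(standardize_mention(cand[perm, ], v$lexicon), base)
})

test_that("the category table has exactly 23 entries with HPO roots", {
  tab <- hpo_category_table()
  expect_equal(nrow(tab), 23L)
  expect_equal(anyDuplicated(tab$category), 0L)
  expect_equal(anyDuplicated(tab$hpo_id), 0L)
  expect_true(all(grepl("^HP:\\d{7}$", tab$hpo_id)))
})

test_that("top-level category traversal matches the all-ancestors oracle", {
  v <- fixture_vocab()
  h <- v$hierarchy
  for (id in h$nodes$id)
    expect_equal(top_level_category(id, h), category_oracle(id, h),
                 info = id)
  # leaf under the nervous-system root
  expect_equal(top_level_category("HP:0001250", h),
               "Abnormality of the nervous system")
  # multi-root node: direct Neoplasm parent (depth 1) beats breast (depth 2)
  expect_equal(top_level_category("HP:0003002", h), "Neoplasm")
  # node reaching no category root
  expect_equal(top_level_category("HP:0400001", h), "NA")
  expect_equal(top_level_category(NA_character_, h), "NA")
  expect_warning(res <- top_level_category("HP:9999999", h), "unknown")
  expect_equal(res, "NA")
})

test_that("equal-depth multi-root ties break by category table order", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: HP:0000118", "name: root", "",
               "[Term]", "id: HP:0002664", "name: Neoplasm",
               "is_a: HP:0000118", "",
               "[Term]", "id: HP:0000769", "name: Breast",
               "is_a: HP:0000118", "",
               "[Term]", "id: HP:0999001", "name: tied child",
               "is_a: HP:0002664", "is_a: HP:0000769"), obo)
  h <- read_hpo_obo(obo)
  # breast (row 7) precedes neoplasm (row 23) in the table
  expect_equal(top_level_category("HP:0999001", h),
               "Abnormality of the breast")
  expect_equal(category_oracle("HP:0999001", h),
               "Abnormality of the breast")
})

test_that("a cyclic is-a file is rejected", {
  obo <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: HP:1", "name: a", "is_a: HP:2", "",
               "[Term]", "id: HP:2", "name: b", "is_a: HP:1"), obo)
  expect_error(read_hpo_obo(obo), "cycle")
})

test_that("corpus standardization collapses synonyms and counts per source", {
  v <- fixture_vocab()
  sents <- sentences_from_text(c(
    "MECP2 related seizures were described",
    "MECP2 related convulsions were described",
    "DRD2 was linked to depression",
    "FMR1 was linked to Fragile X syndrome"))
  mn <- mine_corpus(sents, v$genes, v$index)
  std <- standardize_corpus(mn, v$lexicon, v$hierarchy)
  # the two seizure synonym surfaces collapse to one standardized concept
  seiz <- std[std$concept_id == "C0036572", ]
  expect_equal(nrow(seiz), 2L)
  expect_equal(unique(seiz$preferred_name), "Seizure")
  expect_equal(unique(seiz$source), "HPO")
  # non-HPO concepts get category NA
  expect_equal(std$category[std$concept_id == "C0016667"], "NA")
  sc <- attr(std, "source_counts")
  expect_equal(sum(sc), length(unique(std$concept_id)))
  # empty input gives an empty table
  empty <- standardize_corpus(mine_corpus(sentences_from_text("Nothing"),
                                          v$genes, v$index),
                              v$lexicon, v$hierarchy)
  expect_equal(nrow(empty), 0L)
})
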