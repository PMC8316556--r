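test_that("concept parsing drops non-English rows and reports malformed lines", {
  f <- withr::local_tempfile(fileext = ".rrf")
  mk <- function(cui, lat, sab, str) {
    fld <- rep("", 16); fld[1] <- cui; fld[2] <- lat; fld[12] <- sab
    fld[13] <- "PT"; fld[14] <- "X"; fld[15] <- str
    paste(fld, collapse = "|")
  }
  lines <- c(mk("C1", "ENG", "MSH", "alpha"), mk("C2", "ENG", "MSH", "beta"),
             mk("C3", "ENG", "OMIM", "gamma"), mk("C4", "ENG", "HPO", "delta"),
             mk("C5", "ENG", "DDB", "epsilon"), mk("C1", "FRE", "MSH", "alphe"))
  writeLines(lines, f)
  rows <- parse_concept_file(f)
  expect_equal(nrow(rows), 5L)
  expect_false(any(rows$cui == "C1" & rows$str == "alphe"))

  # one malformed line among ten -> nine rows and a logged skip
  lines10 <- c(lines[1:5], mk("C6", "ENG", "MSH", "s6"),
               mk("C7", "ENG", "MSH", "s7"), mk("C8", "ENG", "MSH", "s8"),
               mk("C9", "ENG", "MSH", "s9"), "C10|ENG|truncated")
  writeLines(lines10, f)
  expect_warning(rows10 <- parse_concept_file(f), "malformed")
  expect_equal(nrow(rows10), 9L)

  writeLines(character(0), f)
  expect_equal(nrow(parse_concept_file(f)), 0L)
  expect_error(parse_concept_file(file.path(tempdir(), "absent.rrf")),
               "not found")
})

test_that("semantic types accumulate per concept", {
  f <- withr::local_tempfile(fileext = ".rrf")
  writeLines(c("C1|T047||", "C1|T184||", "C2|T048||", "C3|T079||",
               "C4|T047||"), f)
  m <- parse_semantic_types(f)
  expect_equal(m[["C1"]], c("T047", "T184"))
  expect_length(m, 4L)
  writeLines(character(0), f)
  expect_length(parse_semantic_types(f), 0L)
})

test_that("two-layer filtering keeps admitted sources and semantic types", {
  v <- fixture_vocab()
  lex <- v$lexicon
  # hand-applied filter on the synthetic vocabulary: 12 surviving concepts
  expect_s3_class(lex, "phenotype_lexicon")
  expect_equal(nrow(lex), synthetic_vocabulary_def()$n_lexicon_concepts)
  # OMIM concept with T047 retained
  expect_true(any(lex$concept_id == "C0016667" & lex$source == "OMIM"))
  # SNOMED concept typed only T079 excluded; HPO concept typed T079 excluded
  expect_false(any(lex$concept_id == "C0439228"))
  expect_false(any(lex$concept_id == "C0439234"))
  # ASDPTO appended without semantic-type filtering
  expect_equal(sum(lex$source == "ASDPTO"), 2L)
  # every non-HPO/ASDPTO concept intersects the include set
  f <- semantic_type_filter()
  non_hpo <- lex[!(lex$source %in% c("HPO", "ASDPTO")), ]
  for (i in seq_len(nrow(non_hpo)))
    expect_gt(length(intersect(non_hpo$semantic_types[[i]],
                               f$include_codes)), 0L)
  # synonyms include the preferred name
  for (i in seq_len(nrow(lex)))
    expect_true(lex$preferred_name[i] %in% lex$synonyms[[i]])
})

test_that("lexicon filtering matches an independent re-implementation", {
  v <- fixture_vocab()
  f <- semantic_type_filter()
  # independent filter over raw rows
  keys <- unique(paste(v$rows$cui, v$rows$sab, sep = "/"))
  keys <- keys[sub("^.*/", "", keys) %in%
                 c("HPO", "OMIM", "DDB", "SNOMEDCT_US", "MSH")]
  survives <- vapply(keys, function(k) {
    cui <- sub("/.*$", "", k); sab <- sub("^.*/", "", k)
    sty <- v$sem[[cui]]
    if (sab == "HPO") !any(sty %in% f$hpo_exclude_codes)
    else !is.null(sty) && any(sty %in% f$include_codes)
  }, logical(1))
  expected_n <- sum(survives) + nrow(v$asd)
  expect_equal(nrow(v$lexicon), expected_n)
})

test_that("lexicon build is deterministic and ordered", {
  v <- fixture_vocab()
  lex2 <- build_phenotype_lexicon(v$rows, v$sem, asdpto = v$asd)
  expect_identical(as.data.frame(v$lexicon), as.data.frame(lex2))
  expect_identical(order(lex2$concept_id, lex2$source), seq_len(nrow(lex2)))
  # permuting input row order leaves the lexicon unchanged
  set.seed(3)
  lex3 <- build_phenotype_lexicon(v$rows[sample(nrow(v$rows)), ], v$sem,
                                  asdpto = v$asd)
  expect_identical(lex2$concept_id, lex3$concept_id)
  expect_identical(lex2$preferred_name, lex3$preferred_name)
})

test_that("lexicon JSON serialization round-trips", {
  v <- fixture_vocab()
  f <- withr::local_tempfile(fileext = ".json")
  write_lexicon(v$lexicon, f, genes = v$genes)
  back <- read_lexicon(f)
  expect_equal(back$phenotypes$concept_id, v$lexicon$concept_id)
  expect_equal(back$phenotypes$hpo_id, v$lexicon$hpo_id)
  expect_equal(back$phenotypes$synonyms, v$lexicon$synonyms)
  expect_equal(as.data.frame(back$genes), as.data.frame(v$genes))
})

test_that("gene list loading deduplicates and validates classes", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("MECP2,1", "DRD2,3", "XYZ,"), f)
  g <- load_gene_list(f)
  expect_equal(nrow(g), 3L)
  expect_equal(g$risk_class, c("1", "3", NA))

  writeLines(c("FMR1,1", "FMR1,1", "MECP2,2"), f)
  expect_equal(nrow(load_gene_list(f)), 2L)

  # 10 rows with 2 exact duplicates -> 8 entries
  writeLines(c(paste0("G", 1:8, ",1"), "G1,1", "G2,1"), f)
  expect_equal(nrow(load_gene_list(f)), 8L)

  writeLines(c("FMR1,1", "FMR1,2"), f)
  expect_error(load_gene_list(f), "conflicting")

  writeLines(c("ABC,9"), f)
  expect_warning(g <- load_gene_list(f), "unknown risk class")
  expect_true(is.na(g$risk_class[1]))
})

test_that("priority order and filter configuration are validated", {
  pr <- source_priority()
  expect_equal(names(pr)[order(pr)],
               c("HPO", "ASDPTO", "OMIM", "DDB", "SNOMEDCT_US", "MSH"))
  expect_equal(anyDuplicated(pr), 0L)
  expect_error(semantic_type_filter(include_codes = c("T047", "T079")),
               "disjoint")
})
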