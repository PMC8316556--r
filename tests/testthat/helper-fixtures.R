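# Shared fixtures, built in code at test time.

# Vocabulary files + parsed lexicon, built once per test run.
fixture_vocab <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "genepheno-vocab")
      paths <- generate_vocabulary(dir)
      rows <- parse_concept_file(paths$concepts)
      sem <- parse_semantic_types(paths$semtypes)
      asd <- load_asdpto_terms(paths$asdpto)
      lex <- build_phenotype_lexicon(rows, sem, asdpto = asd)
      cache <<- list(paths = paths, rows = rows, sem = sem, asd = asd,
                     lexicon = lex, genes = load_gene_list(paths$genes),
                     hierarchy = read_hpo_obo(paths$hpo),
                     index = phenotype_index(lex))
    }
    cache
  }
})

# A sentence table built directly from raw text lines (bypasses XML).
sentences_from_text <- function(texts, article_id = "A1") {
  data.frame(article_id = rep_len(article_id, length(texts)),
             index = seq_along(texts) - 1L,
             text = texts, stringsAsFactors = FALSE)
}

# Minimal JATS article writer for corpus_io tests.
write_jats <- function(path, title, paragraphs, pmc = NULL,
                       ref_text = NULL) {
  xml <- c("<?xml version=\"1.0\"?>", "<article>", "<front>")
  if (!is.null(pmc))
    xml <- c(xml, "<article-meta>",
             sprintf("<article-id pub-id-type=\"pmc\">%s</article-id>", pmc),
             "</article-meta>")
  xml <- c(xml,
           sprintf("<title-group><article-title>%s</article-title></title-group>",
                   title),
           "</front>", "<body>",
           sprintf("<p>%s</p>", paragraphs))
  if (!is.null(ref_text))
    xml <- c(xml, sprintf("<ref-list><ref><p>%s</p></ref></ref-list>",
                          ref_text))
  xml <- c(xml, "</body>", "</article>")
  writeLines(xml, path)
  path
}

# Small association record table with hand-set values.
records_fixture <- function(gene, concept_id, npmi, n_GP = 10L,
                            preferred_name = concept_id,
                            category = "NA", hpo_id = NA_character_,
                            n_tot = 1000L) {
  n <- length(gene)
  data.frame(gene = gene, concept_id = concept_id,
             preferred_name = rep_len(preferred_name, n),
             source = "HPO", hpo_id = rep_len(hpo_id, n),
             category = rep_len(category, n),
             n_G = pmax(n_GP, 20L), n_P = pmax(n_GP, 20L),
             n_GP = rep_len(as.integer(n_GP), n),
             n_tot = n_tot, npmi = npmi, stringsAsFactors = FALSE)
}
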