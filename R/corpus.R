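# Corpus I/O and text preprocessing: JATS-style XML reading, sentence
# segmentation, tokenization, stop-word removal and rule-based lemmatization.
# All preprocessing is deterministic rule code so that the same pipeline can
# be applied identically to vocabulary terms and corpus sentences.

.gp_env <- new.env(parent = emptyenv())

#' Packaged English stop-word list
#'
#' Loaded from a plain-text file shipped with the package (one word per
#' line) rather than an implicit library default, for reproducibility.
#'
#' @param path Optional path to an alternative stop-word file.
#' @return Character vector of stop words.
#' @export
stopword_list <- function(path = NULL) {
  if (!is.null(path)) return(readLines(path, warn = FALSE))
  if (is.null(.gp_env$stopwords)) {
    f <- system.file("extdata", "stopwords_en.txt", package = "genepheno")
    .gp_env$stopwords <- readLines(f, warn = FALSE)
  }
  .gp_env$stopwords
}

# Irregular noun/verb forms the suffix rules cannot reach.
.irregular_lemmas <- c(
  mice = "mouse", children = "child", men = "man", women = "woman",
  feet = "foot", teeth = "tooth", geese = "goose", people = "person",
  criteria = "criterion", phenomena = "phenomenon", analyses = "analysis",
  diagnoses = "diagnosis", hypotheses = "hypothesis", nuclei = "nucleus",
  stimuli = "stimulus", foci = "focus", loci = "locus", genera = "genus",
  ran = "run", went = "go", found = "find", showed = "show", gave = "give",
  took = "take", made = "make", saw = "see", was = "be", were = "be")

#' Rule-based English lemmatizer
#'
#' Lowercases tokens and reduces common inflections with an irregular-form
#' table followed by deterministic suffix rules (plural `-ies`/`-es`/`-s`,
#' progressive `-ing`, past `-ed` with final-consonant undoubling). The rules
#' are intentionally simple: what matters for dictionary matching is that the
#' identical transformation is applied to vocabulary terms and to sentences,
#' so inflectional variants on both sides collapse to the same key.
#'
#' @param tokens Character vector of raw tokens.
#' @return Character vector of lowercased lemmas.
#' @export
#' @examples
#' lemmatize_tokens(c("Epilepsies", "seizures", "running", "mice"))
lemmatize_tokens <- function(tokens) {
  x <- tolower(tokens)
  irr <- .irregular_lemmas[x]
  hit <- !is.na(irr)
  x[hit] <- irr[hit]
  w <- !hit
  n <- nchar(x)
  undouble <- function(s) {
    # strip one of a doubled final consonant (stopp -> stop), keep ll/ss
    sub("([b-df-hj-np-tv-z])\\1$", "\\1", s)
  }
  # plural -ies -> -y (epilepsies -> epilepsy)
  i <- w & n > 4L & endsWith(x, "ies")
  x[i] <- sub("ies$", "y", x[i])
  # -sses/-xes/-ches/-shes/-zes/-oes -> strip "es"
  i <- w & n > 4L & grepl("(sses|xes|ches|shes|zes|oes)$", x)
  x[i] <- sub("es$", "", x[i])
  # remaining plural -s (not -ss/-us/-is): seizures -> seizure
  i <- w & n > 3L & endsWith(x, "s") &
    !grepl("(ss|us|is|ies)$", x)
  x[i] <- sub("s$", "", x[i])
  # progressive -ing: running -> run
  n <- nchar(x)
  i <- w & n > 5L & endsWith(x, "ing")
  x[i] <- undouble(sub("ing$", "", x[i]))
  # past -ed: stopped -> stop
  n <- nchar(x)
  i <- w & n > 4L & endsWith(x, "ed")
  x[i] <- undouble(sub("ed$", "", x[i]))
  x
}

#' Tokenize raw text with character offsets
#'
#' Tokens are maximal runs of letters, digits, apostrophes and internal
#' hyphens. Offsets are 0-based, half-open against the input string.
#'
#' @param text A single string.
#' @return Data frame with columns `token`, `start`, `end`.
#' @export
tokenize_raw <- function(text) {
  if (is.na(text) || !nzchar(text))
    return(empty_df(token = "character", start = "integer", end = "integer"))
  loc <- stringi::stri_locate_all_regex(text, "[A-Za-z0-9][A-Za-z0-9'\\-]*")[[1]]
  if (is.na(loc[1L, 1L]))
    return(empty_df(token = "character", start = "integer", end = "integer"))
  data.frame(token = stringi::stri_sub(text, loc[, 1L], loc[, 2L]),
             start = as.integer(loc[, 1L] - 1L),
             end = as.integer(loc[, 2L]),
             stringsAsFactors = FALSE)
}

#' Preprocess one sentence into lemma tokens
#'
#' Tokenizes, lowercases and lemmatizes a sentence, removing stop words.
#' The raw-character span of every surviving lemma is retained so phenotype
#' mention spans can be mapped back to the original text. Gene matching uses
#' the raw case-sensitive token stream from [tokenize_raw()] instead, so
#' symbol case is never folded.
#'
#' @param raw_text Sentence string.
#' @param stopwords Stop-word vector (defaults to the packaged list).
#' @return Data frame with columns `lemma`, `start`, `end`.
#' @export
#' @examples
#' preprocess_sentence("The mice were running")
preprocess_sentence <- function(raw_text, stopwords = stopword_list()) {
  tok <- tokenize_raw(raw_text)
  if (nrow(tok) == 0L)
    return(empty_df(lemma = "character", start = "integer", end = "integer"))
  keep <- !(tolower(tok$token) %in% stopwords)
  tok <- tok[keep, , drop = FALSE]
  if (nrow(tok) == 0L)
    return(empty_df(lemma = "character", start = "integer", end = "integer"))
  out <- data.frame(lemma = lemmatize_tokens(tok$token),
                    start = tok$start, end = tok$end,
                    stringsAsFactors = FALSE)
  out <- out[nzchar(out$lemma), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Preprocess a vocabulary term into its lemma key
#'
#' Applies the same tokenize/stop-word/lemmatize pipeline as
#' [preprocess_sentence()]. A term whose every token is a stop word reduces
#' to zero tokens and is flagged for exclusion from the match index.
#'
#' @param term Vocabulary term string.
#' @param stopwords Stop-word vector.
#' @return Character vector of lemmas; `character(0)` for degenerate terms.
#' @export
#' @examples
#' preprocess_term("Epilepsies, Partial")
preprocess_term <- function(term, stopwords = stopword_list()) {
  preprocess_sentence(term, stopwords)$lemma
}

# Abbreviations that never end a sentence when followed by more text.
.abbreviations <- c("al", "fig", "figs", "e.g", "i.e", "vs", "cf", "ca",
                    "approx", "dr", "mr", "mrs", "ms", "prof", "no", "nos",
                    "st", "etc", "ref", "refs", "eq", "eqs", "suppl", "vol")

#' Segment article text into sentences
#'
#' Deterministic rule-based segmentation: a sentence boundary is a run of
#' `.`, `!` or `?` followed by whitespace and an upper-case letter, digit or
#' opening quote/parenthesis, unless the preceding word is a known
#' abbreviation ("et al.", "Fig.", initials, ...). Text blocks (title,
#' paragraphs) are segmented independently and never merged across blocks.
#'
#' @param article An article from [read_article_xml()], or a character vector
#'   of text blocks.
#' @return Data frame with columns `article_id`, `index` (0-based,
#'   consecutive within the article) and `text`.
#' @export
segment_sentences <- function(article) {
  if (is.character(article)) {
    blocks <- article
    article_id <- "article"
  } else {
    blocks <- article$blocks
    article_id <- article$article_id
  }
  sentences <- character(0)
  for (block in blocks) {
    block <- stringi::stri_trim_both(block)
    if (!nzchar(block)) next
    sentences <- c(sentences, split_block_sentences(block))
  }
  if (length(sentences) == 0L)
    return(empty_df(article_id = "character", index = "integer",
                    text = "character"))
  data.frame(article_id = article_id,
             index = seq_along(sentences) - 1L,
             text = sentences, stringsAsFactors = FALSE)
}

#' @noRd
split_block_sentences <- function(block) {
  cand <- stringi::stri_locate_all_regex(
    block, "[.!?]+(?=\\s+[\"'(\\[]?[A-Z0-9])")[[1]]
  if (is.na(cand[1L, 1L])) return(block)
  cuts <- integer(0)
  for (r in seq_len(nrow(cand))) {
    pos <- cand[r, 1L]
    before <- stringi::stri_sub(block, 1L, pos - 1L)
    word <- stringi::stri_extract_last_regex(before, "[A-Za-z.]+")
    if (!is.na(word)) {
      w <- tolower(sub("\\.$", "", word))
      if (w %in% .abbreviations) next
      # single-letter initials ("J. Smith") never end a sentence
      if (nchar(w) == 1L && grepl("^[A-Za-z]$", w)) next
    }
    cuts <- c(cuts, cand[r, 2L])
  }
  if (length(cuts) == 0L) return(block)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, nchar(block))
  out <- stringi::stri_trim_both(stringi::stri_sub(block, starts, ends))
  out[nzchar(out)]
}

#' Read one JATS-style article XML file
#'
#' Extracts the article id (PMC id when present, else the filename stem),
#' the title, abstract paragraphs and body paragraphs in document order.
#' Reference lists, tables and figure captions are excluded.
#'
#' @param path Path to an `.xml`/`.nxml` file.
#' @return List with elements `article_id`, `title` and `blocks` (character
#'   vector: title, then abstract and body paragraphs).
#' @export
read_article_xml <- function(path) {
  doc <- xml2::read_xml(path)
  pmc <- xml2::xml_find_first(doc, ".//front//article-id[@pub-id-type='pmc']")
  article_id <- if (!inherits(pmc, "xml_missing")) {
    paste0("PMC", sub("^PMC", "", xml2::xml_text(pmc)))
  } else {
    tools::file_path_sans_ext(basename(path))
  }
  title_node <- xml2::xml_find_first(doc, ".//front//article-title")
  title <- if (inherits(title_node, "xml_missing")) "" else
    squeeze_ws(xml2::xml_text(title_node))
  exclude <- paste0("not(ancestor::ref-list) and not(ancestor::table-wrap) ",
                    "and not(ancestor::fig) and not(ancestor::caption) ",
                    "and not(ancestor::table)")
  abs_ps <- xml2::xml_find_all(doc, sprintf(".//front//abstract//p[%s]", exclude))
  body_ps <- xml2::xml_find_all(doc, sprintf(".//body//p[%s]", exclude))
  paras <- vapply(c(abs_ps, body_ps), function(n) squeeze_ws(xml2::xml_text(n)),
                  character(1))
  blocks <- c(if (nzchar(title)) title, paras[nzchar(paras)])
  list(article_id = article_id, title = title,
       blocks = as.character(blocks %||% character(0)))
}

#' @noRd
squeeze_ws <- function(x) stringi::stri_trim_both(gsub("\\s+", " ", x))

#' Read a corpus directory of article XML files
#'
#' Malformed files are skipped with a logged message; the run continues.
#'
#' @param dir Directory containing `.xml`/`.nxml` files.
#' @return List of articles (see [read_article_xml()]).
#' @export
read_corpus <- function(dir) {
  if (!dir.exists(dir)) gp_stop("corpus directory not found: %s", dir)
  files <- sort(list.files(dir, pattern = "\\.(xml|nxml)$", full.names = TRUE))
  articles <- list()
  for (f in files) {
    art <- tryCatch(read_article_xml(f), error = function(e) {
      message(sprintf("skipping malformed article %s: %s",
                      basename(f), conditionMessage(e)))
      NULL
    })
    if (!is.null(art)) articles[[length(articles) + 1L]] <- art
  }
  ids <- vapply(articles, `[[`, character(1), "article_id")
  if (anyDuplicated(ids))
    gp_stop("duplicate article id(s) in corpus: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  articles
}

#' Segment a whole corpus into a sentence table
#'
#' @param articles List of articles from [read_corpus()].
#' @return Data frame of sentences (`article_id`, `index`, `text`) ordered by
#'   article id then index.
#' @export
corpus_sentences <- function(articles) {
  parts <- lapply(articles, segment_sentences)
  out <- do.call(rbind, c(parts, list(
    empty_df(article_id = "character", index = "integer", text = "character"))))
  out <- out[order(out$article_id, out$index), , drop = FALSE]
  rownames(out) <- NULL
  out
}
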