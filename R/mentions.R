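# Mention detection: case-sensitive whole-token gene matching on the raw
# token stream, and longest-leftmost lemma n-gram matching for phenotypes.

#' Build the phenotype match index
#'
#' Every synonym of every lexicon concept is preprocessed with
#' [preprocess_term()] into a lemma n-gram key. Terms that reduce to zero
#' tokens (all stop words) are flagged and excluded with a warning. A key
#' matched in text yields all candidate concepts that share it; resolution
#' to a single concept is deferred to the standardization step.
#'
#' @param lexicon A `phenotype_lexicon`.
#' @param stopwords Stop-word vector.
#' @return An object of class `phenotype_index`.
#' @export
phenotype_index <- function(lexicon, stopwords = stopword_list()) {
  keys <- character(0); cids <- character(0); srcs <- character(0)
  degenerate <- character(0)
  for (i in seq_len(nrow(lexicon))) {
    for (syn in lexicon$synonyms[[i]]) {
      lemmas <- preprocess_term(syn, stopwords)
      if (length(lemmas) == 0L) {
        degenerate <- c(degenerate, syn)
        next
      }
      keys <- c(keys, paste(lemmas, collapse = " "))
      cids <- c(cids, lexicon$concept_id[i])
      srcs <- c(srcs, lexicon$source[i])
    }
  }
  if (length(degenerate) > 0L)
    gp_warn("excluded %d degenerate term(s) reducing to zero tokens: %s",
            length(degenerate),
            paste(unique(utils::head(degenerate, 5L)), collapse = ", "))
  df <- unique(data.frame(key = keys, concept_id = cids, source = srcs,
                          stringsAsFactors = FALSE))
  terms <- split(df[c("concept_id", "source")], df$key)
  lens <- if (length(terms) > 0L)
    vapply(strsplit(names(terms), " ", fixed = TRUE), length, integer(1))
  else integer(0)
  structure(list(terms = terms, ngram_lengths = sort(unique(lens),
                                                     decreasing = TRUE)),
            class = "phenotype_index")
}

#' @export
print.phenotype_index <- function(x, ...) {
  cat(sprintf("<phenotype_index> %d term key(s), n-gram lengths: %s\n",
              length(x$terms), paste(x$ngram_lengths, collapse = ", ")))
  invisible(x)
}

#' Match gene symbols in one sentence
#'
#' Whole-token matches of gene symbols against the raw (case-preserving)
#' token stream. Case-sensitive by default: `CAT` does not fire inside
#' "scatter", nor on lowercase "cat". All occurrences are reported.
#'
#' @param raw_text Sentence text (or a precomputed [tokenize_raw()] frame
#'   via `tokens`).
#' @param symbols Character vector of gene symbols.
#' @param case_sensitive Match symbols case-sensitively (default `TRUE`).
#' @param tokens Optional precomputed token frame.
#' @return Data frame of mentions: `surface`, `symbol`, `start`, `end`.
#' @export
match_genes <- function(raw_text, symbols, case_sensitive = TRUE,
                        tokens = NULL) {
  tok <- tokens %||% tokenize_raw(raw_text)
  if (nrow(tok) == 0L)
    return(empty_df(surface = "character", symbol = "character",
                    start = "integer", end = "integer"))
  if (case_sensitive) {
    idx <- match(tok$token, symbols)
  } else {
    idx <- match(toupper(tok$token), toupper(symbols))
  }
  hit <- !is.na(idx)
  data.frame(surface = tok$token[hit], symbol = symbols[idx[hit]],
             start = tok$start[hit], end = tok$end[hit],
             stringsAsFactors = FALSE)
}

#' Match phenotype terms in one sentence
#'
#' Contiguous lemma n-gram matching against the phenotype index. Overlapping
#' candidate matches are resolved longest-match-first, then leftmost, so the
#' final mention set is non-overlapping ("breast cancer" wins over "cancer").
#' Spans are mapped back to raw character offsets (0-based, half-open).
#'
#' @param raw_text Sentence text.
#' @param index A [phenotype_index()].
#' @param lemmas Optional precomputed [preprocess_sentence()] frame.
#' @return Data frame of mentions with columns `surface`, `key`, `start`,
#'   `end` and a list-column `candidates` (data frame of `concept_id`,
#'   `source` per mention).
#' @export
match_phenotypes <- function(raw_text, index, lemmas = NULL) {
  lem <- lemmas %||% preprocess_sentence(raw_text)
  out <- empty_df(surface = "character", key = "character",
                  start = "integer", end = "integer")
  out$candidates <- list()
  n <- nrow(lem)
  if (n == 0L || length(index$terms) == 0L) return(out)
  taken <- rep(FALSE, n)
  hits <- list()
  for (len in index$ngram_lengths) {
    if (len > n) next
    for (s in seq_len(n - len + 1L)) {
      e <- s + len - 1L
      if (any(taken[s:e])) next
      key <- paste(lem$lemma[s:e], collapse = " ")
      cand <- index$terms[[key]]
      if (is.null(cand)) next
      taken[s:e] <- TRUE
      hits[[length(hits) + 1L]] <- list(
        key = key, start = lem$start[s], end = lem$end[e], candidates = cand)
    }
  }
  if (length(hits) == 0L) return(out)
  out <- data.frame(
    surface = vapply(hits, function(h)
      stringi::stri_sub(raw_text, h$start + 1L, h$end), character(1)),
    key = vapply(hits, `[[`, character(1), "key"),
    start = vapply(hits, function(h) as.integer(h$start), integer(1)),
    end = vapply(hits, function(h) as.integer(h$end), integer(1)),
    stringsAsFactors = FALSE)
  out$candidates <- lapply(hits, `[[`, "candidates")
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mine a sentence table for gene and phenotype mentions
#'
#' Runs both matchers over every sentence and identifies target sentences:
#' those with at least one gene mention and at least one phenotype mention.
#'
#' @param sentences Sentence table from [corpus_sentences()].
#' @param gene_lexicon A `gene_lexicon`.
#' @param index A [phenotype_index()].
#' @param case_sensitive Passed to [match_genes()].
#' @return An object of class `mention_set`: list with data frames
#'   `gene_mentions` (`article_id`, `sentence_index`, `surface`, `symbol`,
#'   `start`, `end`), `phenotype_mentions` (adds `mention_id`, `key`,
#'   list-column `candidates`), and `targets` (`article_id`, `index`), all
#'   ordered by article id then sentence index.
#' @export
mine_corpus <- function(sentences, gene_lexicon, index,
                        case_sensitive = TRUE) {
  symbols <- gene_lexicon$symbol
  gm <- list(); pm <- list()
  tgt_art <- character(0); tgt_idx <- integer(0)
  mention_id <- 0L
  for (i in seq_len(nrow(sentences))) {
    txt <- sentences$text[i]
    tok <- tokenize_raw(txt)
    g <- match_genes(txt, symbols, case_sensitive, tokens = tok)
    keep <- !(tolower(tok$token) %in% stopword_list())
    lem <- tok[keep, , drop = FALSE]
    if (nrow(lem) > 0L) {
      lem <- data.frame(lemma = lemmatize_tokens(lem$token),
                        start = lem$start, end = lem$end,
                        stringsAsFactors = FALSE)
      lem <- lem[nzchar(lem$lemma), , drop = FALSE]
    } else {
      lem <- empty_df(lemma = "character", start = "integer", end = "integer")
    }
    p <- match_phenotypes(txt, index, lemmas = lem)
    if (nrow(g) > 0L) {
      g$article_id <- sentences$article_id[i]
      g$sentence_index <- sentences$index[i]
      gm[[length(gm) + 1L]] <- g
    }
    if (nrow(p) > 0L) {
      p$article_id <- sentences$article_id[i]
      p$sentence_index <- sentences$index[i]
      p$mention_id <- mention_id + seq_len(nrow(p))
      mention_id <- mention_id + nrow(p)
      pm[[length(pm) + 1L]] <- p
    }
    if (nrow(g) > 0L && nrow(p) > 0L) {
      tgt_art <- c(tgt_art, sentences$article_id[i])
      tgt_idx <- c(tgt_idx, sentences$index[i])
    }
  }
  gene_mentions <- if (length(gm) > 0L) do.call(rbind, gm) else
    cbind(empty_df(surface = "character", symbol = "character",
                   start = "integer", end = "integer"),
          empty_df(article_id = "character", sentence_index = "integer"))
  phen0 <- empty_df(surface = "character", key = "character",
                    start = "integer", end = "integer")
  phen0$candidates <- list()
  phen0$article_id <- character(0); phen0$sentence_index <- integer(0)
  phen0$mention_id <- integer(0)
  phenotype_mentions <- if (length(pm) > 0L) do.call(rbind, pm) else phen0
  cols_g <- c("article_id", "sentence_index", "surface", "symbol",
              "start", "end")
  cols_p <- c("mention_id", "article_id", "sentence_index", "surface", "key",
              "start", "end", "candidates")
  gene_mentions <- gene_mentions[order(gene_mentions$article_id,
                                       gene_mentions$sentence_index,
                                       gene_mentions$start), cols_g,
                                 drop = FALSE]
  phenotype_mentions <- phenotype_mentions[
    order(phenotype_mentions$article_id, phenotype_mentions$sentence_index,
          phenotype_mentions$start), cols_p, drop = FALSE]
  rownames(gene_mentions) <- rownames(phenotype_mentions) <- NULL
  targets <- data.frame(article_id = tgt_art, index = tgt_idx,
                        stringsAsFactors = FALSE)
  targets <- targets[order(targets$article_id, targets$index), , drop = FALSE]
  rownames(targets) <- NULL
  structure(list(gene_mentions = gene_mentions,
                 phenotype_mentions = phenotype_mentions,
                 targets = targets,
                 n_sentences = nrow(sentences)),
            class = "mention_set")
}

#' @export
print.mention_set <- function(x, ...) {
  cat(sprintf(paste0("<mention_set> %d gene mention(s), %d phenotype ",
                     "mention(s), %d target sentence(s) over %d sentence(s)\n"),
              nrow(x$gene_mentions), nrow(x$phenotype_mentions),
              nrow(x$targets), x$n_sentences))
  invisible(x)
}

#' Extract gene-phenotype pairs from one target sentence
#'
#' The Cartesian product of distinct gene symbols and distinct phenotype
#' concept ids mentioned in the sentence, duplicates collapsed.
#'
#' @param gene_symbols Character vector of gene symbols mentioned (possibly
#'   with repeats).
#' @param concept_ids Character vector of phenotype concept ids mentioned.
#' @return Data frame with columns `gene`, `concept_id`.
#' @export
extract_pairs <- function(gene_symbols, concept_ids) {
  g <- unique(gene_symbols)
  p <- unique(concept_ids)
  if (length(g) == 0L || length(p) == 0L)
    return(empty_df(gene = "character", concept_id = "character"))
  out <- expand.grid(gene = g, concept_id = p, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  out[order(out$gene, out$concept_id), , drop = FALSE]
}
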