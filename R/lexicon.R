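# Lexicon construction: parse UMLS-style RRF files, apply the two-layer
# source-vocabulary / semantic-type filter, and load the gene list.

#' Source vocabulary priority order
#'
#' The fixed priority ranking used to resolve a phenotype mention to a single
#' standardized concept when several vocabularies contain the matched string.
#' HPO is the highest-priority source; the remaining vocabularies complement
#' it in descending order ASDPTO, OMIM, DDB, SNOMED-CT (US edition), MSH.
#'
#' @return Named integer vector mapping source abbreviation to rank
#'   (1 = highest priority).
#' @export
#' @examples
#' source_priority()["HPO"]
source_priority <- function() {
  c(HPO = 1L, ASDPTO = 2L, OMIM = 3L, DDB = 4L, SNOMEDCT_US = 5L, MSH = 6L)
}

#' Default RRF column layout
#'
#' Column indices into pipe-delimited concept (MRCONSO-dialect) and semantic
#' type (MRSTY-dialect) files. Defaults follow the public RRF layout; they are
#' configurable so miniature format-valid fixtures can be used.
#'
#' @param cui,lat,sab,tty,code,str 1-based column indices in the concept file:
#'   concept identifier, language, source abbreviation, term type, source code
#'   (carries the HPO id for HPO rows), and term string.
#' @param sty_cui,sty_tui 1-based column indices in the semantic-type file:
#'   concept identifier and semantic-type T-code.
#' @return A list of column indices.
#' @export
rrf_columns <- function(cui = 1L, lat = 2L, sab = 12L, tty = 13L,
                        code = 14L, str = 15L, sty_cui = 1L, sty_tui = 2L) {
  list(cui = cui, lat = lat, sab = sab, tty = tty, code = code, str = str,
       sty_cui = sty_cui, sty_tui = sty_tui)
}

#' Semantic-type filter configuration
#'
#' Non-HPO source vocabularies contribute only concepts whose semantic types
#' intersect `include_codes` (default: T047 Disease or Syndrome, T048 Mental
#' or Behavioral Dysfunction, T184 Sign or Symptom). HPO contributes all
#' concepts except those typed with any of `hpo_exclude_codes`. The published
#' exclusion list is open-ended, so it is exposed as configuration with the
#' six printed codes as the default.
#'
#' @param include_codes Character vector of T-codes admitted for non-HPO
#'   sources.
#' @param hpo_exclude_codes Character vector of T-codes excluded for HPO.
#' @return An object of class `semantic_type_filter`.
#' @export
semantic_type_filter <- function(include_codes = c("T047", "T048", "T184"),
                                 hpo_exclude_codes = c("T045", "T077", "T079",
                                                       "T080", "T082", "T169")) {
  if (length(intersect(include_codes, hpo_exclude_codes)) > 0L)
    gp_stop("include_codes and hpo_exclude_codes must be disjoint")
  structure(list(include_codes = include_codes,
                 hpo_exclude_codes = hpo_exclude_codes),
            class = "semantic_type_filter")
}

#' Parse an RRF-dialect concept file
#'
#' Reads a pipe-delimited concept file (MRCONSO dialect), keeping one row per
#' line. Rows whose language column is not `ENG` are dropped; lines with too
#' few fields are skipped and reported with their line numbers.
#'
#' @param path Path to the pipe-delimited concept file.
#' @param columns Column layout from [rrf_columns()].
#' @return A data frame with columns `cui`, `sab`, `tty`, `code`, `str`.
#' @export
parse_concept_file <- function(path, columns = rrf_columns()) {
  if (!file.exists(path)) gp_stop("concept file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- empty_df(cui = "character", sab = "character", tty = "character",
                  code = "character", str = "character")
  if (length(lines) == 0L) return(out)
  need <- max(columns$cui, columns$lat, columns$sab, columns$tty,
              columns$code, columns$str)
  fields <- stringi::stri_split_fixed(lines, "|")
  nf <- lengths(fields)
  bad <- which(nf < need)
  if (length(bad) > 0L) {
    gp_warn("skipped %d malformed concept line(s): %s", length(bad),
            paste(utils::head(bad, 10L), collapse = ", "))
    fields <- fields[-bad]
  }
  if (length(fields) == 0L) return(out)
  m <- do.call(rbind, lapply(fields, function(f)
    f[c(columns$cui, columns$lat, columns$sab, columns$tty,
        columns$code, columns$str)]))
  df <- data.frame(cui = m[, 1L], lat = m[, 2L], sab = m[, 3L],
                   tty = m[, 4L], code = m[, 5L], str = m[, 6L],
                   stringsAsFactors = FALSE)
  df <- df[df$lat == "ENG", c("cui", "sab", "tty", "code", "str")]
  rownames(df) <- NULL
  df
}

#' Parse an RRF-dialect semantic-type file
#'
#' Reads a pipe-delimited semantic-type file (MRSTY dialect) into a map from
#' concept identifier to the set of its T-codes. Concepts with several rows
#' accumulate all codes.
#'
#' @inheritParams parse_concept_file
#' @return Named list mapping concept id to a character vector of T-codes.
#' @export
parse_semantic_types <- function(path, columns = rrf_columns()) {
  if (!file.exists(path)) gp_stop("semantic-type file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(structure(list(), names = character(0)))
  need <- max(columns$sty_cui, columns$sty_tui)
  fields <- stringi::stri_split_fixed(lines, "|")
  nf <- lengths(fields)
  bad <- which(nf < need)
  if (length(bad) > 0L) {
    gp_warn("skipped %d malformed semantic-type line(s): %s", length(bad),
            paste(utils::head(bad, 10L), collapse = ", "))
    fields <- fields[-bad]
  }
  cui <- vapply(fields, `[`, character(1), columns$sty_cui)
  tui <- vapply(fields, `[`, character(1), columns$sty_tui)
  lapply(split(tui, cui), function(x) sort(unique(x)))
}

#' Load an ASDPTO flat term list
#'
#' Tab-separated file with columns `id`, `name`, optional `synonyms`
#' (pipe-separated) and optional `hpo_id` (cross-reference into HPO).
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `id`, `name`, `synonyms`, `hpo_id`.
#' @export
load_asdpto_terms <- function(path) {
  df <- read_tsv_plain(path)
  if (is.null(df) || nrow(df) == 0L)
    return(empty_df(id = "character", name = "character",
                    synonyms = "character", hpo_id = "character"))
  if (!all(c("id", "name") %in% names(df)))
    gp_stop("ASDPTO file must have 'id' and 'name' columns: %s", path)
  df$synonyms <- if ("synonyms" %in% names(df)) as.character(df$synonyms) else ""
  df$hpo_id <- if ("hpo_id" %in% names(df)) as.character(df$hpo_id) else NA_character_
  df$hpo_id[!nzchar(df$hpo_id) | is.na(df$hpo_id)] <- NA_character_
  df[, c("id", "name", "synonyms", "hpo_id")]
}

#' Build the filtered phenotype lexicon
#'
#' Applies the two-layer filter to parsed concept rows: (1) keep only rows
#' from the admitted source vocabularies (HPO, OMIM, DDB, SNOMED-CT US, MSH);
#' (2) for non-HPO sources keep only concepts whose semantic types intersect
#' the include set, while HPO keeps every concept not typed with an excluded
#' code. ASDPTO terms are appended as their own source with no semantic-type
#' filter. Synonyms sharing a concept id within one source are grouped under
#' one concept; the preferred name is the term-type-preferred row (`PT`/`PN`)
#' when present, otherwise the first row encountered.
#'
#' @param rows Concept rows from [parse_concept_file()].
#' @param semtype_map Semantic-type map from [parse_semantic_types()].
#' @param filter A [semantic_type_filter()].
#' @param asdpto Optional ASDPTO data frame from [load_asdpto_terms()].
#' @return An object of class `phenotype_lexicon`: a data frame with one row
#'   per (concept_id, source) holding `concept_id`, `source`, `preferred_name`,
#'   `hpo_id`, and list-columns `synonyms` and `semantic_types`, ordered by
#'   concept id then source.
#' @export
build_phenotype_lexicon <- function(rows, semtype_map,
                                    filter = semantic_type_filter(),
                                    asdpto = NULL) {
  keep_sources <- c("HPO", "OMIM", "DDB", "SNOMEDCT_US", "MSH")
  rows <- rows[rows$sab %in% keep_sources, , drop = FALSE]
  concepts <- list()
  if (nrow(rows) > 0L) {
    key <- paste(rows$cui, rows$sab, sep = "\r")
    dropped_nosty <- character(0)
    for (grp in split(seq_len(nrow(rows)), key)) {
      cui <- rows$cui[grp[1L]]
      sab <- rows$sab[grp[1L]]
      sty <- semtype_map[[cui]] %||% character(0)
      if (sab == "HPO") {
        if (length(intersect(sty, filter$hpo_exclude_codes)) > 0L) next
      } else {
        if (length(sty) == 0L) {
          dropped_nosty <- c(dropped_nosty, paste0(cui, "/", sab))
          next
        }
        if (length(intersect(sty, filter$include_codes)) == 0L) next
      }
      tty <- rows$tty[grp]
      pref_i <- grp[match(TRUE, tty %in% c("PT", "PN"))]
      if (is.na(pref_i)) pref_i <- grp[1L]
      syns <- unique(rows$str[grp])
      hpo_id <- NA_character_
      if (sab == "HPO") {
        code <- rows$code[grp]
        code <- code[grepl("^HP:", code)]
        if (length(code) > 0L) hpo_id <- code[1L]
      }
      concepts[[length(concepts) + 1L]] <- list(
        concept_id = cui, source = sab,
        preferred_name = rows$str[pref_i],
        hpo_id = hpo_id, synonyms = syns, semantic_types = sty)
    }
    if (length(dropped_nosty) > 0L)
      message(sprintf("excluded %d non-HPO concept(s) with no semantic-type entry: %s",
                      length(dropped_nosty),
                      paste(utils::head(dropped_nosty, 5L), collapse = ", ")))
  }
  if (!is.null(asdpto) && nrow(asdpto) > 0L) {
    for (i in seq_len(nrow(asdpto))) {
      syns <- unique(c(asdpto$name[i],
                       Filter(nzchar, stringi::stri_split_fixed(
                         asdpto$synonyms[i] %||% "", "|")[[1]])))
      concepts[[length(concepts) + 1L]] <- list(
        concept_id = asdpto$id[i], source = "ASDPTO",
        preferred_name = asdpto$name[i],
        hpo_id = asdpto$hpo_id[i], synonyms = syns,
        semantic_types = character(0))
    }
  }
  if (length(concepts) == 0L) {
    lex <- empty_df(concept_id = "character", source = "character",
                    preferred_name = "character", hpo_id = "character")
    lex$synonyms <- list()
    lex$semantic_types <- list()
  } else {
    lex <- data.frame(
      concept_id = vapply(concepts, `[[`, character(1), "concept_id"),
      source = vapply(concepts, `[[`, character(1), "source"),
      preferred_name = vapply(concepts, `[[`, character(1), "preferred_name"),
      hpo_id = vapply(concepts, `[[`, character(1), "hpo_id"),
      stringsAsFactors = FALSE)
    lex$synonyms <- lapply(concepts, `[[`, "synonyms")
    lex$semantic_types <- lapply(concepts, `[[`, "semantic_types")
    ord <- order(lex$concept_id, lex$source)
    lex <- lex[ord, , drop = FALSE]
    rownames(lex) <- NULL
  }
  # synonyms always include the preferred name
  lex$synonyms <- lapply(seq_len(nrow(lex)), function(i)
    unique(c(lex$preferred_name[i], lex$synonyms[[i]])))
  structure(lex, class = c("phenotype_lexicon", "data.frame"))
}

#' @export
print.phenotype_lexicon <- function(x, ...) {
  cat(sprintf("<phenotype_lexicon> %d concept(s) from %d source(s)\n",
              nrow(x), length(unique(x$source))))
  if (nrow(x) > 0L) print(table(source = x$source))
  invisible(x)
}

#' Load a gene list
#'
#' Reads a gene list with one symbol per row and an optional risk-class
#' column (values `1`, `2`, `3`, `S`; anything else maps to `NA` with a
#' warning). Tab- and comma-separated files are both accepted. Exact
#' duplicate rows collapse silently; the same symbol listed with two
#' different classes is a fatal inconsistency.
#'
#' @param path Path to the gene list file.
#' @return An object of class `gene_lexicon`: data frame with columns
#'   `symbol` and `risk_class`.
#' @export
load_gene_list <- function(path) {
  if (!file.exists(path)) gp_stop("gene list not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sep <- if (any(grepl("\t", lines))) "\t" else ","
  parts <- stringi::stri_split_fixed(lines, sep)
  symbol <- trimws(vapply(parts, `[`, character(1), 1L))
  cls <- trimws(vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "", character(1)))
  if (length(symbol) > 0L && symbol[1L] %in% c("symbol", "gene", "Gene")) {
    symbol <- symbol[-1L]; cls <- cls[-1L]
  }
  keep <- nzchar(symbol)
  symbol <- symbol[keep]; cls <- cls[keep]
  bad <- nzchar(cls) & !(cls %in% c("1", "2", "3", "S"))
  if (any(bad)) {
    gp_warn("unknown risk class value(s) mapped to NA: %s",
            paste(unique(cls[bad]), collapse = ", "))
    cls[bad] <- ""
  }
  cls[!nzchar(cls)] <- NA_character_
  df <- unique(data.frame(symbol = symbol, risk_class = cls,
                          stringsAsFactors = FALSE))
  dup <- df$symbol[duplicated(df$symbol)]
  if (length(dup) > 0L) {
    conf <- df[df$symbol %in% dup, ]
    gp_stop("duplicate gene symbol(s) with conflicting classes:\n%s",
            paste(sprintf("  %s -> %s", conf$symbol, conf$risk_class),
                  collapse = "\n"))
  }
  rownames(df) <- NULL
  structure(df, class = c("gene_lexicon", "data.frame"))
}

#' Serialize a phenotype and gene lexicon to JSON
#'
#' @param phenotypes A `phenotype_lexicon`.
#' @param genes A `gene_lexicon` (optional).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(phenotypes, path, genes = NULL) {
  obj <- list(
    phenotypes = lapply(seq_len(nrow(phenotypes)), function(i) list(
      concept_id = phenotypes$concept_id[i],
      source = phenotypes$source[i],
      preferred_name = phenotypes$preferred_name[i],
      hpo_id = phenotypes$hpo_id[i],
      synonyms = as.list(phenotypes$synonyms[[i]]),
      semantic_types = as.list(phenotypes$semantic_types[[i]]))),
    genes = if (!is.null(genes)) lapply(seq_len(nrow(genes)), function(i) list(
      symbol = genes$symbol[i], risk_class = genes$risk_class[i])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a lexicon serialized by [write_lexicon()]
#'
#' @param path JSON path.
#' @return List with elements `phenotypes` (`phenotype_lexicon`) and `genes`
#'   (`gene_lexicon` or `NULL`).
#' @export
read_lexicon <- function(path) {
  obj <- jsonlite::read_json(path)
  ph <- obj$phenotypes
  if (length(ph) == 0L) {
    lex <- build_phenotype_lexicon(
      empty_df(cui = "character", sab = "character", tty = "character",
               code = "character", str = "character"),
      structure(list(), names = character(0)))
  } else {
    lex <- data.frame(
      concept_id = vapply(ph, function(p) p$concept_id, character(1)),
      source = vapply(ph, function(p) p$source, character(1)),
      preferred_name = vapply(ph, function(p) p$preferred_name, character(1)),
      hpo_id = vapply(ph, function(p) p$hpo_id %||% NA_character_, character(1)),
      stringsAsFactors = FALSE)
    lex$synonyms <- lapply(ph, function(p) unlist(p$synonyms) %||% character(0))
    lex$semantic_types <- lapply(ph, function(p)
      as.character(unlist(p$semantic_types) %||% character(0)))
    lex <- structure(lex, class = c("phenotype_lexicon", "data.frame"))
  }
  genes <- NULL
  if (length(obj$genes) > 0L) {
    genes <- data.frame(
      symbol = vapply(obj$genes, function(g) g$symbol, character(1)),
      risk_class = vapply(obj$genes, function(g) g$risk_class %||% NA_character_,
                          character(1)),
      stringsAsFactors = FALSE)
    genes <- structure(genes, class = c("gene_lexicon", "data.frame"))
  }
  list(phenotypes = lex, genes = genes)
}
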