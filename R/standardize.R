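# Phenotype standardization: source-priority resolution of mention
# candidates and top-level phenotypic category assignment via the HPO is-a
# hierarchy.

#' Top-level phenotypic category table
#'
#' The 23 top-level categories of phenotypic abnormality used to label
#' standardized phenotypes, each anchored to the HPO id of the corresponding
#' child of "Phenotypic abnormality" (HP:0000118). Roots are configured by
#' HPO id, not by label matching, so ontology label edits do not break the
#' mapping.
#'
#' @return Data frame with columns `category` and `hpo_id`, 23 rows.
#' @export
hpo_category_table <- function() {
  data.frame(
    category = c(
      "Abnormal cellular phenotype",
      "Abnormality of blood and blood-forming tissues",
      "Abnormality of head or neck",
      "Abnormality of limbs",
      "Abnormality of metabolism/homeostasis",
      "Abnormality of prenatal development or birth",
      "Abnormality of the breast",
      "Abnormality of the cardiovascular system",
      "Abnormality of the digestive system",
      "Abnormality of the ear",
      "Abnormality of the endocrine system",
      "Abnormality of the eye",
      "Abnormality of the genitourinary system",
      "Abnormality of the immune system",
      "Abnormality of the integument",
      "Abnormality of the musculoskeletal system",
      "Abnormality of the nervous system",
      "Abnormality of the respiratory system",
      "Abnormality of the thoracic cavity",
      "Abnormality of the voice",
      "Constitutional symptom",
      "Growth abnormality",
      "Neoplasm"),
    hpo_id = c(
      "HP:0025354", "HP:0001871", "HP:0000152", "HP:0040064", "HP:0001939",
      "HP:0001197", "HP:0000769", "HP:0001626", "HP:0025031", "HP:0000598",
      "HP:0000818", "HP:0000478", "HP:0000119", "HP:0002715", "HP:0001574",
      "HP:0033127", "HP:0000707", "HP:0002086", "HP:0045027", "HP:0001608",
      "HP:0025142", "HP:0001507", "HP:0002664"),
    stringsAsFactors = FALSE)
}

#' Read a minimal OBO-dialect HPO hierarchy
#'
#' Parses `[Term]` stanzas with `id:`, `name:` and `is_a:` lines into an
#' is-a DAG. Relationship types other than is_a are out of scope; the
#' dialect is small enough that fixtures are hand-writable.
#'
#' @param path Path to the OBO-like flat file.
#' @return An object of class `hpo_hierarchy`: list with `nodes` (data frame
#'   `id`, `name`) and `parents` (named list id -> character vector of
#'   parent ids).
#' @export
read_hpo_obo <- function(path) {
  if (!file.exists(path)) gp_stop("HPO file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  ids <- character(0); names_ <- character(0)
  parents <- list()
  cur_id <- NA_character_
  for (line in lines) {
    line <- trimws(line)
    if (line == "[Term]") {
      cur_id <- NA_character_
    } else if (startsWith(line, "id:")) {
      cur_id <- trimws(substring(line, 4L))
      ids <- c(ids, cur_id)
      names_ <- c(names_, "")
      parents[[cur_id]] <- character(0)
    } else if (startsWith(line, "name:") && !is.na(cur_id)) {
      names_[length(names_)] <- trimws(substring(line, 6L))
    } else if (startsWith(line, "is_a:") && !is.na(cur_id)) {
      p <- trimws(substring(line, 6L))
      p <- trimws(sub("!.*$", "", p))
      parents[[cur_id]] <- c(parents[[cur_id]], p)
    }
  }
  h <- structure(list(nodes = data.frame(id = ids, name = names_,
                                         stringsAsFactors = FALSE),
                      parents = parents),
                 class = "hpo_hierarchy")
  assert_acyclic(h)
  h
}

#' @noRd
assert_acyclic <- function(hierarchy) {
  color <- new.env(parent = emptyenv())
  visit <- function(id) {
    st <- get0(id, envir = color, ifnotfound = 0L)
    if (st == 1L) gp_stop("cycle detected in is-a hierarchy at %s", id)
    if (st == 2L) return(invisible())
    assign(id, 1L, envir = color)
    for (p in hierarchy$parents[[id]] %||% character(0)) visit(p)
    assign(id, 2L, envir = color)
  }
  for (id in hierarchy$nodes$id) visit(id)
  invisible(hierarchy)
}

#' Assign the top-level phenotypic category of an HPO term
#'
#' Breadth-first ancestor traversal from `hpo_id` over is-a edges. The
#' category whose root is reached first (shortest path) wins; among roots at
#' equal depth the one earlier in the category table wins. Terms absent from
#' the hierarchy, or from which no category root is reachable, map to
#' `"NA"`.
#'
#' @param hpo_id HPO identifier (or `NA`).
#' @param hierarchy An `hpo_hierarchy`.
#' @param table Category table (defaults to [hpo_category_table()]).
#' @return Category name, or the string `"NA"`.
#' @export
top_level_category <- function(hpo_id, hierarchy,
                               table = hpo_category_table()) {
  if (is.na(hpo_id) || !nzchar(hpo_id)) return("NA")
  if (!(hpo_id %in% names(hierarchy$parents))) {
    gp_warn("unknown HPO id: %s", hpo_id)
    return("NA")
  }
  frontier <- hpo_id
  seen <- character(0)
  while (length(frontier) > 0L) {
    hit <- match(table$hpo_id, frontier)
    if (any(!is.na(hit))) return(table$category[which(!is.na(hit))[1L]])
    seen <- c(seen, frontier)
    nxt <- unique(unlist(hierarchy$parents[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
  }
  "NA"
}

#' Resolve mention candidates to one standardized phenotype
#'
#' Among the candidate concepts of a mention, the concept whose source
#' vocabulary has the best (lowest) priority rank wins; ties at equal rank
#' break by lexicographic concept id, making resolution a total order
#' invariant under candidate permutation.
#'
#' @param candidates Data frame with columns `concept_id`, `source`.
#' @param lexicon A `phenotype_lexicon` supplying preferred names/HPO ids.
#' @return One-row data frame: `concept_id`, `preferred_name`, `source`,
#'   `hpo_id`.
#' @export
standardize_mention <- function(candidates, lexicon) {
  if (is.null(candidates) || nrow(candidates) == 0L)
    gp_stop("mention has no candidate concepts (mentions module contract)")
  rank <- source_priority()[candidates$source]
  ord <- order(rank, candidates$concept_id)
  win <- candidates[ord[1L], ]
  i <- which(lexicon$concept_id == win$concept_id &
               lexicon$source == win$source)[1L]
  if (is.na(i)) gp_stop("candidate %s/%s not in lexicon",
                        win$concept_id, win$source)
  data.frame(concept_id = lexicon$concept_id[i],
             preferred_name = lexicon$preferred_name[i],
             source = lexicon$source[i],
             hpo_id = lexicon$hpo_id[i],
             stringsAsFactors = FALSE)
}

#' Standardize every phenotype mention in a mined corpus
#'
#' Replaces each phenotype mention with exactly one standardized phenotype
#' (priority resolution) and assigns its top-level phenotypic category.
#' Concepts without an HPO id (including ASDPTO terms lacking an explicit
#' HPO cross-reference) receive category `"NA"`.
#'
#' @param mentions A `mention_set` from [mine_corpus()].
#' @param lexicon A `phenotype_lexicon`.
#' @param hierarchy An `hpo_hierarchy`, or `NULL` to skip categories.
#' @param table Category table.
#' @return Data frame of standardized mentions: `article_id`,
#'   `sentence_index`, `surface`, `start`, `end`, `concept_id`,
#'   `preferred_name`, `source`, `hpo_id`, `category`; the per-source count
#'   of distinct standardized concepts is attached as attribute
#'   `source_counts`.
#' @export
standardize_corpus <- function(mentions, lexicon, hierarchy = NULL,
                               table = hpo_category_table()) {
  pm <- mentions$phenotype_mentions
  out <- empty_df(article_id = "character", sentence_index = "integer",
                  surface = "character", start = "integer", end = "integer",
                  concept_id = "character", preferred_name = "character",
                  source = "character", hpo_id = "character",
                  category = "character")
  if (nrow(pm) == 0L) {
    attr(out, "source_counts") <- integer(0)
    return(out)
  }
  std <- do.call(rbind, lapply(pm$candidates, standardize_mention,
                               lexicon = lexicon))
  category <- rep("NA", nrow(std))
  if (!is.null(hierarchy)) {
    uniq <- unique(std$hpo_id[!is.na(std$hpo_id)])
    cat_map <- vapply(uniq, top_level_category, character(1),
                      hierarchy = hierarchy, table = table)
    hit <- match(std$hpo_id, uniq)
    category[!is.na(hit)] <- cat_map[hit[!is.na(hit)]]
  }
  out <- data.frame(article_id = pm$article_id,
                    sentence_index = pm$sentence_index,
                    surface = pm$surface, start = pm$start, end = pm$end,
                    concept_id = std$concept_id,
                    preferred_name = std$preferred_name,
                    source = std$source, hpo_id = std$hpo_id,
                    category = category, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  uniq_concepts <- unique(out[c("concept_id", "source")])
  attr(out, "source_counts") <-
    vapply(split(uniq_concepts$concept_id, uniq_concepts$source),
           function(x) length(unique(x)), integer(1))
  out
}
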