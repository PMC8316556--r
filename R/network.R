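# Phenotype-sharing genetic interaction network: edge construction from
# qualifying shared phenotypes, betweenness-centrality ranking, top-fraction
# selection, and keyword-filtered sub-networks.

#' Global average NPMI threshold
#'
#' Arithmetic mean of NPMI over all retained (finite) association records,
#' used as the qualification threshold when building the interaction graph.
#' A flag restricts the mean to positive-NPMI records.
#'
#' @param records Association record table.
#' @param positive_only Average over records with NPMI > 0 only.
#' @return The mean NPMI.
#' @export
global_average_npmi <- function(records, positive_only = FALSE) {
  v <- records$npmi[is.finite(records$npmi)]
  if (positive_only) v <- v[v > 0]
  if (length(v) == 0L) gp_stop("no association records to average")
  mean(v)
}

#' Build the phenotype-sharing interaction graph
#'
#' A phenotype links two genes when both of their associations with it have
#' NPMI at or above the threshold. Parallel links between the same gene pair
#' are compressed into one undirected edge whose weight is the number of
#' shared qualifying phenotypes. No self-loops; every edge has weight >= 1.
#'
#' @param records Association record table.
#' @param threshold NPMI qualification threshold (defaults to
#'   [global_average_npmi()] of `records`).
#' @param genes Optional node set restriction (e.g. SFARI genes); nodes with
#'   no qualifying shared phenotype remain as isolated vertices. `NULL`
#'   uses every gene appearing in a qualifying record.
#' @param gene_lexicon Optional `gene_lexicon`; risk classes are attached as
#'   a vertex attribute.
#' @return An `igraph` undirected graph with edge attribute `weight`.
#' @export
build_graph <- function(records, threshold = global_average_npmi(records),
                        genes = NULL, gene_lexicon = NULL) {
  qual <- records[records$npmi >= threshold, , drop = FALSE]
  if (!is.null(genes)) qual <- qual[qual$gene %in% genes, , drop = FALSE]
  pair_key <- character(0)
  if (nrow(qual) > 0L) {
    for (grp in split(qual$gene, qual$concept_id)) {
      gs <- sort(unique(grp))
      if (length(gs) < 2L) next
      cmb <- utils::combn(gs, 2L)
      pair_key <- c(pair_key, paste(cmb[1L, ], cmb[2L, ], sep = "\r"))
    }
  }
  nodes <- sort(unique(if (is.null(genes)) qual$gene else genes))
  if (length(pair_key) > 0L) {
    w <- table(pair_key)
    parts <- stringi::stri_split_fixed(names(w), "\r")
    edges <- data.frame(from = vapply(parts, `[`, character(1), 1L),
                        to = vapply(parts, `[`, character(1), 2L),
                        weight = as.numeric(w), stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  } else {
    edges <- empty_df(from = "character", to = "character",
                      weight = "numeric")
  }
  vertices <- data.frame(name = nodes, stringsAsFactors = FALSE)
  if (!is.null(gene_lexicon)) {
    rc <- gene_lexicon$risk_class[match(nodes, gene_lexicon$symbol)]
    rc[is.na(rc)] <- "NA"
    vertices$risk_class <- rc
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Betweenness centrality of the interaction graph
#'
#' Raw (unnormalized) betweenness: for each node v, the sum over unordered
#' node pairs s != v != t of the fraction of shortest s-t paths passing
#' through v; disconnected pairs contribute 0. In weighted mode the edge
#' length is `1/weight` by default, so a higher shared-phenotype count means
#' a shorter distance; `distance = "weight"` switches to using the weight
#' itself as the length.
#'
#' @param graph Graph from [build_graph()].
#' @param weighted Use weighted shortest paths (default `TRUE`).
#' @param distance How edge weight maps to path length in weighted mode.
#' @return Named numeric vector of betweenness scores per gene.
#' @export
betweenness_centrality <- function(graph, weighted = TRUE,
                                   distance = c("inverse_weight", "weight")) {
  distance <- match.arg(distance)
  w <- if (!weighted || igraph::ecount(graph) == 0L) {
    NA
  } else {
    ew <- igraph::E(graph)$weight
    if (distance == "inverse_weight") 1 / ew else ew
  }
  scores <- igraph::betweenness(graph, directed = FALSE,
                                weights = if (identical(w, NA)) NA else w,
                                normalized = FALSE)
  stats::setNames(as.numeric(scores), igraph::V(graph)$name)
}

#' Select the top fraction of genes by centrality
#'
#' `ceiling(fraction * n)` genes in descending score order; ties at the cut
#' break by symbol order and are reported in the `ties_at_cut` attribute.
#'
#' @param scores Named score vector from [betweenness_centrality()].
#' @param fraction Fraction to select (default 0.10).
#' @return Character vector of selected gene symbols.
#' @export
top_fraction <- function(scores, fraction = 0.10) {
  if (length(scores) == 0L) return(character(0))
  n_sel <- min(length(scores), as.integer(ceiling(fraction * length(scores))))
  ord <- order(-scores, names(scores))
  sel <- names(scores)[ord[seq_len(n_sel)]]
  ties <- character(0)
  if (n_sel > 0L && n_sel < length(scores)) {
    cut_score <- scores[ord[n_sel]]
    left_out <- scores[ord[(n_sel + 1L):length(scores)]]
    if (any(left_out == cut_score))
      ties <- sort(names(scores)[scores == cut_score])
  }
  attr(sel, "ties_at_cut") <- ties
  sel
}

#' Keyword-filtered phenotype sub-network
#'
#' Case-insensitive keyword filter on standardized preferred names; returns
#' the matching records and the induced phenotype-sharing sub-graph over the
#' genes linked by the matching phenotypes.
#'
#' @param records Association record table.
#' @param keywords Non-empty character vector of keywords.
#' @param threshold NPMI qualification threshold for the induced graph
#'   (defaults to the global average over the full `records`).
#' @return List with `records` (matching rows) and `graph` (induced
#'   interaction graph).
#' @export
subset_by_phenotype_keyword <- function(records, keywords,
                                        threshold = global_average_npmi(records)) {
  if (length(keywords) == 0L) gp_stop("keywords must be non-empty")
  pat <- paste(vapply(keywords, function(k)
    stringi::stri_replace_all_regex(k, "([\\\\.^$|()\\[\\]{}*+?])", "\\\\$1"),
    character(1)), collapse = "|")
  hit <- stringi::stri_detect_regex(records$preferred_name, pat,
                                    case_insensitive = TRUE)
  sub <- records[hit, , drop = FALSE]
  rownames(sub) <- NULL
  if (nrow(sub) == 0L) {
    gp_warn("no phenotype matched keyword(s): %s",
            paste(keywords, collapse = ", "))
    return(list(records = sub,
                graph = igraph::make_empty_graph(0, directed = FALSE)))
  }
  list(records = sub, graph = build_graph(sub, threshold = threshold))
}
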