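# End-to-end pipeline orchestration: lexicon build, sentence segmentation,
# mention mining, standardization, NPMI scoring, optional clustering and
# network stages, optional evaluation; run manifest with config echo.

#' Assemble a pipeline run configuration
#'
#' Every effective parameter is echoed into the run manifest; there are no
#' hidden defaults.
#'
#' @param concepts,semtypes,asdpto,genes,corpus Input paths (vocabulary
#'   files, gene list, corpus directory).
#' @param hpo Path to the OBO-dialect hierarchy (optional; categories become
#'   "NA" without it).
#' @param gold Optional gold JSONL for evaluation.
#' @param reference Optional reference association TSV (`gene`,
#'   `phenotype_id`).
#' @param out Output directory.
#' @param npmi_min,count_min Association filter thresholds.
#' @param k Number of k-means clusters; `NULL` skips the clustering stage
#'   (no default is inherited from any publication; choose per corpus).
#' @param seed Seed for embedding/clustering.
#' @param perplexity t-SNE perplexity (`NULL` = auto).
#' @param top_fraction Fraction of genes selected by centrality.
#' @param weighted Use weighted shortest paths in the network stage.
#' @param edge_threshold `"global_mean"` or a numeric NPMI threshold.
#' @param case_sensitive Case-sensitive gene matching.
#' @return A `run_config` list.
#' @export
run_config <- function(concepts, semtypes, asdpto, genes, corpus, out,
                       hpo = NULL, gold = NULL, reference = NULL,
                       npmi_min = 0, count_min = 5, k = NULL, seed = 42L,
                       perplexity = NULL, top_fraction = 0.10,
                       weighted = TRUE, edge_threshold = "global_mean",
                       case_sensitive = TRUE) {
  structure(list(concepts = concepts, semtypes = semtypes, asdpto = asdpto,
                 genes = genes, corpus = corpus, out = out, hpo = hpo,
                 gold = gold, reference = reference, npmi_min = npmi_min,
                 count_min = count_min, k = k, seed = seed,
                 perplexity = perplexity, top_fraction = top_fraction,
                 weighted = weighted, edge_threshold = edge_threshold,
                 case_sensitive = case_sensitive),
            class = "run_config")
}

#' Run the full mining pipeline
#'
#' Stages run in dependency order: lexicon, sentencize, mine, standardize,
#' score, then the optional cluster, network and evaluate stages. Each stage
#' writes its outputs under `config$out`; a JSON manifest echoes the full
#' configuration and package version.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results (`lexicon`,
#'   `sentences`, `mentions`, `standardized`, `records`, `filtered`, and
#'   when enabled `matrix`, `coords`, `clusters`, `concordance`, `graph`,
#'   `centrality`, `selection`, `evaluation`).
#' @export
run_pipeline <- function(config) {
  out <- config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  res <- list()

  # lexicon
  rows <- parse_concept_file(config$concepts)
  sem <- parse_semantic_types(config$semtypes)
  asd <- load_asdpto_terms(config$asdpto)
  lex <- build_phenotype_lexicon(rows, sem, asdpto = asd)
  gene_lex <- load_gene_list(config$genes)
  write_lexicon(lex, file.path(out, "lexicon.json"), genes = gene_lex)
  res$lexicon <- lex; res$genes <- gene_lex

  # sentencize
  articles <- read_corpus(config$corpus)
  sentences <- corpus_sentences(articles)
  write_tsv_plain(sentences, file.path(out, "sentences.tsv"))
  res$sentences <- sentences

  # mine
  idx <- phenotype_index(lex)
  mentions <- mine_corpus(sentences, gene_lex, idx,
                          case_sensitive = config$case_sensitive)
  gm <- mentions$gene_mentions
  gm_out <- data.frame(article_id = gm$article_id,
                       sentence_index = gm$sentence_index, kind = "gene",
                       surface = gm$surface, span_start = gm$start,
                       span_end = gm$end, lexicon_ref = gm$symbol,
                       stringsAsFactors = FALSE)
  res$mentions <- mentions

  # standardize
  hierarchy <- if (!is.null(config$hpo)) read_hpo_obo(config$hpo) else NULL
  std <- standardize_corpus(mentions, lex, hierarchy)
  pm_out <- data.frame(article_id = std$article_id,
                       sentence_index = std$sentence_index,
                       kind = "phenotype", surface = std$surface,
                       span_start = std$start, span_end = std$end,
                       lexicon_ref = std$concept_id, stringsAsFactors = FALSE)
  write_tsv_plain(rbind(gm_out, pm_out), file.path(out, "mentions.tsv"))
  write_tsv_plain(std, file.path(out, "standardized_mentions.tsv"))
  res$standardized <- std

  # score
  counts <- count_occurrences(mentions, std)
  records <- build_associations(counts, std)
  filtered <- filter_associations(records, config$npmi_min, config$count_min)
  write_tsv_plain(records, file.path(out, "associations.tsv"))
  write_tsv_plain(filtered, file.path(out, "associations_filtered.tsv"))
  res$counts <- counts; res$records <- records; res$filtered <- filtered

  # cluster (optional)
  if (!is.null(config$k) && length(unique(records$gene)) >= 3L) {
    m <- build_matrix(records)
    coords <- embed_2d(m, seed = config$seed,
                       perplexity = config$perplexity)
    clusters <- kmeans_cluster(coords, k = config$k, seed = config$seed)
    labels <- label_by_top_category(records)
    common <- intersect(names(clusters), names(labels))
    conc <- if (length(common) >= 2L)
      concordance_scores(clusters[common], labels[common]) else NULL
    coords_df <- data.frame(gene = rownames(coords), coords,
                            stringsAsFactors = FALSE)
    write_tsv_plain(coords_df, file.path(out, "tsne_coordinates.tsv"))
    write_tsv_plain(data.frame(gene = names(clusters),
                               cluster = as.integer(clusters),
                               stringsAsFactors = FALSE),
                    file.path(out, "cluster_labels.tsv"))
    if (!is.null(conc))
      jsonlite::write_json(conc, file.path(out, "concordance.json"),
                           auto_unbox = TRUE, digits = NA)
    res$matrix <- m; res$coords <- coords; res$clusters <- clusters
    res$labels <- labels; res$concordance <- conc
  }

  # network
  if (nrow(records) > 0L) {
    thr <- if (identical(config$edge_threshold, "global_mean"))
      global_average_npmi(records) else as.numeric(config$edge_threshold)
    graph <- build_graph(records, threshold = thr, gene_lexicon = gene_lex)
    cb <- betweenness_centrality(graph, weighted = config$weighted)
    sel <- top_fraction(cb, config$top_fraction)
    el <- igraph::as_data_frame(graph, what = "edges")
    names(el)[1:2] <- c("gene1", "gene2")
    write_tsv_plain(el, file.path(out, "network_edges.tsv"))
    write_tsv_plain(data.frame(gene = names(cb), betweenness = as.numeric(cb),
                               stringsAsFactors = FALSE),
                    file.path(out, "centrality.tsv"))
    sel_df <- data.frame(gene = sel, stringsAsFactors = FALSE)
    sel_df$risk_class <- gene_lex$risk_class[match(sel, gene_lex$symbol)]
    write_tsv_plain(sel_df, file.path(out, "top_genes.tsv"))
    res$graph <- graph; res$centrality <- cb; res$selection <- sel
    res$edge_threshold <- thr
  }

  # evaluate (optional)
  if (!is.null(config$gold)) {
    gold <- read_gold_jsonl(config$gold)
    ev <- evaluate_pipeline(mentions, std, gold)
    pr <- do.call(rbind, lapply(ev, function(x) data.frame(
      level = x$level, benchmark = x$benchmark, tp = x$tp, fp = x$fp,
      fn = x$fn, precision_pct = round(100 * x$precision, 1),
      recall_pct = round(100 * x$recall, 1), stringsAsFactors = FALSE)))
    write_tsv_plain(pr, file.path(out, "evaluation_pr.tsv"))
    res$evaluation <- ev
    if (!is.null(config$reference)) {
      ref <- read_tsv_plain(config$reference)
      tpr <- reference_tp_rate(records, ref, gene_lex)
      write_tsv_plain(tpr, file.path(out, "reference_tp_rates.tsv"))
      res$reference_tp <- tpr
    }
  }

  manifest <- c(unclass(config),
                list(package_version =
                       as.character(utils::packageVersion("genepheno")),
                     r_version = as.character(getRversion())))
  manifest <- manifest[!vapply(manifest, is.null, logical(1))]
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
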