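# Association scoring: sentence-level occurrence counting, normalized
# pointwise mutual information (NPMI), filtering, and ranking.

#' Count sentence-level occurrences and co-occurrences
#'
#' A sentence contributes at most one count to each gene, each standardized
#' phenotype concept, and each (gene, concept) pair it mentions, however many
#' times the mention repeats. `n_tot` counts every sentence the corpus
#' reader emitted, not only target sentences.
#'
#' @param mentions A `mention_set` from [mine_corpus()] (supplies gene
#'   mentions and the total sentence count).
#' @param standardized Standardized mention table from
#'   [standardize_corpus()].
#' @return An object of class `corpus_counts`: list with `n_tot`, named
#'   vectors `n_G`, `n_P`, `papers_G`, and a data frame `pairs`
#'   (`gene`, `concept_id`, `n_GP`).
#' @export
count_occurrences <- function(mentions, standardized) {
  n_tot <- mentions$n_sentences
  gm <- mentions$gene_mentions
  skey <- function(a, i) paste(a, i, sep = "\r")
  g_sent <- unique(data.frame(s = skey(gm$article_id, gm$sentence_index),
                              article = gm$article_id, gene = gm$symbol,
                              stringsAsFactors = FALSE))
  p_sent <- unique(data.frame(s = skey(standardized$article_id,
                                       standardized$sentence_index),
                              concept_id = standardized$concept_id,
                              stringsAsFactors = FALSE))
  n_G <- if (nrow(g_sent) > 0L) {
    v <- table(g_sent$gene); stats::setNames(as.integer(v), names(v))
  } else stats::setNames(integer(0), character(0))
  papers_G <- if (nrow(g_sent) > 0L) {
    u <- unique(g_sent[c("article", "gene")])
    v <- table(u$gene); stats::setNames(as.integer(v), names(v))
  } else stats::setNames(integer(0), character(0))
  n_P <- if (nrow(p_sent) > 0L) {
    v <- table(p_sent$concept_id); stats::setNames(as.integer(v), names(v))
  } else stats::setNames(integer(0), character(0))
  pairs <- empty_df(gene = "character", concept_id = "character",
                    n_GP = "integer")
  if (nrow(g_sent) > 0L && nrow(p_sent) > 0L) {
    j <- merge(g_sent[c("s", "gene")], p_sent, by = "s")
    if (nrow(j) > 0L) {
      agg <- stats::aggregate(list(n_GP = j$s),
                              by = list(gene = j$gene,
                                        concept_id = j$concept_id),
                              FUN = function(x) length(unique(x)))
      agg$n_GP <- as.integer(agg$n_GP)
      pairs <- agg[order(agg$gene, agg$concept_id), , drop = FALSE]
      rownames(pairs) <- NULL
    }
  }
  counts <- structure(list(n_tot = n_tot, n_G = n_G, n_P = n_P,
                           papers_G = papers_G, pairs = pairs),
                      class = "corpus_counts")
  validate_counts(counts)
  counts
}

#' @noRd
validate_counts <- function(counts) {
  p <- counts$pairs
  if (nrow(p) == 0L) return(invisible(counts))
  ng <- counts$n_G[p$gene]
  np <- counts$n_P[p$concept_id]
  if (any(is.na(ng)) || any(is.na(np)) ||
      any(p$n_GP > pmin(ng, np)) || any(pmin(ng, np) > counts$n_tot))
    gp_stop("count corruption: n_GP must be <= min(n_G, n_P) <= n_tot")
  invisible(counts)
}

#' Normalized pointwise mutual information of a gene-phenotype pair
#'
#' \deqn{NPMI(G,P) = \ln\!\frac{n_{GP}\, n_{tot}}{n_G\, n_P} \Big/
#'   \left(-\ln \frac{n_{GP}}{n_{tot}}\right)}
#'
#' computed with natural logarithms and clamped to \[-1, 1\] against
#' rounding. Boundary conventions are the analytic limits: `n_GP = 0` gives
#' -1 (terms never co-occur) and `n_GP = n_tot` gives 1. A pair that
#' co-occurs in every sentence mentioning either term
#' (`n_GP = n_G = n_P`) scores exactly 1; statistically independent terms
#' (`n_GP / n_tot = (n_G/n_tot)(n_P/n_tot)`) score exactly 0.
#'
#' @param n_G,n_P Sentence counts for the gene and the phenotype.
#' @param n_GP Co-occurrence sentence count.
#' @param n_tot Total sentence count; must be positive.
#' @return NPMI value(s) in \[-1, 1\]; vectorized over the count arguments.
#' @export
#' @examples
#' npmi(10, 10, 10, 100)   # always together -> 1
#' npmi(20, 10, 2, 100)    # independent -> 0
#' npmi(10, 10, 0, 100)    # never together -> -1
npmi <- function(n_G, n_P, n_GP, n_tot) {
  k <- max(length(n_G), length(n_P), length(n_GP), length(n_tot))
  n_G <- rep_len(as.numeric(n_G), k); n_P <- rep_len(as.numeric(n_P), k)
  n_GP <- rep_len(as.numeric(n_GP), k); n_tot <- rep_len(as.numeric(n_tot), k)
  if (any(n_tot <= 0)) gp_stop("n_tot must be positive")
  if (any(n_GP < 0) || any(n_G < 0) || any(n_P < 0))
    gp_stop("counts must be non-negative")
  if (any(n_GP > pmin(n_G, n_P)))
    gp_stop("count corruption: n_GP exceeds min(n_G, n_P)")
  out <- numeric(k)
  zero <- n_GP == 0
  full <- n_GP == n_tot
  mid <- !zero & !full
  out[zero] <- -1
  out[full] <- 1
  if (any(mid)) {
    val <- log((n_GP[mid] * n_tot[mid]) / (n_G[mid] * n_P[mid])) /
      (-log(n_GP[mid] / n_tot[mid]))
    out[mid] <- pmin(1, pmax(-1, val))
  }
  out
}

#' Build the association record table
#'
#' One record per observed (gene, standardized phenotype) pair, carrying the
#' counts and NPMI. Phenotype metadata (preferred name, source, HPO id,
#' category) is joined from the standardized mention table; `n_P`
#' aggregates sentences mentioning any synonym of the concept.
#'
#' @param counts A `corpus_counts`.
#' @param standardized Standardized mention table (for phenotype metadata).
#' @return Data frame of association records: `gene`, `concept_id`,
#'   `preferred_name`, `source`, `hpo_id`, `category`, `n_G`, `n_P`,
#'   `n_GP`, `n_tot`, `npmi`.
#' @export
build_associations <- function(counts, standardized) {
  p <- counts$pairs
  meta <- unique(standardized[c("concept_id", "preferred_name", "source",
                                "hpo_id", "category")])
  out <- merge(p, meta, by = "concept_id", sort = FALSE)
  if (nrow(out) == 0L) {
    out <- empty_df(gene = "character", concept_id = "character",
                    preferred_name = "character", source = "character",
                    hpo_id = "character", category = "character",
                    n_G = "integer", n_P = "integer", n_GP = "integer",
                    n_tot = "integer", npmi = "numeric")
    return(out)
  }
  out$n_G <- as.integer(counts$n_G[out$gene])
  out$n_P <- as.integer(counts$n_P[out$concept_id])
  out$n_tot <- counts$n_tot
  out$npmi <- npmi(out$n_G, out$n_P, out$n_GP, out$n_tot)
  out <- out[order(out$gene, out$concept_id),
             c("gene", "concept_id", "preferred_name", "source", "hpo_id",
               "category", "n_G", "n_P", "n_GP", "n_tot", "npmi"),
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter low-confidence associations
#'
#' Keeps records with `npmi > npmi_min` and `n_GP > count_min` (both strict,
#' both configurable; defaults NPMI > 0 and n_GP > 5).
#'
#' @param records Association record table.
#' @param npmi_min Exclusive NPMI threshold (default 0).
#' @param count_min Exclusive co-occurrence count threshold (default 5).
#' @return Filtered records.
#' @export
filter_associations <- function(records, npmi_min = 0, count_min = 5) {
  out <- records[records$npmi > npmi_min & records$n_GP > count_min, ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top phenotypes for one gene by NPMI
#'
#' Descending NPMI; ties break by `n_GP` descending then concept id
#' ascending. Returns at most `k` records; an absent gene yields an empty
#' table.
#'
#' @param records Association record table (typically pre-filtered).
#' @param gene Gene symbol.
#' @param k Maximum records to return (default 3).
#' @return Record rows for the gene, ranked.
#' @export
rank_phenotypes_for_gene <- function(records, gene, k = 3L) {
  r <- records[records$gene == gene, , drop = FALSE]
  if (nrow(r) == 0L) return(r)
  r <- r[order(-r$npmi, -r$n_GP, r$concept_id), , drop = FALSE]
  r <- utils::head(r, k)
  rownames(r) <- NULL
  r
}

#' Frequency summaries of genes and phenotypes
#'
#' Per-risk-class shares of distinct genes and of associations, the top
#' `top_n` genes by number of distinct referencing articles, and the top
#' `top_n` standardized phenotypes by mention-sentence count annotated with
#' their category.
#'
#' @param counts A `corpus_counts`.
#' @param records Association record table.
#' @param gene_lexicon A `gene_lexicon` (supplies risk classes).
#' @param top_n Size of the top lists (default 30).
#' @return List with data frames `gene_class_share` (`risk_class`,
#'   `n_genes`, `pct_genes`, `n_assoc`, `pct_assoc`), `top_genes`
#'   (`gene`, `risk_class`, `papers`), and `top_phenotypes`
#'   (`concept_id`, `preferred_name`, `category`, `n_P`).
#' @export
summarize_frequencies <- function(counts, records, gene_lexicon,
                                  top_n = 30L) {
  genes <- unique(records$gene)
  cls <- gene_lexicon$risk_class[match(genes, gene_lexicon$symbol)]
  cls[is.na(cls)] <- "NA"
  rec_cls <- gene_lexicon$risk_class[match(records$gene, gene_lexicon$symbol)]
  rec_cls[is.na(rec_cls)] <- "NA"
  levels_ <- c("1", "2", "3", "S", "NA")
  n_genes <- vapply(levels_, function(l) sum(cls == l), integer(1))
  n_assoc <- vapply(levels_, function(l) sum(rec_cls == l), integer(1))
  share <- data.frame(
    risk_class = levels_, n_genes = n_genes,
    pct_genes = if (length(genes) > 0L) 100 * n_genes / length(genes) else 0,
    n_assoc = n_assoc,
    pct_assoc = if (nrow(records) > 0L) 100 * n_assoc / nrow(records) else 0,
    stringsAsFactors = FALSE)
  pg <- counts$papers_G
  tg <- data.frame(gene = names(pg), papers = as.integer(pg),
                   stringsAsFactors = FALSE)
  tg$risk_class <- gene_lexicon$risk_class[match(tg$gene, gene_lexicon$symbol)]
  tg$risk_class[is.na(tg$risk_class)] <- "NA"
  tg <- tg[order(-tg$papers, tg$gene), c("gene", "risk_class", "papers"),
           drop = FALSE]
  tg <- utils::head(tg, top_n)
  rownames(tg) <- NULL
  meta <- unique(records[c("concept_id", "preferred_name", "category")])
  np <- counts$n_P
  tp <- data.frame(concept_id = names(np), n_P = as.integer(np),
                   stringsAsFactors = FALSE)
  tp <- merge(tp, meta, by = "concept_id", all.x = TRUE, sort = FALSE)
  tp <- tp[order(-tp$n_P, tp$concept_id),
           c("concept_id", "preferred_name", "category", "n_P"), drop = FALSE]
  tp <- utils::head(tp, top_n)
  rownames(tp) <- NULL
  list(gene_class_share = share, top_genes = tg, top_phenotypes = tp)
}
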