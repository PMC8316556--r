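# Evaluation: precision/recall against gold annotations at gene, phenotype
# and sentence level, and true-positive rates against a reference
# gene-phenotype association database.

#' Precision and recall against a gold set
#'
#' Set comparison of identity keys: `tp = |pred intersect gold|`,
#' `fp = |pred \\ gold|`, `fn = |gold \\ pred|`; benchmark is the gold size
#' (`tp + fn`). Precision and recall are stored as proportions; the print
#' method reports percentages to one decimal.
#'
#' @param predicted Character vector of predicted identity keys (duplicates
#'   collapse).
#' @param gold Character vector of gold identity keys.
#' @param level One of `"gene"`, `"phenotype"`, `"sentence"` (annotation
#'   only).
#' @return An object of class `pr_result`: list with `level`, `benchmark`,
#'   `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
#' @examples
#' r <- precision_recall(c("a", "b", "c"), c("a", "b", "d"))
#' r$precision
precision_recall <- function(predicted, gold,
                             level = c("gene", "phenotype", "sentence")) {
  level <- match.arg(level)
  predicted <- unique(predicted)
  gold <- unique(gold)
  tp <- length(intersect(predicted, gold))
  fp <- length(setdiff(predicted, gold))
  fn <- length(setdiff(gold, predicted))
  structure(list(
    level = level, benchmark = tp + fn, tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0L) tp / (tp + fn) else NA_real_),
    class = "pr_result")
}

#' Precision and recall from raw confusion counts
#'
#' The same arithmetic as [precision_recall()] when the per-item sets are
#' not available, only the tallies (as when checking published confusion
#' tables).
#'
#' @param tp,fp,fn Non-negative counts.
#' @param level Annotation level.
#' @return A `pr_result`.
#' @export
pr_from_counts <- function(tp, fp, fn,
                           level = c("gene", "phenotype", "sentence")) {
  level <- match.arg(level)
  if (any(c(tp, fp, fn) < 0)) gp_stop("counts must be non-negative")
  structure(list(
    level = level, benchmark = tp + fn, tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_),
    class = "pr_result")
}

#' @export
print.pr_result <- function(x, ...) {
  cat(sprintf(
    "<pr_result> %s level: benchmark %d, TP %d, FP %d, FN %d\n  precision %.1f%%  recall %.1f%%\n",
    x$level, x$benchmark, x$tp, x$fp, x$fn,
    100 * x$precision, 100 * x$recall))
  invisible(x)
}

#' Read gold annotations (JSONL)
#'
#' One JSON object per line per article:
#' `{"article_id": ..., "genes": [{"sentence_index": i, "symbol": s}, ...],
#' "phenotypes": [{"sentence_index": i, "concept_id": c}, ...],
#' "target_sentences": [i, ...]}`.
#'
#' @param path Path to the JSONL file.
#' @return List with identity-key character vectors `genes`, `phenotypes`,
#'   `sentences`.
#' @export
read_gold_jsonl <- function(path) {
  if (!file.exists(path)) gp_stop("gold file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  genes <- character(0); phens <- character(0); sents <- character(0)
  for (line in lines) {
    obj <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    aid <- obj$article_id
    for (g in obj$genes %||% list())
      genes <- c(genes, paste(aid, g$sentence_index, g$symbol, sep = "\r"))
    for (p in obj$phenotypes %||% list())
      phens <- c(phens, paste(aid, p$sentence_index, p$concept_id, sep = "\r"))
    for (i in obj$target_sentences %||% list())
      sents <- c(sents, paste(aid, i, sep = "\r"))
  }
  list(genes = unique(genes), phenotypes = unique(phens),
       sentences = unique(sents))
}

#' Evaluate mined output against gold annotations
#'
#' Mention identity at the gene and phenotype levels is
#' (article, sentence, lexicon reference) -- spans are ignored so
#' annotations need not be character-exact. Sentence level compares target
#' sentence identities (article, index).
#'
#' @param mentions A `mention_set` from [mine_corpus()].
#' @param standardized Standardized mention table from
#'   [standardize_corpus()].
#' @param gold Gold annotation list from [read_gold_jsonl()].
#' @return List of three `pr_result` objects: `gene`, `phenotype`,
#'   `sentence`.
#' @export
evaluate_pipeline <- function(mentions, standardized, gold) {
  gm <- mentions$gene_mentions
  pred_genes <- unique(paste(gm$article_id, gm$sentence_index, gm$symbol,
                             sep = "\r"))
  pred_phens <- unique(paste(standardized$article_id,
                             standardized$sentence_index,
                             standardized$concept_id, sep = "\r"))
  tg <- mentions$targets
  pred_sents <- unique(paste(tg$article_id, tg$index, sep = "\r"))
  list(gene = precision_recall(pred_genes, gold$genes, "gene"),
       phenotype = precision_recall(pred_phens, gold$phenotypes, "phenotype"),
       sentence = precision_recall(pred_sents, gold$sentences, "sentence"))
}

#' True-positive rates against a reference association database
#'
#' Only genes present in both the mined records and the reference are
#' evaluated. A gene is a true positive when at least one of its mined
#' associations is also in the reference; overlap is keyed on `hpo_id` when
#' the mined concept has one, else on `concept_id`. Rates are reported per
#' risk class.
#'
#' @param records Association record table.
#' @param reference Data frame with columns `gene` and `phenotype_id`
#'   (HPO id or concept id).
#' @param gene_lexicon A `gene_lexicon` supplying risk classes.
#' @return Data frame with columns `risk_class`, `n_evaluated`, `n_tp`,
#'   `tp_rate`.
#' @export
reference_tp_rate <- function(records, reference, gene_lexicon) {
  if (is.null(reference) || nrow(reference) == 0L)
    gp_stop("reference association set is empty")
  key <- ifelse(!is.na(records$hpo_id), records$hpo_id, records$concept_id)
  mined <- unique(data.frame(gene = records$gene, pid = key,
                             stringsAsFactors = FALSE))
  common <- intersect(unique(mined$gene), unique(reference$gene))
  ref_key <- paste(reference$gene, reference$phenotype_id, sep = "\r")
  is_tp <- vapply(common, function(g) {
    any(paste(g, mined$pid[mined$gene == g], sep = "\r") %in% ref_key)
  }, logical(1))
  cls <- gene_lexicon$risk_class[match(common, gene_lexicon$symbol)]
  cls[is.na(cls)] <- "NA"
  levels_ <- c("1", "2", "3", "S", "NA")
  out <- data.frame(
    risk_class = levels_,
    n_evaluated = vapply(levels_, function(l) sum(cls == l), integer(1)),
    n_tp = vapply(levels_, function(l) sum(is_tp[cls == l]), integer(1)),
    stringsAsFactors = FALSE)
  out$tp_rate <- ifelse(out$n_evaluated > 0L, out$n_tp / out$n_evaluated,
                        NA_real_)
  out
}
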