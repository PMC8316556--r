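# Synthetic data generation: format-valid miniature vocabularies, gene
# lists, HPO hierarchies and JATS-style corpora with planted gene-phenotype
# co-occurrence structure plus matching ground truth, so every other module
# is testable offline. All content is synthetic; no licensed vocabulary
# material is reproduced.

#' Default synthetic vocabulary definition
#'
#' A miniature multi-source vocabulary exercising every lexicon feature:
#' synonym pairs, one multi-source concept (priority resolution), a
#' multi-word term, concepts outside HPO (category "NA"), a non-English row,
#' and rows excluded by each layer of the semantic-type filter.
#'
#' @return List describing concepts, ASDPTO terms, the HPO mini-hierarchy
#'   and the gene list (internal structure; consumed by
#'   [generate_vocabulary()]).
#' @export
synthetic_vocabulary_def <- function() {
  concepts <- list(
    list(cui = "C0036572", sab = "HPO", code = "HP:0001250", sty = "T184",
         names = c("Seizure", "Convulsion")),
    list(cui = "C0036572", sab = "MSH", code = "D012640", sty = "T184",
         names = c("Seizures")),
    list(cui = "C0004352", sab = "HPO", code = "HP:0000717", sty = "T048",
         names = c("Autism", "Autistic disorder")),
    list(cui = "C0026650", sab = "HPO", code = "HP:0001270", sty = "T048",
         names = c("Motor delay", "Delayed motor development")),
    list(cui = "C0041582", sab = "HPO", code = "HP:0001252", sty = "T184",
         names = c("Hypotonia", "Muscular hypotonia")),
    list(cui = "C0006142", sab = "HPO", code = "HP:0003002", sty = "T047",
         names = c("Breast cancer", "Breast carcinoma")),
    list(cui = "C0439234", sab = "HPO", code = "HP:0400001", sty = "T079",
         names = c("Year")),                        # excluded: HPO T-code
    list(cui = "C0006826", sab = "MSH", code = "D009369", sty = "T047",
         names = c("Cancer", "Malignant neoplasm")),
    list(cui = "C0016667", sab = "OMIM", code = "300624", sty = "T047",
         names = c("Fragile X syndrome", "FRAXA")),
    list(cui = "C0011570", sab = "SNOMEDCT_US", code = "35489007",
         sty = "T048", names = c("Depression", "Depressive disorder")),
    list(cui = "C0439228", sab = "SNOMEDCT_US", code = "103335007",
         sty = "T079", names = c("Duration")),      # excluded: not included
    list(cui = "C0020538", sab = "DDB", code = "6330", sty = "T047",
         names = c("Hypertension")))
  asdpto <- data.frame(
    id = c("ASDPTO:0001", "ASDPTO:0002"),
    name = c("Social difficulty", "Language impairment"),
    synonyms = c("Impaired social interaction", ""),
    hpo_id = c(NA_character_, "HP:0002463"),
    stringsAsFactors = FALSE)
  hpo <- c(
    "HP:0000001|All|",
    "HP:0000118|Phenotypic abnormality|HP:0000001",
    "HP:0000707|Abnormality of the nervous system|HP:0000118",
    "HP:0002664|Neoplasm|HP:0000118",
    "HP:0000769|Abnormality of the breast|HP:0000118",
    "HP:0012638|Abnormal nervous system physiology|HP:0000707",
    "HP:0001250|Seizure|HP:0012638",
    "HP:0000717|Autism|HP:0012638",
    "HP:0001270|Motor delay|HP:0012638",
    "HP:0001252|Hypotonia|HP:0012638",
    "HP:0002463|Language impairment|HP:0012638",
    "HP:0100013|Neoplasm of the breast|HP:0000769",
    "HP:0003002|Breast carcinoma|HP:0002664,HP:0100013",
    "HP:0400001|Year|HP:0000001")
  genes <- data.frame(
    symbol = c("MECP2", "FMR1", "CNTNAP2", "GRIN2A", "DRD2", "BRCA2",
               "CACNA1A", "DMD", "TP53", "STAT3"),
    risk_class = c("1", "1", "2", "2", "3", "3", "S", "S", NA, NA),
    stringsAsFactors = FALSE)
  list(concepts = concepts, asdpto = asdpto, hpo = hpo, genes = genes,
       n_lexicon_concepts = 12L)  # 10 surviving RRF concepts + 2 ASDPTO
}

#' Write the synthetic vocabulary files
#'
#' Emits an RRF-dialect concept file (with a non-English row for the
#' language filter), a semantic-type file, an ASDPTO TSV, a minimal
#' OBO-dialect HPO hierarchy and a gene list TSV. The files round-trip
#' through the lexicon and standardization modules without warnings.
#'
#' @param dir Output directory (created if missing).
#' @param def Vocabulary definition (default
#'   [synthetic_vocabulary_def()]).
#' @return Named list of file paths (`concepts`, `semtypes`, `asdpto`,
#'   `hpo`, `genes`) with the definition attached as attribute `def`.
#' @export
generate_vocabulary <- function(dir, def = synthetic_vocabulary_def()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rrf_row <- function(cui, lat, sab, tty, code, str) {
    f <- rep("", 16L)
    f[1] <- cui; f[2] <- lat; f[12] <- sab; f[13] <- tty
    f[14] <- code; f[15] <- str
    paste(f, collapse = "|")
  }
  conso <- character(0)
  sty_lines <- character(0)
  for (cpt in def$concepts) {
    for (j in seq_along(cpt$names)) {
      tty <- if (j == 1L) "PT" else "SY"
      conso <- c(conso, rrf_row(cpt$cui, "ENG", cpt$sab, tty, cpt$code,
                                cpt$names[j]))
    }
    sty_lines <- c(sty_lines, paste0(cpt$cui, "|", cpt$sty, "||"))
  }
  # non-English row, dropped by the language filter
  conso <- c(conso, rrf_row("C0036572", "FRE", "MSH", "PT", "D012640",
                            "Crise convulsive"))
  sty_lines <- unique(sty_lines)
  paths <- list(concepts = file.path(dir, "concepts.rrf"),
                semtypes = file.path(dir, "semtypes.rrf"),
                asdpto = file.path(dir, "asdpto.tsv"),
                hpo = file.path(dir, "hpo_mini.obo"),
                genes = file.path(dir, "genes.tsv"))
  writeLines(conso, paths$concepts)
  writeLines(sty_lines, paths$semtypes)
  asd <- def$asdpto
  asd$hpo_id[is.na(asd$hpo_id)] <- ""
  write_tsv_plain(asd, paths$asdpto)
  obo <- c("format-version: 1.2", "")
  for (line in def$hpo) {
    p <- stringi::stri_split_fixed(line, "|")[[1]]
    obo <- c(obo, "[Term]", paste0("id: ", p[1]), paste0("name: ", p[2]))
    if (nzchar(p[3]))
      for (par in stringi::stri_split_fixed(p[3], ",")[[1]])
        obo <- c(obo, paste0("is_a: ", par))
    obo <- c(obo, "")
  }
  writeLines(obo, paths$hpo)
  g <- def$genes
  g$risk_class[is.na(g$risk_class)] <- ""
  writeLines(paste(g$symbol, g$risk_class, sep = "\t"), paths$genes)
  attr(paths, "def") <- def
  paths
}

#' Planting specification for a synthetic corpus
#'
#' Defines per-sentence mention probabilities. Genes and phenotypes in
#' `joint` pairs are sampled jointly from a 2x2 per-sentence distribution
#' with the stated joint probability (each such gene/phenotype may belong to
#' at most one pair, so the marginals stay exact); all other entries are
#' independent Bernoulli draws. Defaults plant ten genes and eleven
#' standardized concepts over 50 articles x 100 sentences (5,000 corpus
#' sentences plus one title line per article), with pair strengths spanning
#' strong positive association, exact independence, and a never-co-occurring
#' pair -- the regimes the NPMI scale distinguishes.
#'
#' @param n_articles Number of articles.
#' @param sentences_per_article Body sentences per article.
#' @param genes Data frame `symbol`, `prob`.
#' @param phenotypes Data frame `concept_id`, `prob`.
#' @param joint Data frame `gene`, `concept_id`, `joint_prob`.
#' @param distractors Insert distractor sentences containing lexicon
#'   substrings inside non-phenotype noun phrases (false-positive
#'   regression mode). Probability per sentence of replacing a filler.
#' @return An object of class `planting_spec`.
#' @export
planting_spec <- function(n_articles = 50L, sentences_per_article = 100L,
                          genes = NULL, phenotypes = NULL, joint = NULL,
                          distractors = 0) {
  genes <- genes %||% data.frame(
    symbol = c("MECP2", "FMR1", "CNTNAP2", "GRIN2A", "DRD2", "BRCA2",
               "CACNA1A", "DMD", "TP53", "STAT3"),
    prob = c(0.08, 0.06, 0.05, 0.04, 0.04, 0.04, 0.03, 0.03, 0.05, 0.03),
    stringsAsFactors = FALSE)
  phenotypes <- phenotypes %||% data.frame(
    concept_id = c("C0036572", "C0004352", "C0006142", "C0016667",
                   "C0011570", "C0026650", "C0020538", "C0041582",
                   "ASDPTO:0001", "C0006826", "ASDPTO:0002"),
    prob = c(0.08, 0.06, 0.05, 0.03, 0.03, 0.04, 0.02, 0.02, 0.03, 0.02,
             0.02),
    stringsAsFactors = FALSE)
  joint <- joint %||% data.frame(
    gene = c("MECP2", "FMR1", "BRCA2", "DRD2", "GRIN2A", "TP53"),
    concept_id = c("C0036572", "C0016667", "C0006142", "C0011570",
                   "C0004352", "C0026650"),
    joint_prob = c(0.03, 0.02, 0.02, 0.012, 0.0024, 0),
    stringsAsFactors = FALSE)
  stopifnot(all(genes$prob >= 0 & genes$prob <= 1),
            all(phenotypes$prob >= 0 & phenotypes$prob <= 1))
  if (anyDuplicated(joint$gene) || anyDuplicated(joint$concept_id))
    gp_stop("each gene/phenotype may appear in at most one joint pair")
  pg <- genes$prob[match(joint$gene, genes$symbol)]
  pp <- phenotypes$prob[match(joint$concept_id, phenotypes$concept_id)]
  if (any(is.na(pg)) || any(is.na(pp)))
    gp_stop("joint pairs must reference listed genes and phenotypes")
  if (any(joint$joint_prob > pmin(pg, pp) + 1e-12))
    gp_stop("joint probability exceeds a marginal")
  structure(list(n_articles = as.integer(n_articles),
                 sentences_per_article = as.integer(sentences_per_article),
                 genes = genes, phenotypes = phenotypes, joint = joint,
                 distractors = distractors),
            class = "planting_spec")
}

#' Analytic NPMI of planted probabilities
#'
#' NPMI evaluated on the planting distribution itself: zero joint
#' probability gives -1 by convention, a joint probability of 1 gives 1.
#'
#' @param p_g,p_p Marginal per-sentence probabilities.
#' @param p_gp Joint per-sentence probability.
#' @return Analytic NPMI.
#' @export
#' @examples
#' analytic_npmi(0.1, 0.1, 0.05)
analytic_npmi <- function(p_g, p_p, p_gp) {
  if (p_gp == 0) return(-1)
  if (p_gp == 1) return(1)
  min(1, max(-1, log(p_gp / (p_g * p_p)) / (-log(p_gp))))
}

#' Sampling standard deviation of estimated NPMI
#'
#' Delta-method propagation of the binomial sampling noise of
#' (n_G, n_P, n_GP) through the NPMI formula at the planted probabilities,
#' including the covariances induced by co-occurrence counting. Used to set
#' tolerance bands when comparing estimated against analytic NPMI.
#'
#' @inheritParams analytic_npmi
#' @param n Number of sentences.
#' @return Approximate standard deviation of the NPMI estimate.
#' @export
npmi_sampling_sd <- function(p_g, p_p, p_gp, n) {
  if (p_gp <= 0 || p_gp >= 1) return(0)
  x <- n * p_gp; a <- n * p_g; b <- n * p_p
  v <- log(n) - log(x)
  u <- log(x) + log(n) - log(a) - log(b)
  dx <- (v + u) / (x * v^2)
  da <- -1 / (a * v)
  db <- -1 / (b * v)
  var_x <- n * p_gp * (1 - p_gp)
  var_a <- n * p_g * (1 - p_g)
  var_b <- n * p_p * (1 - p_p)
  cov_ax <- n * p_gp * (1 - p_g)
  cov_bx <- n * p_gp * (1 - p_p)
  cov_ab <- n * (p_gp - p_g * p_p)
  sqrt(max(0, dx^2 * var_x + da^2 * var_a + db^2 * var_b +
             2 * dx * da * cov_ax + 2 * dx * db * cov_bx +
             2 * da * db * cov_ab))
}

# Sentence templates. Words are chosen to avoid every lexicon lemma and
# every gene symbol, so the no-distractor corpus contains no accidental
# mentions.
.fillers <- c(
  "The protocol was approved by the institutional review board.",
  "Libraries were prepared following standard procedures.",
  "Statistical testing used a two-sided significance level.",
  "Recruitment took place across three clinical sites.",
  "Informed consent was obtained from all participants.")

.distractor_sentences <- c(
  "Specimens were archived at the National Cancer Center.",
  "Ratings were collected with the Childhood Autism Rating Scale.")

#' @noRd
compose_sentence <- function(genes, surfaces) {
  gtxt <- paste(genes, collapse = " and ")
  ptxt <- paste(surfaces, collapse = " and ")
  if (length(genes) > 0L && length(surfaces) > 0L) {
    sprintf("Variants in %s were reported together with %s in probands.",
            gtxt, ptxt)
  } else if (length(genes) > 0L) {
    sprintf("Expression of %s was quantified in cortical tissue.", gtxt)
  } else {
    sprintf("Probands presented with %s at enrollment.", ptxt)
  }
}

#' Generate a synthetic corpus with planted co-occurrence structure
#'
#' Writes one JATS-style XML article per file (title plus one paragraph per
#' sentence) and returns the planted ground truth: per-sentence mentions,
#' expected count tables, and the analytic NPMI per planted pair. All
#' randomness flows from `seed`; the generator never consults global random
#' state outside the localized RNG.
#'
#' @param spec A [planting_spec()].
#' @param dir Output directory for the XML files.
#' @param seed Integer seed.
#' @param vocab_def Vocabulary definition supplying concept synonyms for
#'   surface realization.
#' @return An object of class `planted_truth`: list with `sentences`
#'   (data frame `article_id`, `index`, `genes`, `concepts` as list-columns),
#'   `n_sentences` (total emitted, titles included), `expected` (data frames
#'   `genes`, `phenotypes`, `pairs` with expected counts and binomial SDs and
#'   analytic NPMI), and `dir`.
#' @export
generate_corpus <- function(spec, dir, seed = 1L,
                            vocab_def = synthetic_vocabulary_def()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  syn_map <- list()
  for (cpt in vocab_def$concepts) {
    if (cpt$sab == "HPO" || is.null(syn_map[[cpt$cui]]))
      syn_map[[cpt$cui]] <- cpt$names
  }
  for (i in seq_len(nrow(vocab_def$asdpto))) {
    syns <- c(vocab_def$asdpto$name[i],
              Filter(nzchar, stringi::stri_split_fixed(
                vocab_def$asdpto$synonyms[i], "|")[[1]]))
    syn_map[[vocab_def$asdpto$id[i]]] <- syns
  }
  missing <- setdiff(spec$phenotypes$concept_id, names(syn_map))
  if (length(missing) > 0L)
    gp_stop("no synonyms for planted concept(s): %s",
            paste(missing, collapse = ", "))
  paired_genes <- spec$joint$gene
  paired_phens <- spec$joint$concept_id
  free_genes <- spec$genes[!(spec$genes$symbol %in% paired_genes), ,
                           drop = FALSE]
  free_phens <- spec$phenotypes[!(spec$phenotypes$concept_id %in%
                                    paired_phens), , drop = FALSE]
  pg_pair <- spec$genes$prob[match(paired_genes, spec$genes$symbol)]
  pp_pair <- spec$phenotypes$prob[match(paired_phens,
                                        spec$phenotypes$concept_id)]
  n_body <- spec$n_articles * spec$sentences_per_article
  rows <- vector("list", n_body)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv), add = TRUE)
  set.seed(seed)
  k <- 0L
  for (art in seq_len(spec$n_articles)) {
    article_id <- sprintf("SYN%04d", art)
    for (s in seq_len(spec$sentences_per_article)) {
      g_here <- character(0); p_here <- character(0)
      for (j in seq_along(paired_genes)) {
        pj <- spec$joint$joint_prob[j]
        probs <- c(pj, pg_pair[j] - pj, pp_pair[j] - pj,
                   1 - pg_pair[j] - pp_pair[j] + pj)
        cell <- sample.int(4L, 1L, prob = probs)
        if (cell == 1L) {
          g_here <- c(g_here, paired_genes[j])
          p_here <- c(p_here, paired_phens[j])
        } else if (cell == 2L) {
          g_here <- c(g_here, paired_genes[j])
        } else if (cell == 3L) {
          p_here <- c(p_here, paired_phens[j])
        }
      }
      if (nrow(free_genes) > 0L) {
        hit <- stats::runif(nrow(free_genes)) < free_genes$prob
        g_here <- c(g_here, free_genes$symbol[hit])
      }
      if (nrow(free_phens) > 0L) {
        hit <- stats::runif(nrow(free_phens)) < free_phens$prob
        p_here <- c(p_here, free_phens$concept_id[hit])
      }
      surfaces <- vapply(p_here, function(cid) {
        syns <- syn_map[[cid]]
        syns[sample.int(length(syns), 1L)]
      }, character(1))
      if (length(g_here) == 0L && length(p_here) == 0L) {
        text <- if (spec$distractors > 0 &&
                    stats::runif(1) < spec$distractors) {
          .distractor_sentences[sample.int(length(.distractor_sentences), 1L)]
        } else {
          .fillers[((s - 1L) %% length(.fillers)) + 1L]
        }
      } else {
        text <- compose_sentence(g_here, surfaces)
      }
      k <- k + 1L
      rows[[k]] <- list(article_id = article_id, body_pos = s, text = text,
                        genes = g_here, concepts = p_here)
    }
  }
  truth <- data.frame(
    article_id = vapply(rows, `[[`, character(1), "article_id"),
    index = vapply(rows, `[[`, integer(1), "body_pos"),  # title is index 0
    stringsAsFactors = FALSE)
  truth$text <- vapply(rows, `[[`, character(1), "text")
  truth$genes <- lapply(rows, `[[`, "genes")
  truth$concepts <- lapply(rows, `[[`, "concepts")
  for (art in seq_len(spec$n_articles)) {
    article_id <- sprintf("SYN%04d", art)
    sents <- truth$text[truth$article_id == article_id]
    xml <- c(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<article>",
      "  <front>",
      "    <article-meta>",
      sprintf("      <article-id pub-id-type=\"pmc\">%s</article-id>",
              sub("^SYN", "", article_id)),
      "      <title-group>",
      sprintf("        <article-title>Synthetic corpus document %d</article-title>",
              art),
      "      </title-group>",
      "    </article-meta>",
      "  </front>",
      "  <body>",
      sprintf("    <p>%s</p>", xml_escape(sents)),
      "  </body>",
      "</article>")
    writeLines(xml, file.path(dir, paste0(article_id, ".xml")))
  }
  truth$article_id <- paste0("PMC", sub("^SYN", "", truth$article_id))
  n_sentences <- n_body + spec$n_articles  # one title line per article
  expected <- planted_expectations(spec, n_sentences)
  structure(list(sentences = truth, n_sentences = n_sentences,
                 expected = expected, dir = dir, seed = seed),
            class = "planted_truth")
}

#' @noRd
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' @noRd
planted_expectations <- function(spec, n_sentences) {
  n <- n_sentences
  genes <- data.frame(symbol = spec$genes$symbol,
                      expected = n * spec$genes$prob,
                      sd = sqrt(n * spec$genes$prob * (1 - spec$genes$prob)),
                      stringsAsFactors = FALSE)
  phens <- data.frame(concept_id = spec$phenotypes$concept_id,
                      expected = n * spec$phenotypes$prob,
                      sd = sqrt(n * spec$phenotypes$prob *
                                  (1 - spec$phenotypes$prob)),
                      stringsAsFactors = FALSE)
  pairs <- spec$joint
  pg <- spec$genes$prob[match(pairs$gene, spec$genes$symbol)]
  pp <- spec$phenotypes$prob[match(pairs$concept_id,
                                   spec$phenotypes$concept_id)]
  pairs$expected <- n * pairs$joint_prob
  pairs$sd <- sqrt(n * pairs$joint_prob * (1 - pairs$joint_prob))
  pairs$analytic_npmi <- mapply(analytic_npmi, pg, pp, pairs$joint_prob)
  pairs$npmi_sd <- mapply(npmi_sampling_sd, pg, pp, pairs$joint_prob,
                          MoreArgs = list(n = n))
  list(genes = genes, phenotypes = phens, pairs = pairs)
}

#' Write gold annotations for a planted corpus
#'
#' Emits the ground truth as the JSONL gold format the evaluation module
#' consumes. Note the planted body sentences sit at indices 1..S within each
#' article; index 0 is the article title.
#'
#' @param truth A `planted_truth` from [generate_corpus()].
#' @param path Output JSONL path.
#' @return `path`, invisibly.
#' @export
write_gold_jsonl <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (aid in unique(truth$sentences$article_id)) {
    sub <- truth$sentences[truth$sentences$article_id == aid, , drop = FALSE]
    genes <- list(); phens <- list(); targets <- list()
    for (i in seq_len(nrow(sub))) {
      for (g in sub$genes[[i]])
        genes[[length(genes) + 1L]] <-
          list(sentence_index = sub$index[i], symbol = g)
      for (p in sub$concepts[[i]])
        phens[[length(phens) + 1L]] <-
          list(sentence_index = sub$index[i], concept_id = p)
      if (length(sub$genes[[i]]) > 0L && length(sub$concepts[[i]]) > 0L)
        targets[[length(targets) + 1L]] <- sub$index[i]
    }
    writeLines(jsonlite::toJSON(
      list(article_id = aid, genes = genes, phenotypes = phens,
           target_sentences = targets),
      auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
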