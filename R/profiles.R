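# Gene phenotype profiles: binary incidence matrix, 2-D embedding, k-means
# clustering, category labelling, and partition concordance metrics.

#' Build the binary gene-phenotype matrix
#'
#' Rows are genes, columns are standardized phenotype concepts; an entry is 1
#' exactly when the pair's NPMI is larger than zero (a zero or negative NPMI,
#' like an absent pair, gives 0). Row and column order is sorted and unique,
#' so the build is idempotent and independent of record input order.
#'
#' @param records Association record table.
#' @return Integer matrix with gene rownames and concept-id colnames.
#' @export
build_matrix <- function(records) {
  genes <- sort(unique(records$gene))
  phens <- sort(unique(records$concept_id))
  m <- matrix(0L, nrow = length(genes), ncol = length(phens),
              dimnames = list(genes, phens))
  pos <- records[records$npmi > 0, , drop = FALSE]
  if (nrow(pos) > 0L)
    m[cbind(match(pos$gene, genes), match(pos$concept_id, phens))] <- 1L
  m
}

#' Label genes by the category of their strongest phenotype
#'
#' For each gene, the phenotype with the highest NPMI (ties by `n_GP`
#' descending then concept id, matching [rank_phenotypes_for_gene()]) is
#' selected and its top-level category becomes the gene label. Genes whose
#' strongest phenotype has category `"NA"` (not traceable into HPO) are
#' dropped from the labeled set.
#'
#' @param records Association record table with a `category` column.
#' @return Named character vector: gene -> category, only for retained genes.
#' @export
label_by_top_category <- function(records) {
  out <- character(0)
  for (g in sort(unique(records$gene))) {
    top <- rank_phenotypes_for_gene(records, g, k = 1L)
    if (nrow(top) == 1L && !is.na(top$category) && top$category != "NA")
      out[g] <- top$category
  }
  out
}

#' Embed the gene-phenotype matrix in two dimensions with t-SNE
#'
#' Exact (theta = 0) t-SNE on the binary matrix rows. Deterministic for a
#' given seed; hyperparameters are recorded as attributes for reproducibility.
#'
#' @param matrix Binary gene-phenotype matrix from [build_matrix()].
#' @param seed Random seed.
#' @param perplexity t-SNE perplexity; must satisfy `3 * perplexity < n - 1`.
#'   The default shrinks to fit small inputs.
#' @param max_iter Iterations (default 1000).
#' @return Numeric matrix (genes x 2) of coordinates, with attributes
#'   `seed`, `perplexity`, `max_iter`.
#' @export
embed_2d <- function(matrix, seed = 42L, perplexity = NULL, max_iter = 1000L) {
  n <- nrow(matrix)
  if (n < 3L) gp_stop("embedding needs at least 3 genes, got %d", n)
  if (is.null(perplexity)) perplexity <- min(30, (n - 2) / 3)
  if (3 * perplexity >= n - 1)
    gp_stop("perplexity %.2f too large for %d genes (need 3*perplexity < n-1)",
            perplexity, n)
  set.seed(seed)
  fit <- Rtsne::Rtsne(matrix, dims = 2, perplexity = perplexity,
                      theta = 0, max_iter = max_iter, pca = FALSE,
                      check_duplicates = FALSE, verbose = FALSE)
  coords <- fit$Y
  rownames(coords) <- rownames(matrix)
  colnames(coords) <- c("tsne1", "tsne2")
  if (!all(is.finite(coords))) gp_stop("t-SNE produced non-finite coordinates")
  attr(coords, "seed") <- seed
  attr(coords, "perplexity") <- perplexity
  attr(coords, "max_iter") <- max_iter
  coords
}

#' k-means clustering of embedded genes
#'
#' Deterministic for a given seed. Empty clusters (possible when k-means
#' converges with fewer occupied centers) are reported in the
#' `empty_clusters` attribute.
#'
#' @param coordinates Gene x 2 coordinate matrix from [embed_2d()].
#' @param k Number of clusters (2 <= k <= n).
#' @param seed Random seed.
#' @param nstart Random restarts (default 10).
#' @return Named integer vector of cluster ids per gene.
#' @export
kmeans_cluster <- function(coordinates, k, seed = 42L, nstart = 10L) {
  n <- nrow(coordinates)
  if (k < 2L || k > n) gp_stop("invalid k = %s for %d genes", k, n)
  if (k == n) {  # every gene its own cluster; nothing to optimize
    labels <- stats::setNames(seq_len(n), rownames(coordinates))
    attr(labels, "empty_clusters") <- integer(0)
    return(labels)
  }
  set.seed(seed)
  fit <- stats::kmeans(coordinates, centers = k, nstart = nstart,
                       iter.max = 100L)
  labels <- stats::setNames(as.integer(fit$cluster), rownames(coordinates))
  empty <- setdiff(seq_len(k), unique(labels))
  if (length(empty) > 0L)
    gp_warn("empty cluster id(s): %s", paste(empty, collapse = ", "))
  attr(labels, "empty_clusters") <- empty
  labels
}

#' @noRd
contingency <- function(a, b) {
  if (length(a) != length(b))
    gp_stop("label vectors differ in length (%d vs %d)", length(a), length(b))
  if (length(a) == 0L) gp_stop("empty label vectors")
  table(as.character(a), as.character(b))
}

#' Adjusted Rand index of two partitions
#'
#' Pair-counting agreement corrected for chance; 1 for identical partitions,
#' around 0 for independent ones, negative when concordance is below chance.
#'
#' @param a,b Equal-length label vectors over the same items.
#' @return ARI value.
#' @export
adjusted_rand_index <- function(a, b) {
  ct <- contingency(a, b)
  n <- sum(ct)
  sum_ij <- sum(choose(ct, 2))
  ai <- sum(choose(rowSums(ct), 2))
  bj <- sum(choose(colSums(ct), 2))
  expected <- ai * bj / choose(n, 2)
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)  # both partitions trivial and identical
  (sum_ij - expected) / (maxi - expected)
}

#' Jaccard index of two partitions
#'
#' Pair-counting Jaccard: pairs co-clustered in both partitions over pairs
#' co-clustered in at least one. Pairs separated in both partitions are
#' ignored by construction.
#'
#' @inheritParams adjusted_rand_index
#' @return Jaccard value in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  ct <- contingency(a, b)
  s11 <- sum(choose(ct, 2))
  s1_ <- sum(choose(rowSums(ct), 2))
  s_1 <- sum(choose(colSums(ct), 2))
  denom <- s1_ + s_1 - s11
  if (denom == 0) return(1)  # no co-clustered pairs anywhere: all singletons
  s11 / denom
}

#' Normalized mutual information of two partitions
#'
#' Mutual information of the label distributions normalized by the
#' arithmetic mean of the two entropies; 1 for identical partitions, 0 for
#' independent ones. Two trivial (single-cluster) partitions are identical
#' and score 1.
#'
#' @inheritParams adjusted_rand_index
#' @return NMI value in \[0, 1\].
#' @export
normalized_mutual_information <- function(a, b) {
  ct <- contingency(a, b)
  n <- sum(ct)
  p <- ct / n
  pa <- rowSums(p); pb <- colSums(p)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  outer_p <- outer(pa, pb)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer_p[nz]))
  min(1, max(0, mi / ((ha + hb) / 2)))
}

#' Purity of a clustering against reference labels
#'
#' The proportion of items assigned to the majority reference label of their
#' cluster: `sum_c max_t |c intersect t| / N`. Direction matters: the first
#' argument is the clustering being scored, the second the reference
#' labelling.
#'
#' @param clusters Cluster label vector.
#' @param reference Reference label vector.
#' @return Purity in \[0, 1\].
#' @export
purity <- function(clusters, reference) {
  ct <- contingency(clusters, reference)
  sum(apply(ct, 1L, max)) / sum(ct)
}

#' All four partition concordance metrics at once
#'
#' @param clusters Cluster labels (e.g. k-means result).
#' @param reference Reference labels (e.g. top-level categories).
#' @return List with `adjusted_rand`, `jaccard`, `nmi`, `purity`.
#' @export
concordance_scores <- function(clusters, reference) {
  list(adjusted_rand = adjusted_rand_index(clusters, reference),
       jaccard = jaccard_index(clusters, reference),
       nmi = normalized_mutual_information(clusters, reference),
       purity = purity(clusters, reference))
}
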