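# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# --- partition concordance by explicit pair enumeration ------------------

pair_counts_oracle <- function(a, b) {
  n <- length(a)
  a11 <- a10 <- a01 <- a00 <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) a11 <- a11 + 1L
      else if (sa && !sb) a10 <- a10 + 1L
      else if (!sa && sb) a01 <- a01 + 1L
      else a00 <- a00 + 1L
    }
  }
  list(a11 = a11, a10 = a10, a01 = a01, a00 = a00)
}

ari_oracle <- function(a, b) {
  p <- pair_counts_oracle(a, b)
  num <- 2 * (as.numeric(p$a11) * p$a00 - as.numeric(p$a10) * p$a01)
  den <- (p$a11 + p$a10) * (p$a10 + p$a00) +
    (p$a11 + p$a01) * (p$a01 + p$a00)
  if (den == 0) return(1)
  num / den
}

jaccard_oracle <- function(a, b) {
  p <- pair_counts_oracle(a, b)
  den <- p$a11 + p$a10 + p$a01
  if (den == 0) return(1)
  p$a11 / den
}

nmi_oracle <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  joint <- matrix(0, length(ua), length(ub))
  for (k in seq_len(n))
    joint[match(a[k], ua), match(b[k], ub)] <-
      joint[match(a[k], ua), match(b[k], ub)] + 1
  joint <- joint / n
  pa <- rowSums(joint); pb <- colSums(joint)
  ent <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  mi <- 0
  for (i in seq_along(ua)) for (j in seq_along(ub))
    if (joint[i, j] > 0)
      mi <- mi + joint[i, j] * log(joint[i, j] / (pa[i] * pb[j]))
  if (ent(pa) == 0 && ent(pb) == 0) return(1)
  if (ent(pa) == 0 || ent(pb) == 0) return(0)
  mi / ((ent(pa) + ent(pb)) / 2)
}

purity_oracle <- function(clusters, reference) {
  total <- 0L
  for (cl in unique(clusters)) {
    members <- reference[clusters == cl]
    total <- total + max(table(members))
  }
  as.numeric(total) / length(clusters)
}

# --- betweenness by exhaustive simple-path enumeration -------------------

# edges: data.frame(from, to, length); undirected. Enumerates every simple
# path between each unordered node pair, finds the minimum total length,
# and accumulates pass-through fractions for interior nodes.
betweenness_oracle <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    f <- edges$from[i]; t <- edges$to[i]; w <- edges$length[i]
    adj[[f]] <- rbind(adj[[f]], data.frame(to = t, w = w))
    adj[[t]] <- rbind(adj[[t]], data.frame(to = f, w = w))
  }
  score <- stats::setNames(numeric(length(nodes)), nodes)
  all_paths <- function(cur, target, visited, len) {
    if (cur == target) return(list(list(path = visited, len = len)))
    out <- list()
    nb <- adj[[cur]]
    if (is.null(nb)) return(out)
    for (r in seq_len(nrow(nb))) {
      nxt <- nb$to[r]
      if (nxt %in% visited) next
      out <- c(out, all_paths(nxt, target, c(visited, nxt), len + nb$w[r]))
    }
    out
  }
  nn <- length(nodes)
  for (i in seq_len(nn - 1L)) {
    for (j in (i + 1L):nn) {
      s <- nodes[i]; t <- nodes[j]
      paths <- all_paths(s, t, s, 0)
      if (length(paths) == 0L) next
      lens <- vapply(paths, `[[`, numeric(1), "len")
      shortest <- paths[abs(lens - min(lens)) < 1e-9]
      sigma <- length(shortest)
      interior <- unlist(lapply(shortest, function(p)
        setdiff(p$path, c(s, t))))
      if (length(interior) > 0L) {
        tab <- table(interior)
        score[names(tab)] <- score[names(tab)] + as.numeric(tab) / sigma
      }
    }
  }
  score
}

# --- top-level category by all-ancestor-path enumeration -----------------

# Enumerates every ancestor path from a node, records the minimum depth at
# which each category root occurs, and applies the shortest-depth /
# table-order rule.
category_oracle <- function(hpo_id, hierarchy, table = hpo_category_table()) {
  if (is.na(hpo_id) || !(hpo_id %in% names(hierarchy$parents))) return("NA")
  depths <- new.env(parent = emptyenv())
  walk <- function(id, d) {
    prev <- get0(id, envir = depths, ifnotfound = Inf)
    if (d < prev) assign(id, d, envir = depths)
    for (p in hierarchy$parents[[id]]) walk(p, d + 1L)
  }
  walk(hpo_id, 0L)
  reached <- vapply(table$hpo_id, function(r)
    get0(r, envir = depths, ifnotfound = Inf), numeric(1))
  if (all(is.infinite(reached))) return("NA")
  table$category[which.min(reached)]  # which.min: first (table order) on ties
}

# igraph-free random partition generator
random_partition <- function(n, k, seed) {
  set.seed(seed)
  sample.int(k, n, replace = TRUE)
}
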