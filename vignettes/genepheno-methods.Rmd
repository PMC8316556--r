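---
title: "Methods: mining and scoring sentence-level gene–phenotype associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and scoring sentence-level gene–phenotype associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genepheno)
```

# The model

`genepheno` operationalizes a simple but auditable definition of a
gene–phenotype association: the two entities are associated to the degree
that they are mentioned *in the same sentence* more often than chance
would predict. The unit of observation is the sentence; the statistic is
normalized pointwise mutual information over sentence counts,

$$\mathrm{NPMI}(G,P) \;=\;
\frac{\ln \dfrac{n_{GP}\, n_{tot}}{n_G\, n_P}}
     {-\ln \dfrac{n_{GP}}{n_{tot}}},$$

with $n_G$, $n_P$, $n_{GP}$ the numbers of sentences containing the gene,
the standardized phenotype (any synonym), and both, and $n_{tot}$ the
total number of sentences in the corpus. The normalization bounds the
score in $[-1, 1]$: 1 when the terms always co-occur, 0 when they occur
independently, $-1$ when they never co-occur. Repeated mentions within
one sentence contribute a single count, so verbose sentences are not
over-weighted.

The approach is deliberately correlational: no linguistic relation
(negation, causality, dosage) between the co-mentioned entities is
extracted, so a sentence denying an association counts the same as one
asserting it. This is a known limitation of co-occurrence mining and the
reason the output should be read as a ranked screen, not a curated
database.

## Numerical conventions

Two boundary cases of the formula are indeterminate and are defined by
their analytic limits: $n_{GP} = 0$ yields $-1$ and $n_{GP} = n_{tot}$
yields $1$. Interior values are clamped to $[-1, 1]$ against floating
point rounding. Natural logarithms are used throughout. Count corruption
($n_{GP} > \min(n_G, n_P)$) is a fatal error rather than a clamped value,
because it can only arise from a bookkeeping bug upstream.

# Lexicon construction

The phenotype lexicon is assembled from pipe-delimited concept and
semantic-type files in the RRF dialect, with configurable column indices
(defaults follow the public layout) so miniature hand-written fixtures
remain format-valid. Filtering is two-layer: by source vocabulary (HPO,
OMIM, DDB, SNOMED-CT US, MSH), then by semantic type — non-HPO concepts
must carry at least one of T047/T048/T184, while HPO contributes
everything not typed with an excluded code. The published exclusion list
for HPO is open-ended ("T045, T077, T079, T080, T082, T169, …"), so the
excluded set is a configuration parameter defaulting to exactly those six
codes; anything beyond them is a user decision, not a package guess.
Non-English rows are dropped (the matcher targets English literature).
ASDPTO terms join as their own source with no semantic-type filter, since
the flat term list carries no T-codes.

A concept is keyed by (identifier, source); its synonyms are grouped under
it, and when one surface string belongs to several concepts, all
candidates are retained and resolution is deferred to the
standardization step. Ordering is deterministic (concept id, then
source), so rebuilding from the same inputs is byte-identical.

# Text preprocessing

There is no lemmatizer among the package's R dependencies, and dictionary
matching does not need a linguistically perfect one — it needs a
*consistent* one. The package therefore ships a deterministic rule-based
lemmatizer (irregular-form table plus suffix rules for plural `-ies` /
`-es` / `-s`, progressive `-ing` and past `-ed` with final-consonant
undoubling) and applies the identical tokenize → stop-word →
lemmatize pipeline to vocabulary terms and to sentences. An imperfect
lemma like `making → mak` is harmless because both sides of the match
make the same error; what matters is that "Epilepsies, Partial" and
"partial epilepsy" collapse to comparable keys. The stop-word list is a
packaged editable text file, not a library default, for reproducibility.

Sentence segmentation is rule-based and deterministic: boundaries at
`.`/`!`/`?` followed by whitespace and an upper-case letter, digit or
opening quote, with a guard list of abbreviations ("et al.", "Fig.",
initials, …). Article XML is read from the JATS dialect: title, abstract
and body paragraphs in document order; reference lists, tables and figure
captions are excluded, which avoids affiliation-style false positives
("National Cancer Center") at the cost of possibly diverging from corpora
mined with other inclusion rules. Which sections a published corpus
actually mined is rarely stated; this package mines title + abstract +
body and says so.

Gene matching runs on a parallel raw-token stream and is case-sensitive
whole-token by default ("CAT" does not fire inside "scatter", nor on
"cat"), with a flag for case-insensitive matching. Phenotype matching is
longest-match-first, then leftmost, over contiguous lemma n-grams, so
"breast cancer" beats its embedded "cancer" and the final mention set
never overlaps.

# Standardization

A mention's candidate concepts are resolved by source priority — HPO
first, then ASDPTO, OMIM, DDB, SNOMED-CT, MSH — with ties at equal rank
broken by lexicographic concept id. The result is a total order, so
resolution is invariant under candidate permutation.

Top-level categories are the 23 children of HPO's "Phenotypic
abnormality", configured by HPO id rather than by label so ontology label
edits are harmless. Category assignment is a breadth-first ancestor
traversal; when a term reaches several category roots, the shortest path
wins and residual ties break by table order — a deterministic, auditable
rule for a case the source material leaves open. Concepts with no HPO id
(including ASDPTO terms without an explicit cross-reference) map to
`"NA"`, since only HPO defines the categories.

# Profiles, clustering, concordance

The binary gene × phenotype matrix sets an entry to 1 exactly when
NPMI > 0 (zero or negative scores, like absent pairs, give 0). Genes are
embedded with exact (theta = 0) t-SNE and clustered with k-means on the
two embedding dimensions; both are seeded, and hyperparameters are
recorded on the outputs. The number of clusters `k` is a user parameter
with no package default: no defensible universal value exists, and the
appropriate `k` depends on the corpus. Genes are labeled by the top-level
category of their highest-NPMI phenotype (ties by co-occurrence count,
then concept id — the same rule as the per-gene ranking); genes whose top
phenotype is not traceable into HPO are dropped from the labeled set.

Concordance between the clustering and the category labelling is scored
with four metrics computed from the contingency table: pair-counting
adjusted Rand and Jaccard indices, normalized mutual information, and
purity ($\sum_c \max_t |c \cap t| / N$; the first argument is the
clustering, the second the reference labels). NMI is normalized by the
arithmetic mean of the two entropies; two degenerate single-cluster
partitions are defined to agree perfectly. The test suite checks all four
against an independent brute-force pair-enumeration oracle.

# The interaction network

Two genes are linked by every phenotype with which *both* associate at or
above a threshold; the default threshold is the global mean NPMI over all
retained records (a positive-only variant is a flag, since the source
convention is unstated), and qualification uses $\ge$ (the strictness is
likewise unstated; documented and configurable). Parallel links compress
into a single undirected edge weighted by the number of shared qualifying
phenotypes.

Betweenness centrality is computed exactly (Brandes' algorithm via
`igraph`), unnormalized, counting each unordered pair once. In weighted
mode the edge length is `1/weight`: weights are affinities (more shared
phenotypes = closer), which is the standard convention for
similarity-weighted graphs; a flag switches to `length = weight` for
distance-like weights. The top fraction (default 10%) of genes by
descending score is selected with `ceiling`, ties at the cut broken by
symbol order and reported.

# Evaluation

Precision and recall against gold annotations are set comparisons at
three levels; mention identity is (article, sentence, lexicon reference),
ignoring character spans so annotations need not be offset-exact, and
instance-level per sentence (each annotated sentence counts separately).
The gold format is a documented JSONL, one article per line. Reference
database comparison marks a gene as a true positive when at least one of
its mined associations also appears in the reference, keyed on HPO id
when available, else concept id; rates are reported per risk class.

# The synthetic data generator

The generator exists so that every module can be exercised offline with
format-valid inputs: RRF-dialect files with a synonym pair, a
multi-source concept, a multi-word term, a non-English row, rows excluded
by each filter layer; a minimal OBO-dialect hierarchy including a
multi-root node; a gene list covering all risk classes.

Corpora are built from sentence templates whose non-mention vocabulary is
chosen to avoid every lexicon lemma and gene symbol, so the clean corpus
contains no accidental mentions and recovery can be asserted exactly.
Planted pairs are drawn per sentence from a 2×2 joint distribution with
specified joint probability (each gene/phenotype belongs to at most one
pair, keeping marginals exact); unpaired entities are independent
Bernoulli draws. The default specification — 50 articles × 100 sentences,
per-sentence marginals between 0.02 and 0.08, and pair strengths spanning
a strong positive association, exact independence, and a
never-co-occurring pair — covers the regimes the NPMI scale
distinguishes, at a size (≈5,000 sentences) where binomial sampling bands
are tight enough to be informative. Expected counts carry
$\sqrt{np(1-p)}$ standard deviations; estimated NPMI is compared with the
analytic NPMI of the planted distribution using a delta-method standard
deviation that propagates the binomial noise of all three counts
including their covariances. All randomness flows from a single seed and
global RNG state is restored on exit.

What the generator does *not* emulate: real scientific prose (templates
are fixed), non-normalized gene symbol forms, abbreviation ambiguity, and
the long-tailed vocabulary of real literature. Passing the recovery tests
therefore demonstrates the correctness of the matching, counting and
scoring machinery — not the real-world recall of the dictionary approach,
which on genuine articles is limited by exactly the phenomena the noise
mode caricatures (an optional distractor mode plants strings such as
"National Cancer Center" to regression-test the known false-positive
modes).

# Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `include_codes` | T047, T048, T184 | semantic types admitted for non-HPO sources |
| `hpo_exclude_codes` | T045, T077, T079, T080, T082, T169 | semantic types excluded for HPO |
| `npmi_min` | 0 (strict) | association filter threshold |
| `count_min` | 5 (strict) | minimum sentence co-occurrence count |
| `case_sensitive` | TRUE | gene symbol matching mode |
| `k` | none | k-means cluster count (corpus-dependent) |
| `perplexity` | min(30, (n−2)/3) | t-SNE perplexity, shrunk for small inputs |
| edge threshold | global mean NPMI | network qualification threshold (≥) |
| `top_fraction` | 0.10 | centrality selection fraction |

# Known limitations

Co-occurrence is not causation; negated and hypothetical statements count
as mentions. Dictionary matching misses phenotype paraphrases absent from
the vocabularies and can fire on non-phenotype noun phrases. Whole-token
case-sensitive gene matching trades recall on non-normalized symbol forms
for precision against abbreviation collisions; both behaviors are
flag-adjustable. Corpus-scale outputs (association counts, concordance
values, selected gene lists) depend on the corpus, the vocabulary
release, and the clustering seed, and are not comparable across runs that
vary any of these.
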