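---
title: "Identifying higher-order biological themes from gene-set enrichment results"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying higher-order biological themes from gene-set enrichment results}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsThemes)
```

## Motivation and model

Gene-set enrichment analyses routinely return hundreds to thousands of
significant gene-sets, largely because knowledgebases (GO, Reactome, KEGG,
MSigDB collections) encode the same biology redundantly and hierarchically.
Reading the top N sets therefore re-reads the same signal. gsThemes
condenses an enrichment result into *higher-order biological themes*:
clusters of mutually overlapping gene-sets, each treated as one
encompassing process, each annotated with keywords, member genes and
protein-interaction context.

The model is deliberately simple and assumption-light:

1. **Gene-sets as binary partitions of the measured-gene universe.** With
   *n* measured genes, each gene-set X is an n-dimensional 0/1 membership
   vector. Similarity between two sets is computed from the 2×2 contingency
   table of joint membership, as the adjusted Rand index (ARI), the Jaccard
   index (JI = n11 / (n01 + n10 + n11)), or the overlap coefficient
   (OC = n11 / min(|X|, |Y|)). The ARI is chance-corrected, which matters
   because two large sets over a small universe overlap substantially by
   chance alone; the OC highlights parent–child containment and is most
   useful within a single hierarchical database.
2. **Thresholding into an overlap graph.** Pairs at or above the similarity
   threshold become weighted edges; sets with no connection are dropped
   from the clustering (but reported — they can still matter biologically).
3. **Walktrap community detection.** Clusters of gene-sets are communities
   found by short random walks (Pons–Latapy), with the merge tree cut at
   maximum modularity. The assumption is that gene-sets sharing many genes
   represent related processes, so communities in the overlap graph are
   coherent higher-order processes.
4. **Prioritisation by product of ranks.** Clusters are ranked by
   size (1 = largest) and by median gene-set statistic (1 = best); the
   product of the two ranks orders the clusters, lower being better. This
   favours large clusters with strong statistics without committing to any
   distributional assumption about the statistic.
5. **Characterisation.** Each theme gets (a) a TF-IDF keyword table mined
   from member gene-set names or descriptions, (b) a gene table pairing
   membership frequency with the experimental statistic, and (c) optionally
   an induced protein–protein interaction subnetwork as an independent line
   of evidence.

A rank-based scoring module (singscore-style) connects the pipeline to
unsupervised workflows: genes are ranked by factor loadings (e.g. a
principal component of single-cell or spatial transcriptomics data), each
gene-set receives the centred normalised mean rank of its members
(range [−0.5, +0.5]), and sets with |score| > 0.2 feed theme detection with
the score as the node statistic.

## Parameters that matter

| Parameter | Default | Meaning and guidance |
|---|---|---|
| `measure` | `"ari"` | ARI or JI for multi-database inputs; OC for one hierarchical database. |
| `threshold` | 0.25 | Similarity cut for edges. Useful ARI thresholds sit around 0.2–0.4: lower values connect more, giving fewer, broader themes; higher values give smaller, more specific themes. Weak inequality (≥) by default, strict available; the choice changes boundary-pair counts and is recorded in the metadata. |
| `steps` | 4 | Walktrap random-walk length (the reference default). Longer walks favour coarser communities. |
| `direction`, `absolute` | larger-better, FALSE | How the median gene-set statistic is ranked. For p-value-like statistics pass a −log10 transform or `direction = "smaller-better"`; for signed two-sided statistics (logFC) `absolute = TRUE` ranks on magnitude. |
| `topTerms` | 25 | Terms retained per theme (keeps word clouds readable). |
| idf log base | e | The idf is log(N/df); natural log by default, base 2 available. Base only rescales tf-idf, never reorders it. |
| score threshold | 0.2 | Absolute singscore cut for factor workflows (strict >; scores are bounded by 0.5). |
| PPI `minConfidence`, `minDegree` | 0, 0 | Confidence and degree filters on induced subnetworks. |

**Universe.** All similarities are computed over the measured-gene universe
(*n*), after restricting every set to it. When `runVisse()` receives a
per-gene statistics table its genes define the universe (measured genes are
the genes with statistics); with neither a universe nor gene statistics the
union of all set members is used so the tool degrades gracefully. The
universe choice genuinely matters: a too-small universe inflates chance
overlap and with it every ARI. Sets emptied by restriction are kept and
flagged, not silently discarded.

## Text annotation pipeline

Names (or short descriptions) of all gene-sets in a cluster form one
document; the reference collection forms the corpus. Text is split on
`_ / @ ( ) |` and whitespace, lowercased, stripped of punctuation; purely
numeric tokens, English stop words (packaged Snowball list) and exclusion
words are removed. The default exclusion list holds database
prefixes/suffixes (kegg, reactome, hallmark, gobp, ...) and is a packaged,
user-replaceable file — informative words such as "pathway" or "signaling"
are deliberately kept. Lemmatisation is dictionary-plus-rule based (a small
exception table, then regular plural stripping) and runs after stop-word
removal, with exclusions re-applied to the lemmas; the lemmatiser maps
unknown words to themselves, so it can never invent terms. Term frequency
is the raw count in the cluster document (no length normalisation; a
relative-frequency mode exists), idf = log(N/df) over the corpus, and up to
25 terms with the highest tf-idf represent the theme, ties broken
alphabetically. Terms absent from the corpus — possible when cluster text
and corpus source differ — are scored with df = 1 (maximal idf) and
flagged rather than dropped.

## Numerical and degenerate-case choices

- **ARI arithmetic.** Binomial coefficients are computed exactly in double
  precision and the expected-index term is factored as A·B / C(n,2) before
  any multiplication, keeping magnitudes small; agreement with an
  independent adjusted-Rand implementation is tested to 1e−12.
- **ARI degeneracy.** When the denominator is zero both membership
  partitions are trivial one-block partitions, hence identical as
  partitions; the conventional value 1 is returned (complementary proper
  subsets need no convention — the formula itself yields 1).
- **JI/OC conventions.** Both-empty pairs score 0 (JI); either-empty pairs
  score 0 (OC).
- **Deterministic clustering.** Walktrap is deterministic for a fixed
  graph; cluster ids are additionally renumbered by lexicographically
  smallest member so outputs are stable under any internal relabelling.
  Rank ties use midranks; rank-product ties break by better statistic
  rank, then cluster id.
- **Missing statistics** take the worst statistic rank at the cluster
  level, and are flagged (not dropped) at the gene level.
- **PPI degree filter.** Degree is computed once on the confidence-filtered
  induced graph; nodes below `minDegree` are removed with their edges, and
  nodes left isolated by that removal are removed too. There is no
  iteration to a fixpoint — on a star with `minDegree = 2` the leaves go
  first and the hub, now isolated, follows, yielding an empty network. The
  single-pass rule is simple to reason about and reproducible.
- **PPI dedup.** Duplicate records of an unordered pair keep the maximum
  confidence; a merged edge counts as ortholog-inferred only if every
  contributing record was inferred, so native evidence always wins.

## The synthetic benchmark

`simulateCollection()` generates collections whose truth is known at every
level: K themes with disjoint gene pools (an overlap parameter allows
correlated themes), s sets per theme sampling a fraction f of the pool plus
q background genes, names built from a planted theme keyword plus filler
tokens, and gene statistics drawn from theme-specific normal distributions.
The defaults (n = 5000 genes, K = 5 themes, 20 sets per theme, pool 150,
f = 0.4, q = 10 noise genes, theme means 2–4 against sd 0.5) give moderate
within-theme Jaccard overlap (~0.25) and zero structural between-theme
overlap — roughly the regime of a redundant pathway database restricted to
an expression experiment, at a size that keeps the full validation suite
fast.

What the generator emulates: redundancy within themes, noise membership,
theme-correlated statistics, database-style naming. What it does not:
hierarchical (nested) set structure, long-tailed set-size distributions,
correlated significance from a real differential-expression analysis,
inconsistent human naming, and between-theme gene sharing (unless enabled).
Passing the planted-recovery tests therefore shows the machinery is
correct, not that any particular threshold is optimal for a given real
dataset — threshold choice on real data remains the analyst's decision.

## A complete run

```{r, eval = FALSE}
sim <- simulateCollection(seed = 42)
bundle <- runVisse(sim$collection, sim$setStats, sim$geneStats,
                   universe = universe(sim$collection))
bundle$clusterTable
head(bundle$termTables[["1"]])
head(bundle$geneTables[["1"]])
```

With real inputs, `collection` is a GMT path, `setStats` the per-set
statistics TSV from any enrichment method (limma::fry, fgsea, singscore
scores, ...), and `geneStats` the per-gene statistics (logFC, loadings).
The factor workflow first scores a collection against loadings:

```{r, eval = FALSE}
scores <- scoreCollection(collection, loadings)
selected <- selectScoredSets(scores, threshold = 0.2)
bundle <- runVisse(collection[selected$set_name], selected, geneStats)
```

## Validation design

Every stage is checked against an independent route: similarities against
brute-force recomputation from raw sets (and, for ARI, a standard
adjusted-Rand implementation on label vectors, to 1e−12); walktrap against
a self-contained Pons–Latapy reference implementation written for the test
suite; cluster ordering against hand-computed rank products; idf against
closed-form values; factor scores against the closed-form bounds and a
worked example; and the whole pipeline against planted ground truth
(recovery adjusted Rand and keyword recovery, each summarised as a median
over 20 generator seeds). `scripts/acceptance.R` re-runs this validation
from scratch and writes the resulting numbers as JSON.

## Known limitations

- Semantic (ontology-graph) similarity is out of scope; similarity is
  purely membership-based.
- Clustering quality inherits walktrap's behaviour on very dense graphs;
  alternative algorithms are an extension point, not an option today.
- The annotation quality depends on naming quality of the input
  collections; inconsistently named collections (e.g. perturbation
  signatures) yield weak word clouds.
- The default exclusion list is an editable approximation, not a frozen
  vocabulary.
- Identifier namespaces are the caller's responsibility throughout (no
  symbol/Entrez conversion), including in PPI and ortholog tables.
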