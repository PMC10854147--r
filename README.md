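# gsThemes

Higher-order biological theme discovery from gene-set enrichment results.

Gene-set enrichment analyses of transcriptomics experiments routinely
return hundreds to thousands of significant gene-sets, most of them
redundant: related pathways reach significance through the same underlying
genes, and hierarchical knowledgebases (GO, Reactome, KEGG, MSigDB) encode
the same biology at many resolutions. gsThemes is for analysts who want to
read such a result as a handful of *higher-order biological themes* rather
than a top-N list — and then drill from each theme down to its gene-sets,
its keywords, its genes, and its protein-interaction context.

## Method

Given n measured genes, every gene-set is an n-dimensional binary
membership vector. For each pair of sets X, Y a 2×2 contingency table over
the universe gives

- adjusted Rand index: ARI = (Σᵢⱼ C(nᵢⱼ,2) − [Σᵢ C(aᵢ,2) Σⱼ C(bⱼ,2)]/C(n,2)) /
  (½[Σᵢ C(aᵢ,2) + Σⱼ C(bⱼ,2)] − [Σᵢ C(aᵢ,2) Σⱼ C(bⱼ,2)]/C(n,2))
- Jaccard index: JI = n₁₁ / (n₀₁ + n₁₀ + n₁₁)
- overlap coefficient: OC = n₁₁ / min(a₁, b₁)

The similarity matrix is thresholded (default ARI ≥ 0.25) into a weighted
overlap graph; disconnected sets are dropped and reported. Walktrap
community detection (Pons–Latapy random walks, merge tree cut at maximum
modularity) identifies clusters of gene-sets — the themes. Themes are
ordered by the product of their size rank and their median-statistic rank
(lower product = higher priority), annotated with TF-IDF keyword tables
(tf over the cluster's concatenated set names, idf = log(N/df) over the
reference corpus, top 25 terms), characterised by per-gene membership
frequency against experimental statistics, and optionally contextualised
with induced protein–protein interaction subnetworks (max-confidence
deduplication, ortholog inference, confidence/degree filtering).

A rank-based (singscore-style) module scores gene-sets against factor
loadings — score = (R̄ − (m+1)/2)/(n−m) − ½ ∈ [−0.5, 0.5] for a set of m
ranked members — so principal components of single-cell or spatial data
can be interpreted by running theme discovery on sets with |score| > 0.2.

## Worked example

The packaged generator plants known themes so the whole pipeline can be
demonstrated (and validated) without downloads:

```r
library(gsThemes)
sim <- simulateCollection(seed = 42)   # 5 themes x 20 sets, 5000 genes
bundle <- runVisse(sim$collection, sim$setStats, sim$geneStats,
                   universe = universe(sim$collection))
```

```
input: 100 gene-set(s), universe of 5000 gene(s), 0 empty after restriction
overlap graph (ari >= 0.25): 100 node(s), 926 edge(s); dropped 0 disconnected set(s)
walktrap: 5 cluster(s)
```

```r
bundle$clusterTable[, c("cluster", "size", "medianStat", "rankProduct", "order")]
#>   cluster size medianStat rankProduct order
#> 1       1   20   3.468441           3     1
#> 2       5   20   2.923690           6     2
#> 3       2   20   2.556856           9     3
#> 4       4   20   2.145705          12     4
#> 5       3   20   1.725700          15     5
```

All five planted themes are recovered; sizes tie (size rank 3 each), so the
product of ranks orders the themes by their median gene-set statistic.
The top theme's keyword table identifies its planted vocabulary:

```r
head(bundle$termTables[["1"]], 3)
#>           term tf      idf     tfidf rank
#> 1     adhesion 20 1.609438 32.188758    1
#> 2 organization  6 1.714798 10.288791    2
#> 3    component  5 1.966113  9.830564    3
```

"adhesion" appears in all 20 member set names but only in 20 of the 100
corpus sets (idf = ln 5), so its tf-idf dominates the filler vocabulary.
The gene table surfaces genes that are frequent in the theme *and* strong
in the experiment:

```r
head(bundle$geneTables[["1"]], 3)
#>     gene frequency statistic
#> 1 g00660        13  3.751367
#> 2 g00661        12  4.429730
#> 3 g00706        12  4.249842
```

With real data, pass a GMT path, the per-set statistics TSV of any
enrichment method and a per-gene statistics TSV; `writeReportBundle()` (or
`outDir=`) writes clusters, term tables, gene tables, graphs and metadata
to disk. A command-line front end with stage subcommands (`run`,
`simulate`, `similarity`, `network`, `cluster`, `annotate`, `genes`,
`ppi`) ships at `inst/scripts/gsthemes.R`.

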