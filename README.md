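# gretarget

Integrative ranking of differentially expressed genes by their likelihood
of being **direct transcription-factor targets**, built around the workflow
used to nominate glucocorticoid-receptor (GR) targets in human pancreatic
islets and beta-cells.

A perturbation experiment (e.g. dexamethasone treatment) yields hundreds to
thousands of differentially expressed (DE) genes, most of them downstream
of secondary regulation. `gretarget` combines the factor's ChIP-seq binding
sites with accessible-chromatin annotation, enhancer–target association
scores and binding-motif occurrences to pull the probable *direct* targets
out of that list.

## The method

1. **Responsive elements.** Each gene is associated with every ChIP peak
   whose centre lies within a window of its TSS (default 150 kb), giving
   signed peak–TSS distances and a proximal/distal label at 3 kb. For GR
   these peak–gene associations are the glucocorticoid responsive elements
   (GREs).
2. **Regulatory potential and function prediction.** Per gene,
   `RP = Σᵢ exp(−(0.5 + 4·dᵢ/10⁵))` over its associated peaks (dᵢ the
   absolute TSS distance in bp). Genes are ranked by RP from high to low
   and the cumulative fractions of up-regulated, down-regulated and non-DE
   (background) genes are compared along the ranking with one-sided
   two-sample Kolmogorov–Smirnov tests — an activating factor concentrates
   its up-genes at high RP.
3. **Annotation scores.** Per DE gene: the *Open Chromatin Score* (sum over
   its peaks of the overlapped chromatin-class weight), the
   *Enhancer-Target Score* (sum of enhancer–gene association scores for
   peaks overlapping enhancers annotated to that gene), and the *motif
   number* (count of primary-motif hits at exact p < 10⁻⁴, computed by a
   FIMO-style dynamic programme over the discretised log-odds score null).
4. **Normalized Annotation Score and rank product.** The three features are
   min-max scaled to [0, 1] (`(x − min)/(max − min)`) and summed into the
   NAS ∈ [0, 3]. With `rank_DEC` the gene's rank by Differential Expression
   Change (|log2FC|, rank 1 highest) and `rank_NAS` its rank by NAS,

   `rank product = (rank_DEC / n) · (rank_NAS / n)`,

   n the number of DE genes. Low rank products mark probable direct
   targets.
5. **NAS-only mode.** For a factor without its own perturbation data, genes
   are associated at 100 kb, associations are hard-filtered to
   open-chromatin overlap, and candidates are ranked by NAS alone.

A seeded synthetic-data generator (`simulate_target_dataset()`) builds a
complete miniature input universe — gene table with DE statistics, peaks,
open chromatin with a class-weight table, enhancer links, peak sequences
with planted motif instances, bulk and single-cell matrices — with known
planted direct targets, so the whole pipeline is testable without any
external download.

## Worked example

```r
library(gretarget)
library(dplyr)

bundle  <- simulate_target_dataset(synthetic_config(seed = 17))
weights <- setNames(bundle$class_weights$weight, bundle$class_weights$chromatin_class)

ranking <- rank_direct_targets(bundle$genes, bundle$peaks, bundle$open_chromatin,
                               weights, bundle$enhancers, bundle$pwm, bundle$sequences)
ranking |> select(gene_id, log2fc, n_gres, nas, dec, rank_dec, rank_nas, rank_product)
#> # A tibble: 304 × 8
#>   gene_id   log2fc n_gres   nas   dec rank_dec rank_nas rank_product
#>   <chr>      <dbl>  <int> <dbl> <dbl>    <dbl>    <dbl>        <dbl>
#> 1 gene_0725   3.68     10 2.39   3.68        2        4    0.0000866
#> 2 gene_0019   3.29      8 2.45   3.29        9        3    0.000292
#> 3 gene_0025   2.44      9 2.74   2.44       29        1    0.000314
#> 4 gene_0004  -3.96      3 0.806  3.96        1       41    0.000444
#> 5 gene_0508  -2.56     10 2.56   2.56       26        2    0.000563
#> # ℹ 299 more rows
```

304 of the 1000 simulated genes are DE; the table interleaves every
intermediate quantity (peak count, NAS, DEC, both ranks) so a ranking can
be audited. Here 48 of the 50 planted direct targets land in the top 50
rows:

```r
sum(head(ranking$gene_id, 50) %in% bundle$truth$direct_target_ids)
#> [1] 48
```

Distance structure and activator/repressor call on the same data:

```r
gres <- assign_peaks_to_genes(bundle$peaks, bundle$genes)
distal_fraction(gres)
#> [1] 0.963

fp <- function_prediction(regulatory_potential(gres, genes = bundle$genes), bundle$genes)
fp
#> <function_prediction> 154 up / 150 down vs 696 background genes
#>   KS (greater): up D=0.119 p=0.0282; down D=0.139 p=0.00868
```

Both DE directions sit at significantly higher regulatory potential than
the non-DE background — the planted coupling between binding and
expression change is detected. `autoplot(fp)` draws the cumulative curves,
`autoplot(ranking)` the rank-product profile; `tidy()`/`glance()` give
broom-style summaries.

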