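---
title: "Methods: scoring genes as direct transcription-factor targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring genes as direct transcription-factor targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gretarget` implements an integrative procedure for deciding which
differentially expressed (DE) genes in a transcription-factor perturbation
experiment are plausibly *direct* targets of the factor. This vignette
documents the model, its tunable parameters, the numerical choices, and
what the synthetic validation data do and do not establish.

## Peak-to-gene association

A ChIP peak is associated with every gene whose TSS lies within a window
of the peak anchor (default 150 kb, inclusive at the boundary). Both sides
of the TSS count, a peak can serve several genes and a gene several peaks.
Associations at or below 3 kb are *proximal*, those from 3001 bp to the
window edge *distal*.

Open choices, and how they were fixed:

* **Anchor.** The distance is measured from the floor of the peak midpoint
  to the TSS. A ChIP peak summit is usually near its centre and the
  midpoint is well-defined for any input; `anchor = "nearest_edge"`
  (distance 0 when the TSS falls inside the peak) is available for
  sensitivity analysis.
* **Coordinates.** All intervals are 0-based half-open (BED convention);
  two half-open intervals overlap iff they share at least one base, with
  no minimum-overlap fraction. 1-based inputs must be declared at the
  reading boundary (`read_bed(one_based = TRUE)`); chromosome names are
  never normalised.
* **TSS.** Gene tables supply the TSS directly; a converter from
  annotation with start/end would use the start for `+` genes and the end
  for `-` genes.

## Regulatory potential and function prediction

Per gene, `RP = sum_i exp(-(offset + k * d_i / decay_scale))` with
defaults `offset = 0.5`, `k = 4`, `decay_scale = 1e5` bp. This is the
binding-and-expression-association form in which a site at the TSS
contributes `exp(-0.5) ≈ 0.61` and the contribution decays e-fold every
25 kb; all three constants are arguments of `regulatory_potential()`. The
score is additive over sites, zero for a gene with none, and strictly
increased by every added site.

`function_prediction()` sorts genes by RP (descending, ties broken by
gene id for determinism) and accumulates the fraction of up-regulated,
down-regulated and background genes along the ranking. The background is
the non-DE genes by default — an `"all"` option exists because the
alternative reading (every gene as background) is defensible. Each DE
direction is compared with the background by a two-sample
Kolmogorov–Smirnov test on the rank distributions. The test is one-sided
by default ("the DE group sits at higher regulatory potential"), because
the scientific question is directional — does the factor's binding
concentrate near its responders; the two-sided variant is an argument.
P-values use the asymptotic approximation (`exact = FALSE`), which is what
keeps the test well-behaved under the heavy rank ties produced by
zero-score genes.

## Motif scanning with exact p-values

Scores are log2 odds of the pseudocounted motif probability over a 0-order
background, `p' = (p + 0.1 * bg) / 1.1` (pseudocount 0.1, an argument).
The null distribution of the window score under i.i.d. background letters
is computed exactly by dynamic programming over integer-discretised column
scores; scanning then happens in the same integer score space, so the
p-value attached to a hit is exact for its discretised score. The
discretisation step (default 1/1000 bit) is the single approximation in
the motif stack, and the test suite pins the dynamic programme against
exhaustive enumeration of all `4^L` words for widths up to 8.

Retention uses strict `p < 1e-4` (stringent) and `p < 1e-3` (lenient)
thresholds. Because the null is discrete, the largest attainable p-value
below a threshold — not the threshold itself — is the per-window
false-positive rate; the scanning test uses that value as its Poisson
expectation. Both strands are scanned by default; a minus-strand hit is
reported at its forward-strand offset. Windows containing non-ACGT bases
are skipped by default (`ambiguous = "background"` scores them with a
zero log-odds contribution instead). The background model defaults to
uniform and can be supplied per motif; composite-element summaries
(`composite_element_stats()`) report motif co-occurrence fractions whose
observed values are data-dependent, so the package treats them as
simulation-recovery properties rather than fixed constants.

## Annotation scores, NAS, rank product

* **Open Chromatin Score**: per peak, the *maximum* class weight among
  overlapped open-chromatin regions (stacked annotations should not double
  count; a `sum` rule is a flag), summed over the gene's peaks.
* **Enhancer-Target Score**: sum of association scores over (peak,
  enhancer) overlap pairs whose enhancer targets that same gene.
* **Motif number**: count of stringent primary-motif hits over the gene's
  peaks; a peak shared by two genes counts for both.

The three features are min-max scaled across the ranked gene set; a
degenerate feature (max = min) scales to all zeros rather than NaN. Their
sum is the Normalized Annotation Score (NAS, range 0–3). The Differential
Expression Change (DEC) defaults to |log2FC| — the source procedure never
defines it beyond "fold-change values", and the absolute value treats
activation and repression symmetrically; signed log2FC and −log10 padj are
config options recorded in the output's `config` attribute. Ranks are
descending (rank 1 = largest), ties share the mean rank, and
`rank_product = (rank_DEC/n) * (rank_NAS/n)`.

Genes with zero associated peaks stay in the ranking with all-zero
annotation scores so that `n` equals the DE-gene count; dropping them
would silently shrink the rank-product denominator. In the NAS-only factor
mode (default window 100 kb) open chromatin acts instead as a *hard
filter*: candidate genes must retain at least one open-chromatin-
overlapping peak, and are then sorted by NAS descending.

## The synthetic-data generator

`simulate_target_dataset()` draws a miniature input universe: 1000 genes
over 4 chromosomes of 50 Mb; 50 planted direct targets with Poisson(5)
peaks against Poisson(1) for background genes; peak–TSS distances 5%
proximal (uniform within 3 kb) and otherwise log-uniform on 3–140 kb,
mimicking the strongly distal character of nuclear-receptor binding
(expected distal fraction ≈ 95%); open-chromatin overlap probability
0.9 vs 0.25 and enhancer-link probability 0.8 vs 0.1 for direct vs
background peaks; motif planting probability 0.9 vs 0.1 per peak using a
15-bp inverted-repeat receptor-like matrix; |log2FC| ~ N(2.5, 0.6) for
direct targets, N(1.2, 0.4) for the 25% of other genes that are
indirect-DE, N(0, 0.15) otherwise. Sequences are 0-order background at
GC 0.41 with consensus instances planted at recorded offsets and strands.
Every output stream draws from its own seed derived from the master seed,
so disabling one stream (e.g. sequences) never perturbs another, and
identical configurations produce byte-identical written bundles.
`simulate_null_dataset()` keeps every marginal and permutes the expression
columns across genes, breaking the label–feature coupling.

What the generator does *not* emulate: higher-order sequence composition,
chromatin-state autocorrelation along the genome, realistic gene-density
or peak-width distributions, correlated biological replicates, or mapping
noise. Recovery results on synthetic data therefore demonstrate that the
implementation measures what it claims under known ground truth — not
that real direct targets will be recovered at those rates.

## Validation experiment sizes

The test suite and the acceptance script run: the default 1000-gene
recovery experiment (50 planted targets, expecting ≥ 45 of them in the
rank-product top 50 at the default seed); a 500-gene NAS-only recovery
(30 planted targets, ≥ 80% in the top 30); a type-I experiment of 300–500
null datasets of 250 genes each with equalised peak rates, whose KS
rejection rate at α = 0.05 must stay within 3 binomial SDs of 0.05; and a
DE-overlap reconstruction at the scale of two deposited DE lists (581
shared genes, 309 up- and 272 down-concordant, planted in synthetic
tables and recomputed). These sizes keep each experiment well inside a
minute or two on one CPU while leaving the binomial bands tight enough to
detect calibration errors.

## Known limitations

* The rank product is used as an ordering; no permutation p-value is
  attached to it.
* De novo motif discovery is out of scope: the primary and auxiliary
  motifs are user-supplied PWMs (MEME minimal format).
* Enhancer tables must be pre-converted to the package's five-column
  dialect; database-specific dump formats are not parsed.
* The exact-p scanner is quadratic in sequence length times motif width in
  pure R; it is comfortable at the tens-of-megabases scale of peak sets,
  not whole-genome scans.
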