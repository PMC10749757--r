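---
title: "Comparing gene expression across species with variability, diversity and specificity metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing gene expression across species with variability, diversity and specificity metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossGEx)
```

## Why relative, not direct, comparison

Directly comparing expression levels of orthologous genes between species
is confounded by annotation depth, library composition, batch structure
and genuinely different baseline expression. crossGEx therefore compares
*patterns*: for each gene (or tissue) within one species it computes
summary metrics — coefficient of variation across tissues or species, and
Shannon-entropy diversity and specificity of the expression profile — and
the cross-species comparison happens between these per-species summaries.
The metrics are descriptive visual aids; they are not test statistics and
should not feed downstream inference.

Six species are supported (human, mouse, rat, zebrafish, fly, worm),
keyed by short name with NCBI taxon-id aliases. Ortholog resolution uses
local HomoloGene-style group tables; identifier conversion uses local
cross-reference tables. Both are deliberately file-driven so that an
analysis is hermetic and reproducible without network access.

## The preprocessing model

The metrics consume variance-stabilized (VST) expression values. The
model is the standard negative-binomial mean-dispersion family with a
parametric trend

$$\alpha(\mu) = a_0 + \frac{a_1}{\mu},$$

where $a_0$ (dimensionless, $>0$) is the asymptotic dispersion dominating
at high expression and $a_1$ ($\ge 0$) the extra-Poisson term dominating
at low expression, giving variance $(1+a_1)\mu + a_0\mu^2$. The trend is
fitted by per-gene moment estimates
$\hat\alpha_g = \max(0, (s^2_g-\bar\mu_g)/\bar\mu_g^2)$ and an unweighted
least-squares regression of $\hat\alpha$ on $1/\bar\mu$ over genes with a
positive moment estimate and mean above 1; at least 10 usable genes are
required, otherwise the fit fails loudly. After the fit $a_0$ is floored
at $10^{-8}$ and $a_1$ at 0, because the closed-form stabilizer below is
undefined at $a_0 \le 0$ (near-Poisson data can otherwise fit a slightly
negative intercept).

The stabilizer itself is the closed form for this family,

$$f(q) = \log_2\!\frac{1 + a_1 + 2a_0 q +
  2\sqrt{a_0 q\,(1 + a_1 + a_0 q)}}{4 a_0},$$

which is strictly increasing, applied elementwise, and satisfies
$f'(q) = \sqrt{a_0} \big/ \big(\ln 2\,\sqrt{(1+a_1)q + a_0 q^2}\big)$ —
i.e. it equals the stabilizing integral
$\int\! d\mu/\sqrt{\mathrm{Var}(\mu)}$ rescaled by $\sqrt{a_0}/\ln 2$ so
that it behaves like $\log_2 q$ for large $q$. The test suite anchors the
implementation against numerical quadrature of that integral and against
a direct variance-flatness check on simulated negative-binomial data.
Because TPM values are count-like in their mean-variance behaviour, the
fit and transform accept any nonnegative matrix, not only integers. A
`log2(x+1)` fallback exists behind an explicit flag (`fallbackLog2`) for
tables with too few genes to fit a trend; it is never the default.

Two choices here were genuinely open and are recorded as this package's
own conventions: the trend is fitted **per species** (each species' table
is its own fit, noted in the result's provenance), and median aggregation
uses the conventional midpoint for even sample counts.

## The metrics

**Coefficient of variation.** `computeCV()` is the sample standard
deviation (denominator $n-1$) divided by the **median**, a deliberately
robust denominator for the skewed profiles typical of expression data.
`cvAnalysis()` offers two modes: `cv_tissue` gives one CV per (gene,
species) across that species' tissues, and `cv_species` one CV per (gene,
tissue) across species, after ortholog ids have been harmonized upstream.
By default the CV runs over per-group **medians** of the VST values
(`on = "medians"`); medians are computed before any cross-group
comparison, and a config switch (`on = "samples"`) exposes the pooled
sample-level alternative since either reading is defensible.

**Diversity and specificity.** Per species, the pipeline is: per-(gene,
tissue) medians of VST values; per-gene min–max rescaling of the median
profile (preserving shape and ranks while mapping onto $[0,1]$);
normalization to a probability profile. For a gene profile $p$ over $T$
tissues,

$$D = \frac{H(p)}{\log_2 T}, \qquad
  S = \frac{KL(p\,\|\,\mathrm{uniform})}{\log_2 T} = 1 - D,$$

so both metrics are in $[0,1]$ and exactly complementary at gene level —
a uniformly expressed gene scores $(1, 0)$, a one-tissue gene $(0, 1)$.
At tissue level, diversity is the normalized entropy of the tissue's
profile over genes, and specificity is the expression-weighted mean of
the genes' unnormalized specificities,
$\sum_g q_{g|t}\,(\log_2 T - H(p_g)) / \log_2 T$: a tissue expressing
mostly tissue-restricted genes scores high. Tissue diversity and
specificity are *not* complements, which is why tissue points sit off the
anti-diagonal in diversity–specificity scatter plots.

Min–max scaling is applied **per gene row** (each gene's profile within
one species), so each profile lives on its own $[0,1]$ scale; scaling the
whole matrix instead would let a single highly expressed gene flatten
every other profile. Degenerate rows need a convention: a gene expressed
at the same *nonzero* level in every tissue has no range to rescale and
is treated as uniformly expressed (diversity 1) with a
`degenerate_uniform` flag; an all-zero row is reported missing
(`all_zero`), never silently zero-filled. Probability profiles keep their
zeros and must sum to 1 within $10^{-12}$.

The four analysis modes slice the same median matrix differently:
`ds_gene` scores selected genes over selected tissues, `ds_gene_all` over
all tissues, `ds_tissue` scores selected tissues over selected genes,
`ds_tissue_all` over all genes. In gene modes the matrix keeps all genes
(row scaling is per gene, so co-selected genes cannot influence each
other) and the selection only picks which units are reported; in tissue
modes the gene selection restricts the matrix itself because tissue
profiles run over genes. `ds_gene` on the full tissue set equals
`ds_gene_all` by construction, and the suite asserts it.

## What the synthetic generator emulates

`simulateCounts()` draws negative-binomial counts with mean
$\mu_{g,s,t}$ = baseline × per-effect fold factors and variance
$\mu + \alpha(\mu)\mu^2$ using the same trend parametrization as the
preprocessing — deliberately closing the loop so the dispersion fit can
be validated against known truth. Effects are per gene, optionally
per species: `flat`, `tissue_specific(tissue, fold)`,
`species_variable(species, foldProfile)` and `high_var(spread)`. The
`high_var` profile is a *deterministic* symmetric log-spaced ladder of
tissue folds from `1/spread` to `spread`; making the spread deterministic
(rather than drawing random folds) means the designed ordering "this gene
is the most variable across tissues" is a property of the design, robust
across seeds, while NB sampling noise still perturbs every value.

`makeExampleExpression()` is the five-gene demonstration: 5 genes ×
2 species × 5 tissues × 4 samples per cell, baseline mean 100 counts,
dispersion $(a_0, a_1) = (0.05, 2)$. Genes 1, 3, 4 are flat; gene5 is
`high_var(spread = 8)` in both species; gene2 is
`tissue_specific(tissue1, fold = 8)` in the first species and flat in the
second. Baseline 100 puts the VST values near 6.6 with fold-8 effects
moving them by ±3 — large against the ≈0.2 noise of a 4-sample tissue
median, which is what makes the designed orderings (gene5 most variable
everywhere; gene2 the largest cross-species CV gap; gene2 specific in
species 1 but diverse in species 2) hold in ≥95 of 100 seeds, as the
acceptance suite verifies ordinally. Because only five genes are
simulated, the demonstration pipeline applies the VST directly to the
simulated counts with the generating trend: per-sample TPM normalization
over five genes is dominated by compositional coupling (boosting one gene
deflates the other four), which would corrupt the designed flat genes.
`tpmFromCounts()` is independently implemented and tested for real,
genome-scale use.

What the generator does **not** emulate: library-size heterogeneity,
batch structure, correlated tissue programs, or realistic ortholog
divergence. A passing suite therefore shows the metrics behave as
designed on clean NB data with known effects; it does not certify
behaviour on curated public expression compendia.

## Numerical conventions and edge cases

* CV is missing with reason `insufficient_values` below 2 finite values
  and `zero_median` when $|\mathrm{median}| < 10^{-12}$.
* Profiles failing nonnegativity or normalization raise validation
  errors; nothing is silently renormalized.
* Empty median cells are `NA` and propagate as missing.
* One-to-many identifier or ortholog resolutions are returned
  exhaustively with `ambiguous` / `one_to_many` flags; the package never
  collapses them to a first match, and metric runs expect the user to
  resolve them first.
* Output TSVs are sorted by each result type's natural key and floats
  rendered at 6 significant digits, so reruns are byte-identical.

## Problem sizes

The shipped tests and the reproduction script use: 1000 fuzzed profiles
for the entropy oracle; 20 random trends × 9 quadrature points for the
VST oracle; 500 genes × 50 samples for dispersion recovery; 100 seeds of
the 200-record demonstration dataset for the ordinal pattern checks.
These sizes give stable results (Monte-Carlo error well inside the
asserted margins) while keeping a full run in well under a minute.

## Limitations

Tissue vocabularies are free-text exact-match — no ontology resolution,
so cross-dataset tissue harmonization is the user's job. HomoloGene-style
group files and identifier cross-references must be supplied locally.
When HomoloGene-derived and annotation-pipeline-derived ortholog tables
disagree, the package keeps them as separate inputs and the user chooses
one per call; no merging heuristic is applied.
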