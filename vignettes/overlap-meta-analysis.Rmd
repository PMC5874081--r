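---
title: "Signed gene-set overlap meta-analysis: models and methods"
author: "degOverlap maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signed gene-set overlap meta-analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degOverlap)
```

## The problem

When a chromatin regulator is perturbed — say a histone deacetylase
complex in *Arabidopsis* — the resulting lists of differentially
expressed genes (DEGs) are routinely compared against gene lists from
other perturbations and against binary chromatin annotations such as
"genes with high H2A.Z enrichment in their gene bodies" or "H3K9
acetylated genes". The scientific question is whether two lists share
more genes than chance would allow, and whether the shared genes move in
the same direction. Because the lists come from different labs, tissues
and platforms, the only safe join key is the locus-level gene
identifier, and the only honest null model is one the analyst controls
explicitly.

degOverlap packages that analysis: signed DEG lists, hypergeometric
overlap tests, directional concordance partitions, stratified overlaps
against annotation tracks, Monte Carlo calibration of the overlap
p-values, Fisher-exact enrichment with Benjamini–Yekutieli correction,
and the two-factor interaction ANOVA used for the companion phenotype
claims (genotype-by-environment reaction norms).

## The overlap model

Fix a gene universe of size $N$. For two gene sets $A$ and $B$ with
$|A| = n_a$, $|B| = n_b$, both restricted to the universe, the overlap
size $X = |A \cap B|$ under random, independent draws is
hypergeometric. The enrichment statistic is the upper tail

$$ p = P[X \ge k] \;=\; \sum_{j=k}^{\min(n_a, n_b)}
   \frac{\binom{n_a}{j}\binom{N-n_a}{n_b-j}}{\binom{N}{n_b}}. $$

The test is one-sided for enrichment by design: the meta-analyses this
supports report "significant overlap" or "not significant" and never
depletion. A lower-tail flag exists (`tail = "lower"`) for depletion but
is never the default.

**Numerics.** Observed overlaps can be so extreme that the tail
probability underflows double precision if computed naively. The sum is
therefore accumulated in log space from `lchoose()` (log-gamma) terms
with a log-sum-exp reduction; results are exact to ~1e-15 relative error
against direct summation (checked for all margins with $N \le 25$) and
remain positive down to the smallest positive normal double. A p-value
is never reported as 0. When $k$ equals the minimum feasible overlap
$\max(0, n_a + n_b - N)$ the result is exactly 1.

**The universe matters.** Every p-value conditions on $N$. The analyses
this package emulates never published their universe size, so
degOverlap makes $N$ an explicit input everywhere and defaults the
synthetic universe to 27,416 genes — a stand-in for the TAIR10
protein-coding gene count, clearly a package choice, not a published
value. Inputs are always restricted to the universe first
(`restrictToUniverse()`), so the marginals are well defined; dropped
genes are reported.

## Directional partitions

When both lists carry per-gene directions (+1 up, −1 down), the overlap
decomposes into four classes: concordant up, concordant down, and the
two discordant classes (up in A but down in B, and the mirror). The
class counts always sum to $k$. Each class also receives its own
upper-tail p-value. The margins for those per-class tests are the
per-direction sublist sizes — e.g. the up-genes of A versus the up-genes
of B over the same $N$ — because the class-specific question is "do the
up-regulated genes of A preferentially appear among the up-regulated
genes of B". The source analyses never state their choice of margins;
conditioning on the full list sizes instead would reuse the same margins
for all four classes and could not distinguish them. This is the one
place the package had to commit to a convention; it is applied
uniformly and logged in every report row.

## DEG lists and merging

A DEG is a gene with Benjamini–Hochberg adjusted p-value strictly below
the threshold (default $\alpha$ = 0.05, `padj < alpha` exactly as the
convention prints it), signed by its log2 fold change. A gene passing
the filter with a fold change of exactly zero has no direction and is
an error rather than a silent guess.

Cross-dataset "compiled" lists are built by
`mergeDirectionConsistent()`: the union of members across datasets,
excluding any gene observed up in one dataset and down in another.
Genes absent from a dataset are "not measured", never a conflict. Union
rather than intersection is the default because the compiled lists this
mirrors grow with each added dataset while excluding
direction-inconsistent genes; an `"intersection"` mode is exposed for
the stricter reading. The merge is order-invariant, and
$|\mathrm{merge}| = |A \cup B|$ exactly when no conflicts exist.

## Monte Carlo null calibration

A hypergeometric p-value is only as credible as its independence
assumptions, so the package rebuilds the null empirically: `simulateNull()`
draws $K$ random pairs of gene lists from the universe (sizes uniform
over [500, 2000] by default, each list sampled without replacement,
lists independent of each other) and records the overlap p-value of
each pair. `empiricalPercentile()` then locates an observed p-value in
that distribution; the add-one estimate $(\#\{p_{null} \le p_{obs}\}+1)/(K+1)$
is the recommended empirical p-value. Observations smaller than the
simulated minimum are flagged "outside the null".

Choices worth stating:

* The two list sizes of a pair are drawn independently (the source
  protocol does not say whether one or two sizes were drawn; two
  independent draws is the less constrained reading).
* The full-scale default is $K = 100{,}000$; the test suite runs
  $K = 10{,}000$, which puts ~3 Monte Carlo standard errors at about
  0.007 on the CDF at 0.05 — tight enough to verify super-uniformity.
* One seeded generator is consumed in the documented order (size_a,
  list_a, size_b, list_b per replicate); the generator algorithm is
  recorded in the serialized output, so runs are reproducible across
  platforms with the same RNG.
* The null is deliberately unmatched: no attempt is made to resample
  lists matched on expression level, GC content or chromatin state.
  Observed p-values calibrated against it answer "is this overlap
  larger than random gene sampling allows", nothing stronger.

## Enrichment tests and multiple testing

Flat-annotation enrichment (the GO-style question, without any ontology
machinery) is a one-sided Fisher exact test. For the 2×2 table
$(a, b, c, d)$ the enrichment tail equals the hypergeometric upper tail
with margins $(a+b)$ and $(a+c)$ over $N = a+b+c+d$, and
`fisherExactUpper()` computes it exactly that way, so the two routes
cannot disagree. Families of enrichment p-values are adjusted with
Benjamini–Yekutieli (`stats::p.adjust(method = "BY")`), the FDR control
valid under arbitrary dependence — appropriate because annotation
categories overlap heavily. BY inflates by the harmonic sum
$c(m) = \sum_{i \le m} 1/i$ and is therefore never below BH, which is
never below the raw p-values; the suite asserts this ordering.

## Phenotype statistics

The phenotype side of such studies asks whether a genotype's response
to an environment differs from the wild type's: a
genotype-by-environment (GxE) interaction, i.e. non-parallel reaction
norms. `twoWayAnovaInteraction()` fits the two-factor fixed-effects
model and tests the interaction by model comparison (Type II): the
interaction SS is the residual SS of the additive model minus that of
the full model. On balanced designs this equals the classical
partition (asserted in the tests); on unbalanced data — common when
seedlings are lost — Type II is the conventional default when the
interaction is the term of interest, and the source analyses never
state their flavor. Empty cells and designs without residual degrees
of freedom are errors, not NaNs.

`studentsT()` defaults to the pooled-variance Student's t because that
is the named test in the analyses this mirrors; Welch is behind a flag.
Degenerate zero-variance inputs follow explicit conventions (equal
means: p = 1; unequal: p = 0) instead of erroring mid-pipeline. No
multiple-testing correction is applied across phenotype panels — the
convention is to report raw per-panel p-values.

## The synthetic-data generator

All inputs can be generated synthetically, so the entire pipeline is
testable without downloads. The generator's defaults are the study
conditions the package is designed around:

| knob | default | meaning |
|---|---|---|
| `universeSize` | 27,416 | TAIR10-like protein-coding universe (stand-in) |
| track sizes | 4081, 1984 | high-H2A.Z-like and H3K9ac-like tracks |
| DEG list sizes | 500–2000 | the range of real DEG lists in such studies |
| `theta` | 1 | inclusion-odds multiplier for target-track genes |
| `rho` | 1 | cross-list direction concordance |
| phenotype | 2×2, n = 15, σ = 0.5 mm | hypocotyl-length-like design |

DEG lists are drawn by weighted sampling without replacement
(draw-and-remove), so list sizes are exact as in real DEG calling;
Bernoulli inclusion would randomize $n_a$ and change the test's
conditioning. `theta = 1` recovers the uniform null exactly (the
p-value distribution over seeds is super-uniform); `theta = Inf` nests
the list inside the track.

Directions follow a latent per-gene sign drawn once per configuration.
The first generated list copies the latent signs exactly — it plays the
role of the reference dataset — and each later list copies each sign
with probability `rho`, flipping otherwise. Pairwise sign agreement
with the reference is then exactly `rho`, so concordant classes
dominate partitions when `rho > 0.5` and discordant classes when
`rho < 0.5`. (Had every list independently copied the latent sign with
probability `rho`, pairwise agreement would be
$\rho^2 + (1-\rho)^2 \ge 1/2$ and low-concordance regimes would be
unreachable; anchoring the first list is what makes `rho` the
agreement probability.)

Track generation can pin the exact overlap between two tracks (e.g.
850 shared genes between a 1984-gene and a 4081-gene track), which is
how fixtures reproducing published contingency structures are built.
Infeasible requests error at generation time.

What the generator does **not** emulate: read-level noise, DE-calling
variance, correlated gene co-regulation, or chromatin-state-dependent
sampling bias. Tests passing on synthetic data therefore demonstrate
that the statistics are computed correctly and are calibrated under
their stated null — not that any particular biological overlap is
real.

## Problem sizes used by the checks

The package's own verification runs at these scales, chosen to keep a
full check of the method comfortably interactive: exhaustive
enumeration oracles to $N \le 25$ (subset enumeration to $N \le 8$);
null calibration at $K = 10{,}000$ in the tests and $K = 100{,}000$ in
the acceptance script; 100 seeded replicates for planted-enrichment
recovery; 2,000 simulations for ANOVA size and 200 for power. All
randomness flows from explicit seeds.

## Known limitations

* Locus-level ID normalization (uppercase, strip `.n` suffixes) is the
  only joining logic; no ortholog or alias mapping.
* The hypergeometric model assumes exchangeable genes; genes are not
  exchangeable in real genomes (expression level, length and chromatin
  state all bias DEG membership), which is exactly why the Monte Carlo
  null and its "outside the distribution" flag are part of the method
  rather than an afterthought.
* Per-class partition p-values are not corrected for testing four
  classes per comparison; they are descriptive companions to the
  overall overlap test.
* The ANOVA is fixed-effects only; no mixed models, and dose-response
  designs are handled as plain factors.

## A worked example

```{r example, eval = FALSE}
library(degOverlap)
cfgPath <- system.file("extdata", "demo_config.yaml",
                       package = "degOverlap")
res <- runPipeline(cfgPath, outDir = tempfile("demo"))
overlapResultTable(res$overlaps)
res$nullReport$observations
```

The demo config plants a theta = 3 enrichment of an 800-gene DEG list
for a 4081-gene track in a 27,416-gene universe, adds a theta = 1
negative control, and calibrates both against a 2,000-replicate null:
the planted list lands outside the simulated null distribution, the
control does not.
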