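---
title: "Population proteomics with triplex labelling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population proteomics with triplex labelling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteopop)
```

## The problem

proteopop analyzes quantitative proteomics experiments that compare many
*populations* of an organism — here, honey bee (*Apis mellifera*) colonies
descended from queens of eight geographically distinct breeders — using
triplex isotopic labelling. Each LC-MS/MS run (a *block*) mixes three
differentially labelled samples, so all quantitation is relative within a
block, and no block can hold every population: the experiment is an
incomplete block design. The pipeline covers the full path from design
construction and peptide-spectrum-match (PSM) tables to per-protein
population effects, overlap and enrichment statistics, clustering of
expression profiles, and pathway-level regression against the latitude of
population origin.

## The block design

Every colony is sampled in triplicate, giving `3 * n_colonies` sample
units. A design assigns each unit to a block of three and to one of the
labels light/medium/heavy under two constraints: no two colonies of the
same population share a block, and no colony reuses a label across its
three replicates (each block also uses the three labels once each). With
58 colonies this always yields exactly 58 blocks, since the number of
blocks is the total sample count divided by three.

`generate_design()` builds a feasible design by (i) partitioning samples
into blocks greedily, always drawing from the three populations with the
most unassigned samples (feasible whenever no population holds more than a
third of all samples), and (ii) colouring the colony-block incidence graph.
That graph is 3-regular bipartite for any valid blocking, so by König's
theorem it decomposes into three perfect matchings, one per label; we
compute them with augmenting-path matching. This is exact, so label
assignment never fails for a feasible blocking.

Designs are scored by a Ds-type criterion: the log-determinant of the
information matrix of the population contrasts after adjusting for the
block and label nuisance factors. Maximizing it minimizes the generalized
variance of the estimated population effects, which is the stated purpose
of the design. A seeded multi-restart exchange heuristic (same-label block
swaps, accepted only when they keep the constraints and strictly improve
the criterion) refines random feasible starts; the best design across
restarts is kept, so more restarts never return a worse criterion. Ties
are broken by a canonical lexicographic block ordering, making the output
deterministic for a fixed seed. On rosters small enough for exhaustive
enumeration the optimizer attains the brute-force optimum (this is tested).

## From PSMs to a ratio matrix

PSMs are filtered at an inclusive ion-score cut-off of 25; identification
error is summarized by the reversed-decoy estimate FDR = rev/(for + rev).
Protein inference is a parsimony (minimal set cover) heuristic: proteins
ranked by distinct peptide count, subsumed proteins merged as group
members, ties broken by accession order for determinism. Peptide channel
intensities are log2-transformed first and then averaged per group and
block (log-then-average, the more outlier-robust order; the raw export
convention leaves the choice open). Peptides shared between non-nested
groups count toward each by default (`unique_only` reverses this); the
matrix stores log channel values rather than ratios to one reference
channel, because the block-centering step below makes the two conventions
equivalent.

## Normalization

Two stages, in fixed order:

1. **Block centering** — per protein and block, subtract the mean of the
   observed channel values. Fully observed triples then sum to zero; this
   removes arbitrary per-block intensity scale and is exactly the
   projection a per-protein block fixed effect would apply.
2. **Label standardization** — per label channel, subtract the median and
   divide by the median absolute deviation, both computed across all
   proteins and blocks pooled. The raw MAD (no 1.4826 consistency
   constant) is the default since the procedure is a plain median/MAD
   standardization; the constant, and a per-(block, label) mode, are
   options. Pooling blocks per label is the default because block effects
   are already removed by stage 1 and re-adjusted in the model.

Stage 2 is idempotent and invariant to shifting or positively scaling a
label; a label with zero MAD is a hard error naming the label.

## The per-protein mixed model

For each protein, the normalized values are modelled as

```
value ~ population + block + label + (1 | colony)
```

with sum-to-zero population coding (the population effects average to
zero by construction), treatment-coded block and label nuisance factors,
and a colony random intercept for the three repeated measures per colony.
Estimation is REML via lme4. Per population we report the effect, its
standard error, the one-sided P-value `p1 = pnorm(effect/se)` (values near
1 mean strongly up, near 0 strongly down) and the folded two-sided value
`p2 = 1 - 2*|p1 - 0.5|`. The normal reference for `p1` is used rather than
a t distribution because residual degrees of freedom are ill-defined
across unbalanced, partially observed proteins; at the study's block
counts the difference is negligible.

**Choice of factor test.** The overall population test defaults to a Wald
F on the REML fit (numerator df = populations − 1, denominator df =
observations − fixed parameters). A maximum-likelihood likelihood-ratio
chi-squared test is available (`factor_test = "lrt"`), but with a
58-level block factor the fixed-effect count is a sizable fraction of the
observation count and the chi-squared reference is strongly
anticonservative there (empirical null rejection around 20% at a nominal
5%), so it is not the default. The Wald F is exact in the
vanishing-colony-variance limit and calibrates at close to the nominal
level in the package's null simulations. With very few colonies per
population the mixed model is more conservative than a fixed-effects F
test — correctly so, since population is a between-colony contrast.

Proteins are retained for modelling when observed in at least
`floor(0.25 * n_blocks)` blocks (14 of 58); the floor is the only reading
that keeps a protein seen in exactly 14 blocks while dropping one seen in
13. Significance uses a strict `factor_pvalue < alpha` with `alpha = 0.05`
by default; significant proteins are assigned per population to up/down
sets by the sign of the effect, with zero effects joining neither set.
Proteins whose fit fails (rank deficiency, convergence error) are excluded
from downstream sets and flagged in the per-protein table; boundary
("singular") variance estimates are kept, as they simply reduce to the
fixed-effects model.

## Overlap and enrichment

Pairwise population similarity uses the representation factor
`o * N / (n_x * n_y)` — observed over expected overlap of the two
significant sets against the quantified background `N` — with an exact
one-tailed hypergeometric P-value `P(X >= o)`. By default proteins count
as shared only when their effects agree in sign in both populations
(overlap of expression *patterns*); a direction-blind mode exists. The
background is always the post-observation-filter quantified set, never the
full identified list. Term enrichment is the same upper-tail
hypergeometric test per annotation term against that background, with
Benjamini–Hochberg adjustment across tested terms (the era-appropriate
default of GO enrichment tools); default significance is 0.05 on the
adjusted P, configurable (e.g. 0.1). Foreground proteins missing from the
annotation table count as un-annotated rather than being dropped.

## SOTA clustering

Profiles (the 8-vectors of one-sided P-values of the significant proteins)
are clustered with a self-organizing tree algorithm: a binary tree grown
from a single cell, each cycle splitting the leaf with the greatest
*diversity* (mean Euclidean distance of members to the cell centroid)
into two daughters initialized at the parent centroid, followed by
adaptation epochs in which each profile moves its nearest leaf (and, when
the sibling is a leaf, the mother and sister cells) toward it by the
winner/mother/sister learning rates. Defaults are rates (0.01, 0.005,
0.001) and per-cycle relative-error tolerance 1e-6, standard values for
this algorithm family; the originals are unpublished for this study.
Growth stops at `max_cycles + 1` leaves (default 7 cycles, so at most 8
hard clusters) or when every leaf diversity is at or below `max_diversity`
(default 0.8; the loosely reported "low diversity > 0.75" is read as the
same threshold). Determinism comes from fixed presentation order and
ties-to-first rules, not from RNG. After each cycle leaf centroids are
snapped to their members' means so that reported diversity is a property
of the hard partition (singletons score exactly 0). Within clusters,
protein and population dendrograms use Euclidean distance with average
linkage (UPGMA, the default of the named visualization tool; single and
complete are options) and export as Newick strings.

## Pathways and latitude

Per pathway and population, member-protein effects are aggregated by the
median (default; the mean is an option because the two summaries are both
referenced in the source material — the discrepancy is recorded, not
resolved). Composite pathways are unions of member sets. The aggregate is
regressed on absolute latitude `A` with ordinary least squares,
`Y = b0 + b1*A + b2*A^2`; the aggregate is the response and `A` the
regressor (the original figure caption transposes the dependent/
independent labels). Reported are the coefficients, R², and the Pearson
correlation between fitted and observed values.

## The synthetic generator

`make_ground_truth()` + `simulate_ratio_matrix()` generate data under
exactly the additive log-scale model the analysis assumes: per-protein
population effects (zero-mean across populations), global block and label
shifts, per-(protein, colony) random intercepts, Gaussian residual noise,
and whole-cell protein-by-block missingness. Defaults mirror the study
conditions: the eight-population roster with colony counts
(4, 4, 4, 8, 8, 10, 11, 9), three replicates per colony, 58 triplex
blocks. The original work reports no effect-size or variance-component
magnitudes, so the defaults are calibration choices of this package, set
once to values typical of dimethyl-labelling tissue data on the log2
scale: residual SD 0.3, colony SD 0.15, block SD 0.2, label SD 0.1,
missingness 0.2, effect size 0.5 (about 1.4-fold).

What the generator does **not** emulate: intensity-dependent missingness,
peptide-level variance heterogeneity, isotope-envelope interference,
retention-time drift, or correlated proteins. Passing recovery and
calibration tests therefore demonstrate correctness of the estimation
machinery under the stated model, not robustness to every pathology of
real LC-MS/MS data.

Recovery tests compare estimates to truth on the block-centered scale
(standardization off), because label standardization rescales all values
by the per-label MAD and would change the units of the planted truth; the
null-calibration tests run the full normalization since the null is
scale-free.

## Problem sizes and numerical choices

The shipped tests run the null calibration at 500 proteins and parameter
recovery at 200 proteins on the full 58-block design, exhaustive
hypergeometric sweeps for backgrounds up to 25 with randomized checks to
60, and exhaustive design enumeration at 9 samples — sizes chosen so the
whole suite completes in about a minute while every stage is exercised at
study scale. Floating-point tie-breaks are deterministic throughout
(lexicographic orderings, ties-to-first nearest-leaf assignment);
criterion comparisons in the design optimizer require strict improvement
beyond 1e-12 to avoid cycling.

## Known limitations

- The exact counts of the original study (578 quantified and 172
  significant proteins) depend on the original quantitation table, which
  is not redistributed here; the package reproduces the rules, and its
  statistical behaviour is validated on synthetic data at the same scale.
- The factor test of the original analysis is unspecified; different
  reasonable choices (Wald F, LRT, Kenward–Roger) will disagree on
  borderline proteins.
- Shared-peptide quantitation and the ratio reference convention are
  under-documented in the source material; both are explicit options
  here.
- SOTA results depend on learning rates and presentation order; the
  defaults are fixed and documented, but they are conventions, not
  reproductions.
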