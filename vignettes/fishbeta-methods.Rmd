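---
title: "Methods: temporal beta-diversity analysis of species checklists"
author: "fishbeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal beta-diversity analysis of species checklists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishbeta)
```

## The problem

Freshwater fish faunas of large river--lake basins are documented mainly
through species checklists: published survey inventories that record which
species were found in which basin unit, with no abundances. Comparing such
checklists between a historical and a current survey period answers three
questions: how much richness was lost (alpha and gamma diversity), *which*
species were lost (extirpation by area and by ecological type), and whether
the spatial structure of the fauna changed (beta diversity, its turnover and
nestedness components, and their geographical drivers). `fishbeta`
implements this whole chain on binary area-by-species incidence matrices,
one per period.

## Incidence matrices

`build_incidence()` collapses long-format records into a binary matrix: a
cell is 1 if the species was recorded at least once in the area during the
period (union over sources; the reconciliation of multiple sources beyond
union is not modelled, since checklist compilations do not preserve the
information needed for anything finer). Species columns are ordered
lexicographically, which makes the matrix invariant to the order of the
input records. Records may carry a period label directly or a survey year;
years below 2000 map to the historical period and 2000 upward to the
current one (the two survey windows share the boundary year, which we
assign to the current period). Scientific-name synonymy is resolved only
through an explicit user-supplied table (`normalize_names()`); chained maps
are rejected so the operation is idempotent, and no fuzzy matching is
attempted. Species present in the checklist but missing from the attribute
table are treated as native with unknown ecotypes and excluded from ecotype
summaries, because published ecotype tables cover only classified species.

## Richness and loss accounting

Alpha diversity is the per-area row sum, gamma the size of the species
union. `extirpation_summary()` counts, per area, historical natives,
current natives, their difference (extirpated natives) and current exotics.
Two percentage conventions are fixed package-wide:

* extirpation percentage = extirpated / historical natives of that area;
* introduction percentage = exotics / (current natives + exotics), i.e.
  relative to the current total assemblage.

All printed percentages go through one rounding rule, `round1()`:
round-half-up to one decimal. Half-up (rather than R's default
half-to-even) is used because it is the convention of the published basin
tables this layout mirrors (e.g. 3/48 = 6.25% prints as 6.3%).
`ecotype_loss()` is basin-wide by construction: a species counts as lost
only when it is absent from *every* area currently, which matches how
single per-category loss percentages are reported in the literature.

## Beta-diversity partitioning

For two areas with `a` shared species and `b`, `c` species unique to each,

$$\beta_{sor} = \frac{b + c}{2a + b + c}, \qquad
  \beta_{sim} = \frac{\min(b, c)}{a + \min(b, c)}, \qquad
  \beta_{sne} = \frac{|b - c|}{2a + b + c} \cdot \frac{a}{a + \min(b, c)}.$$

$\beta_{sor}$ is total compositional dissimilarity, $\beta_{sim}$ the
richness-independent replacement (spatial turnover) part, and $\beta_{sne}$
the nestedness-resultant part. The absolute value $|b - c|$ in
$\beta_{sne}$ is deliberate: the component is sometimes printed without it,
but then it can go negative and the additive identity fails; with it,
$\beta_{sor} = \beta_{sim} + \beta_{sne}$ holds exactly (to machine
precision, asserted at $10^{-12}$ in the tests) and $\beta_{sne}$ equals
$\beta_{sor}$ exactly for nested pairs. Degenerate pairs are defined by
their limits: a pair with one empty assemblage is pure nestedness
($\beta_{sor} = \beta_{sne} = 1$, $\beta_{sim} = 0$, with a warning), and a
pair of two empty assemblages is an error. Group summaries report the
sample standard deviation (n-1 denominator). Two summary modes exist
because published per-basin mean &plusmn; SD tables do not define their
sampling units: *area-focal* (per area, over the pairs involving it, with a
grand mean of the per-area means) and *subset* (recompute the matrix on a
species subset -- a family, natives, exotics -- and summarise over all
pairs). Neither mode claims to reproduce any particular published table's
numbers, since those depend on unpublished sub-site structure; the shapes
match.

## Ordination

`pcoa()` is classical principal coordinates analysis: eigendecomposition of
the Gower-centred matrix $-\tfrac12 J D^2 J$. Sorensen-family
dissimilarities are generally non-Euclidean, so negative eigenvalues are
expected; the default reports their share of the absolute spectrum rather
than correcting (variance fractions are computed over positive eigenvalues
only), and a Lingoes correction ($d'^2 = d^2 + 2c$, $c = -\lambda_{\min}$)
is available by flag. Axis signs are canonicalized (largest-magnitude
loading positive) so repeated runs and different eigensolvers agree; two
axes are retained by default, matching the planar ordination plots used for
six-unit basins.

## Mantel tests

`mantel_test()` correlates upper-triangle vectors (Spearman with midrank
ties by default) and permutes the object labels of the second matrix for
the null. The Monte-Carlo p-value uses the +1 correction
$p = (k+1)/(B+1)$, so $p \ge 1/(B+1)$; `exact = TRUE` enumerates all $n!$
relabelings for $n \le 8$. The default tail is two-sided: compositional
dissimilarity can correlate *negatively* with drivers (e.g. turnover
decreasing with drainage-area difference), which a one-sided "greater"
test cannot detect. Scalar drivers (drainage area, annual runoff) become
matrices of absolute pairwise differences via `driver_to_matrix()`;
measured waterway-distance matrices pass through unchanged. No
multiple-testing adjustment is applied across the driver grid by default,
matching common practice for these tables; users can apply `p.adjust` to
the grid's `p` column.

## Richness estimation and completeness

`chao_estimate()` implements the classic Chao formula
$S_{obs} + q_1^2 / (2 q_2)$ with the usual fallback to the bias-corrected
form $S_{obs} + q_1(q_1-1)/(2(q_2+1))$ when $q_2 = 0$. Checklist data are
presence/absence over repeated survey lists, so `richness_estimate()`
defaults to the incidence form ($Q_1$/$Q_2$ = species in exactly one/two
sampling units, with the $(T-1)/T$ small-sample factor); the abundance form
is available for count data. Completeness is $S_{obs}$ over the estimate.
Confidence intervals are percentile bootstrap over resampled sampling
units, 100 replications by default (BCa is not implemented; the percentile
interval at this replication count is the procedure the package
standardises on, and the count is configurable). Rarefaction uses the
exact hypergeometric formula
$S(t) = S_{obs} - \sum_i \binom{T - Y_i}{t} / \binom{T}{t}$
(computed with `lchoose` for stability), and extrapolation follows the
Chao-asymptote form, capped at $2T$ with a warning -- the standard
practical bound beyond which asymptotic estimators are unreliable.

## The synthetic metacommunity generator

Real checklist compilations for this kind of basin live in heterogeneous
supplementary files, so validation runs on a generator
(`generate_metacommunity()`) that emulates the study conditions and knows
its own truth. Defaults describe a six-unit river--lake basin: pool of 212
species; per-area expected richness fractions (0.717, 0.854, 0.599, 0.651,
0.401, 0.392) of the pool, i.e. the historical native richness profile of
a large lake unit, its main tributary, three mid-sized rivers and a small
one; nine introduced exotics; and life-habit extirpation probabilities
0.367 (migratory), 0.325 (mountain-stream), 0.158 (resident) -- the loss
regime in which migratory fish, cut off from river--lake connectivity, are
hit hardest.

Each species' historical range comes from one of two mechanisms. With
probability `1 - turnover_weight` it is *nested*: the species occupies
every area whose richness fraction exceeds one uniform draw, so poorer
areas hold subsets of richer ones (a species whose draw exceeds every
fraction is placed in the richest area alone, preserving nestedness). With
probability `turnover_weight` it is *turnover*: the species occupies the
contiguous window of areas within `window_halfwidth` of a uniform position
on a 1-D waterway axis, so composition replaces itself along the axis. The
default half-width makes expected window coverage match the mean richness
fraction. `turnover_weight = 0` therefore gives $\beta_{sim} = 0$ exactly,
and the mean $\beta_{sim}/\beta_{sor}$ ratio rises monotonically with the
weight (a recovery property asserted over 50 seeds per setting); the
default 0.35 puts the basin in the nestedness-dominant regime that
motivates single-large-reserve conservation advice. The current period
deletes each native wholesale with its ecotype's probability (categories
from any of the three axes combine as independent hazards), optionally
thins surviving occurrences per area (default 0), and adds exotics to 1--3
random areas each. A per-area survey-unit layer (5 units, detection
probability 0.7 by default) emulates repeated survey lists for
completeness estimation; detection probability 1 is the saturated-survey
mode in which $Q_1 = 0$ forces completeness 1. Waterway positions
(0--650 km) and per-area drainage/runoff magnitudes are plausible values
for a basin of this size, chosen once and fixed.

What the generator does *not* emulate: river-network topology (the waterway
axis is 1-D), detection bias differing between survey gears or periods,
abundance dynamics, and invasion spread. Passing tests on synthetic data
therefore demonstrate correctness of the statistical machinery and
recoverability of known structure, not robustness to those real-data
complications.

## Numerical choices and degenerate inputs

* One RNG stream per generation, explicitly seeded; same seed, bit-identical
  truth. Derived seeds in the pipeline are offsets of the master seed and
  are recorded in the run manifest.
* Dissimilarity validation symmetrises inputs at tolerance 1e-8 and rejects
  asymmetry, negative entries and non-zero diagonals beyond it.
* PCoA positive-eigenvalue threshold: 1e-9 scaled by the matrix maximum.
* Mantel tie handling: midranks; permutation extremeness compared with a
  1e-12 slack so exact ties count as extreme.
* Empty incidence matrices (a period with no records) are valid but warned
  about; all-zero species columns are dropped by the generator because a
  checklist only contains recorded species.

## Problem sizes used in validation

The test suite and the reproduction script run on the scale of the study
design itself (6 areas, 212-species pool), which keeps every property
check exact or tightly banded: 1,000 random pairs for the partition
algebra, exhaustive 4! enumeration against 9,999 Monte-Carlo permutations
for the Mantel p, 200 replicates for the type-I error band, 50 seeds per
`turnover_weight` setting for the recovery curve, and 10,000 random
subsamples for the rarefaction oracle.

## Known limitations

* Pairwise decomposition only; multiple-site (simultaneous n-area) beta
  metrics and abundance-based (Bray--Curtis) decompositions are out of
  scope.
* No partial Mantel or distance-decay regression.
* Published per-basin SD columns cannot be reproduced from area-level
  checklists alone (the underlying sampling units are not public); the
  package reports both defensible modes instead.
* Only richness (Hill order 0) machinery: no Shannon/Simpson diversities,
  no coverage-based standardisation.
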