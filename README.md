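# fishbeta

Temporal and spatial beta-diversity analysis of species checklists, built
for the common study design in freshwater fish conservation: a river–lake
basin divided into areas, each with a historical and a current species
inventory, and the question of how much of the fauna was lost, where, and
whether the basin's compositional structure shifted between the periods.

The package turns long-format checklists into binary area × species
incidence matrices (one per period) and runs the full analysis chain on
them:

* **Richness and loss** — alpha/gamma richness, per-area
  extirpation/introduction tables with the standard percentage conventions,
  basin-wide ecotype-loss summaries (life habit, feeding, water layer),
  red-list tallies.
* **Beta-diversity partitioning** — pairwise Sørensen dissimilarity
  decomposed into spatial turnover and nestedness:

  β_sor = (b + c) / (2a + b + c),
  β_sim = min(b, c) / (a + min(b, c)),
  β_sne = |b − c| / (2a + b + c) · a / (a + min(b, c)),

  where `a` is the number of species shared by two areas and `b`, `c` the
  numbers unique to each. The absolute value keeps β_sne non-negative, so
  β_sor = β_sim + β_sne holds exactly.
* **Ordination** — principal coordinates analysis of the dissimilarity
  matrices (Gower double-centring; negative-eigenvalue share reported,
  Lingoes correction available).
* **Drivers** — permutation Mantel tests (Spearman, two-sided, +1-corrected
  p; exact enumeration for ≤ 8 areas) against waterway distance, drainage
  area and annual runoff.
* **Survey completeness** — Chao richness estimation (classic and
  bias-corrected, abundance and incidence forms), percentile-bootstrap
  confidence intervals, exact rarefaction and Chao-asymptote
  extrapolation.
* **Synthetic metacommunities** — a seeded generator with a controllable
  nested-subsets vs spatial-turnover mixture, trait-dependent extirpation
  and exotic introductions, used to validate the whole chain against known
  truth.

## Worked example

Generate a six-area, two-period basin at the default study scale (212
species in the pool, nine exotics, migratory fish extirpated hardest) and
analyse it:

```r
library(fishbeta)

t <- generate_metacommunity(synthetic_config(seed = 1))
t$historical
#> Incidence matrix (historical period): 6 areas x 212 species, 766 presences
t$current
#> Incidence matrix (current period): 6 areas x 178 species, 631 presences

extirpation_summary(t$historical, t$current, t$attributes)
#>             area n_hist_native n_curr_native n_extirpated pct_extirpated n_introduced pct_introduced
#> 1    Poyang Lake           129           104           25           19.4            3            2.8
#> 2 Ganjiang River           167           139           28           16.8            5            3.5
#> 3     Fuhe River           128           103           25           19.5            1            1.0
#> 4 Xinjiang River           141           111           30           21.3            2            1.8
#> 5    Raohe River           108            83           25           23.1            4            4.6
#> 6    Xiuhe River            93            71           22           23.7            5            6.6
```

Each row counts native species recorded historically and currently in that
area; `pct_extirpated` is the bracketed-style percentage of historical
natives lost, `pct_introduced` the share of exotics in the current
assemblage. Which ecological types carried the losses:

```r
ecotype_loss(t$historical, t$current, t$attributes, "life_habit")
#>          category n_historical n_extirpated pct_extirpated
#> 1       migration           40           17           42.5
#> 2      settlement          140           19           13.6
#> 3 mountain_stream           32            7           21.9
```

Migratory species lost 42.5% of their historical roster basin-wide, versus
13.6% of residents — the generator's default loss regime. Spatial
structure and its drivers:

```r
pcoa(beta_pairwise(t$current, "sor"))
#> PCoA of 6 objects: 2 positive axes retained (none correction)
#> variance explained: 78.8%, 15.8%
#> negative eigenvalue share: 0.046

mantel_grid(beta_decompose(t$current), list(distance = t$distance),
            n_permutations = 999, seed = 10)
#>   index   driver         r     p seed
#> 1   sor distance 0.8870976 0.006   11
#> 2   sim distance 0.9257322 0.003   12
#> 3   sne distance 0.1032796 0.701   13
```

Turnover (β_sim) tracks waterway distance strongly here because the
generator placed a third of the species as contiguous windows along the
waterway axis. Survey completeness for one area from its five simulated
survey lists:

```r
richness_estimate(t$survey$current[["Poyang Lake"]], seed = 4)
#> Chao richness (incidence): S_obs = 107, Q1 = 2, Q2 = 13, estimate = 107.1, completeness = 0.999
#> 95% bootstrap CI (100 reps): [96.5, 315.8]
```

`run_analysis()` executes all of the above (plus summaries and exports) in
one call and writes every table as CSV with a seeded `manifest.json`, either
from a synthetic configuration or from real files read with
`read_checklist()` / `read_attributes()`.

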