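# ropeteam

Higher-order network analysis of group relationships in mountaineering:
who climbed with whom before, and what that structure does to summit
success.

Pairwise networks cannot tell a trio that climbed together once from
three pairs that each climbed together — yet the two situations carry
very different group dynamics. `ropeteam` models the relationships inside
an expedition as a **weighted simplicial complex**: every subgroup
*s* of the current roster (|*s*| ≥ 2) that appears together in at least
τ strictly earlier expeditions is a simplex of dimension |*s*| − 1 with
weight

&nbsp;&nbsp;&nbsp;&nbsp;*w(s)* = #{earlier expeditions whose roster contains *s*},

so the complex is closed under inclusion by construction, and raising the
threshold τ yields a persistence-style filtration in which only strong
(frequently repeated) relationships survive. On top of the complex the
package computes, per climber and expedition, the **influence**
ζ — the dimension of the largest simplex containing the climber — and
per expedition the **co-influence** (mean ζ over the roster).

The analysis stages, each a data-frame-in / tibble-out function:

| stage | question |
|---|---|
| `failure_ratio_analysis()` | do failure rates drop when climbing with a repeated partner, per failure cause and experience level? |
| `influence_by_outcome()` | is influence higher among summiters? (Mann–Whitney U per experience bin, normalized influence histograms) |
| `influence_tau_sweep()` | does that hold when only strong relationships are kept? |
| `style_curves()` | is the expedition polarized or cooperative? (outsider success vs maximal dimension; success-rate correlation across τ) |
| `centrality_comparison()` | which personal features separate successful from unsuccessful climbers? (bipartite projection *I* = *P*ᵀ*P*, eigenvector centrality) |
| `factor_correlations()` | which expedition-wide factors track the success rate? |

`generate_cohort()` produces synthetic climber/expedition cohorts with
*planted* structure — persistent subgroups, a configurable influence
effect on success, cooperative vs polarized regimes, a repeated-partner
failure multiplier — so the whole pipeline is testable without access to
any external expedition database, and the test suite verifies that each
stage recovers what was planted. `run_pipeline()` chains every stage from
a YAML/JSON/list configuration into CSV tables plus a JSON manifest with
provenance hashes; results come with `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

```r
library(ropeteam)

cohort <- generate_cohort(generator_config(rng_seed = 42))
cohort
#> <climber_cohort> 2800 records, 400 expeditions, 100 climbers (seed 42)

inf <- influence_table(cohort$expeditions, tau = 1)
io  <- influence_by_outcome(inf, cohort$records, cohort$expeditions)
tidy(io)
#> # A tibble: 4 × 8
#>   experience_bin n_success n_no_summit      u  p_value significant skipped
#> 1 5-10                 305         155 32462. 5.71e-12 TRUE        FALSE
#> 2 10-15                338         155 35453  3.03e-11 TRUE        FALSE
#> 3 15-20                306         143 30762. 2.01e-13 TRUE        FALSE
#> 4 20-25                261         103 17160  1.19e- 5 TRUE        FALSE
```

The generator planted 0.8 log-odds of success per unit influence; the
Mann–Whitney tests recover the effect in every experience bin (p-values
far below the reported α = 0.1).

```r
style <- style_curves(cohort$records, cohort$expeditions, tau_values = 1:4)
tidy(style)
#> # A tibble: 4 × 6
#>     tau n_expeditions mean_max_dimension pcc_r    pcc_p degenerate
#> 1     1           392               2.39 0.343 2.74e-12 FALSE
#> 2     2           364               1.47 0.208 6.51e- 5 FALSE
#> 3     3           310               1.16 0.179 1.54e- 3 FALSE
#> 4     4           235               1.08 0.119 6.75e- 2 FALSE
```

Mean maximal simplicial dimension falls as the weight threshold rises
(large subgroups have weak ties), and the correlation between expedition
success rate and mean simplicial dimension is strongest in the
unthresholded complex — the cooperative signature. `autoplot(style)`,
`autoplot(io)` and `plot_failure_ratios()` draw the corresponding
figures.

The single-expedition layer is available directly:

```r
cx <- build_complex(cohort$expeditions, "E00400", tau = 1)
influence(cx, attr(cx, "roster")[1])
simplex_census(cx)
```

## Documentation

The package vignette
(`vignettes/simplicial-expedition-analysis.Rmd`) describes the model and
its assumptions, the generator's planted-effect design and its limits,
and every numerical choice (tie handling, thresholds, degenerate-input
behaviour) in detail.
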