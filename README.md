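# stagetrend

Genes that matter for disease *progression* often do not separate any two
disease subtypes cleanly — they drift up or down across the whole ordered
sequence of stages (control → low-risk → high-risk → acute). Pairwise
differential expression between heterogeneous subtypes misses them.
`stagetrend` finds them in two steps:

1. **Gamma screen.** Every gene is correlated with the ordinal stage
   variable using the Goodman–Kruskal gamma, γ = (C − D)/(C + D) over
   concordant and discordant sample pairs — the rank correlation of choice
   when one variable is massively tied, as a stage factor is. Pair
   orderings on the expression side are scored *fuzzily*: differences
   smaller than a tolerance r (10 % of the gene's interquartile range by
   default) count only partially, via a linear ramp combined with the min
   t-norm, so measurement noise does not masquerade as ordering.
   Significance comes from stage-label permutations (B = 1000, two-sided,
   add-one estimator) with Benjamini–Hochberg FDR control; genes with
   |γ| > 0.50 and q < 0.05 are selected.
2. **Pattern discovery.** Selected genes are z-scored, oriented so rising
   and falling trends are comparable, intensity-sorted, and clustered on a
   3 × 3 self-organizing map. Each pattern is annotated with its δ/2
   half-change point — the interpolated stage coordinate where the
   pattern's mean profile completes half of its total change — classifying
   it as an *early* or *late* trend.

A staged negative-binomial count simulator with ground-truth trend
archetypes (up-early, up-late, down-early, down-late) supports validation
and power exploration, and a pipeline runner plus `stagetrend` CLI make
runs reproducible end to end.

Intended users: bioinformaticians analyzing bulk or single-cell expression
cohorts with a clinically ordered stage annotation (microarray log-signal
or RNA-seq counts alike — the statistic is rank-based).

## Worked example

Simulate the default staged experiment (1000 genes, 18 samples in 6 stages
of 3 replicates, 200 trend genes), screen on the log2 scale, and cluster
the selected genes:

```r
library(stagetrend)

sim <- simulate_dataset(sim_config(seed = 1))
expr <- as_expression(
  dplyr::mutate(tibble::as_tibble(sim$expr),
                dplyr::across(-gene_id, ~ log2(.x + 1))))

screen <- screen_genes(expr, sim$design, gamma_params(seed = 2))
glance(screen)
#> # A tibble: 1 × 8
#>   n_genes n_undefined n_selected  n_up n_down gamma_threshold fdr_threshold
#>     <int>       <int>      <int> <int>  <int>           <dbl>         <dbl>
#> 1    1000           0         87    48     39             0.5          0.05

profiles <- standardize_and_orient(expr, sim$design,
                                   screen$gene_id[screen$selected])
model <- train_som(profiles, seed = 3)
patterns <- summarize_patterns(model, profiles)
dplyr::select(tibble::as_tibble(patterns), unit:flat)
#> # A tibble: 6 × 9
#>    unit n_genes main   n_up n_down delta half_change_position trend_class flat
#>   <int>   <int> <lgl> <int>  <int> <dbl>                <dbl> <chr>       <lgl>
#> 1     1      18 TRUE     18      0  2.43                 2.68 early       FALSE
#> 2     3      11 TRUE      0     11  2.35                 2.45 early       FALSE
#> 3     4      19 TRUE     19      0  2.27                 3.55 late        FALSE
#> 4     6       8 TRUE      0      8  2.22                 3.41 early       FALSE
#> 5     7      11 TRUE     11      0  2.37                 4.35 late        FALSE
#> 6     9      20 TRUE      0     20  2.07                 4.23 late        FALSE
```

87 genes pass the screen (48 rising, 39 falling). The map groups them into
patterns of pure direction; `half_change_position` places each pattern's
δ/2 point on the 1–6 stage axis, so unit 1 is an early-rising pattern
(half its change done by stage 2.7) while unit 9 falls late. Against the
simulation's ground truth:

```r
evaluate_detection(sim$truth, screen, model)
#> # detection vs ground truth: 87 detected (TP 81, FP 6, FN 119)
#>   precision 0.931, classification accuracy 0.875
```

Detection is conservative under the simulator's default noise: the default
dispersion (mean 0.3) puts the expected gamma of a 4-fold trend near the
0.50 selection threshold, so roughly half the injected genes clear it —
see the power discussion in `vignettes/stagetrend-methods.Rmd`. Precision
stays high: few null genes sneak in.

`autoplot(screen)`, `autoplot(model)` and `autoplot(patterns)` give the
volcano view, the codebook grid and the per-stage pattern profiles;
`tidy(model)` returns the gene-to-unit assignments.

The same analysis from a shell:

```sh
./exec/stagetrend simulate --out sim/ --seed 1
./exec/stagetrend run --expr sim/counts.tsv --stages sim/stages.tsv \
    --stage-order S1,S2,S3,S4,S5,S6 --out run/ --seed 7
./exec/stagetrend evaluate --truth sim/truth.tsv --gamma run/gamma.tsv \
    --membership run/membership.tsv --out metrics.json
```

`run/` then holds the gamma table, pattern membership, pattern summaries,
codebook and a JSON manifest that records every resolved parameter, input
checksums and per-phase timings; re-running with the same seed reproduces
every table byte for byte.

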