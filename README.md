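# evoccur

Occurrence-based selection of differentially expressed genes from paired
two-condition expression data measured on several donors, with
knowledge-network-driven optimization of the selection stringency.

## Who this is for

Transcriptomics analysts working with paired designs — stimulated versus
unstimulated cells from the same individual, assayed for a small cohort of
donors — who need an objective way to set the differential-expression
threshold. A stringent per-gene cut keeps only the largest expression
changes and misses consistent moderate responders; a permissive cut floods
the list with noise. `evoccur` replaces the single cut with a per-donor
**Expression Variation (EV)** statistic plus an **occurrence** rule across
donors, and picks the occurrence stringency by how well the selected genes
organize into interaction-network structure.

## The statistic

Per donor, intensities are Box–Cox transformed (λ by profile maximum
likelihood) and each gene becomes a point in the dispersion space
(A, M) = ((y_test + y_ref)/2, y_test − y_ref). Cubic smoothing splines
fitted to windowed robust location and scale of M give intensity-dependent
confidence bands; then

    EV = |M − center(A)| / spread(A),   p = P(Z ≥ EV),  Z ~ N(0,1)

so EV 1.28 ↔ p ≤ 0.1 and EV 2.32 ↔ p ≤ 0.01 (one-sided; displayed values
truncate the quantiles 1.2816 / 2.3263). A gene's **occurrence** is the
number of donors (k of n) with EV above threshold *in the same regulation
direction*; combined significance is reported both as the product bound
p_thr^k (10⁻⁶ at 6/6, p ≤ 0.1) and as the binomial tail P(Bin(n, p_thr) ≥ k).
Selected "focus" genes are grouped into ≤35-gene networks on an interaction
graph and scored by −log₁₀ of the hypergeometric tail; per stringency
level, the percentage of network-eligible genes shared by ≥2 networks is
the structuring signal that peaks at the optimal occurrence threshold.
Inter-donor variability decomposes as total = 100 − overlap =
technical + biological, with expected counts across levels following
n·(1−v)^Δk.

## Worked example

```r
library(evoccur)
cohort <- generate_cohort(cohort_spec(seed = 1))   # 2000 genes, 6 donors, 10% DE
gg     <- generate_graph(cohort$truth, seed = 1)   # module-structured knowledge graph
evt    <- ev_table(cohort$tables)                  # Box-Cox + bands + EV per donor
grid   <- run_grid(evt, gg$kg, config = run_config(seed = 1))
grid_metrics(grid)
```

```
  level genes_output eligible common common_pct main_size specific specific_pct best_score
1   6/6           16       16      0       0.00        16       16       100.00   30.12653
2 >=5/6           77       77     27      35.06        77       50        64.94   20.09506
3 >=4/6          143      140     57      40.71       134       77        55.00   28.40050
4 >=3/6          258      233     88      37.77       188      100        42.92   29.61241
```

The common-gene percentage rises to its maximum at occurrence ≥4/6 — the
cohort was simulated with a donor response probability of 0.7 (expected
occurrence 4.2/6) — and falls when the looser ≥3/6 level admits noise genes
that land in small unconnected networks.

```r
choose_threshold(grid)
#> recommended stringency: >=4/6 -- best-score continuity never broke;
#> structuring peak (Rule A) decides
```

```r
variability_report(evt, n_observed = 300, reference_k = 4)
#> variability_report: avg overlap 35.7 % -> total 64.3 % = technical 20 % + biological 44.3 %
#>   k delta_k expected
#> 1 4       0      300
#> 2 5       1      107
#> 3 6       2       38
```

(The synthetic cohort is noisier between donors than a real one: donors
share a selection only when a gene responds in both, so at response
probability 0.7 the expected high-stringency overlap is roughly 50–60%.)

Reference arithmetic anchors, independent of simulation:

```r
ev_display(p_to_ev(0.1));  ev_display(p_to_ev(0.01))   # 1.28, 2.32
combined_p(6, 6, 0.1)                                  # product bound 1e-06
structuring_metrics(300, 202, 63, 193, 63)$common_pct  # 31.19
decompose_variability(54, 20)$biological               # 26
project_counts(300, 0.46, 1:2)                         # 162, 87
```

## Command line

```sh
Rscript -e 'evoccur::evoccur_cli()' simulate --seed 7 --out-dir sim
Rscript -e 'evoccur::evoccur_cli()' optimize \
  --expr D1=sim/expr_D1.tsv --expr D2=sim/expr_D2.tsv \
  --expr D3=sim/expr_D3.tsv --expr D4=sim/expr_D4.tsv \
  --expr D5=sim/expr_D5.tsv --expr D6=sim/expr_D6.tsv \
  --edges sim/edges.tsv --gmt sim/sets.gmt --out-dir out
```

Subcommands: `simulate`, `ev`, `select`, `networks`, `optimize`,
`variability`; common flags `--config` (YAML), `--seed`, `--out-dir`.
Each stage writes TSV tables and a `run_summary.json`.

## Documentation

`vignettes/ev-occurrence-analysis.Rmd` describes the model and its
assumptions, every tunable parameter with its default and rationale, what
the synthetic generators emulate (and what they deliberately omit),
numerical choices, and known limitations — notably that the best-score
continuity rule for threshold selection is unstable on desk-scale cohorts,
where the structuring-peak rule should be weighted instead.
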