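# stmgrn

Reconstruction and modelling of the gene-regulatory network around
SHOOT MERISTEMLESS (STM), the KNOX transcription factor that maintains
the shoot apical meristem in *Arabidopsis*. The package is aimed at
plant systems biologists who have induction/knockdown expression data
and a public expression compendium and want to (i) find robustly
STM-responsive genes, (ii) infer a consensus regulatory network among
them, and (iii) test whether the inferred STM–CUC1–miR164–TCP circuit
can pattern the meristem–organ boundary in space.

Three stages, usable independently:

1. **Meta-analysis.** Per-contrast Welch tests (or any p-value table you
   bring) are combined per gene with Fisher's inverse chi-squared
   statistic, $X^2 = -2\sum_j \ln p_j \sim \chi^2_{2k}$, with
   Benjamini–Hochberg and Storey q-value FDR control on the omnibus
   p-values; plus DEG filtering (p < 0.01, two-fold change), UPGMA and
   k-means clustering, hypergeometric gene-set enrichment, and
   $2^{-\Delta\Delta C_T}$ utilities.
2. **Consensus Bayesian network.** A log2 compendium is discretised to
   three states (more than two-fold above/below each gene's average),
   DAGs are scored with the BDeu marginal likelihood (ess = 1) and
   searched by compiled simulated annealing (T₀ = 10000, cooling 0.7,
   reannealing at 800, max 5 parents, random restarts). The 20
   top-scoring distinct structures yield a consensus network: per pair,
   edge significance = f(u→v) + f(v→u), retained when > 0.4, with
   Spearman-based influence signs; exported as SIF or GraphML.
3. **Boundary model.** A 10-cell file with primordium identity (PrIF) in
   cells 1–3 carries a 7-species-per-cell Hill-kinetics ODE system —
   STM mRNA/protein (protein diffuses), CUC1 mRNA/protein, TCP, miR164c
   and miR164a/b — solved to steady state, with perturbation variants
   (no diffusion, no autoregulation, STM or CUC1 overexpression) and
   one-at-a-time parameter sensitivity.

A synthetic-data module (`stm_fixture_bn()`, `sample_compendium()`,
`make_timecourse()`) generates ground-truth fixtures for every stage, so
the whole pipeline is testable offline.

## Worked example

Sample a 1000-array compendium from the six-node STM fixture network,
search structures, and build the consensus:

```r
library(stmgrn)
fix <- sample_compendium(stm_fixture_bn(), n_samples = 1000, seed = 1)
ens <- anneal_search(fix$discrete,
                     anneal_schedule(budget = 2e6, restarts = 10, seed = 1))
ens
#> Network ensemble: 3 distinct DAGs over 6 nodes; best score -4508.1468
cn <- consensus(ens, threshold = 0.4, data = fix$discrete)
tidy(cn)
#> # A tibble: 5 × 8
#>   from  to    freq_fwd freq_rev significance retained direction sign
#>   <chr> <chr>    <dbl>    <dbl>        <dbl> <lgl>    <chr>     <chr>
#> 1 STM   AIL7     0.667    0.333            1 TRUE     forward   +
#> 2 STM   CHR40    1        0                1 TRUE     forward   +
#> 3 STM   CUC1     1        0                1 TRUE     forward   +
#> 4 STM   TCP3     0.667    0.333            1 TRUE     forward   -
#> 5 STM   TCP4     0.667    0.333            1 TRUE     forward   -
recovery_eval(stm_fixture_bn(), cn)
#> # A tibble: 1 × 5
#>   precision recall direction_accuracy n_retained n_true
#>       <dbl>  <dbl>              <dbl>      <int>  <int>
#> 1         1      1                  1          5      5
```

Every true adjacency is retained with significance 1.0 (the sum of both
directional frequencies), no false pair survives the 0.4 threshold, the
activating children carry `+` influence signs and the TCP repression
targets carry `-`. The fractional directional frequencies reflect
orientation ambiguity within the Markov equivalence class — reversing a
single star edge is statistically indistinguishable from the truth, which
is why direction accuracy is reported separately from skeleton recovery.

The boundary model, at its frozen reference parameters:

```r
prof <- simulate_to_steady_state()
glance(prof)
#> # A tibble: 1 × 9
#>   converged residual  time cuc1_peak_cell cuc1_peak_unique boundary_centre_ratio
#>   <lgl>        <dbl> <dbl>          <int> <lgl>                            <dbl>
#> 1 TRUE      1.22e-15   150              4 TRUE                              2.07
#> # ℹ 3 more variables: stm_monotonicity_violations <int>,
#> #   tcp_leakage_ratio <dbl>, mir164c_argmax_cell <int>
autoplot(prof)
```

CUC1 protein peaks uniquely at cell 4 — the meristem–organ boundary —
at 2.07× the meristem-interior maximum, STM rises monotonically toward
the central zone, TCP stays in the primordium (leakage 0), and miR164c
peaks in the central zone (cell 10). `run_variant(variant =
"no-diffusion")` flattens the ratio to 1.00: STM mobility is what
resolves CUC1 to the boundary.

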