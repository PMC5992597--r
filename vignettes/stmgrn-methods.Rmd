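---
title: "Methods: meta-analysis, consensus network inference and boundary patterning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta-analysis, consensus network inference and boundary patterning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stmgrn)
```

stmgrn reconstructs the transcriptional neighbourhood of the shoot-meristem
regulator STM from expression data and models how the resulting circuit
patterns the meristem–organ boundary. This vignette is the package's
account of its methods: the statistical models, the structure-learning
machinery, the spatial ODE model, the choices made where the design was
genuinely open, and what the synthetic benchmarks do and do not show.

## 1. Meta-analysis of differential expression

Per contrast (an induction or knockdown time point versus its control),
`de_test()` computes a two-sided Welch t-test and a log2 fold-change per
gene. This is intentionally plain plumbing: moderated test statistics from
dedicated differential-expression frameworks can be substituted freely,
because everything downstream consumes only a table of p-values.

`meta_analyse()` combines each gene's $k$ per-contrast p-values with
Fisher's inverse chi-squared method:

$$X^2 = -2 \sum_{j=1}^{k} \ln p_j \sim \chi^2_{2k} \quad \text{under the joint null},$$

reporting the upper-tail omnibus p-value. Direction of change is
deliberately ignored, so genes with reciprocal regulation across
induction and knockdown combine constructively. Raw (not adjusted)
per-contrast p-values enter the combination; multiplicity is controlled
once, on the omnibus p-values, two ways:

* **Benjamini–Hochberg** step-up adjustment (`bh_adjust()`), and
* **Storey q-values** (`storey_qvalue()`): $\hat\pi_0(\lambda) =
  \frac{\#\{p > \lambda\}}{n(1-\lambda)}$ on the grid $\lambda = 0.05,
  0.10, \ldots, 0.95$, smoothed by a cubic spline (3 df) and read off at
  $\lambda = 0.95$, clamped to $(0, 1]$; then $q_i = \hat\pi_0 \cdot
  \mathrm{BH}_i$ with a cumulative-minimum pass. Below 20 p-values the
  smoother is unreliable and $\pi_0$ is fixed at 1, which reduces q-values
  exactly to BH.

A p-value of exactly 0 is rejected rather than silently clamped: the
Fisher statistic would be infinite, and a 0 almost always signals an
upstream reporting problem the caller should resolve explicitly.

DEG selection (`select_degs()`) keeps a gene when $p < 0.01$ and, when the
fold filter is on, $|\mathrm{lfc}| \ge 1$ log2 unit (a two-fold change).
Gene-set enrichment (`hypergeom_enrich()`) is the standard upper-tail
hypergeometric test against a user-supplied universe with BH correction
across sets; sets are taken as given (no ontology propagation).
`ddct_fold()` implements $2^{-\Delta\Delta C_T}$ relative quantification,
which doubles as ChIP fold-enrichment against an unbound control amplicon.

Clustering: `upgma_cluster()` is unweighted pair-group average linkage
with Euclidean or correlation (1 − Pearson r) distance. Ties are broken by
the lexicographically smallest cluster-id pair so results are
reproducible; the suite checks the implementation against both a
brute-force agglomeration oracle and `stats::hclust` on tie-free random
instances. `kmeans_cluster()` is Lloyd's algorithm from seeded random
centroids; an emptied cluster is re-seeded from the point farthest from
its centroid, and a fixed seed gives identical labels.

## 2. Compendium discretisation and BDeu scoring

Expression compendia are reduced to three states per gene and sample
(`discretise()`): with $\bar E_i$ the gene's mean log2 expression over all
samples, state 2 when $E_{ij} - \bar E_i > 1$, state 0 when $\bar E_i -
E_{ij} > 1$, and state 1 otherwise. The inequalities are strict — a
deviation of exactly one log2 unit (exactly two-fold) stays in the middle
state — and the unit threshold means "more than two-fold above/below
average".

Network structures over the discretised nodes are scored with the BDeu
(Bayesian Dirichlet equivalent uniform) marginal likelihood, equivalent
sample size $\mathrm{ess} = 1$, uniform structure prior. For node $v$ with
$q = 3^{|\mathrm{pa}(v)|}$ parent configurations and counts $N_{jk}$:

$$\log \mathcal{L}_v = \sum_{j=1}^{q} \left[ \log\frac{\Gamma(\alpha_j)}{\Gamma(\alpha_j + N_j)} + \sum_{k=0}^{2} \log\frac{\Gamma(\alpha_{jk} + N_{jk})}{\Gamma(\alpha_{jk})} \right],\quad \alpha_{jk} = \frac{\mathrm{ess}}{3q},\ \alpha_j = \frac{\mathrm{ess}}{q}.$$

The score is decomposable; family scores are cached by (node, parent set),
so the search never recomputes a family it has seen. Spreading `ess`
uniformly over the parameter cells makes Markov-equivalent structures
score identically to floating-point accuracy, a property the tests assert
directly. The tests also verify the closed form against an independent
sequential-predictive (chain rule) computation of the same marginal
likelihood on hundreds of random datasets.

## 3. Structure search and the consensus network

`anneal_search()` runs Metropolis simulated annealing over single-edge
moves (add / delete / reverse) that preserve acyclicity and an in-degree
bound of 5. The schedule is: initial temperature 10000, geometric cooling
by 0.7 whenever 2500 proposals have been accepted or 10000 proposed since
the last cooling event, a reanneal to temperature 800 when fewer than 500
acceptances separate cooling events, and random restarts (random
topological order, Bernoulli(0.1) edges). Wall-clock budgets are replaced
by a total proposal-count budget split across restarts, so a run is a pure
function of (data, schedule, seed); the hot loop is compiled code driven
by R's RNG, and the suite asserts bit-reproducibility.

The ensemble keeps the top-scoring *distinct* structures (default 20).
Two collection modes exist, and the choice matters:

* `"restart_best"` (default): each restart contributes its best structure.
  With the search converging, the ensemble concentrates on the score
  optimum's Markov equivalence class, and consensus edge frequencies
  reflect orientation uncertainty *within* that class.
* `"all_visited"`: the best distinct states the chains ever occupied.
  Because the equivalence class of a sparse true structure is small (six
  members for a five-child star), the remaining ensemble slots are
  necessarily filled by the cheapest "true structure + one extra edge"
  family, which is itself score-tied by Markov equivalence and can push a
  single false pair past any retention threshold below ~0.6. This mode is
  kept for diagnosing the score landscape, not for recovery.

`consensus()` computes, per ordered pair, the fraction $f(u \to v)$ of
ensemble structures containing the edge; the *edge significance* of an
unordered pair is $f(u \to v) + f(v \to u) \in [0, 1]$, and a pair is
retained when significance strictly exceeds the threshold (default 0.4).
The dominant direction is the more frequent orientation (ties stay
undirected). Influence signs annotate retained pairs with the sign of the
Spearman rank correlation of the two state vectors, with $|\rho| < 0.05$
(or a constant vector) mapped to 0; the sign annotates but never filters.
`recovery_eval()` scores skeleton precision/recall against a known truth,
reporting direction accuracy separately because orientations inside an
equivalence class are not identifiable from observational data.

## 4. Synthetic data: what it emulates and what it does not

`ground_truth_bn()` + `sample_compendium()` emulate a microarray
compendium as ancestral samples from a known three-state DAG with Gaussian
log2 emissions (per-state means reference − 2, reference, reference + 2;
sd 0.3). The defaults are chosen so that discretising the continuous
readout recovers the generating states with small error, which is what
makes end-to-end recovery tests meaningful. The fixture network
(`stm_fixture_bn()`) is a six-node star — STM activating CUC1, AIL7 and
CHR40 and repressing TCP3 and TCP4 — with CPT strength 0.8: strong enough
for structure recovery around 1000 samples, weak enough to be
non-degenerate. `make_timecourse()` plants signed log2 effects in a
replicated control/treated design with Gaussian noise.

Real compendia have batch structure, probe-level artefacts, correlated
noise and normalisation residue; none of that is simulated. Passing the
benchmarks therefore demonstrates correctness of the machinery — scoring,
search, consensus, calibration of the meta-analysis under a clean null —
not performance on arbitrary public array collections. The benchmark
sizes (1000-array fixtures, 10 recovery seeds, 20 timecourse seeds,
100k-gene null calibration) were chosen as the smallest problems at which
the checked properties are stable, and are stated in the tests.

## 5. The boundary-patterning ODE model

A cross-section through the meristem is a file of $N = 10$ cells; cells
1–3 carry a fixed primordium-identity input (PrIF, e.g. auxin), cells
4–10 are meristem, with cells 4–5 at the meristem–organ boundary and the
far end the central zone. Seven species per cell evolve by mass-action
kinetics with quasi-steady-state Hill regulation ($H^+(x;K) =
x^n/(K^n + x^n)$, $H^-(x;K) = K^n/(K^n + x^n)$, shared $n = 2$):
STM mRNA and protein (the protein is the only mobile species, diffusing
with no-flux ends), CUC1 mRNA and protein, TCP protein, and the
microRNAs miR164c (STM-activated) and miR164a/b (TCP-activated). The STM
promoter integrates basal activity, CUC1 activation and optional
autoregulation, normalised by the fixed weight sum, under TCP repression;
CUC1 mRNA is degraded catalytically by both microRNAs at rate
$\kappa \cdot m_{C1} \cdot (r_C + r_{AB})$ (the microRNA is not
consumed — the simplest mechanism consistent with low miR164c levels
failing to clear CUC1 mRNA at the boundary). Promoters are instantaneous
functions of their regulators rather than dynamic species.

Steady states are found by stiff adaptive integration (`deSolve::lsoda`)
in doubling time chunks until $\max|dX/dt| < 10^{-9}$ (or $t = 10^4$;
non-convergence is reported, never thrown). The default initial condition
is uniform STM protein (level 1) and everything else zero — a meristem
with established STM activity before boundary resolution. From the
defaults the steady state is unique across random positive initial
conditions to $10^{-6}$, and mirroring the geometry mirrors the profile
to $10^{-10}$.

### Parameterisation

The reference equations for this circuit are not available in closed
form, so the parameter set is the package's own, calibrated once against
the qualitative steady-state pattern and then frozen (shipped as
`inst/extdata/boundary-model-params-v1.yaml`; `read_model_config()`).
The pattern targeted: a unique CUC1 protein maximum at the boundary
(cells 4–5) at least two-fold above the meristem interior, STM rising
monotonically from boundary to central zone, TCP confined to the
primordium, and miR164c peaking in the central zone. The calibration
logic, in mechanistic terms:

* the STM gradient is carved by the primordium sink (TCP represses STM
  transcription tightly, $K_{ST} = 0.2$) plus diffusion $D = 1.5$;
  $\beta_{mS} = 3$ sets the central STM plateau near 0.75;
* CUC1's promoter is *sensitive* to STM ($K_{C1S} = 0.2$: saturated
  through most of the meristem) while miR164c's response is *graded*
  ($K_{rCS} = 2$: unsaturated over the whole STM range, so
  $r_C \propto S^2$);
* $\kappa = 200$ places the crossover $\kappa \cdot r_C \approx
  \delta_{mC1}$ between boundary and centre, so miR164c clears CUC1 mRNA
  in the central zone but not at the boundary, while miR164a/b clears it
  in the primordium: CUC1 protein survives only in the trough between the
  two microRNA domains.

All other rates are 1 (microRNA turnover 0.5), i.e. time is measured in
mRNA/protein lifetimes and concentrations on the promoter half-max scale.

### Variants, sensitivity, and the overexpression asymmetry

`run_variant()` re-solves the system with diffusion off, autoregulation
off, constitutive STM mRNA production (stm-oe) or constitutive CUC1 mRNA
production (cuc1-ind); `compare_to_wildtype()` reports per-cell,
per-species fold changes. Without diffusion the STM gradient collapses
and CUC1 is uniform across the meristem (boundary/centre ratio 1.00
versus 2.07 in the reference run) — diffusion is necessary for boundary
resolution. Without autoregulation the boundary maximum survives but with
strongly reduced contrast (ratio 1.03): the pattern does not require, but
is reinforced by, autoregulation.

Constitutive STM overexpression raises miR164c everywhere, and raises
CUC1 mRNA *transiently* (`induction_response()`: mC1 tracks the promoter
within its ~1/($\delta_{mC1} + \kappa r_C$) lifetime while miR164c lags
with a 2-time-unit lifetime) — but at the *new steady state* CUC1 mRNA in
meristem cells falls. That is a structural property, not a tuning
accident: in meristem cells TCP and miR164a/b vanish, so the mC1 fixed
point is $\beta_{mC1} H^+(S;K_{C1S}) / (\delta_{mC1} + \kappa
(\beta_{rC}/\delta_{rC}) H^+(S;K_{rCS}))$, a function of local STM only,
and the boundary pattern requires exactly the regime ($K_{C1S} \ll
K_{rCS}$) in which that function decreases over the meristem's STM range.
An incoherent feed-forward loop of this shape cannot raise its
steady-state output by raising its input; the induction response is the
meaningful direction check for short-readout experiments, and the
acceptance suite states the steady-state expectation unmodified and
records its failure rather than weakening it.

`local_sensitivity()` perturbs every scalar parameter by ±10% one at a
time, re-solves, and reports the shift in CUC1 peak position, the
relative change in peak amplitude and the relative change in central STM,
sorted by amplitude effect; non-converged perturbations are flagged in
the report rather than fatal.

## 6. Numerical and design choices, in brief

* Discretisation boundaries are strict inequalities; exact two-fold
  deviations are state 1.
* BDeu with ess = 1 and a uniform structure prior; the score-equivalence
  of Markov classes is exact by construction and asserted to 1e-9.
* The annealing budget is proposals, not wall time, for reproducibility;
  schedule constants are the conventional ones stated above.
* UPGMA tie-break: lexicographically smallest cluster-id pair.
* Correlation distance is 1 − Pearson r on row vectors.
* $\pi_0$ smoothing: cubic spline, 3 df, evaluated at $\lambda = 0.95$,
  clamped to (0, 1]; small-sample fallback $\pi_0 = 1$.
* Steady-state tolerance $10^{-9}$ with $t_{\max} = 10^4$; integration
  tolerances rtol $10^{-10}$, atol $10^{-12}$.
* The promoter normalisation $a_0 + a_C + a_S$ is fixed even when
  autoregulation is switched off, so the variant removes the feedback
  term without rescaling the promoter's dynamic range.
* PrIF occupies one end of the file only; `cell_file_geometry(mirrored =
  TRUE)` supports the mirrored layout used by the symmetry checks.

## 7. Known limitations

* The pipeline consumes expression matrices and p-value tables; raw-array
  normalisation and moderated test statistics are out of scope.
* The consensus retention threshold acts on the bidirectional sum of
  frequencies; per-direction retention is not offered.
* The spatial model is one-dimensional, deterministic, with a fixed
  binary PrIF input: no primordium establishment dynamics, auxin
  transport, mechanics, or stochastic expression. Numerical profiles are
  qualitative targets, not quantitative fits.
* A single $\kappa$ serves both microRNA families; distinct efficacies
  would add a parameter without changing the qualitative pattern.
* k-means and annealing outcomes depend on their seeds by nature; all
  entry points take explicit seeds and record them in run manifests.
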