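---
title: "Controllability of anatomical brain networks and moderation of language response times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controllability of anatomical brain networks and moderation of language response times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis in one paragraph

`connectrol` quantifies the theoretical capacity of individual brain
regions to steer large-scale network dynamics, and asks whether that
capacity at a target region (an inferior-frontal-gyrus analog) moderates
language production costs and the behavioral effect of inhibitory
transcranial magnetic stimulation (TMS).  The network side rests on a
noise-free linear discrete-time model over a weighted, undirected
anatomical connectome; the behavioral side on mixed-effects models of
log response times (RTs) from two word-production tasks — sentence
completion and verb generation — performed before and after active or
sham stimulation.

## Dynamics model and modal controllability

A connectome is a graph $G=(V,E)$ on $N$ regions with symmetric,
nonnegative, zero-diagonal adjacency $A=[a_{ij}]$, where $a_{ij}$ is a
streamline density (optionally the raw streamline count divided by the
summed volumes of regions $i$ and $j$; `normalize_by_volume()`).  Node
states evolve as

$$x(t+1) = A\,x(t) + B_K\,u(t),$$

with $B_K = [e_{k_1} \dots e_{k_m}]$ selecting the control set
(`build_input_matrix()`, `control_system()`).  Before analysis the
adjacency is rescaled (`stabilize()`):

* **`mean-edge` (default):** divide every entry by the mean edge weight,
  computed over the *nonzero* off-diagonal entries with each undirected
  edge counted once.  Including structural zeros would make the scale
  depend on network density, and a mean *edge* weight is a statistic of
  edges, not of matrix cells.  This mode does not bound the spectral
  radius.
* **`spectral`:** divide by $1+\lambda_{\max}$, guaranteeing
  $\rho(A)<1$.

Modal controllability of node $i$ is computed from the eigensystem
$A = V\Lambda V^\top$ as

$$\phi_i = \sum_{j=1}^{N}\left(1-\lambda_j^2\right)v_{ij}^2 ,$$

a scaled summary of how well node $i$ can excite all $N$ modes,
especially the fast-decaying (hard-to-reach, high-energy) ones.  Under
`mean-edge` scaling some factors $1-\lambda_j^2$ can be negative
(whenever $\rho(A)>1$); both scalings are exposed and neither behavior
is asserted as the "right" one — the default follows the convention of
rescaling by the mean edge weight, and users who need
$1-\lambda_j^2 \ge 0$ can select `spectral`.  In either mode $\phi$ is
strongly *anticorrelated* with weighted degree on modular weighted
networks (a property the test suite asserts at Spearman
$\rho < -0.3$ across 20 generated networks): weakly connected nodes are
the ones whose input best reaches otherwise-inaccessible configurations.

Gramian diagnostics (`controllability_gramian()`, `is_controllable()`)
certify reachability: $W=\sum_{t=0}^{h-1}A^tBB^\top(A^\top)^t$ with
default horizon $h=N$ (by Cayley–Hamilton, rank cannot grow beyond
that), rank tolerance $N\,\varepsilon\,\sigma_{\max}$.  For symmetric
$A$ with distinct eigenvalues and a single control node the verdict
coincides with the PBH eigenvector test, which the suite checks on
random systems.

## Boundary controllability

Boundary controllers are regions placed to couple or decouple network
modules.  The package operationalizes this in three steps.

1. **Partitioning.** Modularity
   $Q=\frac{1}{2m}\sum_{ij}\left(a_{ij}-\gamma\frac{k_ik_j}{2m}\right)\delta(m_i,m_j)$
   is maximized with a locally greedy Louvain algorithm
   (`louvain_partition()`, delegated to `igraph` with the resolution
   parameter $\gamma$; each run is fully determined by its seed).
2. **Resolution selection.** `sweep_and_select()` runs `n_opt`
   optimizations (default 100) at every $\gamma$ on a grid (default 1.0
   to 4.0 in steps of 0.1) and scores each resolution by the mean
   pairwise z-Rand coefficient of its ensemble — the pair-counting Rand
   statistic standardized against its exact hypergeometric-null mean and
   variance (`zrand()`; the null variance was verified against
   exhaustive permutation enumeration).  $\gamma^*$ maximizes mean
   z-Rand; ties break toward the *smallest* $\gamma$ because coarser
   partitions are the conservative choice for boundary identification.
   Reproducibility-based selection has a known failure mode at extreme
   resolutions (for example, near-singleton partitions at very large
   $\gamma$ are trivially reproducible), which is one reason the grid is
   bounded.
3. **Consensus and ranking.** The ensemble at $\gamma^*$ is summarized
   by association-matrix consensus (`consensus_partition()`): threshold
   the co-assignment frequency matrix at the level expected from random
   label permutations, recluster with the same Louvain procedure, and
   iterate until all runs agree (at most 10 iterations; the modal
   partition is returned with a warning otherwise).  This
   Lancichinetti–Fortunato-style consensus is the default; selecting
   the single max-mean-z-Rand partition is available via
   `method = "best"`.  Per iteration the package runs 20 reclustering
   draws (capped at the ensemble size) — enough to detect disagreement
   while keeping the sweep affordable.

The literature defers the concrete boundary-controllability algorithm
to engineering sources that leave several operational choices open, so
the package defines a deterministic, exactly testable surrogate
(`boundary_controllability()`): each node's *boundary fraction* is the
share of its strength on inter-module edges; nodes with at least one
inter-module edge are boundary nodes and always outrank non-boundary
nodes; ties break by the number of distinct foreign modules, then input
order; non-boundary nodes are ordered by descending strength.  Rank 1
is the *strongest* boundary controller (the direction of "rank" is an
open convention; this package fixes it and also reports the
zero-centered rank $\mathrm{rank}-(N+1)/2$, the form used as the
moderator in the behavioral models).

## Behavioral models

`preprocess_trials()` drops error trials and responses outside
200–10,000 ms (impulsive onsets below, off-task responses above) and
takes the natural log of RT; raw RTs are right-skewed and the log is the
standard transform for lme4-style RT analysis (any log base differs
only by scale).  `split_demands()` discretizes the item covariates —
LSA-style *entropy* (selection demand: how many competing responses an
item invites) and *association strength* (retrieval ease) — by a
per-task median split for interactions with categorical task terms
(values at the median go to `"low"`, a deterministic and documented tie
rule), and centers them per task for interactions with continuous
controllability.

`fit_rt_model()` fits registered model families (see
`model_registry()`; the YAML registry in `inst/extdata/` lists the
fixed effects and trial subset for each).  All families share: response
`log_rt`; maximum-likelihood estimation; random intercept *and* random
trial-order slope per subject (the superset of the two random-effects
descriptions in circulation for this design, with `drop_slope = TRUE`
to fit the intercept-only form); Satterthwaite degrees of freedom, with
a flagged residual-df fallback; treatment contrasts with reference
levels sham / pre / verb_generation / low, which reproduce the sign
conventions of the moderation analyses.  Non-convergent fits are
retried once with a different optimizer and otherwise returned flagged,
never silently.  The between-group comparison of boundary values uses
the unpaired two-sample Wilcoxon rank-sum test
(`compare_groups_boundary()`).

When both volume normalization and stabilization are requested, volume
normalization is applied first (it is part of network *construction*)
and stabilization second (part of the *dynamics* definition), matching
the order in which the two operations are motivated.

## What the synthetic generators emulate

No diffusion-imaging or behavioral recordings ship with the package, so
`generate_connectome()` and `generate_trials()` produce inputs with the
statistical structure the analysis assumes.

**Connectomes** are weighted stochastic-block networks: 111 nodes
(matching the anatomical parcellation size the pipeline emulates), 4
planted modules, within/between edge probabilities 0.5 / 0.0625 (an 8:1
contrast, overall density about 0.17 — in the range of deterministic
tractography networks), and log-normal weights (meanlog 3, sdlog 0.5)
because streamline densities are positive and right-skewed.  The weight
dispersion was fixed at design time: strongly heavy-tailed weights
(sdlog around 1) make weighted modularity fragment modules regardless
of algorithm or seed, which would confound every partition-recovery
property with a weight-law artifact rather than test the machinery.
Real connectomes differ in ways the generator does not model —
spatially embedded hub structure, heavier weight tails,
distance-dependent connection probabilities, nested module hierarchy —
so passing recovery tests demonstrates the correctness of the
machinery, not field performance on empirical tractography data.

**Trials** follow the fitted models' own generative structure: a linear
predictor on log RT over indicator-coded stimulation, session and task,
continuous item covariates drawn per item from Beta(2, 2) (items are
split between sessions and shared across subjects, with per-subject
presentation order), per-subject boundary and modal values entering main
effects and interactions, Gaussian subject intercepts (SD 0.12),
per-subject trial-order slopes (SD 0.002 per trial) and residuals (SD
0.35) — magnitudes that put simulated RTs and their dispersion in the
observed range (about 500–3000 ms around $e^{7.2}$).  Default
coefficients carry the magnitudes of the published moderation analysis
(session slowing 0.072 on sentence completion, TMS-by-session speeding
about −0.092 there, boundary moderation of order 0.001–0.003 per
boundary-rank unit).  Contamination is injected at 0.5% fast
(< 200 ms), 0.5% slow (> 10,000 ms) and 4.5% error trials, giving
per-cell rejection rates in the observed 3–13% band.  Because the
generator matches the fitted model family, recovery and coverage tests
verify the estimation machinery — they cannot detect misspecification
that real data might exhibit (non-Gaussian residuals,
heteroskedasticity across conditions, item random effects).

## Numerical choices and degenerate inputs

* Asymmetry up to $10^{-9}$ is treated as numeric noise and averaged
  away; larger asymmetry is an error (the model assumes symmetric $A$).
  Diagonals must be zero to within $10^{-12}$.
* Indices are 1-based throughout (idiomatic R); label files are the
  source of truth for region identity.  Module ids are contiguous
  integers in order of first appearance, making seeded runs comparable
  with `identical()`.
* z-Rand of degenerate pairs (for example two all-singleton partitions)
  has zero null variance and is defined as 0 with a warning.  Note that
  the raw pair count is always maximized by comparing a partition with
  itself, but the *z-score* is only guaranteed to peak at the identity
  among partners with the same module-size profile: the null variance
  depends on that profile, so z-scores against structurally different
  partners are standardized on different scales (a counterexample on 6
  nodes is exercised in the test suite).
* An edgeless network cannot be stabilized (error); an edgeless graph
  passed to Louvain returns the all-singleton partition with quality
  `NA`.
* Ranks are always a permutation of $1..N$; isolated nodes get boundary
  fraction 0.
* Exclusion preprocessing commutes with task subsetting, so analyses
  may filter in either order.
* Adjacency and report files are written with 17 significant digits, so
  write→read round-trips are bit-identical and the pipeline manifest's
  MD5 hashes are reproducible across runs.

## Problem sizes used by the checks

The test suite exercises oracle equivalence on 8-node systems (100
random draws), partition properties on 48–100-node networks, and the
mixed-model calibration at 200 subjects × 50 trials/cell for coverage
(100 replicates) and 40 subjects for the type-I-error rate (500
replicates) — sizes chosen to give the binomial bounds in the
assertions adequate power while keeping a full run in the minutes
range.  The acceptance script runs the complete pipeline at the study's
own size (41 subjects, 111 nodes, $\gamma$ grid 1.0–4.0 step 0.1) with
24 optimizations per resolution, a reproducibility-ensemble size at
which the mean pairwise z-Rand estimator is already stable on networks
of this size.

## Known limitations

* Boundary controllability here is the inter-module-strength surrogate
  described above, not the hierarchical multiscale algorithm of the
  engineering literature it approximates.
* Reproducibility-based $\gamma$ selection can be attracted to trivially
  stable extremes; bound the grid to the regime of interest.
* Variance (heteroskedasticity) modeling in the mixed models is not
  implemented; there is no stated trigger for when it would be needed.
* Minimum-energy control trajectories and average controllability are
  out of scope.
* The observed-input mode analyzes one network; per-subject empirical
  networks should be run per subject and joined on the subject column.
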