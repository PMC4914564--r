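---
title: "Modeling the dynamics of animal social networks with saomnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the dynamics of animal social networks with saomnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`saomnet` analyses how relationships in a social group change between
repeated network observations ("waves"), using a stochastic actor-oriented
model (SAOM). This vignette explains the model, the data-preparation
conventions, the estimation machinery, the synthetic-data generator used
for validation, and the design decisions taken where the methodology left
genuine choices open.

## From scan samples to binary partner networks

Field observations arrive as scan-sampling records: for a focal animal,
the identities of grooming partners and of neighbors within 1 m and 5 m.
Per three-month period these are tallied into three dyadic count matrices.
Grooming is directed at the count stage and symmetrized by the dyadic sum
(grooming given plus received); proximity is inherently symmetric, so one
record increments both orientations once and the dyad value equals the
record count.

The SAOM operates on binary networks, so each valued matrix is thresholded
at **mean + sd/3** of its dyadic values — computed over *all* unordered
off-diagonal dyads, zeros included, with the sample (n−1) standard
deviation — and a dyad becomes a "mutual preferred social partner" tie
when it strictly exceeds the threshold in **at least two of the three**
behaviors.

Three conventions deserve mention because the protocol leaves them open:

* *Zeros are included in the threshold population.* Excluding them would
  make the threshold depend on the sparsity of observed interaction and
  inflate it in poorly sampled periods; including them is the conservative
  reading of "for each behavioral matrix".
* *Strict inequality.* "Larger than the average" excludes ties at the
  threshold; in the degenerate all-equal case the threshold equals the
  mean and no link can form (a warning is emitted).
* *Mutuality is dyadic, not directional.* Each behavior matrix is
  symmetrized before thresholding, so "mutual associates" means the dyad's
  combined value is high. A per-direction rule (both orientations above
  threshold) would require a directed protocol the data cannot support for
  proximity. The number of behaviors required (default 2 of 3) is the
  `mutuality_rule` configuration entry.

Counts are used raw, not as rates per scan: an optional per-dyad
normalization hook exists in the ingestion layer but is off by default,
since the observation design keeps scan effort approximately balanced
across dyads within a period.

## Dominance ranking

Hierarchies come from winner–loser count matrices via the I&SI criterion:
find an order minimizing the number of inconsistencies *I* (dyads in which
the lower-ranked actor won strictly more often), breaking ties by the
summed rank distances *SI* of the remaining inconsistencies. Dyads with
equal wins in both directions — including never-observed 0–0 dyads —
impose no constraint, which is the standard treatment of unknown
relationships.

For up to 8 actors the optimum is found exhaustively. Beyond that a
heuristic runs pairwise-swap *and* single-actor-insertion descent from the
win-proportion order, with randomized restarts (default 20) because the
(I, SI) landscape has local optima that pure swap descent cannot leave.
On hundreds of random matrices with n ≤ 7 the heuristic attains the
exhaustive optimum (this is asserted in the test suite). When several
orders are optimal, exhaustive mode returns the lexicographically smallest
by actor id and flags the tie.

## The dynamic model

Between two observed waves the network is assumed to evolve by a
continuous-time Markov chain of *microsteps*. Actor *i* receives change
opportunities at rate

$$\lambda_i = \rho_m \exp\Big(\sum_h \alpha_h v_{hi}\Big),$$

where $\rho_m > 0$ is the basic rate of period *m* (the period has unit
duration; $\rho_m$ absorbs the time scale) and the $\alpha_h$ modify the
rate by actor covariates. At an opportunity the actor considers keeping
the network or toggling the tie to one other present actor — $n$ options —
and selects with multinomial-logit probabilities proportional to
$\exp f_i(x')$ of the resulting network, where

$$f_i(x) = \sum_k \beta_k s_{ik}(x)$$

is the evaluation function. The implemented statistics are

| statistic | formula | interpretation |
|---|---|---|
| density | $\sum_j x_{ij}$ | baseline cost/benefit of ties |
| transitive triplets | $\sum_{j,h} x_{ij} x_{ih} x_{jh}$ | triadic closure |
| degree popularity | $\sum_j x_{ij} \deg(j)$ | attraction to central partners |
| covariate similarity | $\sum_j x_{ij}(\mathrm{sim}_{ij} - \overline{\mathrm{sim}})$ | homophily |
| ego × alter | $v_i \sum_j x_{ij} v_j$ | main-effect control for homophily |

Similarity is an equality indicator for categorical covariates (sex,
matriline, age class) and $1 - |v_i - v_j|/\mathrm{range}(v)$ for ordinal
ones (rank), with the range and the centering mean taken over the actors
present in the wave.

Design decisions in this module:

* **The density effect is always included.** A model with only
  transitive-triplet, popularity and similarity terms assigns no cost to
  tie creation and degenerates toward the complete graph; the baseline
  out-degree effect is what keeps the choice model well defined. Model
  constructors refuse a specification without it.
* **Undirected changes use the forcing convention**: the selected actor
  unilaterally imposes the symmetric toggle. This is the simplest
  single-mover scheme and keeps the choice set at size *n*; pairwise
  agreement modalities would change the meaning of the parameters.
* **The degree-dependent rate factor is disabled** (identically 1). Its
  conventional printed form conflates a covariate index with a network
  quantity and no analysis here requires it; rate heterogeneity enters
  through covariates only.
* **Covariate coding.** Similarity and ego × alter use centered
  quantities, following the centered-statistic convention. Rate covariates
  use raw numeric codes, so for a 0/1 covariate $e^{\alpha}$ is directly
  the rate ratio between the two classes — the natural reading of a
  reported rate effect.
* **Composition change.** Actors absent from a wave are structural zeros:
  excluded from mover selection, partner choice, similarity means, and
  from the moment statistics of any period at whose start or end they are
  absent. Joiners enter without ties at a period boundary.

The microstep loop is implemented in C++ (Rcpp) with incremental
change-statistics; a test asserts bit-level agreement between the
incremental evaluation and a full re-evaluation of $f_i$ in R. With all
parameters zero, the chain's transition kernel is symmetric, so its
stationary distribution is uniform over graphs and the long-run edge
density is 1/2 — a property the test suite checks by simulation.

## Estimation

Parameters are estimated by the method of moments with a three-phase
stochastic approximation. The moment targets are, per evaluation effect,
the end-wave statistic summed over jointly present actors and over
periods; per period, the Hamming distance between consecutive waves
(matched by the basic rate $\rho_m$); and per rate covariate, the
covariate-weighted count of per-actor tie changes. Estimation is
unconditional: each period is simulated forward from the *observed*
starting wave.

* **Phase 1** estimates the derivative matrix $D = \partial E[S]/\partial
  \theta$ by *central* finite differences with common random numbers
  (default step 0.2; proportional for rates). Central differences matter:
  the statistic response is convex in the structural parameters near the
  dense regime, and forward differences overestimate slopes, which in turn
  deflates standard errors.
* **Phase 2** iterates $\theta \leftarrow \theta - a D^{-1} (S_{sim} -
  S_{obs})$ in sub-phases (default 4), halving the gain (default 0.2) and
  doubling the iteration count (default base 50) at each, with trajectory
  averaging at sub-phase ends. Updates are trust-region capped (default
  0.5 per parameter per unit gain) and the derivative is conditioned by a
  scaled ridge when near-singular; basic rates are clamped positive.
  After the first sub-phase the derivative is re-estimated at the current
  answer, since the Phase-1 estimate was taken at the start value.
* **Phase 3** simulates at the final estimate (default 500 draws) to get
  per-statistic convergence t-ratios (mean deviation / sd of deviations),
  the statistic covariance $\hat\Sigma$, and delta-method standard errors
  $\sqrt{\mathrm{diag}(D^{-1}\hat\Sigma D^{-\top})}$ with a re-estimated
  derivative. A fit is declared converged when every |t| < 0.15. If the
  check fails, up to `max_retries` further small-gain Phase-2 blocks are
  run from the current answer before giving up.

Initial values: basic rates start at $3H/n$ (a period's Hamming distance
understates the number of microstep changes because back-and-forth
toggles cancel; the factor 3 is a serviceable inflation), other
parameters at the caller's start values.

Inference is by single-parameter Wald tests, $\chi^2_1 =
(\hat\beta/\mathrm{se})^2$. Stepwise forward selection mirrors the
protocol of adding candidates one at a time to a baseline of density plus
rates, keeping an addition only when significant at 0.05 (no
multiple-testing correction, deliberately, following the analytical
protocol this package operationalizes); covariate homophily enters as a
similarity + ego × alter *pair* and is kept only when both members are
significant. A candidate whose refit fails the convergence check is
dropped with an annotation. Joint multi-parameter Wald blocks on the full
covariance are not implemented; published SAOM tables sometimes report
chi-squared values that are not the square of the printed rounded
estimate/se ratio, which single-parameter tests cannot and do not try to
reproduce.

## Goodness of fit

Fit is assessed on auxiliary statistics not directly targeted by the
moments: the degree distribution (0..K; K defaults to the maximum
observed end-wave degree + 2), the geodesic distribution (1..L with L = 5
plus an unreachable bin) and the four-class undirected triad census.
Each period is simulated from the fitted model `n_sims` times; vectors are
pooled (summed) across end waves, and the observed vector's Mahalanobis
distance from the simulated cloud is compared with the simulated
replicates' own distances. Three numerical choices:

* zero-variance coordinates are dropped before inversion, with a
  Moore–Penrose pseudo-inverse as fallback — small simulation samples make
  the covariance singular;
* the one-tailed Monte Carlo p-value uses the add-one estimator
  $p = (1 + \#\{d_{sim} \ge d_{obs}\})/(1 + n_{sims})$, avoiding p = 0;
* simulated distances are computed **leave-one-out** (each replicate is
  removed from its own reference cloud). The observation is never part of
  the cloud, so leave-one-in simulated distances would be systematically
  smaller than the observed one and the test anticonservative; with
  leave-one-out the two are exchangeable under the model and the test
  calibrates (the suite checks a rejection rate near 0.05 under the
  generating model).

A pooled test is the default; `per_wave = TRUE` gives one test per period.

## The synthetic-data generator

Real scan data of this kind are rarely released, so validation runs on a
generator whose defaults emulate the study system the package was built
for: groups of 25–48 vervet monkeys observed over 8 quarterly waves, with
a roughly even sex ratio (observed range 44–56% female), about 40% adults,
a few matrilines holding contiguous rank blocks, and male-biased turnover
available through per-boundary join/leave counts. Scan counts are
Binomial per dyad — `n_scans = 200`, detection 0.3 on true ties against a
0.02 background — with the three behaviors sharing the true network but
carrying independent noise, so the two-of-three rule is genuinely
exercised. Agonistic bouts fall on random dyads and the higher-ranked
actor wins with probability 0.9 by default.

The default truth dynamics are density −1.8, transitive triplets 0.4,
degree popularity 0.1, same-sex homophily 0.5, with basic rate 1.5 per
period from a sparse (density 0.05) start. The rate value is a considered
choice: these structural parameters favor densification, and at
substantially higher rates the simulated panels drift into the
near-complete regime within eight waves, where statistics become
uninformative and estimation degenerates. At rate 1.5 a quarter replaces
a moderate minority of ties — consistent with field reports of
relationship stability over months — and the panels stay informative.

What the generator does *not* emulate: observation effort imbalance
between individuals, observer error, seasonal variation in rates,
behavioral co-evolution (covariates are fixed over waves except presence),
and any dependence of scan detection on dyad strength beyond the binary
tie. Passing recovery tests therefore demonstrates the correctness and
calibration of the machinery on data that satisfy the model's
assumptions, not robustness to the violations real field data bring.

## Problem sizes used in validation

The test suite validates at sizes chosen to exercise the study scale
while keeping a full run practical on one CPU: oracle equivalence of all
effect statistics against brute-force loops on 200 random graphs (n ≤ 8);
null-dynamics density over 50 runs of 5,000 microsteps (n = 10);
parameter recovery over 20 replicates of the full study design (n = 30,
8 waves) with reduced phase budgets; Wald calibration over 200 reduced
replicates (n = 15, 5 waves); selection over 20 replicates (n = 25,
6 waves); I&SI optimality on 200 matrices (n ≤ 7); binarization recovery
over 50 replicates; GOF calibration over 100 replicates. The acceptance
script reruns scaled-down versions of the same experiments from a single
seed.

## Known limitations

* Directed-network effects (e.g., reciprocity) and behavior co-evolution
  are out of scope; the engine is undirected-only.
* Only single-parameter Wald tests are provided; no score-type tests for
  fixed effects, no multi-group or multilevel joint estimation.
* Method-of-moments estimates on short sparse panels carry finite-sample
  bias along weakly identified directions (notably the transitive-triplet
  / degree-popularity pair); reported standard errors reflect this
  uncertainty, and the recovery tests check coverage, not exactness.
* The estimator assumes the panel stays away from the empty and complete
  boundaries; degenerate chains are caught by a microstep cap and
  reported rather than silently truncated.
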