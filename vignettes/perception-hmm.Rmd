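---
title: "Perception-augmented hidden Markov models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perception-augmented hidden Markov models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

perceptHMM fits a three-layer latent-state model for longitudinal
multivariate outcomes reported by several members of a cluster — the
motivating design is a parent–child dyad followed over clinic visits in a
two-arm behavioral trial, with each member reporting two questionnaire
scores per visit.

## The model

**Layer 1 — cluster chain.** Each cluster $i$ carries an unobserved state
sequence $Z_{it} \in \{1,\dots,C\}$ forming a first-order, time-homogeneous
Markov chain with arm-specific initial probabilities $\pi^{s}$ and
transition matrices $P^{s}$. Arm-specific transition matrices are the
vehicle for asking whether an intervention changes how clusters move
between relationship states.

**Layer 2 — perception.** Member $m$ does not observe $Z_{it}$ but forms a
perceived state $Z^m_{it} \in \{1,\dots,C_m\}$ through a row-stochastic
perception matrix $Q^m$: $\Pr(Z^m_{it}=j \mid Z_{it}=k) = Q^m_{kj}$,
independently across members given the cluster state. Three perception
modes are supported: *identity* ($Q^m = I$, collapsing the model to the
mixed hidden Markov model, MHMM), *shared* (member-specific, arm-common
$Q^m$ — the pHMM), and *arm-specific* ($Q^{m,s}$ — the pHMMe).

**Layer 3 — emissions.** Given $Z^m_{it}=k$, outcome $j$ of member $m$ is
Gaussian with mean $u_k^\top \tau^m_j + X_{it}^\top \beta^m_j + b_{ie}$ and
variance $u_k^\top \gamma^m_j$, where $u_k$ has ones in its first $k$
entries: state means and variances are *cumulative sums* of the increment
vectors $\tau$ and $\gamma$. Each of the $r = \sum_m J_m$ outcome series
loads one coordinate of a cluster random effect
$b_i \sim N_r(0, \Sigma)$, giving correlated series within a cluster.
Missing outcome cells contribute no emission factor (conditional
independence makes cell-wise omission exact), so no imputation step is
required.

The observed-data likelihood marginalizes the member states analytically:
the forward recursion uses visit-level mixture matrices $G(y_{it})$ whose
$h$-th diagonal entry is
$\prod_m \sum_k \left[\prod_j f(y^m_{ijt} \mid k)\right] Q^m_{hk}$.
The sum over the perceived state sits *outside* the product over that
member's outcomes, because a single perceived state drives all of a
member's outcomes at a visit. (An alternative published rendering places
the product outside the sum; that outcome-wise form contradicts the
generative model and is almost surely a typographical slip, but it is
available via `g_form = "printed"` for comparison.) The index convention
is $Q^m[h \to k]$ = probability that cluster state $h$ is perceived as
member state $k$ — the only reading that makes $G$ a proper mixture.

## Priors and the Gibbs sampler

All priors are conjugate where possible: symmetric Dirichlet(1) on every
row of $\pi$, $P$ and $Q$; a flat prior on the regression block
$(\tau, \beta)$; inverse-Gamma(0.001, 0.0002) on variance parameters;
inverse-Wishart($r+1$, $I$) on $\Sigma$. The sampler alternates

1. forward-filtering backward-sampling (FFBS) of each cluster's state
   path from its exact conditional, using per-visit scaled forward
   probabilities (scaling constants double as the pointwise
   log-likelihood record);
2. member-state draws $Z^m_{it} \propto Q^m[Z_{it} \to k]\prod_j f(y \mid k)$;
3. Dirichlet updates of $\pi$, $P$ (counts by arm) and $Q$ (cluster-state
   by member-state cross-counts, pooled or by arm);
4. a joint weighted-least-squares Gaussian draw of $(\tau, \beta)$ per
   series, with the cumulative state encoding as design columns (a ridge
   jitter, logged, covers the rank-deficient case of a never-visited
   state);
5. variance updates (two parameterizations, below);
6. exact Gaussian draws of each $b_i$ (the cluster precision matrices
   share $\Sigma^{-1}$ and differ only on the diagonal, so a small
   Cholesky is unrolled across clusters);
7. an inverse-Wishart draw of $\Sigma$.

**Variance parameterization.** The inverse-Gamma prior is stated on the
variance *increments* $\gamma$, which forces nondecreasing state
variances and is jointly non-conjugate — and the source text is silent on
how it was actually sampled. The package default is therefore a `direct`
mode: per-state variances get independent conjugate inverse-Gamma
updates, and increments (possibly negative) are derived afterwards. The
faithful `increments` mode runs per-increment random-walk Metropolis on
the log scale under the inverse-Gamma prior, counting rejections; it
enforces monotone variances, a real modeling constraint that `direct`
mode deliberately drops.

**Two-phase schedule.** A short adaptation run is followed by a longer
inference run started from the adaptation run's posterior means. Default
lengths are 4000/3000 and 40000/30000 (iterations/burn-in); all study
code in this package uses reduced schedules (300/150 plus 1600/800 at
thinning 2 for the acceptance computations; shorter in unit tests),
chosen as the package's reduced problem scale.

**Relabeling.** Latent labels are only identified up to permutation.
Although label switching may never occur in a well-separated application,
a library must guard: after every iteration, states of a reference
member-outcome series (by default the last member's first outcome — the
parent task-involvement score, whose state means are strictly decreasing
in the motivating analysis) are ordered by decreasing state mean; cluster
states are then aligned to the reference member through the dominant
diagonal of its perception matrix, and remaining members likewise. In
`increments` variance mode a permutation that would break variance
monotonicity is skipped and counted. Relabeling events are reported in
the fit metadata.

**Initialization.** Cluster states are initialized by quantile-binning a
composite standardized outcome score per cluster-visit; $b$ starts at
zero and $\Sigma$ at the prior scale. The source analysis reports no
initialization scheme; this one is deliberately crude and cheap, with
phase 1 absorbing its bias.

## The scenario simulator

`scenario_preset()` encodes three generating configurations for a
390-cluster, five-visit, two-member, two-outcome, two-arm panel with
three latent states (Discordant, Harmonious, Indifferent):

* initial probabilities $(0.76, 0.18, 0.06)$ — the explicitly stated
  generating values (the fitted table's initial column, which sums to
  1.01 after rounding, is not used);
* arm-specific transition matrices and member perception matrices taken
  from the fitted tables of the motivating analysis (one perception row
  summing to 0.99 after rounding is renormalized);
* state means from the fitted fixed-effects table (non-monotone across
  states for the task-involvement series, which is why mean increments
  may be negative);
* scenario 1 uses identity perception, scenario 2 the member-specific
  matrices, scenario 3 adds a synthetic arm-specific sharpening
  (row-normalized midpoint between the scenario-2 matrix and the
  identity) for the intervention arm, since the true arm-specific
  matrices are not published.

**Emission variances.** Within-state variances and $\Sigma$ are not
published. They are fixed once at within-state variance 1 for the
task-involvement scores and 0.003 for log-conflict scores, random-effect
variances 4 and 0.01, and cross-correlations 0.3. The reasoning:
within-state reporting noise must sit below the between-state mean gaps
for the documented three-class structure to be recognizable, family-level
heterogeneity plausibly dominates within-state noise (a high intraclass
correlation, typical of repeated family questionnaires), and — decisive —
under this configuration the correctly specified model reproduces the
recovery regime the original simulation study reports (posterior means
close to the generating values, near-nominal interval coverage). Noisier
configurations that also match the real data's observed total variances
make the states substantially harder to separate than that reported
recovery behavior implies.

Covariates mimic the trial cohort: gender Bernoulli(0.49) and baseline
age Normal(12.5, 1.5²) truncated to [8, 17] (the age spread is not
published; the truncation spans pre-adolescence/adolescence). Emission
coefficients default to zero because only state intercepts are published.
Arms alternate 1:1 by default (195/195), with a `"trial"` option fixing
the 201/189 margin.

What the generator does **not** emulate: dropout and informative
missingness (cells can be blanked but no mechanism is modeled), visit
timing irregularity, non-Gaussian questionnaire floors/ceilings, and any
time-inhomogeneity in transitions or perception. Passing recovery tests
therefore speak to estimator correctness under the model, not to
robustness against these real-data features.

## Model assessment

* **WAIC** uses pointwise log-likelihood per cluster-visit, conditional
  on each draw's random effects, with member states marginalized through
  $G$ — the natural unit given what FFBS already computes, and standard
  for mixed HMMs. A marginal option Monte-Carlo-integrates the random
  effects with the cluster as pointwise unit; whether the original
  analysis conditioned on $b$ is unstated, so both are provided.
* **Posterior predictive checks** simulate full replicate panels (new
  latent paths, new random effects, observed design and missingness
  pattern retained) from sampled draws and place the observed mean and
  variance of each outcome series within the predictive distributions.
  Note one systematic reduced-scale effect: the inverse-Wishart prior
  with identity scale inflates very small random-effect variances (the
  log-conflict series) for panels much smaller than the trial, which
  pushes those variance placements low; the effect shrinks as $N$ grows.
* **Pseudo-residuals** are one-step-ahead forecast residuals:
  $\Phi^{-1}$ of the predictive CDF of each cell given the cluster's
  earlier visits, averaged over draws (visit-1 cells use the
  initial-distribution predictive). Forecast residuals were chosen over
  ordinary (leave-one-out) residuals; the cited methodology supports
  both and the source does not say which was used. CDF values are
  clipped to $(\varepsilon, 1-\varepsilon)$ with the clip count reported.
* **Convergence summaries** give rank-normalized split-R-hat and
  autocorrelation-based effective sample sizes per scalar parameter.

## Summaries and metrics

Arm contrasts (transition entries and stationary distributions) and
parent-minus-child perception contrasts are computed per posterior draw
and then summarized with central 95% credible intervals — differences of
draws, not differences of posterior means. Stationary distributions come
from a direct linear solve with a Cesàro-average fallback (flagged) for
reducible draws, which are excluded from contrasts with a logged count.

Latent states are decoded by the per-cell posterior mode (ties to the
lowest index). The identity-model (MHMM) perception approximation fits
the identity-perception model to the full panel and to each member's
outcomes alone, decodes each fit, aligns member labels to the family fit
by the agreement-maximizing permutation — the member-specific outcome
means are not monotone for the child, so the reference-ordering rule
cannot align a child-only fit — and row-normalizes the cross-tab of
decoded states; `constrained` mode freezes the member fits' emission
parameters at the family fit's posterior means.

State-calling metrics implement the six published criteria exactly,
including an F-score written as $PR/(P+R)$ — half the conventional
harmonic mean, so perfect calling scores 0.5. The printed formula is the
default for fidelity; `f_score = "conventional"` restores the factor 2.
Before scoring, predicted labels are aligned to the truth by exhaustive
permutation search ($C! \le 120$), since latent labels are arbitrary and
the published criteria presuppose aligned labels without saying how.

## Numerical choices

Per-visit scaling (normalized forward rows with accumulated log
constants) rather than log-space recursion, because FFBS needs the
filtered probabilities anyway. Mixture sums use max-shifted
exponentiation. Variance draws for states with no assigned cells are
clamped to $[10^{-12}, 10^{12}]$ to absorb inverse-Gamma(0.001, ·)
under/overflow. The regression ridge fallback starts at $10^{-8}$ times
the mean normal-matrix diagonal and escalates tenfold, with events
counted. All state indexing is 1-based in the public data model.

## Known limitations

Transition and perception matrices are time-homogeneous and
covariate-free; emissions are Gaussian only; unequal member state counts
are supported by the machinery but weakly identified (a common count is
the intended use); the reduced schedules used by the packaged studies
trade Monte Carlo precision for runtime, and posterior means of simplex
entries inherit a mild pull toward uniformity from the Dirichlet(1)
prior at trial-scale information.
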