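# perceptHMM

Bayesian perception-augmented hidden Markov models (pHMM) for
longitudinal multivariate outcomes reported by several members of a
cluster — typically a parent–child dyad followed over clinic visits in a
randomized behavioral trial, each member completing the same
questionnaires at each visit.

## The problem and the model

Questionnaire scores from both members are driven by an unobserved,
evolving cluster-level state (e.g., a Discordant / Harmonious /
Indifferent parent–child relationship), but the two members may
*perceive* that state differently, so forcing a single shared hidden
state (the mixed hidden Markov model, MHMM) misattributes their
disagreement to noise. The pHMM inserts a perception layer:

1. **Cluster chain** — $Z_{it} \in \{1,\dots,C\}$ is first-order Markov
   with arm-specific initial probabilities $\pi^s$ and transition
   matrices $P^s$, so treatment effects on relationship dynamics are read
   off arm contrasts of $P^s$ and of its stationary distribution.
2. **Perception** — member $m$ perceives state $k$ as $j$ with
   probability $Q^m_{kj}$ (row-stochastic; optionally arm-specific,
   "pHMMe"; the identity matrix recovers the MHMM).
3. **Emissions** — given the perceived state $k$, outcome $j$ of member
   $m$ is Gaussian,
   $y^m_{ijt} \sim N(u_k^\top \tau^m_j + X_{it}^\top \beta^m_j + b_{ie},\;
   u_k^\top \gamma^m_j)$, with cumulative-sum state means/variances and a
   cluster random effect $b_i \sim N_r(0, \Sigma)$ correlating the
   outcome series. Missing cells simply drop out of the likelihood.

Estimation is a conjugate Gibbs sampler (Dirichlet rows,
forward-filtering backward-sampling for state paths, weighted least
squares for $(\tau,\beta)$, inverse-Gamma variances, inverse-Wishart
$\Sigma$) with per-draw relabeling to guard against label switching.
Model assessment: WAIC, posterior predictive checks, forecast
pseudo-residuals, effective-sample-size / split-R-hat summaries. A
scenario simulator, arm and perception contrasts, posterior-mode state
decoding, and multi-class state-calling metrics round out the toolkit.
See the methods vignette (`vignettes/perception-hmm.Rmd`) for the design
decisions and numerical details.

## Worked example

Simulate a two-arm panel from the shared-perception scenario truth
(child and parent perceive differently) and refit it:

```r
library(perceptHMM)

preset <- scenario_preset(2, N = 150)          # pHMM truth, 150 dyads, 5 visits
sim    <- simulate_dataset(preset, seed = 42)
spec   <- model_spec(C = 3, M = 2, J = c(2, 2), S = 2, q = 2,
                     perception_mode = "shared")
cfg    <- sampler_config(phase1_iter = 200,  phase1_burn = 100,
                         phase2_iter = 1000, phase2_burn = 500,
                         thin = 2, seed = 7)
fit <- run_sampler(sim$panel, spec, cfg)
summary(fit)
```

```
initial probabilities (posterior mean; rows = arms):
      [,1]  [,2]  [,3]
[1,] 0.768 0.150 0.082
[2,] 0.787 0.115 0.097
perception matrix, member 1 (posterior mean):
      [,1]  [,2]  [,3]
[1,] 0.477 0.485 0.038
[2,] 0.082 0.717 0.201
[3,] 0.032 0.318 0.651
perception matrix, member 2 (posterior mean):
      [,1]  [,2]  [,3]
[1,] 0.753 0.219 0.027
[2,] 0.042 0.898 0.059
[3,] 0.012 0.027 0.962
```

The generating initial probabilities were (0.76, 0.18, 0.06), the
child's first perception row (0.52, 0.44, 0.04) and the parent's
(0.75, 0.23, 0.02): the fit recovers the child's diffuse perception and
the parent's near-identity perception. Member contrasts quantify the
difference per posterior draw:

```r
pc <- perception_contrasts(fit)           # parent minus child
pc[pc$contrast %in% c("Q[1->1]", "Q[2->2]", "Q[3->3]"), ]
```

```
 contrast mean lower upper excludes_zero
  Q[1->1] 0.28 0.100  0.45          TRUE
  Q[2->2] 0.18 0.029  0.33          TRUE
  Q[3->3] 0.31 0.210  0.41          TRUE
```

All three diagonal contrasts exclude zero: the parent is credibly more
likely than the child to perceive the relationship state as it is.
Model comparison uses WAIC on the stored pointwise log-likelihoods:

```r
waic(fit)
#> WAIC (conditional): 2487.2  (lppd -675.4, p_waic 568.2)
```

A thin command-line front end over the same functions ships in
`inst/cli/phmm.R` (`simulate`, `fit`, `waic`, `ppc`, `summarize`,
`metrics`, `recover`).

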