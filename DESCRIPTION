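Package: perceptHMM
Title: Perception-Augmented Hidden Markov Models for Longitudinal
    Multi-Member Cluster Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits perception-augmented hidden Markov models (pHMM) to
    longitudinal multivariate outcomes collected from several members of a
    cluster (for example parent-child dyads followed over clinic visits). A
    cluster-level latent Markov chain with arm-specific initial and
    transition probabilities is perceived by each member through a
    row-stochastic perception matrix, and member-level latent states drive
    Gaussian mixed-effect emissions with cumulative-sum state means and
    variances. Estimation is by a conjugate Gibbs sampler with
    forward-filtering backward-sampling. Includes a scenario simulator,
    WAIC model selection, posterior predictive checks, forecast
    pseudo-residuals, arm and member contrasts with credible intervals,
    and multi-class latent-state-calling metrics. The mixed hidden Markov
    model (MHMM) is recovered as the identity-perception special case.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
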