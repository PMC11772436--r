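---
title: "Modeling latent crisis states in experience-sampling data with multilevel hidden Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling latent crisis states in experience-sampling data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`crisishmm` analyzes intensive longitudinal experience-sampling (ESM)
panels: each patient answers a short symptom questionnaire several times
a day, yielding, per patient, a multivariate time series of `K`
continuous scores on a 1–100 scale. The working model is a multilevel
(mixed-effects) hidden Markov model:

* At each occasion `t` a patient occupies a latent state
  `S_t ∈ {1, …, m}` interpreted as a crisis severity level. States
  follow a first-order Markov chain: the distribution of `S_{t+1}`
  depends only on `S_t` through a patient-specific transition matrix
  `Γ_i`.
* Given the state, the `K` channels are conditionally independent
  Gaussians: `y_{ikt} | S_t = s ~ N(μ_{isk}, σ_{sk})`. Emission SDs
  `σ_{sk}` are shared across patients; that is the parsimonious
  variance structure — random effects sit on the emission means and on
  the transition probabilities, which is where the substantive
  patient heterogeneity lives.
* The two-level hierarchy: patient emission means are drawn from the
  group level, `μ_{isk} ~ N(μ_{sk}, τ_{sk})`. Transition rows are
  parametrized as multinomial logits with the row's first column as
  reference category, `α_i[s, j] = log Γ_i[s, j+1] / Γ_i[s, 1]`, and
  patient logits get independent Gaussian random effects,
  `α_i[s, j] ~ N(ᾱ[s, j], ω[s, j])`. The logit scale is what makes
  Gaussian random effects on a probability simplex coherent.
* The first occasion's state distribution is the stationary
  distribution of `Γ_i`, recomputed for every parameter draw. The
  alternative — estimating a free initial distribution from one
  observation per patient — is essentially unidentified at these
  panel sizes, and stationarity matches the steady-state reading of
  an ongoing clinical process.
* Missing occasions are missing at random: a fully missing occasion
  contributes no emission factor but still advances the transition
  structure. The chain is never split at gaps, which encodes the
  equal-spacing assumption of the design (the overnight interval is
  treated like any other; that is a known approximation).

## Priors

"Weakly informative" is made concrete and scale-aware for 1–100 scores:
group emission means `N(50, 25²)` (centered on the scale, covering it
at 2 SD); `σ` and `τ` half-Cauchy(0, 10); group transition logits
`N(0, 5²)` (probabilities from ~e^-10 to ~1); `ω` half-Cauchy(0, 1)
(logit-scale heterogeneity up to "very large" with heavy tails). The
half-Cauchy priors enter through their inverse-gamma scale-mixture
representation, so every variance update in the sampler is a conjugate
Gibbs draw.

## Estimation

`fit_mhmm()` is a Metropolis-within-Gibbs sampler. Per iteration:

1. **State paths** — exact forward-filtering backward-sampling (FFBS)
   per patient, sharing one scaled forward pass with the likelihood
   computation.
2. **Subject parameters** — conjugate Gaussian updates for subject
   emission means given the sampled states; row-wise Gaussian
   random-walk Metropolis on subject transition logits (three scans per
   iteration), with the proposal SD adapted toward 0.35 acceptance
   during burn-in by a Robbins–Monro recursion and frozen afterwards so
   detailed balance holds exactly in the retained draws.
3. **Group parameters** — conjugate draws for group means, `τ`, `σ`,
   `ᾱ` and `ω` (inverse-gamma via the mixture auxiliaries).
4. **Interweaving moves** — the centered updates above mix slowly when
   each patient carries little information about a parameter, which is
   exactly the regime of 26 patients × 60 occasions. The sampler
   therefore alternates with non-centered (ancillarity–sufficiency)
   kernels: an exact Gaussian redraw of each group mean with the
   subject offsets held fixed; a log-scale Metropolis rescale of each
   `τ` cell with standardized offsets fixed; a translation move that
   shifts a group logit cell together with every patient's
   corresponding cell; and the matching rescale for each `ω` cell.
   These moves are what brings the Gelman–Rubin statistics of the
   transition hyperparameters under the 1.20 bound at realistic panel
   sizes.

Chains are initialized from a k-means clustering of the complete
occasions (centers ordered by the severity channel, jittered per
chain). A per-channel quantile initialization was rejected after it
proved actively harmful: it forces every channel's starting means to be
monotone across states, and when the true state structure is
non-monotone in a channel — contact desire is lowest in the *worst*
state — chains started that way can settle in a spurious mode. K-means
respects the joint structure and is the standard mixture-model
starting-value recipe.

Label switching is handled after sampling: `relabel_states()` permutes
every retained draw so the group negative-affect means ascend with the
state index (ties broken by self-control descending, then state
index). Negative affect is the ordering channel because it is monotone
and well separated across severity levels. Transition parameters are
permuted exactly on the probability scale and mapped back to logits;
`ω` has no exact transform under a reference-category change and is
permuted by row and destination state — an approximation that only
touches draws where a permutation actually fired (counted in
`$relabel_count`, typically zero or a whole chain in a consistent
alternative labeling).

Everything is driven by R's RNG with derived seeds per patient, chain
and stage, so a run is replayable bit-exactly and a simulated panel is
stable under patient subsetting.

## The synthetic-data generator

`default_study_config()` encodes the design the package emulates:
26 patients × 60 occasions (3 beeps/day), five channels
(self-control, negative affect, contact avoidance, contact desire,
suicidal ideation), four states whose group-level emission means and
staying probabilities (0.84, 0.73, 0.63, 0.57) are set to the reported
sample-level estimates, and whole-occasion missingness at rate
14.23/60 ≈ 0.237, applied completely at random. Quantities the source
tables do not pin down are package defaults, chosen once: off-diagonal
transition mass follows the reported qualitative switching pattern
(rows 0.84/0.10/0.04/0.02, 0.06/0.73/0.14/0.07, 0.04/0.20/0.63/0.13,
0.02/0.13/0.28/0.57); `within_sd = 12` and `between_sd = 8` score
points and `transition_re_sd = 0.7` logits give visible but
recoverable heterogeneity; the initial distribution is the stationary
distribution of the group matrix.

What the generator does *not* emulate: bounded, integer-ish response
styles (scores are continuous Gaussians; clipping to [1, 100] is a
realism toggle that should stay off for recovery experiments, since
the model itself assumes unbounded Gaussians), unequal overnight
intervals, channel-wise partial missingness, and any dependence of
missingness on severity. Passing recovery tests therefore demonstrates
that the estimation machinery is correct under the model's own
assumptions — not that real crisis data satisfy those assumptions.

## Numerical choices

* Forward recursions use normalized filtered probabilities with
  accumulated log scalers (per-occasion max-subtraction), so FFBS, the
  likelihood and the filter share one pass and cannot underflow for
  any realistic panel; genuine underflow raises an error naming the
  occasion.
* Viterbi ties break toward the lower state index (deterministic
  output; ties have measure zero for continuous emissions).
* Variances are floored at tiny values (`τ² ≥ 1e-12`, `σ² ≥ 1e-8`) so
  degenerate no-heterogeneity configurations remain computable.
* Transition summaries are computed on the probability scale per draw
  and then summarized cellwise; cellwise medians of simplex draws need
  not sum to 1, so the point matrices are renormalized and the long
  summaries document the raw medians.
* AIC is `-2·Σ_i ℓ_i(group point parameters) + 2p` with
  `p = 2mK + m(m-1)`: group emission means and SDs plus group
  transition logits, evaluated at posterior medians. Counting only
  group-level parameters makes the criterion a comparison of
  sample-level descriptions; the subject level is integrated out of
  the comparison rather than penalized, a deliberate and documented
  convention.
* Pseudo-residuals are one-step-ahead probability integral transforms
  under the state-prediction-weighted Gaussian mixture, mapped through
  the standard normal quantile, using subject-level posterior-median
  parameters; PITs of exactly 0/1 are clamped and counted.

## Problem sizes used in the shipped checks

The recovery experiment fits 3 chains of 15,000 iterations (7,500
burn-in) to one 26 × 60 panel — a deliberate extension of the study's
10,000/5,000 protocol because the transition random-effect hierarchy is
the slowest-mixing block at this panel size. State-count selection runs
shorter single chains (1,500 iterations, half burn-in) per candidate
`m` over several seeds: long enough for the group-level point
parameters that enter the AIC to stabilize, though far too short for
reporting parameter estimates. On panels this small the 3- versus
4-state decision is genuinely close — adjacent severity states overlap
— so selection is assessed as a majority across seeds rather than
per-panel.

## Known limitations

* Discrete-time with equal spacing; no continuous-time or semi-Markov
  variant, no covariates on transitions or emissions.
* Diagonal random-effect covariance (independent logit cells and
  independent mean cells); correlated heterogeneity is absorbed only
  approximately.
* With weakly separated adjacent states (states 2 and 3 in the default
  configuration), group-level posteriors are honest but diffuse at
  n = 26 patients; point recoveries of extreme cells (e.g. a true mean
  of 3.85 on a 1–100 scale) carry credible intervals several score
  points wide, and state-allocation ambiguity can push posterior
  medians a few points toward the adjacent state's values while
  coverage is preserved.
* The AIC convention above is one of several defensible choices; it is
  recorded in the output rather than claimed universal.
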