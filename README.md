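# crisishmm

Multilevel Bayesian hidden Markov models for experience-sampling (ESM)
crisis data.

## What problem this solves

Patients at risk of (suicidal) crisis fluctuate between qualitatively
different symptom configurations — low-symptom periods, rising
distress, full crisis — and those dynamics differ strongly between
individuals. Intensive longitudinal ESM designs (a few short
self-report questionnaires per day over weeks) capture the raw
fluctuations, but turning ~60 noisy multivariate measurements per
patient into interpretable *states* and *transition dynamics* needs a
model. `crisishmm` implements the multilevel (mixed-effects) hidden
Markov model for this setting, for methodologists and applied
researchers working with ESM panels of continuous symptom scores.

The model: at occasion `t` patient `i` occupies a latent crisis state
`S_t ∈ {1, …, m}` following a first-order Markov chain with
patient-specific transition matrix `Γ_i`; given the state, the `K`
symptom channels are conditionally independent Gaussians
`y_kt ~ N(μ_i[s,k], σ[s,k])`. Patient parameters are tied together by
a second level: emission means `μ_i[s,k] ~ N(μ[s,k], τ[s,k])` and
transition-row logits `α_i[s,j] ~ N(ᾱ[s,j], ω[s,j])` (multinomial-logit
parametrization, reference = staying column 1 of each row). Estimation
is by Metropolis-within-Gibbs MCMC with exact forward-filtering
backward-sampling of the state paths, interweaved centered/non-centered
kernels for the hierarchy, post-hoc severity relabeling, AIC selection
of `m`, Gelman–Rubin convergence checks, posterior predictive checks,
one-step-ahead pseudo-residuals, and Viterbi decoding of per-patient
trajectories. A seeded synthetic-data generator reproduces the
26-patients × 60-occasions, 5-channel, 4-state study design (with its
beep-level missingness) so the whole pipeline is testable without
restricted clinical data.

## Worked example

A small two-state run (12 patients × 60 occasions simulated from the
generator, two chains):

```r
library(crisishmm)

cfg <- default_study_config(seed = 8, clip_to_scale = FALSE)
cfg$n_patients <- 12L
cfg$m <- 2L
cfg$group_means <- cfg$group_means[c(1, 4), ]   # low-crisis and crisis profiles
cfg$between_sd <- cfg$between_sd[c(1, 4), ]
cfg$within_sd  <- cfg$within_sd[c(1, 4), ]
cfg$group_transition <- matrix(c(0.85, 0.15, 0.30, 0.70), 2, 2, byrow = TRUE)
cfg$init_distribution <- stationary_distribution(cfg$group_transition)

sim  <- simulate_panel(cfg)
fit  <- relabel_states(fit_mhmm(sim$panel, m = 2, n_iter = 2000,
                                burn_in = 1000, chains = 2, seed = 8))
summ <- posterior_summary(fit)
summ
#> Multilevel HMM posterior summary (2000 draws)
#> Group emission means (posterior medians):
#>      self_control negative_affect contact_avoidance contact_desire
#> [1,]        42.75           31.19             17.03          41.79
#> [2,]        12.71           73.29             44.97           4.15
#>      suicidal_ideation
#> [1,]              1.46
#> [2,]             69.94
#> Staying probabilities (median [95% CI]):
#>   state 1: 0.812 [0.729, 0.872]
#>   state 2: 0.712 [0.627, 0.780]

max(gelman_rubin(fit))
#> [1] 1.006

dec <- decode_trajectories(sim$panel, subject_point_params(summ))
occupancy_and_trajectories(dec, m = 2)$pooled_incidence
#> [1] 0.635 0.365
```

Reading the output: the two recovered states reproduce the generating
profiles (state 1 ≈ calm: high self-control, negative affect ~31,
almost no suicidal ideation; state 2 ≈ crisis: self-control collapsed,
suicidal ideation ~70, contact desire near the floor at 4). The
staying probabilities — the diagonal of the group transition matrix —
recover the generating 0.85/0.70; both chains agree (max R̂ 1.006);
and patients spend about 64% of decoded occasions in the calm state.
On this synthetic panel the Viterbi-decoded states match the true
simulated states on 94% of occasions.

The same workflow scales to the full design:
`simulate_panel(default_study_config())`, `fit_mhmm(panel, m = 4, …)`,
`select_num_states(panel, 2:5, …)` for the AIC table,
`state_composition()` / `dynamics_summary()` /
`occupancy_and_trajectories()` for the reporting tables, or
`run_pipeline()` to execute every stage into an output directory with
a replayable manifest.

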