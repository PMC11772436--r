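# The multilevel sampler: initialization, conjugate blocks, label
# control, and posterior summaries.

small_panel <- function(seed = 1, n = 6, Tn = 40, m = 2, miss = 0.1) {
  cfg <- default_study_config(seed = seed, clip_to_scale = FALSE,
                              missing_rate = miss)
  cfg$n_patients <- as.integer(n)
  cfg$n_occasions <- as.integer(Tn)
  if (m == 2) {
    cfg$m <- 2L
    cfg$group_means <- cfg$group_means[c(1, 4), ]
    cfg$between_sd <- cfg$between_sd[c(1, 4), ]
    cfg$within_sd <- cfg$within_sd[c(1, 4), ]
    cfg$group_transition <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE)
    cfg$init_distribution <- stationary_distribution(cfg$group_transition)
  }
  simulate_panel(cfg)
}

test_that("chain initialization is ordered, seeded and guards bad input", {
  sim <- small_panel(seed = 4, n = 10, Tn = 60, m = 2)
  ini1 <- init_chain(sim$panel, m = 4, seed = 1)
  ini2 <- init_chain(sim$panel, m = 4, seed = 2)
  # negative-affect initial means non-decreasing across states
  expect_true(all(diff(ini1$group$mu[, 2]) >= 0))
  # different seeds give different starting values
  expect_false(isTRUE(all.equal(ini1$group$mu, ini2$group$mu)))
  # two-point mixture: m = 2 initial means bracket the modes
  ini <- init_chain(sim$panel, m = 2, seed = 3)
  na_means <- ini$group$mu[, 2]
  expect_lt(na_means[1], 45)
  expect_gt(na_means[2], 55)
  # entirely missing channel is a data error
  bad <- sim$panel
  bad$contact_desire <- NA_real_
  expect_error(init_chain(bad, 2), "entirely missing")
})

test_that("m = 1 fit reduces to the hierarchical Gaussian means model", {
  set.seed(15)
  n <- 20; Tn <- 40
  truth <- c(25, 70)
  panel <- do.call(rbind, lapply(seq_len(n), function(i) {
    mu_i <- truth + rnorm(2) * 6
    data.frame(patient_id = i, occasion = 1:Tn, day = 1, beep = 1,
               ch1 = rnorm(Tn, mu_i[1], 10), ch2 = rnorm(Tn, mu_i[2], 10))
  }))
  fit <- fit_mhmm(panel, m = 1, n_iter = 1500, burn_in = 500, seed = 8)
  s <- posterior_summary(relabel_states(fit))
  g <- s$group[s$group$parameter == "emission_mean", ]
  for (k in 1:2) {
    post_sd <- (g$upper[k] - g$lower[k]) / (2 * 1.96)
    expect_lt(abs(g$median[k] - truth[k]), 2.5 * post_sd + 0.5)
  }
  gs <- s$group[s$group$parameter == "emission_sd", ]
  expect_equal(gs$median, c(10, 10), tolerance = 0.08)
})

test_that("conjugate blocks match closed-form posterior moments", {
  # one-state, one-channel, no-missing panel: group mean posterior given
  # sigma and tau has a closed form we can compute from the sufficient
  # statistics; the sampler must agree within Monte-Carlo error
  set.seed(33)
  n <- 12; Tn <- 30
  tau_t <- 4; sig_t <- 6; mu_t <- 40
  mu_is <- mu_t + rnorm(n) * tau_t
  panel <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(patient_id = i, occasion = 1:Tn, day = 1, beep = 1,
               ch1 = rnorm(Tn, mu_is[i], sig_t))
  }))
  fit <- fit_mhmm(panel, m = 1, n_iter = 4000, burn_in = 1000, seed = 2)
  s <- posterior_summary(relabel_states(fit))
  # marginal posterior of the group mean: approximately
  # N(weighted mean of patient means, (tau^2 + sig^2/Tn)/n) for
  # weak priors; compare at the estimated variance components
  ybar_i <- tapply(panel$ch1, panel$patient_id, mean)
  g <- s$group[s$group$parameter == "emission_mean", ]
  est_var <- (tau_t^2 + sig_t^2 / Tn) / n
  expect_lt(abs(g$median - mean(ybar_i)), 3 * sqrt(est_var))
  # credible interval width consistent with the closed form (loose)
  width <- (g$upper - g$lower) / (2 * 1.96)
  expect_gt(width, 0.5 * sqrt(est_var))
  expect_lt(width, 2.5 * sqrt(est_var))
})

test_that("near-zero heterogeneity concentrates subjects at the group level", {
  sim <- small_panel(seed = 21, n = 12, Tn = 60, m = 2, miss = 0)
  # regenerate with no random effects
  cfg <- sim$config
  cfg$between_sd[] <- 0
  cfg$transition_re_sd <- 0
  sim0 <- simulate_panel(cfg)
  fit <- fit_mhmm(sim0$panel, m = 2, n_iter = 1200, burn_in = 600, seed = 3)
  s <- posterior_summary(relabel_states(fit))
  # subject medians cluster tightly around the group medians
  gmu <- s$group_point$mu
  spread <- sapply(s$subject_point, function(sp) {
    max(abs(sp$emission_means - gmu))
  })
  expect_lt(median(spread), 4)
})

test_that("relabeling is idempotent and undoes a constructed permutation", {
  sim <- small_panel(seed = 5, n = 5, Tn = 30, m = 2)
  fit <- fit_mhmm(sim$panel, m = 2, n_iter = 400, burn_in = 200, seed = 1)
  r1 <- relabel_states(fit)
  r2 <- relabel_states(r1)
  expect_equal(r1$chains[[1]]$mu, r2$chains[[1]]$mu, tolerance = 1e-12)
  expect_equal(r1$chains[[1]]$states, r2$chains[[1]]$states)

  # swap states everywhere in one draw; relabeling must restore it
  d <- r1$chains[[1]]
  it <- r1$burn_in + 5
  perm <- c(2, 1)
  sw <- r1
  dd <- sw$chains[[1]]
  dd$mu[it, , ] <- dd$mu[it, perm, ]
  dd$sigma[it, , ] <- dd$sigma[it, perm, ]
  dd$tau[it, , ] <- dd$tau[it, perm, ]
  G <- gamma_from_alpha_cpp(matrix(dd$alpha_bar[it, , ], 2, 1), 2L)
  dd$alpha_bar[it, , ] <- crisishmm:::transition_logits(G[perm, perm])
  for (i in seq_len(sw$n_patients)) {
    dd$mu_i[it, , , i] <- dd$mu_i[it, perm, , i]
    Gi <- gamma_from_alpha_cpp(matrix(dd$alpha_i[it, , , i], 2, 1), 2L)
    dd$alpha_i[it, , , i] <- crisishmm:::transition_logits(Gi[perm, perm])
  }
  dd$states[it, ] <- perm[dd$states[it, ]]
  sw$chains[[1]] <- dd
  back <- relabel_states(sw)
  expect_equal(back$chains[[1]]$mu[it, , ], r1$chains[[1]]$mu[it, , ],
               tolerance = 1e-10)
  expect_equal(back$chains[[1]]$states[it, ], r1$chains[[1]]$states[it, ])
})

test_that("posterior summaries have coherent structure", {
  sim <- small_panel(seed = 6, n = 5, Tn = 30, m = 2)
  fit <- fit_mhmm(sim$panel, m = 2, n_iter = 400, burn_in = 200, seed = 2)
  expect_error(posterior_summary(fit), "relabel")
  fit <- relabel_states(fit)
  s <- posterior_summary(fit)
  # transition medians nearly row-stochastic (simplex summaries)
  tr <- s$gamma_median
  expect_true(all(abs(rowSums(tr) - 1) < 0.05))
  # point matrices exactly renormalized
  expect_equal(rowSums(s$group_point$Gamma), rep(1, 2), tolerance = 1e-12)
  # subject summaries keyed by patient id, one block per patient
  expect_setequal(unique(s$subject$patient_id), as.character(1:5))
  expect_equal(nrow(s$subject[s$subject$parameter == "emission_mean", ]),
               5 * 2 * 5)
  # insufficient draws guarded
  tiny <- fit_mhmm(sim$panel, m = 2, n_iter = 60, burn_in = 10, seed = 3)
  expect_error(posterior_summary(relabel_states(tiny)), "at least 100")
})

test_that("metropolis acceptance stays in a healthy band after adaptation", {
  sim <- small_panel(seed = 9, n = 8, Tn = 60, m = 2)
  fit <- fit_mhmm(sim$panel, m = 2, n_iter = 1000, burn_in = 500, seed = 4)
  acc <- fit$chains[[1]]$accept_rate
  expect_gt(mean(acc), 0.10)
  expect_lt(mean(acc), 0.60)
})

test_that("fits are bit-exactly reproducible given the seed", {
  sim <- small_panel(seed = 10, n = 4, Tn = 25, m = 2)
  f1 <- fit_mhmm(sim$panel, m = 2, n_iter = 150, burn_in = 50, seed = 11)
  f2 <- fit_mhmm(sim$panel, m = 2, n_iter = 150, burn_in = 50, seed = 11)
  expect_identical(f1$chains[[1]]$mu, f2$chains[[1]]$mu)
  expect_identical(f1$chains[[1]]$states, f2$chains[[1]]$states)
  f3 <- fit_mhmm(sim$panel, m = 2, n_iter = 150, burn_in = 50, seed = 12)
  expect_false(identical(f1$chains[[1]]$mu, f3$chains[[1]]$mu))
})
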