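# Model selection and goodness-of-fit diagnostics.

fit_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- default_study_config(seed = 41, clip_to_scale = FALSE)
      cfg$n_patients <- 10L
      cfg$m <- 2L
      cfg$group_means <- cfg$group_means[c(1, 4), ]
      cfg$between_sd <- cfg$between_sd[c(1, 4), ]
      cfg$within_sd <- cfg$within_sd[c(1, 4), ]
      cfg$group_transition <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2,
                                     byrow = TRUE)
      cfg$init_distribution <-
        stationary_distribution(cfg$group_transition)
      sim <- simulate_panel(cfg)
      fit <- relabel_states(fit_mhmm(sim$panel, m = 2, n_iter = 800,
                                     burn_in = 400, chains = 2, seed = 6))
      cache <<- list(sim = sim, fit = fit, summary = posterior_summary(fit))
    }
    cache
  }
})

test_that("AIC follows its documented formula and penalty monotonicity", {
  x <- fit_cached()
  aic <- compute_aic(x$sim$panel, x$summary)
  ll <- attr(aic, "loglik")
  p <- attr(aic, "p")
  expect_equal(p, 2 * 2 * 5 + 2 * 1)
  expect_equal(as.numeric(aic), -2 * ll + 2 * p, tolerance = 1e-10)
  # formula arithmetic: L = -1000, m = 4, K = 5 gives 2000 + 2 * 52
  expect_equal(-2 * (-1000) + 2 * (2 * 4 * 5 + 4 * 3), 2104)
  # identical log-likelihood, larger m: strictly larger AIC
  expect_gt(-2 * ll + 2 * (2 * 3 * 5 + 3 * 2), as.numeric(aic))
  # mismatched panel rejected
  other <- x$sim$panel
  other$self_control <- other$self_control + 1
  expect_error(compute_aic(other, x$summary), "fingerprint")
})

test_that("AIC is invariant to state relabeling of the point parameters", {
  x <- fit_cached()
  gp <- x$summary$group_point
  perm <- c(2, 1)
  s2 <- x$summary
  s2$group_point <- list(mu = gp$mu[perm, ], sigma = gp$sigma[perm, ],
                         Gamma = gp$Gamma[perm, perm], pi = gp$pi[perm])
  expect_equal(as.numeric(compute_aic(x$sim$panel, x$summary)),
               as.numeric(compute_aic(x$sim$panel, s2)), tolerance = 1e-8)
})

test_that("state-count selection prefers the generating number of states", {
  x <- fit_cached()
  sel <- suppressWarnings( # overfitted m can starve a state, by design
    select_num_states(x$sim$panel, m_range = 2:3, n_iter = 500,
                      burn_in = 250, seed = 19))
  expect_equal(sel$selected_m, 2)
  expect_true(all(is.finite(sel$aic_by_m$aic)))
  expect_error(select_num_states(x$sim$panel, m_range = c(2, 4)),
               "contiguous")
  expect_error(select_num_states(x$sim$panel, m_range = 1:2), ">= 2")
})

test_that("PSRF matches a direct formula oracle and is 1 for copied chains", {
  # formula oracle on random inputs
  set.seed(7)
  for (r in 1:5) {
    M <- cbind(rnorm(500), rnorm(500, if (r == 3) 3 else 0), rnorm(500, 0, 2))
    W <- mean(apply(M, 2, var))
    B_over_n <- var(colMeans(M))
    oracle <- sqrt((W + B_over_n) / W)
    expect_equal(crisishmm:::psrf(M), oracle, tolerance = 1e-9)
  }
  # identical chains give exactly 1
  v <- rnorm(300)
  expect_equal(crisishmm:::psrf(cbind(v, v)), 1, tolerance = 1e-9)
  # well-separated chains give a large value
  expect_gt(crisishmm:::psrf(cbind(rnorm(1000), rnorm(1000, 3))), 1.5)
})

test_that("gelman_rubin requires multiple chains and stays near 1 when healthy", {
  x <- fit_cached()
  rh <- gelman_rubin(x$fit)
  expect_true(all(rh >= 1 - 1e-6))
  expect_lt(max(rh), 1.3)
  one_chain <- fit_mhmm(x$sim$panel, m = 2, n_iter = 300, burn_in = 100,
                        chains = 1, seed = 3)
  expect_error(gelman_rubin(one_chain), "2 chains")
})

test_that("posterior predictive checks pass for self-generated data and flag misfit", {
  x <- fit_cached()
  ppc <- posterior_predictive_check(x$fit, x$sim$panel, n_rep = 150,
                                    seed = 2)
  inside <- ppc$observed >= ppc$lower & ppc$observed <= ppc$upper
  expect_gte(sum(inside), 9) # >= 9 of 10 channel x statistic cells
  # constructed misfit: one channel shifted +30
  shifted <- x$sim$panel
  shifted$negative_affect <- shifted$negative_affect + 30
  # same draws, shifted observations
  ppc2 <- posterior_predictive_check(x$fit, shifted, n_rep = 150, seed = 2)
  row <- ppc2[ppc2$channel == "negative_affect" & ppc2$stat == "mean", ]
  expect_gt(row$observed, row$upper)
  expect_error(posterior_predictive_check(x$fit, x$sim$panel, n_rep
               = 1e6), "exceeds")
})

test_that("predictive intervals widen with emission noise", {
  base <- default_study_config(seed = 51, clip_to_scale = FALSE)
  base$n_patients <- 6L
  width <- numeric(2)
  for (j in 1:2) {
    cfg <- base
    cfg$within_sd[] <- c(6, 18)[j]
    sim <- simulate_panel(cfg)
    fit <- relabel_states(fit_mhmm(sim$panel, m = 4, n_iter = 400,
                                   burn_in = 200, seed = 5))
    ppc <- posterior_predictive_check(fit, sim$panel, n_rep = 100, seed = 3)
    width[j] <- mean(ppc$upper - ppc$lower)
  }
  expect_gt(width[2], width[1])
})

test_that("pseudo-residuals reduce to z-scores for m = 1 and behave for HMM data", {
  # m = 1 closed form
  sp <- subject_params(matrix(c(10, 50), 1, 2), matrix(c(2, 5), 1, 2),
                       matrix(1, 1, 1))
  set.seed(12)
  panel <- data.frame(patient_id = 1, occasion = 1:30, day = 1, beep = 1,
                      a = rnorm(30, 10, 2), b = rnorm(30, 50, 5))
  pr <- pseudo_residuals(panel, list("1" = sp))
  expect_equal(pr$residuals$residual[pr$residuals$channel == "a"],
               (panel$a - 10) / 2, tolerance = 1e-9)
  expect_equal(pr$residuals$residual[pr$residuals$channel == "b"],
               (panel$b - 50) / 5, tolerance = 1e-9)

  # well-specified 2-state data: residuals near standard normal,
  # lag-1 autocorrelation near zero
  x <- fit_cached()
  pr2 <- pseudo_residuals(x$sim$panel, subject_point_params(x$summary))
  r <- pr2$residuals$residual
  expect_lt(abs(mean(r)), 0.1)
  expect_lt(abs(sd(r) - 1), 0.12)
  expect_lt(max(abs(pr2$summary$lag1_acf), na.rm = TRUE), 0.45)
  expect_lt(abs(mean(pr2$summary$lag1_acf, na.rm = TRUE)), 0.1)
  # normality of pooled residuals (generous alpha)
  expect_gt(stats::shapiro.test(sample(r, min(3000, length(r))))$p.value,
            1e-4)
})
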