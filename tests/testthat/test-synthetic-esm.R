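# Synthetic ESM panel generator: design constants, reproducibility,
# random-effect structure and missingness semantics.

test_that("default study configuration encodes the study design", {
  cfg <- default_study_config()
  expect_equal(cfg$n_patients, 26L)
  expect_equal(cfg$n_occasions, 60L)
  expect_equal(cfg$m, 4L)
  expect_equal(cfg$K, 5L)
  expect_equal(cfg$channel_names[1], "self_control")
  expect_equal(cfg$group_means[4, "self_control"], 13.30)
  expect_equal(cfg$group_means[1, "suicidal_ideation"], 3.85)
  expect_equal(unname(diag(cfg$group_transition)), c(0.84, 0.73, 0.63, 0.57))
  expect_equal(cfg$missing_rate, 14.23 / 60, tolerance = 1e-12)
  expect_equal(round(cfg$missing_rate, 4), 0.2372)
  expect_equal(rowSums(cfg$group_transition), rep(1, 4), tolerance = 1e-12)
  expect_equal(sum(cfg$init_distribution), 1, tolerance = 1e-12)
})

test_that("config invariant violations are reported by name", {
  cfg <- default_study_config()
  bad <- cfg
  bad$within_sd[2, 3] <- -1
  expect_error(validate_sim_config(bad), "within_sd")
  bad <- cfg
  bad$missing_rate <- 1
  expect_error(validate_sim_config(bad), "missing_rate")
  bad <- cfg
  bad$group_transition[1, 1] <- 0.9
  expect_error(validate_sim_config(bad), "group_transition")
})

test_that("complete panel has the full design size", {
  cfg <- default_study_config(seed = 5, missing_rate = 0)
  sim <- simulate_panel(cfg)
  expect_equal(nrow(sim$panel), 26 * 60)
  for (ch in cfg$channel_names)
    expect_equal(sum(!is.na(sim$panel[[ch]])), 1560)
  expect_equal(nrow(sim$states), 26 * 60)
  # occasions consecutive from 1; day/beep structure
  p1 <- sim$panel[sim$panel$patient_id == 1, ]
  expect_equal(p1$occasion, 1:60)
  expect_equal(p1$beep, rep(1:3, 20))
  expect_equal(p1$day, rep(1:20, each = 3))
  # clipped scale
  y <- as.matrix(sim$panel[, cfg$channel_names])
  expect_true(all(y >= 1 & y <= 100))
})

test_that("no random effects collapses subjects onto the group model", {
  cfg <- default_study_config(seed = 2, missing_rate = 0)
  cfg$between_sd[] <- 0
  cfg$transition_re_sd <- 0
  sim <- simulate_panel(cfg)
  for (sp in sim$subject_params) {
    expect_equal(sp$emission_means, cfg$group_means, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(sp$transition, cfg$group_transition, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("panels are deterministic given the seed and stable under subsetting", {
  cfg <- default_study_config(seed = 31)
  s1 <- simulate_panel(cfg)
  s2 <- simulate_panel(cfg)
  expect_identical(s1$panel, s2$panel)
  expect_identical(s1$states, s2$states)
  # patient streams derive from (seed, patient index): patient 3 identical
  cfg5 <- cfg
  cfg5$n_patients <- 5L
  s3 <- simulate_panel(cfg5)
  expect_identical(s3$panel[s3$panel$patient_id == 3, ],
                   s1$panel[s1$panel$patient_id == 3, ])
})

test_that("empirical transition frequencies match the subject matrix", {
  cfg <- default_study_config(seed = 8, missing_rate = 0)
  cfg$n_patients <- 1L
  cfg$n_occasions <- 5000L
  sim <- simulate_panel(cfg)
  S <- sim$states$state
  G_true <- sim$subject_params[[1]]$transition
  tab <- table(factor(S[-length(S)], 1:4), factor(S[-1], 1:4))
  emp <- prop.table(tab, 1)
  n_from <- rowSums(tab)
  for (s in 1:4) for (j in 1:4) {
    se <- sqrt(G_true[s, j] * (1 - G_true[s, j]) / n_from[s])
    expect_lt(abs(emp[s, j] - G_true[s, j]), 3 * se + 1e-9)
  }
})

test_that("well-separated noiseless channels identify the true states", {
  cfg <- default_study_config(seed = 13, missing_rate = 0,
                              clip_to_scale = FALSE)
  cfg$between_sd[] <- 0
  cfg$transition_re_sd <- 0
  cfg$within_sd[] <- 1e-6
  sim <- simulate_panel(cfg)
  y <- as.matrix(sim$panel[, cfg$channel_names])
  # max-likelihood channel assignment: nearest state mean
  d2 <- sapply(1:4, function(s) {
    rowSums((y - matrix(cfg$group_means[s, ], nrow(y), 5, byrow = TRUE))^2)
  })
  expect_equal(max.col(-d2), sim$states$state)
})

test_that("pooled per-state empirical means converge to group means", {
  cfg <- default_study_config(seed = 17, missing_rate = 0,
                              clip_to_scale = FALSE)
  cfg$n_patients <- 200L
  cfg$n_occasions <- 200L
  sim <- simulate_panel(cfg)
  y <- as.matrix(sim$panel[, cfg$channel_names])
  st <- sim$states$state
  for (s in 1:4) {
    emp <- colMeans(y[st == s, ])
    n_s <- sum(st == s)
    # per-cell spread = between_sd (patient means) + within noise
    mc_se <- sqrt(8^2 / 200 + 12^2 / n_s) * 4
    expect_true(all(abs(emp - cfg$group_means[s, ]) < pmax(mc_se, 0.8)),
                label = sprintf("state %d pooled means", s))
  }
})

test_that("missingness masks whole occasions at the configured rate", {
  cfg <- default_study_config(seed = 3, missing_rate = 0)
  sim <- simulate_panel(cfg)
  expect_identical(apply_missingness(sim$panel, 0), sim$panel)
  expect_error(apply_missingness(sim$panel, 1.2), "missing_rate")

  rate <- 14.23 / 60
  miss_per_patient <- numeric(0)
  for (sd_i in 1:200) {
    p <- apply_missingness(sim$panel, rate, seed = sd_i)
    expect_equal(nrow(p), nrow(sim$panel)) # masking, never deletion
    nm <- is.na(p$self_control)
    # beep-level: all channels missing together
    expect_identical(nm, is.na(p$suicidal_ideation))
    miss_per_patient <- c(miss_per_patient, sum(nm) / 26)
  }
  expect_gt(mean(miss_per_patient), 13.2)
  expect_lt(mean(miss_per_patient), 15.3)
})

test_that("panel CSV round trip is bit-exact and YAML config round-trips", {
  cfg <- default_study_config(seed = 23)
  cfg$n_patients <- 4L
  sim <- simulate_panel(cfg)
  f <- tempfile(fileext = ".csv")
  write_panel(sim$panel, f)
  back <- read_panel(f)
  for (ch in cfg$channel_names)
    expect_identical(back[[ch]], sim$panel[[ch]])
  expect_identical(is.na(back$negative_affect), is.na(sim$panel$negative_affect))

  fy <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, fy)
  cfg2 <- read_sim_config(fy)
  expect_equal(cfg2$group_means, cfg$group_means, ignore_attr = TRUE)
  expect_equal(cfg2$group_transition, cfg$group_transition, ignore_attr = TRUE)
  expect_equal(cfg2$missing_rate, cfg$missing_rate)

  # truth files
  d <- tempfile()
  write_sim_truth(sim, d)
  st <- read.csv(file.path(d, "true_states.csv"))
  expect_equal(nrow(st), nrow(sim$states))
})

test_that("out-of-scale scores are rejected on read unless allowed", {
  cfg <- default_study_config(seed = 29, clip_to_scale = FALSE,
                              missing_rate = 0)
  cfg$n_patients <- 3L
  cfg$group_means[1, 5] <- -20 # force out-of-range draws
  sim <- simulate_panel(cfg)
  f <- tempfile(fileext = ".csv")
  write_panel(sim$panel, f)
  expect_error(read_panel(f), "outside")
  expect_silent(read_panel(f, check_scale = FALSE))
})
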