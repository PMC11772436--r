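# Model selection and goodness of fit: AIC across candidate numbers of
# states, Gelman-Rubin convergence, posterior predictive checks, and
# one-step-ahead pseudo-residuals.

#' AIC of a fitted multilevel HMM
#'
#' `AIC = -2 * sum_i forward_loglik(patient i, group point parameters)
#' + 2 * p` with `p = 2mK + m(m-1)`: the group-level emission means and
#' SDs plus the group-level transition logits. The likelihood is
#' evaluated at the group-level posterior medians (not the subject-level
#' parameters), so the criterion compares sample-level descriptions of
#' the panel across state counts; this convention is recorded in the
#' returned attributes.
#'
#' @param panel The panel the summary was fitted to.
#' @param summary An `mhmm_summary` from [posterior_summary()].
#' @param m Number of states (consistency-checked against the summary).
#' @return Scalar AIC with attributes `loglik` and `p`.
#' @export
compute_aic <- function(panel, summary, m = summary$m) {
  stopifnot(inherits(summary, "mhmm_summary"))
  if (m != summary$m) stop("m does not match the summary")
  if (!identical(panel_hash(panel), summary$panel_hash))
    stop("panel does not match the fitted summary (data fingerprint differs)")
  gp <- summary$group_point
  params <- subject_params(gp$mu, gp$sigma, gp$Gamma, gp$pi)
  ll <- sum(vapply(panel_matrices(panel, summary$channel_names),
                   forward_loglik, numeric(1), params = params))
  K <- summary$K
  p <- 2 * m * K + m * (m - 1)
  structure(-2 * ll + 2 * p, loglik = ll, p = p)
}

#' Fit candidate state counts and select by AIC
#'
#' Fits the multilevel HMM for each `m` in `m_range`, tabulates AIC and
#' selects the minimum (ties within 1e-6 go to the smaller `m`). A
#' failed fit is recorded and selection runs over the successes.
#'
#' @param panel An ESM panel data frame.
#' @param m_range Contiguous integer range of state counts, minimum
#'   `>= 2`.
#' @param n_iter,burn_in,chains,priors,seed Passed to [fit_mhmm()].
#' @param keep_fits Keep the full summaries (memory-heavy) or AIC only.
#' @return List with `aic_by_m` (data frame: m, aic, loglik, p, max_rhat,
#'   error), `selected_m`, and (optionally) `summaries`.
#' @export
select_num_states <- function(panel, m_range = 2:5, n_iter = 1000,
                              burn_in = 500, chains = 1,
                              priors = mhmm_priors(), seed = 1L,
                              keep_fits = FALSE) {
  m_range <- sort(unique(as.integer(m_range)))
  if (min(m_range) < 2) stop("m_range minimum must be >= 2")
  if (!all(diff(m_range) == 1)) stop("m_range must be contiguous")
  rows <- list()
  summaries <- list()
  for (m in m_range) {
    res <- tryCatch({
      fit <- fit_mhmm(panel, m, n_iter = n_iter, burn_in = burn_in,
                      chains = chains, priors = priors,
                      seed = derive_seed(seed, m, 13L), keep_states = FALSE)
      fit <- relabel_states(fit)
      sm <- posterior_summary(fit)
      aic <- compute_aic(panel, sm)
      rhat <- if (chains >= 2) max(gelman_rubin(fit)) else NA_real_
      list(aic = as.numeric(aic), loglik = attr(aic, "loglik"),
           p = attr(aic, "p"), rhat = rhat, summary = sm, error = NA_character_)
    }, error = function(e) {
      list(aic = NA_real_, loglik = NA_real_, p = NA_real_, rhat = NA_real_,
           summary = NULL, error = conditionMessage(e))
    })
    rows[[as.character(m)]] <- data.frame(
      m = m, aic = res$aic, loglik = res$loglik, p = res$p,
      max_rhat = res$rhat, error = res$error)
    if (keep_fits && !is.null(res$summary))
      summaries[[as.character(m)]] <- res$summary
  }
  aic_by_m <- do.call(rbind, rows)
  rownames(aic_by_m) <- NULL
  ok <- which(!is.na(aic_by_m$aic))
  if (length(ok) == 0) stop("all candidate fits failed")
  best <- ok[which(aic_by_m$aic[ok] <= min(aic_by_m$aic[ok]) + 1e-6)]
  selected <- min(aic_by_m$m[best])
  out <- list(aic_by_m = aic_by_m, selected_m = selected)
  if (keep_fits) out$summaries <- summaries
  out
}

#' Gelman-Rubin potential scale reduction factors
#'
#' Classic (non-split) PSRF per scalar group-level parameter, comparing
#' between- and within-chain variance over the post-burn-in draws, in
#' its large-sample form `R-hat = sqrt((W + B/n) / W)` (with `B/n` the
#' variance of the chain means), which is `>= 1` by construction and
#' exactly 1 for identical chains. Parameters with `R-hat >= 1.20`
#' indicate non-convergence under the bound used here.
#'
#' @param draws An `mhmm_draws` with at least two chains.
#' @param params Which group-level blocks to include.
#' @return Named numeric vector of PSRFs.
#' @export
gelman_rubin <- function(draws, params = c("mu", "sigma", "tau",
                                           "alpha_bar", "omega")) {
  stopifnot(inherits(draws, "mhmm_draws"))
  if (draws$n_chains < 2) stop("gelman_rubin needs at least 2 chains")
  keep <- (draws$burn_in + 1):draws$n_iter
  if (length(keep) < 100) stop("need at least 100 post-burn-in draws")
  out <- numeric(0)
  for (what in params) {
    dims <- dim(draws$chains[[1]][[what]])
    if (is.null(dims) || prod(dims[-1]) == 0) next
    for (s in seq_len(dims[2])) for (j in seq_len(dims[3])) {
      M <- vapply(draws$chains, function(d) d[[what]][keep, s, j],
                  numeric(length(keep)))
      out[[sprintf("%s[%d,%d]", what, s, j)]] <- psrf(M)
    }
  }
  out
}

# PSRF for an iterations x chains matrix (large-sample form, >= 1).
psrf <- function(M) {
  W <- mean(apply(M, 2, var))
  B_n <- var(colMeans(M)) # = B / n
  if (W <= 0) return(1)
  sqrt((W + B_n) / W)
}

#' Posterior predictive check of pooled channel moments
#'
#' For `n_rep` thinned post-burn-in draws, a replicate panel is
#' simulated from the drawn subject-level parameters (same design, the
#' observed missingness mask reapplied) and the pooled per-channel mean
#' and SD are computed. Observed statistics are compared with the
#' replicate 2.5/50/97.5 percentiles and a two-sided predictive p-value.
#'
#' @param draws A (relabeled or not) `mhmm_draws` with stored state
#'   dimensions; label permutations do not affect pooled statistics.
#' @param panel The observed panel.
#' @param n_rep Number of replicate panels (must not exceed the
#'   available post-burn-in draws).
#' @param seed Integer seed for the replicate simulations.
#' @return Data frame `channel, stat, observed, lower, median, upper,
#'   p_value` (class `ppc_table`).
#' @export
posterior_predictive_check <- function(draws, panel, n_rep = 200, seed = 1L) {
  stopifnot(inherits(draws, "mhmm_draws"))
  if (n_rep < 2) stop("n_rep must be >= 2")
  keep <- (draws$burn_in + 1):draws$n_iter
  total <- length(keep) * draws$n_chains
  if (n_rep > total)
    stop("n_rep (", n_rep, ") exceeds available post-burn-in draws (",
         total, ")")
  channels <- draws$channel_names
  mats <- panel_matrices(panel, channels)
  m <- draws$m
  K <- draws$K

  # evenly thinned (chain, iteration) pairs
  pick <- floor(seq(1, total, length.out = n_rep))
  chain_of <- (pick - 1) %/% length(keep) + 1
  iter_of <- keep[(pick - 1) %% length(keep) + 1]

  rep_mean <- matrix(NA_real_, n_rep, K)
  rep_sd <- matrix(NA_real_, n_rep, K)
  set.seed(derive_seed(seed, 0L, 17L))
  for (r in seq_len(n_rep)) {
    d <- draws$chains[[chain_of[r]]]
    it <- iter_of[r]
    sig <- matrix(d$sigma[it, , ], m, K)
    acc <- matrix(NA_real_, 0, K)
    for (i in seq_len(draws$n_patients)) {
      Tn <- nrow(mats[[i]])
      mu_i <- matrix(d$mu_i[it, , , i], m, K)
      Gi <- if (m > 1) {
        gamma_from_alpha_cpp(matrix(d$alpha_i[it, , , i], m, m - 1), m)
      } else {
        matrix(1, 1, 1)
      }
      pi_i <- as.numeric(stationary_cpp(Gi))
      S <- integer(Tn)
      S[1] <- sample.int(m, 1, prob = pi_i)
      if (Tn > 1) for (t in 2:Tn) S[t] <- sample.int(m, 1, prob = Gi[S[t - 1], ])
      yr <- mu_i[S, , drop = FALSE] +
        matrix(rnorm(Tn * K), Tn, K) * sig[S, , drop = FALSE]
      yr[is.na(mats[[i]])] <- NA_real_
      acc <- rbind(acc, yr)
    }
    rep_mean[r, ] <- colMeans(acc, na.rm = TRUE)
    rep_sd[r, ] <- apply(acc, 2, sd, na.rm = TRUE)
  }

  yobs <- do.call(rbind, mats)
  obs <- rbind(mean = colMeans(yobs, na.rm = TRUE),
               sd = apply(yobs, 2, sd, na.rm = TRUE))
  out <- list()
  for (k in seq_len(K)) for (st in c("mean", "sd")) {
    repv <- if (st == "mean") rep_mean[, k] else rep_sd[, k]
    o <- obs[st, k]
    qs <- quantile(repv, c(0.025, 0.5, 0.975), names = FALSE)
    p <- 2 * min((sum(repv <= o) + 1) / (n_rep + 1),
                 (sum(repv >= o) + 1) / (n_rep + 1))
    out[[length(out) + 1]] <- data.frame(
      channel = channels[k], stat = st, observed = o,
      lower = qs[1], median = qs[2], upper = qs[3], p_value = min(p, 1))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ppc_table", "data.frame")
  res
}

#' One-step-ahead pseudo-residuals
#'
#' For every observed channel value, the probability integral transform
#' under its one-step-ahead forecast distribution — the state-prediction
#' weighted Gaussian mixture CDF, with state predictions from the
#' forward filter over occasions `1..t-1` — mapped through the standard
#' normal quantile. Under a well-specified model the residuals are iid
#' standard normal. PITs of exactly 0 or 1 are clamped to the nearest
#' representable value and counted.
#'
#' @param panel An ESM panel data frame.
#' @param subject_params_list Named list of [subject_params()] per
#'   patient (e.g. [subject_point_params()]).
#' @return List with `residuals` (long data frame: patient_id, occasion,
#'   channel, residual) and `summary` (per patient x channel: n, mean,
#'   sd, lag-1 autocorrelation, clamped count).
#' @export
pseudo_residuals <- function(panel, subject_params_list) {
  channels <- panel_channels(panel)
  mats <- panel_matrices(panel, channels)
  res_rows <- list()
  sum_rows <- list()
  eps <- 1e-12
  for (id in names(mats)) {
    sp <- subject_params_list[[id]]
    if (is.null(sp)) stop("no subject parameters for patient ", id)
    y <- mats[[id]]
    Tn <- nrow(y)
    m <- sp$m
    ld <- emission_logdens_cpp(y, sp$emission_means, sp$emission_sds)
    filt <- matrix(NA_real_, Tn, m)
    pred <- matrix(NA_real_, Tn, m)
    for (t in seq_len(Tn)) {
      pred[t, ] <- if (t == 1) sp$init else filt[t - 1, ] %*% sp$transition
      a <- pred[t, ] * exp(ld[t, ] - max(ld[t, ]))
      filt[t, ] <- a / sum(a)
    }
    R <- matrix(NA_real_, Tn, length(channels))
    clamped <- integer(length(channels))
    for (k in seq_along(channels)) {
      obs_t <- which(!is.na(y[, k]))
      for (t in obs_t) {
        u <- sum(pred[t, ] * pnorm(y[t, k], sp$emission_means[, k],
                                   sp$emission_sds[, k]))
        if (u <= 0 || u >= 1) {
          clamped[k] <- clamped[k] + 1L
          u <- min(max(u, eps), 1 - eps)
        }
        R[t, k] <- qnorm(u)
      }
      r <- R[obs_t, k]
      l1 <- if (length(r) > 2 && sd(r) > 0) {
        acf(r, lag.max = 1, plot = FALSE)$acf[2]
      } else {
        NA_real_
      }
      sum_rows[[length(sum_rows) + 1]] <- data.frame(
        patient_id = id, channel = channels[k], n = length(r),
        mean = mean(r), sd = sd(r), lag1_acf = l1, n_clamped = clamped[k])
    }
    res_rows[[length(res_rows) + 1]] <- data.frame(
      patient_id = id, occasion = rep(seq_len(Tn), length(channels)),
      channel = rep(channels, each = Tn), residual = as.numeric(R))
  }
  residuals <- do.call(rbind, res_rows)
  residuals <- residuals[!is.na(residuals$residual), ]
  rownames(residuals) <- NULL
  list(residuals = residuals, summary = do.call(rbind, sum_rows))
}
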