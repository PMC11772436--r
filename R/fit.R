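# Multilevel Bayesian estimation: Metropolis-within-Gibbs over subject
# state paths, subject parameters, and group-level hyperparameters.

#' Prior specification for the multilevel HMM
#'
#' Weakly informative, scale-aware defaults for the 1-100 ESM score
#' scale: group emission means `Normal(50, 25^2)` (centered on the
#' scale); within-patient SDs `sigma` and between-patient SDs `tau`
#' half-Cauchy(0, 10); group transition logits `Normal(0, 5^2)`;
#' transition random-effect SDs `omega` half-Cauchy(0, 1). The
#' half-Cauchy priors are implemented through their inverse-gamma
#' scale-mixture representation so every variance update is a conjugate
#' Gibbs draw.
#'
#' @param mean_loc,mean_scale Location and scale of the Gaussian prior on
#'   group emission means.
#' @param sd_scale Half-Cauchy scale for `sigma` and `tau` (score units).
#' @param logit_loc,logit_scale Gaussian prior on group transition logits.
#' @param omega_scale Half-Cauchy scale for transition random-effect SDs.
#' @return Object of class `mhmm_priors`.
#' @export
mhmm_priors <- function(mean_loc = 50, mean_scale = 25, sd_scale = 10,
                        logit_loc = 0, logit_scale = 5, omega_scale = 1) {
  stopifnot(mean_scale > 0, sd_scale > 0, logit_scale > 0, omega_scale > 0)
  structure(list(mean_loc = mean_loc, mean_scale = mean_scale,
                 sd_scale = sd_scale, logit_loc = logit_loc,
                 logit_scale = logit_scale, omega_scale = omega_scale),
            class = "mhmm_priors")
}

#' Initialize one MCMC chain
#'
#' Emission means start at the centers of a k-means clustering of the
#' complete occasions (which captures the joint state structure even
#' when a channel's state means are not monotone in severity), jittered
#' by the chain seed and ordered on the ordering channel so chains start
#' in the common labeling; when too few complete occasions exist the
#' fallback is `m` equally spaced pooled per-channel quantiles.
#' Emission SDs start at within-cluster SDs; transitions start
#' diagonal-dominant (0.7 on the diagonal); subject-level parameters
#' start at the group values.
#'
#' @param panel An ESM panel data frame.
#' @param m Number of states.
#' @param seed Integer seed (different seeds give different, jittered
#'   starting values for additional chains).
#' @param order_channel Channel used for the severity ordering of
#'   states; defaults to `"negative_affect"` when present, else the
#'   first channel.
#' @return List with elements `group` (mu, sigma, tau, alpha_bar, omega)
#'   and `subject` (mu_i, alpha_i cubes).
#' @export
init_chain <- function(panel, m, seed = 1L, order_channel = NULL) {
  channels <- panel_channels(panel)
  K <- length(channels)
  n <- length(unique(panel$patient_id))
  y <- as.matrix(panel[, channels, drop = FALSE])
  miss <- colSums(!is.na(y)) == 0
  if (any(miss))
    stop("channel(s) entirely missing across the panel: ",
         paste(channels[miss], collapse = ", "))
  order_channel <- order_channel %||%
    if ("negative_affect" %in% channels) "negative_affect" else channels[1]
  oc <- match(order_channel, channels)

  set.seed(derive_seed(seed, 0L, 3L))
  sd_pool <- apply(y, 2, sd, na.rm = TRUE)
  sd_pool[!is.finite(sd_pool) | sd_pool <= 0] <- 1
  yc <- y[stats::complete.cases(y), , drop = FALSE]
  km <- NULL
  if (nrow(yc) >= 5 * m && m > 1) {
    km <- tryCatch(stats::kmeans(yc, centers = m, nstart = 5, iter.max = 50),
                   error = function(e) NULL)
  }
  if (!is.null(km)) {
    mu0 <- km$centers
    sigma0 <- t(vapply(seq_len(m), function(s) {
      v <- apply(yc[km$cluster == s, , drop = FALSE], 2, sd)
      ifelse(is.finite(v) & v > 0, v, sd_pool * 0.6)
    }, numeric(K)))
    if (m == 1) sigma0 <- matrix(sigma0, 1, K)
  } else {
    probs <- (seq_len(m) - 0.5) / m
    mu0 <- matrix(sapply(seq_len(K), function(k) {
      as.numeric(quantile(y[, k], probs, na.rm = TRUE))
    }), m, K)
    sigma0 <- matrix(rep(sd_pool * 0.6, each = m), m, K)
  }
  mu0 <- mu0 + matrix(rnorm(m * K, 0, 2), m, K)
  ord <- order(mu0[, oc])
  mu0 <- mu0[ord, , drop = FALSE]
  sigma0 <- pmax(sigma0[ord, , drop = FALSE], 1e-2)
  tau0 <- matrix(rep(pmax(sd_pool * 0.3, 1e-2), each = m), m, K)
  if (m > 1) {
    G0 <- matrix(0.3 / (m - 1), m, m)
    diag(G0) <- 0.7
    ab0 <- transition_logits(G0)
    om0 <- matrix(0.5, m, m - 1)
  } else {
    ab0 <- matrix(0, 1, 0)
    om0 <- matrix(0, 1, 0)
  }
  list(
    group = list(mu = mu0, sigma = sigma0, tau = tau0,
                 alpha_bar = ab0, omega = om0),
    subject = list(
      mu_i = array(mu0, dim = c(m, K, n)),
      alpha_i = array(ab0, dim = c(m, max(m - 1, 0), n))
    ),
    order_channel = order_channel
  )
}

#' Fit the multilevel hidden Markov model by MCMC
#'
#' Metropolis-within-Gibbs sampler. Per iteration and patient: (1) the
#' latent state path is drawn exactly by forward-filtering
#' backward-sampling given the patient's current parameters (initial
#' distribution = the patient's stationary distribution); (2) subject
#' emission means get conjugate Gaussian updates given the sampled
#' states, shrinking toward the group means; (3) subject transition-row
#' logits get row-wise Gaussian random-walk Metropolis updates whose
#' proposal SD adapts toward 0.35 acceptance during burn-in
#' (Robbins-Monro) and is frozen afterwards. Group-level updates are
#' conjugate: Gaussian for group means and transition logits, and
#' inverse-gamma (via the half-Cauchy scale-mixture auxiliaries) for
#' `sigma`, `tau` and `omega`. Missing channels contribute nothing to
#' emission updates (missing at random). Runs are bit-exactly
#' reproducible given `(seed, chains)`; chain `c` uses the derived seed
#' `(seed, c)`.
#'
#' @param panel An ESM panel data frame (`patient_id`, `occasion`,
#'   channel columns; `NA` = missing).
#' @param m Number of latent states (`m = 1` reduces to a hierarchical
#'   Gaussian means model, useful for testing).
#' @param n_iter Total MCMC iterations per chain.
#' @param burn_in Burn-in iterations (`< n_iter`).
#' @param chains Number of chains (run sequentially).
#' @param priors An [mhmm_priors()].
#' @param seed Integer master seed.
#' @param order_channel Passed to [init_chain()].
#' @param keep_states Store the sampled state paths per iteration?
#'   Needed by [relabel_states()]-consistent decoding summaries; on by
#'   default.
#' @param verbose Print progress every 10% of iterations.
#' @return Object of class `mhmm_draws`: per-chain draw arrays for all
#'   group- and subject-level parameters plus sampled state paths,
#'   acceptance rates for the Metropolis blocks, and run metadata.
#' @export
fit_mhmm <- function(panel, m, n_iter = 10000, burn_in = 5000, chains = 1,
                     priors = mhmm_priors(), seed = 1L,
                     order_channel = NULL, keep_states = TRUE,
                     verbose = FALSE) {
  stopifnot(n_iter > burn_in, burn_in >= 0, chains >= 1, m >= 1)
  channels <- panel_channels(panel)
  K <- length(channels)
  mats <- panel_matrices(panel, channels)
  ids <- names(mats)
  n <- length(ids)
  Ts <- vapply(mats, nrow, integer(1))
  row_index <- c(0L, cumsum(Ts))
  mk1 <- max(m - 1L, 0L)

  chain_list <- vector("list", chains)
  for (ch in seq_len(chains)) {
    cseed <- derive_seed(seed, ch, 7L)
    ini <- init_chain(panel, m, seed = cseed, order_channel = order_channel)
    set.seed(cseed)
    g <- ini$group
    mu_i <- ini$subject$mu_i
    alpha_i <- ini$subject$alpha_i
    sig2 <- g$sigma^2
    tau2 <- g$tau^2
    om2 <- if (m > 1) g$omega^2 else matrix(0, 1, 0)
    a_sig <- matrix(1, m, K)
    a_tau <- matrix(1, m, K)
    a_om <- matrix(1, m, mk1)
    prop_sd <- matrix(0.4, n, m)
    prop_ab <- matrix(0.15, m, mk1)
    prop_om <- matrix(0.3, m, mk1)
    prior_mu_prec <- 1 / priors$mean_scale^2
    prior_ab_prec <- 1 / priors$logit_scale^2

    draws <- list(
      mu = array(NA_real_, c(n_iter, m, K)),
      sigma = array(NA_real_, c(n_iter, m, K)),
      tau = array(NA_real_, c(n_iter, m, K)),
      alpha_bar = array(NA_real_, c(n_iter, m, mk1)),
      omega = array(NA_real_, c(n_iter, m, mk1)),
      mu_i = array(NA_real_, c(n_iter, m, K, n)),
      alpha_i = array(NA_real_, c(n_iter, m, mk1, n)),
      states = if (keep_states) {
        matrix(NA_integer_, n_iter, sum(Ts))
      }
    )
    acc_post <- matrix(0, n, m)
    starve <- integer(m)
    starve_warned <- logical(m)

    for (it in seq_len(n_iter)) {
      sw <- sweep_all_cpp(mats, mu_i, sqrt(sig2), alpha_i,
                          g$alpha_bar, if (m > 1) sqrt(pmax(om2, 1e-12)) else om2,
                          prop_sd, 3L)
      alpha_i <- sw$alpha_i
      nc <- sw$n
      sm <- sw$sum
      sq <- sw$sumsq

      # state starvation bookkeeping (zero occupancy across all patients)
      occ <- apply(nc, 1, sum)
      starve <- ifelse(occ == 0, starve + 1L, 0L)
      for (s in which(starve > 50 & !starve_warned)) {
        warning("state ", s, " unoccupied for > 50 consecutive iterations ",
                "(chain ", ch, ")", call. = FALSE)
        starve_warned[s] <- TRUE
      }

      # subject emission means: conjugate Normal given states
      tau2f <- pmax(tau2, 1e-12)
      prec <- nc / array(sig2, c(m, K, n)) + array(1 / tau2f, c(m, K, n))
      mean_post <- (sm / array(sig2, c(m, K, n)) +
                      array(g$mu / tau2f, c(m, K, n))) / prec
      mu_i <- array(rnorm(m * K * n, mean_post, 1 / sqrt(prec)), c(m, K, n))

      # shared within-patient variances sigma^2 (inverse-gamma)
      SS <- apply(sq - 2 * mu_i * sm + nc * mu_i^2, c(1, 2), sum)
      Ntot <- apply(nc, c(1, 2), sum)
      sig2 <- 1 / rgamma(m * K, shape = 0.5 + Ntot / 2,
                         rate = 1 / a_sig + pmax(SS, 0) / 2)
      sig2 <- matrix(pmax(sig2, 1e-8), m, K)
      a_sig <- matrix(1 / rgamma(m * K, 1, rate = 1 / priors$sd_scale^2 +
                                   1 / sig2), m, K)

      # group emission means and between-patient SDs tau
      mi_sum <- apply(mu_i, c(1, 2), sum)
      prec_g <- n / tau2f + prior_mu_prec
      mean_g <- (mi_sum / tau2f + priors$mean_loc * prior_mu_prec) / prec_g
      g$mu <- matrix(rnorm(m * K, mean_g, 1 / sqrt(prec_g)), m, K)
      SS_tau <- apply((mu_i - array(g$mu, c(m, K, n)))^2, c(1, 2), sum)
      tau2 <- 1 / rgamma(m * K, shape = 0.5 + n / 2,
                         rate = 1 / a_tau + SS_tau / 2)
      tau2 <- matrix(pmax(tau2, 1e-12), m, K)
      a_tau <- matrix(1 / rgamma(m * K, 1, rate = 1 / priors$sd_scale^2 +
                                   1 / tau2), m, K)

      # interweaving (non-centered) redraw of the group means: with the
      # subject offsets b_i = mu_i - mu held fixed, mu has an exact
      # Gaussian conditional informed directly by the data, which breaks
      # the slow coupling between group means and state allocations
      b <- mu_i - array(g$mu, c(m, K, n))
      prec_nc <- Ntot / sig2 + prior_mu_prec
      mean_nc <- (apply((sm - nc * b) / array(sig2, c(m, K, n)), c(1, 2), sum) +
                    priors$mean_loc * prior_mu_prec) / prec_nc
      g$mu <- matrix(rnorm(m * K, mean_nc, 1 / sqrt(prec_nc)), m, K)
      mu_i <- array(g$mu, c(m, K, n)) + b

      # matching log-scale Metropolis for tau with standardized subject
      # offsets held fixed (target from sufficient statistics; prior is
      # the conditional of the half-Cauchy mixture given its auxiliary)
      tau_c <- sqrt(tau2)
      cstd <- b / array(tau_c, c(m, K, n))
      A_t <- apply(nc * cstd^2, c(1, 2), sum) / sig2
      B_t <- apply(cstd * (sm - nc * array(g$mu, c(m, K, n))),
                   c(1, 2), sum) / sig2
      tau_p <- tau_c * exp(rnorm(m * K, 0, 0.25))
      lp_t <- function(tt) {
        -0.5 * A_t * tt^2 + B_t * tt - log(tt) - 1 / (a_tau * tt^2)
      }
      acc_t <- log(runif(m * K)) < lp_t(tau_p) - lp_t(tau_c)
      tau_new <- ifelse(acc_t, tau_p, tau_c)
      mu_i <- array(g$mu, c(m, K, n)) +
        cstd * array(tau_new, c(m, K, n))
      tau2 <- matrix(pmax(tau_new^2, 1e-12), m, K)

      if (m > 1) {
        # joint translation move for each group logit row (alpha_bar and
        # all subject rows together, residuals fixed) — lets the group
        # transition parameters mix despite weak per-patient information
        s1 <- vapply(sw$states, function(p) p[1], integer(1))
        asis <- asis_alpha_bar_cpp(g$alpha_bar, alpha_i, sw$trans, s1 - 1L,
                                   prop_ab, priors$logit_loc,
                                   priors$logit_scale)
        g$alpha_bar <- asis$alpha_bar
        alpha_i <- asis$alpha_i
        if (it <= burn_in) {
          step <- min(0.05, 1 / sqrt(it))
          prop_ab <- prop_ab * exp(step * (asis$accept - 0.35))
          prop_ab <- pmin(pmax(prop_ab, 0.01), 3)
        }

        # matching rescaling move for the random-effect SDs
        asis2 <- asis_omega_cpp(sqrt(pmax(om2, 1e-12)), g$alpha_bar, alpha_i,
                                sw$trans, s1 - 1L, a_om, prop_om)
        om2 <- matrix(asis2$omega^2, m, mk1)
        alpha_i <- asis2$alpha_i
        if (it <= burn_in) {
          step <- min(0.05, 1 / sqrt(it))
          prop_om <- prop_om * exp(step * (asis2$accept - 0.3))
          prop_om <- pmin(pmax(prop_om, 0.01), 3)
        }

        # group transition logits and random-effect SDs omega
        om2f <- pmax(om2, 1e-12)
        ai_sum <- apply(alpha_i, c(1, 2), sum)
        prec_ab <- n / om2f + prior_ab_prec
        mean_ab <- (ai_sum / om2f + priors$logit_loc * prior_ab_prec) / prec_ab
        g$alpha_bar <- matrix(rnorm(m * mk1, mean_ab, 1 / sqrt(prec_ab)),
                              m, mk1)
        SS_om <- apply((alpha_i - array(g$alpha_bar, c(m, mk1, n)))^2,
                       c(1, 2), sum)
        om2 <- 1 / rgamma(m * mk1, shape = 0.5 + n / 2,
                          rate = 1 / a_om + SS_om / 2)
        om2 <- matrix(pmax(om2, 1e-12), m, mk1)
        a_om <- matrix(1 / rgamma(m * mk1, 1, rate = 1 / priors$omega_scale^2 +
                                    1 / om2), m, mk1)

        # proposal adaptation during burn-in (frozen afterwards)
        if (it <= burn_in) {
          step <- min(0.05, 1 / sqrt(it))
          prop_sd <- prop_sd * exp(step * (sw$accept / 3 - 0.35))
          prop_sd <- pmin(pmax(prop_sd, 0.01), 5)
        } else {
          acc_post <- acc_post + sw$accept / 3
        }
      }

      draws$mu[it, , ] <- g$mu
      draws$sigma[it, , ] <- sqrt(sig2)
      draws$tau[it, , ] <- sqrt(tau2)
      if (m > 1) {
        draws$alpha_bar[it, , ] <- g$alpha_bar
        draws$omega[it, , ] <- sqrt(om2)
      }
      draws$mu_i[it, , , ] <- mu_i
      draws$alpha_i[it, , , ] <- alpha_i
      if (keep_states)
        draws$states[it, ] <- unlist(sw$states, use.names = FALSE)

      if (verbose && it %% max(1, n_iter %/% 10) == 0)
        message("chain ", ch, ": iteration ", it, "/", n_iter)
    }
    draws$accept_rate <- acc_post / max(n_iter - burn_in, 1)
    draws$prop_sd <- prop_sd
    draws$init <- ini
    chain_list[[ch]] <- draws
  }

  structure(list(
    chains = chain_list, m = m, K = K, n_patients = n,
    patient_ids = ids, channel_names = channels,
    occasions = Ts, row_index = row_index,
    n_iter = n_iter, burn_in = burn_in, n_chains = chains,
    priors = priors, seed = seed,
    order_channel = chain_list[[1]]$init$order_channel,
    panel_hash = panel_hash(panel),
    relabeled = FALSE
  ), class = "mhmm_draws")
}

#' @export
print.mhmm_draws <- function(x, ...) {
  cat("Multilevel HMM posterior draws\n")
  cat(sprintf("  states: %d, channels: %d, patients: %d\n",
              x$m, x$K, x$n_patients))
  cat(sprintf("  chains: %d, iterations: %d (burn-in %d)%s\n",
              x$n_chains, x$n_iter, x$burn_in,
              if (x$relabeled) ", relabeled" else ""))
  invisible(x)
}
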