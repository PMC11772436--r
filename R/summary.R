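# Post-processing of posterior draws: label-switching control and
# posterior summaries.

# Vectorized softmax over (0, A) for a draws x (m-1) matrix of logits.
probs_from_logit_draws <- function(A) {
  A <- as.matrix(A)
  Z <- cbind(0, A)
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Relabel posterior draws into the severity ordering
#'
#' Hidden-state labels are only identified up to permutation. Every
#' post-burn-in draw is permuted so the group-level means of the
#' ordering channel (negative affect, by default) are increasing in the
#' state index; the same permutation is applied to all group- and
#' subject-level parameters and to the sampled state paths of that draw.
#' Transition parameters are permuted exactly on the probability scale
#' and mapped back to logits (reference = column 1). Ties on the
#' ordering channel are broken by self-control descending, then by state
#' index. Idempotent.
#'
#' @param draws An `mhmm_draws` from [fit_mhmm()].
#' @return The relabeled `mhmm_draws` (`$relabeled` set, and
#'   `$relabel_count` recording how many draws needed permuting).
#' @export
relabel_states <- function(draws) {
  stopifnot(inherits(draws, "mhmm_draws"))
  m <- draws$m
  if (m == 1) {
    draws$relabeled <- TRUE
    draws$relabel_count <- 0L
    return(draws)
  }
  oc <- match(draws$order_channel, draws$channel_names)
  sc <- match("self_control", draws$channel_names)
  keep <- (draws$burn_in + 1):draws$n_iter
  n_moved <- 0L
  for (ch in seq_len(draws$n_chains)) {
    d <- draws$chains[[ch]]
    for (it in keep) {
      vals <- d$mu[it, , oc]
      tie2 <- if (!is.na(sc)) -d$mu[it, , sc] else seq_len(m)
      perm <- order(vals, tie2, seq_len(m))
      if (all(perm == seq_len(m))) next
      n_moved <- n_moved + 1L
      inv <- integer(m)
      inv[perm] <- seq_len(m)
      d$mu[it, , ] <- d$mu[it, perm, ]
      d$sigma[it, , ] <- d$sigma[it, perm, ]
      d$tau[it, , ] <- d$tau[it, perm, ]
      G <- gamma_from_alpha_cpp(matrix(d$alpha_bar[it, , ], m, m - 1), m)
      d$alpha_bar[it, , ] <- transition_logits(G[perm, perm, drop = FALSE],
                                               clamp = TRUE)
      # omega has no exact transform under a reference-category change;
      # permute rows and map columns by destination state where defined
      om <- matrix(d$omega[it, , ], m, m - 1)
      colmap <- pmin(pmax(perm[-1] - 1L, 1L), m - 1L)
      d$omega[it, , ] <- om[perm, colmap, drop = FALSE]
      for (i in seq_len(draws$n_patients)) {
        d$mu_i[it, , , i] <- d$mu_i[it, perm, , i]
        Gi <- gamma_from_alpha_cpp(matrix(d$alpha_i[it, , , i], m, m - 1), m)
        d$alpha_i[it, , , i] <- transition_logits(Gi[perm, perm, drop = FALSE],
                                                  clamp = TRUE)
      }
      if (!is.null(d$states)) d$states[it, ] <- inv[d$states[it, ]]
    }
    draws$chains[[ch]] <- d
  }
  draws$relabeled <- TRUE
  draws$relabel_count <- n_moved
  draws
}

# Stack post-burn-in draws of a group-level array across chains into a
# draws x ... matrix/array.
stack_group <- function(draws, what) {
  keep <- (draws$burn_in + 1):draws$n_iter
  do.call(abind_first, lapply(draws$chains, function(d) {
    x <- d[[what]]
    if (length(dim(x)) == 3) x[keep, , , drop = FALSE] else x[keep, , drop = FALSE]
  }))
}

abind_first <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  out <- array(NA_real_, c(sum(vapply(xs, function(x) dim(x)[1], numeric(1))),
                           d[-1]))
  at <- 0
  for (x in xs) {
    idx <- at + seq_len(dim(x)[1])
    if (length(d) == 3) out[idx, , ] <- x else out[idx, , , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

# Post-burn-in draws of a subject-level array for patient i, stacked
# across chains into (kept x m x width).
stack_subject <- function(draws, what, i) {
  keep <- (draws$burn_in + 1):draws$n_iter
  parts <- lapply(draws$chains, function(d) {
    x <- d[[what]][keep, , , i, drop = FALSE]
    array(x, dim = dim(x)[1:3])
  })
  do.call(abind_first, parts)
}

q_summary <- function(v) {
  qs <- quantile(v, c(0.5, 0.025, 0.975), names = FALSE, na.rm = TRUE)
  c(median = qs[1], lower = qs[2], upper = qs[3])
}

#' Posterior point estimates and credible intervals
#'
#' Posterior medians and central 95% credible intervals for all
#' group-level parameters and for every patient's emission means and
#' transition matrix. Transition parameters are summarized on the
#' probability scale: each retained draw's logits are transformed to a
#' transition row first, then the rows of cellwise medians are reported
#' (and renormalized for the point matrices, since cellwise medians of
#' simplex draws need not sum to 1 exactly).
#'
#' @param draws A relabeled `mhmm_draws` (see [relabel_states()]).
#' @return Object of class `mhmm_summary` with long-format data frames
#'   `group` and `subject`, point-parameter matrices in `group_point`
#'   (`mu`, `sigma`, `Gamma`, `pi`) and `subject_point` (a named list of
#'   [subject_params()]), plus staying-probability summaries.
#' @export
posterior_summary <- function(draws) {
  stopifnot(inherits(draws, "mhmm_draws"))
  if (!isTRUE(draws$relabeled))
    stop("run relabel_states() before summarizing")
  n_kept <- (draws$n_iter - draws$burn_in) * draws$n_chains
  if (n_kept < 100) stop("need at least 100 post-burn-in draws, have ", n_kept)
  m <- draws$m
  K <- draws$K
  channels <- draws$channel_names

  mu_d <- stack_group(draws, "mu")
  sig_d <- stack_group(draws, "sigma")
  tau_d <- stack_group(draws, "tau")

  grp <- list()
  for (what in c("mu", "sigma", "tau")) {
    arr <- switch(what, mu = mu_d, sigma = sig_d, tau = tau_d)
    for (s in seq_len(m)) for (k in seq_len(K)) {
      qs <- q_summary(arr[, s, k])
      grp[[length(grp) + 1]] <- data.frame(
        parameter = switch(what, mu = "emission_mean",
                           sigma = "emission_sd", tau = "between_sd"),
        state = s, column = channels[k],
        median = qs[1], lower = qs[2], upper = qs[3])
    }
  }

  gamma_med <- diag(m)
  staying <- data.frame()
  if (m > 1) {
    ab_d <- stack_group(draws, "alpha_bar")
    gam_draws <- array(NA_real_, c(dim(ab_d)[1], m, m))
    for (s in seq_len(m)) {
      gam_draws[, s, ] <- probs_from_logit_draws(
        matrix(ab_d[, s, ], ncol = m - 1))
    }
    for (s in seq_len(m)) for (j in seq_len(m)) {
      qs <- q_summary(gam_draws[, s, j])
      grp[[length(grp) + 1]] <- data.frame(
        parameter = "transition", state = s, column = as.character(j),
        median = qs[1], lower = qs[2], upper = qs[3])
      gamma_med[s, j] <- qs[1]
    }
    staying <- do.call(rbind, lapply(seq_len(m), function(s) {
      qs <- q_summary(gam_draws[, s, s])
      data.frame(state = s, median = qs[1], lower = qs[2], upper = qs[3])
    }))
    om_d <- stack_group(draws, "omega")
    for (s in seq_len(m)) for (j in seq_len(m - 1)) {
      qs <- q_summary(om_d[, s, j])
      grp[[length(grp) + 1]] <- data.frame(
        parameter = "transition_re_sd", state = s,
        column = as.character(j + 1),
        median = qs[1], lower = qs[2], upper = qs[3])
    }
  }
  group <- do.call(rbind, grp)
  rownames(group) <- NULL

  mu_point <- apply(mu_d, c(2, 3), median)
  sig_point <- apply(sig_d, c(2, 3), median)
  colnames(mu_point) <- colnames(sig_point) <- channels
  Gamma_point <- gamma_med / rowSums(gamma_med)
  pi_point <- as.numeric(stationary_cpp(Gamma_point))

  # subject-level summaries
  keep <- (draws$burn_in + 1):draws$n_iter
  subj_rows <- list()
  subject_point <- list()
  for (i in seq_len(draws$n_patients)) {
    mui <- stack_subject(draws, "mu_i", i)
    mu_i_med <- apply(mui, c(2, 3), median)
    for (s in seq_len(m)) for (k in seq_len(K)) {
      qs <- q_summary(mui[, s, k])
      subj_rows[[length(subj_rows) + 1]] <- data.frame(
        patient_id = draws$patient_ids[i], parameter = "emission_mean",
        state = s, column = channels[k],
        median = qs[1], lower = qs[2], upper = qs[3])
    }
    if (m > 1) {
      ai <- stack_subject(draws, "alpha_i", i)
      Gi_med <- matrix(NA_real_, m, m)
      for (s in seq_len(m)) {
        P <- probs_from_logit_draws(matrix(ai[, s, ], ncol = m - 1))
        Gi_med[s, ] <- apply(P, 2, median)
        qs <- q_summary(P[, s])
        subj_rows[[length(subj_rows) + 1]] <- data.frame(
          patient_id = draws$patient_ids[i], parameter = "staying",
          state = s, column = as.character(s),
          median = qs[1], lower = qs[2], upper = qs[3])
      }
      Gi <- Gi_med / rowSums(Gi_med)
    } else {
      Gi <- matrix(1, 1, 1)
    }
    colnames(mu_i_med) <- channels
    subject_point[[draws$patient_ids[i]]] <- subject_params(
      emission_means = mu_i_med, emission_sds = sig_point,
      transition = Gi, patient_id = draws$patient_ids[i])
  }
  subject <- do.call(rbind, subj_rows)
  rownames(subject) <- NULL

  structure(list(
    m = m, K = K, channel_names = channels,
    patient_ids = draws$patient_ids, n_draws = n_kept,
    group = group, subject = subject,
    group_point = list(mu = mu_point, sigma = sig_point,
                       Gamma = Gamma_point, pi = pi_point),
    staying = staying, gamma_median = gamma_med,
    subject_point = subject_point,
    order_channel = draws$order_channel,
    panel_hash = draws$panel_hash,
    relabeled = TRUE
  ), class = "mhmm_summary")
}

#' Patient-level point parameters from a posterior summary
#'
#' @param summary An `mhmm_summary`.
#' @return Named list of [subject_params()] keyed by patient id, using
#'   subject-level posterior medians for means and transitions and the
#'   group-level posterior-median emission SDs.
#' @export
subject_point_params <- function(summary) {
  stopifnot(inherits(summary, "mhmm_summary"))
  summary$subject_point
}

#' @export
print.mhmm_summary <- function(x, ...) {
  cat("Multilevel HMM posterior summary (", x$n_draws, " draws)\n", sep = "")
  cat("Group emission means (posterior medians):\n")
  print(round(x$group_point$mu, 2))
  if (nrow(x$staying) > 0) {
    cat("Staying probabilities (median [95% CI]):\n")
    for (s in seq_len(x$m))
      cat(sprintf("  state %d: %.3f [%.3f, %.3f]\n", s,
                  x$staying$median[s], x$staying$lower[s], x$staying$upper[s]))
  }
  invisible(x)
}
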