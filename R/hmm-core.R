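# Single-subject HMM computations: emission densities with missing data,
# forward log-likelihood, FFBS draws and Viterbi decoding.

#' Patient-level HMM parameters
#'
#' Container for one patient's hidden Markov model: state-dependent
#' Gaussian emission means and SDs per channel, a transition matrix, and
#' an initial state distribution (defaulting to the stationary
#' distribution of the transition matrix, recomputed on construction).
#'
#' @param emission_means `m x K` matrix of state x channel means.
#' @param emission_sds `m x K` matrix (or scalar) of positive SDs.
#' @param transition `m x m` row-stochastic matrix.
#' @param init Initial state distribution; default stationary.
#' @param patient_id Optional identifier carried through summaries.
#' @return Object of class `subject_params`.
#' @export
subject_params <- function(emission_means, emission_sds, transition,
                           init = NULL, patient_id = NULL) {
  mu <- as.matrix(emission_means)
  m <- nrow(mu)
  K <- ncol(mu)
  sig <- if (length(emission_sds) == 1) matrix(emission_sds, m, K) else
    as.matrix(emission_sds)
  Gamma <- as.matrix(transition)
  check_stochastic(Gamma, tol = 1e-8)
  if (any(sig <= 0)) stop("emission_sds must be > 0")
  if (!all(dim(sig) == c(m, K))) stop("emission_sds must be m x K")
  if (nrow(Gamma) != m) stop("transition must be m x m")
  init <- init %||% as.numeric(stationary_cpp(Gamma))
  if (length(init) != m || any(init < 0) || abs(sum(init) - 1) > 1e-8)
    stop("init must be a probability vector of length m")
  structure(list(m = m, K = K, emission_means = mu, emission_sds = sig,
                 transition = Gamma, init = init / sum(init),
                 patient_id = patient_id),
            class = "subject_params")
}

# Coerce one patient's data to a T x K numeric matrix.
as_sequence_matrix <- function(sequence, params) {
  y <- if (is.data.frame(sequence)) {
    as.matrix(sequence[, panel_channels(sequence), drop = FALSE])
  } else {
    as.matrix(sequence)
  }
  if (nrow(y) == 0) stop("empty observation sequence")
  if (ncol(y) != params$K) stop("sequence has ", ncol(y),
                                " channels, params expect ", params$K)
  storage.mode(y) <- "double"
  y
}

#' State-conditional log emission density of one occasion
#'
#' Sum of univariate Gaussian log densities over the observed channels
#' only; `NA` channels are marginalized out (contribute 0), so a fully
#' missing occasion has log density 0 in every state.
#'
#' @param y Numeric vector of length `K`, `NA` for missing channels.
#' @param state State index in `1..m`.
#' @param params A [subject_params()].
#' @return Scalar log density.
#' @export
emission_logdensity <- function(y, state, params) {
  ld <- emission_logdens_cpp(matrix(as.numeric(y), 1, params$K),
                             params$emission_means, params$emission_sds)
  ld[1, state]
}

#' Exact marginal log-likelihood of one patient's sequence
#'
#' Scaled forward recursion over the full occasion grid; missing
#' occasions contribute transition structure only. The chain is never
#' split at gaps (equal-spacing assumption).
#'
#' @param sequence `T x K` matrix or a one-patient panel slice; `NA` for
#'   missing values.
#' @param params A [subject_params()].
#' @return Scalar log-likelihood.
#' @export
forward_loglik <- function(sequence, params) {
  y <- as_sequence_matrix(sequence, params)
  forward_loglik_cpp(y, params$emission_means, params$emission_sds,
                     params$transition, params$init)
}

#' Draw one latent state path from its conditional posterior (FFBS)
#'
#' Forward filtering with scaling followed by backward sampling: one
#' exact draw from `P(S_1..T | y, params)` using R's RNG stream.
#'
#' @inheritParams forward_loglik
#' @return Integer vector of states in `1..m`.
#' @export
ffbs_sample <- function(sequence, params) {
  y <- as_sequence_matrix(sequence, params)
  ffbs_cpp(y, params$emission_means, params$emission_sds,
           params$transition, params$init)
}

#' Viterbi decoding of the most likely state path
#'
#' Joint maximum-a-posteriori path by log-space dynamic programming;
#' ties are broken toward the lower state index. Missing occasions are
#' decoded from the transition structure alone.
#'
#' @inheritParams forward_loglik
#' @return Integer vector of states in `1..m`.
#' @export
viterbi_decode <- function(sequence, params) {
  y <- as_sequence_matrix(sequence, params)
  viterbi_cpp(y, params$emission_means, params$emission_sds,
              params$transition, params$init)
}

#' Viterbi-decode every patient in a panel
#'
#' @param panel An ESM panel data frame.
#' @param subject_params_list Named list of [subject_params()], one per
#'   patient (names = patient ids), e.g. from [subject_point_params()].
#' @return Data frame `patient_id`, `occasion`, `state` (class
#'   `decoded_trajectory`).
#' @export
decode_trajectories <- function(panel, subject_params_list) {
  mats <- panel_matrices(panel)
  out <- lapply(names(mats), function(id) {
    sp <- subject_params_list[[id]]
    if (is.null(sp)) stop("no subject parameters for patient ", id)
    data.frame(patient_id = id, occasion = seq_len(nrow(mats[[id]])),
               state = viterbi_decode(mats[[id]], sp))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("decoded_trajectory", "data.frame")
  res
}
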