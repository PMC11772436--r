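# Simulation configuration: the generative model for synthetic
# experience-sampling (ESM) panels.

#' Build a simulation configuration
#'
#' Describes the generative multilevel HMM used by [simulate_panel()]:
#' `m` latent states emitting `K` Gaussian channels on the 1-100 ESM
#' score scale, patient-level Gaussian random effects on emission means
#' (`between_sd`) and on transition-row logits (`transition_re_sd`), and
#' beep-level missingness applied completely at random.
#'
#' @param n_patients Number of patients.
#' @param n_occasions Measurement occasions per patient (3 beeps/day).
#' @param m Number of latent states.
#' @param channel_names Character vector of `K` channel names.
#' @param group_means `m x K` matrix of group-level state-dependent means
#'   (score units).
#' @param between_sd `m x K` matrix (or scalar) of between-patient SDs of
#'   the emission means (score units), `>= 0`.
#' @param within_sd `m x K` matrix (or scalar) of within-patient residual
#'   SDs (score units), `> 0`.
#' @param group_transition `m x m` row-stochastic group transition matrix.
#' @param transition_re_sd Scalar SD (logit units) of patient random
#'   effects on transition-row logits, `>= 0`.
#' @param missing_rate Probability in `[0, 1)` that a whole occasion is
#'   missing.
#' @param init_distribution Initial state distribution; default the
#'   stationary distribution of `group_transition`.
#' @param seed Integer master seed.
#' @param clip_to_scale Clip generated scores to `[1, 100]`? The model
#'   itself assumes unbounded Gaussians, so clipping is a realism toggle
#'   that should be off for parameter-recovery experiments.
#' @return An object of class `sim_config`.
#' @seealso [default_study_config()], [simulate_panel()]
#' @export
sim_config <- function(n_patients, n_occasions, m, channel_names,
                       group_means, between_sd, within_sd,
                       group_transition, transition_re_sd = 0,
                       missing_rate = 0, init_distribution = NULL,
                       seed = 1L, clip_to_scale = TRUE) {
  K <- length(channel_names)
  expand <- function(x) {
    if (length(x) == 1) matrix(x, m, K) else as.matrix(x)
  }
  cfg <- structure(list(
    n_patients = as.integer(n_patients),
    n_occasions = as.integer(n_occasions),
    m = as.integer(m), K = as.integer(K),
    channel_names = channel_names,
    group_means = as.matrix(group_means),
    between_sd = expand(between_sd),
    within_sd = expand(within_sd),
    group_transition = as.matrix(group_transition),
    transition_re_sd = transition_re_sd,
    missing_rate = missing_rate,
    init_distribution = init_distribution %||%
      as.numeric(stationary_cpp(as.matrix(group_transition))),
    seed = as.integer(seed),
    clip_to_scale = isTRUE(clip_to_scale)
  ), class = "sim_config")
  dimnames(cfg$group_means) <- list(NULL, channel_names)
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks every structural invariant and fails naming the violated one.
#'
#' @param config A `sim_config`.
#' @return The config, invisibly, if valid.
#' @export
validate_sim_config <- function(config) {
  fail <- function(msg) stop("invalid sim_config: ", msg, call. = FALSE)
  with(config, {
    if (n_patients < 1 || n_occasions < 1) fail("n_patients and n_occasions must be >= 1")
    if (m < 1) fail("m must be >= 1")
    if (K < 1 || length(channel_names) != K) fail("K channel names required")
    if (!all(dim(group_means) == c(m, K))) fail("group_means must be m x K")
    if (!all(dim(between_sd) == c(m, K))) fail("between_sd must be m x K")
    if (!all(dim(within_sd) == c(m, K))) fail("within_sd must be m x K")
    if (any(within_sd <= 0)) fail("within_sd must be > 0 elementwise")
    if (any(between_sd < 0)) fail("between_sd must be >= 0 elementwise")
    if (!all(dim(group_transition) == c(m, m))) fail("group_transition must be m x m")
    if (any(group_transition < 0) || any(abs(rowSums(group_transition) - 1) > 1e-12))
      fail("group_transition rows must sum to 1 within 1e-12")
    if (transition_re_sd < 0) fail("transition_re_sd must be >= 0")
    if (missing_rate < 0 || missing_rate >= 1) fail("missing_rate must lie in [0, 1)")
    if (length(init_distribution) != m ||
        any(init_distribution < 0) ||
        abs(sum(init_distribution) - 1) > 1e-12)
      fail("init_distribution must sum to 1 within 1e-12")
  })
  invisible(config)
}

#' The default study design configuration
#'
#' The study design this package emulates: 26 patients, 60 occasions
#' (3 beeps/day), five symptom channels (self-control, negative affect,
#' contact avoidance, contact desire, suicidal ideation) on a 1-100
#' scale, four latent crisis states whose group-level emission means and
#' staying probabilities (0.84, 0.73, 0.63, 0.57) equal the reported
#' sample-level estimates, and a beep-level missingness rate of
#' 14.23 / 60 occasions. Off-diagonal transition mass follows the
#' reported qualitative switching pattern (from state 1 mostly to 2,
#' from 2 mostly upward, from 3 mostly back to 2, from 4 mostly to 3);
#' dispersions (`within_sd` 12, `between_sd` 8, `transition_re_sd` 0.7)
#' are package defaults chosen to give visible but recoverable
#' patient heterogeneity.
#'
#' @param seed Integer master seed.
#' @param clip_to_scale Clip scores to `[1, 100]`? Use `FALSE` for
#'   parameter-recovery experiments.
#' @param missing_rate Occasion-level missingness probability.
#' @return A `sim_config`.
#' @examples
#' cfg <- default_study_config()
#' cfg$group_means["4", "self_control"] # 13.30
#' @export
default_study_config <- function(seed = 1L, clip_to_scale = TRUE,
                                 missing_rate = 14.23 / 60) {
  channels <- c("self_control", "negative_affect", "contact_avoidance",
                "contact_desire", "suicidal_ideation")
  mu <- cbind(
    self_control = c(43.53, 37.16, 30.25, 13.30),
    negative_affect = c(31.80, 49.84, 62.15, 72.31),
    contact_avoidance = c(17.29, 28.23, 40.75, 48.17),
    contact_desire = c(41.38, 41.59, 40.22, 6.67),
    suicidal_ideation = c(3.85, 46.51, 58.07, 65.71)
  )
  rownames(mu) <- as.character(1:4)
  Gamma <- rbind(
    c(0.84, 0.10, 0.04, 0.02),
    c(0.06, 0.73, 0.14, 0.07),
    c(0.04, 0.20, 0.63, 0.13),
    c(0.02, 0.13, 0.28, 0.57)
  )
  cfg <- sim_config(
    n_patients = 26L, n_occasions = 60L, m = 4L,
    channel_names = channels, group_means = mu,
    between_sd = 8, within_sd = 12, group_transition = Gamma,
    transition_re_sd = 0.7, missing_rate = missing_rate,
    seed = seed, clip_to_scale = clip_to_scale
  )
  rownames(cfg$group_means) <- as.character(1:4)
  cfg
}

#' Write / read a simulation configuration as YAML
#'
#' @param config A `sim_config`.
#' @param path File path.
#' @return `read_sim_config()` returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$group_means <- apply(x$group_means, 1, as.numeric, simplify = FALSE)
  x$between_sd <- apply(x$between_sd, 1, as.numeric, simplify = FALSE)
  x$within_sd <- apply(x$within_sd, 1, as.numeric, simplify = FALSE)
  x$group_transition <- apply(x$group_transition, 1, as.numeric, simplify = FALSE)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  rowbind <- function(l) do.call(rbind, lapply(l, as.numeric))
  # YAML stores limited decimal precision; renormalize simplexes that
  # are off by no more than that truncation
  renorm <- function(p) {
    if (abs(sum(p) - 1) > 1e-4) stop("probabilities in ", path,
                                     " do not sum to 1")
    p / sum(p)
  }
  G <- rowbind(x$group_transition)
  G <- t(apply(G, 1, renorm))
  sim_config(
    n_patients = x$n_patients, n_occasions = x$n_occasions, m = x$m,
    channel_names = x$channel_names,
    group_means = rowbind(x$group_means),
    between_sd = rowbind(x$between_sd),
    within_sd = rowbind(x$within_sd),
    group_transition = G,
    transition_re_sd = x$transition_re_sd,
    missing_rate = x$missing_rate,
    init_distribution = renorm(as.numeric(x$init_distribution)),
    seed = x$seed, clip_to_scale = x$clip_to_scale
  )
}
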