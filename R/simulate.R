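# Synthetic ESM panel generator: the generative multilevel HMM.

#' Simulate a multilevel ESM panel
#'
#' Draws, per patient: emission means from
#' `Normal(group_means, between_sd)` for every state x channel; a
#' transition matrix by adding `Normal(0, transition_re_sd)` noise to the
#' group transition-row logits and mapping back to probabilities; a
#' latent state chain from `init_distribution` and the patient's
#' transition matrix; and observations from
#' `Normal(subject mean, within_sd)`, clipped to `[1, 100]` when
#' `clip_to_scale` is set. Beep-level missingness is then applied at
#' `missing_rate` via [apply_missingness()]. Per-patient random streams
#' are derived from `(seed, patient index)`, so the panel for any subset
#' of patients is reproducible.
#'
#' @param config A [sim_config()].
#' @return A list of class `esm_sim` with elements
#'   \describe{
#'     \item{panel}{data frame: `patient_id`, `occasion`, `day`, `beep`,
#'       and one column per channel (NA where missing).}
#'     \item{states}{data frame of true latent states for every occasion,
#'       including missing-observation occasions.}
#'     \item{subject_params}{list (one per patient) of
#'       [subject_params()] holding the true patient-level parameters.}
#'     \item{config}{the generating configuration.}
#'   }
#' @examples
#' cfg <- default_study_config(seed = 7, missing_rate = 0)
#' sim <- simulate_panel(cfg)
#' nrow(sim$panel) # 26 * 60
#' @export
simulate_panel <- function(config) {
  validate_sim_config(config)
  m <- config$m
  K <- config$K
  Tn <- config$n_occasions
  group_logits <- transition_logits(config$group_transition)

  panels <- vector("list", config$n_patients)
  states <- vector("list", config$n_patients)
  subj <- vector("list", config$n_patients)
  for (i in seq_len(config$n_patients)) {
    set.seed(derive_seed(config$seed, i))
    mu_i <- config$group_means +
      matrix(rnorm(m * K), m, K) * config$between_sd
    if (m > 1) {
      alpha_i <- group_logits +
        matrix(rnorm(m * (m - 1)), m, m - 1) * config$transition_re_sd
      Gamma_i <- gamma_from_alpha_cpp(alpha_i, m)
    } else {
      Gamma_i <- matrix(1, 1, 1)
    }
    S <- integer(Tn)
    S[1] <- sample.int(m, 1, prob = config$init_distribution)
    if (Tn > 1) {
      for (t in 2:Tn) S[t] <- sample.int(m, 1, prob = Gamma_i[S[t - 1], ])
    }
    y <- mu_i[S, , drop = FALSE] +
      matrix(rnorm(Tn * K), Tn, K) * config$within_sd[S, , drop = FALSE]
    if (config$clip_to_scale) y <- pmin(pmax(y, 1), 100)
    colnames(y) <- config$channel_names
    panels[[i]] <- data.frame(
      patient_id = i, occasion = seq_len(Tn),
      day = (seq_len(Tn) - 1L) %/% 3L + 1L,
      beep = (seq_len(Tn) - 1L) %% 3L + 1L,
      y, check.names = FALSE
    )
    states[[i]] <- data.frame(patient_id = i, occasion = seq_len(Tn), state = S)
    subj[[i]] <- subject_params(
      emission_means = mu_i, emission_sds = config$within_sd,
      transition = Gamma_i, init = config$init_distribution,
      patient_id = i
    )
  }
  panel <- do.call(rbind, panels)
  rownames(panel) <- NULL
  if (config$missing_rate > 0) {
    panel <- apply_missingness(panel, config$missing_rate,
                               seed = derive_seed(config$seed, 0L, 1L))
  }
  structure(list(
    panel = panel,
    states = do.call(rbind, states),
    subject_params = subj,
    config = config
  ), class = "esm_sim")
}

#' Apply beep-level missingness to a panel
#'
#' Each occasion is independently set fully missing (all channels) with
#' probability `missing_rate`, independent of states and values, i.e.
#' missing completely at random — the strongest form compatible with the
#' missing-at-random treatment in the likelihood. Rows are masked, never
#' deleted, so the design shape is preserved. Per-patient random streams
#' derive from `(seed, patient index)`.
#'
#' @param panel An ESM panel data frame (see [simulate_panel()]).
#' @param missing_rate Probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The panel with masked occasions set to `NA` in every channel.
#' @export
apply_missingness <- function(panel, missing_rate, seed = 1L) {
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (missing_rate == 0) return(panel)
  channels <- panel_channels(panel)
  ids <- unique(panel$patient_id)
  for (idx in seq_along(ids)) {
    rows <- which(panel$patient_id == ids[idx])
    set.seed(derive_seed(seed, idx, 2L))
    drop <- runif(length(rows)) < missing_rate
    panel[rows[drop], channels] <- NA_real_
  }
  panel
}

# Channel columns of a panel = everything beyond the design columns.
panel_channels <- function(panel) {
  setdiff(colnames(panel), c("patient_id", "occasion", "day", "beep"))
}

# Split a panel into per-patient numeric T x K matrices, ordered by
# occasion; used by the fitting and decoding code.
panel_matrices <- function(panel, channels = NULL) {
  channels <- channels %||% panel_channels(panel)
  ids <- unique(panel$patient_id)
  out <- lapply(ids, function(id) {
    sl <- panel[panel$patient_id == id, , drop = FALSE]
    sl <- sl[order(sl$occasion), , drop = FALSE]
    if (!all(sl$occasion == seq_len(nrow(sl))))
      stop("occasions within a patient must be consecutive from 1 (patient ",
           id, ")")
    as.matrix(sl[, channels, drop = FALSE])
  })
  names(out) <- as.character(ids)
  out
}
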