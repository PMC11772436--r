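# Substantive outputs: state composition, state dynamics (staying
# probabilities, high-staying classification, normalized switching
# probabilities, incidence), and per-patient trajectories.

#' State composition table
#'
#' Long table of state-dependent channel means — posterior medians with
#' 95% credible intervals — at the sample level and per patient (the
#' data behind bar-plus-dots composition figures). Sample rows come
#' first. Monotonicity of the ordering channel across states is checked
#' and reported in the `ordering_monotone` attribute.
#'
#' @param summary A relabeled `mhmm_summary`.
#' @return Data frame `level, patient_id, state, channel, median, lower,
#'   upper` with attribute `ordering_monotone`.
#' @export
state_composition <- function(summary) {
  stopifnot(inherits(summary, "mhmm_summary"))
  if (!isTRUE(summary$relabeled))
    stop("state_composition requires a relabeled summary")
  g <- summary$group[summary$group$parameter == "emission_mean", ]
  sample_rows <- data.frame(level = "sample", patient_id = NA_character_,
                            state = g$state, channel = g$column,
                            median = g$median, lower = g$lower,
                            upper = g$upper)
  s <- summary$subject[summary$subject$parameter == "emission_mean", ]
  patient_rows <- data.frame(level = "patient",
                             patient_id = as.character(s$patient_id),
                             state = s$state, channel = s$column,
                             median = s$median, lower = s$lower,
                             upper = s$upper)
  out <- rbind(sample_rows, patient_rows)
  rownames(out) <- NULL
  oc <- summary$order_channel
  ocm <- sample_rows$median[sample_rows$channel == oc]
  attr(out, "ordering_monotone") <- all(diff(ocm[order(
    sample_rows$state[sample_rows$channel == oc])]) > 0)
  out
}

#' State-dynamics summary of a transition matrix
#'
#' Staying probabilities (the diagonal), their classification as "high"
#' when `>= threshold` (default 0.70), normalized switching
#' probabilities — each off-diagonal entry divided by one minus the
#' row's staying probability, discounting the diagonal so switch
#' destinations are comparable across departure states — and state
#' incidence (occupancy proportions of the decoded trajectory when
#' given, else the stationary distribution).
#'
#' @param transition `m x m` row-stochastic matrix (sample- or
#'   patient-level).
#' @param decoded Optional [decode_trajectories()] output (or any data
#'   frame with a `state` column) for occupancy-based incidence.
#' @param threshold High-staying classification threshold in `(0, 1)`.
#' @param level Label stored on the result (`"sample"` or `"patient"`).
#' @return Object of class `dynamics_summary`: list with `staying`,
#'   `high_flags`, `switching_norm` (diagonal 0; an all-zero row when a
#'   state is absorbing within 1e-12), `incidence`, `unvisited` (states
#'   never decoded, patient level), `threshold`, `level`.
#' @export
dynamics_summary <- function(transition, decoded = NULL, threshold = 0.70,
                             level = if (is.null(decoded)) "sample" else "patient") {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  Gamma <- as.matrix(transition)
  check_stochastic(Gamma)
  m <- nrow(Gamma)
  staying <- diag(Gamma)
  high_flags <- staying >= threshold
  switching_norm <- matrix(0, m, m)
  for (s in seq_len(m)) {
    rest <- 1 - staying[s]
    if (rest > 1e-12) {
      switching_norm[s, ] <- Gamma[s, ] / rest
      switching_norm[s, s] <- 0
    }
  }
  unvisited <- integer(0)
  if (!is.null(decoded)) {
    st <- decoded$state
    occ <- tabulate(st, nbins = m)
    incidence <- occ / sum(occ)
    unvisited <- which(occ == 0)
  } else {
    incidence <- as.numeric(stationary_cpp(Gamma))
  }
  structure(list(staying = staying, high_flags = high_flags,
                 switching_norm = switching_norm, incidence = incidence,
                 unvisited = unvisited, threshold = threshold,
                 level = level, m = m),
            class = "dynamics_summary")
}

#' @export
print.dynamics_summary <- function(x, ...) {
  cat(sprintf("State dynamics (%s level, high-staying threshold %.2f)\n",
              x$level, x$threshold))
  for (s in seq_len(x$m))
    cat(sprintf("  state %d: staying %.3f%s, incidence %.3f\n", s,
                x$staying[s], if (x$high_flags[s]) " [high]" else "",
                x$incidence[s]))
  if (length(x$unvisited) > 0)
    cat("  unvisited states:", paste(x$unvisited, collapse = ", "), "\n")
  invisible(x)
}

#' Occupancy and trajectory tables from decoded state paths
#'
#' @param decoded A [decode_trajectories()] data frame.
#' @param m Number of states (default: maximum decoded state).
#' @return List with `occupancy` (per patient x state proportions),
#'   `pooled_incidence` (sums to 1), `switches` (per-patient count of
#'   occasions with a state change), and `trajectories` (the long
#'   `patient_id, occasion, state` table, raster-plot ready).
#' @export
occupancy_and_trajectories <- function(decoded, m = max(decoded$state)) {
  ids <- unique(decoded$patient_id)
  occ <- t(vapply(ids, function(id) {
    st <- decoded$state[decoded$patient_id == id]
    tabulate(st, nbins = m) / length(st)
  }, numeric(m)))
  rownames(occ) <- as.character(ids)
  colnames(occ) <- as.character(seq_len(m))
  switches <- vapply(ids, function(id) {
    sl <- decoded[decoded$patient_id == id, ]
    st <- sl$state[order(sl$occasion)]
    sum(st[-1] != st[-length(st)])
  }, numeric(1))
  names(switches) <- as.character(ids)
  pooled <- tabulate(decoded$state, nbins = m) / nrow(decoded)
  traj <- decoded[order(decoded$patient_id, decoded$occasion),
                  c("patient_id", "occasion", "state")]
  rownames(traj) <- NULL
  list(occupancy = occ, pooled_incidence = pooled, switches = switches,
       trajectories = traj)
}

#' Dynamics summaries for every patient plus the sample level
#'
#' Convenience wrapper building [dynamics_summary()] for the group-level
#' posterior-median transition matrix (occupancy-based incidence pooled
#' over decoded trajectories) and for each patient's posterior-median
#' transition matrix with its own decoded trajectory.
#'
#' @param summary A relabeled `mhmm_summary`.
#' @param decoded A [decode_trajectories()] data frame for all patients.
#' @param threshold High-staying threshold.
#' @return List with `sample` and `patient` (named list) summaries.
#' @export
dynamics_report <- function(summary, decoded, threshold = 0.70) {
  stopifnot(inherits(summary, "mhmm_summary"))
  sample_dyn <- dynamics_summary(summary$group_point$Gamma, decoded,
                                 threshold = threshold, level = "sample")
  pat <- lapply(summary$patient_ids, function(id) {
    sp <- summary$subject_point[[id]]
    dynamics_summary(sp$transition,
                     decoded[decoded$patient_id == id, , drop = FALSE],
                     threshold = threshold, level = "patient")
  })
  names(pat) <- summary$patient_ids
  list(sample = sample_dyn, patient = pat)
}
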