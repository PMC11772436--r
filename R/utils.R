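# Internal helpers shared across modules.

# Deterministic derived seeds: one master seed, independent streams per
# patient / chain / stage, all below 2^31.
derive_seed <- function(seed, idx, offset = 0L) {
  s <- as.numeric(seed) %% 2147483647
  v <- (s * 48271 + as.numeric(idx) * 96731 + as.numeric(offset) * 69621 + 11) %%
    2147483647
  as.integer(v)
}

#' Map transition-row logits to a probability row
#'
#' The multinomial-logit parametrization used for transition rows: the
#' first column of each row is the reference category with logit 0, so a
#' row of an `m`-state transition matrix is described by `m - 1` log-odds.
#' This parametrization is what allows Gaussian random effects on
#' transition probabilities.
#'
#' @param alpha_row Numeric vector of length `m - 1`, finite log-odds of
#'   moving to columns `2..m` relative to column 1.
#' @return Strictly positive probability vector of length `m` summing to 1.
#' @seealso [logits_from_row_probs()]
#' @examples
#' row_probs_from_logits(c(0, 0, 0)) # uniform over 4 states
#' @export
row_probs_from_logits <- function(alpha_row) {
  if (!all(is.finite(alpha_row))) stop("non-finite transition logits")
  z <- c(0, alpha_row)
  e <- exp(z - max(z))
  e / sum(e)
}

#' Map a strictly positive probability row to transition logits
#'
#' Inverse of [row_probs_from_logits()]; defined for strictly positive
#' rows (column 1 is the reference category).
#'
#' @param p Probability vector of length `m`, strictly positive.
#' @return Numeric vector of length `m - 1` of log-odds vs. column 1.
#' @export
logits_from_row_probs <- function(p) {
  if (any(p <= 0)) stop("logits undefined for zero probabilities")
  log(p[-1]) - log(p[1])
}

#' Stationary distribution of a transition matrix
#'
#' @param Gamma Row-stochastic square matrix.
#' @return Probability vector `pi` with `pi %*% Gamma == pi`.
#' @export
stationary_distribution <- function(Gamma) {
  Gamma <- as.matrix(Gamma)
  check_stochastic(Gamma)
  as.numeric(stationary_cpp(Gamma))
}

check_stochastic <- function(Gamma, tol = 1e-8) {
  if (!is.matrix(Gamma) || nrow(Gamma) != ncol(Gamma))
    stop("transition matrix must be square")
  if (any(Gamma < -tol) || any(abs(rowSums(Gamma) - 1) > tol))
    stop("transition matrix rows must be nonnegative and sum to 1")
  invisible(TRUE)
}

# Cheap content fingerprint used to match panels with fits/summaries.
panel_hash <- function(panel) {
  y <- as.matrix(panel[, panel_channels(panel), drop = FALSE])
  v <- y[!is.na(y)]
  sprintf("%d:%d:%.6f:%.6f", nrow(panel), length(v), sum(v), sum(v^2) / 1e4)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# m x (m-1) matrix of row logits (reference column 1) for a strictly
# positive row-stochastic matrix. clamp guards against cells that have
# underflowed to zero (e.g. rows of a state unoccupied in a draw).
transition_logits <- function(Gamma, clamp = FALSE) {
  m <- nrow(Gamma)
  if (m == 1) return(matrix(0, 1, 0))
  if (clamp) Gamma <- pmax(Gamma, 1e-290)
  out <- matrix(0, m, m - 1)
  for (s in seq_len(m)) out[s, ] <- logits_from_row_probs(Gamma[s, ])
  out
}

# Numeric formatting that survives a CSV round trip bit-exactly.
format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}
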