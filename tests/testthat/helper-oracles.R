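# Brute-force oracles for small HMM instances: enumerate all m^T state
# paths directly from the model definition.

enum_paths <- function(m, Tn) {
  as.matrix(expand.grid(rep(list(seq_len(m)), Tn)))
}

# log density of observations y (T x K, NA allowed) along a fixed path
path_logdens <- function(y, path, params) {
  ll <- log(params$init[path[1]])
  Tn <- nrow(y)
  for (t in seq_len(Tn)) {
    if (t > 1) ll <- ll + log(params$transition[path[t - 1], path[t]])
    for (k in seq_len(ncol(y))) {
      if (!is.na(y[t, k]))
        ll <- ll + dnorm(y[t, k], params$emission_means[path[t], k],
                         params$emission_sds[path[t], k], log = TRUE)
    }
  }
  ll
}

enum_loglik <- function(y, params) {
  paths <- enum_paths(params$m, nrow(y))
  lls <- apply(paths, 1, function(p) path_logdens(y, p, params))
  mx <- max(lls)
  mx + log(sum(exp(lls - mx)))
}

# exact posterior over complete paths, named by collapsed path string
enum_path_posterior <- function(y, params) {
  paths <- enum_paths(params$m, nrow(y))
  lls <- apply(paths, 1, function(p) path_logdens(y, p, params))
  w <- exp(lls - max(lls))
  w <- w / sum(w)
  names(w) <- apply(paths, 1, paste, collapse = "")
  w
}

enum_map_path <- function(y, params) {
  paths <- enum_paths(params$m, nrow(y))
  lls <- apply(paths, 1, function(p) path_logdens(y, p, params))
  # ties toward the lower path in row-major enumeration order; the
  # enumeration varies the first occasion fastest, so resolve ties by
  # lexicographic path order explicitly
  best <- which(lls >= max(lls) - 1e-12)
  ord <- do.call(order, as.data.frame(paths[best, , drop = FALSE]))
  paths[best[ord[1]], ]
}

# deterministic toy parameters
toy_params <- function(m = 2, K = 1, seed = 1) {
  set.seed(seed)
  mu <- matrix(seq(0, 60, length.out = m * K), m, K)
  sig <- matrix(runif(m * K, 5, 12), m, K)
  G <- matrix(runif(m * m, 0.2, 1), m, m)
  G <- G / rowSums(G)
  subject_params(mu, sig, G)
}

toy_obs <- function(Tn, K = 1, seed = 2, miss = integer(0)) {
  set.seed(seed)
  y <- matrix(rnorm(Tn * K, 30, 25), Tn, K)
  if (length(miss) > 0) y[miss, ] <- NA
  y
}
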