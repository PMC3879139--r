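# Shared fixtures, all generated in code.

# Small K-pairwise model with broad couplings, reproducible.
toy_model <- function(N = 5, seed = 1, v_scale = 0.2, j_sd = 0.5) {
  set.seed(seed)
  h <- rnorm(N, -2, 1)
  J <- matrix(0, N, N)
  J[upper.tri(J)] <- rnorm(N * (N - 1) / 2, 0, j_sd)
  J <- J + t(J)
  V <- c(0, cumsum(rnorm(N, 0, v_scale)))
  maxent_model(h, J, V, "k_pairwise")
}

toy_pairwise <- function(N = 5, seed = 1, j_sd = 0.5) {
  m <- toy_model(N, seed, v_scale = 0, j_sd = j_sd)
  maxent_model(m$h, m$J, NULL, "pairwise")
}

independent_model <- function(p) maxent_model(qlogis(p),
                                              model_class = "independent")

# Exhaustive 2^N word matrix via base R (independent of all_words()).
brute_words <- function(N) as.matrix(expand.grid(rep(list(0:1), N)))

# Brute-force energies/distribution, independent of the C++ path.
brute_distribution <- function(model) {
  w <- brute_words(model$n_neurons)
  E <- apply(w, 1, function(s) {
    -sum(model$h * s) - 0.5 * sum(outer(s, s) * model$J) +
      model$V[sum(s) + 1]
  })
  P <- exp(-E)
  list(words = w, E = E, P = P / sum(P), log_z = log(sum(exp(-E))))
}

# Small raster drawn i.i.d. from independent neurons.
independent_raster <- function(N, T_, p, seed = 1, n_repeats = 1L,
                               bin_width = 0.02) {
  set.seed(seed)
  vals <- matrix(rbinom(N * T_, 1, rep(p, length.out = N)), nrow = N)
  spike_raster(vals, bin_width, n_repeats)
}

# exact stats object (no sampling noise) from a small model
exact_stats <- function(model, n_samples = 1e6) {
  en <- enumerate_exact(model)
  structure(list(p = en$p, m = en$m, pk = en$pk,
                 p_se = NULL, m_se = NULL, pk_se = NULL,
                 n_samples = n_samples, n_neurons = model$n_neurons),
            class = "empirical_stats")
}

binary_entropy_bits_oracle <- function(p) {
  vapply(p, function(x) {
    if (x <= 0 || x >= 1) return(0)
    -x * log2(x) - (1 - x) * log2(1 - x)
  }, numeric(1))
}

logsumexp_oracle <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

jsd_bits <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) sum(ifelse(a > 0, a * log2(a / b), 0))
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

model_probs <- function(model) {
  enumerate_exact(model, moments = FALSE, probabilities = TRUE)$prob
}
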