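#' All binary words of length N
#'
#' Rows ordered by the integer index `sum_i s_i 2^(i-1)` (neuron 1 is
#' the least significant bit), matching the state indexing of
#' [enumerate_exact].
#' @param N word length (N <= 25).
#' @return `2^N x N` integer matrix.
#' @export
all_words <- function(N) {
  if (N > 25) stop("too many words to enumerate")
  idx <- 0:(2^N - 1)
  m <- sapply(seq_len(N), function(i) bitwAnd(idx, bitwShiftL(1L, i - 1L)) > 0)
  storage.mode(m) <- "integer"
  matrix(m, ncol = N)
}

#' Exact enumeration of a model's distribution
#'
#' Sums over all `2^N` words with a Gray-code sweep (one spin flip per
#' step) to obtain the exact log partition function, mean and variance
#' of the energy, the synchrony distribution and (optionally) the
#' first and second moments and the full probability vector.
#'
#' @param model a [maxent_model].
#' @param moments also accumulate `p` and `m` (adds an O(K^2)
#'   per-state cost).
#' @param probabilities also return the full `2^N` probability vector
#'   (N <= 20, indexed as in [all_words]).
#' @param max_n hard cap on N (default 25); beyond it, use
#'   [metropolis_sample] instead.
#' @return list with `log_z`, `mean_E`, `var_E`, `pk`, `entropy_bits`,
#'   and optionally `p`, `m`, `prob`, `energies`.
#' @export
enumerate_exact <- function(model, moments = TRUE, probabilities = FALSE,
                            max_n = 25L) {
  N <- model$n_neurons
  if (N > max_n)
    stop(sprintf(paste0("N = %d exceeds the enumeration cap (%d); use ",
                        "metropolis_sample / wang_landau instead"), N, max_n))
  want_E <- probabilities
  if (want_E && N > 20) stop("probability vector limited to N <= 20")
  res <- enumerate_gray_cpp(model$h, model$J, model$V,
                            want_moments = moments,
                            want_energies = want_E)
  # S = <E> + log Z in nats (T = 1)
  res$entropy_bits <- nats_to_bits(res$mean_E + res$log_z)
  if (want_E) {
    res$prob <- exp(-(res$energies) - res$log_z)
  }
  res$n_neurons <- N
  res
}

random_word <- function(N, p = 0.5) as.integer(runif(N) < p)

resolve_init <- function(init, N) {
  if (is.character(init)) {
    switch(init,
           random = random_word(N),
           silence = integer(N),
           stop("unknown init spec"))
  } else {
    as.integer(init)
  }
}

#' Metropolis Monte Carlo sampling from a model
#'
#' Single-spin-flip Metropolis chain at temperature `T = 1/beta`
#' (default 1): a uniformly chosen spin is proposed for flipping and
#' accepted with probability `min(1, exp(-beta * dE))`. Burn-in and
#' thinning are counted in sweeps of N attempted flips. Deterministic
#' under a fixed seed.
#'
#' @param model a [maxent_model].
#' @param n_samples number of recorded samples.
#' @param burn_in burn-in sweeps (default `100 * N`).
#' @param thin sweeps between recorded samples (default 1).
#' @param seed RNG seed.
#' @param init `"random"`, `"silence"`, or an explicit word.
#' @param beta inverse temperature scaling of the whole energy.
#' @return list with `samples` (`n_samples x N` matrix), `energies`,
#'   and the call parameters. Class `mc_sample`.
#' @export
metropolis_sample <- function(model, n_samples, burn_in = NULL,
                              thin = 1L, seed = NULL, init = "random",
                              beta = 1) {
  N <- model$n_neurons
  if (is.null(burn_in)) burn_in <- 100L * N
  with_seed(seed, {
    s0 <- resolve_init(init, N)
    out <- metropolis_cpp(model$h, model$J, model$V, as.integer(n_samples),
                          as.integer(burn_in), as.integer(thin), beta, s0)
  })
  structure(list(samples = out$samples, energies = out$energies,
                 n_samples = n_samples, burn_in = burn_in, thin = thin,
                 beta = beta, n_neurons = N),
            class = "mc_sample")
}

#' Convert Monte Carlo samples to a spike raster
#' @param mc an `mc_sample` (or plain sample matrix).
#' @param bin_width nominal bin width in seconds.
#' @param n_repeats impose a repeat structure on the sample stream.
#' @export
mc_to_raster <- function(mc, bin_width = 0.02, n_repeats = 1L) {
  samples <- if (is.list(mc)) mc$samples else mc
  spike_raster(t(samples), bin_width, n_repeats)
}

#' Equilibration diagnostics for the Metropolis sampler
#'
#' Runs `n_chains` chains from different random initial words and
#' compares the sampled energy and magnetization (K) distributions
#' across chains with two-sample Kolmogorov-Smirnov tests at level
#' 0.05 (Bonferroni-corrected across comparisons), plus a drift check
#' (Spearman trend of energy against sample index within each chain).
#' Pass means no systematic dependence on the initial condition.
#'
#' @param model a [maxent_model].
#' @param n_chains number of chains (>= 2).
#' @param n_samples,burn_in,thin per-chain Metropolis budgets.
#' @param seed RNG seed.
#' @param level test level before correction (default 0.05).
#' @return list with `pass`, per-test p-values, and per-chain rates.
#' @export
equilibration_check <- function(model, n_chains = 4L, n_samples = 2000L,
                                burn_in = NULL, thin = 1L, seed = NULL,
                                level = 0.05) {
  stopifnot(n_chains >= 2)
  with_seed(seed, {
    chains <- lapply(seq_len(n_chains), function(ch)
      metropolis_sample(model, n_samples, burn_in, thin, seed = NULL,
                        init = "random"))
  })
  e_list <- lapply(chains, `[[`, "energies")
  k_list <- lapply(chains, function(ch) rowSums(ch$samples))
  # KS assumes independent continuous samples: thin by the integrated
  # autocorrelation time and break ties (the sampled energies are
  # atoms whose float representation drifts between chains) with a
  # small common jitter
  tau <- max(1, ceiling(max(vapply(e_list, acf_tau, numeric(1)))))
  prep <- function(x, scale) {
    x <- x[seq(1, length(x), by = tau)]
    x + runif(length(x), -scale, scale)
  }
  e_scale <- 0.05 * max(1e-8, stats::median(abs(diff(sort(
    unique(round(unlist(e_list), 6)))))))
  pairs <- combn(n_chains, 2)
  ks_p <- apply(pairs, 2, function(pr) {
    c(energy = suppressWarnings(
        ks.test(prep(e_list[[pr[1]]], e_scale),
                prep(e_list[[pr[2]]], e_scale))$p.value),
      magnetization = suppressWarnings(
        ks.test(prep(k_list[[pr[1]]], 0.4),
                prep(k_list[[pr[2]]], 0.4))$p.value))
  })
  n_tests <- length(ks_p)
  ks_pass <- all(ks_p > level / n_tests)
  # drift: first-half vs second-half mean energy, with the standard
  # error inflated by the chain's integrated autocorrelation time
  drift_p <- vapply(e_list, function(e) {
    half <- seq_len(length(e) %/% 2)
    tau <- max(1, acf_tau(e))
    se <- sd(e) * sqrt(2 * tau * 2 / length(e))
    z <- (mean(e[half]) - mean(e[-half])) / se
    2 * pnorm(-abs(z))
  }, numeric(1))
  drift_pass <- all(drift_p > level / n_chains)
  rates <- t(vapply(chains, function(ch) colMeans(ch$samples),
                    numeric(model$n_neurons)))
  list(pass = ks_pass && drift_pass, ks_pass = ks_pass,
       drift_pass = drift_pass, ks_p = ks_p, drift_p = drift_p,
       chain_rates = rates)
}

# Bracket the reachable energy range of a model: exact at small N,
# otherwise greedy descent/ascent extremes plus sampled bulk, padded.
energy_range <- function(model, seed = NULL, pad_frac = 0.05) {
  N <- model$n_neurons
  if (N <= 20) {
    en <- enumerate_gray_cpp(model$h, model$J, model$V, FALSE, TRUE)$energies
    r <- range(en)
  } else {
    with_seed(seed, {
      mc <- metropolis_sample(model, 2000, burn_in = 100 * N)
      # uniform random words dominate the multiplicity bulk
      unif <- matrix(as.integer(runif(2000 * N) < 0.5), ncol = N)
      e_unif <- energy_words_cpp(unif, model$h, model$J, model$V)
      # descend for the minimum; ascend (descend on -E) for the maximum
      starts <- rbind(mc$samples[sample.int(nrow(mc$samples), 50), ],
                      unif[sample.int(nrow(unif), 50), ],
                      matrix(0L, 1, N), matrix(1L, 1, N))
      lo <- min(descend_cpp(model$h, model$J, model$V, starts)$energies)
      hi <- max(-descend_cpp(-model$h, -model$J, -model$V,
                             starts)$energies)
      r <- range(c(lo, hi, mc$energies, e_unif, 0))
    })
  }
  pad <- pad_frac * diff(r)
  c(r[1] - pad, r[2] + pad)
}

#' Wang-Landau estimate of the density of states
#'
#' Adaptive flat-histogram Monte Carlo estimate of the multiplicity
#' `g(E)` on a fixed energy grid. The modification factor `ln f`
#' starts at 1 and is halved every time the visit histogram over the
#' reachable bins is flat (minimum >= `flatness` times the mean),
#' terminating at `ln_f_final`. `log g` is normalized so that the
#' total multiplicity over visited bins equals `2^N`. The energy range
#' is bracketed exactly at small N and by padded greedy/sampled
#' extremes otherwise; bins never visited are reported and excluded.
#'
#' @param model a [maxent_model].
#' @param energy_bins number of uniform bins (default 200).
#' @param flatness flatness fraction (default 0.80).
#' @param ln_f_final terminal modification factor (default 1e-8).
#' @param seed RNG seed.
#' @param e_range optional explicit `c(min, max)` energy bracket.
#' @param sweeps_per_check sweeps between flatness checks.
#' @param max_checks cap on flatness checks (guards runtime).
#' @param n_runs independent walkers whose normalized `log g` is
#'   averaged (reduces the run-to-run statistical error of the
#'   converged estimate, which does not vanish with `ln_f_final`).
#' @return object of class `density_of_states`: bin `edges`, centers
#'   (visit-weighted in-bin mean energies), normalized `log_g`,
#'   `visited` mask, `n_neurons`, convergence info.
#' @export
wang_landau <- function(model, energy_bins = 200L, flatness = 0.8,
                        ln_f_final = 1e-8, seed = NULL, e_range = NULL,
                        sweeps_per_check = 4000L, max_checks = 100000L,
                        n_runs = 3L) {
  N <- model$n_neurons
  if (is.null(e_range)) e_range <- energy_range(model, seed = seed)
  edges <- seq(e_range[1], e_range[2], length.out = energy_bins + 1)
  with_seed(seed, {
    runs <- lapply(seq_len(n_runs), function(r) {
      init <- resolve_init("random", N)
      wang_landau_cpp(model$h, model$J, model$V, edges, flatness,
                      ln_f_final, as.integer(sweeps_per_check),
                      as.integer(max_checks), init)
    })
  })
  vis <- Reduce(`&`, lapply(runs, `[[`, "visited"))
  norm_lg <- function(res) {
    lg <- res$log_g[vis]
    lg - logsumexp(lg) + N * log(2)       # sum g = 2^N
  }
  lg_mat <- vapply(runs, norm_lg, numeric(sum(vis)))
  log_g <- rep(-Inf, energy_bins)
  log_g[vis] <- rowMeans(matrix(lg_mat, ncol = n_runs))
  # renormalize after averaging
  log_g[vis] <- log_g[vis] - logsumexp(log_g[vis]) + N * log(2)
  # representative energy per bin: the visit-weighted mean (close to
  # the multiplicity-weighted in-bin energy), falling back to centers
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  emv_mat <- vapply(runs, function(r) r$e_visit_mean, numeric(energy_bins))
  emv <- rowMeans(matrix(emv_mat, ncol = n_runs), na.rm = TRUE)
  centers[!is.na(emv)] <- emv[!is.na(emv)]
  structure(list(edges = edges,
                 centers = centers,
                 log_g = log_g, visited = vis, n_neurons = N,
                 converged = all(vapply(runs, `[[`, TRUE, "converged")),
                 ln_f = max(vapply(runs, `[[`, 1, "ln_f")),
                 n_refinements = min(vapply(runs, `[[`, 0L,
                                            "n_refinements")),
                 n_runs = n_runs),
            class = "density_of_states")
}

#' @export
print.density_of_states <- function(x, ...) {
  cat(sprintf(paste0("<density_of_states> N=%d, %d bins (%d visited), ",
                     "ln f=%.2g, converged=%s\n"),
              x$n_neurons, length(x$log_g), sum(x$visited), x$ln_f,
              x$converged))
  invisible(x)
}

#' Write a density of states as two-column text (E, log g)
#' @param dos a [wang_landau] result.
#' @param path output path.
#' @export
write_dos <- function(dos, path) {
  data.table::fwrite(data.frame(E = dos$centers[dos$visited],
                                log_g = dos$log_g[dos$visited]),
                     path, sep = "\t")
  invisible(path)
}
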