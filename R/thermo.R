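entropy_estimate <- function(value_nats, method, se_nats = NA_real_,
                             diagnostics = list()) {
  structure(list(value = nats_to_bits(value_nats),
                 value_nats = value_nats,
                 se = nats_to_bits(se_nats), method = method,
                 diagnostics = diagnostics),
            class = "entropy_estimate")
}

#' @export
print.entropy_estimate <- function(x, ...) {
  cat(sprintf("<entropy_estimate:%s> %.4f bits%s\n", x$method, x$value,
              if (is.finite(x$se)) sprintf(" (se %.4f)", x$se) else ""))
  invisible(x)
}

#' Heat capacity along the temperature family
#'
#' Extends the model to `P_T(s) propto exp(-E(s)/T)` (same parameters,
#' scaled energy; `T` is a mathematical device, not a physical
#' temperature) and estimates the heat capacity
#' `C(T) = Var_T(E) / T^2` by Metropolis sampling at each requested
#' temperature. Chains are initialized at the all-silent word for
#' `T <= 1` (the low-temperature mode) and at a random word above. A
#' per-temperature drift flag compares the first and second half mean
#' energy.
#'
#' @param model a [maxent_model].
#' @param T_grid positive temperatures.
#' @param n_samples,burn_in,thin per-temperature Metropolis budgets.
#' @param seed RNG seed.
#' @return data.frame with columns `T`, `C`, `C_se`, `mean_E`,
#'   `var_E`, `drift_flag`.
#' @export
heat_capacity_curve <- function(model, T_grid, n_samples = 20000L,
                                burn_in = NULL, thin = 1L, seed = NULL) {
  if (any(T_grid <= 0)) stop("temperatures must be positive")
  N <- model$n_neurons
  if (is.null(burn_in)) burn_in <- 100L * N
  with_seed(seed, {
    rows <- lapply(T_grid, function(Tt) {
      init <- if (Tt <= 1) "silence" else "random"
      sm <- metropolis_sample(model, n_samples, burn_in = burn_in,
                              thin = thin, init = init, beta = 1 / Tt)
      e <- sm$energies
      v <- var(e)
      # blocked s.e. of the variance (10 blocks)
      nb <- 10L
      bl <- split(e, cut(seq_along(e), nb, labels = FALSE))
      v_bl <- vapply(bl, var, numeric(1))
      v_se <- sd(v_bl) / sqrt(nb)
      half <- seq_len(length(e) %/% 2)
      drift <- abs(mean(e[half]) - mean(e[-half])) >
        3 * sqrt(v * 2 / length(e)) * sqrt(max(1, acf_tau(e)))
      data.frame(T = Tt, C = v / Tt^2, C_se = v_se / Tt^2,
                 mean_E = mean(e), var_E = v, drift_flag = drift)
    })
  })
  do.call(rbind, rows)
}

# crude integrated autocorrelation time of a series (capped)
acf_tau <- function(x, max_lag = 50L) {
  a <- acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  a <- a[cumsum(a < 0.05) == 0]      # stop at first small lag
  1 + 2 * sum(a)
}

#' Entropy by heat-capacity temperature integration
#'
#' `S(1) = int_0^1 C(T)/T dT`, or equivalently
#' `S(1) = N log 2 - int_1^Inf C(T)/T dT` using `S(Inf) = N` bits.
#' The integrand is evaluated on a geometric temperature grid (the
#' integral is done by the trapezoid rule in log T, where it is
#' smooth) and the truncated tails are bounded and reported: below
#' `T_min` the system is frozen into its ground state and the
#' remainder is at most about `C(T_min)`; above `T_max` the
#' `C ~ Var_unif(E)/T^2` decay gives a tail of
#' `Var_unif(E) / (2 T_max^2)`, which is added to the estimate.
#'
#' @param model a [maxent_model].
#' @param direction `"0to1"` (default) or `"1toInf"`.
#' @param grid explicit temperature grid, or `NULL` for the default
#'   geometric grid (`points_per_decade` points per decade of T,
#'   `[0.02, 1]` or `[1, 30]`).
#' @param points_per_decade grid density (default 100).
#' @param n_samples,burn_in,thin per-temperature Metropolis budgets.
#' @param seed RNG seed.
#' @return an `entropy_estimate` (bits) with grid and tail diagnostics.
#' @export
entropy_via_heat_capacity <- function(model,
                                      direction = c("0to1", "1toInf"),
                                      grid = NULL,
                                      points_per_decade = 100L,
                                      n_samples = 20000L,
                                      burn_in = NULL, thin = 1L,
                                      seed = NULL) {
  direction <- match.arg(direction)
  N <- model$n_neurons
  if (is.null(grid)) {
    rng <- if (direction == "0to1") c(0.02, 1) else c(1, 30)
    n_pts <- max(10L, ceiling(points_per_decade * log10(rng[2] / rng[1])))
    grid <- exp(seq(log(rng[1]), log(rng[2]), length.out = n_pts))
  }
  grid <- sort(grid)
  if (direction == "0to1" && abs(grid[length(grid)] - 1) > 1e-9)
    stop("grid must reach T = 1")
  if (direction == "1toInf" && abs(grid[1] - 1) > 1e-9)
    stop("grid must start at T = 1")
  cc <- heat_capacity_curve(model, grid, n_samples = n_samples,
                            burn_in = burn_in, thin = thin, seed = seed)
  x <- log(cc$T)
  y <- cc$C                       # int C/T dT = int C d(log T)
  wts <- c(diff(x) / 2, 0) + c(0, diff(x) / 2)
  integral <- sum(wts * y)
  se <- sqrt(sum((wts * cc$C_se)^2))
  if (direction == "0to1") {
    tail_bound <- cc$C[1]         # frozen low-T remainder, reported
    s_nats <- integral
  } else {
    with_seed(seed, {
      unif <- matrix(as.integer(runif(2000 * N) < 0.5), ncol = N)
    })
    var_unif <- var(energy_words_cpp(unif, model$h, model$J, model$V))
    t_max <- max(grid)
    tail_bound <- var_unif / (2 * t_max^2)
    s_nats <- N * log(2) - integral - tail_bound
  }
  entropy_estimate(s_nats, "heat_capacity", se,
                   diagnostics = list(direction = direction,
                                      T_grid = grid, curve = cc,
                                      tail_bound_nats = tail_bound,
                                      n_samples = n_samples))
}

#' Partition function and entropy from the probability of silence
#'
#' In the canonical gauge the all-silent word has zero energy, so
#' `P(silence) = 1/Z` and `log Z = -log P(silence)`. The entropy then
#' follows from `S = <E> + log Z` (nats), with `<E>` estimated from a
#' single Metropolis run at `T = 1`. For K-pairwise models
#' `P(silence)` is matched to the data by construction, so it may be
#' supplied from data; otherwise it is estimated from the same model
#' by MC (the source is recorded in the diagnostics).
#'
#' @param model a [maxent_model] in canonical gauge.
#' @param p_silence optional externally supplied probability of the
#'   all-silent word; `NULL` estimates it by model MC.
#' @param n_samples,burn_in,thin Metropolis budgets.
#' @param seed RNG seed.
#' @return list with `log_z` and `entropy` (an `entropy_estimate`).
#' @export
partition_and_entropy_from_silence <- function(model, p_silence = NULL,
                                               n_samples = 200000L,
                                               burn_in = NULL, thin = 1L,
                                               seed = NULL) {
  if (abs(model$V[1]) > 1e-12 || !identical(model$gauge, "canonical"))
    stop("silence route requires the canonical gauge; run gauge_fix()")
  source <- if (is.null(p_silence)) "model_mc" else "supplied"
  sm <- metropolis_sample(model, as.integer(n_samples),
                          burn_in = burn_in, thin = thin, seed = seed)
  if (is.null(p_silence)) {
    K <- rowSums(sm$samples)
    p_silence <- mean(K == 0)
    if (p_silence <= 0)
      stop("silent word never sampled; supply p_silence explicitly")
  }
  if (p_silence <= 0 || p_silence >= 1)
    stop("p_silence must lie in (0, 1)")
  log_z <- -log(p_silence)
  e_mean <- mean(sm$energies)
  tau <- acf_tau(sm$energies)
  e_se <- sd(sm$energies) * sqrt(tau / length(sm$energies))
  p_se <- sqrt(p_silence * (1 - p_silence) * tau / n_samples)
  s_nats <- e_mean + log_z
  se_nats <- sqrt(e_se^2 + (p_se / p_silence)^2)
  list(log_z = log_z,
       entropy = entropy_estimate(s_nats, "silence", se_nats,
                                  diagnostics = list(
                                    p_silence = p_silence,
                                    p_silence_source = source,
                                    mean_E = e_mean,
                                    n_samples = n_samples)))
}

#' Entropy and partition function from a density of states
#'
#' With the multiplicity `g(E)` normalized to `sum g = 2^N`,
#' `Z = sum_E g(E) exp(-E)`, `<E> = sum_E E g(E) exp(-E) / Z`, and
#' `S = <E> + log Z` (nats, converted to bits).
#' @param dos a [wang_landau] result (normalized).
#' @return list with `log_z` and `entropy` (an `entropy_estimate`).
#' @export
entropy_from_density_of_states <- function(dos) {
  v <- dos$visited
  lg <- dos$log_g[v]
  tot <- logsumexp(lg)
  if (abs(tot - dos$n_neurons * log(2)) > 1e-6)
    stop("density of states is not normalized to 2^N")
  E <- dos$centers[v]
  lw <- lg - E
  log_z <- logsumexp(lw)
  p <- exp(lw - log_z)
  e_mean <- sum(p * E)
  s_nats <- e_mean + log_z
  list(log_z = log_z,
       entropy = entropy_estimate(s_nats, "wang_landau",
                                  diagnostics = list(
                                    n_bins = length(dos$log_g),
                                    n_visited = sum(v),
                                    converged = dos$converged)))
}

#' Multi-information captured by a model
#'
#' `I_N = sum_i H(p_i) - S_model` in bits: the reduction of entropy
#' relative to independent neurons with the same rates; non-negative
#' up to estimator error.
#' @param S_model an `entropy_estimate` (or value in bits).
#' @param stats an [moment_stats()] result supplying the rates.
#' @export
multi_information <- function(S_model, stats) {
  s_bits <- if (inherits(S_model, "entropy_estimate")) S_model$value
            else as.numeric(S_model)
  sum(binary_entropy_bits(stats$p)) - s_bits
}

#' Compare energy distributions of data and model
#'
#' Energies of the recorded words versus energies of model-sampled
#' words: cumulative counts `N_<(E)` (strictly below) and `N_>(E)`
#' (at or above; ties counted once, in `N_>`), and the relative
#' differences of the mean and standard deviation of the energy.
#'
#' @param model a [maxent_model].
#' @param raster evaluation [spike_raster] on the same neurons.
#' @param n_samples model MC sample count (default: data size).
#' @param seed RNG seed.
#' @return list with the two energy vectors, cumulative-count
#'   functions, and relative moment differences.
#' @export
energy_distribution_report <- function(model, raster, n_samples = NULL,
                                       seed = NULL) {
  if (is.null(n_samples)) n_samples <- n_bins(raster)
  e_data <- energy_words_cpp(t(raster$values), model$h, model$J, model$V)
  sm <- metropolis_sample(model, as.integer(n_samples), seed = seed)
  e_model <- sm$energies
  cum <- function(e) {
    f <- ecdf(e)
    list(n_below = function(E) round(f(E - 1e-12) * length(e)),
         n_above = function(E) length(e) - round(f(E - 1e-12) * length(e)))
  }
  list(e_data = e_data, e_model = e_model,
       data_cumulative = cum(e_data), model_cumulative = cum(e_model),
       rel_diff_mean = (mean(e_model) - mean(e_data)) /
         abs(mean(e_data)),
       rel_diff_sd = (sd(e_model) - sd(e_data)) / sd(e_data),
       tie_convention = "ties counted once, in N_>(E)")
}
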