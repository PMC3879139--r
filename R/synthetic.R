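#' Specification of a synthetic ground-truth world
#'
#' Captures the statistical structure the generator emulates: dense
#' retinal recordings with N neurons at a mean spike probability of
#' about 3.1% per 20 ms bin, weak widespread couplings of both signs,
#' and a repeat design of R = 297 repeats x B = 953 bins. Optional
#' repeat-locked temporal modulation adds per-bin field offsets shared
#' across repeats (sparse smooth bumps emulating the brief transients
#' of naturalistic responses).
#'
#' @param n_neurons population size N.
#' @param p_mean target mean spike probability per bin (default 0.031).
#' @param h_sd spread of fields around the logit of `p_mean`
#'   (default 0.7, giving a realistic firing-rate spread of roughly
#'   1-10% per bin).
#' @param coupling list: `mean`, `sd` (default 0.55, calibrated by
#'   pilot sampling so the median |c_ij| at N = 100 lands near the
#'   recording-like 0.01), `density` (fraction of nonzero couplings,
#'   default 1).
#' @param v_shape optional function `K -> V(K)` for a ground-truth
#'   synchrony potential (`NULL` for none).
#' @param n_repeats,bins_per_repeat repeat structure (297 x 953).
#' @param bin_width bin width in seconds (0.020).
#' @param modulation `NULL`, or a list with `n_bumps`, `width_bins`,
#'   `amplitude` describing the shared temporal drive.
#' @return object of class `generator_spec`.
#' @export
generator_spec <- function(n_neurons, p_mean = 0.031, h_sd = 0.7,
                           coupling = list(), v_shape = NULL,
                           n_repeats = 297L, bins_per_repeat = 953L,
                           bin_width = 0.020, modulation = NULL) {
  coupling <- utils::modifyList(list(mean = 0, sd = 0.55, density = 1),
                                coupling)
  if (!is.null(modulation))
    modulation <- utils::modifyList(
      list(n_bumps = 24L, width_bins = 2.5, amplitude = 3), modulation)
  structure(list(n_neurons = as.integer(n_neurons), p_mean = p_mean,
                 h_sd = h_sd, coupling = coupling, v_shape = v_shape,
                 n_repeats = as.integer(n_repeats),
                 bins_per_repeat = as.integer(bins_per_repeat),
                 bin_width = bin_width, modulation = modulation),
            class = "generator_spec")
}

#' Draw a ground-truth maximum entropy model
#'
#' Fields are drawn around the logit of the target rate and corrected
#' at mean-field level for the couplings (`h_i -= sum_j J_ij p_j`), so
#' the realized rates land near the target; couplings are i.i.d.
#' normal with the requested mean/sd and density, symmetrized, both
#' signs present. With symmetric sign draws about half of all
#' interacting triplets are frustrated. Deterministic under a seed.
#'
#' @param spec a [generator_spec].
#' @param seed RNG seed.
#' @return a [maxent_model].
#' @export
make_ground_truth_model <- function(spec, seed = NULL) {
  N <- spec$n_neurons
  with_seed(seed, {
    # lognormal correction: at low rates plogis(logit(p) + x) ~ p e^x,
    # so recenter by -h_sd^2/2 to keep the population mean on target
    p_i <- plogis(qlogis(spec$p_mean) - spec$h_sd^2 / 2 +
                    rnorm(N, 0, spec$h_sd))
    J <- matrix(0, N, N)
    ut <- upper.tri(J)
    vals <- rnorm(sum(ut), spec$coupling$mean, spec$coupling$sd)
    if (spec$coupling$density < 1)
      vals <- vals * rbinom(length(vals), 1, spec$coupling$density)
    J[ut] <- vals
    J <- J + t(J)
  })
  # mean-field compensation (with the second-order cumulant of the
  # coupling field), so realized rates stay near the targets
  h <- qlogis(p_i) - as.numeric(J %*% p_i) -
    0.5 * as.numeric(J^2 %*% (p_i * (1 - p_i)))
  V <- numeric(N + 1)
  cls <- "pairwise"
  if (!is.null(spec$v_shape)) {
    V <- spec$v_shape(0:N)
    V <- V - V[1]
    cls <- "k_pairwise"
  }
  if (all(J == 0) && all(V == 0)) cls <- "independent"
  mdl <- maxent_model(h, J, V, cls)
  mdl
}

make_modulation <- function(spec, seed = NULL) {
  B <- spec$bins_per_repeat
  m <- spec$modulation
  with_seed(seed, {
    centers <- sort(runif(m$n_bumps, 1, B))
    amps <- m$amplitude * (0.4 + 0.6 * runif(m$n_bumps))
  })
  a <- numeric(B)
  for (q in seq_along(centers))
    a <- a + amps[q] * exp(-0.5 * ((seq_len(B) - centers[q]) /
                                     m$width_bins)^2)
  a
}

#' Generate a synthetic spike raster from a model
#'
#' Static case: Metropolis-samples `R * B` words (one sweep of
#' thinning between bins). Modulated case: a continuous
#' non-stationary chain sweeps through the bins of each repeat with
#' the shared per-bin field offsets added, producing repeat-locked
#' PSTH transients and positively skewed correlations, as in
#' stimulus-driven recordings.
#'
#' @param model a [maxent_model] (typically from
#'   [make_ground_truth_model]).
#' @param spec the matching [generator_spec].
#' @param seed RNG seed.
#' @param sweeps_per_bin chain sweeps per recorded bin (modulated
#'   case).
#' @param thin sweeps between recorded words in the static case
#'   (default 3, enough to make successive words nearly independent
#'   at retinal spike probabilities).
#' @return a [spike_raster] of dimensions `N x (R * B)`.
#' @export
generate_raster <- function(model, spec, seed = NULL,
                            sweeps_per_bin = 3L, thin = 3L) {
  N <- model$n_neurons
  R <- spec$n_repeats
  B <- spec$bins_per_repeat
  if (is.null(spec$modulation)) {
    sm <- metropolis_sample(model, R * B, burn_in = 100L * N,
                            thin = thin, seed = seed)
    mat <- t(sm$samples)
  } else {
    a <- make_modulation(spec, seed = seed)
    with_seed(seed, {
      init <- resolve_init("random", N)
      mat <- t(generate_modulated_cpp(model$h, model$J, model$V,
                                      rep(1, N), a, R,
                                      as.integer(sweeps_per_bin), init))
    })
  }
  spike_raster(mat, spec$bin_width, R)
}

# P(X > g1, Y > g2) for standard bivariate normal with correlation rho
bvn_orthant <- function(g1, g2, rho) {
  if (abs(rho) < 1e-12) return(pnorm(g1, lower.tail = FALSE) *
                                 pnorm(g2, lower.tail = FALSE))
  f <- function(x) dnorm(x) *
    pnorm((g2 - rho * x) / sqrt(1 - rho^2), lower.tail = FALSE)
  integrate(f, g1, Inf, rel.tol = 1e-10)$value
}

#' Dichotomized Gaussian surrogate raster
#'
#' Thresholds a latent multivariate normal to produce binary patterns
#' with prescribed rates and pairwise second moments: thresholds
#' solve `Phi(-gamma_i) = p_i`, and each latent correlation is found
#' by root-finding on the bivariate normal orthant probability so that
#' `P(X_i > gamma_i, X_j > gamma_j) = m_ij`. Pairs with no feasible
#' latent correlation are flagged and left at 0; a non-positive-
#' definite latent matrix is repaired by eigenvalue clipping (nearest-
#' PD projection, reported).
#'
#' @param stats an [moment_stats()] result, or a list with `p` and
#'   `m`.
#' @param n_samples number of binary samples T to draw.
#' @param seed RNG seed.
#' @param bin_width nominal bin width of the output raster.
#' @return list with `raster` (a [spike_raster]), `thresholds`,
#'   `latent_correlation` matrix, `infeasible_pairs`, `pd_repaired`.
#' @export
dichotomized_gaussian <- function(stats, n_samples, seed = NULL,
                                  bin_width = 0.02) {
  p <- stats$p
  if (any(p <= 0 | p >= 1)) stop("rates must lie strictly in (0, 1)")
  m <- stats$m
  N <- length(p)
  gam <- qnorm(1 - p)        # latent > gamma  <=>  spike
  L <- diag(N)
  infeasible <- matrix(FALSE, N, N)
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      target <- m[i, j]
      lo_b <- max(0, p[i] + p[j] - 1)
      hi_b <- min(p[i], p[j])
      if (target <= lo_b || target >= hi_b) {
        if (abs(target - p[i] * p[j]) > 1e-12)
          infeasible[i, j] <- infeasible[j, i] <- TRUE
        next
      }
      g <- function(r) bvn_orthant(gam[i], gam[j], r) - target
      r <- tryCatch(uniroot(g, c(-0.999, 0.999), tol = 1e-9)$root,
                    error = function(e) NA_real_)
      if (is.na(r)) {
        infeasible[i, j] <- infeasible[j, i] <- TRUE
      } else {
        L[i, j] <- L[j, i] <- r
      }
    }
  }
  ev <- eigen(L, symmetric = TRUE)
  repaired <- FALSE
  if (min(ev$values) < 1e-8) {
    repaired <- TRUE
    vals <- pmax(ev$values, 1e-8)
    L2 <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    d <- sqrt(diag(L2))
    L <- L2 / outer(d, d)
  }
  ch <- chol(L)
  with_seed(seed, {
    Z <- matrix(rnorm(n_samples * N), n_samples, N) %*% ch
  })
  X <- t(1L * (Z > matrix(gam, n_samples, N, byrow = TRUE)))
  list(raster = spike_raster(X, bin_width, 1L),
       thresholds = gam, latent_correlation = L,
       infeasible_pairs = which(infeasible & upper.tri(infeasible),
                                arr.ind = TRUE),
       pd_repaired = repaired)
}
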