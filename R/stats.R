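#' Empirical constraint statistics with bootstrap errors
#'
#' Computes the plug-in estimates that the maximum entropy models
#' constrain: per-neuron spike probabilities `p_i = <s_i>`, second
#' moments `m_ij = <s_i s_j>`, Pearson correlation coefficients
#' `c_ij = (m_ij - p_i p_j) / sqrt(p_i(1-p_i) p_j(1-p_j))`, and the
#' synchrony distribution `P(K)`. Bootstrap standard errors resample
#' whole stimulus repeats with replacement, because bins within a
#' repeat are temporally dependent while repeats are plausibly
#' independent.
#'
#' Neurons with `p_i` of exactly 0 or 1 have undefined correlation
#' coefficients; their pairs are set to `NA` and the neurons listed in
#' the `flagged` field rather than silently zeroed.
#'
#' @param raster a [spike_raster] with at least 2 time bins.
#' @param n_bootstrap number of repeat resamples (0 disables errors).
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `empirical_stats`: list with fields
#'   `p`, `m`, `c`, `pk`, the bootstrap standard errors `p_se`, `m_se`,
#'   `c_se`, `pk_se`, sample counts and repeat structure.
#' @export
moment_stats <- function(raster, n_bootstrap = 0L, seed = NULL) {
  X <- raster$values
  T_ <- ncol(X)
  if (T_ < 2) stop("need at least two time bins")
  N <- nrow(X)
  est <- function(M) {
    p <- rowMeans(M)
    m <- tcrossprod(M) / ncol(M)
    v <- p * (1 - p)
    denom <- sqrt(outer(v, v))
    cc <- (m - outer(p, p)) / denom
    cc[denom == 0] <- NA_real_
    diag(cc) <- 1
    K <- colSums(M)
    pk <- tabulate(K + 1L, nbins = N + 1L) / ncol(M)
    list(p = p, m = m, c = cc, pk = pk)
  }
  e <- est(X)
  flagged <- which(e$p %in% c(0, 1))
  out <- list(p = e$p, m = e$m, c = e$c, pk = e$pk,
              p_se = NULL, m_se = NULL, c_se = NULL, pk_se = NULL,
              n_samples = T_, n_neurons = N,
              n_repeats = raster$n_repeats,
              bins_per_repeat = raster$bins_per_repeat,
              n_bootstrap = n_bootstrap,
              flagged = flagged, neuron_ids = raster$neuron_ids)
  if (n_bootstrap > 0) {
    R <- raster$n_repeats
    B <- raster$bins_per_repeat
    with_seed(seed, {
      bp <- array(NA_real_, c(N, n_bootstrap))
      bm <- array(NA_real_, c(N, N, n_bootstrap))
      bc <- array(NA_real_, c(N, N, n_bootstrap))
      bpk <- array(NA_real_, c(N + 1L, n_bootstrap))
      for (b in seq_len(n_bootstrap)) {
        rs <- sample.int(R, R, replace = TRUE)
        cols <- as.vector(outer(seq_len(B), (rs - 1L) * B, `+`))
        eb <- est(X[, cols, drop = FALSE])
        bp[, b] <- eb$p
        bm[, , b] <- eb$m
        bc[, , b] <- eb$c
        bpk[, b] <- eb$pk
      }
      out$p_se <- apply(bp, 1, sd)
      out$m_se <- apply(bm, c(1, 2), sd)
      out$c_se <- apply(bc, c(1, 2), sd)
      out$pk_se <- apply(bpk, 1, sd)
    })
  }
  class(out) <- "empirical_stats"
  out
}

#' @export
print.empirical_stats <- function(x, ...) {
  cc <- x$c[upper.tri(x$c)]
  cat(sprintf(paste0("<empirical_stats> N=%d, T=%d; mean rate %.4f; ",
                     "median c %.2g (sd %.2g)\n"),
              x$n_neurons, x$n_samples, mean(x$p),
              stats::median(cc, na.rm = TRUE), sd(cc, na.rm = TRUE)))
  invisible(x)
}

#' Connected three-point correlations
#'
#' `C_ijk = <(s_i - p_i)(s_j - p_j)(s_k - p_k)>` for each requested
#' triplet of distinct neurons.
#'
#' @param raster a [spike_raster].
#' @param triplets integer matrix with 3 columns (one triplet per row).
#' @return numeric vector of connected correlations, one per triplet.
#' @export
triplet_correlations <- function(raster, triplets) {
  triplets <- matrix(as.integer(triplets), ncol = 3)
  if (any(triplets < 1 | triplets > raster$n_neurons))
    stop("triplet index out of range")
  if (any(apply(triplets, 1, anyDuplicated) > 0))
    stop("triplets must consist of distinct neurons")
  X <- raster$values
  Xc <- X - rowMeans(X)
  vapply(seq_len(nrow(triplets)), function(r) {
    ijk <- triplets[r, ]
    mean(Xc[ijk[1], ] * Xc[ijk[2], ] * Xc[ijk[3], ])
  }, numeric(1))
}

#' Empirical synchrony distribution P(K)
#'
#' Frequency of `K = sum_i s_i` spikes per time bin, over the support
#' `K = 0..N`.
#' @param raster a [spike_raster].
#' @return numeric vector of length `N + 1`, names `"0".."N"`.
#' @export
synchrony_distribution <- function(raster) {
  N <- raster$n_neurons
  K <- colSums(raster$values)
  pk <- tabulate(K + 1L, nbins = N + 1L) / n_bins(raster)
  names(pk) <- 0:N
  pk
}

#' Empirical coincidence probability
#'
#' Probability that two time bins drawn at random without replacement
#' carry exactly the same N-bit word, computed exactly from pattern
#' counts: `sum_w n_w (n_w - 1) / (T (T - 1))`. The with-replacement
#' version differs by O(1/T) and is not used.
#'
#' @param raster a [spike_raster].
#' @return scalar probability.
#' @export
coincidence_probability_empirical <- function(raster) {
  T_ <- n_bins(raster)
  if (T_ < 2) stop("need at least two time bins")
  nw <- table(word_keys(t(raster$values)))
  sum(as.numeric(nw) * (as.numeric(nw) - 1)) / (T_ * (T_ - 1))
}

#' Effective number of independent samples
#'
#' Bins within a repeat are temporally correlated, so the raster's
#' `T` bins carry fewer than `T` independent samples. The estimate
#' resamples subsets of `r` repeats, measures the scaling of the error
#' of the mean firing rate (which should fall as `1/sqrt(r)`), and
#' compares the fitted amplitude against the same construction on a
#' fully time-shuffled raster (which is independent by construction):
#' `T_eff = T * (shuffled amplitude / observed amplitude)^2`.
#'
#' @param raster a [spike_raster] with at least 4 repeats.
#' @param n_subsets resampled subsets per subset size.
#' @param seed RNG seed.
#' @return `T_eff` (scalar); attributes carry the fitted amplitudes.
#' @export
effective_sample_size <- function(raster, n_subsets = 20L, seed = NULL) {
  R <- raster$n_repeats
  if (R < 4) stop("need at least 4 repeats to fit the error scaling")
  sizes <- unique(pmax(2L, round(R * c(0.125, 0.25, 0.5, 0.75))))
  if (length(sizes) < 2) stop("too few distinct subset sizes")
  B <- raster$bins_per_repeat
  err_amplitude <- function(X) {
    errs <- vapply(sizes, function(r) {
      devs <- vapply(seq_len(n_subsets), function(s) {
        rs <- sample.int(R, r)
        cols <- as.vector(outer(seq_len(B), (rs - 1L) * B, `+`))
        sqrt(mean((rowMeans(X[, cols, drop = FALSE]) - rowMeans(X))^2))
      }, numeric(1))
      sqrt(mean(devs^2))
    }, numeric(1))
    # fit err = A / sqrt(r) by least squares in logs
    exp(mean(log(errs) + 0.5 * log(sizes)))
  }
  with_seed(seed, {
    a_obs <- err_amplitude(raster$values)
    shuf <- shuffle_raster(raster)
    a_shuf <- err_amplitude(shuf$values)
  })
  t_eff <- n_bins(raster) * (a_shuf / a_obs)^2
  structure(t_eff, amplitude_observed = a_obs,
            amplitude_shuffled = a_shuf)
}

#' Peri-stimulus time histogram of one neuron
#'
#' Per-bin spike probability averaged across repeats (length `B`);
#' with `as_rate = TRUE` it is divided by the bin width and returned in
#' spikes/s.
#' @param raster a [spike_raster].
#' @param neuron row index or neuron id.
#' @param as_rate return rate instead of probability.
#' @export
psth <- function(raster, neuron, as_rate = FALSE) {
  if (is.character(neuron)) neuron <- match(neuron, raster$neuron_ids)
  tr <- matrix(raster$values[neuron, ], nrow = raster$bins_per_repeat)
  out <- rowMeans(tr)
  if (as_rate) out <- out / raster$bin_width
  out
}

#' Serialize statistics to a columnar text report
#' @param stats an [moment_stats()] result.
#' @param path output path; `<path>.pk` receives P(K) as two-column
#'   text.
#' @export
write_stats <- function(stats, path) {
  N <- stats$n_neurons
  ut <- which(upper.tri(stats$m), arr.ind = TRUE)
  df <- data.frame(
    kind = c(rep("rate", N), rep("moment", nrow(ut))),
    i = c(seq_len(N), ut[, 1]), j = c(rep(NA, N), ut[, 2]),
    value = c(stats$p, stats$m[ut]),
    se = c(if (is.null(stats$p_se)) rep(NA, N) else stats$p_se,
           if (is.null(stats$m_se)) rep(NA, nrow(ut)) else stats$m_se[ut]))
  data.table::fwrite(df, path, sep = "\t")
  data.table::fwrite(data.frame(K = 0:N, P = stats$pk),
                     paste0(path, ".pk"), sep = "\t")
  invisible(path)
}
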