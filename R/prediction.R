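resolve_engine <- function(model, engine) {
  if (engine == "auto")
    engine <- if (model$n_neurons <= 20) "exact" else "mc"
  engine
}

#' Model-predicted synchrony distribution P(K)
#'
#' By exact enumeration for small N, or from a long Metropolis run.
#' For a K-pairwise fit this is a constraint audit (matched by
#' construction); for independent and pairwise models it is a genuine
#' prediction, and synchrony-heavy data expose the missing tail.
#'
#' @param model a [maxent_model].
#' @param engine `"auto"`, `"exact"` or `"mc"`.
#' @param n_samples MC budget when sampling.
#' @param seed RNG seed.
#' @return numeric vector of length N+1 (names `"0".."N"`).
#' @export
predict_synchrony <- function(model, engine = "auto",
                              n_samples = 200000L, seed = NULL) {
  engine <- resolve_engine(model, engine)
  N <- model$n_neurons
  if (engine == "exact") {
    pk <- enumerate_exact(model, moments = FALSE)$pk
  } else {
    sm <- metropolis_sample(model, as.integer(n_samples), seed = seed)
    pk <- tabulate(rowSums(sm$samples) + 1L, nbins = N + 1L) / n_samples
  }
  names(pk) <- 0:N
  pk
}

#' Triplet-correlation prediction report
#'
#' Compares connected three-point correlations measured from the data
#' against the model's prediction for the same triplets (computed from
#' a model-sampled raster of equal size). Data values are binned into
#' `n_bins` equally populated bins, per-bin model mean and s.d. are
#' reported, and the headline number is the mean absolute deviation
#' (MAD) of model from data across triplets.
#'
#' @param model a [maxent_model].
#' @param raster evaluation [spike_raster].
#' @param n_bins equal-population bins (default 1000; reduced with a
#'   warning if there are fewer triplets).
#' @param max_triplets random subsample cap on the triplet list.
#' @param n_samples model MC sample count (default: data size).
#' @param seed RNG seed.
#' @return list with the per-triplet values, the binned table, and
#'   `mad`.
#' @export
triplet_prediction_report <- function(model, raster, n_bins = 1000L,
                                      max_triplets = 20000L,
                                      n_samples = NULL, seed = NULL) {
  N <- raster$n_neurons
  trips <- t(combn(N, 3))
  with_seed(seed, {
    if (nrow(trips) > max_triplets)
      trips <- trips[sample.int(nrow(trips), max_triplets), ]
    if (is.null(n_samples)) n_samples <- ncol(raster$values)
    sm <- metropolis_sample(model, as.integer(n_samples))
  })
  c_data <- triplet_correlations(raster, trips)
  model_raster <- mc_to_raster(sm, raster$bin_width)
  c_model <- triplet_correlations(model_raster, trips)
  if (n_bins > length(c_data)) {
    warning("fewer triplets than bins; reducing bin count")
    n_bins <- max(1L, length(c_data) %/% 5L)
  }
  ord <- order(c_data)
  bin <- ceiling(seq_along(ord) / (length(ord) / n_bins))
  tab <- data.frame(
    data_mean = tapply(c_data[ord], bin, mean),
    data_sd = tapply(c_data[ord], bin, sd),
    model_mean = tapply(c_model[ord], bin, mean),
    model_sd = tapply(c_model[ord], bin, sd))
  list(triplets = trips, c_data = c_data, c_model = c_model,
       binned = tab, mad = mean(abs(c_model - c_data)))
}

#' Effective-field curve: binned spike probability vs h_eff
#'
#' For every recorded word and every neuron, computes the effective
#' field exerted by the other N-1 cells, bins the values (30
#' equal-width bins over the central 99% of the sampled range, bins
#' with fewer than `min_obs` observations dropped), and tabulates the
#' empirical spike frequency per bin. If the model is right the curve
#' follows the parameter-free logistic `P(spike) = 1/(1+exp(-h_eff))`.
#'
#' @param model a [maxent_model].
#' @param raster evaluation [spike_raster].
#' @param n_field_bins number of bins (default 30).
#' @param min_obs minimum observations per kept bin (default 50).
#' @return data.frame with bin centers, empirical frequency, binomial
#'   standard error, count, and the logistic prediction.
#' @export
effective_field_curve <- function(model, raster, n_field_bins = 30L,
                                  min_obs = 50L) {
  W <- t(raster$values)
  Hf <- effective_fields_all(model, W)
  hv <- as.vector(Hf)
  sv <- as.vector(W)
  qs <- quantile(hv, c(0.005, 0.995))
  edges <- seq(qs[1], qs[2], length.out = n_field_bins + 1)
  bin <- cut(hv, edges, include.lowest = TRUE, labels = FALSE)
  keep <- !is.na(bin)
  bin <- bin[keep]; sv2 <- sv[keep]; hv2 <- hv[keep]
  cnt <- tabulate(bin, nbins = n_field_bins)
  freq <- vapply(seq_len(n_field_bins), function(b)
    if (cnt[b] > 0) mean(sv2[bin == b]) else NA_real_, numeric(1))
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  se <- sqrt(freq * (1 - freq) / pmax(cnt, 1))
  out <- data.frame(h_eff = centers, frequency = freq, se = se,
                    n = cnt, logistic = plogis(centers))
  out[out$n >= min_obs, ]
}

#' Predict a neuron's PSTH from the rest of the network
#'
#' For every time bin and repeat, the conditional spike probability of
#' the chosen neuron given the observed state of the other N-1 cells
#' (effective field through the logistic link). Makes no reference to
#' the stimulus. Two summary correlations against the empirical PSTH
#' are returned: `cc_trial` (mean of per-repeat correlations) and
#' `cc_mean` (correlation of the across-repeat mean prediction).
#'
#' @param model a [maxent_model].
#' @param raster a [spike_raster] with repeat structure.
#' @param neuron index or id of the predicted neuron.
#' @return list with the B x R prediction matrix, the empirical PSTH,
#'   and the two correlation summaries (NA, flagged, when the PSTH has
#'   zero variance).
#' @export
predict_psth <- function(model, raster, neuron) {
  if (is.character(neuron)) neuron <- match(neuron, raster$neuron_ids)
  W <- t(raster$values)
  W[, neuron] <- 0L   # field from the *other* cells only
  hf <- effective_fields_all(model, W)[, neuron]
  pred <- matrix(plogis(hf), nrow = raster$bins_per_repeat)
  obs <- psth(raster, neuron)
  if (sd(obs) == 0) {
    warning("zero-variance PSTH; correlations undefined")
    cc_trial <- cc_mean <- NA_real_
  } else {
    per_rep <- apply(pred, 2, function(x)
      if (sd(x) > 0) cor(x, obs) else NA_real_)
    cc_trial <- mean(per_rep, na.rm = TRUE)
    mp <- rowMeans(pred)
    cc_mean <- if (sd(mp) > 0) cor(mp, obs) else NA_real_
  }
  list(prediction = pred, psth = obs, cc_trial = cc_trial,
       cc_mean = cc_mean)
}

#' Model coincidence probability
#'
#' `P_c = sum_s P(s)^2`: the probability that two independent draws
#' from the model coincide. Exact by enumeration at small N; with the
#' MC engine it uses `P_c = <P(s)>_P`, averaging `exp(-E - log Z)`
#' over model samples (requires `log_z`). Also reports
#' `-log2(P_c)/N` for extrapolation plots.
#'
#' @param model a [maxent_model].
#' @param engine `"auto"`, `"exact"` or `"mc"`.
#' @param n_samples MC budget.
#' @param seed RNG seed.
#' @return list with `p_coincidence`, `minus_log2_pc_per_n`, `se`.
#' @export
coincidence_probability_model <- function(model, engine = "auto",
                                          n_samples = 200000L,
                                          seed = NULL) {
  engine <- resolve_engine(model, engine)
  N <- model$n_neurons
  if (engine == "exact") {
    en <- enumerate_exact(model, moments = FALSE, probabilities = TRUE)
    pc <- sum(en$prob^2)
    se <- 0
  } else {
    if (is.null(model$log_z))
      stop("MC coincidence estimate requires log_z on the model")
    sm <- metropolis_sample(model, as.integer(n_samples), seed = seed)
    pv <- exp(-sm$energies - model$log_z)
    tau <- acf_tau(sm$energies)
    pc <- mean(pv)
    se <- sd(pv) * sqrt(tau / length(pv))
  }
  list(p_coincidence = pc, minus_log2_pc_per_n = -log2(pc) / N,
       se = se)
}
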