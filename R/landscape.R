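#' Greedy descent to a metastable state
#'
#' Sweeps the neurons in ascending index order, retaining any
#' single-spin flip that strictly lowers the energy, and repeats until
#' a full sweep changes nothing. Ties (zero energy change) are not
#' accepted, so the descent cannot cycle; it always terminates because
#' the energy strictly decreases on a finite state space. The result
#' is locally stable: every one of the N single-flip perturbations
#' raises the energy.
#'
#' @param model a [maxent_model].
#' @param pattern binary word (or matrix of words, one per row).
#' @return list with `pattern` (metastable word(s)) and `energy`.
#' @export
descend_to_metastable <- function(model, pattern) {
  w <- as_word_matrix(pattern, model$n_neurons)
  res <- descend_cpp(model$h, model$J, model$V, w)
  if (nrow(w) == 1)
    list(pattern = as.integer(res$states[1, ]), energy = res$energies[1])
  else list(pattern = res$states, energy = res$energies)
}

is_locally_stable <- function(model, pattern) {
  e0 <- energy(model, pattern)
  flips <- matrix(rep(as.integer(pattern), each = length(pattern)),
                  nrow = length(pattern), byrow = FALSE)
  flips <- t(sapply(seq_along(pattern), function(i) {
    p <- as.integer(pattern)
    p[i] <- 1L - p[i]
    p
  }))
  all(energy(model, flips) > e0)
}

#' Census of basins of attraction over recorded data
#'
#' Descends from every recorded word, deduplicates the resulting
#' metastable (MS) states, and assigns each data word to its basin.
#' Basin size is the number of *recorded* words that descend to the MS
#' state (so sizes partition the data); subsets of basins occupied
#' more than 10 and more than 100 times are also reported. Basins are
#' ordered by decreasing size; the all-silent basin, when present, is
#' flagged.
#'
#' @param model a [maxent_model].
#' @param raster a [spike_raster] on the same neurons.
#' @return object of class `landscape_summary`: MS `patterns` matrix,
#'   `energies`, `assignment` (basin index per time bin), `sizes`,
#'   occupancy-threshold counts, `silent_basin` index or NA.
#' @export
census_basins <- function(model, raster) {
  words <- t(raster$values)
  keys <- word_keys(words)
  uni <- !duplicated(keys)
  uwords <- words[uni, , drop = FALSE]
  res <- descend_cpp(model$h, model$J, model$V, uwords)
  ms_keys_per_word <- word_keys(res$states)
  ms_uni <- !duplicated(ms_keys_per_word)
  ms_patterns <- res$states[ms_uni, , drop = FALSE]
  ms_energies <- res$energies[ms_uni]
  ms_keys <- ms_keys_per_word[ms_uni]
  # basin of each unique data word, then propagate to every time bin
  basin_of_unique <- match(ms_keys_per_word, ms_keys)
  assignment <- basin_of_unique[match(keys, keys[uni])]
  sizes <- tabulate(assignment, nbins = nrow(ms_patterns))
  ord <- order(sizes, decreasing = TRUE)
  rank <- match(seq_along(ord), ord)
  out <- list(patterns = ms_patterns[ord, , drop = FALSE],
              energies = ms_energies[ord],
              assignment = rank[assignment],
              sizes = sizes[ord],
              n_basins = nrow(ms_patterns),
              n_over_10 = sum(sizes > 10),
              n_over_100 = sum(sizes > 100),
              silent_basin = {
                sk <- which(rowSums(ms_patterns[ord, , drop = FALSE]) == 0)
                if (length(sk)) sk else NA_integer_
              },
              n_repeats = raster$n_repeats,
              bins_per_repeat = raster$bins_per_repeat,
              bin_width = raster$bin_width)
  class(out) <- "landscape_summary"
  out
}

#' @export
print.landscape_summary <- function(x, ...) {
  cat(sprintf(paste0("<landscape_summary> %d basins (%d with >10, %d ",
                     "with >100 occurrences); silent basin: %s\n"),
              x$n_basins, x$n_over_10, x$n_over_100,
              ifelse(is.na(x$silent_basin), "absent",
                     paste0("#", x$silent_basin))))
  invisible(x)
}

#' Cosine overlaps between binary patterns
#'
#' `q(s, s') = sum_i s_i s'_i / sqrt(sum s_i * sum s'_i)`; 1 for
#' identical patterns, 0 for disjoint supports. The all-silent word
#' has an undefined norm: its rows/columns are `NA` and flagged.
#' @param patterns matrix of binary words, one per row.
#' @return symmetric overlap matrix; attribute `zero_words` lists
#'   flagged all-silent rows.
#' @export
overlaps <- function(patterns) {
  patterns <- as.matrix(patterns)
  storage.mode(patterns) <- "double"
  k <- rowSums(patterns)
  q <- tcrossprod(patterns) / sqrt(outer(k, k))
  zero <- which(k == 0)
  q[zero, ] <- NA_real_
  q[, zero] <- NA_real_
  structure(q, zero_words = zero)
}

#' Hamming similarity between binary patterns (alternative overlap)
#' @param patterns matrix of binary words, one per row.
#' @return matrix of `1 - hamming/N`.
#' @export
hamming_similarity <- function(patterns) {
  patterns <- as.matrix(patterns)
  storage.mode(patterns) <- "double"
  N <- ncol(patterns)
  agree <- tcrossprod(patterns) +
    tcrossprod(1 - patterns)
  agree / N
}

#' Stochastic exploration of transitions out of a basin
#'
#' Runs Metropolis walks at `T = 1` from a metastable state; after
#' every accepted flip the current word is descended, and the walk
#' ends when it first descends to a different metastable state. Each
#' exit records the end basin pattern, the barrier
#' `dE = max energy along the path - start energy` (non-negative by
#' construction), and the number of attempted flips `L`. Walks that
#' exhaust the budget are censored records.
#'
#' @param model a [maxent_model].
#' @param start a metastable word (checked).
#' @param n_walks number of walks (default 1000).
#' @param max_attempts per-walk attempt budget.
#' @param seed RNG seed.
#' @return list: `records` data.frame (`barrier`, `L`, `exited`,
#'   `end_basin` key), `end_patterns` matrix, `P_L` and barrier
#'   summaries over uncensored walks.
#' @export
explore_transitions <- function(model, start, n_walks = 1000L,
                                max_attempts = 100000L, seed = NULL) {
  start <- as.integer(start)
  if (!is_locally_stable(model, start))
    stop("start pattern is not metastable")
  with_seed(seed, {
    res <- explore_transitions_cpp(model$h, model$J, model$V, start,
                                   as.integer(n_walks),
                                   as.integer(max_attempts), 1.0)
  })
  exited <- res$exited
  ends <- res$ends
  end_key <- rep(NA_character_, n_walks)
  if (any(exited))
    end_key[exited] <- word_keys(ends[exited, , drop = FALSE])
  records <- data.frame(barrier = res$barrier, L = res$L,
                        exited = exited, end_basin = end_key,
                        stringsAsFactors = FALSE)
  ok <- exited
  list(records = records, end_patterns = ends,
       start_energy = energy(model, start),
       P_L = if (any(ok)) table(records$L[ok]) / sum(ok) else NULL,
       barrier_mean = if (any(ok)) mean(records$barrier[ok]) else NA,
       n_censored = sum(!ok))
}

#' Basin occupancy dynamics across stimulus repeats
#'
#' Assigns every time bin to its basin, then computes, per bin within
#' the repeat, the probability across repeats of being in each basin;
#' the coherence (probability of the dominant non-silent basin among
#' all non-silent basins, per bin); and the mean autocorrelation of
#' the basin indicator traces with an exponential fit of its decay
#' time constant tau (reported in bins and seconds).
#'
#' @param model a [maxent_model].
#' @param raster a [spike_raster] with repeat structure.
#' @param census optional precomputed [census_basins] result.
#' @param max_basins restrict traces to the most occupied basins.
#' @param max_lag autocorrelation fit range (bins).
#' @return list with `occupancy` (B x n_basins matrix), `coherence`
#'   (per bin), `tau_bins`, `tau_seconds`, `acf_mean`, `census`.
#' @export
basin_dynamics <- function(model, raster, census = NULL,
                           max_basins = 20L, max_lag = 10L) {
  if (raster$n_repeats < 2)
    stop("basin dynamics needs repeat structure")
  if (is.null(census)) census <- census_basins(model, raster)
  B <- raster$bins_per_repeat
  R <- raster$n_repeats
  A <- matrix(census$assignment, nrow = B)    # bins x repeats
  nb <- min(census$n_basins, max_basins)
  occupancy <- sapply(seq_len(nb), function(b) rowMeans(A == b))
  occupancy <- matrix(occupancy, nrow = B)
  silent <- census$silent_basin
  non_silent <- setdiff(seq_len(nb), silent)
  coherence <- rep(NA_real_, B)
  if (length(non_silent) > 0) {
    ns_occ <- occupancy[, non_silent, drop = FALSE]
    tot <- rowSums(ns_occ)
    coherence <- ifelse(tot > 0, apply(ns_occ, 1, max) / tot, NA_real_)
  }
  # mean autocorrelation of basin indicator traces (within repeats)
  acf_sum <- numeric(max_lag)
  wsum <- 0
  for (b in seq_len(nb)) {
    z <- 1 * (A == b)
    if (sd(z) == 0) next
    ac <- rowMeans(sapply(seq_len(R), function(r) {
      acf(z[, r], lag.max = max_lag, plot = FALSE,
          demean = TRUE)$acf[-1]
    }), na.rm = TRUE)
    wgt <- census$sizes[b]
    acf_sum <- acf_sum + wgt * ac
    wsum <- wsum + wgt
  }
  acf_mean <- if (wsum > 0) acf_sum / wsum else rep(NA_real_, max_lag)
  tau_bins <- NA_real_
  pos <- which(acf_mean > 0)
  if (length(pos) >= 2) {
    lag <- seq_len(max_lag)[pos]
    fit <- lm(log(acf_mean[pos]) ~ lag)
    sl <- coef(fit)[["lag"]]
    if (sl < 0) tau_bins <- -1 / sl
  }
  list(occupancy = occupancy, coherence = coherence,
       acf_mean = acf_mean, tau_bins = tau_bins,
       tau_seconds = tau_bins * raster$bin_width, census = census)
}
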