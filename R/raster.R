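#' Binary spike raster with repeat structure
#'
#' The basic data container of the package: an `n_neurons x (R * B)`
#' binary matrix of spike/silence indicators, where `R` repeats of the
#' same stimulus each contribute `B` consecutive time bins of width
#' `bin_width` seconds. Column order is repeat-major: columns
#' `1..B` are repeat 1, `B+1..2B` repeat 2, and so on.
#'
#' @param values binary matrix, neurons in rows, time bins in columns.
#' @param bin_width bin width in seconds (e.g. 0.02 for 20 ms bins).
#' @param n_repeats number of stimulus repeats `R`; the number of
#'   columns must be divisible by it.
#' @param neuron_ids optional unique labels, default `"n1".."nN"`.
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(values, bin_width, n_repeats = 1L,
                         neuron_ids = NULL) {
  values <- as.matrix(values)
  if (!all(values %in% c(0L, 1L)))
    stop("raster entries must be 0 or 1")
  storage.mode(values) <- "integer"
  if (bin_width <= 0) stop("bin_width must be positive")
  n_repeats <- as.integer(n_repeats)
  if (ncol(values) %% n_repeats != 0)
    stop("number of time bins is not divisible by n_repeats")
  if (is.null(neuron_ids)) neuron_ids <- paste0("n", seq_len(nrow(values)))
  if (anyDuplicated(neuron_ids)) stop("neuron_ids must be unique")
  rownames(values) <- neuron_ids
  structure(list(values = values,
                 n_neurons = nrow(values),
                 n_repeats = n_repeats,
                 bins_per_repeat = ncol(values) %/% n_repeats,
                 bin_width = bin_width,
                 neuron_ids = neuron_ids),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf(paste0("<spike_raster> %d neurons, %d repeats x %d bins ",
                     "(%.0f ms bins), mean spike prob %.4f\n"),
              x$n_neurons, x$n_repeats, x$bins_per_repeat,
              1000 * x$bin_width, mean(x$values)))
  invisible(x)
}

#' @export
dim.spike_raster <- function(x) dim(x$values)

n_bins <- function(raster) ncol(raster$values)

#' Bin spike times into a binary raster
#'
#' Bins are half-open `[t*dt, (t+1)*dt)`, 0-based, over the global
#' recording time `[0, n_repeats * repeat_duration)`. A bin is set to 1
#' if the neuron fired at least once in it; bins holding more than one
#' spike are still recorded as 1 (binarization rule for 20 ms bins,
#' which affects well under 1% of bins at retinal firing rates).
#'
#' @param events data.frame with columns `neuron_id` and `time_s`
#'   (global spike times in seconds).
#' @param bin_width bin width in seconds.
#' @param n_repeats number of stimulus repeats.
#' @param repeat_duration duration of one repeat in seconds; must be an
#'   integer multiple of `bin_width` (within rounding tolerance).
#' @param neuron_ids universe of neuron labels; defaults to the sorted
#'   unique ids present in `events`. Events with ids outside this set
#'   are an error.
#' @return A [spike_raster]. Spike times outside the recording are
#'   dropped; their count is reported in attribute `n_rejected` and via
#'   a warning.
#' @export
bin_spike_times <- function(events, bin_width, n_repeats,
                            repeat_duration, neuron_ids = NULL) {
  stopifnot(bin_width > 0, n_repeats >= 1, repeat_duration > 0)
  B <- repeat_duration / bin_width
  if (abs(B - round(B)) > 1e-8)
    stop("repeat_duration must be a multiple of bin_width")
  B <- as.integer(round(B))
  if (is.null(neuron_ids)) neuron_ids <- sort(unique(events$neuron_id))
  if (!all(events$neuron_id %in% neuron_ids))
    stop("events contain unknown neuron ids")
  total <- n_repeats * repeat_duration
  ok <- events$time_s >= 0 & events$time_s < total
  n_rej <- sum(!ok)
  if (n_rej > 0)
    warning(sprintf("%d spike times outside [0, %g s) rejected",
                    n_rej, total))
  events <- events[ok, , drop = FALSE]
  N <- length(neuron_ids)
  T_ <- n_repeats * B
  vals <- matrix(0L, N, T_)
  if (nrow(events) > 0) {
    row <- match(events$neuron_id, neuron_ids)
    col <- floor(events$time_s / bin_width) + 1L
    vals[cbind(row, col)] <- 1L
  }
  out <- spike_raster(vals, bin_width, n_repeats, neuron_ids)
  attr(out, "n_rejected") <- n_rej
  out
}

#' Randomly sample subgroups of neurons
#'
#' Draws `n_groups` subgroups (rows sampled without replacement) for
#' every requested size. Groups are independent draws and may overlap
#' across draws.
#'
#' @param raster a [spike_raster].
#' @param sizes integer vector of subgroup sizes.
#' @param n_groups number of subgroups per size.
#' @param seed RNG seed for reproducible membership.
#' @return Nested list: `out[[as.character(size)]][[g]]` is a
#'   [spike_raster] on the sampled neurons.
#' @export
sample_subgroups <- function(raster, sizes, n_groups, seed = NULL) {
  stopifnot(n_groups >= 1)
  if (any(sizes > raster$n_neurons))
    stop("subgroup size exceeds number of neurons")
  with_seed(seed, {
    out <- lapply(sizes, function(sz) {
      lapply(seq_len(n_groups), function(g) {
        idx <- sort(sample.int(raster$n_neurons, sz))
        subset_neurons(raster, idx)
      })
    })
    names(out) <- as.character(sizes)
    out
  })
}

#' Subset a raster to a set of neurons
#' @param raster a [spike_raster].
#' @param idx row indices or neuron ids.
#' @export
subset_neurons <- function(raster, idx) {
  if (is.character(idx)) idx <- match(idx, raster$neuron_ids)
  spike_raster(raster$values[idx, , drop = FALSE], raster$bin_width,
               raster$n_repeats, raster$neuron_ids[idx])
}

#' Split a raster into train and test repeats
#'
#' Withholds a random selection of `n_test` whole repeats as a test
#' set; the remaining repeats form the training set. The two parts are
#' disjoint and together cover every repeat.
#'
#' @param raster a [spike_raster] with `R >= 2` repeats.
#' @param n_test number of repeats to withhold (`0 < n_test < R`).
#' @param seed RNG seed.
#' @return list with elements `train` and `test` ([spike_raster]s).
#' @export
split_repeats <- function(raster, n_test, seed = NULL) {
  R <- raster$n_repeats
  if (n_test <= 0 || n_test >= R)
    stop("n_test must satisfy 0 < n_test < n_repeats")
  with_seed(seed, {
    test_r <- sort(sample.int(R, n_test))
    B <- raster$bins_per_repeat
    cols_of <- function(rs) as.vector(outer(seq_len(B), (rs - 1L) * B, `+`))
    train_r <- setdiff(seq_len(R), test_r)
    list(train = spike_raster(raster$values[, cols_of(train_r), drop = FALSE],
                              raster$bin_width, length(train_r),
                              raster$neuron_ids),
         test = spike_raster(raster$values[, cols_of(test_r), drop = FALSE],
                             raster$bin_width, length(test_r),
                             raster$neuron_ids))
  })
}

#' Shuffle a raster, destroying all cross-neuron structure
#'
#' Permutes each neuron's time series independently across all
#' (repeat, bin) slots. Per-neuron spike counts (hence firing rates)
#' are preserved exactly; pairwise and temporal correlations are
#' reduced to the sampling floor, s.d. about `1/sqrt(T)`.
#'
#' @param raster a [spike_raster].
#' @param seed RNG seed.
#' @return A shuffled [spike_raster].
#' @export
shuffle_raster <- function(raster, seed = NULL) {
  with_seed(seed, {
    T_ <- n_bins(raster)
    vals <- raster$values
    for (i in seq_len(nrow(vals)))
      vals[i, ] <- vals[i, sample.int(T_)]
    spike_raster(vals, raster$bin_width, raster$n_repeats,
                 raster$neuron_ids)
  })
}

# ---- raster / event-list disk formats -------------------------------

#' Write a raster as delimited text plus a sidecar metadata file
#'
#' The matrix is written one neuron per row, 0/1 entries separated by
#' spaces; `<path>.meta` records `bin_width`, `n_repeats`,
#' `bins_per_repeat` and the neuron ids as `key: value` lines.
#' @param raster a [spike_raster].
#' @param path output file path.
#' @export
write_raster <- function(raster, path) {
  data.table::fwrite(data.table::as.data.table(raster$values), path,
                     sep = " ", col.names = FALSE)
  meta <- c(sprintf("bin_width: %.17g", raster$bin_width),
            sprintf("n_repeats: %d", raster$n_repeats),
            sprintf("bins_per_repeat: %d", raster$bins_per_repeat),
            sprintf("neuron_ids: %s",
                    paste(raster$neuron_ids, collapse = ",")))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read a raster written by [write_raster]
#' @param path file path (expects `<path>.meta` next to it).
#' @export
read_raster <- function(path) {
  vals <- as.matrix(data.table::fread(path, header = FALSE, sep = " "))
  meta <- readLines(paste0(path, ".meta"))
  kv <- function(key) {
    ln <- grep(paste0("^", key, ":"), meta, value = TRUE)
    trimws(sub("^[^:]+:", "", ln))
  }
  spike_raster(vals, as.numeric(kv("bin_width")),
               as.integer(kv("n_repeats")),
               strsplit(kv("neuron_ids"), ",")[[1]])
}

#' Write spike events as tab-separated text
#'
#' Format: header line, then `neuron_id <TAB> time_s <TAB>
#' repeat_index` with times relative to the start of the repeat.
#' @param raster a [spike_raster] (events are the 1-bins' centers).
#' @param path output path.
#' @export
write_events <- function(raster, path) {
  idx <- which(raster$values == 1L, arr.ind = TRUE)
  B <- raster$bins_per_repeat
  bin0 <- idx[, 2] - 1L
  rep_i <- bin0 %/% B + 1L
  within <- bin0 %% B
  df <- data.frame(neuron_id = raster$neuron_ids[idx[, 1]],
                   time_s = (within + 0.5) * raster$bin_width,
                   repeat_index = rep_i)
  df <- df[order(df$repeat_index, df$time_s, df$neuron_id), ]
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a tab-separated event list and bin it
#' @param path event-list path (see [write_events]).
#' @param bin_width,n_repeats,repeat_duration binning parameters passed
#'   to [bin_spike_times].
#' @param neuron_ids optional id universe.
#' @export
read_events <- function(path, bin_width, n_repeats, repeat_duration,
                        neuron_ids = NULL) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  df$time_s <- df$time_s + (df$repeat_index - 1) * repeat_duration
  bin_spike_times(df[, c("neuron_id", "time_s")], bin_width, n_repeats,
                  repeat_duration, neuron_ids)
}
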