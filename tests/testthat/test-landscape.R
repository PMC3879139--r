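test_that("descent terminates at locally stable words and matches brute force", {
  # independent model with all h < 0: unique minimum at silence
  mi <- independent_model(c(0.1, 0.2, 0.05, 0.3))
  set.seed(1)
  w <- matrix(rbinom(40, 1, 0.5), ncol = 4)
  d <- descend_to_metastable(mi, w)
  expect_true(all(d$pattern == 0))
  expect_true(all(d$energy == 0))
  # two-neuron ferromagnet with two stable states
  mf <- maxent_model(c(1, 1), matrix(c(0, 3, 3, 0), 2), NULL, "pairwise")
  # oracle: descend all 4 words by exhaustive neighbor comparison
  all4 <- brute_words(2)
  for (q in 1:4) {
    d1 <- descend_to_metastable(mf, all4[q, ])
    # the result is locally stable
    for (i in 1:2) {
      flip <- d1$pattern
      flip[i] <- 1L - flip[i]
      expect_gt(energy(mf, flip), d1$energy)
    }
  }
  # generic model: every descent output passes the N-flip audit
  m <- toy_model(8, seed = 2, j_sd = 0.9)
  set.seed(3)
  words <- matrix(rbinom(160, 1, 0.3), ncol = 8)
  dd <- descend_to_metastable(m, words)
  for (q in seq_len(nrow(words))) {
    e0 <- dd$energy[q]
    for (i in 1:8) {
      flip <- dd$pattern[q, ]
      flip[i] <- 1L - flip[i]
      expect_gt(energy(m, flip), e0)
    }
  }
  # determinism: same word, same model -> same metastable state
  d2 <- descend_to_metastable(m, words)
  expect_identical(dd$pattern, d2$pattern)
})

test_that("census partitions recorded words into basins", {
  m <- toy_model(8, seed = 4, j_sd = 1.2)
  sm <- metropolis_sample(m, 5000, seed = 5)
  ras <- mc_to_raster(sm)
  cen <- census_basins(m, ras)
  expect_equal(sum(cen$sizes), 5000)
  expect_equal(length(cen$assignment), 5000)
  # every reported metastable state passes the stability audit
  for (q in seq_len(cen$n_basins)) {
    e0 <- cen$energies[q]
    for (i in 1:8) {
      flip <- cen$patterns[q, ]
      flip[i] <- 1L - flip[i]
      expect_gt(energy(m, flip), e0)
    }
  }
  # sizes are sorted and consistent with the assignment
  expect_true(!is.unsorted(rev(cen$sizes)))
  expect_equal(tabulate(cen$assignment, cen$n_basins), cen$sizes)
  # assignment is invariant to word order
  perm <- sample(5000)
  ras2 <- spike_raster(ras$values[, perm], ras$bin_width)
  cen2 <- census_basins(m, ras2)
  expect_equal(cen2$assignment, cen$assignment[perm])
  # weakly coupled sparse model: single silent basin
  mw <- independent_model(rep(0.05, 8))
  cw <- census_basins(mw, mc_to_raster(metropolis_sample(mw, 2000,
                                                         seed = 6)))
  expect_equal(cw$n_basins, 1L)
  expect_equal(cw$silent_basin, 1L)
})

test_that("overlaps are cosine similarities with flagged zero words", {
  pat <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1),
               c(1, 0, 1, 0), c(0, 0, 0, 0))
  q <- overlaps(pat)
  expect_equal(q[1, 2], 1)
  expect_equal(q[1, 3], 0)
  expect_equal(q[1, 4], 1 / 2)
  expect_true(all(is.na(q[5, ])))
  expect_equal(attr(q, "zero_words"), 5L)
  expect_equal(diag(hamming_similarity(pat)), rep(1, 5))
})

test_that("transition walks exit over non-negative barriers to other basins", {
  m <- toy_model(8, seed = 7, j_sd = 1.2)
  sm <- metropolis_sample(m, 4000, seed = 8)
  cen <- census_basins(m, mc_to_raster(sm))
  start <- cen$patterns[1, ]
  tr <- explore_transitions(m, start, n_walks = 200,
                            max_attempts = 20000, seed = 9)
  ok <- tr$records$exited
  expect_gt(sum(ok), 0)
  expect_true(all(tr$records$barrier[ok] >= 0))
  # every exit lands in a *different* basin
  start_key <- paste(start, collapse = "")
  expect_false(any(tr$records$end_basin[ok] == start_key))
  # and the end states are themselves metastable
  ends <- unique(tr$end_patterns[ok, , drop = FALSE])
  for (q in seq_len(nrow(ends))) {
    e0 <- energy(m, ends[q, ])
    for (i in 1:8) {
      flip <- ends[q, ]
      flip[i] <- 1L - flip[i]
      expect_gt(energy(m, flip), e0)
    }
  }
  expect_error(explore_transitions(m, rep(1L, 8), n_walks = 2),
               "not metastable")
})

test_that("basin dynamics sees repeat-locked structure", {
  # strongly bistable 6-neuron model driven by shared modulation
  spec <- generator_spec(6, p_mean = 0.05, h_sd = 0.3,
                         coupling = list(mean = 0.9, sd = 0.4),
                         n_repeats = 60, bins_per_repeat = 120,
                         modulation = list(n_bumps = 4, width_bins = 3,
                                           amplitude = 4))
  truth <- make_ground_truth_model(spec, seed = 10)
  ras <- generate_raster(truth, spec, seed = 11)
  bd <- basin_dynamics(truth, ras)
  # per-bin basin probabilities sum to (at most) 1
  expect_true(all(rowSums(bd$occupancy) <= 1 + 1e-12))
  expect_true(all(bd$occupancy >= 0))
  # repeat-locked drive: occupancy of the non-silent basins is far
  # more structured across bins than under a repeat-shuffled control
  sil <- bd$census$silent_basin
  act <- 1 - bd$occupancy[, sil]
  shuf <- shuffle_raster(ras, seed = 12)
  bs <- basin_dynamics(truth, shuf)
  act_s <- if (is.na(bs$census$silent_basin)) rowMeans(bs$occupancy) else
    1 - bs$occupancy[, bs$census$silent_basin]
  expect_gt(sd(act), 3 * sd(act_s))
  # autocorrelation decay time is positive and finite when fit
  if (is.finite(bd$tau_bins)) {
    expect_gt(bd$tau_bins, 0)
    expect_equal(bd$tau_seconds, bd$tau_bins * ras$bin_width)
  }
})
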