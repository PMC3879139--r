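test_that("heat capacity matches the closed form for an independent model", {
  p <- c(0.1, 0.3, 0.05)
  m <- independent_model(p)
  Tg <- c(0.5, 1, 2)
  cc <- heat_capacity_curve(m, Tg, n_samples = 40000, seed = 1)
  # closed form: per-spin two-state system with energy gap -h_i
  C_oracle <- vapply(Tg, function(Tt) {
    sum(vapply(m$h, function(h) {
      pT <- 1 / (1 + exp(-h / Tt))
      (h / Tt)^2 * pT * (1 - pT)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(cc$C >= 0))
  expect_equal(cc$C, C_oracle, tolerance = 0.12)
  # C -> 0 in the uniform (T -> infinity) limit
  cc_inf <- heat_capacity_curve(m, 2000, n_samples = 20000, seed = 2)
  expect_lt(cc_inf$C, 0.01)
})

test_that("heat-capacity integration recovers known entropies", {
  # uniform model: S = N bits exactly, C identically 0. The ground
  # state is maximally degenerate here, so the T: 0 -> 1 direction
  # (which assumes S(0) = 0) does not apply; integrate from above.
  mu <- maxent_model(rep(0, 6), model_class = "independent")
  su <- entropy_via_heat_capacity(mu, "1toInf", n_samples = 2000,
                                  points_per_decade = 15, seed = 3)
  expect_equal(su$value, 6, tolerance = 1e-6)
  # independent model: S = sum H(p_i) within 0.5% by both directions
  # (rates chosen away from 1/2 so the ground state is unique)
  p <- c(0.04, 0.1, 0.25, 0.45, 0.08)
  mi <- independent_model(p)
  target <- sum(binary_entropy_bits_oracle(p))
  s1 <- entropy_via_heat_capacity(mi, "0to1", n_samples = 8000,
                                  points_per_decade = 60, seed = 4)
  expect_equal(s1$value, target, tolerance = 0.005 * target)
  s2 <- entropy_via_heat_capacity(mi, "1toInf", n_samples = 8000,
                                  points_per_decade = 60, seed = 5)
  expect_equal(s2$value, target, tolerance = 0.01 * target)
  # both directions agree on a generic model
  mk <- toy_model(8, seed = 6)
  ex <- enumerate_exact(mk)$entropy_bits
  sa <- entropy_via_heat_capacity(mk, "0to1", n_samples = 8000,
                                  points_per_decade = 60, seed = 7)
  expect_equal(sa$value, ex, tolerance = 0.015 * ex)
})

test_that("silence route: log Z = -log P(silence), S = <E> + log Z", {
  p <- c(0.04, 0.1, 0.25, 0.5, 0.08)
  mi <- independent_model(p)
  res <- partition_and_entropy_from_silence(mi, n_samples = 150000,
                                            seed = 8)
  expect_equal(res$log_z, -sum(log(1 - p)), tolerance = 0.02)
  expect_equal(res$entropy$value, sum(binary_entropy_bits_oracle(p)),
               tolerance = 0.01 * res$entropy$value)
  # supplied p_silence short-circuits the MC estimate of p0
  res2 <- partition_and_entropy_from_silence(mi, p_silence = prod(1 - p),
                                             n_samples = 50000, seed = 9)
  expect_equal(res2$log_z, -sum(log(1 - p)), tolerance = 1e-12)
  expect_equal(res2$entropy$diagnostics$p_silence_source, "supplied")
  # degenerate limit: P(silence) -> 1 means log Z -> 0 and S -> 0
  m0 <- independent_model(rep(1e-6, 4))
  r0 <- partition_and_entropy_from_silence(m0, p_silence = 1 - 4e-6,
                                           n_samples = 5000, seed = 10)
  expect_equal(r0$log_z, 0, tolerance = 1e-4)
  expect_equal(r0$entropy$value, 0, tolerance = 1e-3)
  # non-canonical gauge is refused with advice
  bad <- toy_model(4, seed = 11)
  bad$V[1] <- 0.5
  bad$gauge <- "other"
  expect_error(partition_and_entropy_from_silence(bad), "gauge_fix")
})

test_that("density-of-states route matches closed forms", {
  # uniform model: g concentrated at E = 0 -> S = N bits
  mu <- maxent_model(rep(0, 6), model_class = "independent")
  dos <- wang_landau(mu, energy_bins = 10, e_range = c(-0.5, 0.5),
                     ln_f_final = 1e-4, seed = 12)
  ru <- entropy_from_density_of_states(dos)
  expect_equal(ru$entropy$value, 6, tolerance = 1e-6)
  expect_equal(ru$log_z, 6 * log(2), tolerance = 1e-6)
  # independent model within 1%
  p <- c(0.04, 0.1, 0.25, 0.5, 0.08, 0.15)
  mi <- independent_model(p)
  di <- wang_landau(mi, energy_bins = 150, flatness = 0.9,
                    ln_f_final = 1e-7, seed = 13)
  ri <- entropy_from_density_of_states(di)
  target <- sum(binary_entropy_bits_oracle(p))
  expect_equal(ri$entropy$value, target, tolerance = 0.01 * target)
  # unnormalized densities are refused
  dos_bad <- dos
  dos_bad$log_g <- dos_bad$log_g + 1
  expect_error(entropy_from_density_of_states(dos_bad), "normalized")
})

test_that("multi-information is zero for independence, positive otherwise", {
  p <- c(0.1, 0.2, 0.3)
  st <- list(p = p)
  mi <- independent_model(p)
  s_ind <- enumerate_exact(mi)$entropy_bits
  expect_equal(multi_information(s_ind, st), 0, tolerance = 1e-10)
  mk <- toy_model(3, seed = 14, j_sd = 0.8)
  en <- enumerate_exact(mk)
  st2 <- list(p = en$p)
  expect_gt(multi_information(en$entropy_bits, st2), 0)
})

test_that("energy distribution report is self-consistent", {
  m <- toy_model(6, seed = 15)
  sm <- metropolis_sample(m, 20000, seed = 16)
  ras <- mc_to_raster(sm)
  rep_ <- energy_distribution_report(m, ras, n_samples = 20000, seed = 17)
  # model evaluated against its own samples: moments agree within error
  expect_lt(abs(rep_$rel_diff_mean), 0.05)
  expect_lt(abs(rep_$rel_diff_sd), 0.05)
  # cumulative counts partition the words at any threshold
  for (E in quantile(rep_$e_data, c(0.1, 0.5, 0.9))) {
    nb <- rep_$data_cumulative$n_below(E)
    na <- rep_$data_cumulative$n_above(E)
    expect_equal(nb + na, length(rep_$e_data))
  }
  # N_< is nondecreasing
  Es <- seq(min(rep_$e_data), max(rep_$e_data), length.out = 20)
  expect_true(!is.unsorted(rep_$data_cumulative$n_below(Es)))
})

test_that("2^-S lower-bounds the model coincidence probability", {
  for (sd_ in c(20, 21)) {
    m <- toy_model(6, seed = sd_)
    en <- enumerate_exact(m, probabilities = TRUE)
    pc <- sum(en$prob^2)
    expect_gte(pc, 2^(-en$entropy_bits) - 1e-12)
  }
})
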