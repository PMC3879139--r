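test_that("fit_independent is the closed-form logit solution", {
  st <- list(p = c(0.5, 0.031, 0.2), n_samples = 1000, n_neurons = 3)
  m <- fit_independent(st)
  expect_equal(m$h[1], 0)
  expect_equal(m$h[2], qlogis(0.031), tolerance = 1e-12)
  expect_equal(m$h[2], -3.442, tolerance = 1e-3)
  # enumeration of the fitted model returns the input rates exactly
  expect_equal(enumerate_exact(m)$p, st$p, tolerance = 1e-12)
  expect_equal(m$log_z, -sum(log(1 - st$p)))
  st0 <- list(p = c(0, 0.5), n_samples = 10, n_neurons = 2)
  expect_error(fit_independent(st0), "pseudocount")
  mp <- fit_independent(st0, pseudocount = TRUE)
  expect_true(all(is.finite(mp$h)))
})

test_that("exact engine recovers a known pairwise model from exact stats", {
  truth <- toy_pairwise(5, seed = 21, j_sd = 0.4)
  st <- exact_stats(truth)
  fit <- fit_model(st, "pairwise", engine = "exact", l1_strength = 0,
                   abs_tol = 1e-8, max_sweeps = 500)
  expect_true(fit$report$converged)
  # constraints matched far below 1e-6 ...
  en <- enumerate_exact(fit$model)
  expect_lt(max(abs(en$p - st$p)), 1e-6)
  expect_lt(max(abs(en$m - st$m)), 1e-6)
  # ... and the unique solution is the generator itself
  expect_lt(max(abs(fit$model$h - truth$h)), 1e-4)
  expect_lt(max(abs(fit$model$J - truth$J)), 1e-4)
})

test_that("k_pairwise exact fit matches rates, moments and P(K)", {
  truth <- toy_model(6, seed = 22, v_scale = 0.25)
  st <- exact_stats(truth)
  fit <- fit_model(st, "k_pairwise", engine = "exact", l1_strength = 0,
                   abs_tol = 1e-7, max_sweeps = 800)
  expect_true(fit$report$converged)
  en <- enumerate_exact(fit$model)
  expect_lt(max(abs(en$p - st$p)), 1e-6)
  expect_lt(max(abs(en$m - st$m)), 1e-6)
  expect_lt(max(abs(en$pk - st$pk)), 1e-6)
  # result is in canonical gauge
  expect_equal(fit$model$V[1], 0)
  expect_equal(fit$model$gauge, "canonical")
  # distribution equals the generator's despite the gauge freedom
  expect_lt(jsd_bits(model_probs(fit$model), model_probs(truth)), 1e-10)
})

test_that("fits from different seeds agree in distribution (uniqueness)", {
  truth <- toy_pairwise(6, seed = 23, j_sd = 0.3)
  spec <- generator_spec(6, n_repeats = 40, bins_per_repeat = 500)
  ras <- generate_raster(truth, spec, seed = 24)
  st <- moment_stats(ras, n_bootstrap = 15, seed = 25)
  f1 <- suppressWarnings(
    fit_model(st, "pairwise", engine = "mc", seed = 26,
              mc = list(n_max = 60000L), max_sweeps = 60))
  f2 <- suppressWarnings(
    fit_model(st, "pairwise", engine = "mc", seed = 27,
              mc = list(n_max = 60000L), max_sweeps = 60))
  expect_lt(jsd_bits(model_probs(f1$model), model_probs(f2$model)), 1e-4)
})

test_that("entropy is monotone under added constraints", {
  truth <- toy_model(7, seed = 28, v_scale = 0.3, j_sd = 0.4)
  st <- exact_stats(truth)
  fi <- fit_model(st, "independent")
  fp <- fit_model(st, "pairwise", engine = "exact", l1_strength = 0,
                  abs_tol = 1e-7, max_sweeps = 500)
  fk <- suppressWarnings(
    fit_model(st, "k_pairwise", engine = "exact", l1_strength = 0,
              abs_tol = 1e-6, max_sweeps = 800))
  s_i <- enumerate_exact(fi$model)$entropy_bits
  s_p <- enumerate_exact(fp$model)$entropy_bits
  s_k <- enumerate_exact(fk$model)$entropy_bits
  expect_lte(s_k, s_p + 1e-6)
  expect_lte(s_p, s_i + 1e-6)
})

test_that("evaluate_fit flags the wrong generator and accepts the right one", {
  truth <- toy_pairwise(6, seed = 29, j_sd = 0.3)
  spec <- generator_spec(6, n_repeats = 60, bins_per_repeat = 400)
  ras <- generate_raster(truth, spec, seed = 30)
  sp <- split_repeats(ras, 10, seed = 31)
  st <- moment_stats(sp$train, n_bootstrap = 10, seed = 32)
  fit <- fit_model(st, "pairwise", engine = "exact", max_sweeps = 400,
                   z_tol = 0.5, seed = 33)
  ev <- evaluate_fit(fit$model, sp$train, sp$test)
  expect_equal(ev$ratio, 1, tolerance = 0.03)
  # a different generator fits the same data strictly worse
  other <- toy_pairwise(6, seed = 99, j_sd = 0.3)
  other$log_z <- enumerate_exact(other, moments = FALSE)$log_z
  ev2 <- evaluate_fit(other, sp$train, sp$test)
  expect_lt(ev2$ll_test, ev$ll_test)
  # missing log_z on a large-N model is an instructive error
  big <- maxent_model(rep(-3, 25), model_class = "independent")
  big$log_z <- NULL
  expect_error(evaluate_fit(big, sp$train, sp$test), "silence")
})

test_that("perturbative couplings are exact for a pair, zero when independent", {
  # independence: m = p p' -> J = 0
  st0 <- list(p = c(0.2, 0.3), m = rbind(c(0.2, 0.06), c(0.06, 0.3)),
              n_neurons = 2)
  expect_equal(perturbative_couplings(st0)[1, 2], 0)
  # isolated pair: equals the exactly fitted coupling
  truth <- toy_pairwise(2, seed = 34, j_sd = 0.6)
  st <- exact_stats(truth)
  Jp <- perturbative_couplings(st)
  expect_equal(Jp[1, 2], truth$J[1, 2], tolerance = 1e-9)
  # degenerate arguments flagged as NA
  stb <- list(p = c(0.5, 0.5), m = rbind(c(0.5, 0.5), c(0.5, 0.5)),
              n_neurons = 2)
  expect_true(is.na(perturbative_couplings(stb)[1, 2]))
})
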