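#' Fit an independent maximum entropy model
#'
#' Constrains only the firing rates; the solution is closed-form,
#' `h_i = log(p_i / (1 - p_i))`, with `J = 0`, `V = 0`, and
#' `log Z = -sum_i log(1 - p_i)` in the canonical gauge.
#'
#' @param stats an [moment_stats()] result (or list with `p`).
#' @param pseudocount apply a half-count correction for rates of
#'   exactly 0 or 1 (needs `n_samples`); off by default.
#' @return a [maxent_model] of class `independent`.
#' @export
fit_independent <- function(stats, pseudocount = FALSE) {
  p <- stats$p
  if (any(p <= 0 | p >= 1)) {
    if (!pseudocount)
      stop("rates of exactly 0 or 1; rerun with pseudocount = TRUE")
    T_ <- stats$n_samples
    p <- (p * T_ + 0.5) / (T_ + 1)
  }
  maxent_model(qlogis(p), model_class = "independent",
               log_z = -sum(log(1 - p)))
}

# Constraint bookkeeping shared by the fitting engines --------------------

build_constraints <- function(stats, model_class, l1_strength) {
  N <- stats$n_neurons
  p <- stats$p
  pairs <- which(upper.tri(diag(N)), arr.ind = TRUE)
  m_target <- stats$m[pairs]
  p_se <- if (!is.null(stats$p_se)) stats$p_se else rep(0, N)
  m_se <- if (!is.null(stats$m_se)) stats$m_se[pairs] else
    rep(0, nrow(pairs))
  cons <- list(N = N, p = p, p_se = p_se, pairs = pairs,
               m = m_target, m_se = m_se,
               l1_t = l1_strength * m_se)
  if (model_class == "k_pairwise") {
    pk <- stats$pk
    k_cap <- max(which(pk > 0)) - 1L            # largest observed K
    k_set <- seq_len(k_cap)                     # V(0) pinned by gauge
    T_ <- stats$n_samples
    pk_target <- pmax(pk[k_set + 1L], 0.5 / T_) # floor interior zeros
    pk_se <- if (!is.null(stats$pk_se)) stats$pk_se[k_set + 1L] else
      rep(0, length(k_set))
    cons$k_set <- k_set
    cons$k_cap <- k_cap
    cons$pk <- pk_target
    cons$pk_se <- pk_se
  }
  cons
}

# Weighted expectations of all constrained statistics over a batch of
# words S (n x N) with weights w.
batch_expectations <- function(S, Kvec, w, cons) {
  sw <- sum(w)
  p_m <- as.numeric(crossprod(S, w)) / sw
  Sw <- S * w
  m_full <- crossprod(S, Sw) / sw
  m_m <- m_full[cons$pairs]
  out <- list(p = p_m, m = m_m)
  if (!is.null(cons$k_set)) {
    pk_m <- vapply(cons$k_set, function(k) sum(w[Kvec == k]), numeric(1)) / sw
    out$pk <- pk_m
  }
  out
}

constraint_residuals <- function(ex, cons, extra_var = NULL) {
  res <- c(ex$p - cons$p, ex$m - cons$m,
           if (!is.null(cons$k_set)) ex$pk - cons$pk)
  se <- c(cons$p_se, cons$m_se, if (!is.null(cons$k_set)) cons$pk_se)
  if (!is.null(extra_var)) se <- sqrt(se^2 + extra_var)
  z <- ifelse(se > 0, res / se, NA_real_)
  list(res = res, se = se, z = z)
}

#' Fit a pairwise or K-pairwise maximum entropy model
#'
#' Iterative constraint matching in the style of L1-regularized
#' sequential maxent learning: within each sweep the parameters are
#' visited in greedy order (largest current residual relative to its
#' error bar first) and each receives a damped log-ratio coordinate
#' step; model expectations are tracked by exact enumeration (small N)
#' or by Metropolis sampling with histogram reweighting between
#' updates, resampling whenever the cumulative parameter change
#' exceeds a trust region. Couplings carry an L1 penalty with a
#' per-parameter threshold proportional to the bootstrap error of the
#' constrained moment (zero when errors are absent, e.g. on exact
#' synthetic statistics). K-pairwise results are returned in canonical
#' gauge via [gauge_fix].
#'
#' Convergence: every residual z-score (model minus data over the
#' data error bar, MC noise included for the MC engine) must fall
#' below `z_tol`; when the statistics carry no error bars, absolute
#' residuals below `abs_tol` are required instead. Non-convergence is
#' reported in the fit report, not silently accepted.
#'
#' @param stats an [moment_stats()] result.
#' @param model_class `"pairwise"`, `"k_pairwise"`, or
#'   `"independent"` (delegates to [fit_independent]).
#' @param engine `"exact"` (enumeration, N <= 20) or `"mc"`.
#' @param l1_strength L1 threshold in units of the moment's bootstrap
#'   error (default 0.25; 0 disables).
#' @param z_tol convergence threshold on residual z-scores.
#' @param abs_tol absolute-residual convergence threshold used when
#'   error bars are absent or zero.
#' @param max_sweeps sweep budget.
#' @param damping step damping factor eta (default 0.5).
#' @param delta_max per-update parameter change clip.
#' @param trust resample the MC batch when the cumulative |change|
#'   since the last batch exceeds this bound (the batch is also
#'   refreshed whenever the importance-weight effective sample size
#'   drops below 40% of the batch).
#' @param v_cap clip on |V(K)| (suppresses unobserved synchrony).
#' @param mc list of MC-engine budgets: `n0` initial batch, `n_max`
#'   final batch, `growth` per-sweep batch growth, `thin`, `avg_tail`
#'   (number of final sweeps whose parameters are averaged).
#' @param seed RNG seed.
#' @param verbose print sweep diagnostics.
#' @return list with `model` (a [maxent_model]) and `report` (a
#'   `fit_report`: residuals, z-scores, convergence trace, settings).
#' @export
fit_model <- function(stats,
                      model_class = c("pairwise", "k_pairwise",
                                      "independent"),
                      engine = c("exact", "mc"),
                      l1_strength = 0.25, z_tol = 2, abs_tol = 1e-7,
                      max_sweeps = 200L, damping = 0.5, delta_max = 1,
                      trust = 3, v_cap = 20,
                      mc = list(), seed = NULL, verbose = FALSE) {
  model_class <- match.arg(model_class)
  engine <- match.arg(engine)
  if (model_class == "independent") {
    model <- fit_independent(stats)
    return(list(model = model,
                report = structure(list(converged = TRUE, n_sweeps = 0,
                                        engine = "closed_form"),
                                   class = "fit_report")))
  }
  N <- stats$n_neurons
  if (engine == "exact" && N > 20)
    stop("exact engine limited to N <= 20; use engine = 'mc'")
  mc_def <- list(n0 = 5000L, n_max = 200000L, growth = 1.35, thin = 1L,
                 avg_tail = 8L)
  mc <- utils::modifyList(mc_def, mc)
  cons <- build_constraints(stats, model_class, l1_strength)
  eps <- 1e-12

  # parameters
  h <- qlogis(pmin(pmax(cons$p, 1e-6), 1 - 1e-6))
  Jv <- rep(0, nrow(cons$pairs))
  Vv <- if (!is.null(cons$k_set)) rep(0, length(cons$k_set)) else numeric(0)
  n_par <- N + length(Jv) + length(Vv)
  par_kind <- c(rep("h", N), rep("J", length(Jv)), rep("V", length(Vv)))
  par_idx <- c(seq_len(N), seq_along(Jv), seq_along(Vv))

  make_model <- function(hh, jj, vv) {
    J <- matrix(0, N, N)
    J[cons$pairs] <- jj
    J <- J + t(J)
    V <- numeric(N + 1)
    if (length(vv)) {
      V[cons$k_set + 1L] <- vv
      if (cons$k_cap < N) {   # extrapolate beyond observed synchrony
        slope <- max(1, if (cons$k_cap >= 2)
          vv[cons$k_cap] - vv[cons$k_cap - 1] else 1)
        kk <- (cons$k_cap + 1L):N
        V[kk + 1L] <- pmin(v_cap + 5, vv[cons$k_cap] +
                             slope * (kk - cons$k_cap))
      }
    }
    maxent_model(hh, J, V,
                 if (length(vv)) "k_pairwise" else "pairwise")
  }

  with_seed(seed, {
    if (engine == "exact") {
      S <- all_words(N)
      storage.mode(S) <- "double"
      Kvec <- rowSums(S)
      logw <- as.numeric(S %*% h)   # -E up to V; V starts at 0
      w <- exp(logw - max(logw))
    } else {
      S <- NULL
    }

    batch <- NULL
    resample <- function(n) {
      mdl <- make_model(h, Jv, Vv)
      init <- if (is.null(batch)) "random" else batch$last
      sm <- metropolis_sample(mdl, n,
                              burn_in = if (is.null(batch)) 100L * N
                                        else 20L,
                              thin = mc$thin, init = init)
      Sb <- sm$samples
      storage.mode(Sb) <- "double"
      list(S = Sb, K = rowSums(Sb), w = rep(1, n),
           last = sm$samples[n, ], n = n)
    }

    feature_col <- function(kind, idx, Sm, Km) {
      switch(kind,
             h = Sm[, idx],
             J = Sm[, cons$pairs[idx, 1]] * Sm[, cons$pairs[idx, 2]],
             V = as.numeric(Km == cons$k_set[idx]))
    }
    target_of <- function(kind, idx) {
      switch(kind, h = cons$p[idx], J = cons$m[idx], V = cons$pk[idx])
    }

    trace <- numeric(0)
    converged <- FALSE
    consec_ok <- 0L
    snapshots <- list()
    snap_i <- 0L
    n_cur <- mc$n0
    eta <- damping

    for (sweep in seq_len(max_sweeps)) {
      if (engine == "mc") {
        batch <- resample(as.integer(n_cur))
        Sm <- batch$S; Km <- batch$K; w <- batch$w
        n_cur <- min(mc$n_max, ceiling(n_cur * mc$growth))
      } else {
        Sm <- S; Km <- Kvec
        w <- w / sum(w)   # guard against under/overflow across sweeps
      }
      ex <- batch_expectations(Sm, Km, w, cons)
      mc_var <- if (engine == "mc") {
        f_all <- c(ex$p, ex$m, if (!is.null(cons$k_set)) ex$pk)
        pmax(f_all * (1 - f_all), 1e-12) / batch$n
      } else NULL
      cr <- constraint_residuals(ex, cons, extra_var = mc_var)
      score <- ifelse(cr$se > 0, abs(cr$res) / cr$se, abs(cr$res) * 1e6)
      ord <- order(score, decreasing = TRUE)

      # convergence check before updating (expectations are fresh);
      # the MC loop stops slightly above z_tol and lets the larger
      # fresh final audit decide, since the in-loop z of ~500
      # constraints has an extreme-value noise floor of its own
      loop_tol <- if (engine == "mc") 1.25 * z_tol else z_tol
      ok <- ifelse(cr$se > 0, abs(cr$z) <= loop_tol,
                   abs(cr$res) <= abs_tol)
      trace <- c(trace, max(ifelse(cr$se > 0, abs(cr$z),
                                   abs(cr$res) / abs_tol)))
      if (all(ok)) {
        consec_ok <- consec_ok + 1L
        need <- if (engine == "mc") 2L else 1L
        if (consec_ok >= need) { converged <- TRUE }
      } else consec_ok <- 0L
      if (converged && engine == "exact") break
      if (converged && engine == "mc" &&
          length(snapshots) >= mc$avg_tail) break
      # once the batch is at its cap, anneal the step size so MC
      # noise stops being re-injected into the parameters
      if (engine == "mc" && batch$n >= mc$n_max)
        eta <- max(0.1 * damping, eta * 0.85)

      cum_delta <- 0
      sw_sum <- sum(w)
      for (q in ord) {
        # greedy: leave already-matched constraints untouched (their
        # update would only inject sampling noise)
        if (engine == "mc" && score[q] <= 1) break
        kind <- par_kind[q]; idx <- par_idx[q]
        f <- feature_col(kind, idx, Sm, Km)
        ef <- sum(w * f) / sw_sum
        tgt <- target_of(kind, idx)
        n_eff <- if (engine == "mc") batch$n else Inf
        floor_m <- if (is.finite(n_eff)) 0.25 / n_eff else eps
        delta <- 0
        if (kind == "h") {
          pm <- min(max(ef, floor_m), 1 - floor_m)
          delta <- eta * (qlogis(tgt) - qlogis(pm))
          delta <- max(-delta_max, min(delta_max, delta))
          h[idx] <- h[idx] + delta
          lw_mult <- delta * f
        } else if (kind == "J") {
          g <- tgt - ef
          t_l1 <- if (length(cons$l1_t)) cons$l1_t[idx] else 0
          if (Jv[idx] == 0 && abs(g) <= t_l1) next
          sgn <- if (Jv[idx] != 0) sign(Jv[idx]) else sign(g)
          tgt_adj <- max(tgt - t_l1 * sgn, floor_m)
          em <- max(ef, floor_m)
          delta <- eta * log(tgt_adj / em)
          delta <- max(-delta_max, min(delta_max, delta))
          j_new <- Jv[idx] + delta
          if (t_l1 > 0 && Jv[idx] != 0 && sign(j_new) != sign(Jv[idx])) {
            delta <- -Jv[idx]
            j_new <- 0
          }
          Jv[idx] <- j_new
          lw_mult <- delta * f
        } else {
          em <- max(ef, floor_m)
          delta <- -eta * log(tgt / em)
          delta <- max(-delta_max, min(delta_max, delta))
          v_new <- max(-v_cap, min(v_cap, Vv[idx] + delta))
          delta <- v_new - Vv[idx]
          Vv[idx] <- v_new
          lw_mult <- -delta * f
        }
        if (delta != 0) {
          w <- w * exp(lw_mult)
          sw_sum <- sum(w)
          cum_delta <- cum_delta + abs(delta)
          if (engine == "mc") {
            ess <- sw_sum^2 / sum(w^2)
            if (ess < 0.4 * batch$n || cum_delta > trust) {
              batch <- resample(batch$n)
              Sm <- batch$S; Km <- batch$K; w <- batch$w
              sw_sum <- sum(w)
              cum_delta <- 0
            }
          }
        }
      }
      if (engine == "mc") {
        snap_i <- snap_i + 1L
        snapshots[[(snap_i - 1L) %% mc$avg_tail + 1L]] <-
          list(h = h, J = Jv, V = Vv)
      }
      if (verbose)
        message(sprintf("sweep %d: max score %.3g%s", sweep,
                        max(score),
                        if (engine == "mc")
                          sprintf(" (batch %d)", batch$n) else ""))
    }

    if (engine == "mc" && length(snapshots) >= 2) {
      # tail-average the parameter trajectory to cancel MC jitter
      h <- rowMeans(sapply(snapshots, `[[`, "h"))
      Jv <- rowMeans(sapply(snapshots, `[[`, "J"))
      if (length(Vv))
        Vv <- rowMeans(sapply(snapshots, `[[`, "V"))
    }

    model <- make_model(h, Jv, Vv)
    if (model_class == "k_pairwise") model <- gauge_fix(model)

    # final residual audit on fresh expectations
    if (engine == "exact") {
      en <- enumerate_exact(model, moments = TRUE)
      ex_f <- list(p = en$p, m = en$m[cons$pairs],
                   pk = if (!is.null(cons$k_set))
                     en$pk[cons$k_set + 1L])
      mc_var_f <- NULL
      model$log_z <- en$log_z
    } else {
      sm <- metropolis_sample(model, 2L * as.integer(mc$n_max),
                              burn_in = 100L * N, thin = mc$thin)
      Sb <- sm$samples
      storage.mode(Sb) <- "double"
      ex_f <- batch_expectations(Sb, rowSums(Sb), rep(1, nrow(Sb)), cons)
      f_all <- c(ex_f$p, ex_f$m, if (!is.null(cons$k_set)) ex_f$pk)
      mc_var_f <- pmax(f_all * (1 - f_all), 1e-12) / nrow(Sb)
    }
    cr_f <- constraint_residuals(ex_f, cons, extra_var = mc_var_f)
    if (engine == "mc") {
      # the final word on convergence comes from the fresh audit
      ok_f <- ifelse(cr_f$se > 0, abs(cr_f$z) <= z_tol,
                     abs(cr_f$res) <= abs_tol)
      converged <- all(ok_f)
    }
  })

  report <- structure(
    list(residuals = cr_f$res, z = cr_f$z,
         z_width = sd(cr_f$z[is.finite(cr_f$z)]),
         max_abs_residual = max(abs(cr_f$res)),
         converged = converged, n_sweeps = length(trace),
         trace = trace, engine = engine, model_class = model_class,
         l1_strength = l1_strength, seed = seed,
         constraint_kind = par_kind),
    class = "fit_report")
  if (!converged)
    warning(sprintf(paste0("fit did not converge in %d sweeps; worst ",
                           "residual %.3g"), length(trace),
                    max(abs(cr_f$res))))
  list(model = model, report = report)
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf(paste0("<fit_report:%s/%s> converged=%s after %d sweeps",
                     "; max |residual| %.3g%s\n"),
              x$model_class %||% "independent", x$engine, x$converged,
              x$n_sweeps, x$max_abs_residual %||% NA,
              if (!is.null(x$z_width) && is.finite(x$z_width %||% NA))
                sprintf("; z width %.2f", x$z_width) else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train/test likelihood audit of a fitted model
#'
#' Per-neuron average log-likelihood (`mean log P(word) / N`, nats) on
#' the training and withheld test repeats; their ratio near 1 means no
#' overfitting. Also recomputes constraint residual z-scores against
#' the training statistics from a fresh Metropolis run.
#'
#' @param model a fitted [maxent_model] with `log_z` set (enumeration,
#'   the silence trick, or the density of states can supply it).
#' @param train,test disjoint-repeat [spike_raster]s.
#' @param n_bootstrap bootstrap resamples for the training error bars.
#' @param mc_samples fresh-MC sample count for the residual audit
#'   (0 skips it).
#' @param seed RNG seed.
#' @return list with per-neuron log-likelihoods, their ratio, and
#'   optionally the fresh-MC z-scores.
#' @export
evaluate_fit <- function(model, train, test, n_bootstrap = 20L,
                         mc_samples = 0L, seed = NULL) {
  if (is.null(model$log_z)) {
    if (model$n_neurons <= 20) {
      model$log_z <- enumerate_exact(model, moments = FALSE)$log_z
    } else {
      stop(paste("log_z missing: obtain it by exact enumeration (N <= 20),",
                 "partition_and_entropy_from_silence(), or",
                 "entropy_from_density_of_states()"))
    }
  }
  ll <- function(raster) {
    E <- energy_words_cpp(t(raster$values), model$h, model$J, model$V)
    mean(-E - model$log_z) / model$n_neurons
  }
  ll_train <- ll(train)
  ll_test <- ll(test)
  out <- list(ll_train = ll_train, ll_test = ll_test,
              ratio = ll_test / ll_train)
  if (mc_samples > 0) {
    st <- moment_stats(train, n_bootstrap = n_bootstrap, seed = seed)
    cons <- build_constraints(st, model$model_class, 0)
    sm <- metropolis_sample(model, as.integer(mc_samples), seed = seed)
    Sb <- sm$samples
    storage.mode(Sb) <- "double"
    ex <- batch_expectations(Sb, rowSums(Sb), rep(1, nrow(Sb)), cons)
    cr <- constraint_residuals(ex, cons)
    out$z <- cr$z
    out$z_width <- sd(cr$z[is.finite(cr$z)])
  }
  out
}

#' Lowest-order perturbative couplings
#'
#' The independent-pair (lowest order) approximation
#' `J_ij = log[ m_ij (1 - p_i - p_j + m_ij) /
#'              ((p_i - m_ij)(p_j - m_ij)) ]`,
#' which is the exact solution for an isolated pair and the standard
#' low-order expansion point. Used for comparison against the exact
#' fitted couplings; in strongly interacting networks the two
#' increasingly disagree with N.
#'
#' @param stats an [moment_stats()] result.
#' @return NxN matrix; entries with non-positive log arguments are
#'   `NA` (flagged undefined), diagonal 0.
#' @export
perturbative_couplings <- function(stats) {
  p <- stats$p
  if (any(p <= 0 | p >= 1)) stop("rates must lie strictly in (0, 1)")
  m <- stats$m
  N <- length(p)
  num <- m * (1 - outer(p, p, `+`) + m)
  den <- (outer(p, rep(1, N)) - m) * (outer(rep(1, N), p) - m)
  J <- matrix(NA_real_, N, N)
  ok <- num > 0 & den > 0
  J[ok] <- log(num[ok] / den[ok])
  diag(J) <- 0
  J
}
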