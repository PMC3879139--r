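#' Maximum entropy model of a binary population
#'
#' Container for the three model classes. The energy of a word
#' `s in {0,1}^N` is
#' `E(s) = -sum_i h_i s_i - 1/2 sum_{i!=j} J_ij s_i s_j + V(K)`,
#' `K = sum_i s_i`, and `P(s) = exp(-E(s)) / Z`. Fields `h` are in
#' natural-log (logit) units; `J` is symmetric with zero diagonal and
#' all-zero for the independent class; `V` is a potential over
#' `K = 0..N`, all-zero unless `k_pairwise`. In the canonical gauge
#' `V(0) = 0`, so the all-silent word has exactly zero energy and
#' `Z = 1 / P(silence)`.
#'
#' @param h length-N field vector.
#' @param J symmetric NxN coupling matrix, zero diagonal; `NULL` for 0.
#' @param V length-(N+1) synchrony potential; `NULL` for 0.
#' @param model_class one of `"independent"`, `"pairwise"`,
#'   `"k_pairwise"`.
#' @param log_z optional cached log partition function.
#' @param gauge gauge tag, default `"canonical"`.
#' @return object of class `maxent_model`.
#' @export
maxent_model <- function(h, J = NULL, V = NULL,
                         model_class = c("k_pairwise", "pairwise",
                                         "independent"),
                         log_z = NULL, gauge = "canonical") {
  model_class <- match.arg(model_class)
  N <- length(h)
  if (is.null(J)) J <- matrix(0, N, N)
  if (is.null(V)) V <- numeric(N + 1)
  J <- as.matrix(J)
  if (!isTRUE(all.equal(J, t(J), tolerance = 1e-10)))
    stop("J must be symmetric")
  J <- (J + t(J)) / 2
  if (any(abs(diag(J)) > 1e-12)) stop("J must have zero diagonal")
  diag(J) <- 0
  if (length(V) != N + 1) stop("V must have length N + 1")
  if (model_class == "independent" && any(J != 0))
    stop("independent model cannot have couplings")
  if (model_class != "k_pairwise" && any(V != 0))
    stop("only the k_pairwise class carries a V(K) potential")
  if (identical(gauge, "canonical") && abs(V[1]) > 1e-12)
    stop("canonical gauge requires V(0) = 0")
  structure(list(model_class = model_class, n_neurons = N,
                 h = as.numeric(h), J = J, V = as.numeric(V),
                 log_z = log_z, gauge = gauge),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("<maxent_model:%s> N=%d, gauge=%s%s\n", x$model_class,
              x$n_neurons, x$gauge,
              if (is.null(x$log_z)) "" else
                sprintf(", log Z=%.4f", x$log_z)))
  invisible(x)
}

as_word_matrix <- function(pattern, N) {
  if (is.matrix(pattern)) w <- pattern else w <- matrix(pattern, nrow = 1)
  if (ncol(w) != N) stop("pattern length does not match model size")
  if (!all(w %in% c(0, 1))) stop("pattern entries must be 0 or 1")
  storage.mode(w) <- "integer"
  w
}

#' Energy of binary words under a model
#'
#' `E(s) = -sum h_i s_i - 1/2 sum_{i!=j} J_ij s_i s_j + V(K)`. In the
#' canonical gauge the all-silent word has energy 0.
#' @param model a [maxent_model].
#' @param pattern binary vector of length N, or a matrix with one word
#'   per row.
#' @return numeric vector of energies.
#' @export
energy <- function(model, pattern) {
  w <- as_word_matrix(pattern, model$n_neurons)
  energy_words_cpp(w, model$h, model$J, model$V)
}

#' Effective field on one neuron
#'
#' The energy difference between the neuron's silent and spiking
#' states with the rest of the word held fixed,
#' `h_eff,i = E(s_i = 0) - E(s_i = 1)`
#' `        = h_i + sum_{j != i} J_ij s_j - [V(K'+1) - V(K')]`,
#' with `K'` the spike count among the other neurons. Defined via the
#' energy difference, so it is exact for every model class.
#' @param model a [maxent_model].
#' @param pattern binary word (vector) or matrix of words (rows).
#' @param neuron index of the neuron.
#' @return numeric vector, one value per word.
#' @export
effective_field <- function(model, pattern, neuron) {
  N <- model$n_neurons
  if (neuron < 1 || neuron > N) stop("neuron index out of range")
  w <- as_word_matrix(pattern, N)
  w0 <- w
  w0[, neuron] <- 0L
  w1 <- w
  w1[, neuron] <- 1L
  energy_words_cpp(w0, model$h, model$J, model$V) -
    energy_words_cpp(w1, model$h, model$J, model$V)
}

# Effective fields for all neurons over many words at once
# (words: T x N matrix). Used by the prediction module.
effective_fields_all <- function(model, words) {
  N <- model$n_neurons
  W <- as_word_matrix(words, N)
  storage.mode(W) <- "double"
  F_ <- W %*% model$J            # J_ii = 0, so self term drops out
  K <- rowSums(W)
  K_not <- K - W                 # spike count among the other neurons
  dV <- matrix(model$V[K_not + 2] - model$V[K_not + 1], nrow(W), N)
  matrix(model$h, nrow(W), N, byrow = TRUE) + F_ - dV
}

#' Conditional spike probability given the effective field
#'
#' The logistic link `P(s_i = 1 | rest) = 1 / (1 + exp(-h_eff))`,
#' which is exact for every model in this family.
#' @param h_eff effective field value(s).
#' @export
conditional_spike_probability <- function(h_eff) plogis(h_eff)

#' Fix the gauge of a K-pairwise model
#'
#' The K-pairwise parametrization is degenerate: a uniform offset of
#' all fields adds a term linear in `K` to `V`, and a uniform offset of
#' all couplings adds a quadratic term. This removes the best-fit
#' (least squares over `K = 0..N`) linear and quadratic component
#' `a + bK + cK^2` from `V`, absorbs it into `h <- h - (b + c)` and
#' `J <- J - 2c` off-diagonal (valid identities because `s^2 = s`),
#' and pins `V(0) = 0`; constants move into `log_z`. Every pattern
#' probability is unchanged.
#' @param model a `k_pairwise` [maxent_model].
#' @return gauge-fixed [maxent_model].
#' @export
gauge_fix <- function(model) {
  if (model$model_class != "k_pairwise")
    stop("gauge_fix applies to k_pairwise models only")
  N <- model$n_neurons
  K <- 0:N
  fit <- lm(model$V ~ K + I(K^2))
  b <- coef(fit)[["K"]]
  cc <- coef(fit)[["I(K^2)"]]
  V <- model$V - (coef(fit)[[1]] + b * K + cc * K^2)
  h <- model$h - (b + cc)
  J <- model$J - 2 * cc
  diag(J) <- 0
  shift <- V[1]                  # pin V(0) = 0
  V <- V - shift
  log_z <- model$log_z
  # E -> E + (total removed constant); P(s) unchanged, Z rescales
  const <- coef(fit)[[1]] + shift
  if (!is.null(log_z)) log_z <- log_z + const
  maxent_model(h, J, V, "k_pairwise", log_z = log_z,
               gauge = "canonical")
}

#' Fraction of frustrated triplets
#'
#' A triplet (i, j, k) with all three couplings nonzero is frustrated
#' when `J_ij J_jk J_ki < 0`: no joint assignment of the three neurons
#' satisfies all pairwise preferences. Returns the frustrated fraction
#' among fully-interacting triplets.
#' @param model a pairwise or k_pairwise [maxent_model].
#' @export
frustration_fraction <- function(model) {
  if (model$model_class == "independent")
    stop("frustration is defined for interacting models")
  N <- model$n_neurons
  if (N < 3) stop("need at least 3 neurons")
  tr <- combn(N, 3)
  J <- model$J
  prod3 <- J[cbind(tr[1, ], tr[2, ])] * J[cbind(tr[2, ], tr[3, ])] *
    J[cbind(tr[3, ], tr[1, ])]
  interacting <- J[cbind(tr[1, ], tr[2, ])] != 0 &
    J[cbind(tr[2, ], tr[3, ])] != 0 & J[cbind(tr[3, ], tr[1, ])] != 0
  if (!any(interacting)) return(NaN)
  mean(prod3[interacting] < 0)
}

# ---- model disk format ----------------------------------------------

#' Write a model as structured key-value text
#'
#' Layout: header keys (`n_neurons`, `model_class`, `gauge`, optional
#' `log_z`), then `h:` with N comma-separated values, `V:` with N+1
#' values, and one `J i j value` line per nonzero upper-triangle
#' coupling.
#' @param model a [maxent_model].
#' @param path output path.
#' @export
write_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("n_neurons: %d", model$n_neurons),
               sprintf("model_class: %s", model$model_class),
               sprintf("gauge: %s", model$gauge)), con)
  if (!is.null(model$log_z))
    writeLines(sprintf("log_z: %.17g", model$log_z), con)
  writeLines(sprintf("h: %s",
                     paste(sprintf("%.17g", model$h), collapse = ",")), con)
  writeLines(sprintf("V: %s",
                     paste(sprintf("%.17g", model$V), collapse = ",")), con)
  ut <- which(upper.tri(model$J) & model$J != 0, arr.ind = TRUE)
  if (nrow(ut) > 0)
    writeLines(sprintf("J %d %d %.17g", ut[, 1], ut[, 2],
                       model$J[ut]), con)
  invisible(path)
}

#' Read a model written by [write_model]
#' @param path file path.
#' @export
read_model <- function(path) {
  ln <- readLines(path)
  kv <- function(key) {
    hit <- grep(paste0("^", key, ":"), ln, value = TRUE)
    if (length(hit) == 0) return(NULL)
    trimws(sub("^[^:]+:", "", hit[1]))
  }
  h <- as.numeric(strsplit(kv("h"), ",")[[1]])
  V <- as.numeric(strsplit(kv("V"), ",")[[1]])
  N <- as.integer(kv("n_neurons"))
  J <- matrix(0, N, N)
  jl <- grep("^J ", ln, value = TRUE)
  if (length(jl) > 0) {
    parts <- do.call(rbind, strsplit(jl, " "))
    i <- as.integer(parts[, 2])
    j <- as.integer(parts[, 3])
    v <- as.numeric(parts[, 4])
    J[cbind(i, j)] <- v
    J[cbind(j, i)] <- v
  }
  lz <- kv("log_z")
  maxent_model(h, J, V, kv("model_class"),
               log_z = if (is.null(lz)) NULL else as.numeric(lz),
               gauge = kv("gauge"))
}
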