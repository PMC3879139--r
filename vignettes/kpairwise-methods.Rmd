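---
title: "Maximum entropy models of spiking populations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum entropy models of spiking populations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model family

A population of $N$ neurons, observed in time bins of width
$\Delta\tau$ (20 ms by default), is reduced to binary words
$\sigma \in \{0,1\}^N$: $\sigma_i = 1$ if neuron $i$ fired at least
once in the bin. The package fits the least-structured (maximum
entropy) distribution consistent with chosen measured statistics. All
three classes share the Boltzmann form
$P(\sigma) = Z^{-1} e^{-E(\sigma)}$ with

$$E(\sigma) \;=\; -\sum_i h_i \sigma_i
  \;-\; \tfrac{1}{2}\sum_{i \neq j} J_{ij}\sigma_i\sigma_j
  \;+\; V(K), \qquad K = \sum_i \sigma_i ,$$

* **independent**: only the firing rates $\langle\sigma_i\rangle$ are
  constrained; $J = 0$, $V = 0$, and $h_i = \mathrm{logit}(p_i)$ in
  closed form;
* **pairwise (Ising)**: rates plus all second moments
  $\langle\sigma_i\sigma_j\rangle$; fields $h$ and couplings $J$;
* **K-pairwise**: additionally the full synchrony distribution
  $P(K)$, via the global potential $V(K)$ — about $N$ extra
  parameters that act like a soft global inhibition.

Spins are coded $\{0,1\}$ throughout (never $\pm1$): the identities
$\sigma^2 = \sigma$ and $K^2 = K + \sum_{i\neq j}\sigma_i\sigma_j$
that underlie the gauge fixing hold only in this coding.

**Gauge.** The K-pairwise parametrization is degenerate: uniform
offsets of $h$ (or $J$) are equivalent to linear (or quadratic) terms
in $V$. `gauge_fix()` removes the least-squares linear+quadratic part
of $V$ over $K = 0..N$, absorbs it into $h$ and $J$, and pins
$V(0) = 0$, so the all-silent word has exactly zero energy and
$Z = 1/P(\text{silence})$. Pattern probabilities are invariant (tested
by enumeration to $10^{-12}$). The absorption direction is
$h \leftarrow h - (b + c)$, $J \leftarrow J - 2c$ for a removed
$a + bK + cK^2$; the sign follows from $V$ entering $E$ with $+$.

## Inference

`fit_model()` performs damped iterative constraint matching. Within a
sweep, parameters are visited in greedy order (largest residual
relative to its error bar first) and each receives a log-ratio
coordinate step, e.g. $\Delta J_{ij} = \eta \log
(\tilde m_{ij} / m_{ij}^{\text{model}})$ with $\eta = 0.5$, clipped at
1. Model expectations are maintained

* **exact engine** ($N \le 20$): a probability vector over all $2^N$
  words, reweighted multiplicatively after every single-parameter
  update — the sequential scheme is exact and cheap;
* **MC engine**: a Metropolis sample batch with importance weights
  (histogram reweighting). The batch is refreshed when the cumulative
  parameter change exceeds a trust region (default 3) or when the
  weight effective sample size falls below 40% of the batch. Batches
  grow geometrically to `n_max` (2e5 by default).

Constraints whose residual is already below one (combined) error bar
are skipped within a sweep: updating them would only inject sampling
noise. Once the batch has reached its cap the step size is annealed
($\eta \leftarrow 0.85\,\eta$, floor $0.05$), and the parameters of
the last `avg_tail` sweeps are averaged — a stochastic-approximation
tail average that cancels the residual MC jitter. The MC sampling
noise acts as implicit regularization; an explicit L1 analogue is
reproducible, so couplings also carry a proximal threshold
proportional to the bootstrap error of their moment
(`l1_strength`, default 0.25 error bars; 0 disables).

**Convergence semantics.** The target is "constraints matched to
within measurement precision": every residual $z$-score (model minus
data over the data error bar, with the audit's own MC error included)
below `z_tol = 2`, checked on a fresh final sample twice the size of
the largest batch. With many hundreds of constraints the *maximum*
|z| of even a perfect model sits at the extreme-value floor
$\approx\sqrt{2\log n_{\text{con}}}$ times the MC-noise fraction, so
near-threshold non-convergence warnings at large $N$ should be read
together with the reported z-width (which is $\approx 0.7$–$1.2$ on a
good fit, matching the measurement-precision criterion). Residuals
and the convergence trace are always returned; failure warns rather
than silently succeeding.

Rates of exactly 0 or 1 abort the independent fit unless a half-count
pseudocount is requested (off by default). Interior zeros of the
empirical $P(K)$ are floored at $0.5/T$; $V$ beyond the largest
observed $K$ is extrapolated linearly upward (capped), which only
suppresses states the data say are absent.

## Entropy and partition function, three ways

1. **Heat capacity.** The one-parameter family
   $P_T \propto e^{-E/T}$ gives $C(T) = \mathrm{Var}_T(E)/T^2$ and
   $S(1) = \int_0^1 C/T\,dT$, or equivalently
   $S(1) = N\log 2 - \int_1^\infty C/T\,dT$. The integrand is sampled
   on a geometric grid (100 points/decade, $T\in[0.02,1]$ or
   $[1,30]$) and integrated by trapezoid in $\log T$, where it is
   smooth. Truncation is bounded and reported: below $T_{\min}$ a
   gapped model is frozen (remainder $\lesssim C(T_{\min})$); above
   $T_{\max}$, $C \to \mathrm{Var}_{\text{unif}}(E)/T^2$ gives a
   $\mathrm{Var}_{\text{unif}}(E)/2T_{\max}^2$ tail that is added.
   The $0\!\to\!1$ direction assumes a unique ground state
   ($S(0)=0$); for degenerate cases (e.g. any $p_i = 1/2$ exactly,
   or the uniform model) use `direction = "1toInf"`.
2. **Wang–Landau.** A flat-histogram walk estimates $\log g(E)$ on a
   fixed energy grid bracketed exactly at small $N$ and by padded
   greedy-descent/ascent extremes plus sampled bulk otherwise. Three
   modifications, each motivated by a measured bias on exact
   references: an exploration phase holds $\ln f = 1$ until the
   visited-bin set stops growing, then freezes the support (premature
   refinement biases late-discovered tails; float drift of the
   incrementally updated energy can otherwise split discrete levels
   across bin edges); the entropy computation represents each bin by
   its visit-weighted mean energy rather than its center (removes an
   $O(\text{bin width})$ bias in $\langle E\rangle$); and `n_runs`
   independent walkers are averaged, because the converged WL
   estimate has a run-to-run error that `ln_f_final` does not control.
   $g$ is normalized to $\sum g = 2^N$ over the visited support;
   then $Z=\sum g e^{-E}$ and $S = \langle E\rangle + \log Z$.
3. **Silence route.** In the canonical gauge
   $\log Z = -\log P(\text{silence})$ — for K-pairwise fits the
   silence probability is a matched constraint — and
   $S = \langle E \rangle + \log Z$ with $\langle E\rangle$ from one
   $T=1$ Metropolis run. Standard errors combine the autocorrelation-
   corrected errors of $\hat p_0$ and $\langle E\rangle$.

Entropies are computed in nats and reported in bits; conversion
happens only at the boundary. On a fitted $N=30$ K-pairwise model the
three routes agree to a few tenths of a percent (the acceptance suite
asserts < 1%), and each route is separately validated against closed
forms (independent: $\sum_i H(p_i)$; uniform: $N$ bits; equal-field
multiplicities: binomial coefficients).

## Energy landscape

Greedy descent sweeps neurons in ascending index and keeps any single
flip that *strictly* lowers the energy (ties rejected, so plateaus
cannot cycle); it terminates because energy strictly decreases on a
finite space, and every output is audited against all $N$ single-flip
perturbations. `census_basins()` descends from each recorded word, so
basin sizes partition the data by construction — the census counts
only minima reachable from observed patterns, not all minima of the
Hamiltonian. Transition exploration runs Metropolis walks from a
metastable state, re-descending after every accepted flip; the
barrier is the path's maximum energy minus the start energy, and $L$
counts attempted flips. Overlaps between patterns use the cosine
normalization $q = \sigma\cdot\sigma' / \sqrt{K K'}$ (all-silent
flagged undefined; Hamming similarity available). Basin dynamics
reduce each time bin to its basin index and report per-bin occupancy
probabilities across repeats, the coherence of the dominant
non-silent basin, and an exponential fit to the mean indicator
autocorrelation.

## The synthetic world

Dense retinal recordings of the relevant scale are generally not
redistributable, so the generator emulates their statistical
structure and every claim a
green test establishes is relative to that world:

* $N$ up to ~160 neurons, mean spike probability 0.031 per 20 ms bin
  with a lognormal-like spread (`h_sd = 0.7`, rates roughly 1–10%),
  recentred by $-h_{sd}^2/2$ so the population mean stays on target;
* couplings i.i.d. symmetric Gaussian, both signs, frustration
  fraction ~1/2. The scale (sd 0.55) was calibrated once by pilot
  sampling so that the median $|c_{ij}|$ at $N = 100$ lands at the
  recording-like 0.01 (measured 0.0103, 90% range $[-0.018, 0.053]$,
  mean rate 0.033). Fields get a second-order mean-field
  compensation so realized rates track the targets;
* repeat structure 297 × 953 bins; static rasters record every 3
  Metropolis sweeps so that the $T \approx 2.8\times10^5$ words are
  effectively independent samples;
* optional repeat-locked drive: sparse Gaussian bumps (default ~24
  per repeat, 2–3 bins wide) added to all fields, produced by a
  continuously running non-stationary chain — this yields the
  PSTH transients and the repeat-locked basin revisits that the
  prediction and basin-dynamics modules test.

What the generator does **not** emulate: stimulus-induced positive
correlation skew (the signed median $c_{ij}$ of static worlds is
~0), refractoriness and other within-bin temporal structure, spike
sorting artifacts, and recording-scale higher-order structure (e.g.
the dichotomized-Gaussian coincidence *under*-estimation reported at
$N \gtrsim 100$ does not emerge at $N \le 10$; the test suite asserts
only the robust ordering that a K-pairwise fit reproduces coincidence
probabilities far better than the DG surrogate).

The dichotomized Gaussian itself solves
$\Phi(-\gamma_i) = p_i$ for thresholds and root-finds the latent
pairwise correlation on the bivariate-normal orthant probability
(numerical integration, tolerance $10^{-10}$); infeasible moments are
flagged per pair and a non-PD latent matrix is repaired by eigenvalue
clipping with a report.

## Numerical choices and degenerate inputs

* Metropolis: single uniform spin flip, acceptance
  $\min(1, e^{-\Delta E/T})$; budgets in sweeps of $N$ attempts;
  default burn-in $100N$ sweeps; all randomness through R's RNG so a
  single seed reproduces everything.
* Equilibration: cross-chain two-sample KS tests on energy and $K$ at
  level 0.05 (Bonferroni), after thinning by the integrated
  autocorrelation time and a small common jitter (the sampled
  energies are atoms whose float representation drifts between
  chains); plus a half-versus-half drift check.
* Bins are half-open $[t\Delta\tau, (t+1)\Delta\tau)$, 0-based; bins
  with multiple spikes record 1.
* Bootstrap errors resample whole repeats (bins within a repeat are
  dependent); `effective_sample_size()` quantifies exactly that
  dependence.
* Neurons with $p_i \in \{0,1\}$: correlation entries flagged `NA`
  and listed, never silently zeroed.
* Coincidence estimators pair bins without replacement; the
  with-replacement variant differs by $O(1/T)$.

## Known limitations

* The exact engine and enumeration stop at $N \le 20$–$25$ (memory
  and time); beyond that everything is MC with reported errors.
* The heat-capacity $0\!\to\!1$ route silently assumes a unique
  ground state; the package cannot detect near-degeneracy cheaply, so
  the two-direction agreement check is the practical safeguard.
* Basin censuses depend on the descent rule (ascending index,
  strict); patterns on ridges can be assigned differently under other
  rules, though metastability itself is rule-independent.
* The MC learner's `converged` flag is conservative at large
  constraint counts (see Inference above).
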