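---
title: "Designing b-value protocols for diffusion kurtosis imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing b-value protocols for diffusion kurtosis imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dkidesign)
```

## The model and its assumptions

`dkidesign` works with the mono-exponential kurtosis representation of
the directionally averaged diffusion-weighted signal,

$$S(b) = S_0 \, e^{-bD + K b^2 D^2 / 6},$$

a truncated cumulant expansion in which $D$ (um^2/ms) is the apparent
diffusion coefficient and $K$ (dimensionless) the excess kurtosis of
the water displacement distribution; $K = 0$ recovers Gaussian
(mono-exponential) decay. Three assumptions matter throughout:

* **Validity bound.** The truncation is only meaningful up to
  $b = 3/(DK)$ — beyond it the quadratic term makes the model signal
  turn upward. In the dimensionless encoding variable $x = bD$ the
  bound is $x \le 3/K$ (`max_allowable_bd()`), and the optimizer never
  places points beyond it unless the user overrides `bd_max`.
* **Gaussian noise.** Estimation errors are propagated assuming
  additive Gaussian noise of standard deviation
  $\sigma_0 = S_0/\mathrm{SNR}$, equal at every b value. Magnitude MR
  noise is Rician, but for SNR above roughly 4 the Gaussian
  approximation is adequate; the command-line `evaluate` warns below
  that level, and the Monte-Carlo module can simulate the Rician case
  exactly.
* **Scale invariance.** $S$ depends on $b$ and $D$ only through $bD$,
  so every design question can be posed in $bD$ units and rescaled:
  with $b$ in s/mm^2 and $D$ in um^2/ms, $bD = b \cdot D \cdot 10^{-3}$.
  A design is therefore portable across tissues by scaling with the
  target $D$.

## Error propagation

For a protocol $\{b_1, \dots, b_m\}$ the m x 3 design matrix $A$ stacks
the partial derivatives of the signal with respect to $(S_0, D, K)$,
each divided by $\sigma_0$ (`dki_design_matrix()`; column order is
fixed so that the second and third diagonal elements of the covariance
matrix correspond to $D$ and $K$). The covariance of any unbiased
least-squares estimate is bounded by

$$Q = (A^\top A)^{-1},$$

and the package reports relative errors
$\mathrm{CoV}_i = \sqrt{Q_{ii}} / a_i$ normalised by the target
parameter values, plus the trace of $Q$ as a total mean squared error
(`dki_crlb()`). At SNR 20 the b = 0 parameter always has
$\mathrm{CoV}_{S_0} \approx 1/\mathrm{SNR} = 0.05$, a useful sanity
check. When $K = 0$ its CoV is undefined and reported as `Inf` rather
than an error, so sweeps across $K$ degrade gracefully.

Two closed-form rescalings avoid re-evaluation (`rescale_cov()`): CoVs
scale as $1/\mathrm{SNR}$, and signal lost to transverse relaxation at
echo time $T_E$ multiplies every CoV by $e^{T_E/T_2}$.

### Numerical choices

* $A^\top A$ is inverted by Cholesky factorisation after an explicit
  eigenvalue check; a design is declared singular when the smallest
  eigenvalue is non-positive or the condition number exceeds `1e12`
  (default `cond_tol`). Nearly coincident b values thus fail loudly
  with the offending protocol named, instead of returning absurd CoVs.
  Fewer than three distinct b values is always singular: the model has
  three parameters.
* Inside the optimizer's hot loop the 3 x 3 inverses are computed from
  cofactors in vectorised form (millions of candidates per search);
  candidates with non-positive determinant or non-positive variance
  cofactors are marked singular and skipped, never propagated.

## The optimizer

`dki_optimize()` minimises one of `cov_d`, `cov_k`,
`cov_d_plus_cov_k` (default: both diffusion parameters matter) or
`mse` over designs drawn from a uniform grid on $[0, bd_{max}]$.

* **Grid step 0.05** in $bD$ by default: fine enough that published
  optima (0.75, 0.9, 0.95, 1.05, 1.1, ...) lie on the lattice, coarse
  enough that an exhaustive 3-point search over the widest bound
  ($3/K = 10$ for $K = 0.3$, 201 grid points, ~1.4 million multisets)
  takes about a second.
* **Search bound** $bd_{max} = \min(3/K,\; b_{max}^{scanner} \cdot D
  \cdot 10^{-3})$: the physical scanner limit can bind before the
  model bound, which is precisely the regime where kurtosis errors
  blow up for low-$D$, low-$K$ tissues.
* **$b = 0$ is a grid point but never forced** into designs. Every
  known optimum contains it, and letting it emerge from the search is
  a useful internal check.
* **Support points.** For $n \ge 4$ the default search enumerates
  designs with at most three distinct b values (multiplicities summing
  to $n$) — the classical support bound for a three-parameter model,
  obeyed by every optimum we have ever observed. Exhaustive
  enumeration remains available (`search_mode = "exhaustive"`) and the
  test suite confirms both modes agree on coarse grids.
* **Determinism.** Candidates are enumerated in lexicographic order
  and ties are broken toward the lexicographically smallest sorted
  design, so identical inputs give bit-identical results.

A recurring structural result: optimized designs always include at
least one acquisition at $bd_{max}$ (the kurtosis term is weighted by
$b^2$, so the bound is where $K$ is encoded), and they beat equally
spaced designs (`equally_spaced_protocol()`) by a widening margin as
$n$ grows. `robustness_sweep()` re-evaluates a fixed design over a
range of true $D$ or $K$ to show the advantage persists when the
tissue deviates from the design target.

## Monte-Carlo verification

`dki_montecarlo()` simulates the full pipeline: noise-free signals for
the protocol, plus Gaussian noise of SD $\sigma_0$ — or Rician
magnitudes $\sqrt{(S + n_1)^2 + n_2^2}$ with independent
$n_i \sim N(0, \sigma_0^2)$, which is exactly the Rician density with
offset $S$ and scale $\sigma_0$ — then a box-constrained
Levenberg-Marquardt refit (`minpack.lm::nls.lm` with analytic
Jacobian) per repetition.

Choices the simulation depends on, all overridable:

* **Initialisation**: true parameters + 10% (default), so the
  experiment measures estimator noise rather than global-search
  failures; a data-driven log-linear start (quadratic regression of
  log-signal on b) is the alternative and is what `dki_fit()` uses
  when no start is given.
* **Bounds**: $S_0 \in (0, 10 S_0]$, $D \in (0, 10 D]$,
  $K \in [0, 10]$ — wide enough not to bind for well-posed designs at
  SNR 20, while keeping degenerate noise draws from running away.
* **Failure policy**: non-converged fits are discarded and counted by
  default (`"flag"` keeps them); more than 50% failures aborts with an
  error since the configuration is then pathological.
* **CoV definition**: sample SD divided by the *true* parameter value,
  matching the analytic normalisation; SD over the sample mean is
  reported alongside.

The test suite runs this verification at $10^4$ repetitions per design
over all eighteen reference optimized designs (a deliberate
compromise: the Monte-Carlo standard error of a CoV estimate,
$\approx \mathrm{CoV}/\sqrt{2 n_{reps}}$, is then under 1% relative,
while the whole suite stays around a minute).

### What the simulations do and do not confirm

The empirical CoVs of $S_0$ and $D$ reproduce the covariance-matrix
predictions within a few percent across all reference designs at
SNR 20 — the bound is effectively tight for those parameters. The
kurtosis estimate behaves differently, and the package's tests
document rather than hide this:

* For designs whose maximum point sits at the validity bound $3/K$,
  the sampling distribution of $\hat K$ at SNR 20 is visibly
  heavy-tailed: its moment-based CoV runs some 25-65% above the
  bound, although its interquartile-range-based spread matches well.
  The effect shrinks with noise (ratios near 1.0 by SNR 100): it is
  finite-SNR nonlinearity of the estimator, not an implementation
  artifact (the $D$ and $S_0$ columns of the very same fits agree with
  the bound).
* For low-kurtosis tissues ($K \le 0.5$) the predicted
  $\mathrm{CoV}_K$ is itself enormous (up to 1.5), the estimate
  distribution presses against any sane parameter bounds, and both the
  Gaussian/Rician distinction and the moment-based CoV become
  policy-dependent. Rician noise additionally biases $\hat K$ through
  the magnitude floor $\sigma_0\sqrt{\pi/2}$ at strongly attenuated
  high-b points, shrinking its spread relative to Gaussian noise.

Practical reading: covariance-matrix CoVs are a sound basis for
*ranking* designs and an accurate forecast for $D$; for $K$ they are a
lower bound that is optimistic near the validity bound at clinical
SNR.

### What the synthetic data does not emulate

The generator draws i.i.d. noise per acquisition on a single
directionally averaged signal. It does not model spatially correlated
noise, motion or eddy-current artifacts, multi-directional tensorial
kurtosis, perfusion contamination at low b, or higher cumulant terms
beyond $b^2$ — so passing tests demonstrate correctness of the error
calculus and the optimizer, not that a scanner protocol will achieve
these CoVs in vivo.

## Known limitations

* The error analysis is the Gaussian-noise bound; a Rician-aware
  (maximum-likelihood) analogue is out of scope, as is any Bayesian
  treatment.
* Designs optimize b values only; the number of averages per b value
  under a scan-time budget is not modelled (repeats in a design are
  the discrete version of averaging).
* Physical gradient limits enter only as a maximum b value; the
  gradient-waveform relation producing b is taken as given.
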