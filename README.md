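# dkidesign

Acquisition protocol design for diffusion kurtosis imaging (DKI).

## The problem

Directionally averaged diffusion-weighted MRI signals that deviate from
mono-exponential decay are routinely described by the kurtosis model

    S(b) = S0 * exp(-bD + K b^2 D^2 / 6)

where `b` is the diffusion weighting (s/mm^2), `D` the apparent
diffusion coefficient (um^2/ms) and `K` the dimensionless excess
kurtosis. Fitting this model to signals measured at a handful of b
values gives noisy estimates of `D` and `K`, and how noisy depends
strongly on *which* b values are acquired. `dkidesign` answers, for a
tissue with target values `(D, K)` and a given signal-to-noise ratio:

1. **How precise will my estimates be?** The covariance of the
   nonlinear least-squares estimates is bounded by `Q = (A'A)^-1`,
   where `A` is the m x 3 Jacobian of the signal with respect to
   `(S0, D, K)` scaled by the noise standard deviation
   `sigma0 = S0/SNR`. Per-parameter precision is reported as
   coefficients of variation, `CoV_i = sqrt(Q_ii) / a_i`.
2. **Which b values should I acquire?** A discrete grid search over the
   dimensionless encoding parameter `bD` finds the n-point design
   (repeats allowed) minimizing `CoV_D + CoV_K` (or `CoV_D`, `CoV_K`,
   trace MSE), subject to the model validity bound `bD <= 3/K` and any
   scanner maximum.
3. **Does the bound hold up in practice?** A Monte-Carlo module
   simulates noisy acquisitions (Gaussian or Rician magnitude noise),
   refits the model by Levenberg-Marquardt least squares, and reports
   empirical CoVs for comparison.

Because the signal depends on `b` and `D` only through their product,
designs are expressed in `bD` units and transfer to any tissue: a
design point `bD = 2` means `b = 2000 s/mm^2` where `D = 1 um^2/ms`.

## Worked example

Optimize a 4-point acquisition for a tissue with `D = 1 um^2/ms`,
`K = 1` at SNR 20, then verify by simulation:

```r
library(dkidesign)
opt <- dki_optimize(4, dki_params(d = 1, k = 1), snr = 20)
print(opt)
#> Optimized acquisition design (n = 4, support_points search)
#>   target: D = 1, K = 1; SNR = 20; bD grid step 0.05 on [0, 3]
#>   best design (bD): {0, 0.95, 0.95, 3}
#>   cov_d_plus_cov_k = 0.2969; CoV(S0) = 0.05, CoV(D) = 0.1438, CoV(K) = 0.1531
#>   107970 candidates evaluated (0 singular skipped)

mc <- dki_montecarlo(opt$protocol, dki_params(d = 1, k = 1),
                     n_reps = 5000, seed = 7)
print(mc)
#> Monte-Carlo error estimate (gaussian noise, 5000 reps, 5000 used, 0 failed)
#>   empirical CoV (SD/true): S0 0.05049, D 0.1443, K 0.2063
#>   mean estimates: S0 1, D 0.9983, K 0.95 (true 1, 1, 1)
```

The optimum acquires one b = 0 image, duplicates an intermediate point
near `bD = 1` and places one acquisition at the validity bound
`bD = 3/K`: a 14% relative error in `D` and 15% in `K` is the best any
unbiased fit can do here. The simulation confirms the `S0` and `D`
predictions closely; the empirical spread of `K` exceeds its bound
because the kurtosis estimator is noticeably nonlinear at SNR 20 (see
the methods vignette).

Evaluating a conventional clinical protocol instead shows why design
matters — with `b = {0, 1000, 1500, 2000, 2500} s/mm^2` on a low-kurtosis
tissue (`D = 1`, `K = 0.6`):

```r
res <- dki_crlb(dki_protocol(c(0, 1000, 1500, 2000, 2500),
                             unit = "s_mm2", snr = 20),
                dki_params(d = 1, k = 0.6))
print(res)
#> Predicted estimation error (covariance-matrix bound)
#> Acquisition protocol: 5 b values [s/mm^2], SNR = 20
#>   0, 1000, 1500, 2000, 2500
#>   CoV(S0) = 0.04994, CoV(D) = 0.2147, CoV(K) = 0.7523, trace MSE = 0.2524
```

a 75% error in `K`: the scanner's maximum b (2500 s/mm^2, i.e.
`bD = 2.5`) falls far short of the validity bound `3/K = 5`, so the
kurtosis is barely encoded in the data.

Reference tables of optimized and equally spaced designs for
`K = 0.3 ... 1.5` and `n = 3, 4, 5` are produced by `protocol_table()`,
and a command-line front end is installed under `exec/`:

```sh
dkidesign evaluate --b 0,1000,1500,2000,2500 --unit s_mm2 --D 1 --K 0.6 --snr 20
dkidesign optimize --n 3 --D 1 --K 1.5 --out design.json
dkidesign tables --type both --out tables
```

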