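Package: dkidesign
Title: Acquisition Protocol Design for Diffusion Kurtosis Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Covariance-matrix (Cramer-Rao style) error analysis and b-value
    protocol optimization for the mono-exponential diffusion kurtosis signal
    model S = S0*exp(-bD + K*b^2*D^2/6). Evaluates coefficients of variation
    of the estimated parameters (S0, D, K) for a candidate set of b values
    from the inverse Gram matrix of the noise-scaled sensitivity (Jacobian)
    matrix, searches discrete bD grids for designs minimizing estimation
    error subject to the kurtosis-model validity bound bD <= 3/K and scanner
    limits, and verifies predicted errors by Monte-Carlo simulation with
    Gaussian or Rician noise and nonlinear least-squares refitting. Includes
    SNR and TE/T2 rescaling rules, robustness sweeps of a fixed design over
    tissue parameters, protocol table writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
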