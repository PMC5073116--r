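#' Predict the mono-exponential kurtosis signal
#'
#' Evaluates \eqn{S(b) = S_0 \exp(-bD + K b^2 D^2 / 6)}. The quadratic
#' term in the exponent captures the leading non-Gaussian correction to
#' mono-exponential diffusion decay; `K = 0` recovers the Gaussian
#' (ADC) model.
#'
#' @param b Numeric vector of diffusion weightings (>= 0).
#' @param params A [dki_params()] (or list with `s0`, `d`, `k`).
#' @param unit Unit of `b`: `"bd"` (dimensionless, `b` is bD and the
#'   exponent uses D = 1 relative diffusivity) or `"s_mm2"` (physical,
#'   bD = b * d * 1e-3).
#' @return Numeric vector of noise-free signals, same length as `b`.
#' @examples
#' p <- dki_params(d = 1, k = 1.5)
#' dki_signal(0, p)                       # = s0
#' dki_signal(2, p)                       # exp(-2 + 1.5*4/6) = exp(-1)
#' dki_signal(2000, p, unit = "s_mm2")    # same point, physical units
#' @export
dki_signal <- function(b, params, unit = c("bd", "s_mm2")) {
  unit <- match.arg(unit)
  params <- as_dki_params(params)
  stopifnot(is.numeric(b), all(is.finite(b)))
  if (any(b < 0)) stop("b values must be >= 0")
  bd <- if (unit == "bd") b else b * params$d * 1e-3
  params$s0 * exp(-bd + params$k * bd^2 / 6)
}

#' Noise-scaled parameter sensitivities of the kurtosis signal
#'
#' Returns the rows of the design (Jacobian) matrix: the partial
#' derivatives of the signal with respect to (S0, D, K), each divided by
#' the acquisition noise standard deviation `sigma0`. Column order is
#' fixed as (S0, D, K), so that downstream the second and third diagonal
#' elements of the covariance matrix are var(D) and var(K).
#'
#' @inheritParams dki_signal
#' @param sigma0 Acquisition noise standard deviation (> 0), usually
#'   `s0 / snr`.
#' @return An m x 3 numeric matrix (m = `length(b)`) with columns
#'   `s0`, `d`, `k`.
#' @details With x = bD and E = exp(-x + K x^2/6), the unscaled partials
#'   are (E, s0 E (-x + 2 K x^2/6)/D, s0 E x^2/6); the D column carries a
#'   1/D factor from the chain rule so that it is the derivative with
#'   respect to D in the units of `params$d` whatever the unit of `b`.
#' @examples
#' p <- dki_params(d = 1, k = 0)
#' dki_sensitivity(c(0, 1), p, sigma0 = 0.05)
#' @export
dki_sensitivity <- function(b, params, sigma0, unit = c("bd", "s_mm2")) {
  unit <- match.arg(unit)
  params <- as_dki_params(params)
  stopifnot(is.numeric(b), all(is.finite(b)),
            is.numeric(sigma0), length(sigma0) == 1L, is.finite(sigma0))
  if (any(b < 0)) stop("b values must be >= 0")
  if (sigma0 <= 0) stop("'sigma0' must be > 0")
  bd <- if (unit == "bd") b else b * params$d * 1e-3
  e <- exp(-bd + params$k * bd^2 / 6)
  a <- cbind(s0 = e,
             d = params$s0 * (-bd + 2 * bd^2 * params$k / 6) * e / params$d,
             k = params$s0 * (bd^2 / 6) * e)
  a / sigma0
}

#' Build the design matrix of a protocol
#'
#' Stacks [dki_sensitivity()] rows for every b value of a protocol
#' (repeats contribute separate, identical rows) with
#' `sigma0 = s0 / snr` taken from the protocol's SNR.
#'
#' @param protocol A [dki_protocol()].
#' @param params A [dki_params()].
#' @return An object of class `"dki_design_matrix"`: list with elements
#'   `a` (m x 3 matrix), `sigma0`, `bd` (dimensionless weightings),
#'   `protocol` and `params`.
#' @examples
#' A <- dki_design_matrix(dki_protocol(c(0, 0.75, 2)), dki_params(d = 1, k = 1.5))
#' dim(A$a)
#' @export
dki_design_matrix <- function(protocol, params) {
  stopifnot(inherits(protocol, "dki_protocol"))
  params <- as_dki_params(params)
  sigma0 <- params$s0 / protocol$snr
  a <- dki_sensitivity(protocol$b, params, sigma0, unit = protocol$unit)
  structure(list(a = a, sigma0 = sigma0,
                 bd = protocol_bd(protocol, params),
                 protocol = protocol, params = params),
            class = "dki_design_matrix")
}

#' @export
print.dki_design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix: %d x 3, sigma0 = %g\n", nrow(x$a), x$sigma0))
  print(signif(x$a, 5))
  invisible(x)
}
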