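#' Tissue parameters of the kurtosis signal model
#'
#' Bundles the three parameters of the mono-exponential kurtosis model,
#' \eqn{S = S_0 \exp(-bD + K b^2 D^2 / 6)}, together with an optional
#' transverse relaxation time used only by [rescale_cov()].
#'
#' @param s0 Baseline signal at b = 0 (arbitrary units, > 0). All
#'   dimensionless error computations in this package normalise `s0` to 1.
#' @param d Diffusion coefficient in um^2/ms (> 0).
#' @param k Dimensionless (excess) kurtosis (>= 0). `k = 0` recovers pure
#'   mono-exponential decay.
#' @param t2 Optional transverse relaxation time in ms (> 0); only used when
#'   rescaling coefficients of variation for echo-time changes.
#'
#' @return An object of class `"dki_params"`: a named list with elements
#'   `s0`, `d`, `k` and (possibly `NULL`) `t2`.
#' @examples
#' dki_params(d = 0.86, k = 1.5)      # head-and-neck tumour target values
#' dki_params(d = 1, k = 0.6, t2 = 80)
#' @export
dki_params <- function(s0 = 1, d, k, t2 = NULL) {
  stopifnot(is.numeric(s0), length(s0) == 1L, is.finite(s0),
            is.numeric(d), length(d) == 1L, is.finite(d),
            is.numeric(k), length(k) == 1L, is.finite(k))
  if (s0 <= 0) stop("'s0' must be > 0")
  if (d <= 0) stop("'d' must be > 0")
  if (k < 0) stop("'k' must be >= 0")
  if (!is.null(t2)) {
    stopifnot(is.numeric(t2), length(t2) == 1L, is.finite(t2))
    if (t2 <= 0) stop("'t2' must be > 0")
  }
  structure(list(s0 = s0, d = d, k = k, t2 = t2), class = "dki_params")
}

#' @export
print.dki_params <- function(x, ...) {
  cat("Kurtosis model parameters\n")
  cat(sprintf("  S0 = %g, D = %g um^2/ms, K = %g", x$s0, x$d, x$k))
  if (!is.null(x$t2)) cat(sprintf(", T2 = %g ms", x$t2))
  cat("\n")
  invisible(x)
}

# internal: accept either a dki_params or a plain list-alike
as_dki_params <- function(params) {
  if (inherits(params, "dki_params")) return(params)
  dki_params(s0 = if (is.null(params$s0)) 1 else params$s0,
             d = params$d, k = params$k, t2 = params$t2)
}
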