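#' Covariance matrix of a design
#'
#' Inverts the Gram matrix of the noise-scaled sensitivity matrix,
#' Q = (A'A)^-1: the (Gaussian-noise) lower bound on the covariance of
#' the least-squares estimates of (S0, D, K). Designs whose Gram matrix
#' is singular or numerically near-singular (fewer than three distinct
#' b values, or nearly coincident ones) are rejected.
#'
#' @param a A [dki_design_matrix()] or a plain m x 3 numeric matrix.
#' @param cond_tol Condition-number threshold above which the design is
#'   declared singular (default 1e12).
#' @return Symmetric 3 x 3 covariance matrix with rows/columns
#'   (S0, D, K).
#' @examples
#' A <- dki_design_matrix(dki_protocol(c(0, 0.75, 2)), dki_params(d = 1, k = 1.5))
#' crlb_covariance(A)
#' @export
crlb_covariance <- function(a, cond_tol = 1e12) {
  b_label <- NULL
  if (inherits(a, "dki_design_matrix")) {
    b_label <- a$protocol$b
    a <- a$a
  }
  stopifnot(is.matrix(a), ncol(a) == 3L, is.numeric(a))
  if (nrow(a) < 3L) stop("design matrix needs at least 3 rows (m >= 3)")
  g <- crossprod(a)
  fail_singular <- function() {
    lbl <- if (is.null(b_label)) "" else
      sprintf(" (b values: %s)", paste(signif(b_label, 6), collapse = ", "))
    stop("singular design: the Gram matrix A'A is not invertible", lbl,
         "; at least 3 distinct, well-separated b values are required")
  }
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > cond_tol) fail_singular()
  q <- tryCatch(chol2inv(chol(g)), error = function(e) fail_singular())
  dimnames(q) <- list(c("s0", "d", "k"), c("s0", "d", "k"))
  (q + t(q)) / 2
}

#' Coefficients of variation from a covariance matrix
#'
#' Converts a parameter covariance matrix into per-parameter
#' coefficients of variation, CoV_i = sqrt(Q_ii) / a_i, normalised by
#' the target parameter values, plus the trace of Q (the total mean
#' square error). When `k = 0` the kurtosis CoV is undefined and
#' reported as `Inf`.
#'
#' @param q Symmetric positive-definite 3 x 3 matrix, parameter order
#'   (S0, D, K).
#' @param params A [dki_params()] providing the normalising values.
#' @return Named list with `cov` (named vector `s0`, `d`, `k`) and
#'   `mse` (trace of `q`).
#' @examples
#' crlb_covs(diag(c(1, 0.25, 0.04)), dki_params(s0 = 1, d = 0.5, k = 0.2))
#' @export
crlb_covs <- function(q, params) {
  params <- as_dki_params(params)
  stopifnot(is.matrix(q), all(dim(q) == 3L))
  dq <- diag(q)
  if (any(dq <= 0)) stop("'q' must have positive diagonal elements")
  covs <- c(s0 = sqrt(dq[[1]]) / params$s0,
            d = sqrt(dq[[2]]) / params$d,
            k = if (params$k > 0) sqrt(dq[[3]]) / params$k else Inf)
  list(cov = covs, mse = sum(dq))
}

#' Predicted estimation error of a protocol
#'
#' The central evaluation routine: builds the design matrix of a
#' protocol at target tissue parameters, inverts its Gram matrix and
#' reports the covariance matrix, per-parameter coefficients of
#' variation and trace mean square error. All quantities refer to the
#' precision with which (S0, D, K) can be estimated from signals
#' acquired with that protocol at the protocol's SNR, under Gaussian
#' noise (valid for SNR above about 4, below which the Rician character
#' of magnitude noise becomes material).
#'
#' @param protocol A [dki_protocol()] (>= 3 b values, >= 3 distinct).
#' @param params A [dki_params()] with the target tissue values.
#' @param cond_tol Passed to [crlb_covariance()].
#' @return An object of class `"dki_crlb"`: list with `q` (3 x 3
#'   covariance matrix), `cov` (named CoV vector), `mse`, `params`,
#'   `protocol`.
#' @examples
#' fit <- dki_crlb(dki_protocol(c(0, 0.75, 2)), dki_params(d = 1, k = 1.5))
#' fit$cov   # CoV_S0 = 0.05, CoV_D = 0.220, CoV_K = 0.145
#' @seealso [dki_optimize()] for searching designs, [rescale_cov()] for
#'   SNR and echo-time rescaling, [dki_montecarlo()] for simulation
#'   verification.
#' @export
dki_crlb <- function(protocol, params, cond_tol = 1e12) {
  stopifnot(inherits(protocol, "dki_protocol"))
  params <- as_dki_params(params)
  a <- dki_design_matrix(protocol, params)
  q <- crlb_covariance(a, cond_tol = cond_tol)
  cv <- crlb_covs(q, params)
  structure(list(q = q, cov = cv$cov, mse = cv$mse,
                 params = params, protocol = protocol),
            class = "dki_crlb")
}

#' @export
print.dki_crlb <- function(x, digits = 4, ...) {
  cat("Predicted estimation error (covariance-matrix bound)\n")
  print(x$protocol)
  cat(sprintf("  CoV(S0) = %s, CoV(D) = %s, CoV(K) = %s, trace MSE = %s\n",
              signif(x$cov[["s0"]], digits), signif(x$cov[["d"]], digits),
              signif(x$cov[["k"]], digits), signif(x$mse, digits)))
  invisible(x)
}

#' @export
summary.dki_crlb <- function(object, ...) {
  bd <- protocol_bd(object$protocol, object$params)
  cat("Covariance-matrix error analysis\n")
  print(object$params)
  print(object$protocol)
  if (object$params$k > 0) {
    bd_max <- 3 / object$params$k
    over <- sum(bd > bd_max + 1e-9)
    cat(sprintf("  validity bound bD <= 3/K = %g; %d point(s) beyond it\n",
                signif(bd_max, 4), over))
  }
  cat("  covariance matrix Q:\n")
  print(signif(object$q, 4))
  cat(sprintf("  CoV: S0 %.4g, D %.4g, K %.4g; trace MSE %.4g\n",
              object$cov[["s0"]], object$cov[["d"]], object$cov[["k"]],
              object$mse))
  invisible(object)
}

#' Rescale predicted errors for a different SNR or echo time
#'
#' Coefficients of variation scale inversely with SNR, and signal loss
#' from transverse relaxation at echo time TE multiplies them by
#' exp(TE/T2). This applies both rules without re-evaluating the design:
#' each CoV is multiplied by `(snr_from/snr_to) * exp(te/t2)` and the
#' covariance matrix by the square of that factor.
#'
#' @param x A `"dki_crlb"` result.
#' @param snr_from,snr_to SNR the result was computed at / is wanted at.
#'   `snr_from` defaults to the protocol's SNR.
#' @param te Optional echo time (ms); requires `t2`.
#' @param t2 Optional transverse relaxation time (ms); defaults to
#'   `x$params$t2` when present.
#' @return A `"dki_crlb"` with rescaled `q`, `cov`, `mse`, and the
#'   protocol's SNR updated to `snr_to`.
#' @examples
#' r <- dki_crlb(dki_protocol(c(0, 0.75, 2)), dki_params(d = 1, k = 1.5))
#' rescale_cov(r, snr_to = 30)$cov   # multiplied by 2/3
#' @export
rescale_cov <- function(x, snr_from = NULL, snr_to, te = NULL, t2 = NULL) {
  stopifnot(inherits(x, "dki_crlb"))
  if (is.null(snr_from)) snr_from <- x$protocol$snr
  stopifnot(is.numeric(snr_from), snr_from > 0,
            is.numeric(snr_to), snr_to > 0)
  fac <- snr_from / snr_to
  if (!is.null(te)) {
    if (is.null(t2)) t2 <- x$params$t2
    if (is.null(t2)) stop("'t2' is required when 'te' is given")
    stopifnot(is.numeric(te), te >= 0, is.numeric(t2), t2 > 0)
    fac <- fac * exp(te / t2)
  }
  x$cov <- x$cov * fac
  x$q <- x$q * fac^2
  x$mse <- x$mse * fac^2
  x$protocol$snr <- snr_to
  x
}
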