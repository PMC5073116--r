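#' Acquisition protocol: a multiset of b values plus SNR
#'
#' A protocol is an ordered multiset of diffusion weightings, either as
#' physical b values (s/mm^2) or as the dimensionless encoding parameter
#' bD (b value times diffusion coefficient; with b in s/mm^2 and D in
#' um^2/ms, bD = b * D * 1e-3). Repeated b values are permitted and
#' correspond to signal averaging at that weighting. The signal-to-noise
#' ratio is defined at b = 0 as mean signal over its standard deviation.
#'
#' @param b Numeric vector of diffusion weightings (>= 0, length >= 1).
#' @param unit `"bd"` for dimensionless bD, `"s_mm2"` for physical b values.
#' @param snr Signal-to-noise ratio at b = 0 (> 0). Defaults to 20, the
#'   reference value used throughout the package's design tables.
#' @return An object of class `"dki_protocol"`.
#' @examples
#' dki_protocol(c(0, 0.75, 2))                       # dimensionless
#' dki_protocol(c(0, 1000, 1500, 2000, 2500), unit = "s_mm2")
#' @export
dki_protocol <- function(b, unit = c("bd", "s_mm2"), snr = 20) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(b), length(b) >= 1L, all(is.finite(b)),
            is.numeric(snr), length(snr) == 1L, is.finite(snr))
  if (any(b < 0)) stop("b values must be >= 0")
  if (snr <= 0) stop("'snr' must be > 0")
  structure(list(b = as.numeric(b), unit = unit, snr = snr),
            class = "dki_protocol")
}

#' @export
print.dki_protocol <- function(x, ...) {
  u <- if (x$unit == "bd") "bD (dimensionless)" else "s/mm^2"
  cat(sprintf("Acquisition protocol: %d b values [%s], SNR = %g\n",
              length(x$b), u, x$snr))
  cat("  ", paste(signif(x$b, 6), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Convert a protocol between physical and dimensionless units
#'
#' `to_dimensionless()` maps physical b values (s/mm^2) to the encoding
#' parameter bD = b * d * 1e-3; `to_physical()` is its inverse. Protocols
#' already in the requested unit are returned unchanged.
#'
#' @param protocol A [dki_protocol()].
#' @param d Diffusion coefficient in um^2/ms used for the conversion.
#' @return A [dki_protocol()] in the requested unit.
#' @examples
#' p <- dki_protocol(c(0, 1000, 2500), unit = "s_mm2")
#' to_dimensionless(p, d = 1)   # bD = 0, 1, 2.5
#' @export
to_dimensionless <- function(protocol, d) {
  stopifnot(inherits(protocol, "dki_protocol"), is.numeric(d), d > 0)
  if (protocol$unit == "bd") return(protocol)
  dki_protocol(protocol$b * d * 1e-3, unit = "bd", snr = protocol$snr)
}

#' @rdname to_dimensionless
#' @export
to_physical <- function(protocol, d) {
  stopifnot(inherits(protocol, "dki_protocol"), is.numeric(d), d > 0)
  if (protocol$unit == "s_mm2") return(protocol)
  dki_protocol(protocol$b / (d * 1e-3), unit = "s_mm2", snr = protocol$snr)
}

# internal: dimensionless bD vector of a protocol under given params
protocol_bd <- function(protocol, params) {
  if (protocol$unit == "bd") protocol$b else protocol$b * params$d * 1e-3
}
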