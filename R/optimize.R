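#' Maximum allowable bD for the kurtosis model
#'
#' The truncated cumulant expansion behind the kurtosis signal model is
#' valid only up to b = 3/(DK); in dimensionless encoding units the
#' bound is bD = 3/K. Beyond it the model signal turns upward and the
#' fit is no longer meaningful. The physical scanner limit may bind
#' first; see the `scanner_b_max` argument of [dki_optimize()].
#'
#' @param k Kurtosis (> 0).
#' @return The bound 3/k in bD units.
#' @examples
#' max_allowable_bd(1.5)   # 2
#' max_allowable_bd(0.3)   # 10
#' @export
max_allowable_bd <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k))
  if (k <= 0) {
    stop("the validity bound 3/K is finite only for k > 0; ",
         "supply a scanner b limit instead")
  }
  3 / k
}

# ---- candidate enumeration ------------------------------------------------

# multisets of size r from 1:g as an (choose(g+r-1, r)) x r index matrix,
# rows nondecreasing, lexicographic order
multiset_index <- function(g, r) {
  stopifnot(g >= 1L, r >= 1L)
  m <- matrix(seq_len(g), ncol = 1L)
  for (i in seq_len(r - 1L)) {
    last <- m[, ncol(m)]
    cnt <- g - last + 1L
    m <- cbind(m[rep.int(seq_len(nrow(m)), cnt), , drop = FALSE],
               sequence(cnt, from = last))
  }
  dimnames(m) <- NULL
  m
}

# strictly increasing r-subsets of 1:g, lexicographic order
subset_index <- function(g, r) {
  if (g < r) return(matrix(integer(0), 0L, r))
  m <- multiset_index(g - r + 1L, r)
  m + rep(0L:(r - 1L), each = nrow(m))
}

# compositions of n into 3 positive parts, ordered so that the expanded
# design rep(support, comp) is lexicographically increasing for a fixed
# increasing support: c1 descending, then c2 descending
compositions3 <- function(n) {
  stopifnot(n >= 3L)
  cc <- expand.grid(c1 = seq_len(n - 2L), c2 = seq_len(n - 2L))
  cc$c3 <- n - cc$c1 - cc$c2
  cc <- cc[cc$c3 >= 1L, , drop = FALSE]
  as.matrix(cc[order(-cc$c1, -cc$c2), , drop = FALSE])
}

#' Enumerate candidate designs on a bD grid
#'
#' Lists every candidate acquisition design of `n` b values drawn from a
#' discrete grid. `"exhaustive"` mode yields every multiset of `n` grid
#' points (lexicographic order); `"support_points"` mode yields every
#' design with at most 3 distinct values (support points) and
#' multiplicities summing to `n` — the classical support bound for a
#' 3-parameter model, which every known optimum obeys.
#'
#' @param n Number of acquisitions (>= 3).
#' @param grid Numeric vector of candidate bD values (>= 3 distinct).
#' @param mode `"exhaustive"` or `"support_points"`.
#' @return Numeric matrix with `n` columns; each row one design, values
#'   nondecreasing. No duplicate rows; deterministic order.
#' @examples
#' nrow(design_candidates(3, c(0, 1, 2)))   # choose(5, 3) = 10
#' @export
design_candidates <- function(n, grid, mode = c("exhaustive", "support_points")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(grid), n >= 3L)
  grid <- sort(unique(as.numeric(grid)))
  g <- length(grid)
  if (g < 3L) stop("grid too coarse: at least 3 distinct grid points needed")
  if (mode == "exhaustive") {
    n_cand <- choose(g + n - 1, n)
    if (n_cand > 2e7) {
      stop(sprintf(
        "exhaustive enumeration would generate %.3g candidates; use search_mode = 'support_points'",
        n_cand))
    }
    idx <- multiset_index(g, as.integer(n))
    out <- matrix(grid[idx], nrow(idx), ncol(idx))
  } else {
    blocks <- list()
    # single support point
    blocks[[1L]] <- matrix(rep(grid, times = n), nrow = g)
    # two support points
    pairs <- subset_index(g, 2L)
    two <- do.call(rbind, lapply(seq_len(n - 1L), function(c1) {
      cbind(matrix(grid[pairs[, 1L]], nrow(pairs), c1),
            matrix(grid[pairs[, 2L]], nrow(pairs), n - c1))
    }))
    blocks[[2L]] <- two
    # three support points
    trip <- subset_index(g, 3L)
    comps <- compositions3(as.integer(n))
    three <- do.call(rbind, lapply(seq_len(nrow(comps)), function(i) {
      cc <- comps[i, ]
      cbind(matrix(grid[trip[, 1L]], nrow(trip), cc[1L]),
            matrix(grid[trip[, 2L]], nrow(trip), cc[2L]),
            matrix(grid[trip[, 3L]], nrow(trip), cc[3L]))
    }))
    blocks[[3L]] <- three
    out <- do.call(rbind, blocks)
  }
  dimnames(out) <- NULL
  out
}

# ---- batch objective evaluation -------------------------------------------

# per-grid-point products of the three sensitivity components, g x 6,
# columns (11, 12, 13, 22, 23, 33); dimensionless computation with the
# 1/d chain-rule factor on the D column so results match dki_crlb
grid_products <- function(grid, params, snr) {
  sigma0 <- params$s0 / snr
  e <- exp(-grid + params$k * grid^2 / 6)
  r1 <- e / sigma0
  r2 <- params$s0 * (-grid + 2 * grid^2 * params$k / 6) * e / params$d / sigma0
  r3 <- params$s0 * (grid^2 / 6) * e / sigma0
  cbind(r1 * r1, r1 * r2, r1 * r3, r2 * r2, r2 * r3, r3 * r3)
}

# objective from the 6 unique Gram entries (vectors); Inf marks singular
gram_objective <- function(m11, m12, m13, m22, m23, m33, objective, params) {
  det <- m11 * (m22 * m33 - m23^2) -
         m12 * (m12 * m33 - m23 * m13) +
         m13 * (m12 * m23 - m22 * m13)
  scale <- pmax(m11 * m22 * m33, .Machine$double.xmin)
  ok <- is.finite(det) & det > scale * 1e-12
  q11 <- (m22 * m33 - m23^2) / det
  q22 <- (m11 * m33 - m13^2) / det
  q33 <- (m11 * m22 - m12^2) / det
  ok <- ok & is.finite(q11) & is.finite(q22) & is.finite(q33) &
        q11 > 0 & q22 > 0 & q33 > 0
  q11[!ok] <- NA_real_; q22[!ok] <- NA_real_; q33[!ok] <- NA_real_
  obj <- switch(objective,
    cov_d = sqrt(q22) / params$d,
    cov_k = sqrt(q33) / params$k,
    cov_d_plus_cov_k = sqrt(q22) / params$d + sqrt(q33) / params$k,
    mse = q11 + q22 + q33)
  obj[!ok] <- Inf
  obj
}

# strict lexicographic order on equal-length numeric vectors
lex_less <- function(a, b) {
  d <- a - b
  i <- which(d != 0)
  length(i) > 0L && d[i[1L]] < 0
}

#' Optimize the b-value design of a kurtosis acquisition
#'
#' Searches a discrete bD grid for the set of `n` b values minimizing
#' the predicted estimation error of the kurtosis model at target tissue
#' parameters. The default objective is the sum CoV_D + CoV_K, the
#' combined relative error of the two diffusion parameters; the search
#' ranges over `[0, bd_max]` where `bd_max` defaults to the model
#' validity bound 3/K, clipped by the scanner's physical maximum b when
#' one is given. Repeated b values (signal averaging) are allowed.
#'
#' For `n = 3` the search is exhaustive over all multisets of grid
#' points. For `n >= 4` it restricts, by default, to designs with at
#' most 3 distinct support points (every known optimum has this form for
#' a 3-parameter model); exhaustive search remains available for
#' validation on coarse grids.
#'
#' @param n Number of acquisitions (integer >= 3).
#' @param params A [dki_params()] with the target tissue values
#'   (`k > 0` unless `scanner_b_max` is given).
#' @param snr Signal-to-noise ratio at b = 0 (default 20).
#' @param grid_step bD grid increment (default 0.05).
#' @param bd_max Upper search bound in bD units; default
#'   `min(3/k, scanner_b_max * d * 1e-3)`.
#' @param scanner_b_max Optional physical b limit in s/mm^2.
#' @param objective One of `"cov_d_plus_cov_k"` (default), `"cov_d"`,
#'   `"cov_k"`, `"mse"`.
#' @param search_mode `"exhaustive"` or `"support_points"`; default
#'   exhaustive for `n = 3`, support points for `n >= 4`.
#' @param chunk_size Number of candidates evaluated per vectorized
#'   block (memory/speed trade-off).
#' @return An object of class `"dki_design"`: list with `protocol` (the
#'   winning design, sorted ascending, dimensionless), `crlb` (its
#'   [dki_crlb()] evaluation), `objective`, `objective_value`,
#'   `n_evaluated`, `n_singular`, plus the search settings.
#' @details Singular candidates (e.g. fewer than 3 distinct values) are
#'   skipped and counted, not fatal. Ties are broken by the
#'   lexicographically smallest sorted design, making results fully
#'   deterministic.
#' @examples
#' opt <- dki_optimize(3, dki_params(d = 1, k = 1.5))
#' opt$protocol$b    # 0, 0.75, 2
#' @export
dki_optimize <- function(n, params, snr = 20, grid_step = 0.05,
                         bd_max = NULL, scanner_b_max = NULL,
                         objective = c("cov_d_plus_cov_k", "cov_d", "cov_k", "mse"),
                         search_mode = NULL, chunk_size = 500000L) {
  objective <- match.arg(objective)
  params <- as_dki_params(params)
  stopifnot(is.numeric(n), length(n) == 1L, n >= 3, n == round(n),
            is.numeric(grid_step), grid_step > 0)
  n <- as.integer(n)
  if (is.null(bd_max)) {
    bd_max <- if (params$k > 0) max_allowable_bd(params$k) else Inf
    if (!is.null(scanner_b_max)) {
      bd_max <- min(bd_max, scanner_b_max * params$d * 1e-3)
    }
    if (!is.finite(bd_max)) {
      stop("no finite search bound: k = 0 and no 'scanner_b_max' given")
    }
  }
  stopifnot(is.numeric(bd_max), bd_max > 0)
  if (objective %in% c("cov_k", "cov_d_plus_cov_k") && params$k <= 0) {
    stop("objectives involving CoV_K require k > 0")
  }
  if (is.null(search_mode)) {
    search_mode <- if (n == 3L) "exhaustive" else "support_points"
  }
  search_mode <- match.arg(search_mode, c("exhaustive", "support_points"))

  grid <- seq(0, bd_max, by = grid_step)
  if (abs(grid[length(grid)] - bd_max) > 1e-9) grid <- c(grid, bd_max)
  g <- length(grid)
  if (g < 3L) stop("grid too coarse: fewer than 3 grid points in [0, bd_max]")
  P <- grid_products(grid, params, snr)

  best_obj <- Inf
  best_design <- NULL
  n_eval <- 0
  n_singular <- 0

  eval_block <- function(i, j, l, w = c(1, 1, 1)) {
    # Gram entries of the design with points (i, j, l) and multiplicities w
    m <- w[1L] * P[i, , drop = FALSE] + w[2L] * P[j, , drop = FALSE] +
         w[3L] * P[l, , drop = FALSE]
    gram_objective(m[, 1L], m[, 2L], m[, 3L], m[, 4L], m[, 5L], m[, 6L],
                   objective, params)
  }

  consider <- function(obj, designs) {
    # designs: matrix of sorted candidate rows aligned with obj
    w <- which(is.finite(obj))
    n_singular <<- n_singular + (length(obj) - length(w))
    if (!length(w)) return(invisible())
    i <- w[which.min(obj[w])]
    if (obj[i] < best_obj ||
        (obj[i] == best_obj && !is.null(best_design) &&
         lex_less(designs[i, ], best_design))) {
      best_obj <<- obj[i]
      best_design <<- designs[i, ]
    }
    invisible()
  }

  if (search_mode == "exhaustive") {
    if (n > 3L) {
      n_cand <- choose(g + n - 1, n)
      if (n_cand > 2e7) {
        stop(sprintf(
          "exhaustive search over %.3g candidates is impractical; use search_mode = 'support_points'",
          n_cand))
      }
    }
    idx <- multiset_index(g, n)
    n_eval <- nrow(idx)
    starts <- seq(1L, nrow(idx), by = chunk_size)
    for (s in starts) {
      rows <- s:min(s + chunk_size - 1L, nrow(idx))
      block <- idx[rows, , drop = FALSE]
      m <- P[block[, 1L], , drop = FALSE]
      for (cidx in 2:ncol(block)) m <- m + P[block[, cidx], , drop = FALSE]
      obj <- gram_objective(m[, 1L], m[, 2L], m[, 3L], m[, 4L], m[, 5L],
                            m[, 6L], objective, params)
      consider(obj, matrix(grid[block], nrow(block), ncol(block)))
    }
  } else {
    trip <- subset_index(g, 3L)
    comps <- compositions3(n)
    for (ci in seq_len(nrow(comps))) {
      cc <- comps[ci, ]
      starts <- seq(1L, nrow(trip), by = chunk_size)
      for (s in starts) {
        rows <- s:min(s + chunk_size - 1L, nrow(trip))
        tb <- trip[rows, , drop = FALSE]
        obj <- eval_block(tb[, 1L], tb[, 2L], tb[, 3L], w = cc)
        designs <- cbind(matrix(grid[tb[, 1L]], nrow(tb), cc[1L]),
                         matrix(grid[tb[, 2L]], nrow(tb), cc[2L]),
                         matrix(grid[tb[, 3L]], nrow(tb), cc[3L]))
        consider(obj, designs)
        n_eval <- n_eval + nrow(tb)
      }
    }
  }

  if (is.null(best_design)) {
    stop("all candidate designs were singular; enlarge the grid or bd_max")
  }
  protocol <- dki_protocol(sort(best_design), unit = "bd", snr = snr)
  crlb <- dki_crlb(protocol, params)
  structure(list(protocol = protocol, crlb = crlb,
                 objective = objective, objective_value = best_obj,
                 n_evaluated = n_eval, n_singular = n_singular,
                 grid_step = grid_step, bd_max = bd_max,
                 search_mode = search_mode, snr = snr, params = params),
            class = "dki_design")
}

#' @export
print.dki_design <- function(x, ...) {
  cat(sprintf("Optimized acquisition design (n = %d, %s search)\n",
              length(x$protocol$b), x$search_mode))
  cat(sprintf("  target: D = %g, K = %g; SNR = %g; bD grid step %g on [0, %g]\n",
              x$params$d, x$params$k, x$snr, x$grid_step, signif(x$bd_max, 6)))
  cat(sprintf("  best design (bD): {%s}\n",
              paste(signif(x$protocol$b, 6), collapse = ", ")))
  cat(sprintf("  %s = %.4g; CoV(S0) = %.4g, CoV(D) = %.4g, CoV(K) = %.4g\n",
              x$objective, x$objective_value, x$crlb$cov[["s0"]],
              x$crlb$cov[["d"]], x$crlb$cov[["k"]]))
  cat(sprintf("  %d candidates evaluated (%d singular skipped)\n",
              x$n_evaluated, x$n_singular))
  invisible(x)
}

#' Equally spaced reference protocol
#'
#' The conventional comparison design: `n` b values uniformly spaced
#' from 0 to `bd_max`.
#'
#' @param n Number of acquisitions (>= 2).
#' @param bd_max Maximum bD (> 0).
#' @param snr Signal-to-noise ratio at b = 0.
#' @return A [dki_protocol()] in bD units.
#' @examples
#' equally_spaced_protocol(5, 10)$b   # 0, 2.5, 5, 7.5, 10
#' @export
equally_spaced_protocol <- function(n, bd_max, snr = 20) {
  stopifnot(is.numeric(n), n >= 2, n == round(n),
            is.numeric(bd_max), bd_max > 0)
  dki_protocol(seq(0, bd_max, length.out = n), unit = "bd", snr = snr)
}

#' Sweep predicted errors of a fixed design over tissue parameters
#'
#' Evaluates a fixed protocol at a sequence of true parameter values to
#' show how robust a design (typically optimized at target values) is
#' to the tissue deviating from those targets.
#'
#' @param protocol A [dki_protocol()], held fixed across the sweep.
#' @param params Target [dki_params()]; the swept component is replaced.
#' @param vary `"d"` or `"k"`.
#' @param values Numeric vector of swept values.
#' @return A data frame of class `"dki_sweep"` with columns `value`,
#'   `cov_s0`, `cov_d`, `cov_k`, `mse`; rows with invalid swept values
#'   (or singular evaluations) carry `NA`.
#' @examples
#' p <- dki_protocol(c(0, 0.75, 2))
#' robustness_sweep(p, dki_params(d = 0.86, k = 1.5), "k", seq(1, 1.5, 0.1))
#' @export
robustness_sweep <- function(protocol, params, vary = c("d", "k"), values) {
  vary <- match.arg(vary)
  params <- as_dki_params(params)
  stopifnot(inherits(protocol, "dki_protocol"), is.numeric(values),
            length(values) >= 1L)
  rows <- lapply(values, function(v) {
    r <- tryCatch({
      p2 <- params
      p2[[vary]] <- v
      p2 <- dki_params(s0 = p2$s0, d = p2$d, k = p2$k, t2 = p2$t2)
      res <- dki_crlb(protocol, p2)
      data.frame(value = v, cov_s0 = res$cov[["s0"]], cov_d = res$cov[["d"]],
                 cov_k = res$cov[["k"]], mse = res$mse)
    }, error = function(e) {
      data.frame(value = v, cov_s0 = NA_real_, cov_d = NA_real_,
                 cov_k = NA_real_, mse = NA_real_)
    })
    r
  })
  out <- do.call(rbind, rows)
  attr(out, "vary") <- vary
  attr(out, "protocol") <- protocol
  class(out) <- c("dki_sweep", "data.frame")
  out
}

#' @export
plot.dki_sweep <- function(x, which = c("cov_d", "cov_k"), ...) {
  which <- match.arg(which, c("cov_d", "cov_k", "cov_s0", "mse"),
                     several.ok = TRUE)
  vary <- attr(x, "vary")
  ylim <- range(unlist(x[which]), na.rm = TRUE)
  graphics::plot(NA, xlim = range(x$value), ylim = ylim,
                 xlab = if (vary == "d") "true D (um^2/ms)" else "true K",
                 ylab = "coefficient of variation", ...)
  for (i in seq_along(which)) {
    graphics::lines(x$value, x[[which[i]]], lty = i, col = i)
  }
  graphics::legend("topright", legend = which, lty = seq_along(which),
                   col = seq_along(which), bty = "n")
  invisible(x)
}
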