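#' Reference (n, K) table cells
#'
#' The standard grid of table cells used for design tables: n = 3, 4, 5
#' acquisitions crossed with kurtosis targets K = 1.5, 1, 0.8, 0.6,
#' 0.5, 0.3, each with its validity bound bd_max = 3/K.
#'
#' @return Data frame with columns `n`, `k`, `bd_max` (18 rows).
#' @export
reference_cells <- function() {
  ks <- c(1.5, 1, 0.8, 0.6, 0.5, 0.3)
  out <- expand.grid(k = ks, n = 3:5)[, c("n", "k")]
  out$bd_max <- 3 / out$k
  rownames(out) <- NULL
  out
}

#' Build a protocol table over (n, K) cells
#'
#' For each cell either optimizes the design ([dki_optimize()]) or takes
#' the equally spaced reference ([equally_spaced_protocol()]), evaluates
#' its predicted errors, and collects everything in a fixed-schema data
#' frame mirroring the package's design tables. D is fixed at 1 (the
#' results depend on D only through bD, so the bD designs apply to any
#' D).
#'
#' @param cells Data frame with columns `n`, `k` and optionally
#'   `bd_max` (default 3/k); defaults to [reference_cells()]. May have
#'   zero rows, giving a header-only table.
#' @param type `"optimized"` or `"equally_spaced"`.
#' @param snr Signal-to-noise ratio at b = 0 (default 20).
#' @param grid_step Grid increment for the optimizer.
#' @param ... Further arguments passed to [dki_optimize()].
#' @return Data frame of class `"dki_protocol_table"` with columns
#'   `n`, `bd_1` ... `bd_5`, `bd_max`, `k`, `cov_k`, `cov_d`, `cov_s0`
#'   (unused design slots are `NA`).
#' @examples
#' protocol_table(data.frame(n = 3, k = 1.5), type = "equally_spaced")
#' @export
protocol_table <- function(cells = reference_cells(),
                           type = c("optimized", "equally_spaced"),
                           snr = 20, grid_step = 0.05, ...) {
  type <- match.arg(type)
  stopifnot(is.data.frame(cells), all(c("n", "k") %in% names(cells)))
  if (is.null(cells$bd_max)) cells$bd_max <- 3 / cells$k
  max_n <- 5L
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    n <- as.integer(cells$n[i]); k <- cells$k[i]; bd_max <- cells$bd_max[i]
    if (n > max_n) stop("protocol tables support n <= 5")
    params <- dki_params(d = 1, k = k)
    if (type == "optimized") {
      opt <- dki_optimize(n, params, snr = snr, grid_step = grid_step,
                          bd_max = bd_max, ...)
      prot <- opt$protocol
      res <- opt$crlb
    } else {
      prot <- equally_spaced_protocol(n, bd_max, snr = snr)
      res <- dki_crlb(prot, params)
    }
    bd <- rep(NA_real_, max_n)
    bd[seq_len(n)] <- sort(prot$b)
    data.frame(n = n, bd_1 = bd[1], bd_2 = bd[2], bd_3 = bd[3],
               bd_4 = bd[4], bd_5 = bd[5], bd_max = bd_max, k = k,
               cov_k = res$cov[["k"]], cov_d = res$cov[["d"]],
               cov_s0 = res$cov[["s0"]])
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(n = integer(), bd_1 = numeric(), bd_2 = numeric(),
               bd_3 = numeric(), bd_4 = numeric(), bd_5 = numeric(),
               bd_max = numeric(), k = numeric(), cov_k = numeric(),
               cov_d = numeric(), cov_s0 = numeric())
  class(out) <- c("dki_protocol_table", "data.frame")
  attr(out, "type") <- type
  attr(out, "snr") <- snr
  out
}

protocol_table_columns <- c("n", "bd_1", "bd_2", "bd_3", "bd_4", "bd_5",
                            "bd_max", "k", "cov_k", "cov_d", "cov_s0")

#' Write / read a protocol table as CSV
#'
#' Plain RFC-4180-style CSV with the fixed column schema of
#' [protocol_table()] and locale-independent decimal points. Round trips
#' are lossless to the written precision (15 significant digits).
#'
#' @param table A [protocol_table()] result (or data frame with the same
#'   columns).
#' @param path File path.
#' @return `write_protocol_table()` returns `path` invisibly;
#'   `read_protocol_table()` returns the table.
#' @export
write_protocol_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(protocol_table_columns, names(table))
  if (length(missing_cols)) {
    stop("table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  tab <- as.data.frame(table)[protocol_table_columns]
  for (nm in setdiff(protocol_table_columns, "n")) {
    v <- tab[[nm]]
    tab[[nm]] <- ifelse(is.na(v), "NA",
                        trimws(formatC(v, digits = 15, format = "g")))
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_protocol_table
#' @export
read_protocol_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  missing_cols <- setdiff(protocol_table_columns, header)
  if (length(missing_cols)) {
    stop(sprintf("malformed protocol table '%s' (line 1): missing column(s) %s",
                 path, paste(missing_cols, collapse = ", ")))
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in protocol_table_columns) {
    v <- suppressWarnings(as.numeric(tab[[nm]]))
    bad <- which(is.na(v) & !is.na(tab[[nm]]) & tab[[nm]] != "NA")
    if (length(bad)) {
      stop(sprintf("malformed protocol table '%s' (line %d): non-numeric '%s' in column %s",
                   path, bad[1L] + 1L, tab[[nm]][bad[1L]], nm))
    }
    tab[[nm]] <- v
  }
  tab$n <- as.integer(tab$n)
  class(tab) <- c("dki_protocol_table", "data.frame")
  tab
}

#' @export
print.dki_protocol_table <- function(x, digits = 4, ...) {
  type <- attr(x, "type")
  if (!is.null(type)) {
    cat(sprintf("Protocol table (%s designs%s)\n", type,
                if (!is.null(attr(x, "snr")))
                  sprintf(", SNR = %g", attr(x, "snr")) else ""))
  }
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1L))
  y[num] <- lapply(y[num], signif, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}
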