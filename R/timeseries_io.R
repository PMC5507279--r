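timeseries_columns <- c(
  "step", "time", "n_R_free", "n_P_free", "n_RR_complexes",
  "n_RP_complexes", "n_R_total", "n_P_total", "mean_a_R", "sd_a_R",
  "mean_l_R", "sd_l_R", "mean_a_P", "sd_a_P", "mean_l_P", "sd_l_P")

#' Write a run time series to CSV
#'
#' Header-first CSV with the fixed time-series column order. Floats are
#' written with the shortest round-trippable representation (`%.17g`), so
#' [read_timeseries()] recovers the rows bit for bit. Missing attribute
#' means of an extinct species are written as empty fields (0 is a legal
#' attribute value and must stay distinguishable from "absent").
#'
#' @param rows a time-series data frame (see [rp_series()]).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_timeseries <- function(rows, file) {
  stopifnot(is.data.frame(rows), identical(names(rows), timeseries_columns))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(timeseries_columns, collapse = ","), con)
  if (nrow(rows)) {
    cols <- lapply(rows, function(v) {
      out <- sprintf("%.17g", v)
      out[is.na(v)] <- ""
      out
    })
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  }
  invisible(file)
}

#' Read a run time series from CSV
#'
#' Inverse of [write_timeseries()]. Malformed content (wrong header, wrong
#' field count, non-numeric fields) raises a parse error naming the
#' offending line.
#'
#' @param file path to a CSV written by [write_timeseries()].
#' @return a time-series data frame.
#' @export
read_timeseries <- function(file) {
  lines <- readLines(file)
  if (length(lines) == 0L) stop("parse error: empty file")
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (!identical(header, timeseries_columns))
    stop("parse error at line 1: unexpected header")
  n <- length(lines) - 1L
  out <- matrix(NA_real_, nrow = n, ncol = length(timeseries_columns))
  if (n > 0) {
    fields <- strsplit(lines[-1L], ",", fixed = TRUE)
    for (i in seq_len(n)) {
      f <- fields[[i]]
      # trailing empty fields are dropped by strsplit; pad them back
      if (length(f) < length(timeseries_columns))
        f <- c(f, rep("", length(timeseries_columns) - length(f)))
      if (length(f) != length(timeseries_columns))
        stop(sprintf("parse error at line %d: expected %d fields, got %d",
                     i + 1L, length(timeseries_columns), length(f)))
      blank <- f == ""
      v <- suppressWarnings(as.numeric(f))
      if (any(is.na(v) & !blank))
        stop(sprintf("parse error at line %d: non-numeric field", i + 1L))
      out[i, ] <- v
    }
  }
  out <- as.data.frame(out)
  names(out) <- timeseries_columns
  out
}
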