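#' Detect stabilization of an attribute trajectory
#'
#' Operationalizes "the average stopped changing" as a trailing-window slope
#' test: for every window of `window` consecutive points, fit a least-squares
#' line; the series is considered stabilized from the earliest window end
#' such that the absolute slope of every window from there to the end of the
#' series stays below `tol`.
#'
#' @param series numeric vector of per-step attribute means (`NA`s allowed
#'   only at the tail, e.g. after an extinction; they are dropped).
#' @param window window length in points (>= 2).
#' @param tol slope tolerance, attribute units per step.
#' @return the 1-based index of the end of the first stable window, or
#'   `NA_integer_` if the series never stabilizes or is shorter than the
#'   window.
#' @export
detect_stabilization <- function(series, window, tol) {
  stopifnot(window >= 2, tol >= 0)
  series <- series[!is.na(series)]
  n <- length(series)
  if (n < window) return(NA_integer_)
  w <- window
  x <- seq_len(w)
  sx <- sum(x)
  sxx <- sum(x^2)
  denom <- w * sxx - sx^2
  # rolling sums of y and x*y over each window [t-w+1, t]
  cy <- c(0, cumsum(series))
  sy <- cy[(w + 1):(n + 1)] - cy[1:(n - w + 1)]
  ciy <- c(0, cumsum(series * seq_len(n)))
  siy <- ciy[(w + 1):(n + 1)] - ciy[1:(n - w + 1)]
  # shift absolute index i to window-local x: x = i - (t - w)
  starts <- 0:(n - w) # t - w
  sxy <- siy - starts * sy
  slopes <- (w * sxy - sx * sy) / denom
  ok <- abs(slopes) < tol
  if (!ok[length(ok)]) return(NA_integer_)
  bad <- which(!ok)
  first <- if (length(bad)) max(bad) + 1L else 1L
  as.integer(first + w - 1L)
}
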