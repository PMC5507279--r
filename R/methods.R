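#' @export
print.rp_run <- function(x, ...) {
  cat(sprintf("<rp_run> %s after %d steps (seed %d)\n",
              x$outcome, x$final_step, x$seed))
  final <- x$series[nrow(x$series), ]
  cat(sprintf("  final counts: %g replicases, %g parasites (%g RR, %g RP complexes)\n",
              final$n_R_total, final$n_P_total, final$n_RR_complexes,
              final$n_RP_complexes))
  invisible(x)
}

#' Summary of a finished run
#'
#' Prints the outcome, final counts, and the trailing-window averages of the
#' four attribute means (over the last `trailing` recorded steps with the
#' species alive).
#'
#' @param object an `rp_run`.
#' @param trailing window, in steps, for the trailing attribute averages.
#' @param ... unused.
#' @return invisibly, a list with the printed quantities.
#' @export
summary.rp_run <- function(object, trailing = 10000, ...) {
  s <- object$series
  final <- s[nrow(s), ]
  trail <- function(col) {
    v <- s[[col]]
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    mean(tail(v, trailing))
  }
  out <- list(outcome = object$outcome, final_step = object$final_step,
              n_R = final$n_R_total, n_P = final$n_P_total,
              trailing_mean_a_R = trail("mean_a_R"),
              trailing_mean_l_R = trail("mean_l_R"),
              trailing_mean_a_P = trail("mean_a_P"),
              trailing_mean_l_P = trail("mean_l_P"))
  cat(sprintf("Run outcome: %s at step %d\n", out$outcome, out$final_step))
  cat(sprintf("Final population: %g replicases, %g parasites\n",
              out$n_R, out$n_P))
  cat(sprintf("Trailing means (last %g steps): a_R=%.3f l_R=%.3f a_P=%.3f l_P=%.3f\n",
              trailing, out$trailing_mean_a_R, out$trailing_mean_l_R,
              out$trailing_mean_a_P, out$trailing_mean_l_P))
  invisible(out)
}

#' Plot a run trajectory
#'
#' Two stacked panels: population counts per species over time, and the four
#' population-mean attribute trajectories.
#'
#' @param x an `rp_run`.
#' @param ... forwarded to `matplot`.
#' @return `x`, invisibly.
#' @export
plot.rp_run <- function(x, ...) {
  s <- x$series
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::matplot(s$step, cbind(s$n_R_total, s$n_P_total), type = "l",
                    lty = 1, col = c("blue3", "red3"),
                    xlab = "step", ylab = "molecules", ...)
  graphics::legend("topleft", c("replicases", "parasites"), lty = 1,
                   col = c("blue3", "red3"), bty = "n")
  graphics::matplot(s$step,
                    cbind(s$mean_a_R, s$mean_l_R, s$mean_a_P, s$mean_l_P),
                    type = "l", lty = c(1, 2, 1, 2),
                    col = c("blue3", "blue3", "red3", "red3"),
                    ylim = c(0, 1), xlab = "step", ylab = "population mean")
  graphics::legend("topleft",
                   c("a_R", "l_R", "a_P", "l_P"), lty = c(1, 2, 1, 2),
                   col = c("blue3", "blue3", "red3", "red3"), bty = "n")
  invisible(x)
}
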