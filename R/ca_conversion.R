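#' Lattice-to-continuum parameter conversion
#'
#' The simulator's diffusion coefficients are derived from the move
#' probabilities of the source cellular-automaton (CA) model by matching the
#' per-step displacement variance of a lattice walker with that of the
#' off-lattice Brownian step. These functions expose the conversion and the
#' underlying Moore-neighborhood variance enumerations.
#'
#' A free CA molecule moves to one of its 8 Moore-neighborhood cells: 4
#' orthogonal moves of squared length 1 and 4 diagonal moves of squared
#' length 2, so its per-step displacement variance at move probability `p`
#' is `(4*1 + 4*2)/8 * p = 3/2 * p`.
#'
#' @param p_d_ca per-step diffusion probability of a free CA molecule, in
#'   `[0, 1]`.
#' @return displacement variance in squared length units.
#' @seealso [mas_diffusion_from_ca()]
#' @export
ca_single_move_variance <- function(p_d_ca) {
  check_prob(p_d_ca, "p_d_ca")
  1.5 * p_d_ca
}

#' Free-molecule diffusion coefficient from a CA move probability
#'
#' Equates the lattice per-step variance `3/2 * p` with the Brownian per-step
#' variance `2 * D * dt`, giving `D = 3 * p / (4 * dt)`. With `p = 1` and
#' `dt = 1` this yields the published value `D = 0.75`.
#'
#' @inheritParams ca_single_move_variance
#' @param dt step length (time units, > 0).
#' @return diffusion coefficient `D` in length^2 per time unit.
#' @export
mas_diffusion_from_ca <- function(p_d_ca, dt) {
  check_prob(p_d_ca, "p_d_ca")
  if (dt <= 0) stop("dt must be > 0")
  3 * p_d_ca / (4 * dt)
}

#' Per-step move probability of a complexed CA molecule
#'
#' In the lattice model a complexed molecule moves with half the propensity
#' of a free one and, in the same step, may instead replicate. The
#' probability that its next action is a move is the conditional
#' `(d_ca / 2) / (d_ca / 2 + k_ca)`.
#'
#' @param d_ca CA diffusion rate (>= 0).
#' @param k_ca CA replication rate (>= 0); not both rates may be zero.
#' @return move probability `p'` in `[0, 1]`.
#' @export
ca_complex_move_probability <- function(d_ca, k_ca) {
  stopifnot(d_ca >= 0, k_ca >= 0)
  if (d_ca == 0 && k_ca == 0)
    stop("undefined move probability: both rates are zero")
  (d_ca / 2) / (d_ca / 2 + k_ca)
}

#' Center-of-mass displacement variance of a CA complex move
#'
#' A two-cell lattice complex moving one member into a Moore-neighborhood
#' cell displaces its center of mass by sqrt(2)/2 (4 cases), 1 (1 case) or
#' sqrt(10)/2 (2 cases), with one null case (the two members swapping). The
#' enumeration averages to exactly 1, and either member can initiate the
#' move, so the variance is `2 * p'`.
#'
#' @param p_prime complexed-molecule move probability, in `[0, 1]`.
#' @return displacement variance in squared length units.
#' @export
ca_complex_move_variance <- function(p_prime) {
  check_prob(p_prime, "p_prime")
  2 * p_prime
}

#' Complex diffusion coefficient from the CA move probability
#'
#' Equates the lattice complex variance `2 * p'` with the Brownian per-step
#' variance `2 * D' * dt`, giving `D' = p' / dt`.
#'
#' @inheritParams ca_complex_move_variance
#' @param dt step length (time units, > 0).
#' @return complex diffusion coefficient `D'` in length^2 per time unit.
#' @export
mas_complex_diffusion_from_ca <- function(p_prime, dt) {
  check_prob(p_prime, "p_prime")
  if (dt <= 0) stop("dt must be > 0")
  p_prime / dt
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0 | x > 1))
    stop(sprintf("%s must lie in [0, 1]", name))
  invisible(x)
}
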