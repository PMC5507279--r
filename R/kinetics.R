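#' Kinetic rate constants
#'
#' Container for the reaction-diffusion constants of a run. The defaults are
#' the published simulation constants: decay rate `d = 0.182` per time unit,
#' free-molecule diffusion coefficient `D = 0.75`, complex diffusion
#' coefficient `D' = 0.0476` (both in length^2 per time unit), replication
#' rate `K = 239800` per time unit, step length `dt = 1` time unit, and agent
#' radius `r = 0.5` length units (hence collision distance 1). `K` is
#' deliberately enormous: the exponential replication time it draws expires at
#' the first clock decrement, realizing an effectively immediate (Dirac-delta)
#' replication that can only be preempted by dissociation.
#'
#' `n_max` is the crowding cap: an entity seeing more than `n_max` neighbors
#' at its processing turn is removed (resource limitation). The source
#' lattice model enforces one molecule per cell over a Moore neighborhood of
#' 8 cells, so 8 is used as the default cap.
#'
#' @param d decay rate (per time unit, >= 0; 0 disables decay).
#' @param D free-molecule diffusion coefficient (length^2/time).
#' @param D_complex complex diffusion coefficient (length^2/time).
#' @param K replication rate (per time unit).
#' @param dt simulation step length (time units, > 0).
#' @param radius agent radius (length units, > 0).
#' @param n_max maximum allowed neighbors (positive integer).
#' @return an object of class `rp_kinetics`.
#' @export
kinetic_params <- function(d = 0.182, D = 0.75, D_complex = 0.0476,
                           K = 239800, dt = 1, radius = 0.5, n_max = 8) {
  stopifnot(d >= 0, D >= 0, D_complex >= 0, K >= 0, dt > 0, radius > 0,
            n_max >= 1)
  structure(list(d = d, D = D, D_complex = D_complex, K = K, dt = dt,
                 radius = radius, n_max = as.integer(n_max)),
            class = "rp_kinetics")
}

#' Mutation model parameters
#'
#' On every replication event each offspring attribute is, independently and
#' with its per-species probability, perturbed by an additive offset drawn
#' uniformly from `[-delta, +delta]` and clamped to `[0, 1]`. Clamping (rather
#' than reflection or resampling) lets attribute averages absorb at the
#' boundaries, which is the behavior observed when selection pushes an
#' attribute to its extreme.
#'
#' @param mu_a_R,mu_l_R,mu_a_P,mu_l_P per-replication mutation probabilities
#'   for the affinity (`a`) and folded-state (`l`) attributes of replicases
#'   (R) and parasites (P). A probability of 0 makes the attribute immutable.
#' @param delta perturbation half-width in attribute units (> 0).
#' @return an object of class `rp_mutation`.
#' @export
mutation_params <- function(mu_a_R = 0, mu_l_R = 0, mu_a_P = 0, mu_l_P = 0,
                            delta = 0.05) {
  p <- c(mu_a_R, mu_l_R, mu_a_P, mu_l_P)
  stopifnot(all(p >= 0 & p <= 1), delta > 0)
  structure(list(mu_a_R = mu_a_R, mu_l_R = mu_l_R, mu_a_P = mu_a_P,
                 mu_l_P = mu_l_P, delta = delta), class = "rp_mutation")
}

#' Exponential waiting time from a uniform draw
#'
#' Inverse-CDF transform `-log(u) / k` mapping a uniform draw on `(0, 1]` to
#' an exponential waiting time with rate `k`. All first-order events of the
#' model (decay, replication, complex dissociation) are memoryless, so their
#' times are drawn once, when the molecule or complex is created, instead of
#' being tested every step.
#'
#' @param k event rate (per time unit, > 0).
#' @param u uniform draw(s) on `(0, 1]`; if omitted, `n` draws are taken from
#'   R's RNG (`runif`, which never returns the endpoints).
#' @param n number of draws when `u` is omitted.
#' @return waiting time(s) in time units.
#' @export
sample_waiting_time <- function(k, u = NULL, n = 1L) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("invalid rate: k must be a single finite value > 0")
  if (is.null(u)) u <- runif(n)
  if (any(u <= 0 | u > 1))
    stop("u must lie in the half-open interval (0, 1]")
  -log(u) / k
}

#' One Brownian displacement step
#'
#' Adds `sqrt(2 * coef * dt)` times a standard-normal component to each
#' coordinate and wraps the result onto the torus. The two axes are
#' independent, so the per-axis single-step variance is `2 * coef * dt` and
#' the mean-squared displacement after `T` steps is `4 * coef * dt * T`.
#'
#' @param p position(s): length-2 vector or n x 2 matrix.
#' @param coef diffusion coefficient (length^2/time, >= 0).
#' @param dt step length (time units, > 0).
#' @param gauss standard-normal draw(s), same shape as `p`; if omitted, drawn
#'   from R's RNG.
#' @param geom an [rp_geometry()].
#' @return displaced, wrapped position(s), same shape as `p`.
#' @export
diffusion_step <- function(p, coef, dt, gauss = NULL, geom) {
  stopifnot(coef >= 0, dt > 0)
  xy <- as_xy(p)
  if (is.null(gauss)) gauss <- matrix(stats::rnorm(length(xy)), ncol = 2L)
  g <- as_xy(gauss)
  stopifnot(nrow(g) == nrow(xy))
  out <- wrap_position(xy + sqrt(2 * coef * dt) * g, geom)
  if (is.matrix(p) || is.data.frame(p)) out else out[1L, ]
}

#' Collision distance of two circular agents
#'
#' Two agents can react when their center-to-center distance is strictly
#' below the sum of their radii. With the default radius 0.5 for every
#' molecule, the collision distance is 1 length unit, one lattice cell side.
#'
#' @param r_i,r_j agent radii (length units, > 0).
#' @return `r_i + r_j`.
#' @export
collision_distance <- function(r_i, r_j) {
  if (any(r_i <= 0) || any(r_j <= 0))
    stop("agent radii must be positive")
  r_i + r_j
}

#' Reaction (complex formation) probability
#'
#' Probability that a collision between an eligible pair leads to complex
#' formation: `omega = a * (1 - l)`, a function of the *template's* affinity
#' towards replicases and folded-state probability only. A fully folded
#' template (`l = 1`) never reacts; affinity scales the probability linearly.
#'
#' @param a template affinity towards replicases, in `[0, 1]`.
#' @param l template folded-state probability, in `[0, 1]`.
#' @return reaction probability in `[0, 1]`.
#' @export
reaction_probability <- function(a, l) {
  if (any(a < 0 | a > 1) || any(l < 0 | l > 1))
    stop("attributes must lie in [0, 1]")
  a * (1 - l)
}

#' Mutate an attribute value
#'
#' With probability `mu`, perturbs `v` by an additive offset uniform on
#' `[-delta, +delta]` and clamps to `[0, 1]`; otherwise returns `v`
#' unchanged. Vectorized over `v`; one independent decision per element.
#' Draws come from R's RNG (the simulation engine uses its own stream with
#' the same kernel).
#'
#' @param v attribute value(s) in `[0, 1]`.
#' @param mu mutation probability in `[0, 1]`.
#' @param delta perturbation half-width (> 0).
#' @return mutated value(s), always within `[0, 1]`.
#' @export
mutate_attribute <- function(v, mu, delta = 0.05) {
  if (any(v < 0 | v > 1)) stop("attribute values must lie in [0, 1]")
  stopifnot(mu >= 0, mu <= 1, delta > 0)
  hit <- runif(length(v)) < mu
  if (any(hit)) {
    off <- runif(sum(hit), -delta, delta)
    v[hit] <- pmin(1, pmax(0, v[hit] + off))
  }
  v
}
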