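#' Scenario configuration
#'
#' Everything needed to reproduce one simulation run: arena geometry, initial
#' populations and placement, initial attribute values, mutability and
#' mutation probabilities per species and attribute, kinetic constants, the
#' step limit and the decay mode.
#'
#' Placement `"circle"` puts the two species into opposite half-discs of a
#' disc of radius `disc_radius` centered in the arena (replicases in the
#' upper half, parasites in the lower); `"random"` scatters all molecules
#' uniformly over the torus.
#'
#' The decay mode resolves an ambiguity in how complexed molecules age:
#' `"ticking"` (default) keeps member lifetime clocks running inside a
#' complex, so a member can decay mid-complex, freeing its partner;
#' `"frozen"` pauses member clocks at complex formation and restores them
#' verbatim at dissociation. Both are faithful readings of the source model
#' description; see the methods vignette.
#'
#' @param width,height arena dimensions (length units).
#' @param n_replicases,n_parasites initial population sizes.
#' @param placement `"circle"` or `"random"`.
#' @param disc_radius radius of the initial disc for circle placement.
#' @param a_R0,l_R0,a_P0,l_P0 initial attribute values, shared by all members
#'   of a species.
#' @param mutable_a_R,mutable_l_R,mutable_a_P,mutable_l_P logical mutability
#'   flags; an immutable attribute ignores its mutation probability.
#' @param mu_a_R,mu_l_R,mu_a_P,mu_l_P per-replication mutation probabilities.
#' @param delta mutation perturbation half-width.
#' @param kinetics an [kinetic_params()] object.
#' @param max_steps step limit for the run (> 0).
#' @param decay_mode `"frozen"` (default) or `"ticking"`.
#' @param offspring_offset distance at which the offspring is placed from
#'   the complex position, in a uniformly random direction. The default 0
#'   places the offspring exactly at the complex position ("equal to the
#'   template"); a positive offset emulates placement into a neighboring
#'   lattice cell instead.
#' @param max_density upper bound on initial molecule density (molecules per
#'   unit area); initialization refuses denser configurations.
#' @param seed optional default RNG seed carried with the config.
#' @param label optional free-text label.
#' @return an object of class `rp_scenario`.
#' @export
rp_scenario <- function(width = 256, height = width,
                        n_replicases = 2500, n_parasites = 2500,
                        placement = c("circle", "random"), disc_radius = 64,
                        a_R0 = 0.7, l_R0 = 0, a_P0 = 0.55, l_P0 = 0.2,
                        mutable_a_R = FALSE, mutable_l_R = FALSE,
                        mutable_a_P = TRUE, mutable_l_P = TRUE,
                        mu_a_R = 0.01, mu_l_R = 0.01,
                        mu_a_P = 0.01, mu_l_P = 0.01,
                        delta = 0.05, kinetics = kinetic_params(),
                        max_steps = 150000,
                        decay_mode = c("frozen", "ticking"),
                        offspring_offset = 0, max_density = 3,
                        seed = NULL, label = NULL) {
  placement <- match.arg(placement)
  decay_mode <- match.arg(decay_mode)
  cfg <- structure(list(
    width = width, height = height,
    n_replicases = as.integer(n_replicases),
    n_parasites = as.integer(n_parasites),
    placement = placement, disc_radius = disc_radius,
    a_R0 = a_R0, l_R0 = l_R0, a_P0 = a_P0, l_P0 = l_P0,
    mutable_a_R = mutable_a_R, mutable_l_R = mutable_l_R,
    mutable_a_P = mutable_a_P, mutable_l_P = mutable_l_P,
    mu_a_R = mu_a_R, mu_l_R = mu_l_R, mu_a_P = mu_a_P, mu_l_P = mu_l_P,
    delta = delta, kinetics = kinetics,
    max_steps = as.integer(max_steps), decay_mode = decay_mode,
    offspring_offset = offspring_offset, max_density = max_density,
    seed = if (is.null(seed)) NULL else as.integer(seed),
    label = label), class = "rp_scenario")
  validate_scenario(cfg)
}

#' Validate a scenario configuration
#'
#' Checks ranges (attributes and probabilities in `[0, 1]`, positive
#' dimensions and step limit, density bound) and returns the config
#' invisibly unchanged, or raises an error.
#'
#' @param config an `rp_scenario`.
#' @return the validated config, invisibly.
#' @export
validate_scenario <- function(config) {
  stopifnot(inherits(config, "rp_scenario"))
  with(config, {
    stopifnot(width > 0, height > 0, n_replicases >= 0, n_parasites >= 0,
              disc_radius > 0, max_steps > 0, offspring_offset >= 0,
              is.logical(mutable_a_R), is.logical(mutable_l_R),
              is.logical(mutable_a_P), is.logical(mutable_l_P),
              inherits(kinetics, "rp_kinetics"),
              decay_mode %in% c("ticking", "frozen"))
    attrs <- c(a_R0 = a_R0, l_R0 = l_R0, a_P0 = a_P0, l_P0 = l_P0)
    if (any(attrs < 0 | attrs > 1))
      stop("initial attribute values must lie in [0, 1]")
    mus <- c(mu_a_R = mu_a_R, mu_l_R = mu_l_R, mu_a_P = mu_a_P,
             mu_l_P = mu_l_P)
    if (any(mus < 0 | mus > 1))
      stop("mutation probabilities must lie in [0, 1]")
    if (delta <= 0) stop("delta must be > 0")
    if ((n_replicases + n_parasites) / (width * height) > max_density)
      stop("initial population exceeds the configured density bound")
    if (placement == "circle" && disc_radius > min(width, height) / 2)
      stop("initial disc does not fit in the arena")
  })
  invisible(config)
}

# effective per-species mutation probabilities: immutable => 0
effective_mutation <- function(config) {
  mutation_params(
    mu_a_R = if (config$mutable_a_R) config$mu_a_R else 0,
    mu_l_R = if (config$mutable_l_R) config$mu_l_R else 0,
    mu_a_P = if (config$mutable_a_P) config$mu_a_P else 0,
    mu_l_P = if (config$mutable_l_P) config$mu_l_P else 0,
    delta = config$delta)
}

#' @export
print.rp_scenario <- function(x, ...) {
  cat("<rp_scenario>", if (!is.null(x$label)) x$label else "", "\n")
  cat(sprintf("  arena %g x %g, %d R + %d P (%s placement, disc %g)\n",
              x$width, x$height, x$n_replicases, x$n_parasites,
              x$placement, x$disc_radius))
  cat(sprintf("  R: a0=%g l0=%g (mutable a:%s l:%s, mu %g/%g)\n",
              x$a_R0, x$l_R0, x$mutable_a_R, x$mutable_l_R, x$mu_a_R,
              x$mu_l_R))
  cat(sprintf("  P: a0=%g l0=%g (mutable a:%s l:%s, mu %g/%g)\n",
              x$a_P0, x$l_P0, x$mutable_a_P, x$mutable_l_P, x$mu_a_P,
              x$mu_l_P))
  k <- x$kinetics
  cat(sprintf("  kinetics d=%g D=%g D'=%g K=%g dt=%g r=%g n_max=%d\n",
              k$d, k$D, k$D_complex, k$K, k$dt, k$radius, k$n_max))
  cat(sprintf("  max_steps=%d decay=%s delta=%g offspring_offset=%g\n",
              x$max_steps, x$decay_mode, x$delta, x$offspring_offset))
  invisible(x)
}

# Desk-scale run conditions used by the scaled presets and the acceptance
# protocol: quarter-area arena, populations scaled with the area, step
# budgets per experiment. Chosen once; see the methods vignette.
scaled_dims <- function() {
  list(width = 128, disc_radius = 32, n_each = 1250,
       steps = c(`1` = 30000L, `2` = 30000L, `3` = 16000L, `4` = 50000L,
                 `5` = 50000L))
}

#' Published experiment presets
#'
#' Returns the scenario configurations of the five published computational
#' experiments:
#'
#' * **1** — parasites mutate mildly: `a_P0 = 0.55`, `l_P0 = 0.2`,
#'   `mu_aP = mu_lP = 0.01` (1 config).
#' * **2** — only `l_P` mutates (`mu_lP = 0.19`), `a_P = 0.55` immutable,
#'   `l_P0` swept 0 to 1 in steps of 0.1 (11 configs).
#' * **3** — only `a_P` mutates (`mu_aP = 0.19`), `l_P = 0.2` immutable,
#'   `a_P0` swept 0 to 1 (11 configs).
#' * **4** — `a_P0` swept 0 to 1 but immutable; `l_P` mutates
#'   (`mu_lP = 0.19`) (11 configs).
#' * **5** — all four attributes mutate at probability 0.01;
#'   `l_P0 = l_R0 = 0.2`; seven `(a_P0, a_R0)` pairs, each with circle and
#'   random placement (14 configs).
#'
#' In experiments 1-4 replicases are immutable with `a_R = 0.7`, `l_R = 0`
#' (catalytically active regardless of folding, and always available as
#' templates). All presets carry the published kinetic constants.
#'
#' @param experiment experiment id, 1 to 5.
#' @param index optional 1-based index selecting one config from the list.
#' @param scaled if `TRUE` (default) the preset uses the desk-scale
#'   conditions (128 x 128 arena, 1250 + 1250 molecules, experiment-specific
#'   step budgets); if `FALSE`, the reference scale (256 x 256, 2500 + 2500,
#'   150k steps).
#' @return a list of `rp_scenario` objects, or a single one when `index` is
#'   given.
#' @export
rp_preset <- function(experiment, index = NULL, scaled = TRUE) {
  if (!experiment %in% 1:5) stop("unknown experiment id: ", experiment)
  sd <- scaled_dims()
  base <- function(..., label) {
    if (scaled)
      rp_scenario(width = sd$width, disc_radius = sd$disc_radius,
                  n_replicases = sd$n_each, n_parasites = sd$n_each,
                  max_steps = sd$steps[[as.character(experiment)]],
                  label = paste0(label, " [scaled]"), ...)
    else
      rp_scenario(label = label, ...)
  }
  sweep <- seq(0, 1, by = 0.1)
  cfgs <- switch(as.character(experiment),
    "1" = list(base(a_P0 = 0.55, l_P0 = 0.2,
                    mutable_a_P = TRUE, mutable_l_P = TRUE,
                    mu_a_P = 0.01, mu_l_P = 0.01,
                    label = "experiment 1")),
    "2" = lapply(sweep, function(l0)
      base(a_P0 = 0.55, l_P0 = l0,
           mutable_a_P = FALSE, mutable_l_P = TRUE, mu_l_P = 0.19,
           label = sprintf("experiment 2, l_P0=%.1f", l0))),
    "3" = lapply(sweep, function(a0)
      base(a_P0 = a0, l_P0 = 0.2,
           mutable_a_P = TRUE, mutable_l_P = FALSE, mu_a_P = 0.19,
           label = sprintf("experiment 3, a_P0=%.1f", a0))),
    "4" = lapply(sweep, function(a0)
      base(a_P0 = a0, l_P0 = 0.2,
           mutable_a_P = FALSE, mutable_l_P = TRUE, mu_l_P = 0.19,
           label = sprintf("experiment 4, a_P0=%.1f", a0))),
    "5" = {
      pairs <- rbind(c(0.3, 0.5), c(0.4, 0.6), c(0.4, 0.7), c(0.55, 0.6),
                     c(0.55, 0.7), c(0.8, 0.6), c(0.8, 0.7))
      out <- list()
      for (i in seq_len(nrow(pairs)))
        for (pl in c("circle", "random"))
          out[[length(out) + 1L]] <- base(
            a_P0 = pairs[i, 1], a_R0 = pairs[i, 2],
            l_P0 = 0.2, l_R0 = 0.2, placement = pl,
            mutable_a_R = TRUE, mutable_l_R = TRUE,
            mutable_a_P = TRUE, mutable_l_P = TRUE,
            mu_a_R = 0.01, mu_l_R = 0.01, mu_a_P = 0.01, mu_l_P = 0.01,
            label = sprintf("experiment 5, a_P0=%.2f a_R0=%.1f, %s",
                            pairs[i, 1], pairs[i, 2], pl))
      out
    })
  if (is.null(index)) cfgs
  else {
    if (index < 1 || index > length(cfgs))
      stop("preset index out of range (experiment ", experiment, " has ",
           length(cfgs), " configurations)")
    cfgs[[index]]
  }
}
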