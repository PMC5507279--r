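species_levels <- c("replicase", "parasite")

species_to_code <- function(x) {
  code <- match(x, species_levels) - 1L
  if (any(is.na(code))) stop("species must be 'replicase' or 'parasite'")
  code
}

#' Construct a simulation engine
#'
#' Creates the compiled world for a scenario, seeds its private RNG and
#' places the initial populations. The engine is a mutable handle: stepping
#' advances it in place. All randomness of the run is consumed from the
#' engine's own stream, so `(config, seed)` determines everything.
#'
#' @param config an [rp_scenario()].
#' @param seed integer seed (required here or in `config$seed`).
#' @param populate place the initial populations (default `TRUE`); with
#'   `FALSE` the world starts empty, for use with [rp_engine_from_state()]
#'   style state injection.
#' @return an object of class `rp_engine`.
#' @export
rp_engine <- function(config, seed = config$seed, populate = TRUE) {
  validate_scenario(config)
  if (is.null(seed)) stop("a seed is required")
  kin <- config$kinetics
  mut <- effective_mutation(config)
  ptr <- .cpp_engine_new(config$width, config$height, unclass(kin),
                         unclass(mut),
                         if (config$decay_mode == "ticking") 0L else 1L,
                         config$offspring_offset, as.numeric(seed))
  eng <- structure(list(ptr = ptr, config = config, seed = as.integer(seed)),
                   class = "rp_engine")
  if (populate)
    .cpp_engine_populate(ptr, config$n_replicases, config$n_parasites,
                         config$placement, config$disc_radius,
                         config$a_R0, config$l_R0, config$a_P0, config$l_P0)
  eng
}

#' Build an engine from an explicit world state
#'
#' Injects a hand-built [rp_world()] state into a fresh engine, for
#' controlled experiments and tests (e.g. single-molecule traces or worlds
#' made only of complexes).
#'
#' @param state an `rp_world` state (see [rp_world()] / [rp_state()]).
#' @param kinetics an [kinetic_params()].
#' @param mutation a [mutation_params()].
#' @param seed integer seed for the engine stream.
#' @param decay_mode `"frozen"` (default) or `"ticking"`.
#' @param offspring_offset offspring placement distance (0 = at the complex
#'   position).
#' @return an `rp_engine`.
#' @export
rp_engine_from_state <- function(state, kinetics = kinetic_params(),
                                 mutation = mutation_params(),
                                 seed = 1L,
                                 decay_mode = c("frozen", "ticking"),
                                 offspring_offset = 0) {
  stopifnot(inherits(state, "rp_world"))
  decay_mode <- match.arg(decay_mode)
  geom <- state$geometry
  ptr <- .cpp_engine_new(geom$width, geom$height, unclass(kinetics),
                         unclass(mutation),
                         if (decay_mode == "ticking") 0L else 1L,
                         offspring_offset, as.numeric(seed))
  mol <- state$molecules
  mol_df <- data.frame(id = as.integer(mol$id),
                       species_code = species_to_code(mol$species),
                       x = mol$x, y = mol$y, a = mol$a, l = mol$l,
                       rlt = mol$rlt)
  cx <- state$complexes
  cx_df <- data.frame(x = cx$x, y = cx$y, ttr = cx$ttr,
                      diss_rlt = cx$diss_rlt,
                      cat_id = as.integer(cx$cat_id),
                      cat_species_code = species_to_code(cx$cat_species),
                      cat_a = cx$cat_a, cat_l = cx$cat_l,
                      cat_rlt = cx$cat_rlt, cat_rlt0 = cx$cat_rlt0,
                      tmpl_id = as.integer(cx$tmpl_id),
                      tmpl_species_code = species_to_code(cx$tmpl_species),
                      tmpl_a = cx$tmpl_a, tmpl_l = cx$tmpl_l,
                      tmpl_rlt = cx$tmpl_rlt, tmpl_rlt0 = cx$tmpl_rlt0)
  .cpp_engine_set_state(ptr, mol_df, cx_df, state$time, state$step,
                        as.integer(state$next_id))
  structure(list(ptr = ptr, config = NULL, seed = as.integer(seed),
                 geometry = geom),
            class = "rp_engine")
}

#' Advance an engine
#'
#' Executes up to `n` whole simulation steps in place. With
#' `stop_on_extinction = TRUE` (default) the loop stops as soon as either
#' species (counting complexed members) has died out, before executing
#' another step.
#'
#' @param engine an [rp_engine()].
#' @param n maximum number of steps to execute.
#' @param stop_on_extinction stop when either species count reaches zero.
#' @return invisibly, a list with `steps_done`, current `step`, `time` and
#'   the total species counts.
#' @export
rp_step <- function(engine, n = 1, stop_on_extinction = TRUE) {
  stopifnot(inherits(engine, "rp_engine"), n >= 0)
  invisible(.cpp_engine_run(engine$ptr, as.numeric(n), stop_on_extinction))
}

#' Extract the current world state
#'
#' @param engine an [rp_engine()].
#' @return an [rp_world()] snapshot (free molecules, complexes, clock).
#' @export
rp_state <- function(engine) {
  stopifnot(inherits(engine, "rp_engine"))
  s <- .cpp_engine_state(engine$ptr)
  mol <- s$molecules
  molecules <- data.frame(id = mol$id,
                          species = species_levels[mol$species_code + 1L],
                          x = mol$x, y = mol$y, a = mol$a, l = mol$l,
                          rlt = mol$rlt)
  cx <- s$complexes
  complexes <- data.frame(x = cx$x, y = cx$y, ttr = cx$ttr,
                          diss_rlt = cx$diss_rlt,
                          cat_id = cx$cat_id,
                          cat_species = species_levels[cx$cat_species_code + 1L],
                          cat_a = cx$cat_a, cat_l = cx$cat_l,
                          cat_rlt = cx$cat_rlt, cat_rlt0 = cx$cat_rlt0,
                          tmpl_id = cx$tmpl_id,
                          tmpl_species = species_levels[cx$tmpl_species_code + 1L],
                          tmpl_a = cx$tmpl_a, tmpl_l = cx$tmpl_l,
                          tmpl_rlt = cx$tmpl_rlt, tmpl_rlt0 = cx$tmpl_rlt0)
  geom <- if (!is.null(engine$config))
    rp_geometry(engine$config$width, engine$config$height)
  else engine$geometry
  rp_world(molecules, complexes, geom, time = s$time, step = s$step,
           next_id = s$next_id, check = FALSE)
}

#' Per-step population time series of a run
#'
#' One row per executed step (plus the initial state): free and complexed
#' counts by species, total molecule counts (an RR complex holds two
#' replicases, an RP complex one of each), and the mean and standard
#' deviation of `a` and `l` per species over the whole living population,
#' complexed members included. Means and SDs are `NA` while a species is
#' extinct. SDs are population standard deviations (denominator n).
#'
#' @param engine an [rp_engine()].
#' @return a data frame, one row per recorded step.
#' @export
rp_series <- function(engine) {
  stopifnot(inherits(engine, "rp_engine"))
  .cpp_engine_series(engine$ptr)
}

#' Per-step event log of a run
#'
#' Counts per step of decays of free molecules, decays inside complexes,
#' clock dissociations (a dissociation triggered by the complex lifetime
#' clock; the release that follows every replication is accounted under
#' `replications`), replications, complex formations, and molecules removed
#' by overcrowding. These reconcile exactly with the molecule ledger:
#' the change in total molecules each step equals
#' `replications - decays - overcrowd_removals`.
#'
#' @param engine an [rp_engine()].
#' @return a data frame, one row per recorded step.
#' @export
rp_events <- function(engine) {
  stopifnot(inherits(engine, "rp_engine"))
  .cpp_engine_events(engine$ptr)
}

#' Current species counts of an engine
#'
#' @param engine an [rp_engine()].
#' @return named numeric vector of free, complexed and total counts.
#' @export
rp_counts <- function(engine) {
  stopifnot(inherits(engine, "rp_engine"))
  .cpp_engine_counts(engine$ptr)
}

#' @export
print.rp_engine <- function(x, ...) {
  n <- rp_counts(x)
  cat(sprintf(
    "<rp_engine> seed %d | %g R + %g P (%g RR, %g RP complexes)\n",
    x$seed, n[["n_R_total"]], n[["n_P_total"]], n[["n_RR_complexes"]],
    n[["n_RP_complexes"]]))
  invisible(x)
}

#' Initialize a world from a scenario
#'
#' Places the configured populations (circle or random mode), assigns the
#' shared initial attribute values and draws every molecule's remaining
#' lifetime from Exp(d), consuming the run's RNG stream. This is the state a
#' run starts from.
#'
#' @param config an [rp_scenario()].
#' @param seed integer seed.
#' @return an [rp_world()] snapshot of the initial state.
#' @export
initialize_world <- function(config, seed = config$seed) {
  rp_state(rp_engine(config, seed))
}

#' Run a scenario
#'
#' Executes a full run: initializes the world, steps until the step limit or
#' the extinction of either species, and collects the per-step time series
#' and event log. Optionally invokes an observer callback on periodic state
#' snapshots (e.g. a frame renderer); observers cannot alter the trajectory,
#' which depends only on `(config, seed)`.
#'
#' @param config an [rp_scenario()].
#' @param seed integer seed.
#' @param max_steps optional override of `config$max_steps`.
#' @param observer optional `function(state, step)` called on snapshots.
#' @param observe_every snapshot cadence in steps when `observer` is given.
#' @return an object of class `rp_run` with elements `series`, `events`,
#'   `outcome`, `final_step`, `final_state`, `config`, `seed`.
#' @export
run_scenario <- function(config, seed = config$seed, max_steps = NULL,
                         observer = NULL, observe_every = 1000L) {
  validate_scenario(config)
  if (is.null(max_steps)) max_steps <- config$max_steps
  stopifnot(max_steps > 0)
  eng <- rp_engine(config, seed)
  if (is.null(observer)) {
    rp_step(eng, max_steps, stop_on_extinction = TRUE)
  } else {
    done <- 0
    observer(rp_state(eng), 0L)
    while (done < max_steps) {
      chunk <- min(observe_every, max_steps - done)
      st <- rp_step(eng, chunk, stop_on_extinction = TRUE)
      done <- done + st$steps_done
      observer(rp_state(eng), as.integer(st$step))
      if (st$steps_done < chunk) break # extinction
    }
  }
  series <- rp_series(eng)
  final <- series[nrow(series), ]
  outcome <- classify_outcome(series, max_steps)
  structure(list(series = series, events = rp_events(eng), outcome = outcome,
                 final_step = as.integer(final$step),
                 final_state = rp_state(eng), config = config,
                 seed = as.integer(seed)),
            class = "rp_run")
}

#' Classify the outcome of a finished run
#'
#' `survived` if both species (complexed members included) are present at the
#' step limit; otherwise labeled by which species reached zero
#' (`extinct_parasites`, `extinct_replicases`, or `extinct_both` when both
#' hit zero at the same step).
#'
#' @param series a run time series (from [rp_series()]) or an `rp_run`.
#' @param max_steps the step limit of the run.
#' @return one of `"survived"`, `"extinct_parasites"`,
#'   `"extinct_replicases"`, `"extinct_both"`.
#' @export
classify_outcome <- function(series, max_steps) {
  if (inherits(series, "rp_run")) series <- series$series
  final <- series[nrow(series), ]
  r0 <- final$n_R_total == 0
  p0 <- final$n_P_total == 0
  if (r0 && p0) "extinct_both"
  else if (r0) "extinct_replicases"
  else if (p0) "extinct_parasites"
  else if (final$step >= max_steps) "survived"
  else "survived" # both alive when the loop stopped early
}
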