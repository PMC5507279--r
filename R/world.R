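#' World state container
#'
#' A snapshot of the simulated world: the free molecules, the bound
#' catalyst-template complexes (with their stored member attributes and
#' clocks), the arena geometry and the simulation clock. Complexed molecules
#' never appear in the free-molecule table; a complex carries its two
#' members inline.
#'
#' @param molecules data frame with columns `id`, `species` ("replicase" or
#'   "parasite"), `x`, `y`, `a`, `l`, `rlt`.
#' @param complexes data frame with columns `x`, `y`, `ttr`, `diss_rlt`
#'   (`NA` encodes an infinite dissociation time for template affinity 1),
#'   and for each member (`cat_`/`tmpl_` prefixes) `id`, `species`, `a`,
#'   `l`, `rlt`, `rlt0`. The catalyst must be a replicase.
#' @param geometry an [rp_geometry()].
#' @param time simulation time.
#' @param step step counter.
#' @param next_id next unused molecule id.
#' @param check validate invariants (positions canonical, attributes in
#'   `[0, 1]`, no parasite catalyst, unique ids).
#' @return an object of class `rp_world`.
#' @export
rp_world <- function(molecules = empty_molecules(),
                     complexes = empty_complexes(), geometry,
                     time = 0, step = 0, next_id = NULL, check = TRUE) {
  stopifnot(inherits(geometry, "rp_geometry"))
  if (is.null(next_id)) {
    ids <- c(molecules$id, complexes$cat_id, complexes$tmpl_id)
    next_id <- if (length(ids)) max(ids) + 1L else 1L
  }
  w <- structure(list(molecules = molecules, complexes = complexes,
                      geometry = geometry, time = time, step = step,
                      next_id = as.integer(next_id)),
                 class = "rp_world")
  if (check) validate_world(w)
  w
}

empty_molecules <- function() {
  data.frame(id = integer(), species = character(), x = numeric(),
             y = numeric(), a = numeric(), l = numeric(), rlt = numeric())
}

empty_complexes <- function() {
  data.frame(x = numeric(), y = numeric(), ttr = numeric(),
             diss_rlt = numeric(), cat_id = integer(),
             cat_species = character(), cat_a = numeric(),
             cat_l = numeric(), cat_rlt = numeric(), cat_rlt0 = numeric(),
             tmpl_id = integer(), tmpl_species = character(),
             tmpl_a = numeric(), tmpl_l = numeric(), tmpl_rlt = numeric(),
             tmpl_rlt0 = numeric())
}

validate_world <- function(w) {
  m <- w$molecules
  cx <- w$complexes
  g <- w$geometry
  if (nrow(m)) {
    stopifnot(all(m$species %in% species_levels))
    if (any(m$x < 0 | m$x >= g$width | m$y < 0 | m$y >= g$height))
      stop("molecule positions must be canonical")
    if (any(m$a < 0 | m$a > 1 | m$l < 0 | m$l > 1))
      stop("attributes must lie in [0, 1]")
  }
  if (nrow(cx)) {
    if (any(cx$cat_species != "replicase"))
      stop("a parasite can never be the catalyst of a complex")
    attrs <- c(cx$cat_a, cx$cat_l, cx$tmpl_a, cx$tmpl_l)
    if (any(attrs < 0 | attrs > 1))
      stop("attributes must lie in [0, 1]")
  }
  ids <- c(m$id, cx$cat_id, cx$tmpl_id)
  if (anyDuplicated(ids)) stop("molecule ids must be unique")
  invisible(w)
}

#' @export
print.rp_world <- function(x, ...) {
  r <- record_state(x)
  cat(sprintf(
    "<rp_world> step %g (t=%g): %d free molecules, %d complexes\n",
    x$step, x$time, nrow(x$molecules), nrow(x$complexes)))
  cat(sprintf("  totals: %g replicases, %g parasites\n",
              r$n_R_total, r$n_P_total))
  invisible(x)
}

#' Record population observables from a world state
#'
#' Exact counts and arithmetic means/SDs of `a` and `l` per species over all
#' living molecules, complexed members included. This is the quantity the
#' per-step time series records; the engine's incremental bookkeeping is
#' tested against this full recount.
#'
#' @param state an [rp_world()].
#' @return a one-row data frame in the time-series column layout.
#' @export
record_state <- function(state) {
  stopifnot(inherits(state, "rp_world"))
  m <- state$molecules
  cx <- state$complexes
  rr <- sum(cx$tmpl_species == "replicase")
  rp <- nrow(cx) - rr
  sp <- c(m$species, cx$cat_species, cx$tmpl_species)
  a <- c(m$a, cx$cat_a, cx$tmpl_a)
  l <- c(m$l, cx$cat_l, cx$tmpl_l)
  stat <- function(v, keep) {
    v <- v[keep]
    if (!length(v)) c(NA_real_, NA_real_)
    else c(mean(v), sqrt(max(0, mean(v^2) - mean(v)^2)))
  }
  isR <- sp == "replicase"
  aR <- stat(a, isR); lR <- stat(l, isR)
  aP <- stat(a, !isR); lP <- stat(l, !isR)
  data.frame(step = state$step, time = state$time,
             n_R_free = sum(m$species == "replicase"),
             n_P_free = sum(m$species == "parasite"),
             n_RR_complexes = rr, n_RP_complexes = rp,
             n_R_total = sum(isR), n_P_total = sum(!isR),
             mean_a_R = aR[1], sd_a_R = aR[2],
             mean_l_R = lR[1], sd_l_R = lR[2],
             mean_a_P = aP[1], sd_a_P = aP[2],
             mean_l_P = lP[1], sd_l_P = lP[2])
}
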