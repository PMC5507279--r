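# R-level complex lifecycle operations. These implement the same contracts
# the compiled engine applies in bulk, on single molecule/complex rows in the
# rp_world table layout; they are the reference implementation used in tests
# and for interactive exploration of the rules.

#' Attempt catalyst-template complex formation for a colliding pair
#'
#' Applies the template-selection rule and the reaction test to a pair of
#' free molecules in collision range. If exactly one of the pair is a
#' parasite, the parasite is the template (whichever side initiated); if
#' both are replicases, the non-initiating molecule is the template. Two
#' parasites can never bind. With probability `omega = a_t (1 - l_t)` of the
#' template the pair forms a complex: the replication clock is drawn from
#' Exp(K), the dissociation clock from Exp(1 - a_t) (infinite, encoded `NA`,
#' when `a_t = 1`), the position is the minimal-image midpoint of the pair,
#' and both members' lifetime clocks are stored. Otherwise the collision is
#' elastic and `NULL` is returned.
#'
#' Draws (one uniform for the reaction test; on success the two clock draws)
#' come from R's RNG.
#'
#' @param initiator,candidate one-row data frames in the molecule-table
#'   layout of [rp_world()] (`id`, `species`, `x`, `y`, `a`, `l`, `rlt`).
#' @param kinetics an [kinetic_params()].
#' @param geometry an [rp_geometry()].
#' @return a one-row complex data frame (see [rp_world()]), or `NULL`.
#' @export
attempt_complex_formation <- function(initiator, candidate, kinetics,
                                      geometry) {
  stopifnot(nrow(initiator) == 1L, nrow(candidate) == 1L,
            inherits(kinetics, "rp_kinetics"))
  if (initiator$species == "parasite" && candidate$species == "parasite")
    stop("two parasites can never form a complex")
  if (initiator$species == "parasite") {
    tmpl <- initiator; cat <- candidate
  } else if (candidate$species == "parasite") {
    tmpl <- candidate; cat <- initiator
  } else {
    tmpl <- candidate; cat <- initiator  # R-R: the non-initiator is template
  }
  omega <- reaction_probability(tmpl$a, tmpl$l)
  if (runif(1) >= omega) return(NULL)
  pos <- torus_midpoint(c(initiator$x, initiator$y),
                        c(candidate$x, candidate$y), geometry)
  ttr <- sample_waiting_time(kinetics$K)
  diss <- if (tmpl$a >= 1) NA_real_ else sample_waiting_time(1 - tmpl$a)
  data.frame(x = pos[[1L]], y = pos[[2L]], ttr = ttr, diss_rlt = diss,
             cat_id = cat$id, cat_species = cat$species, cat_a = cat$a,
             cat_l = cat$l, cat_rlt = cat$rlt, cat_rlt0 = cat$rlt,
             tmpl_id = tmpl$id, tmpl_species = tmpl$species,
             tmpl_a = tmpl$a, tmpl_l = tmpl$l, tmpl_rlt = tmpl$rlt,
             tmpl_rlt0 = tmpl$rlt)
}

#' Replicate a complex whose replication clock has expired
#'
#' Produces the offspring (a copy of the template's species and attributes,
#' each attribute then passed through [mutate_attribute()] with its
#' per-species probability), draws its lifetime from Exp(d), places it at
#' the configured offset from the complex position, and releases catalyst
#' and template as free molecules at the complex position (replication is
#' always followed by immediate dissociation). Member clocks on release
#' follow the decay mode: their stored formation-time values under
#' `"frozen"`, their current values under `"ticking"`.
#'
#' @param complex a one-row complex data frame with `ttr <= 0`.
#' @param kinetics an [kinetic_params()].
#' @param mutation a [mutation_params()] (effective per-species
#'   probabilities; 0 disables an attribute).
#' @param geometry an [rp_geometry()].
#' @param offspring_id id to assign to the new molecule.
#' @param offspring_offset placement distance from the complex position.
#' @param decay_mode `"frozen"` or `"ticking"`.
#' @return a list with one-row molecule data frames `offspring`, `catalyst`
#'   and `template`.
#' @export
replicate_complex <- function(complex, kinetics, mutation, geometry,
                              offspring_id = NA_integer_,
                              offspring_offset = 0,
                              decay_mode = c("frozen", "ticking")) {
  stopifnot(nrow(complex) == 1L, inherits(mutation, "rp_mutation"))
  decay_mode <- match.arg(decay_mode)
  if (complex$ttr > 0)
    stop("replication requires an expired replication clock (ttr <= 0)")
  isR <- complex$tmpl_species == "replicase"
  a <- mutate_attribute(complex$tmpl_a,
                        if (isR) mutation$mu_a_R else mutation$mu_a_P,
                        mutation$delta)
  l <- mutate_attribute(complex$tmpl_l,
                        if (isR) mutation$mu_l_R else mutation$mu_l_P,
                        mutation$delta)
  theta <- runif(1, 0, 2 * pi)
  pos <- wrap_position(c(complex$x + offspring_offset * cos(theta),
                         complex$y + offspring_offset * sin(theta)),
                       geometry)
  offspring <- data.frame(id = offspring_id,
                          species = complex$tmpl_species,
                          x = pos[[1L]], y = pos[[2L]], a = a, l = l,
                          rlt = if (kinetics$d > 0)
                            sample_waiting_time(kinetics$d) else Inf)
  released <- dissociate_complex(complex, decay_mode)
  list(offspring = offspring,
       catalyst = released[released$id == complex$cat_id, ],
       template = released[released$id == complex$tmpl_id, ])
}

#' Dissociate a complex into its two free members
#'
#' Both members reappear at the complex position. Their lifetime clocks
#' follow the decay mode: restored verbatim from complex formation under
#' `"frozen"`, kept at their current (decremented) values under
#' `"ticking"`. The molecule ledger is unchanged by dissociation
#' (one complex out, two free molecules in).
#'
#' @param complex a one-row complex data frame.
#' @param decay_mode `"frozen"` or `"ticking"`.
#' @return a two-row molecule data frame (catalyst first).
#' @export
dissociate_complex <- function(complex, decay_mode = c("frozen", "ticking")) {
  stopifnot(nrow(complex) == 1L)
  decay_mode <- match.arg(decay_mode)
  data.frame(id = c(complex$cat_id, complex$tmpl_id),
             species = c(complex$cat_species, complex$tmpl_species),
             x = complex$x, y = complex$y,
             a = c(complex$cat_a, complex$tmpl_a),
             l = c(complex$cat_l, complex$tmpl_l),
             rlt = if (decay_mode == "frozen")
               c(complex$cat_rlt0, complex$tmpl_rlt0)
             else c(complex$cat_rlt, complex$tmpl_rlt))
}
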