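#' Summarize a run as a JSON document
#'
#' Writes a machine-readable run summary: the full configuration echo, the
#' seed, the outcome label, the final step, the per-attribute stabilization
#' step (trailing-window slope test, see [detect_stabilization()]) and the
#' number of recorded steps. The document validates against the JSON schema
#' shipped at `inst/schema/run-summary.schema.json`.
#'
#' @param run an `rp_run` from [run_scenario()].
#' @param file output path.
#' @param stabilization_window window length for [detect_stabilization()].
#' @param stabilization_tol slope tolerance, attribute units per step.
#' @return `file`, invisibly.
#' @export
write_run_summary <- function(run, file, stabilization_window = 10000,
                              stabilization_tol = 1e-6) {
  stopifnot(inherits(run, "rp_run"))
  cfg <- run$config
  stab <- lapply(c(a_R = "mean_a_R", l_R = "mean_l_R",
                   a_P = "mean_a_P", l_P = "mean_l_P"),
                 function(col) {
                   s <- detect_stabilization(run$series[[col]],
                                             stabilization_window,
                                             stabilization_tol)
                   if (is.na(s)) NULL else s
                 })
  doc <- list(
    config = list(
      world = list(width = cfg$width, height = cfg$height),
      kinetics = unclass(cfg$kinetics),
      mutation = list(delta = cfg$delta),
      species = list(
        replicase = list(a0 = cfg$a_R0, l0 = cfg$l_R0,
                         mutable_a = cfg$mutable_a_R,
                         mutable_l = cfg$mutable_l_R,
                         mu_a = cfg$mu_a_R, mu_l = cfg$mu_l_R),
        parasite = list(a0 = cfg$a_P0, l0 = cfg$l_P0,
                        mutable_a = cfg$mutable_a_P,
                        mutable_l = cfg$mutable_l_P,
                        mu_a = cfg$mu_a_P, mu_l = cfg$mu_l_P)),
      init = list(n_replicases = cfg$n_replicases,
                  n_parasites = cfg$n_parasites,
                  placement = cfg$placement,
                  disc_radius = cfg$disc_radius),
      run = list(max_steps = cfg$max_steps, decay_mode = cfg$decay_mode,
                 offspring_offset = cfg$offspring_offset)),
    seed = run$seed,
    outcome = run$outcome,
    final_step = run$final_step,
    stabilization = stab,
    recorded_steps = nrow(run$series) - 1L)
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(file)
}
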