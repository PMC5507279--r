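# Scenario config file I/O.
#
# The dialect is a TOML subset: `[section]` / `[section.sub]` headers and
# scalar `key = value` pairs (double-quoted strings, booleans, numbers),
# with `#` comments. Unknown sections or keys are errors, so typos fail
# fast instead of silently running a different scenario.

strip_comment <- function(line) {
  chars <- strsplit(line, "", fixed = TRUE)[[1L]]
  inq <- FALSE
  for (i in seq_along(chars)) {
    if (chars[i] == '"') inq <- !inq
    if (chars[i] == "#" && !inq) return(substr(line, 1L, i - 1L))
  }
  line
}

parse_toml_value <- function(raw, file, lineno) {
  raw <- trimws(raw)
  if (raw == "")
    stop(sprintf("%s:%d: missing value", file, lineno))
  if (grepl('^".*"$', raw))
    return(gsub('\\"', '"', substr(raw, 2L, nchar(raw) - 1L), fixed = TRUE))
  if (raw == "true") return(TRUE)
  if (raw == "false") return(FALSE)
  v <- suppressWarnings(as.numeric(raw))
  if (is.na(v))
    stop(sprintf("%s:%d: cannot parse value '%s'", file, lineno, raw))
  v
}

read_toml <- function(file) {
  lines <- readLines(file)
  out <- list()
  section <- character(0)
  for (i in seq_along(lines)) {
    line <- trimws(strip_comment(lines[i]))
    if (line == "") next
    if (grepl("^\\[[A-Za-z0-9._-]+\\]$", line)) {
      section <- strsplit(substr(line, 2L, nchar(line) - 1L), ".",
                          fixed = TRUE)[[1L]]
      next
    }
    if (!grepl("=", line, fixed = TRUE))
      stop(sprintf("%s:%d: expected 'key = value'", file, i))
    key <- trimws(sub("=.*$", "", line))
    val <- parse_toml_value(sub("^[^=]*=", "", line), file, i)
    path <- c(section, key)
    out <- assign_nested(out, path, val)
  }
  out
}

assign_nested <- function(lst, path, val) {
  if (length(path) == 1L) {
    lst[[path]] <- val
    return(lst)
  }
  head_ <- path[[1L]]
  sub <- lst[[head_]]
  if (is.null(sub)) sub <- list()
  lst[[head_]] <- assign_nested(sub, path[-1L], val)
  lst
}

toml_scalar <- function(v) {
  if (is.character(v)) sprintf('"%s"', gsub('"', '\\"', v, fixed = TRUE))
  else if (is.logical(v)) if (v) "true" else "false"
  else if (v == round(v) && abs(v) < 2^31) sprintf("%d", as.integer(v))
  else sprintf("%.17g", v)
}

#' Write a scenario configuration file
#'
#' Serializes an [rp_scenario()] to a plain-text config file (TOML subset)
#' with sections `[world]`, `[kinetics]`, `[mutation]`,
#' `[species.replicase]`, `[species.parasite]`, `[init]` and `[run]`.
#' [read_scenario()] restores the scenario losslessly.
#'
#' @param config an [rp_scenario()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_scenario <- function(config, file) {
  validate_scenario(config)
  k <- config$kinetics
  lines <- c(
    "[world]",
    sprintf("width = %s", toml_scalar(config$width)),
    sprintf("height = %s", toml_scalar(config$height)),
    "",
    "[kinetics]",
    sprintf("d = %s", toml_scalar(k$d)),
    sprintf("D = %s", toml_scalar(k$D)),
    sprintf("D_complex = %s", toml_scalar(k$D_complex)),
    sprintf("K = %s", toml_scalar(k$K)),
    sprintf("dt = %s", toml_scalar(k$dt)),
    sprintf("radius = %s", toml_scalar(k$radius)),
    sprintf("n_max = %s", toml_scalar(k$n_max)),
    "",
    "[mutation]",
    sprintf("delta = %s", toml_scalar(config$delta)),
    "",
    "[species.replicase]",
    sprintf("a0 = %s", toml_scalar(config$a_R0)),
    sprintf("l0 = %s", toml_scalar(config$l_R0)),
    sprintf("mutable_a = %s", toml_scalar(config$mutable_a_R)),
    sprintf("mutable_l = %s", toml_scalar(config$mutable_l_R)),
    sprintf("mu_a = %s", toml_scalar(config$mu_a_R)),
    sprintf("mu_l = %s", toml_scalar(config$mu_l_R)),
    "",
    "[species.parasite]",
    sprintf("a0 = %s", toml_scalar(config$a_P0)),
    sprintf("l0 = %s", toml_scalar(config$l_P0)),
    sprintf("mutable_a = %s", toml_scalar(config$mutable_a_P)),
    sprintf("mutable_l = %s", toml_scalar(config$mutable_l_P)),
    sprintf("mu_a = %s", toml_scalar(config$mu_a_P)),
    sprintf("mu_l = %s", toml_scalar(config$mu_l_P)),
    "",
    "[init]",
    sprintf("n_replicases = %s", toml_scalar(config$n_replicases)),
    sprintf("n_parasites = %s", toml_scalar(config$n_parasites)),
    sprintf("placement = %s", toml_scalar(config$placement)),
    sprintf("disc_radius = %s", toml_scalar(config$disc_radius)),
    "",
    "[run]",
    sprintf("max_steps = %s", toml_scalar(config$max_steps)),
    sprintf("decay_mode = %s", toml_scalar(config$decay_mode)),
    sprintf("offspring_offset = %s", toml_scalar(config$offspring_offset)),
    sprintf("max_density = %s", toml_scalar(config$max_density)))
  if (!is.null(config$seed))
    lines <- c(lines, sprintf("seed = %s", toml_scalar(config$seed)))
  if (!is.null(config$label))
    lines <- c(lines, sprintf("label = %s", toml_scalar(config$label)))
  writeLines(lines, file)
  invisible(file)
}

expect_keys <- function(section, got, want, file) {
  extra <- setdiff(got, want)
  if (length(extra))
    stop(sprintf("%s: unknown key(s) in [%s]: %s", file, section,
                 paste(extra, collapse = ", ")))
}

#' Read a scenario configuration file
#'
#' Parses a config file written by [write_scenario()] (or by hand in the
#' same dialect) and validates it. Unknown sections or keys are errors.
#'
#' @param file path to a config file.
#' @return an [rp_scenario()].
#' @export
read_scenario <- function(file) {
  t <- read_toml(file)
  expect_keys("", names(t),
              c("world", "kinetics", "mutation", "species", "init", "run"),
              file)
  expect_keys("world", names(t$world), c("width", "height"), file)
  expect_keys("kinetics", names(t$kinetics),
              c("d", "D", "D_complex", "K", "dt", "radius", "n_max"), file)
  expect_keys("mutation", names(t$mutation), "delta", file)
  for (sp in c("replicase", "parasite"))
    expect_keys(paste0("species.", sp), names(t$species[[sp]]),
                c("a0", "l0", "mutable_a", "mutable_l", "mu_a", "mu_l"),
                file)
  expect_keys("init", names(t$init),
              c("n_replicases", "n_parasites", "placement", "disc_radius"),
              file)
  expect_keys("run", names(t$run),
              c("max_steps", "decay_mode", "offspring_offset",
                "max_density", "seed", "label"), file)
  r <- t$species$replicase
  p <- t$species$parasite
  rp_scenario(
    width = t$world$width, height = t$world$height,
    n_replicases = t$init$n_replicases, n_parasites = t$init$n_parasites,
    placement = t$init$placement, disc_radius = t$init$disc_radius,
    a_R0 = r$a0, l_R0 = r$l0, a_P0 = p$a0, l_P0 = p$l0,
    mutable_a_R = r$mutable_a, mutable_l_R = r$mutable_l,
    mutable_a_P = p$mutable_a, mutable_l_P = p$mutable_l,
    mu_a_R = r$mu_a, mu_l_R = r$mu_l, mu_a_P = p$mu_a, mu_l_P = p$mu_l,
    delta = t$mutation$delta,
    kinetics = kinetic_params(d = t$kinetics$d, D = t$kinetics$D,
                              D_complex = t$kinetics$D_complex,
                              K = t$kinetics$K, dt = t$kinetics$dt,
                              radius = t$kinetics$radius,
                              n_max = t$kinetics$n_max),
    max_steps = t$run$max_steps, decay_mode = t$run$decay_mode,
    offspring_offset = t$run$offspring_offset,
    max_density = t$run$max_density,
    seed = t$run$seed, label = t$run$label)
}
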