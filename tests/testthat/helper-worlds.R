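# Builders for small, fully specified world states used across tests.

make_molecules <- function(n, species = "replicase", x = NULL, y = NULL,
                           a = 0.7, l = 0, rlt = Inf, id_start = 1L) {
  data.frame(id = seq.int(id_start, length.out = n),
             species = rep_len(species, n),
             x = if (is.null(x)) rep(0, n) else rep_len(x, n),
             y = if (is.null(y)) rep(0, n) else rep_len(y, n),
             a = rep_len(a, n), l = rep_len(l, n),
             rlt = rep_len(rlt, n))
}

make_complex <- function(x, y, ttr, diss_rlt, cat_id, tmpl_id,
                         tmpl_species = "replicase",
                         cat_a = 0.7, cat_l = 0, tmpl_a = 0.7, tmpl_l = 0,
                         cat_rlt = Inf, tmpl_rlt = Inf,
                         cat_rlt0 = NULL, tmpl_rlt0 = NULL) {
  data.frame(x = x, y = y, ttr = ttr, diss_rlt = diss_rlt,
             cat_id = cat_id, cat_species = "replicase",
             cat_a = cat_a, cat_l = cat_l, cat_rlt = cat_rlt,
             cat_rlt0 = if (is.null(cat_rlt0)) cat_rlt else cat_rlt0,
             tmpl_id = tmpl_id, tmpl_species = tmpl_species,
             tmpl_a = tmpl_a, tmpl_l = tmpl_l, tmpl_rlt = tmpl_rlt,
             tmpl_rlt0 = if (is.null(tmpl_rlt0)) tmpl_rlt else tmpl_rlt0)
}

# uniform random canonical points
random_points <- function(n, geom) {
  cbind(runif(n, 0, geom$width), runif(n, 0, geom$height))
}

# brute-force all-pairs range query oracle
brute_neighbors <- function(points, i, radius, geom) {
  n <- nrow(points)
  others <- setdiff(seq_len(n), i)
  if (!length(others)) return(integer(0))
  d <- torus_distance(points[others, , drop = FALSE],
                      points[rep(i, length(others)), , drop = FALSE], geom)
  sort(others[d < radius])
}

# tiny scenario that runs in well under a second
tiny_scenario <- function(...) {
  rp_scenario(width = 48, disc_radius = 12, n_replicases = 150,
              n_parasites = 150, max_steps = 200,
              mutable_a_P = TRUE, mutable_l_P = TRUE,
              mu_a_P = 0.01, mu_l_P = 0.01, ...)
}
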