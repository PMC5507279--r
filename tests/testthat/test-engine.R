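test_that("a lone molecule decays exactly when its lifetime clock expires", {
  w <- rp_world(make_molecules(1, x = 5, y = 5, rlt = 5.0),
                geometry = rp_geometry(20))
  eng <- rp_engine_from_state(w, kinetics = kinetic_params(D = 0), seed = 1)
  rp_step(eng, 4, stop_on_extinction = FALSE)
  expect_equal(nrow(rp_state(eng)$molecules), 1L)
  rp_step(eng, 1, stop_on_extinction = FALSE)
  st <- rp_state(eng)
  expect_equal(nrow(st$molecules), 0L)
  ev <- rp_events(eng)
  expect_equal(sum(ev$decays_free), 1)
})

test_that("two touching replicases bind, then replicate at the next step", {
  mol <- make_molecules(2, x = c(5, 5.5), y = 5, a = 1, l = 0)
  w <- rp_world(mol, geometry = rp_geometry(20))
  eng <- rp_engine_from_state(w, kinetics = kinetic_params(d = 0, D = 0,
                                                           D_complex = 0),
                              seed = 4)
  rp_step(eng, 1, stop_on_extinction = FALSE)
  st <- rp_state(eng)
  expect_equal(nrow(st$complexes), 1L)   # omega = 1, bound immediately
  expect_equal(nrow(st$molecules), 0L)
  # complex sits at the midpoint; a = 1 means no dissociation clock
  expect_equal(st$complexes$x, 5.25)
  expect_true(is.na(st$complexes$diss_rlt))
  rp_step(eng, 1, stop_on_extinction = FALSE)
  st <- rp_state(eng)                    # huge K: TTR expires on first tick
  expect_equal(nrow(st$complexes), 0L)
  expect_equal(nrow(st$molecules), 3L)
  expect_true(all(st$molecules$species == "replicase"))
  expect_equal(sum(rp_events(eng)$replications), 1)
})

test_that("fully folded templates never react and the world empties", {
  set.seed(8)
  n <- 60
  mol <- make_molecules(n, species = rep(c("replicase", "parasite"), n / 2),
                        x = runif(n, 0, 12), y = runif(n, 0, 12),
                        a = 0.9, l = 1, rlt = rexp(n, 0.5))
  w <- rp_world(mol, geometry = rp_geometry(12))
  eng <- rp_engine_from_state(w, seed = 2)
  horizon <- ceiling(max(mol$rlt)) + 1
  rp_step(eng, horizon, stop_on_extinction = FALSE)
  s <- rp_series(eng)
  expect_equal(sum(rp_events(eng)$complex_formations), 0)
  expect_true(all(diff(s$n_R_total + s$n_P_total) <= 0))
  expect_equal(s$n_R_total[nrow(s)] + s$n_P_total[nrow(s)], 0)
})

test_that("replication copies the template species", {
  # an RP complex about to replicate adds a parasite, not a replicase
  cx <- make_complex(x = 6, y = 6, ttr = 0.5, diss_rlt = 1e9,
                     cat_id = 1L, tmpl_id = 2L, tmpl_species = "parasite",
                     tmpl_a = 0.55, tmpl_l = 0.2)
  w <- rp_world(make_molecules(0), cx, rp_geometry(20))
  eng <- rp_engine_from_state(w, kinetics = kinetic_params(d = 0, D = 0,
                                                           D_complex = 0),
                              seed = 5)
  rp_step(eng, 1, stop_on_extinction = FALSE)
  st <- rp_state(eng)
  expect_equal(sum(st$molecules$species == "parasite"), 2L)
  expect_equal(sum(st$molecules$species == "replicase"), 1L)
  # without mutation the offspring attributes equal the template's
  off <- st$molecules[st$molecules$id == 3L, ]
  expect_equal(off$a, 0.55)
  expect_equal(off$l, 0.2)
  # default placement: offspring at the complex position
  expect_equal(torus_distance(c(off$x, off$y), c(6, 6), rp_geometry(20)), 0)

  # a positive offset places the offspring on a circle around the complex
  w2 <- rp_world(make_molecules(0), cx, rp_geometry(20))
  eng2 <- rp_engine_from_state(w2, kinetics = kinetic_params(d = 0, D = 0,
                                                             D_complex = 0),
                               seed = 5, offspring_offset = 1)
  rp_step(eng2, 1, stop_on_extinction = FALSE)
  st2 <- rp_state(eng2)
  off2 <- st2$molecules[st2$molecules$id == 3L, ]
  expect_equal(torus_distance(c(off2$x, off2$y), c(6, 6), rp_geometry(20)), 1)
})

test_that("clock dissociation releases both members at the complex position", {
  for (mode in c("ticking", "frozen")) {
    cx <- make_complex(x = 3, y = 9, ttr = 1e9, diss_rlt = 2.5,
                       cat_id = 1L, tmpl_id = 2L,
                       cat_rlt = 10, tmpl_rlt = 8,
                       cat_rlt0 = 10, tmpl_rlt0 = 8)
    w <- rp_world(make_molecules(0), cx, rp_geometry(20))
    eng <- rp_engine_from_state(w, kinetics = kinetic_params(d = 0, D = 0,
                                                             D_complex = 0),
                                seed = 6, decay_mode = mode)
    rp_step(eng, 3, stop_on_extinction = FALSE)
    st <- rp_state(eng)
    expect_equal(nrow(st$complexes), 0L)
    expect_equal(nrow(st$molecules), 2L)
    expect_equal(sum(rp_events(eng)$dissociations), 1)
    expect_equal(st$molecules$x, c(3, 3))
    expect_equal(st$molecules$y, c(9, 9))
    got <- sort(st$molecules$rlt)
    if (mode == "frozen") {
      # clocks restored exactly as stored at formation
      expect_equal(got, c(8, 10))
    } else {
      # member clocks kept ticking during the 3 steps in complex
      expect_equal(got, c(5, 7))
    }
  }
})

test_that("in ticking mode a member can decay inside a complex", {
  cx <- make_complex(x = 3, y = 3, ttr = 1e9, diss_rlt = 1e9,
                     cat_id = 1L, tmpl_id = 2L,
                     cat_rlt = 1.5, tmpl_rlt = 50,
                     cat_rlt0 = 1.5, tmpl_rlt0 = 50)
  w <- rp_world(make_molecules(0), cx, rp_geometry(20))
  eng <- rp_engine_from_state(w, kinetics = kinetic_params(d = 0, D = 0,
                                                           D_complex = 0),
                              seed = 6, decay_mode = "ticking")
  rp_step(eng, 2, stop_on_extinction = FALSE)
  st <- rp_state(eng)
  expect_equal(nrow(st$complexes), 0L)
  expect_equal(nrow(st$molecules), 1L)   # partner freed, member decayed
  expect_equal(st$molecules$id, 2L)
  expect_equal(sum(rp_events(eng)$decays_in_complex), 1)
  # in frozen mode the same complex is still intact after those steps
  w2 <- rp_world(make_molecules(0), cx, rp_geometry(20))
  eng2 <- rp_engine_from_state(w2, kinetics = kinetic_params(d = 0, D = 0,
                                                             D_complex = 0),
                               seed = 6, decay_mode = "frozen")
  rp_step(eng2, 2, stop_on_extinction = FALSE)
  expect_equal(nrow(rp_state(eng2)$complexes), 1L)
})

test_that("overcrowded entities are removed and counted", {
  # 12 molecules stacked within one collision disc, cap of 8 neighbors
  mol <- make_molecules(12, x = 10 + runif(12, 0, 0.1),
                        y = 10 + runif(12, 0, 0.1), a = 0, l = 0)
  w <- rp_world(mol, geometry = rp_geometry(20))
  eng <- rp_engine_from_state(w, kinetics = kinetic_params(d = 0, D = 0,
                                                           n_max = 8),
                              seed = 9)
  rp_step(eng, 1, stop_on_extinction = FALSE)
  ev <- rp_events(eng)
  expect_gt(sum(ev$overcrowd_removals), 0)
  st <- rp_state(eng)
  expect_lt(nrow(st$molecules), 12L)
})

test_that("initialization places species-pure half-discs and Exp(d) clocks", {
  cfg <- rp_scenario(width = 64, disc_radius = 16, n_replicases = 5000,
                     n_parasites = 5000, max_density = 10,
                     placement = "circle")
  st <- initialize_world(cfg, seed = 3)
  m <- st$molecules
  expect_equal(sum(m$species == "replicase"), 5000L)
  expect_equal(sum(m$species == "parasite"), 5000L)
  d <- torus_distance(cbind(m$x, m$y),
                      matrix(32, nrow(m), 2), rp_geometry(64))
  expect_true(all(d <= 16 + 1e-9))
  expect_true(all(m$y[m$species == "replicase"] >= 32))
  expect_true(all(m$y[m$species == "parasite"] <= 32))
  expect_true(all(m$a[m$species == "replicase"] == cfg$a_R0))
  expect_true(all(m$l[m$species == "parasite"] == cfg$l_P0))
  # empirical mean initial lifetime ~ 1/d within 3 standard errors
  se <- (1 / 0.182) / sqrt(nrow(m))
  expect_lt(abs(mean(m$rlt) - 1 / 0.182), 3 * se)
})

test_that("random placement covers the torus uniformly", {
  cfg <- rp_scenario(width = 64, n_replicases = 2000, n_parasites = 2000,
                     placement = "random")
  m <- initialize_world(cfg, seed = 3)$molecules
  expect_true(all(m$x >= 0 & m$x < 64 & m$y >= 0 & m$y < 64))
  # crude uniformity check on quadrant counts
  q <- table(m$x < 32, m$y < 32)
  expect_true(all(q > 800))
})

test_that("a run without parasites terminates at step 0", {
  cfg <- tiny_scenario()
  cfg$n_parasites <- 0L
  run <- run_scenario(cfg, seed = 1)
  expect_equal(run$final_step, 0L)
  expect_equal(run$outcome, "extinct_parasites")
})

test_that("a frozen world with no events survives the whole step budget", {
  # decay off and fully folded molecules: nothing can ever happen
  mol <- make_molecules(20, species = rep(c("replicase", "parasite"), 10),
                        x = seq(1, 39, by = 2), y = 20, a = 0.5, l = 1)
  w <- rp_world(mol, geometry = rp_geometry(40))
  eng <- rp_engine_from_state(w, kinetics = kinetic_params(d = 0),
                              seed = 10)
  rp_step(eng, 100, stop_on_extinction = FALSE)
  s <- rp_series(eng)
  expect_equal(nrow(s), 101L)
  expect_true(all(s$n_R_total == 10))
  expect_true(all(s$n_P_total == 10))
})

test_that("decay mode controls the viability of a founding replicase bloom", {
  grow <- function(mode) {
    cfg <- rp_scenario(width = 48, disc_radius = 12, n_replicases = 600,
                       n_parasites = 0, a_R0 = 0.7, l_R0 = 0,
                       mutable_a_P = FALSE, mutable_l_P = FALSE,
                       max_steps = 150, decay_mode = mode)
    eng <- rp_engine(cfg, seed = 44)
    rp_step(eng, 150, stop_on_extinction = FALSE)
    s <- rp_series(eng)
    s$n_R_total[nrow(s)]
  }
  # with member clocks paused inside complexes the founding disc ignites;
  # with clocks ticking, decay outpaces the paired replication cycle
  expect_gt(grow("frozen"), 600)
  expect_lt(grow("ticking"), 100)
})

test_that("identical config and seed reproduce a run bit for bit", {
  cfg <- tiny_scenario()
  r1 <- run_scenario(cfg, seed = 7)
  r2 <- run_scenario(cfg, seed = 7)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$events, r2$events)
  r3 <- run_scenario(cfg, seed = 8)
  expect_false(identical(r1$series, r3$series))
})

test_that("chunked stepping reproduces a single uninterrupted run", {
  cfg <- tiny_scenario()
  e1 <- rp_engine(cfg, seed = 12)
  rp_step(e1, 120, stop_on_extinction = FALSE)
  e2 <- rp_engine(cfg, seed = 12)
  for (k in c(13, 50, 7, 50)) rp_step(e2, k, stop_on_extinction = FALSE)
  expect_identical(rp_series(e1), rp_series(e2))
})

test_that("the molecule ledger balances at every step of a long run", {
  cfg <- rp_scenario(width = 96, disc_radius = 24, n_replicases = 700,
                     n_parasites = 700, decay_mode = "frozen",
                     mutable_a_P = TRUE, mutable_l_P = TRUE,
                     max_steps = 2000)
  eng <- rp_engine(cfg, seed = 31)
  rp_step(eng, 2000, stop_on_extinction = FALSE)
  s <- rp_series(eng)
  ev <- rp_events(eng)
  total <- s$n_R_total + s$n_P_total
  expect_equal(diff(total),
               (ev$replications - ev$decays_free - ev$decays_in_complex -
                  ev$overcrowd_removals)[-1])
  # complexed counts are consistent with the free/total decomposition
  expect_equal(s$n_R_total, s$n_R_free + 2 * s$n_RR_complexes +
                 s$n_RP_complexes)
  expect_equal(s$n_P_total, s$n_P_free + s$n_RP_complexes)
})

test_that("attributes stay in [0, 1] and no parasite ever catalyzes", {
  cfg <- rp_scenario(width = 64, disc_radius = 16, n_replicases = 600,
                     n_parasites = 600, decay_mode = "frozen",
                     mutable_a_P = TRUE, mutable_l_P = TRUE,
                     mu_a_P = 0.19, mu_l_P = 0.19, max_steps = 1500)
  eng <- rp_engine(cfg, seed = 17)
  for (chunk in 1:15) {
    st <- rp_step(eng, 100, stop_on_extinction = TRUE)
    w <- rp_state(eng)
    vals <- c(w$molecules$a, w$molecules$l, w$complexes$cat_a,
              w$complexes$cat_l, w$complexes$tmpl_a, w$complexes$tmpl_l)
    expect_true(all(vals >= 0 & vals <= 1))
    if (nrow(w$complexes))
      expect_true(all(w$complexes$cat_species == "replicase"))
    if (st$steps_done < 100) break
  }
  s <- rp_series(eng)
  means <- unlist(s[, c("mean_a_R", "mean_l_R", "mean_a_P", "mean_l_P")])
  expect_true(all(is.na(means) | (means >= 0 & means <= 1)))
})
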