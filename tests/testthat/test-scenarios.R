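test_that("presets reproduce the published experiment tables", {
  e1 <- rp_preset(1)
  expect_length(e1, 1L)
  expect_equal(e1[[1]]$a_P0, 0.55)
  expect_equal(e1[[1]]$l_P0, 0.2)
  expect_equal(e1[[1]]$mu_a_P, 0.01)
  expect_equal(e1[[1]]$mu_l_P, 0.01)
  expect_true(e1[[1]]$mutable_a_P && e1[[1]]$mutable_l_P)
  expect_false(e1[[1]]$mutable_a_R || e1[[1]]$mutable_l_R)
  expect_equal(e1[[1]]$a_R0, 0.7)
  expect_equal(e1[[1]]$l_R0, 0)

  e2 <- rp_preset(2)
  expect_length(e2, 11L)
  expect_equal(sapply(e2, `[[`, "l_P0"), seq(0, 1, 0.1))
  expect_true(all(sapply(e2, `[[`, "a_P0") == 0.55))
  expect_true(all(!sapply(e2, `[[`, "mutable_a_P")))
  expect_true(all(sapply(e2, `[[`, "mu_l_P") == 0.19))

  e3 <- rp_preset(3)
  expect_equal(sapply(e3, `[[`, "a_P0"), seq(0, 1, 0.1))
  expect_true(all(sapply(e3, `[[`, "l_P0") == 0.2))
  expect_true(all(sapply(e3, `[[`, "mu_a_P") == 0.19))
  expect_true(all(!sapply(e3, `[[`, "mutable_l_P")))

  e4 <- rp_preset(4)
  expect_true(all(!sapply(e4, `[[`, "mutable_a_P")))
  expect_true(all(sapply(e4, `[[`, "mutable_l_P")))
  expect_equal(sapply(e4, `[[`, "a_P0"), seq(0, 1, 0.1))

  e5 <- rp_preset(5)
  expect_length(e5, 14L)   # 7 published pairs x 2 placements
  key <- sapply(e5, function(c) sprintf("%g/%g/%s", c$a_P0, c$a_R0,
                                        c$placement))
  expect_true(all(c("0.55/0.7/circle", "0.55/0.7/random") %in% key))
  expect_true(all(sapply(e5, function(c)
    c$mutable_a_R && c$mutable_l_R && c$mutable_a_P && c$mutable_l_P)))
  expect_true(all(sapply(e5, function(c)
    all(c(c$mu_a_R, c$mu_l_R, c$mu_a_P, c$mu_l_P) == 0.01))))
  expect_true(all(sapply(e5, function(c) c$l_P0 == 0.2 && c$l_R0 == 0.2)))

  expect_error(rp_preset(9), "unknown experiment")
  expect_error(rp_preset(2, index = 12), "out of range")

  # every preset carries the published kinetic constants
  for (cfg in c(e1, e2[1], e5[1])) {
    k <- cfg$kinetics
    expect_equal(c(k$d, k$D, k$D_complex, k$K, k$dt, k$radius),
                 c(0.182, 0.75, 0.0476, 239800, 1, 0.5))
  }
})

test_that("presets round-trip through the config file format", {
  for (cfg in list(rp_preset(1, 1), rp_preset(2, 4), rp_preset(5, 9),
                   rp_preset(3, 11, scaled = FALSE))) {
    f <- withr::local_tempfile(fileext = ".toml")
    write_scenario(cfg, f)
    back <- read_scenario(f)
    expect_equal(unclass(back), unclass(cfg))
  }
})

test_that("scenario validation rejects out-of-range configurations", {
  expect_error(rp_scenario(width = 10, n_replicases = 200, n_parasites = 200),
               "density")
  expect_error(rp_scenario(a_P0 = 1.2), "\\[0, 1\\]")
  expect_error(rp_scenario(mu_l_P = -0.1), "\\[0, 1\\]")
  expect_error(rp_scenario(width = 64, disc_radius = 40), "disc")
  expect_error(rp_scenario(delta = 0), "delta")
})

test_that("outcomes are classified from the final species counts", {
  mk <- function(step, nR, nP) {
    s <- data.frame(step = c(0, step), n_R_total = c(10, nR),
                    n_P_total = c(10, nP))
    s
  }
  expect_equal(classify_outcome(mk(1000, 5, 3), 1000), "survived")
  expect_equal(classify_outcome(mk(700, 12, 0), 10000), "extinct_parasites")
  expect_equal(classify_outcome(mk(700, 0, 4), 10000), "extinct_replicases")
  expect_equal(classify_outcome(mk(700, 0, 0), 10000), "extinct_both")
})

test_that("stabilization detection matches a brute-force window scan", {
  # constant series stabilizes at the first full window
  expect_equal(detect_stabilization(rep(0.3, 100), window = 20, tol = 1e-9),
               20L)
  # persistent drift never stabilizes
  tol <- 1e-4
  drift <- 0.2 + 10 * tol * seq_len(500)
  expect_true(is.na(detect_stabilization(drift, window = 50, tol = tol)))
  # series shorter than the window
  expect_true(is.na(detect_stabilization(rep(1, 10), window = 20, tol = 1)))

  # saturating-exponential trajectory against an lm()-based full scan
  n <- 1500
  window <- 250
  tol <- 2e-6
  y <- 0.2 + 0.1 * (1 - exp(-(seq_len(n)) / 150))
  oracle <- {
    slopes <- vapply(window:n, function(t) {
      win <- y[(t - window + 1):t]
      unname(coef(lm(win ~ seq_len(window)))[2])
    }, numeric(1))
    ok <- abs(slopes) < tol
    bad <- which(!ok)
    if (!ok[length(ok)]) NA_integer_
    else as.integer((if (length(bad)) max(bad) + 1L else 1L) + window - 1L)
  }
  expect_false(is.na(oracle))
  expect_equal(detect_stabilization(y, window, tol), oracle)
})
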