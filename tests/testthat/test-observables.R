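test_that("recorded observables equal an independent full recount", {
  # counts on a hand-built state: 2 free R, 1 free P, 1 RP + 1 RR complex
  mol <- make_molecules(3, species = c("replicase", "replicase", "parasite"),
                        x = c(1, 2, 3), y = 1, a = c(0.7, 0.7, 0.55),
                        l = c(0, 0, 0.2))
  cx <- rbind(
    make_complex(5, 5, 1, 1, cat_id = 4L, tmpl_id = 5L,
                 tmpl_species = "parasite", tmpl_a = 0.55, tmpl_l = 0.2),
    make_complex(8, 8, 1, 1, cat_id = 6L, tmpl_id = 7L))
  st <- rp_world(mol, cx, rp_geometry(20))
  r <- record_state(st)
  expect_equal(r$n_R_total, 5)
  expect_equal(r$n_P_total, 2)
  expect_equal(r$n_RR_complexes, 1)
  expect_equal(r$n_RP_complexes, 1)
  expect_equal(r$mean_l_P, 0.2)
  expect_equal(r$sd_l_P, 0)

  # engine-recorded series row vs full recount of the matching snapshot
  cfg <- tiny_scenario()
  eng <- rp_engine(cfg, seed = 23)
  rp_step(eng, 37, stop_on_extinction = FALSE)
  s <- rp_series(eng)
  rec <- record_state(rp_state(eng))
  row <- s[s$step == 37, ]
  rownames(row) <- rownames(rec) <- NULL
  rec$time <- row$time
  # counts and means agree to full precision; the standard deviations are
  # sqrt of a near-cancelling difference, so only absolute agreement at the
  # rounding-noise level is meaningful there
  sd_cols <- grep("^sd_", names(row), value = TRUE)
  expect_equal(row[setdiff(names(row), sd_cols)],
               rec[setdiff(names(rec), sd_cols)], tolerance = 1e-12)
  for (cc in sd_cols)
    expect_true(is.na(row[[cc]]) == is.na(rec[[cc]]) &&
                  (is.na(row[[cc]]) || abs(row[[cc]] - rec[[cc]]) < 1e-6))
})

test_that("time series round-trip the CSV format losslessly", {
  cfg <- tiny_scenario()
  run <- run_scenario(cfg, seed = 2, max_steps = 150)
  f <- withr::local_tempfile(fileext = ".csv")
  write_timeseries(run$series, f)
  back <- read_timeseries(f)
  expect_equal(back, run$series)
  # bit-exactness of the full float payload
  expect_identical(back$mean_a_P, run$series$mean_a_P)
})

test_that("empty series yield a header-only file", {
  f <- withr::local_tempfile(fileext = ".csv")
  empty <- rp_series(rp_engine(tiny_scenario(), seed = 1))[0, ]
  write_timeseries(empty, f)
  expect_length(readLines(f), 1L)
  expect_equal(nrow(read_timeseries(f)), 0L)
})

test_that("malformed CSV input names the offending line", {
  f <- withr::local_tempfile(fileext = ".csv")
  run <- run_scenario(tiny_scenario(), seed = 2, max_steps = 5)
  write_timeseries(run$series, f)
  lines <- readLines(f)
  lines[3] <- sub("^[0-9.]+,", "oops,", lines[3])
  writeLines(lines, f)
  expect_error(read_timeseries(f), "line 3")
  writeLines(c("bad,header"), f)
  expect_error(read_timeseries(f), "line 1")
})

test_that("frames render deterministically, complexes as two discs", {
  g <- rp_geometry(16)
  empty <- rp_world(geometry = g)
  img <- render_frame(empty, scale = 2)
  expect_equal(dim(img), c(32L, 32L, 3L))
  expect_true(all(img == 0))

  cx <- make_complex(8, 8, 1, 1, cat_id = 1L, tmpl_id = 2L,
                     tmpl_species = "parasite", tmpl_a = 0.55, tmpl_l = 0.2)
  one_cx <- rp_world(make_molecules(0), cx, g)
  img_cx <- render_frame(one_cx, scale = 4)
  expect_gt(sum(img_cx > 0), 0)
  # two overlapping member discs cover more area than a single molecule
  one_mol <- rp_world(make_molecules(1, x = 8, y = 8), geometry = g)
  img_mol <- render_frame(one_mol, scale = 4)
  expect_gt(sum(rowSums(img_cx, dims = 2) > 0),
            sum(rowSums(img_mol, dims = 2) > 0))
  # species coloring: catalyst is blue-dominant, parasite red-dominant
  expect_gt(sum(img_cx[, , 3]), 0)
  expect_gt(sum(img_cx[, , 1]), 0)
  # byte-identical re-render, and PNG output exists
  expect_identical(img_cx, render_frame(one_cx, scale = 4))
  f <- withr::local_tempfile(fileext = ".png")
  render_frame(one_cx, file = f, scale = 4)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("run summaries carry the schema's required fields", {
  run <- run_scenario(tiny_scenario(), seed = 3, max_steps = 60)
  f <- withr::local_tempfile(fileext = ".json")
  write_run_summary(run, f, stabilization_window = 20,
                    stabilization_tol = 1)
  doc <- jsonlite::read_json(f)
  schema <- jsonlite::read_json(system.file("schema",
                                            "run-summary.schema.json",
                                            package = "rpsim"))
  expect_true(all(unlist(schema$required) %in% names(doc)))
  expect_true(all(unlist(schema$properties$config$required) %in%
                    names(doc$config)))
  expect_true(doc$outcome %in% unlist(schema$properties$outcome$enum))
  expect_equal(doc$seed, 3L)
  expect_true(all(c("a_R", "l_R", "a_P", "l_P") %in%
                    names(doc$stabilization)))
})

test_that("config files reject unknown keys", {
  f <- withr::local_tempfile(fileext = ".toml")
  write_scenario(rp_preset(1, 1), f)
  writeLines(c(readLines(f), "", "[world]", "depth = 3"), f)
  expect_error(read_scenario(f), "unknown key")
  writeLines(c("[world]", "width = ???"), f)
  expect_error(read_scenario(f), "cannot parse")
})
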