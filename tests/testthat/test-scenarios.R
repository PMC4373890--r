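small_homeo_cfg <- function(out_dir = NULL, workers = 1L, seed = 2L,
                            dump_every = 0L)
  scenario_config("homeostasis",
    geometry = list(run_n_axial = 2, run_n_circ = 2,
                    template = list(villus_height = 6L, crypt_depth = 3L,
                                    face_width = 2L)),
    n_steps = 80, equilibration = 20, seed = seed, workers = workers,
    out_dir = out_dir, dump_every = dump_every)

test_that("invalid configurations are rejected with field-level messages", {
  expect_error(scenario_config("volvulus"), "scenario")
  expect_error(scenario_config(geometry = list(diameter_cm = -1)),
               "diameter_cm")
  expect_error(scenario_config(geometry = list(run_n_axial = 0)),
               "run_n_axial")
  expect_error(scenario_config(n_steps = 0), "n_steps")
  expect_error(scenario_config(n_steps = 10, equilibration = 20),
               "equilibration")
  expect_error(scenario_config(knockout = list(mediator = "XYZ")),
               "mediator")
  expect_error(scenario_config(signaling = list(
    mediators = list(WNT = list(D = 0.5, lam = 0.1, basal = 0, emission = 1,
                                source = "crypt_base", source_rows = 2L)))),
    "stability")
})

test_that("a fixed config and seed reproduce every output byte", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_scenario(small_homeo_cfg(out_dir = d1, dump_every = 40L))
  r2 <- run_scenario(small_homeo_cfg(out_dir = d2, dump_every = 40L))
  for (f in c("population.csv", "metrics.csv", "resolved_config.yaml",
              file.path("dumps", "step_000040.csv"),
              file.path("dumps", "step_000080.csv")))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  expect_identical(r1$series, r2$series)
})

test_that("worker count never changes any output", {
  d1 <- withr::local_tempdir()
  d4 <- withr::local_tempdir()
  run_scenario(small_homeo_cfg(out_dir = d1, workers = 1L, dump_every = 40L))
  run_scenario(small_homeo_cfg(out_dir = d4, workers = 4L, dump_every = 40L))
  for (f in c("population.csv", "metrics.csv",
              file.path("dumps", "step_000080.csv")))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d4, f)))
})

test_that("metrics arithmetic matches hand-built states", {
  geom <- tiny_geom(1, 2, hv = 8, dc = 3, fw = 2)
  ts <- init_tissue(geom, fast_params(), seed = 1, occupancy = "empty")
  w <- ts$dec$workers[[1]]
  vill <- which(w$comp == 2L & !w$is_cap & w$row < 5)[1:40]
  cryp <- which(w$comp == 1L & !w$is_cap)[1:10]
  w$lin[vill] <- 3L
  w$lin[cryp] <- 2L
  ts$dec$workers[[1]] <- w
  m <- compute_metrics(ts)
  expect_equal(m$villus_crypt_ratio, 4)    # 40 villus / 10 crypt

  # empty villus -> ratio 0
  w$lin[vill] <- 0L
  ts$dec$workers[[1]] <- w
  expect_equal(compute_metrics(ts)$villus_crypt_ratio, 0)

  # zero crypt population -> undefined sentinel, messaged
  w$lin[cryp] <- 0L
  w$lin[vill] <- 3L
  ts$dec$workers[[1]] <- w
  expect_message(m0 <- compute_metrics(ts), "undefined")
  expect_true(is.na(m0$villus_crypt_ratio))

  # axial bins cover the pouch axis exactly
  expect_equal(nrow(m$axial_bins), min(10, geom$n_axial))
  expect_true(all(m$axial_bins$metaplastic_fraction >= 0 &
                    m$axial_bins$metaplastic_fraction <= 1))
})

test_that("PLY meshes are valid, complete and round-trip", {
  geom <- tiny_geom(1, 2)
  ts <- init_tissue(geom, fast_params(), seed = 3, occupancy = "empty")
  f_empty <- withr::local_tempfile(fileext = ".ply")
  export_mesh(ts, f_empty)
  lines <- readLines(f_empty)
  expect_equal(lines[1], "ply")
  expect_true("element vertex 0" %in% lines)
  expect_equal(nrow(read_mesh_ply(f_empty)), 0)

  ts <- init_tissue(geom, fast_params(), seed = 3)
  f <- withr::local_tempfile(fileext = ".ply")
  export_mesh(ts, f)
  mesh <- read_mesh_ply(f)
  expect_equal(nrow(mesh), agent_counts(ts)[["total"]])
  xyz <- to_3d(ts$idx)
  occ <- which(gather_state(ts, fields = FALSE)$lineage != "EMPTY")
  expect_equal(as.matrix(mesh[, c("x", "y", "z")]), xyz[occ, ],
               tolerance = 1e-5, ignore_attr = TRUE)
  # sub-region selection
  f2 <- withr::local_tempfile(fileext = ".ply")
  export_mesh(ts, f2, units = 0L)
  st <- gather_state(ts, fields = FALSE, occupied_only = TRUE)
  expect_equal(nrow(read_mesh_ply(f2)), sum(st$unit_index == 0))
})

test_that("scenario configs round-trip losslessly through YAML", {
  cfg <- scenario_config("pouchitis",
    geometry = list(run_n_axial = 5, run_n_circ = 3),
    n_steps = 123, equilibration = 45, seed = 9, workers = 2,
    rules = list(p_shed = 0.03),
    stool = list(delta_ip = 0.07, fill_direction = "proximal_first"),
    dump_every = 10L)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_config(cfg, f)
  back <- read_scenario_config(f)
  expect_equal(.resolve_config(back), .resolve_config(cfg))
})

test_that("the knockout scenario flattens the Wnt gradient after the switch", {
  cfg <- scenario_config("knockout",
    geometry = list(run_n_axial = 2, run_n_circ = 2,
                    template = list(villus_height = 6L, crypt_depth = 4L,
                                    face_width = 2L)),
    n_steps = 250, equilibration = 120, seed = 5,
    knockout = list(mediator = "WNT"))
  run <- run_scenario(cfg)
  pr <- gradient_profile(run$state, mediator = "WNT", unit = 0)
  expect_lt(max(pr$mean_concentration), 1e-3)
  # knockout silences divisions once residual Wnt has decayed
  expect_equal(tail(run$series$births, 30), rep(0, 30))
})

test_that("run logs record scenario events", {
  d <- withr::local_tempdir()
  cfg <- scenario_config("ulcer",
    geometry = list(run_n_axial = 2, run_n_circ = 2,
                    template = list(villus_height = 5L, crypt_depth = 3L,
                                    face_width = 2L)),
    n_steps = 40, equilibration = 10, seed = 4,
    ulcer = list(radius_sites = 2), out_dir = d)
  run <- run_scenario(cfg)
  expect_match(paste(run$log, collapse = "\n"), "ulcer radius 2")
  expect_true(file.exists(file.path(d, "log.txt")))
  expect_true(file.exists(file.path(d, "resolved_config.yaml")))
})

test_that("the command-line front end runs a scenario end to end", {
  cli <- system.file("cli", "pouchsim", package = "pouchsim")
  expect_true(nzchar(cli))
  d <- withr::local_tempdir()
  cfgf <- file.path(d, "cfg.yaml")
  write_scenario_config(small_homeo_cfg(), cfgf)
  out <- system2("Rscript",
                 c(cli, "run", "--config", shQuote(cfgf), "--seed", "2",
                   "--steps", "40", "--out", shQuote(file.path(d, "run"))),
                 stdout = TRUE, stderr = TRUE)
  expect_equal(attr(out, "status", exact = TRUE), NULL)  # exit code 0
  expect_match(paste(out, collapse = "\n"), "villus:crypt ratio")
  expect_true(file.exists(file.path(d, "run", "population.csv")))
})
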