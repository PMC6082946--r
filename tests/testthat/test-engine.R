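test_that("zero-duration runs return empty results", {
  expect_error(make_schedule(list(list(t_start_ms = 0, t_end_ms = 0,
                                       params = mode_parameters("normal"),
                                       label = "x"))),
               "positive duration")
  # a syntactically valid schedule cannot have zero duration; the engine
  # itself guards the degenerate step count
  cfg <- simulation_config(constant_schedule(mode_parameters("normal"),
                                             1000), master_seed = 1)
  cfg$schedule$total_duration_ms <- 0
  cfg$schedule$segments <- list()
  res <- run_simulation(cfg)
  expect_equal(nrow(res$raster), 0)
  expect_length(res$psc, 0)
})

test_that("identical configuration reproduces bit-identical rasters", {
  cfg <- simulation_config(constant_schedule(mode_parameters("normal"),
                                             1000), master_seed = 77)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$raster, r2$raster)
  expect_identical(r1$psc, r2$psc)
  expect_identical(r1$astro_trace, r2$astro_trace)
  # a different master seed gives a different realization
  r3 <- run_simulation(simulation_config(
    constant_schedule(mode_parameters("normal"), 1000), master_seed = 78))
  expect_false(identical(r1$raster, r3$raster))
})

test_that("PSC always equals the raster's per-bin spike totals", {
  res <- fig2_run(1)
  expect_equal(sum(res$psc), nrow(res$raster))
  expect_equal(res$psc,
               population_spike_count(res$raster, 1, res$duration_ms))
  expect_length(res$psc, res$duration_ms)
  # voltage never recorded above threshold: every spike is a reset
  expect_true(all(res$raster$time_ms >= 0 &
                    res$raster$time_ms < res$duration_ms))
})

test_that("changing a later segment leaves earlier spikes untouched", {
  base <- make_schedule(list(
    list(t_start_ms = 0, t_end_ms = 1000,
         params = mode_parameters("normal"), label = "a"),
    list(t_start_ms = 1000, t_end_ms = 2000,
         params = mode_parameters("normal"), label = "b")))
  alt <- make_schedule(list(
    list(t_start_ms = 0, t_end_ms = 1000,
         params = mode_parameters("normal"), label = "a"),
    list(t_start_ms = 1000, t_end_ms = 2000,
         params = mode_parameters("acute"), label = "b")))
  r1 <- run_simulation(simulation_config(base, master_seed = 5))
  r2 <- run_simulation(simulation_config(alt, master_seed = 5))
  early1 <- r1$raster[r1$raster$time_ms < 1000, ]
  early2 <- r2$raster[r2$raster$time_ms < 1000, ]
  expect_identical(early1, early2)
  expect_false(identical(r1$raster, r2$raster))
})

test_that("normal-mode firing is positive, finite and mixed across seeds", {
  ok <- 0L
  for (sd in 1:10) {
    res <- cached_run(paste0("normal2s_", sd), simulation_config(
      constant_schedule(mode_parameters("normal"), 2000),
      master_seed = sd))
    rate <- nrow(res$raster) / 1000 / 2
    n_exc_spk <- sum(res$raster$is_excitatory)
    n_inh_spk <- nrow(res$raster) - n_exc_spk
    if (is.finite(rate) && rate > 0 && n_exc_spk > 0 && n_inh_spk > 0)
      ok <- ok + 1L
  }
  expect_gte(ok, 10 * 0.95)
})

test_that("degenerate single-class populations still run", {
  cfg <- simulation_config(constant_schedule(mode_parameters("normal"),
                                             600),
                           master_seed = 2, n_exc = 50, n_inh = 0)
  res <- run_simulation(cfg)
  expect_true(all(res$raster$is_excitatory))
  cfg2 <- simulation_config(constant_schedule(mode_parameters("normal"),
                                              600),
                            master_seed = 2, n_exc = 0, n_inh = 50)
  expect_s3_class(run_simulation(cfg2), "simulation_result")
})

test_that("sweep returns the grid and finds threshold crossings", {
  sw <- sweep_parameter(mode_parameters("normal"), "mode.k_exc",
                        values = c(5, 4), metric = function(res) 1,
                        seeds = 1:2, duration_ms = 600)
  expect_equal(nrow(sw), 4)
  expect_true(all(sw$metric == 1))
  expect_true(is.na(first_crossing(sw, 0.5, "below")))
  # synthetic monotone sweep table
  tab <- data.frame(value = rep(c(10, 8, 6, 4), each = 2),
                    seed = rep(1:2, 4),
                    metric = rep(c(0.9, 0.8, 0.4, 0.2), each = 2))
  expect_equal(first_crossing(tab, 0.5, "below"), 6)
  expect_equal(first_crossing(tab[order(tab$value), ], 0.5, "above"), 8)
  expect_error(sweep_parameter(mode_parameters("normal"), "mode.q",
                               1, seeds = 1), "unknown parameter")
})

test_that("run artifacts export to the documented CSV and JSON forms", {
  res <- cached_run("normal2s_1", simulation_config(
    constant_schedule(mode_parameters("normal"), 2000), master_seed = 1))
  dir <- tempfile(); dir.create(dir)
  write_raster_csv(res$raster, file.path(dir, "raster.csv"))
  write_psc_csv(res$psc, file.path(dir, "psc.csv"))
  write_astro_trace_csv(res$astro_trace, file.path(dir, "astro.csv"))
  write_run_manifest(res, file.path(dir, "manifest.json"))
  expect_identical(readLines(file.path(dir, "psc.csv"), n = 1),
                   "time_ms,count")
  expect_identical(readLines(file.path(dir, "astro.csv"), n = 1),
                   "time_s,c,ce,Sm,Gm,I_astro")
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_equal(man$master_seed, 1)
  expect_equal(length(man$stream_seeds), 4)
  back <- read_raster_csv(file.path(dir, "raster.csv"))
  expect_equal(back, res$raster, ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})
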