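small_sim <- function(...) {
  cfg <- dia_config(library_n = 8, run_length = 120, window_width = 100,
                    ms1_duration = 0.2, ms2_duration = 0.1, ...)
  simulate_experiment(config = cfg)
}

test_that("mzML round-trips spectra, windows and retention times", {
  sim <- small_sim()
  run <- sim$runs[[1]]
  d <- withr::local_tempdir()
  p <- file.path(d, "run.mzML")
  write_mzml(run, p)
  back <- read_mzml(p)
  expect_identical(nrow(back), nrow(run))
  expect_identical(back$ms_level, run$ms_level)
  expect_equal(back$start_time, run$start_time, tolerance = 1e-9)
  i <- which(run$ms_level == 1L & lengths(run$mz) > 2)[1]
  expect_lt(max(abs(back$mz[[i]] - run$mz[[i]])), 1e-9)
  expect_equal(back$intensity[[i]], run$intensity[[i]], tolerance = 1e-6)
  # isolation window target and offsets: [400, 500) -> 450 +/- 50
  j <- which(back$ms_level == 2L)[1]
  expect_equal(back$target_mz[j], 450)
  expect_equal(back$mz_lower[j], 400)
  expect_equal(back$mz_upper[j], 500)
})

test_that("empty runs and unsorted runs are handled at the boundary", {
  sim <- small_sim()
  run <- sim$runs[[1]]
  d <- withr::local_tempdir()
  empty <- run[0, ]
  attr(empty, "instrument") <- attr(run, "instrument")
  p0 <- file.path(d, "empty.mzML")
  write_mzml(empty, p0)
  expect_identical(nrow(read_mzml(p0)), 0L)
  expect_identical(nrow(read_mzml_xml(p0)), 0L)

  shuffled <- run[rev(seq_len(nrow(run))), ]
  expect_error(write_mzml(shuffled, file.path(d, "x.mzML")), "sorted")
  expect_error(write_mzml(run, file.path(d, "no_dir", "x.mzML")),
               "directory")
})

test_that("the independent XML reader agrees with the ProteoWizard path", {
  sim <- small_sim()
  run <- sim$runs[[1]]
  d <- withr::local_tempdir()
  p <- file.path(d, "run.mzML")
  write_mzml(run, p)
  x <- read_mzml_xml(p)
  expect_identical(nrow(x), nrow(run))
  expect_identical(x$ms_level, run$ms_level)
  expect_equal(x$start_time, run$start_time, tolerance = 1e-6)
  for (i in c(1L, which(run$ms_level == 2L & lengths(run$mz) > 0)[1])) {
    expect_equal(x$mz[[i]], run$mz[[i]], tolerance = 1e-12)
    expect_equal(x$intensity[[i]], run$intensity[[i]], tolerance = 1e-6)
  }
})

test_that("ground truth round-trips with absent cells as empty fields", {
  cfg <- dia_config(library_n = 30, run_length = 120, window_width = 100,
                    n_groups = 2, n_replicates = 2,
                    prob_missing_sample = 0.3, seed = 5)
  sim <- simulate_experiment(config = cfg)
  d <- withr::local_tempdir()
  p <- file.path(d, "ground_truth.tsv")
  write_ground_truth(sim$truth, p)
  back <- read_ground_truth(p)
  ab_cols <- grep("^abundance_", names(sim$truth), value = TRUE)
  expect_true(any(is.na(as.matrix(sim$truth[, ab_cols]))))
  expect_identical(is.na(as.matrix(back[, ab_cols])),
                   is.na(as.matrix(sim$truth[, ab_cols])))
  expect_equal(as.matrix(back[, ab_cols]), as.matrix(sim$truth[, ab_cols]),
               tolerance = 1e-12)
  expect_identical(back$precursor_id, sim$truth$precursor_id)
  # absent cells are empty fields in the raw file, not zeros
  raw <- readLines(p)
  expect_true(any(grepl("\t\t|\t$", raw[-1])))
  expect_false(any(grepl("\tNA(\t|$)", raw)))
})

test_that("parameter yaml covers the whole configuration registry", {
  cfg <- dia_config(n_groups = 2)
  d <- withr::local_tempdir()
  p <- file.path(d, "parameters.yaml")
  write_parameter_yaml(cfg, p)
  y <- yaml::read_yaml(p)
  expect_setequal(names(y), config_registry()$key)
  expect_identical(y$n_groups, 2L)
})

test_that("replay reproduces the simulation and detects tampering", {
  cfg <- dia_config(library_n = 6, run_length = 100, window_width = 100,
                    ms1_duration = 0.2, ms2_duration = 0.1,
                    spray_instability_sd = 0.1, ppm_sd = 2, seed = 3)
  sim <- simulate_experiment(config = cfg)
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  sim2 <- replay(file.path(d, "replay.yaml"))
  expect_identical(readr::format_tsv(sim$truth), readr::format_tsv(sim2$truth))
  expect_identical(sim$runs[[1]]$mz, sim2$runs[[1]]$mz)
  expect_identical(sim$runs[[1]]$intensity, sim2$runs[[1]]$intensity)

  # a different seed in the replay file changes the outputs
  bundle <- yaml::read_yaml(file.path(d, "replay.yaml"))
  bundle$config$seed <- bundle$config$seed + 1L
  # the library is seeded separately, so its fingerprint still matches
  p2 <- file.path(d, "replay_edited.yaml")
  yaml::write_yaml(bundle, p2)
  sim3 <- replay(p2)
  expect_false(identical(sim$runs[[1]]$intensity, sim3$runs[[1]]$intensity))

  # fingerprint mismatch is refused
  bundle$library_fingerprint <- "0000"
  p3 <- file.path(d, "replay_bad.yaml")
  yaml::write_yaml(bundle, p3)
  expect_error(replay(p3), "fingerprint mismatch")
})

test_that("windowing changes multiplexing but not the recorded truth", {
  lib <- generate_synthetic_library(25, seed = 17)
  base <- list(library_n = 25, run_length = 120, n_groups = 2,
               n_replicates = 2, seed = 2)
  sim_a <- simulate_experiment(lib, do.call(dia_config, c(base, window_width = 20)))
  sim_b <- simulate_experiment(lib, do.call(dia_config, c(base, window_width = 100)))
  ab <- grep("^abundance_", names(sim_a$truth), value = TRUE)
  expect_equal(colSums(as.matrix(sim_a$truth[, ab])),
               colSums(as.matrix(sim_b$truth[, ab])))
  expect_identical(readr::format_tsv(sim_a$truth), readr::format_tsv(sim_b$truth))
})
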