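test_that("active species carry area-scaled elution weights", {
  sp <- tiny_species()
  expect_identical(nrow(active_species(500, sp)), 0L)
  at_apex <- active_species(100, sp, threshold_frac = 0.01)
  expect_true("AAAK/2" %in% at_apex$precursor_id)
  w <- at_apex$elution_weight[at_apex$precursor_id == "AAAK/2"]
  expect_equal(w, emg_intensity(100, 100, 2, 0, area = 1000))
  # co-eluting species both present with pointwise weights
  both <- active_species(101.5, sp, threshold_frac = 0.01)
  expect_identical(nrow(both), 2L)
  expect_equal(both$elution_weight,
               emg_intensity(101.5, sp$apex_rt, sp$sigma, sp$tau,
                             area = sp$abundance))
})

test_that("MS1 centroids place isotope peaks with ppm error and superpose", {
  sp <- tiny_species()[1, ]
  inst <- instrument_model()
  pk <- centroid_peaks_ms1(sp, t = 100, inst)
  expect_identical(nrow(pk), 2L)  # 2 envelope peaks
  w <- emg_intensity(100, 100, 2, 0, area = 1000)
  expect_equal(pk$intensity, w * c(0.8, 0.2))

  inst10 <- instrument_model(ppm_systematic = 10)
  pk10 <- centroid_peaks_ms1(sp, t = 100, inst10)
  expect_equal(pk10$mz[1], 410 * (1 + 10 / 1e6))

  # two species sharing an exact m/z collapse into one summed centroid
  sp2 <- tiny_species()
  sp2$precursor_mz[2] <- 410
  sp2$apex_rt[2] <- 100
  sp2$envelope[[2]] <- tibble::tibble(mz = c(410, 411), abundance = c(1, 0.1))
  pk2 <- centroid_peaks_ms1(sp2, t = 100, inst)
  expect_identical(sum(abs(pk2$mz - 410) < 1e-9), 1L)
  w2 <- emg_intensity(100, 100, 2, 0, area = 500)
  expect_equal(pk2$intensity[abs(pk2$mz - 410) < 1e-9], w * 0.8 + w2 * 1)
})

test_that("MS2 windows are half-open and collect fragment unions", {
  sp <- tiny_species()  # precursors at 410 and 435
  inst <- instrument_model()
  # lower edge included
  pk <- centroid_peaks_ms2(sp, t = 101, window = c(410, 435), inst)
  expect_equal(sort(pk$mz), sort(sp$fragments[[1]]$mz))
  # upper edge excluded: 435 not in [410, 435)
  expect_identical(nrow(centroid_peaks_ms2(sp[2, ], t = 103,
                                           window = c(410, 435), inst)), 0L)
  # empty window still yields an (empty) spectrum
  expect_identical(nrow(centroid_peaks_ms2(sp, t = 101,
                                           window = c(600, 620), inst)), 0L)
  # both precursors in one window: union of fragments, independent weights
  pk2 <- centroid_peaks_ms2(sp, t = 101, window = c(400, 440), inst)
  expect_identical(nrow(pk2), 4L)
  w1 <- emg_intensity(101, 100, 2, 0, area = 1000)
  w2 <- emg_intensity(101, 103, 2, 0, area = 500)
  expected <- c(w1 * sp$fragments[[1]]$rel_intensity,
                w2 * sp$fragments[[2]]$rel_intensity)
  expect_equal(pk2$intensity[order(pk2$mz)],
               expected[order(c(sp$fragments[[1]]$mz, sp$fragments[[2]]$mz))])
})

test_that("profile rendering preserves area and shapes differ in the tails", {
  centroid <- list(mz = 600, intensity = 1000)
  g <- profileize(centroid, instrument_model(profile_shape = "gaussian"))
  expect_equal(sum(g$intensity) * 0.002, 1000, tolerance = 0.01)
  # FWHM on the grid matches mz / resolution = 0.02
  above <- g$mz[g$intensity > max(g$intensity) / 2]
  expect_equal(max(above) - min(above), 0.02, tolerance = 0.2)

  l <- profileize(centroid, instrument_model(profile_shape = "lorentzian"))
  at <- function(df, mz) df$intensity[which.min(abs(df$mz - mz))]
  expect_gt(at(l, 600 + 3 * 0.02), at(g, 600 + 3 * 0.02))

  e <- profileize(centroid, instrument_model(profile_shape = "emg"))
  expect_equal(sum(e$intensity) * 0.002, 1000, tolerance = 0.01)

  expect_error(
    profileize(centroid, instrument_model(profile_shape = "gaussian",
                                          grid_step = 0.01)),
    "undersamples")
})

test_that("simulated runs are linear in abundance and deterministic", {
  sp <- tiny_species()
  events <- tiny_events()
  inst <- instrument_model(ppm_sd = 2, spray_instability_sd = 0.1)
  r1 <- simulate_run(sp, events, inst, seed = 5)
  r2 <- simulate_run(sp, events, inst, seed = 5)
  expect_identical(r1$mz, r2$mz)
  expect_identical(r1$intensity, r2$intensity)

  sp2 <- sp
  sp2$abundance[1] <- 2 * sp$abundance[1]
  r3 <- simulate_run(sp2, events, inst, seed = 5)
  # every peak of species 1 doubles exactly; species 2 peaks unchanged
  for (i in which(lengths(r1$mz) > 0)) {
    expect_identical(r3$mz[[i]], r1$mz[[i]])
    ratio <- r3$intensity[[i]] / r1$intensity[[i]]
    expect_true(all(abs(ratio - 2) < 1e-12 | abs(ratio - 1) < 1e-12))
  }
})

test_that("every emitted m/z respects the scan range", {
  sp <- tiny_species()
  inst <- instrument_model(scan_range = c(200, 360))
  run <- simulate_run(sp, tiny_events(), inst, seed = 2)
  mzs <- unlist(run$mz)
  expect_true(all(mzs >= 200 & mzs <= 360))
  # fragment at 375.20 and envelope peak at 435 fall outside and are dropped
  expect_false(any(abs(mzs - 375.20) < 0.01))
  expect_false(any(abs(mzs - 435) < 0.01))
})

test_that("MS2 fragments appear exactly in windows containing the precursor", {
  lib <- generate_synthetic_library(40, seed = 13)
  cfg <- dia_config(library_n = 40, run_length = 200, window_width = 50)
  sim <- simulate_experiment(config = cfg,
                             library = lib)
  run <- sim$runs[[1]]
  truth <- sim$truth
  sup <- profile_support(truth$apex_rt, cfg$peak_sigma, cfg$peak_tau,
                         frac = cfg$elution_threshold)
  ms2 <- run[run$ms_level == 2L & lengths(run$mz) > 0, ]
  lib_frags <- setNames(sim$library$fragments, sim$library$precursor_id)
  for (i in sample(seq_len(nrow(ms2)), min(40, nrow(ms2)))) {
    ev <- ms2[i, ]
    contributors <- which(truth$precursor_mz >= ev$mz_lower &
                            truth$precursor_mz < ev$mz_upper &
                            sup$t_start <= ev$start_time &
                            sup$t_end >= ev$start_time)
    allowed <- sort(unique(unlist(purrr::map(
      truth$precursor_id[contributors], function(id) lib_frags[[id]]$mz))))
    observed <- ev$mz[[1]]
    expect_true(all(vapply(observed, function(m) {
      any(abs(allowed - m) < 1e-9)
    }, logical(1))))
  }
})

test_that("spray instability leaves integrated areas unbiased", {
  sp <- tiny_species()[1, ]
  sp$abundance <- 1e4
  events <- tiny_events(run_length = 200, ms1_d = 0.2, ms2_d = 0.1)
  quiet <- simulate_run(sp, events, instrument_model(), seed = 3)
  noisy <- simulate_run(sp, events,
                        instrument_model(spray_instability_sd = 0.15), seed = 3)
  area <- function(run) {
    ms1 <- run[run$ms_level == 1L, ]
    sum(unlist(ms1$intensity)) * median(diff(ms1$start_time))
  }
  expect_equal(area(quiet), 1e4, tolerance = 0.01)
  expect_equal(area(noisy), area(quiet), tolerance = 0.1)
  expect_false(isTRUE(all.equal(area(noisy), area(quiet), tolerance = 1e-6)))
})
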