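test_that("XIC areas recover true abundances for isolated precursors", {
  cfg <- dia_config(library_n = 12, run_length = 400, window_width = 100,
                    ms1_duration = 0.2, ms2_duration = 0.05, seed = 6)
  sim <- simulate_experiment(config = cfg)
  xic <- extract_xic(sim$runs[[1]], sim$truth)
  # the quantifier integrates the monoisotopic trace only, so the expected
  # area is abundance times the monoisotopic envelope fraction
  mono_frac <- vapply(seq_len(nrow(sim$truth)), function(i) {
    isotope_envelope(peptide_composition(sim$truth$stripped_sequence[i]),
                     max_peaks = 1)$abundance
  }, numeric(1))
  expected <- sim$truth$abundance_group1_rep1 * mono_frac
  rel_err <- abs(xic$area - expected) / expected
  # all precursors here are sampled at >= 10 points per peak
  expect_true(all(xic$points_per_peak >= 10))
  expect_lt(max(rel_err), 0.02)
  # empirical PPP within +/-1.5 of the FWHM/cycle-time estimate
  ppp_est <- expected_points_per_peak(sim$schema, cfg$peak_sigma,
                                      cfg$peak_tau)$ppp[1]
  expect_lt(max(abs(xic$points_per_peak - ppp_est)), 1.5)
})

test_that("a species absent from the sample has zero XIC area", {
  cfg <- dia_config(library_n = 10, run_length = 120, window_width = 100,
                    n_groups = 2, n_replicates = 1,
                    prob_missing_group = 0.5, seed = 8)
  sim <- simulate_experiment(config = cfg)
  xic <- extract_xic(sim$runs[["group1_rep1"]], sim$truth)
  absent <- is.na(sim$truth$abundance_group1_rep1)
  expect_true(any(absent))
  expect_true(all(xic$area[absent] == 0))
  expect_true(all(xic$area[!absent] > 0))
})

fake_truth <- function(fc, n_rep = 2) {
  n <- length(fc)
  truth <- tibble::tibble(
    precursor_id = paste0("p", seq_len(n)),
    precursor_mz = 500 + seq_len(n),
    source = "synthetic",
    log2_fc_group2 = fc
  )
  for (g in 1:2) for (r in seq_len(n_rep)) {
    truth[[sprintf("abundance_group%d_rep%d", g, r)]] <-
      1000 * 2^(if (g == 2) fc else 0)
  }
  truth
}

fake_xics <- function(truth, n_rep = 2, noise = 0) {
  smp <- expand.grid(g = 1:2, r = seq_len(n_rep))
  purrr::map2_dfr(smp$g, smp$r, function(g, r) {
    tibble::tibble(
      precursor_id = truth$precursor_id,
      area = truth[[sprintf("abundance_group%d_rep%d", g, r)]] * 2^noise,
      points_per_peak = 10,
      sample = sprintf("group%d_rep%d", g, r))
  })
}

test_that("noise-free recovery is exact and clamps the reported range", {
  fc <- c(-2, 0, 1, 3, 7)  # one precursor beyond the +/-5 reporting range
  truth <- fake_truth(fc)
  rec <- fold_change_recovery(fake_xics(truth), truth)
  expect_equal(rec$precursors$estimated_log2_fc,
               rec$precursors$true_log2_fc, tolerance = 1e-12)
  expect_equal(rec$r2, 1)
  expect_identical(rec$n_used, 4L)  # the fc = 7 precursor is excluded
  expect_false(rec$unreliable)
  expect_identical(nrow(tidy(rec)), 5L)
  expect_identical(names(glance(rec)), c("r2", "avg_ppp", "n_used", "unreliable"))
})

test_that("precursors with absent cells are excluded from recovery", {
  truth <- fake_truth(c(1, -1, 0.5, 2))
  truth$abundance_group2_rep1[2] <- NA
  rec <- fold_change_recovery(fake_xics(truth), truth)
  expect_identical(nrow(rec$precursors), 3L)
  expect_false("p2" %in% rec$precursors$precursor_id)
})

test_that("recovery flags itself unreliable below three usable precursors", {
  truth <- fake_truth(c(1, 2))
  rec <- fold_change_recovery(fake_xics(truth), truth)
  expect_true(rec$unreliable)
})

test_that("end-to-end validation of a written simulation directory", {
  cfg <- dia_config(library_n = 15, run_length = 150, window_width = 100,
                    ms1_duration = 0.2, ms2_duration = 0.1,
                    n_groups = 2, n_replicates = 2,
                    between_group_log2_sd = 1, within_group_log2_sd = 0,
                    seed = 12)
  sim <- simulate_experiment(config = cfg)
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  res <- validate_simulation(d)
  expect_identical(nrow(res$xics), 15L * 4L)
  expect_gt(res$recovery$r2, 0.999)
  # sample-set mismatch is refused
  file.remove(file.path(d, "group1_rep1.mzML"))
  expect_error(validate_simulation(d), "does not match")
  # missing ground truth is refused
  d2 <- withr::local_tempdir()
  expect_error(validate_simulation(d2), "ground_truth")
})
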