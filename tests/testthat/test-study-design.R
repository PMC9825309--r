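small_lib <- function(n = 50, seed = 5) generate_synthetic_library(n, seed = seed)

test_that("zero-variance designs reproduce base abundances exactly", {
  lib <- small_lib(20)
  d <- study_design(n_groups = 2, n_replicates = 2,
                    between_group_log2_sd = 0, within_group_log2_sd = 0)
  ab <- sample_abundances(lib, d)
  expect_equal(ab$abundance,
               rep(lib$base_abundance, each = 4))
  expect_true(all(ab$true_log2_fc == 0))
  # same seed -> identical expansion
  expect_identical(ab, sample_abundances(lib, d))
})

test_that("within-group log2 noise has the configured spread", {
  lib <- small_lib(5000, seed = 8)
  d <- study_design(n_groups = 1, n_replicates = 3,
                    within_group_log2_sd = 0.2, seed = 21)
  ab <- sample_abundances(lib, d)
  resid <- log2(ab$abundance) - rep(log2(lib$base_abundance), each = 3)
  expect_equal(sd(resid), 0.2, tolerance = 0.1)
})

test_that("true fold changes equal noise-free group-mean log ratios", {
  lib <- small_lib(200)
  d <- study_design(n_groups = 3, n_replicates = 2,
                    between_group_log2_sd = 1, within_group_log2_sd = 0,
                    seed = 4)
  ab <- sample_abundances(lib, d)
  means <- ab |>
    dplyr::group_by(precursor_id, group) |>
    dplyr::summarise(m = mean(abundance),
                     fc = true_log2_fc[1], .groups = "drop")
  ref <- means[means$group == 1, ]
  for (g in 2:3) {
    gm <- means[means$group == g, ]
    expect_equal(log2(gm$m / ref$m[match(gm$precursor_id, ref$precursor_id)]),
                 gm$fc, tolerance = 1e-12)
  }
})

test_that("missingness modes are independent and hit their rates", {
  lib <- small_lib(5000, seed = 9)
  d0 <- study_design(n_groups = 2, n_replicates = 3)
  ab <- sample_abundances(lib, d0)
  expect_identical(apply_missingness(ab, d0), ab)

  # degenerate: every group masked
  d1 <- study_design(n_groups = 2, n_replicates = 3, prob_missing_group = 1)
  m1 <- apply_missingness(sample_abundances(lib, d1), d1)
  expect_true(all(m1$absent))

  # sample-specific rate
  d2 <- study_design(n_groups = 2, n_replicates = 3,
                     prob_missing_sample = 0.1, seed = 33)
  m2 <- apply_missingness(sample_abundances(lib, d2), d2)
  expect_equal(mean(m2$absent), 0.1, tolerance = 0.1)
  expect_true(all(is.na(m2$abundance[m2$absent])))

  # combined: expected cell rate 1 - (1-pg)(1-ps)
  d3 <- study_design(n_groups = 2, n_replicates = 3,
                     prob_missing_group = 0.2, prob_missing_sample = 0.1,
                     seed = 34)
  m3 <- apply_missingness(sample_abundances(lib, d3), d3)
  expect_equal(mean(m3$absent), 1 - 0.8 * 0.9, tolerance = 0.05)
  # group-mode masking is all-or-none within a (precursor, group) block
  d4 <- study_design(n_groups = 2, n_replicates = 3,
                     prob_missing_group = 0.3, seed = 35)
  m4 <- apply_missingness(sample_abundances(lib, d4), d4)
  frac <- m4 |>
    dplyr::group_by(precursor_id, group) |>
    dplyr::summarise(f = mean(absent), .groups = "drop")
  expect_true(all(frac$f %in% c(0, 1)))
  expect_equal(mean(frac$f), 0.3, tolerance = 0.05)
})

test_that("decoys land inside the usable gradient, reproducibly", {
  g <- gradient_model(600, rt_range = c(0, 100), padding = 30)
  dec <- tibble::tibble(
    name = paste0("d", 1:200), precursor_mz = runif(200, 400, 900),
    fragments = replicate(200, tibble::tibble(
      series = "other", index = 1L, charge = 1L, mz = 200, rel_intensity = 1),
      simplify = FALSE))
  placed <- place_decoys(dec, g, seed = 6)
  expect_true(all(placed$apex_rt >= 30 & placed$apex_rt <= 570))
  expect_identical(placed$apex_rt, place_decoys(dec, g, seed = 6)$apex_rt)
  expect_identical(placed$source, rep("decoy", 200))
  # empty decoy set yields an empty, well-typed frame
  empty <- place_decoys(dec[0, ], g)
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("precursor_id", "apex_rt", "fragments") %in% names(empty)))
})
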