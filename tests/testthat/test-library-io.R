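make_prosit_csv <- function(df, path = withr::local_tempfile(fileext = ".csv"),
                            .local_envir = parent.frame()) {
  readr::write_csv(df, path)
  path
}

prosit_rows <- function(seq = "PEPTIDEK", z = 2, mz = 464.7333, irt = 50,
                        frag_mz = c(504.27, 605.31), frag_int = c(1, 0.5)) {
  tibble::tibble(
    ModifiedPeptide = seq, StrippedPeptide = seq, PrecursorCharge = z,
    PrecursorMz = mz, iRT = irt, FragmentMz = frag_mz,
    FragmentType = "y", FragmentNumber = seq_along(frag_mz),
    FragmentCharge = 1, RelativeIntensity = frag_int)
}

test_that("Prosit CSV rows group into precursors with normalized fragments", {
  withr::local_envvar(c(dummy = "1"))
  p <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(prosit_rows(frag_int = c(0.5, 1.0)), p)
  lib <- read_prosit_library(p)
  expect_identical(nrow(lib), 1L)
  expect_identical(nrow(lib$fragments[[1]]), 2L)
  expect_equal(sort(lib$fragments[[1]]$rel_intensity), c(0.5, 1.0))
  expect_identical(lib$rt_basis, "irt")
  expect_identical(lib$source, "prosit")
})

test_that("Prosit reader validates columns, emptiness and m/z consistency", {
  p <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(prosit_rows(), -"iRT"), p)
  expect_error(read_prosit_library(p), "iRT")

  p2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(prosit_rows()[0, ], p2)
  expect_error(read_prosit_library(p2), "empty")

  # same precursor listed twice with precursor m/z differing by > 10 ppm
  p3 <- withr::local_tempfile(fileext = ".csv")
  rows <- dplyr::bind_rows(prosit_rows(), prosit_rows(mz = 464.7333 * (1 + 2e-5)))
  readr::write_csv(rows, p3)
  expect_error(read_prosit_library(p3), "conflicting")
})

test_that("generator CSV serialization round-trips through the reader", {
  lib <- generate_synthetic_library(15, seed = 3)
  p <- withr::local_tempfile(fileext = ".csv")
  write_prosit_library(lib, p)
  back <- read_prosit_library(p)
  back <- back[match(lib$precursor_id, back$precursor_id), ]
  expect_equal(back$stripped_sequence, lib$stripped_sequence)
  expect_identical(back$charge, lib$charge)
  expect_equal(back$precursor_mz, lib$precursor_mz, tolerance = 1e-9)
  expect_equal(back$rt_coord, lib$rt_coord, tolerance = 1e-9)
  for (i in seq_len(nrow(lib))) {
    expect_equal(back$fragments[[i]]$mz, lib$fragments[[i]]$mz,
                 tolerance = 1e-9)
    expect_equal(back$fragments[[i]]$rel_intensity,
                 lib$fragments[[i]]$rel_intensity, tolerance = 1e-9)
  }
})

maxquant_fixture <- function(dir, ev, ms) {
  readr::write_tsv(ev, file.path(dir, "evidence.txt"))
  readr::write_tsv(ms, file.path(dir, "msms.txt"))
  dir
}

mq_ev <- function(n = 1) {
  tibble::tibble(
    Sequence = paste0("PEPTIDE", LETTERS[seq_len(n)], "K"),
    Modifications = "Unmodified", Charge = 2,
    `m/z` = 500 + seq_len(n), `Retention time` = 10 + seq_len(n),
    Intensity = 1e6 * seq_len(n), `Best MS/MS` = seq_len(n) - 1)
}

mq_ms <- function(n = 1) {
  tibble::tibble(id = seq_len(n) - 1,
                 Masses = rep("300.1;401.2;502.3", n),
                 Intensities = rep("50;100;25", n))
}

test_that("MaxQuant evidence joins fragments and observed retention times", {
  d <- withr::local_tempdir()
  maxquant_fixture(d, mq_ev(1), mq_ms(1))
  lib <- read_maxquant_evidence(d)
  expect_identical(nrow(lib), 1L)
  expect_identical(lib$rt_basis, "rt_min")
  expect_equal(lib$rt_coord, 11)
  expect_equal(lib$base_abundance, 1e6)
  expect_equal(lib$fragments[[1]]$mz, c(300.1, 401.2, 502.3))
  expect_equal(max(lib$fragments[[1]]$rel_intensity), 1)
})

test_that("MaxQuant rows with unsupported modifications are dropped loudly", {
  d <- withr::local_tempdir()
  ev <- mq_ev(3)
  ev$Modifications[2] <- "Oxidation (M)"
  maxquant_fixture(d, ev, mq_ms(3))
  expect_warning(lib <- read_maxquant_evidence(d), "unsupported modifications")
  expect_identical(nrow(lib), 2L)
})

test_that("missing MaxQuant intensities impute to the library median", {
  d <- withr::local_tempdir()
  ev <- mq_ev(5)
  ev$Intensity <- c(10, 20, NA, 40, 80)
  maxquant_fixture(d, ev, mq_ms(5))
  lib <- read_maxquant_evidence(d)
  # median of the 4 observed values, computed by hand: (20 + 40) / 2 = 30
  expect_equal(lib$base_abundance[3], 30)
})

msp_text <- function() {
  c("Name: contaminant_a",
    "PrecursorMZ: 445.1200",
    "Num Peaks: 3",
    "101.1 50", "201.2 100", "301.3 25",
    "",
    "Name: contaminant_b",
    "MW: 888.24",
    "Charge: 2",
    "Num Peaks: 1",
    "150.05 10")
}

test_that("msp entries parse with normalization and m/z fallback", {
  p <- withr::local_tempfile(fileext = ".msp")
  writeLines(msp_text(), p)
  decoys <- read_msp(p)
  expect_identical(nrow(decoys), 2L)
  expect_identical(nrow(decoys$fragments[[1]]), 3L)
  expect_equal(max(decoys$fragments[[1]]$rel_intensity), 1)
  expect_equal(decoys$precursor_mz[2], ion_mz(888.24, 2))
  # gz-compressed input reads identically
  pz <- withr::local_tempfile(fileext = ".msp.gz")
  con <- gzfile(pz, "wt"); writeLines(msp_text(), con); close(con)
  expect_equal(read_msp(pz)$precursor_mz, decoys$precursor_mz)
})

test_that("msp peak-count mismatches error and empty files are valid", {
  p <- withr::local_tempfile(fileext = ".msp")
  writeLines(c("Name: bad", "PrecursorMZ: 400", "Num Peaks: 2", "100 1"), p)
  expect_error(read_msp(p), "declares 2 peaks but lists 1")
  p2 <- withr::local_tempfile(fileext = ".msp")
  writeLines(character(), p2)
  expect_identical(nrow(read_msp(p2)), 0L)
})

test_that("the synthetic generator is seeded, consistent and tryptic-like", {
  a <- generate_synthetic_library(10, seed = 1)
  b <- generate_synthetic_library(10, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, generate_synthetic_library(10, seed = 2)))

  lib <- generate_synthetic_library(1000, seed = 7)
  expect_true(all(grepl("[KR]$", lib$stripped_sequence)))
  expect_true(all(nchar(lib$stripped_sequence) >= 7 &
                    nchar(lib$stripped_sequence) <= 20))
  expect_true(all(lib$charge %in% 2:3))
  # precursor m/z is exactly the computed ion m/z of the composition
  idx <- seq(1, nrow(lib), by = 37)
  expected <- vapply(idx, function(i) {
    ion_mz(monoisotopic_mass(peptide_composition(lib$stripped_sequence[i])),
           lib$charge[i])
  }, numeric(1))
  expect_identical(lib$precursor_mz[idx], expected)
})
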