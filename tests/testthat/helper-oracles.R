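# Independent oracles and small fixtures shared across tests.

# Brute-force aggregated isotope distribution: enumerate every isotopologue
# (one isotope choice per atom), bin by total extra nucleon count. Exponential
# in atom count, so only for tiny compositions; independent of the package's
# truncated-convolution implementation.
brute_force_envelope <- function(composition, n_peaks) {
  iso <- as.data.frame(isotope_table())
  composition <- composition[composition != 0]
  atoms <- rep(names(composition), composition)
  per_atom <- lapply(atoms, function(el) {
    rows <- iso[iso$element == el, ]
    list(p = rows$abundance, off = rows$nucleons - min(rows$nucleons))
  })
  grid <- do.call(expand.grid, lapply(per_atom, function(a) seq_along(a$p)))
  p <- rep(1, nrow(grid))
  off <- rep(0, nrow(grid))
  for (j in seq_along(atoms)) {
    p <- p * per_atom[[j]]$p[grid[[j]]]
    off <- off + per_atom[[j]]$off[grid[[j]]]
  }
  agg <- tapply(p, off, sum)
  out <- numeric(n_peaks)
  idx <- as.integer(names(agg)) + 1L
  keep <- idx <= n_peaks
  out[idx[keep]] <- agg[keep]
  out
}

# random small composition whose isotopologue enumeration stays tractable
random_small_composition <- function() {
  n_atoms <- sample(1:10, 1)
  els <- sample(c("C", "H", "N", "O", "S", "P"), n_atoms, replace = TRUE,
                prob = c(0.3, 0.3, 0.15, 0.15, 0.05, 0.05))
  tab <- table(els)
  setNames(as.integer(tab), names(tab))
}

# numeric EMG area over a generous window
emg_area_quadrature <- function(mu, sigma, tau, area = 1) {
  stats::integrate(function(t) emg_intensity(t, mu, sigma, tau, area),
                   mu - 20 * sigma, mu + 20 * sigma + 20 * max(tau, sigma),
                   rel.tol = 1e-10)$value
}

# direct enumeration oracle for scan scheduling: walk the cycle event by event
schedule_oracle <- function(schema, run_length) {
  starts <- numeric(0)
  levels <- integer(0)
  t <- 0
  i <- 1L
  n <- nrow(schema)
  repeat {
    d <- schema$duration_s[i]
    if (t + d > run_length + 1e-9) break
    starts <- c(starts, t)
    levels <- c(levels, schema$ms_level[i])
    t <- t + d
    i <- if (i == n) 1L else i + 1L
  }
  data.frame(start_time = starts, ms_level = levels)
}

# minimal two-species fixture with hand-set elution and fragments
tiny_species <- function() {
  tibble::tibble(
    precursor_id = c("AAAK/2", "PPPR/2"),
    stripped_sequence = c("AAAK", "PPPR"),
    charge = c(2L, 2L),
    precursor_mz = c(410, 435),
    apex_rt = c(100, 103),
    sigma = c(2, 2),
    tau = c(0, 0),
    abundance = c(1000, 500),
    envelope = list(tibble::tibble(mz = c(410, 410.5), abundance = c(0.8, 0.2)),
                    tibble::tibble(mz = c(435, 435.5), abundance = c(0.9, 0.1))),
    fragments = list(
      tibble::tibble(series = "y", index = 1:2, charge = 1L,
                     mz = c(218.15, 347.18), rel_intensity = c(1, 0.5)),
      tibble::tibble(series = "y", index = 1:2, charge = 1L,
                     mz = c(272.17, 375.20), rel_intensity = c(1, 0.25))
    )
  )
}

default_instrument <- function(...) instrument_model(...)

# small scheduled event set: one MS1 + two windows, repeated
tiny_events <- function(run_length = 210, ms1_d = 0.5, ms2_d = 0.25,
                        windows = list(c(400, 420), c(420, 440))) {
  schema <- tibble::tibble(
    ms_level = c(1L, rep(2L, length(windows))),
    mz_lower = c(NA, vapply(windows, `[`, numeric(1), 1)),
    mz_upper = c(NA, vapply(windows, `[`, numeric(1), 2)),
    duration_s = c(ms1_d, rep(ms2_d, length(windows)))
  )
  schema$target_mz <- (schema$mz_lower + schema$mz_upper) / 2
  schedule_run(schema, run_length)
}
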