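# Spectrum synthesis: MS1 isotope-envelope peaks, window-gated MS2 fragment
# collection with elution weighting, mass error, spray instability, and
# centroid or profile output.

#' Instrument model
#'
#' Collects the mass-spectral knobs of the simulation.
#'
#' @param resolution Resolving power defining peak FWHM as `mz / resolution`
#'   (constant across m/z).
#' @param scan_range Length-2 m/z range; peaks outside are dropped.
#' @param ppm_systematic Fixed systematic mass error, ppm.
#' @param ppm_sd SD of per-peak Gaussian mass-error jitter, ppm.
#' @param profile_shape `"centroid"` (default), `"gaussian"`, `"lorentzian"`
#'   or `"emg"`; non-centroid shapes are rendered on an m/z grid.
#' @param grid_step Profile-mode m/z grid step, Th.
#' @param spray_instability_sd SD (as a fraction) of the per-scan lognormal
#'   electrospray intensity factor applied coherently to all peaks of a scan;
#'   the factor has mean 1 so integrated areas stay unbiased.
#' @param abundance_to_counts Scale from library abundance units to detector
#'   counts.
#' @param noise_rate Expected number of additive random noise centroids per
#'   spectrum (default 0: off).
#' @param noise_intensity Mean (exponential) intensity of noise centroids.
#' @param mz_tail_frac EMG profile-shape tail constant as a fraction of FWHM.
#' @return An `instrument_model` object.
#' @export
#' @examples
#' instrument_model(resolution = 60000, ppm_sd = 2)
instrument_model <- function(resolution = 30000,
                             scan_range = c(150, 2000),
                             ppm_systematic = 0,
                             ppm_sd = 0,
                             profile_shape = c("centroid", "gaussian",
                                               "lorentzian", "emg"),
                             grid_step = 0.002,
                             spray_instability_sd = 0,
                             abundance_to_counts = 1,
                             noise_rate = 0,
                             noise_intensity = 100,
                             mz_tail_frac = 1) {
  profile_shape <- match.arg(profile_shape)
  stopifnot(resolution > 0, length(scan_range) == 2L,
            scan_range[2] > scan_range[1], ppm_sd >= 0, grid_step > 0,
            spray_instability_sd >= 0, abundance_to_counts > 0,
            noise_rate >= 0)
  structure(
    list(resolution = resolution, scan_range = scan_range,
         ppm_systematic = ppm_systematic, ppm_sd = ppm_sd,
         profile_shape = profile_shape, grid_step = grid_step,
         spray_instability_sd = spray_instability_sd,
         abundance_to_counts = abundance_to_counts,
         noise_rate = noise_rate, noise_intensity = noise_intensity,
         mz_tail_frac = mz_tail_frac),
    class = "instrument_model"
  )
}

#' @export
print.instrument_model <- function(x, ...) {
  cat(sprintf("<instrument_model> R %g, scan range [%g, %g] Th, %s mode, mass error %g +/- %g ppm, spray sd %g\n",
              x$resolution, x$scan_range[1], x$scan_range[2], x$profile_shape,
              x$ppm_systematic, x$ppm_sd, x$spray_instability_sd))
  invisible(x)
}

#' Species eluting at a time point
#'
#' Returns the species whose elution profile exceeds `threshold_frac` of its
#' apex intensity at time `t`, with the absolute (area-scaled) elution weight
#' `emg_intensity(t) * abundance` used for spectral peak intensities.
#'
#' @param t Time, seconds.
#' @param profiles Tibble with columns `precursor_id`, `apex_rt`, `sigma`,
#'   `tau`, `abundance`.
#' @param threshold_frac Support threshold as a fraction of apex intensity,
#'   in (0, 1).
#' @return Tibble `precursor_id`, `elution_weight`.
#' @export
active_species <- function(t, profiles, threshold_frac = 1e-3) {
  stopifnot(threshold_frac > 0, threshold_frac < 1)
  sup <- profile_support(profiles$apex_rt, profiles$sigma, profiles$tau,
                         frac = threshold_frac)
  on <- t >= sup$t_start & t <= sup$t_end
  act <- profiles[on, , drop = FALSE]
  tibble::tibble(
    precursor_id = act$precursor_id,
    elution_weight = emg_intensity(t, act$apex_rt, act$sigma, act$tau,
                                   area = act$abundance)
  )
}

# pair active (species, event) rows: for each species i, MS1/window event
# times inside [t0_i, t1_i]; returns integer vectors (species row, event row)
.active_pairs <- function(times, t0, t1) {
  lo <- findInterval(t0, times, left.open = TRUE) + 1L
  hi <- findInterval(t1, times)
  n <- pmax(hi - lo + 1L, 0L)
  keep <- n > 0L
  if (!any(keep)) {
    return(list(species = integer(), event = integer()))
  }
  list(species = rep(which(keep), n[keep]),
       event = sequence(n[keep], from = lo[keep]))
}

# merge peaks closer than 1e-6 Th within a spectrum; rows must be sorted by
# (event, mz)
.merge_coincident <- function(event, mz, intensity) {
  if (!length(mz)) {
    return(list(event = event, mz = mz, intensity = intensity))
  }
  new_grp <- c(TRUE, diff(event) != 0 | diff(mz) >= 1e-6)
  grp <- cumsum(new_grp)
  keep <- which(new_grp)
  list(event = event[keep],
       mz = mz[keep],
       intensity = as.numeric(rowsum(intensity, grp, reorder = FALSE)))
}

#' Render centroids as profile-mode peak shapes
#'
#' Replaces each centroid by its peak shape (Gaussian, Lorentzian or EMG in
#' m/z) evaluated on a uniform global m/z grid of step `grid_step` over +/- 6
#' FWHM, with FWHM = mz / resolution. Overlapping shapes are summed;
#' zero-intensity grid regions between peaks are omitted (sparse encoding).
#' Shape densities are scaled so the grid-summed intensity times the step
#' recovers the centroid intensity (area preservation).
#'
#' @param centroids Tibble or list with numeric `mz`, `intensity`.
#' @param instrument An [instrument_model()] with a non-centroid
#'   `profile_shape`.
#' @return Tibble with gridded `mz`, `intensity`.
#' @export
profileize <- function(centroids, instrument) {
  stopifnot(inherits(instrument, "instrument_model"),
            instrument$profile_shape != "centroid")
  step <- instrument$grid_step
  fwhm_min <- instrument$scan_range[1] / instrument$resolution
  if (step > fwhm_min / 2) {
    abort(sprintf("grid_step %g undersamples the profile: FWHM at scan-range start is %g (need step <= FWHM/2)",
                  step, fwhm_min))
  }
  mz <- centroids$mz
  intensity <- centroids$intensity
  if (!length(mz)) return(tibble::tibble(mz = numeric(), intensity = numeric()))
  fwhm <- mz / instrument$resolution
  i0 <- ceiling((mz - 6 * fwhm) / step)
  i1 <- floor((mz + 6 * fwhm) / step)
  n <- i1 - i0 + 1L
  idx <- sequence(n, from = i0)
  grid <- idx * step
  center <- rep(mz, n)
  amp <- rep(intensity, n)
  f <- rep(fwhm, n)
  shape <- switch(instrument$profile_shape,
    gaussian = dnorm(grid, center, f / 2.3548),
    lorentzian = dcauchy(grid, center, f / 2),
    emg = {
      sigma <- f / 2.3548
      tau <- instrument$mz_tail_frac * f
      emg_intensity(grid, center, sigma, tau)
    })
  dens <- amp * shape
  agg <- rowsum(dens, idx, reorder = TRUE)
  tibble::tibble(mz = as.numeric(rownames(agg)) * step,
                 intensity = as.numeric(agg))
}

#' Simulate one LC-MS/MS run
#'
#' Synthesizes one spectrum per scheduled scan event. MS1 spectra contain the
#' isotope-envelope peaks of every species eluting at the scan time, weighted
#' by its EMG elution intensity; MS2 spectra collect the fragments of every
#' species whose precursor m/z falls in the event's half-open isolation
#' window, with the same elution weighting, so chromatographically
#' overlapping species superimpose additively. Mass error (systematic +
#' Gaussian ppm jitter), a per-scan lognormal spray-instability factor,
#' optional additive noise centroids and optional profile-mode rendering are
#' applied. Fully deterministic for a given `seed`.
#'
#' @param species Tibble with one row per simulated species: `precursor_id`,
#'   `precursor_mz`, `apex_rt`, `sigma`, `tau`, `abundance` (this sample; `NA`
#'   rows are skipped), `envelope` (list of tibbles `mz`/`abundance`) and
#'   `fragments` (list of tibbles with `mz`, `rel_intensity`; `NULL` or empty
#'   for MS1-only species).
#' @param events Scan events from [schedule_run()].
#' @param instrument An [instrument_model()].
#' @param seed Integer seed. Independent sub-streams (derived as fixed
#'   offsets) drive spray factors, MS1/MS2 mass jitter, noise and fragment
#'   jitter, so disabling one component leaves the others bit-identical.
#' @param elution_threshold Elution support threshold as a fraction of apex
#'   intensity.
#' @param fragment_jitter_sd Per-(species, fragment) log2 intensity jitter
#'   applied once per run (default 0).
#' @return A `dia_run`: the events tibble with list-columns `mz`, `intensity`
#'   and a `tic` column; instrument and seed kept as attributes.
#' @export
simulate_run <- function(species, events, instrument, seed = 1L,
                         elution_threshold = 1e-3, fragment_jitter_sd = 0) {
  stopifnot(inherits(instrument, "instrument_model"))
  species <- species[!is.na(species$abundance), , drop = FALSE]
  n_events <- nrow(events)

  # per-scan spray factor (stream 1)
  spray <- rep(1, n_events)
  if (instrument$spray_instability_sd > 0) {
    sdl <- instrument$spray_instability_sd
    set.seed(seed + 1L)
    spray <- rlnorm(n_events, meanlog = -sdl^2 / 2, sdlog = sdl)
  }

  sup <- profile_support(species$apex_rt, species$sigma, species$tau,
                         frac = elution_threshold)

  build_part <- function(sp, ev, mz_list, int_list) {
    # sp, ev: parallel species-row / event-row indices (into species/events)
    len <- lengths(mz_list)[sp]
    ord <- length(sp)
    if (!ord || !sum(len)) {
      return(tibble::tibble(event = integer(), mz = numeric(),
                            intensity = numeric()))
    }
    w <- emg_intensity(events$start_time[ev], species$apex_rt[sp],
                       species$sigma[sp], species$tau[sp],
                       area = species$abundance[sp])
    pair_rep <- rep.int(seq_along(sp), len)
    tibble::tibble(
      event = ev[pair_rep],
      mz = unlist(mz_list[sp], use.names = FALSE),
      intensity = unlist(int_list[sp], use.names = FALSE) * w[pair_rep] *
        instrument$abundance_to_counts * spray[ev[pair_rep]]
    )
  }

  # --- MS1 ---
  ms1_rows <- which(events$ms_level == 1L)
  env_mz <- purrr::map(species$envelope, "mz")
  env_ab <- purrr::map(species$envelope, "abundance")
  p1 <- .active_pairs(events$start_time[ms1_rows], sup$t_start, sup$t_end)
  ms1 <- build_part(p1$species, ms1_rows[p1$event], env_mz, env_ab)

  # --- MS2 (per distinct window) ---
  frag_mz <- purrr::map(species$fragments, function(f) {
    if (is.null(f)) numeric() else f$mz
  })
  frag_in <- purrr::map(species$fragments, function(f) {
    if (is.null(f)) numeric() else f$rel_intensity
  })
  if (fragment_jitter_sd > 0) {
    set.seed(seed + 5L)
    frag_in <- purrr::map(frag_in, function(v) {
      if (length(v)) v * 2^rnorm(length(v), 0, fragment_jitter_sd) else v
    })
  }
  ms2_rows <- which(events$ms_level == 2L)
  ms2_parts <- list()
  if (length(ms2_rows)) {
    wkey <- paste(events$mz_lower[ms2_rows], events$mz_upper[ms2_rows])
    for (k in unique(wkey)) {
      rows <- ms2_rows[wkey == k]
      lo <- events$mz_lower[rows[1]]
      hi <- events$mz_upper[rows[1]]
      in_win <- which(species$precursor_mz >= lo & species$precursor_mz < hi)
      if (!length(in_win)) next
      p <- .active_pairs(events$start_time[rows],
                         sup$t_start[in_win], sup$t_end[in_win])
      if (!length(p$species)) next
      ms2_parts[[k]] <- build_part(in_win[p$species], rows[p$event],
                                   frag_mz, frag_in)
    }
  }
  peaks <- dplyr::bind_rows(c(list(ms1), ms2_parts))

  # mass error (streams 2/3: MS1 and MS2 jittered independently)
  if (nrow(peaks) &&
      (instrument$ppm_systematic != 0 || instrument$ppm_sd > 0)) {
    peaks <- peaks[order(peaks$event, peaks$mz), , drop = FALSE]
    is_ms1 <- events$ms_level[peaks$event] == 1L
    for (part in 1:2) {
      sel <- if (part == 1) is_ms1 else !is_ms1
      if (!any(sel)) next
      ppm <- rep(instrument$ppm_systematic, sum(sel))
      if (instrument$ppm_sd > 0) {
        set.seed(seed + 1L + part)
        ppm <- ppm + rnorm(sum(sel), 0, instrument$ppm_sd)
      }
      peaks$mz[sel] <- peaks$mz[sel] * (1 + ppm / 1e6)
    }
  }

  # additive noise centroids (stream 4)
  if (instrument$noise_rate > 0) {
    set.seed(seed + 4L)
    n_noise <- rpois(n_events, instrument$noise_rate)
    tot <- sum(n_noise)
    if (tot) {
      peaks <- dplyr::bind_rows(peaks, tibble::tibble(
        event = rep.int(seq_len(n_events), n_noise),
        mz = runif(tot, instrument$scan_range[1], instrument$scan_range[2]),
        intensity = rexp(tot, 1 / instrument$noise_intensity)
      ))
    }
  }

  # scan-range filter, ordering, coincident-peak superposition
  keep <- peaks$mz >= instrument$scan_range[1] &
    peaks$mz <= instrument$scan_range[2]
  peaks <- peaks[keep, , drop = FALSE]
  ord <- order(peaks$event, peaks$mz)
  merged <- .merge_coincident(peaks$event[ord], peaks$mz[ord],
                              peaks$intensity[ord])

  ev_factor <- factor(merged$event, levels = seq_len(n_events))
  mz_list <- split(merged$mz, ev_factor)
  int_list <- split(merged$intensity, ev_factor)
  names(mz_list) <- names(int_list) <- NULL

  if (instrument$profile_shape != "centroid") {
    prof <- purrr::map2(mz_list, int_list, function(m, i) {
      profileize(list(mz = m, intensity = i), instrument)
    })
    mz_list <- purrr::map(prof, "mz")
    int_list <- purrr::map(prof, "intensity")
  }

  run <- events
  run$mz <- mz_list
  run$intensity <- int_list
  run$tic <- vapply(int_list, sum, numeric(1))
  structure(
    tibble::new_tibble(run, class = "dia_run"),
    instrument = instrument, seed = seed,
    cycle_time = attr(events, "cycle_time") %||% NA_real_
  )
}

.one_event_peaks <- function(species, t, window, instrument, seed) {
  events <- tibble::tibble(
    scan_index = 1L, start_time = t,
    ms_level = if (is.null(window)) 1L else 2L,
    mz_lower = if (is.null(window)) NA_real_ else window[1],
    mz_upper = if (is.null(window)) NA_real_ else window[2],
    target_mz = if (is.null(window)) NA_real_ else mean(window),
    duration_s = 1e-3
  )
  run <- simulate_run(species, events, instrument, seed = seed)
  tibble::tibble(mz = run$mz[[1]], intensity = run$intensity[[1]])
}

#' Centroid peak list of a single MS1 scan
#'
#' Convenience wrapper around [simulate_run()] for one MS1 scan event at time
#' `t`: every species eluting at `t` contributes its isotope-envelope peaks,
#' elution-weighted, with the instrument's mass error applied.
#'
#' @inheritParams simulate_run
#' @param t Scan time, seconds.
#' @return Tibble `mz`, `intensity` (ascending m/z, coincident peaks summed).
#' @export
centroid_peaks_ms1 <- function(species, t, instrument, seed = 1L) {
  .one_event_peaks(species, t, NULL, instrument, seed)
}

#' Centroid peak list of a single DIA MS2 scan
#'
#' One MS2 scan at time `t` for the half-open isolation window
#' `[window[1], window[2])`: every species whose precursor m/z lies in the
#' window contributes all its fragments, weighted by the precursor's elution
#' intensity at `t`.
#'
#' @inheritParams centroid_peaks_ms1
#' @param window Length-2 numeric isolation window (lower, upper), Th.
#' @export
centroid_peaks_ms2 <- function(species, t, window, instrument, seed = 1L) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  .one_event_peaks(species, t, window, instrument, seed)
}

#' @export
print.dia_run <- function(x, ...) {
  cat(sprintf("<dia_run> %d spectra (%d MS1 / %d MS2), %.1f s, %s mode\n",
              nrow(x), sum(x$ms_level == 1L), sum(x$ms_level == 2L),
              max(x$start_time + x$duration_s),
              attr(x, "instrument")$profile_shape))
  NextMethod()
}
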