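# End-to-end simulation: expand a library and study design into per-sample
# simulated runs plus the ground-truth table.

# canonical content hash of a library (identity check for replay)
.library_fingerprint <- function(library) {
  flat <- library |>
    dplyr::select("precursor_id", "stripped_sequence", "modified_sequence",
                  "charge", "precursor_mz", "rt_coord", "base_abundance",
                  "source", "fragments") |>
    tidyr::unnest("fragments", names_sep = "_")
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  readr::write_csv(flat, tmp, progress = FALSE)
  unname(tools::md5sum(tmp))
}

# isotope envelopes for every species; decoys (no composition) get a single
# monoisotopic peak
.species_envelopes <- function(species, max_peaks, min_fraction) {
  purrr::pmap(
    list(species$stripped_sequence, species$charge, species$precursor_mz),
    function(seq, z, pmz) {
      if (is.na(seq)) {
        return(tibble::tibble(mz = pmz, abundance = 1))
      }
      isotope_envelope(peptide_composition(seq), max_peaks = max_peaks,
                       charge = z, min_fraction = min_fraction)
    })
}

#' Simulate a complete DIA experiment
#'
#' Runs the whole pipeline: maps the library onto the gradient, assigns EMG
#' elution profiles, expands the study design into per-sample abundances with
#' missingness, places decoys, schedules the duty cycles and synthesizes one
#' simulated run per sample, together with the ground-truth table that
#' generated them.
#'
#' @param library A precursor library tibble (default: built from the config's
#'   `library_source`).
#' @param config A [dia_config()].
#' @param decoys Optional decoy tibble from [read_msp()] (default: read from
#'   the config's `decoy_msp_path` if set).
#' @return A `dia_experiment`: list with `runs` (named list of `dia_run`),
#'   `truth` (ground-truth tibble), `abundances` (long per-sample tibble),
#'   `library`, `schema`, `gradient`, `design`, `instrument`, `config` and
#'   `library_fingerprint`.
#' @export
#' @examples
#' \donttest{
#' cfg <- dia_config(library_n = 20, run_length = 300)
#' sim <- simulate_experiment(config = cfg)
#' sim$runs[[1]]
#' }
simulate_experiment <- function(library = NULL, config = dia_config(),
                                decoys = NULL) {
  stopifnot(inherits(config, "dia_config"))
  if (is.null(library)) library <- .config_library(config)
  if (is.null(decoys) && !is.na(config$decoy_msp_path)) {
    decoys <- read_msp(config$decoy_msp_path)
  }

  design <- .config_design(config)
  instrument <- .config_instrument(config)
  schema <- .config_schema(config)
  gradient <- gradient_model(
    config$run_length,
    rt_range = range(library$rt_coord),
    padding = config$rt_padding_frac * config$run_length
  )

  library <- library |>
    map_rt(gradient) |>
    elution_profiles(peak_sigma = config$peak_sigma,
                     peak_tau = config$peak_tau,
                     sigma_cv = config$sigma_cv,
                     seed = config$seed + 2L)

  abundances <- library |>
    sample_abundances(design) |>
    apply_missingness(design)

  placed_decoys <- if (!is.null(decoys) && nrow(decoys)) {
    place_decoys(decoys, gradient, seed = config$seed + 3L)
  } else {
    place_decoys(tibble::tibble(name = character(), precursor_mz = numeric(),
                                fragments = list()), gradient)
  }
  if (nrow(placed_decoys)) {
    placed_decoys <- dplyr::mutate(placed_decoys,
                                   sigma = config$peak_sigma,
                                   tau = config$peak_tau)
  }

  events <- schedule_run(schema, config$run_length)
  attr(events, "cycle_time") <- cycle_time(schema)

  base_species <- dplyr::bind_rows(
    dplyr::select(library, "precursor_id", "stripped_sequence", "charge",
                  "precursor_mz", "apex_rt", "sigma", "tau", "fragments"),
    if (nrow(placed_decoys)) {
      dplyr::select(placed_decoys, "precursor_id", "stripped_sequence",
                    "charge", "precursor_mz", "apex_rt", "sigma", "tau",
                    "fragments")
    }
  )
  base_species$envelope <- .species_envelopes(
    base_species, config$isotope_max_peaks, config$isotope_min_fraction)

  samples <- design_samples(design)
  decoy_abundance <- placed_decoys$base_abundance
  runs <- purrr::imap(setNames(samples, samples), function(smp, nm) {
    ab <- abundances[abundances$sample == smp, , drop = FALSE]
    species <- base_species
    species$abundance <- c(
      ab$abundance[match(library$precursor_id, ab$precursor_id)],
      decoy_abundance
    )
    sample_seed <- config$seed + 10000L + match(smp, samples)
    simulate_run(species, events, instrument, seed = sample_seed,
                 elution_threshold = config$elution_threshold,
                 fragment_jitter_sd = config$fragment_jitter_sd)
  })

  truth <- .build_truth(library, placed_decoys, abundances, design)

  structure(
    list(runs = runs, truth = truth, abundances = abundances,
         library = library, decoys = placed_decoys, schema = schema,
         events = events, gradient = gradient, design = design,
         instrument = instrument, config = config,
         library_fingerprint = .library_fingerprint(library)),
    class = "dia_experiment"
  )
}

# ground truth: one row per species, per-sample abundance columns and
# per-group true log2 fold changes; deterministic order (apex_rt, then m/z)
.build_truth <- function(library, placed_decoys, abundances, design) {
  wide_ab <- abundances |>
    dplyr::select("precursor_id", "sample", "abundance") |>
    tidyr::pivot_wider(names_from = "sample", values_from = "abundance",
                       names_prefix = "abundance_")
  wide_fc <- abundances |>
    dplyr::distinct(.data$precursor_id, .data$group, .data$true_log2_fc) |>
    tidyr::pivot_wider(names_from = "group", values_from = "true_log2_fc",
                       names_prefix = "log2_fc_group")
  truth <- library |>
    dplyr::select("precursor_id", "stripped_sequence", "modified_sequence",
                  "charge", "precursor_mz", "apex_rt", "source") |>
    dplyr::left_join(wide_ab, by = "precursor_id") |>
    dplyr::left_join(wide_fc, by = "precursor_id")
  if (nrow(placed_decoys)) {
    decoy_rows <- placed_decoys |>
      dplyr::select("precursor_id", "stripped_sequence", "modified_sequence",
                    "charge", "precursor_mz", "apex_rt", "source")
    for (smp in design_samples(design)) {
      decoy_rows[[paste0("abundance_", smp)]] <- placed_decoys$base_abundance
    }
    for (g in seq_len(design$n_groups)) {
      decoy_rows[[paste0("log2_fc_group", g)]] <- 0
    }
    truth <- dplyr::bind_rows(truth, decoy_rows)
  }
  dplyr::arrange(truth, .data$apex_rt, .data$precursor_mz)
}

#' @export
print.dia_experiment <- function(x, ...) {
  cat(sprintf(
    "<dia_experiment> %d precursor(s) + %d decoy(s), %d sample(s) (%d group(s) x %d rep(s)), %d scan events/run\n",
    nrow(x$library), nrow(x$decoys), length(x$runs),
    x$design$n_groups, x$design$n_replicates, nrow(x$events)))
  invisible(x)
}

#' Preview a single precursor
#'
#' Simulates only the scan events overlapping one precursor's elution window
#' (its MS1 scans and the MS2 scans of its containing windows), to verify
#' input parameters before a full simulation. Abundance is the library base
#' abundance (sample 1 of a 1x1 noise-free design).
#'
#' @param library A precursor library tibble.
#' @param config A [dia_config()].
#' @param selector Precursor id (`"SEQ/z"`), or a modified/stripped sequence
#'   matching exactly one library entry.
#' @return A `dia_preview`: list with the subset `run`, `xic` tibble, apex MS1
#'   and MS2 spectra, and a `summary` tibble (apex RT, m/z, isolation window,
#'   expected points per peak).
#' @export
preview_precursor <- function(library, config = dia_config(), selector) {
  hits <- which(library$precursor_id == selector |
                  library$modified_sequence == selector |
                  library$stripped_sequence == selector)
  if (length(hits) != 1L) {
    near <- library$precursor_id[
      stringr::str_detect(library$precursor_id, stringr::fixed(selector))]
    abort(sprintf("selector '%s' matches %d precursors%s", selector,
                  length(hits),
                  if (length(near)) paste0("; near matches: ",
                                           paste(head(near, 5), collapse = ", "))
                  else ""))
  }
  gradient <- gradient_model(config$run_length,
                             rt_range = range(library$rt_coord),
                             padding = config$rt_padding_frac * config$run_length)
  entry <- library |>
    map_rt(gradient) |>
    elution_profiles(peak_sigma = config$peak_sigma, peak_tau = config$peak_tau,
                     sigma_cv = config$sigma_cv, seed = config$seed + 2L) |>
    dplyr::slice(hits)
  schema <- .config_schema(config)
  events <- schedule_run(schema, config$run_length)
  sup <- profile_support(entry$apex_rt, entry$sigma, entry$tau,
                         frac = config$elution_threshold)
  in_window <- !is.na(events$mz_lower) & events$ms_level == 2L &
    events$mz_lower <= entry$precursor_mz & entry$precursor_mz < events$mz_upper
  keep <- (events$ms_level == 1L | in_window) &
    events$start_time >= sup$t_start & events$start_time <= sup$t_end
  sub_events <- events[keep, , drop = FALSE]
  species <- entry |>
    dplyr::select("precursor_id", "stripped_sequence", "charge",
                  "precursor_mz", "apex_rt", "sigma", "tau", "fragments") |>
    dplyr::mutate(abundance = entry$base_abundance)
  species$envelope <- .species_envelopes(species, config$isotope_max_peaks,
                                         config$isotope_min_fraction)
  run <- simulate_run(species, sub_events, .config_instrument(config),
                      seed = config$seed + 10001L,
                      elution_threshold = config$elution_threshold)
  ms1 <- run[run$ms_level == 1L, , drop = FALSE]
  xic <- tibble::tibble(time = ms1$start_time, intensity = ms1$tic)
  apex_ms1 <- ms1[which.min(abs(ms1$start_time - entry$apex_rt)), ]
  ms2 <- run[run$ms_level == 2L, , drop = FALSE]
  apex_ms2 <- if (nrow(ms2)) {
    ms2[which.min(abs(ms2$start_time - entry$apex_rt)), ]
  } else NULL
  ppp <- expected_points_per_peak(schema, entry$sigma, entry$tau)
  structure(
    list(run = run, xic = xic,
         ms1_spectrum = tibble::tibble(mz = apex_ms1$mz[[1]],
                                       intensity = apex_ms1$intensity[[1]]),
         ms2_spectrum = if (!is.null(apex_ms2)) {
           tibble::tibble(mz = apex_ms2$mz[[1]],
                          intensity = apex_ms2$intensity[[1]])
         },
         summary = tibble::tibble(
           precursor_id = entry$precursor_id,
           apex_rt = entry$apex_rt,
           precursor_mz = entry$precursor_mz,
           window_lower = if (any(in_window)) events$mz_lower[which(in_window)[1]]
                          else NA_real_,
           window_upper = if (any(in_window)) events$mz_upper[which(in_window)[1]]
                          else NA_real_,
           expected_ppp_ms1 = ppp$ppp[ppp$ms_level == 1L],
           expected_ppp_ms2 = ppp$ppp[ppp$ms_level == 2L])),
    class = "dia_preview"
  )
}

#' @export
print.dia_preview <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<dia_preview> %s: apex %.1f s, m/z %.4f, window [%s, %s), expected PPP %.1f (MS1) / %.1f (MS2)\n",
              s$precursor_id, s$apex_rt, s$precursor_mz,
              format(s$window_lower), format(s$window_upper),
              s$expected_ppp_ms1, s$expected_ppp_ms2))
  invisible(x)
}
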