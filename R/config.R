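# Run configuration: a flat registry of every configurable key with defaults
# and help strings; resolution order defaults < config file < direct arguments.

.config_registry_tbl <- function() {
  spec <- list(
    list("library_source", "synthetic", "precursor library source: synthetic | prosit | maxquant"),
    list("library_path", NA_character_, "path to the Prosit CSV or MaxQuant evidence table (file sources)"),
    list("library_n", 100L, "number of precursors generated by the synthetic library source"),
    list("library_seed", 1L, "seed of the synthetic library generator"),
    list("run_length", 1200, "chromatographic run length, seconds"),
    list("rt_padding_frac", 0.05, "elution-free padding at each end of the run, fraction of run length"),
    list("peak_sigma", 2.5, "EMG Gaussian peak width, seconds"),
    list("peak_tau", 0.8, "EMG exponential tail constant, seconds"),
    list("sigma_cv", 0, "CV of optional lognormal per-precursor peak-width jitter (0 = off)"),
    list("elution_threshold", 1e-3, "fraction of apex intensity below which a species is inactive in a scan"),
    list("mz_min", 400, "lower bound of the DIA window range, Th"),
    list("mz_max", 1000, "upper bound of the DIA window range, Th"),
    list("window_width", 20, "default fixed isolation window width, Th"),
    list("ms1_duration", 0.05, "MS1 scan duration, seconds"),
    list("ms2_duration", 0.02, "MS2 scan duration, seconds"),
    list("schema_path", NA_character_, "acquisition schema CSV overriding the default window scheme"),
    list("resolution", 30000, "resolving power; peak FWHM = mz / resolution"),
    list("scan_range_min", 150, "lower spectral scan range, Th"),
    list("scan_range_max", 2000, "upper spectral scan range, Th"),
    list("profile_shape", "centroid", "spectrum mode: centroid | gaussian | lorentzian | emg"),
    list("grid_step", 0.002, "profile-mode m/z grid step, Th"),
    list("ppm_systematic", 0, "systematic mass error, ppm"),
    list("ppm_sd", 0, "SD of per-peak Gaussian mass-error jitter, ppm"),
    list("spray_instability_sd", 0, "SD (fraction) of the per-scan lognormal spray-intensity factor"),
    list("abundance_to_counts", 1, "scale from abundance units to detector counts"),
    list("noise_rate", 0, "expected additive noise centroids per spectrum (0 = off)"),
    list("noise_intensity", 100, "mean intensity of additive noise centroids"),
    list("mz_tail_frac", 1, "EMG profile-shape tail constant, fraction of FWHM"),
    list("isotope_max_peaks", 5L, "isotope peaks retained per precursor envelope"),
    list("isotope_min_fraction", 1e-4, "isotope peaks below this fraction are dropped"),
    list("n_groups", 1L, "number of treatment groups (group 1 is the reference)"),
    list("n_replicates", 1L, "replicates per group"),
    list("between_group_log2_sd", 1.0, "SD of true per-group log2 fold changes"),
    list("within_group_log2_sd", 0.2, "SD of within-group per-sample log2 abundance noise"),
    list("prob_missing_group", 0, "probability a precursor is absent from an entire group"),
    list("prob_missing_sample", 0, "probability a precursor is absent from a single sample"),
    list("fragment_jitter_sd", 0, "independent per-fragment log2 intensity jitter (0 = off)"),
    list("decoy_msp_path", NA_character_, "NIST .msp library of decoy species (optional)"),
    list("seed", 1L, "master seed; every random stream derives from it")
  )
  tibble::tibble(
    key = vapply(spec, function(x) x[[1]], character(1)),
    default = lapply(spec, function(x) x[[2]]),
    help = vapply(spec, function(x) x[[3]], character(1))
  )
}

#' Configuration registry
#'
#' Every configurable key of the simulator, with its default value and a help
#' string. [dia_config()] rejects keys not listed here, and the parameter
#' yaml written with every simulation contains exactly these keys.
#'
#' @return A tibble with columns `key`, `default` (list-column), `help`.
#' @export
config_registry <- function() {
  .config_registry_tbl()
}

#' Build a run configuration
#'
#' Resolves a full configuration from the registry defaults, optionally
#' updated by a yaml config file, then by direct arguments (highest
#' precedence). Unknown keys are rejected.
#'
#' @param ... Named configuration values overriding the defaults.
#' @param config_file Optional yaml file of configuration values.
#' @return A named list of all registry keys, class `dia_config`.
#' @export
#' @examples
#' cfg <- dia_config(n_groups = 2, n_replicates = 3, window_width = 25)
#' cfg$window_width
dia_config <- function(..., config_file = NULL) {
  reg <- .config_registry_tbl()
  cfg <- setNames(reg$default, reg$key)
  apply_values <- function(cfg, values, origin) {
    if (!length(values)) return(cfg)
    unknown <- setdiff(names(values), names(cfg))
    if (length(unknown)) {
      abort(paste0("unknown configuration key(s) from ", origin, ": ",
                   paste(unknown, collapse = ", ")))
    }
    for (k in names(values)) {
      v <- values[[k]]
      d <- cfg[[k]]
      if (is.integer(d) && is.numeric(v)) v <- as.integer(v)
      cfg[[k]] <- v
    }
    cfg
  }
  if (!is.null(config_file)) {
    cfg <- apply_values(cfg, yaml::read_yaml(config_file), config_file)
  }
  cfg <- apply_values(cfg, list(...), "arguments")
  structure(cfg, class = "dia_config")
}

#' @export
print.dia_config <- function(x, ...) {
  cat("<dia_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-24s %s\n", k, if (is.na(v) || is.null(v)) "-" else format(v)))
  }
  invisible(x)
}

# sub-objects derived from a config
.config_design <- function(cfg) {
  study_design(
    n_groups = cfg$n_groups, n_replicates = cfg$n_replicates,
    between_group_log2_sd = cfg$between_group_log2_sd,
    within_group_log2_sd = cfg$within_group_log2_sd,
    prob_missing_group = cfg$prob_missing_group,
    prob_missing_sample = cfg$prob_missing_sample,
    fragment_jitter_sd = cfg$fragment_jitter_sd,
    seed = cfg$seed
  )
}

.config_instrument <- function(cfg) {
  instrument_model(
    resolution = cfg$resolution,
    scan_range = c(cfg$scan_range_min, cfg$scan_range_max),
    ppm_systematic = cfg$ppm_systematic, ppm_sd = cfg$ppm_sd,
    profile_shape = cfg$profile_shape, grid_step = cfg$grid_step,
    spray_instability_sd = cfg$spray_instability_sd,
    abundance_to_counts = cfg$abundance_to_counts,
    noise_rate = cfg$noise_rate, noise_intensity = cfg$noise_intensity,
    mz_tail_frac = cfg$mz_tail_frac
  )
}

.config_schema <- function(cfg) {
  if (!is.na(cfg$schema_path)) {
    read_schema(cfg$schema_path)
  } else {
    default_schema(cfg$mz_min, cfg$mz_max, cfg$window_width,
                   cfg$ms1_duration, cfg$ms2_duration)
  }
}

.config_library <- function(cfg) {
  switch(cfg$library_source,
    synthetic = generate_synthetic_library(cfg$library_n,
                                           seed = cfg$library_seed),
    prosit = read_prosit_library(cfg$library_path),
    maxquant = read_maxquant_evidence(cfg$library_path),
    abort(paste0("unknown library_source: ", cfg$library_source))
  )
}
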