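# DIA windowing schemes and duty-cycle scheduling.
#
# An acquisition schema is a tibble of scan-event templates (one duty cycle):
# columns ms_level (1/2), mz_lower, mz_upper (NA for MS1), duration_s.
# Isolation boundaries are half-open [lower, upper) so every m/z belongs to
# exactly one window of the default non-overlapping scheme.

.validate_schema <- function(schema) {
  .require_columns(schema, c("ms_level", "mz_lower", "mz_upper", "duration_s"),
                   "acquisition schema")
  if (!any(schema$ms_level == 1L)) {
    abort("acquisition schema must contain at least one MS1 event per cycle")
  }
  if (any(schema$duration_s <= 0)) abort("scan durations must be > 0")
  ms2 <- schema$ms_level == 2L
  bad <- ms2 & !(schema$mz_lower < schema$mz_upper)
  if (any(bad)) {
    abort(paste0("MS2 row(s) with mz_lower >= mz_upper: row ",
                 paste(which(bad), collapse = ", ")))
  }
  schema
}

#' Default fixed-width non-overlapping DIA window schema
#'
#' Builds one duty cycle: a single MS1 scan followed by contiguous fixed-width
#' MS2 isolation windows covering `[mz_min, mz_max]`; the last window is
#' truncated at `mz_max`. Adjacent windows share a boundary (no gap, no
#' overlap); containment is half-open `[lower, upper)`.
#'
#' @param mz_min,mz_max Precursor m/z range covered by the windows, Th.
#' @param window_width Isolation window width, Th.
#' @param ms1_duration,ms2_duration Scan durations in seconds; together with
#'   the window count they set the duty-cycle time and hence the points
#'   sampled per chromatographic peak.
#' @return An acquisition schema tibble with a `target_mz` midpoint column on
#'   MS2 rows.
#' @export
#' @examples
#' default_schema(400, 1000, 20)
default_schema <- function(mz_min = 400, mz_max = 1000, window_width = 20,
                           ms1_duration = 0.05, ms2_duration = 0.02) {
  if (mz_max <= mz_min) abort("mz_max must exceed mz_min")
  if (window_width <= 0) abort("window_width must be > 0")
  if (ms1_duration <= 0 || ms2_duration <= 0) abort("scan durations must be > 0")
  n_win <- ceiling((mz_max - mz_min) / window_width - 1e-9)
  lower <- mz_min + (seq_len(n_win) - 1L) * window_width
  upper <- pmin(lower + window_width, mz_max)
  schema <- tibble::tibble(
    ms_level = c(1L, rep(2L, n_win)),
    mz_lower = c(NA_real_, lower),
    mz_upper = c(NA_real_, upper),
    duration_s = c(ms1_duration, rep(ms2_duration, n_win))
  )
  schema$target_mz <- (schema$mz_lower + schema$mz_upper) / 2
  .validate_schema(schema)
}

#' Read an acquisition schema file
#'
#' Reads the 4-column schema CSV (`ms_level, mz_lower, mz_upper, duration_s`;
#' m/z fields empty on MS1 rows). Overlapping and variable-width windows are
#' accepted as-is; staggered schemes are expressed by listing the offset
#' window sets of consecutive cycles in one long schema.
#'
#' @param path Schema CSV (optionally gzipped).
#' @return An acquisition schema tibble in file row order.
#' @export
read_schema <- function(path) {
  schema <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                            col_types = readr::cols(
                              ms_level = readr::col_integer(),
                              mz_lower = readr::col_double(),
                              mz_upper = readr::col_double(),
                              duration_s = readr::col_double()))
  schema$target_mz <- (schema$mz_lower + schema$mz_upper) / 2
  .validate_schema(schema)
}

#' Duty-cycle time of a schema
#'
#' @param schema An acquisition schema tibble.
#' @return Sum of event durations, seconds.
#' @export
cycle_time <- function(schema) sum(schema$duration_s)

#' Schedule all scan events of a run
#'
#' Repeats the duty cycle from t = 0, keeping events whose scan would finish
#' within the run (`start_time + duration <= run_length`, to 1 ns tolerance).
#'
#' @param schema An acquisition schema tibble.
#' @param run_length Run length, seconds (must fit at least one full cycle).
#' @return A tibble of scan events: `scan_index`, `start_time`, `ms_level`,
#'   `mz_lower`, `mz_upper`, `target_mz`, `duration_s`.
#' @export
schedule_run <- function(schema, run_length) {
  schema <- .validate_schema(schema)
  ct <- cycle_time(schema)
  if (run_length < ct) abort("run_length shorter than one duty cycle")
  n_cycles <- ceiling(run_length / ct) + 1L
  events <- schema[rep(seq_len(nrow(schema)), n_cycles), , drop = FALSE]
  start <- cumsum(c(0, events$duration_s))[seq_len(nrow(events))]
  keep <- start + events$duration_s <= run_length + 1e-9
  events <- events[keep, , drop = FALSE]
  tibble::tibble(
    scan_index = seq_len(nrow(events)),
    start_time = start[keep],
    ms_level = events$ms_level,
    mz_lower = events$mz_lower,
    mz_upper = events$mz_upper,
    target_mz = if ("target_mz" %in% names(events)) events$target_mz
                else (events$mz_lower + events$mz_upper) / 2,
    duration_s = events$duration_s
  )
}

#' Expected points per chromatographic peak
#'
#' FWHM-based estimate of the number of spectra sampling one elution peak:
#' profile FWHM divided by the duty-cycle time. Because each MS1 scan and
#' each distinct isolation window is visited once per cycle, the estimate
#' applies to MS1 traces and to per-window MS2 traces alike; the `ms_level`
#' column distinguishes them for schemas where a window recurs within a cycle
#' (its MS2 spacing then shortens proportionally).
#'
#' @param schema An acquisition schema tibble.
#' @param sigma,tau EMG profile parameters, seconds.
#' @return A tibble with columns `ms_level` and `ppp`.
#' @export
#' @examples
#' expected_points_per_peak(default_schema(400, 1000, 20), sigma = 2.5, tau = 0.8)
expected_points_per_peak <- function(schema, sigma, tau = 0) {
  ct <- cycle_time(schema)
  fwhm <- with(profile_support(0, sigma, tau, frac = 0.5), t_end - t_start)
  ms2 <- schema[schema$ms_level == 2L, , drop = FALSE]
  # per-window visits per cycle (max over windows; 1 for all standard schemas)
  visits <- if (nrow(ms2)) max(table(paste(ms2$mz_lower, ms2$mz_upper))) else NA
  tibble::tibble(
    ms_level = c(1L, 2L),
    ppp = c(sum(schema$ms_level == 1L) * fwhm / ct,
            if (nrow(ms2)) visits * fwhm / ct else NA_real_)
  )
}
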