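# Naive MS1 XIC quantification of simulated runs and fold-change recovery
# metrics: an in-package benchmark of quantitative accuracy against the
# ground truth, mirroring the scan-speed / points-per-peak analysis that a
# DIA search engine would otherwise provide.

#' Extract MS1 ion chromatograms and integrate them
#'
#' For every ground-truth species, sums MS1 intensity within `ppm_tol` of the
#' monoisotopic m/z in each MS1 spectrum, integrates the trace with the
#' median inter-scan spacing (Riemann sum) and counts the points per peak
#' (scans above half the maximum trace point).
#'
#' Extraction is targeted: when the truth carries an `apex_rt` column, only
#' scans within `rt_half_window` seconds of the species' apex are integrated,
#' as a targeted quantifier anchored on library retention times would do;
#' without gating, a same-m/z species eluting anywhere else in the run would
#' contaminate the area.
#'
#' @param run A `dia_run` (from [simulate_run()] or [read_mzml()]).
#' @param truth Ground-truth tibble (needs `precursor_id`, `precursor_mz`;
#'   `apex_rt` enables retention-time gating).
#' @param ppm_tol Extraction tolerance, ppm (> 0).
#' @param rt_half_window Half-width of the retention-time gate, seconds
#'   (default 30, about four FWHM at the default peak width; `Inf` disables
#'   gating).
#' @return Tibble: `precursor_id`, `area` (intensity x seconds),
#'   `points_per_peak`, `apex_intensity`.
#' @export
extract_xic <- function(run, truth, ppm_tol = 10, rt_half_window = 30) {
  stopifnot(ppm_tol > 0, rt_half_window > 0)
  gate <- is.finite(rt_half_window) && "apex_rt" %in% names(truth)
  ms1 <- run[run$ms_level == 1L, , drop = FALSE]
  n_scan <- nrow(ms1)
  spacing <- if (n_scan > 1) median(diff(ms1$start_time)) else NA_real_
  lens <- lengths(ms1$mz)
  scan_of <- rep.int(seq_len(n_scan), lens)
  all_mz <- unlist(ms1$mz, use.names = FALSE)
  all_int <- unlist(ms1$intensity, use.names = FALSE)
  ord <- order(all_mz)
  all_mz <- all_mz[ord]; all_int <- all_int[ord]; scan_of <- scan_of[ord]
  res <- purrr::map(seq_len(nrow(truth)), function(i) {
    pmz <- truth$precursor_mz[i]
    lo <- pmz * (1 - ppm_tol / 1e6)
    hi <- pmz * (1 + ppm_tol / 1e6)
    i0 <- findInterval(lo, all_mz, left.open = TRUE) + 1L
    i1 <- findInterval(hi, all_mz)
    if (i1 < i0) {
      return(c(area = 0, points_per_peak = 0, apex_intensity = 0))
    }
    sel <- i0:i1
    if (gate) {
      t_scan <- ms1$start_time[scan_of[sel]]
      sel <- sel[abs(t_scan - truth$apex_rt[i]) <= rt_half_window]
      if (!length(sel)) {
        return(c(area = 0, points_per_peak = 0, apex_intensity = 0))
      }
    }
    xic <- rowsum(all_int[sel], scan_of[sel], reorder = FALSE)[, 1]
    apex <- max(xic)
    c(area = sum(xic) * spacing,
      points_per_peak = sum(xic > apex / 2),
      apex_intensity = apex)
  })
  m <- do.call(rbind, res)
  tibble::tibble(precursor_id = truth$precursor_id,
                 area = m[, "area"],
                 points_per_peak = m[, "points_per_peak"],
                 apex_intensity = m[, "apex_intensity"])
}

# infer group/replicate structure from ground-truth abundance columns
.truth_samples <- function(truth) {
  cols <- grep("^abundance_group\\d+_rep\\d+$", names(truth), value = TRUE)
  if (!length(cols)) abort("ground truth carries no per-sample abundance columns")
  tibble::tibble(
    column = cols,
    sample = sub("^abundance_", "", cols),
    group = as.integer(sub("^abundance_group(\\d+)_rep\\d+$", "\\1", cols)),
    replicate = as.integer(sub("^abundance_group\\d+_rep(\\d+)$", "\\1", cols))
  )
}

#' Fold-change recovery against the ground truth
#'
#' Compares estimated log2 fold changes (from integrated MS1 XIC areas) with
#' the true simulated values. Following standard practice for benchmarking
#' quantification, only precursors with no missing values across all samples
#' enter; decoys are excluded. The estimated fold change of each non-reference
#' group is `log2(mean area in group g / mean area in group 1)`; the reported
#' r^2 is the squared Pearson correlation of estimated vs true values,
#' restricted to true fold changes within [-5, 5] for reporting parity with
#' the usual scatter range.
#'
#' @param xics Long tibble of per-sample XIC results: columns of
#'   [extract_xic()] plus a `sample` column (`group{g}_rep{r}`).
#' @param truth Ground-truth tibble.
#' @return An `fc_recovery` object: list with `precursors` (per precursor and
#'   group: `true_log2_fc`, `estimated_log2_fc`), `r2`, `avg_ppp`, `n_used`,
#'   `unreliable` flag.
#' @export
fold_change_recovery <- function(xics, truth) {
  smp <- .truth_samples(truth)
  if (max(smp$group) < 2L) abort("fold-change recovery needs >= 2 groups")
  keep <- truth$source != "decoy"
  complete <- rowSums(is.na(as.matrix(truth[, smp$column]))) == 0
  usable <- truth$precursor_id[keep & complete]

  wide <- xics |>
    dplyr::filter(.data$precursor_id %in% usable, .data$area > 0) |>
    dplyr::inner_join(smp[, c("sample", "group")], by = "sample")
  group_means <- wide |>
    dplyr::group_by(.data$precursor_id, .data$group) |>
    dplyr::summarise(mean_area = mean(.data$area),
                     n = dplyr::n(), .groups = "drop")
  n_rep <- max(smp$replicate)
  full <- group_means |>
    dplyr::group_by(.data$precursor_id) |>
    dplyr::filter(dplyr::n() == max(smp$group), all(.data$n == n_rep)) |>
    dplyr::ungroup()
  ref <- full |>
    dplyr::filter(.data$group == 1L) |>
    dplyr::select("precursor_id", ref_area = "mean_area")
  est <- full |>
    dplyr::filter(.data$group > 1L) |>
    dplyr::inner_join(ref, by = "precursor_id") |>
    dplyr::mutate(estimated_log2_fc = log2(.data$mean_area / .data$ref_area))

  fc_cols <- grep("^log2_fc_group\\d+$", names(truth), value = TRUE)
  true_fc <- truth[, c("precursor_id", fc_cols)] |>
    tidyr::pivot_longer(dplyr::all_of(fc_cols), names_to = "group",
                        values_to = "true_log2_fc") |>
    dplyr::mutate(group = as.integer(sub("log2_fc_group", "", .data$group))) |>
    dplyr::filter(.data$group > 1L)
  precursors <- est |>
    dplyr::inner_join(true_fc, by = c("precursor_id", "group")) |>
    dplyr::select("precursor_id", "group", "true_log2_fc",
                  "estimated_log2_fc")

  in_range <- abs(precursors$true_log2_fc) <= 5
  sub <- precursors[in_range, , drop = FALSE]
  r2 <- if (nrow(sub) >= 3) cor(sub$true_log2_fc, sub$estimated_log2_fc)^2
        else NA_real_
  avg_ppp <- xics |>
    dplyr::filter(.data$precursor_id %in% precursors$precursor_id) |>
    dplyr::pull(.data$points_per_peak) |>
    mean()
  structure(
    list(precursors = precursors, r2 = r2, avg_ppp = avg_ppp,
         n_used = nrow(sub), unreliable = nrow(sub) < 3),
    class = "fc_recovery"
  )
}

#' @export
print.fc_recovery <- function(x, ...) {
  cat(sprintf("<fc_recovery> %d precursor-group estimate(s); r2 = %.4f; avg PPP = %.1f%s\n",
              x$n_used, x$r2, x$avg_ppp,
              if (x$unreliable) " [UNRELIABLE: < 3 usable precursors]" else ""))
  invisible(x)
}

#' @describeIn fold_change_recovery Per-precursor tidy table of true and
#'   estimated log2 fold changes.
#' @param x An `fc_recovery` object.
#' @param ... Unused.
#' @export
tidy.fc_recovery <- function(x, ...) {
  x$precursors
}

#' @describeIn fold_change_recovery One-row summary: `r2`, `avg_ppp`,
#'   `n_used`, `unreliable`.
#' @export
glance.fc_recovery <- function(x, ...) {
  tibble::tibble(r2 = x$r2, avg_ppp = x$avg_ppp, n_used = x$n_used,
                 unreliable = x$unreliable)
}

#' Quantify and score a written simulation
#'
#' Reads a simulation output directory (mzML files + ground truth), extracts
#' per-sample MS1 XICs and computes the fold-change recovery report. The
#' mzML sample set must match the ground truth's sample columns.
#'
#' @param dir Directory written by [write_simulation()].
#' @param ppm_tol XIC extraction tolerance, ppm.
#' @return List with `xics` (long tibble) and `recovery` (`fc_recovery`), or
#'   only `xics` for single-group designs.
#' @export
validate_simulation <- function(dir, ppm_tol = 10) {
  truth_path <- file.path(dir, "ground_truth.tsv")
  if (!file.exists(truth_path)) {
    abort(paste0("no ground_truth.tsv in ", dir))
  }
  truth <- read_ground_truth(truth_path)
  smp <- .truth_samples(truth)
  mzml_files <- list.files(dir, pattern = "\\.mzML$", full.names = TRUE)
  found <- sub("\\.mzML$", "", basename(mzml_files))
  if (!setequal(found, smp$sample)) {
    abort(sprintf("mzML sample set {%s} does not match ground truth {%s}",
                  paste(sort(found), collapse = ", "),
                  paste(sort(smp$sample), collapse = ", ")))
  }
  xics <- purrr::map2(mzml_files, found, function(f, s) {
    run <- read_mzml(f)
    dplyr::mutate(extract_xic(run, truth, ppm_tol = ppm_tol), sample = s)
  }) |> dplyr::bind_rows()
  if (max(smp$group) >= 2L) {
    list(xics = xics, recovery = fold_change_recovery(xics, truth))
  } else {
    list(xics = xics)
  }
}
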