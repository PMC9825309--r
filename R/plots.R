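# ggplot2 visualizations for runs, previews and recovery reports.

#' Plot one spectrum of a run
#'
#' @param run A `dia_run`.
#' @param scan_index Scan to plot.
#' @return A ggplot: peak list drawn as sticks (centroid) or a line (profile).
#' @export
plot_spectrum <- function(run, scan_index) {
  row <- run[run$scan_index == scan_index, , drop = FALSE]
  if (!nrow(row)) abort(paste0("no scan with index ", scan_index))
  df <- tibble::tibble(mz = row$mz[[1]], intensity = row$intensity[[1]])
  instrument <- attr(run, "instrument")
  centroid <- is.null(instrument) || instrument$profile_shape == "centroid"
  lab <- sprintf("MS%d @ %.1f s%s", row$ms_level, row$start_time,
                 if (row$ms_level == 2L) {
                   sprintf(" [%.1f-%.1f)", row$mz_lower, row$mz_upper)
                 } else "")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, y = .data$intensity))
  p <- if (centroid) {
    p + ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0))
  } else {
    p + ggplot2::geom_line()
  }
  p + ggplot2::labs(x = "m/z (Th)", y = "intensity", title = lab) +
    ggplot2::theme_minimal()
}

#' Plot an extracted ion chromatogram
#'
#' @param run A `dia_run`.
#' @param mz Target m/z, Th.
#' @param ppm_tol Extraction tolerance, ppm.
#' @return A ggplot of the MS1 trace at `mz`.
#' @export
plot_xic <- function(run, mz, ppm_tol = 10) {
  ms1 <- run[run$ms_level == 1L, , drop = FALSE]
  lo <- mz * (1 - ppm_tol / 1e6)
  hi <- mz * (1 + ppm_tol / 1e6)
  trace <- purrr::map2_dbl(ms1$mz, ms1$intensity, function(m, i) {
    sum(i[m >= lo & m <= hi])
  })
  ggplot2::ggplot(tibble::tibble(time = ms1$start_time, intensity = trace),
                  ggplot2::aes(x = .data$time, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "retention time (s)", y = "intensity",
                  title = sprintf("XIC %.4f Th (+/- %g ppm)", mz, ppm_tol)) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_spectrum Total ion chromatogram of a run, by MS level.
#' @param object A `dia_run`.
#' @param ... Unused.
#' @export
autoplot.dia_run <- function(object, ...) {
  df <- tibble::tibble(time = object$start_time,
                       tic = object$tic,
                       ms_level = factor(paste0("MS", object$ms_level)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$tic)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ms_level, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "retention time (s)", y = "total ion current") +
    ggplot2::theme_minimal()
}

#' @describeIn preview_precursor XIC plus apex MS1/MS2 spectra of the
#'   previewed precursor.
#' @param object A `dia_preview`.
#' @param ... Unused.
#' @export
autoplot.dia_preview <- function(object, ...) {
  stick <- function(df, title) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
      ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0)) +
      ggplot2::labs(x = "m/z (Th)", y = "intensity", title = title) +
      ggplot2::theme_minimal()
  }
  p_xic <- ggplot2::ggplot(object$xic,
                           ggplot2::aes(x = .data$time, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$summary$apex_rt,
                        linetype = "dashed") +
    ggplot2::labs(x = "retention time (s)", y = "intensity",
                  title = paste0("MS1 XIC: ", object$summary$precursor_id)) +
    ggplot2::theme_minimal()
  plots <- list(xic = p_xic, ms1 = stick(object$ms1_spectrum, "MS1 at apex"))
  if (!is.null(object$ms2_spectrum)) {
    plots$ms2 <- stick(object$ms2_spectrum, "MS2 at apex")
  }
  plots
}

#' @describeIn fold_change_recovery Estimated vs true log2 fold-change
#'   scatter (restricted to [-5, 5]) annotated with r^2 and average PPP.
#' @param object An `fc_recovery` object.
#' @export
autoplot.fc_recovery <- function(object, ...) {
  df <- object$precursors
  df <- df[abs(df$true_log2_fc) <= 5 & abs(df$estimated_log2_fc) <= 5, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true_log2_fc,
                                   y = .data$estimated_log2_fc)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "red") +
    ggplot2::coord_cartesian(xlim = c(-5, 5), ylim = c(-5, 5)) +
    ggplot2::labs(
      x = "true log2 fold change", y = "estimated log2 fold change",
      title = sprintf("r² = %.3f, avg PPP = %.1f",
                      object$r2, object$avg_ppp)) +
    ggplot2::theme_minimal()
}
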