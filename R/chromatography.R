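# Gradient mapping and exponentially modified Gaussian (EMG) elution profiles.

#' Gradient model
#'
#' Describes the simulated LC gradient: the run length, the retention
#' coordinate window of the input library (iRT units for predicted libraries,
#' minutes for observed retention times) and a dead band at the start and end
#' of the run inside which no peptide apex is placed, so elution profiles are
#' not truncated by the run boundaries.
#'
#' @param run_length Run length in seconds.
#' @param rt_range Length-2 numeric: the library retention-coordinate window
#'   mapped onto the gradient (usually `range()` of the library column).
#' @param padding Seconds of elution-free padding at each end of the run
#'   (default 5% of `run_length`).
#' @return A `gradient_model` object.
#' @export
#' @examples
#' gradient_model(600, rt_range = c(0, 100))
gradient_model <- function(run_length, rt_range, padding = 0.05 * run_length) {
  stopifnot(run_length > 0, length(rt_range) == 2L, rt_range[2] > rt_range[1])
  if (run_length <= 2 * padding) abort("run_length must exceed 2 * padding")
  structure(
    list(run_length = run_length,
         rt_min = rt_range[1], rt_max = rt_range[2],
         padding = padding),
    class = "gradient_model"
  )
}

#' @export
print.gradient_model <- function(x, ...) {
  cat(sprintf("<gradient_model> run %g s, padding %g s, library window [%g, %g]\n",
              x$run_length, x$padding, x$rt_min, x$rt_max))
  invisible(x)
}

#' Map library retention coordinates onto the gradient
#'
#' Affine, order-preserving map of the library retention coordinate (`rt_coord`,
#' iRT or observed minutes) onto `[padding, run_length - padding]` seconds.
#' Coordinates outside the gradient's library window are clamped with a
#' warning.
#'
#' @param library A precursor library tibble carrying an `rt_coord` column
#'   (see [generate_synthetic_library()], [read_prosit_library()]).
#' @param gradient A [gradient_model()].
#' @return The library with an `apex_rt` column (seconds) added.
#' @export
map_rt <- function(library, gradient) {
  stopifnot(inherits(gradient, "gradient_model"), "rt_coord" %in% names(library))
  coord <- library$rt_coord
  out_of_window <- coord < gradient$rt_min | coord > gradient$rt_max
  if (any(out_of_window, na.rm = TRUE)) {
    warn(sprintf("%d retention coordinate(s) outside the gradient window; clamped",
                 sum(out_of_window, na.rm = TRUE)))
    coord <- pmin(pmax(coord, gradient$rt_min), gradient$rt_max)
  }
  usable <- gradient$run_length - 2 * gradient$padding
  rel <- (coord - gradient$rt_min) / (gradient$rt_max - gradient$rt_min)
  dplyr::mutate(library, apex_rt = gradient$padding + rel * usable)
}

#' EMG elution intensity
#'
#' Density of the exponentially modified Gaussian at time `t`, scaled by
#' `area` so the full profile integrates to `area`. Evaluated through the
#' log-scale complementary-error formulation (via `pnorm(log.p = TRUE)`), which
#' is stable where the textbook formula overflows (`sigma/tau` large). For
#' `tau` below `1e-4 * sigma` the Gaussian limit is used.
#'
#' All arguments are vectorized and recycled.
#'
#' @param t Time, seconds.
#' @param apex_rt Gaussian center `mu` of the EMG, seconds. (The profile mode
#'   shifts slightly right of `mu` for `tau > 0`; the profile mean is
#'   `mu + tau`.)
#' @param sigma Gaussian width, seconds (> 0).
#' @param tau Exponential tail constant, seconds (>= 0).
#' @param area Total profile area (default 1).
#' @return Intensity values (0 where negligible).
#' @export
#' @examples
#' emg_intensity(0:10, apex_rt = 5, sigma = 1, tau = 0.5)
emg_intensity <- function(t, apex_rt, sigma, tau, area = 1) {
  lens <- c(length(t), length(apex_rt), length(sigma), length(tau), length(area))
  if (any(lens == 0L)) return(numeric(0))
  n <- max(lens)
  t <- rep_len(t, n); mu <- rep_len(apex_rt, n)
  sigma <- rep_len(sigma, n); tau <- rep_len(tau, n); area <- rep_len(area, n)
  stopifnot(all(sigma > 0), all(tau >= 0))
  out <- numeric(n)
  gaussian <- tau < 1e-4 * sigma
  if (any(gaussian)) {
    g <- gaussian
    out[g] <- area[g] * dnorm(t[g], mu[g], sigma[g])
  }
  if (any(!gaussian)) {
    e <- !gaussian
    z <- (sigma[e] / tau[e] - (t[e] - mu[e]) / sigma[e]) / sqrt(2)
    # log f = -log(2 tau) + sigma^2/(2 tau^2) - (t-mu)/tau + log erfc(z)
    log_erfc <- log(2) + pnorm(-sqrt(2) * z, log.p = TRUE)
    log_f <- -log(2 * tau[e]) + sigma[e]^2 / (2 * tau[e]^2) -
      (t[e] - mu[e]) / tau[e] + log_erfc
    val <- exp(log_f)
    val[!is.finite(val) | log_f < -700] <- 0
    out[e] <- area[e] * val
  }
  out
}

# apex (mode) time and intensity of one EMG profile
.emg_apex <- function(apex_rt, sigma, tau, area = 1) {
  if (tau < 1e-4 * sigma) {
    return(list(t = apex_rt, intensity = area / (sigma * sqrt(2 * pi))))
  }
  opt <- optimize(function(t) emg_intensity(t, apex_rt, sigma, tau, area),
                  interval = c(apex_rt - sigma, apex_rt + tau + 2 * sigma),
                  maximum = TRUE, tol = 1e-10)
  list(t = opt$maximum, intensity = opt$objective)
}

#' Time interval over which a profile exceeds a fraction of its apex
#'
#' Returns the smallest interval outside which the elution intensity is below
#' `frac` times the apex intensity. For the Gaussian limit the interval is the
#' closed form `mu +/- sigma * sqrt(2 log(1/frac))`; with tailing (`tau > 0`)
#' it is found by root bracketing and is asymmetric (longer after the apex).
#'
#' @inheritParams emg_intensity
#' @param frac Fraction of apex intensity, in (0, 1). `frac = 0.5` gives the
#'   FWHM interval.
#' @return A tibble with columns `t_start`, `t_end` (one row per profile).
#' @export
profile_support <- function(apex_rt, sigma, tau, frac = 0.5) {
  stopifnot(all(frac > 0), all(frac < 1))
  n <- max(length(apex_rt), length(sigma), length(tau), length(frac))
  apex_rt <- rep_len(apex_rt, n); sigma <- rep_len(sigma, n)
  tau <- rep_len(tau, n); frac <- rep_len(frac, n)
  one <- function(mu, s, tu, fr) {
    if (tu < 1e-4 * s) {
      half <- s * sqrt(2 * log(1 / fr))
      return(c(mu - half, mu + half))
    }
    apex <- .emg_apex(mu, s, tu)
    target <- fr * apex$intensity
    f <- function(t) emg_intensity(t, mu, s, tu) - target
    lo <- mu - s * (sqrt(2 * log(1 / fr)) + 2)
    while (f(lo) > 0) lo <- lo - 2 * s
    hi <- apex$t + s * sqrt(2 * log(1 / fr)) + tu * log(1 / fr) + 2 * s + tu
    while (f(hi) > 0) hi <- hi + 2 * (s + tu)
    c(uniroot(f, c(lo, apex$t), tol = 1e-9)$root,
      uniroot(f, c(apex$t, hi), tol = 1e-9)$root)
  }
  res <- mapply(one, apex_rt, sigma, tau, frac)
  tibble::tibble(t_start = res[1, ], t_end = res[2, ])
}

#' Assign per-precursor elution profiles
#'
#' Gives every library entry an EMG width and tail. The default is a global
#' `peak_sigma`/`peak_tau`; a lognormal per-precursor width jitter with
#' coefficient of variation `sigma_cv` can be enabled (seeded).
#'
#' @param library Library tibble with an `apex_rt` column (from [map_rt()]).
#' @param peak_sigma Gaussian peak width, seconds.
#' @param peak_tau Exponential tail constant, seconds.
#' @param sigma_cv Coefficient of variation of optional per-precursor lognormal
#'   width jitter (0 disables, the default).
#' @param seed Integer seed for the width jitter.
#' @return The library with `sigma` and `tau` columns added.
#' @export
elution_profiles <- function(library, peak_sigma, peak_tau, sigma_cv = 0,
                             seed = 1L) {
  stopifnot("apex_rt" %in% names(library), peak_sigma > 0, peak_tau >= 0)
  n <- nrow(library)
  sigma <- rep(peak_sigma, n)
  if (sigma_cv > 0) {
    sdlog <- sqrt(log(1 + sigma_cv^2))
    set.seed(seed)
    sigma <- sigma * rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  dplyr::mutate(library, sigma = sigma, tau = peak_tau)
}
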