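#' Names of the 19 thermogram metrics, in reporting order
#'
#' @return Character vector of the 19 metric column names used throughout
#'   the package: three peak amplitudes and temperatures, three peak ratios,
#'   the Peak 1-Peak 2 valley and its temperature, three valley ratios, the
#'   global maximum and its temperature, the first-moment temperature, width
#'   at half height, and area.
#' @export
tlb_metric_names <- function() {
  c("peak1", "peak2", "peak3", "t_peak1", "t_peak2", "t_peak3",
    "r_p1p2", "r_p1p3", "r_p2p3", "v12", "t_v12",
    "r_v12p1", "r_v12p2", "r_v12p3",
    "max_amp", "t_max", "t_fm", "width", "area")
}

#' Locate a peak within a temperature window
#'
#' Returns the maximum excess heat capacity over grid points with
#' `window[1] <= T < window[2]` (half-open, so adjacent windows never share a
#' point) and the temperature at which it occurs. Ties are broken toward the
#' lowest temperature.
#'
#' @param tg A `tlb_thermogram`.
#' @param window `c(low, high)` in degrees C, inside 45-90.
#' @return Named list with `amplitude` and `temperature`.
#' @export
find_peak <- function(tg, window) {
  idx <- which(tg$temperature >= window[[1]] - 1e-9 &
                 tg$temperature < window[[2]] - 1e-9)
  if (length(idx) == 0) abort("peak window contains no grid points")
  i <- idx[[which.max(tg$cp_excess[idx])]]
  list(amplitude = tg$cp_excess[[i]], temperature = tg$temperature[[i]])
}

#' Locate the valley between two peaks
#'
#' Minimum excess heat capacity over grid points strictly between `t_left`
#' and `t_right`; ties break toward the lowest temperature.
#'
#' @param tg A `tlb_thermogram`.
#' @param t_left,t_right Bracketing temperatures (typically the detected
#'   Peak 1 and Peak 2 positions), `t_left < t_right`.
#' @return Named list with `amplitude` and `temperature`.
#' @export
find_valley <- function(tg, t_left, t_right) {
  if (t_left >= t_right) abort("t_left must be below t_right")
  idx <- which(tg$temperature > t_left + 1e-9 &
                 tg$temperature < t_right - 1e-9)
  if (length(idx) == 0) abort("no grid points strictly between the peaks")
  i <- idx[[which.min(tg$cp_excess[idx])]]
  list(amplitude = tg$cp_excess[[i]], temperature = tg$temperature[[i]])
}

#' Whole-profile metrics: maximum, first moment, width, area
#'
#' `max_amp`/`t_max` are taken over the full 45-90 grid (ties toward the
#' lowest temperature). `t_fm` is the amplitude-weighted mean temperature
#' (discrete first moment of the normalized profile); if the total signal is
#' not positive it is undefined and returned as `NaN` with a warning. `area`
#' is the trapezoidal integral over 45-90. `width` is the span between the
#' first upward and last downward crossing of half the global maximum, each
#' located by linear interpolation; if the profile never drops below half
#' height on one side the width is truncated at the grid boundary with a
#' warning.
#'
#' @param tg A `tlb_thermogram`.
#' @return Named list with `max_amp`, `t_max`, `t_fm`, `width`, `area`.
#' @export
global_metrics <- function(tg) {
  tt <- tg$temperature
  cp <- tg$cp_excess
  imax <- which.max(cp)
  max_amp <- cp[[imax]]
  t_max <- tt[[imax]]

  total <- sum(cp)
  t_fm <- if (total > 0) sum(tt * cp) / total else {
    warn("total signal is not positive; t_fm is undefined")
    NaN
  }

  h <- diff(tt)
  area <- sum((cp[-1] + cp[-length(cp)]) / 2 * h)

  half <- max_amp / 2
  above <- cp >= half
  if (!any(above)) {  # only possible when the whole profile is negative
    warn("profile maximum is negative; width is undefined")
    return(list(max_amp = max_amp, t_max = t_max, t_fm = t_fm,
                width = NaN, area = area))
  }
  lo_i <- which(above)[[1]]
  hi_i <- which(above)[[length(which(above))]]
  t_lo <- if (lo_i == 1L) {
    warn("profile does not drop below half height before t_max; width truncated at 45")
    tt[[1]]
  } else {
    approx(cp[c(lo_i - 1L, lo_i)], tt[c(lo_i - 1L, lo_i)], xout = half)$y
  }
  t_hi <- if (hi_i == length(cp)) {
    warn("profile does not drop below half height after t_max; width truncated at 90")
    tt[[length(tt)]]
  } else {
    approx(cp[c(hi_i, hi_i + 1L)], tt[c(hi_i, hi_i + 1L)], xout = half)$y
  }
  list(max_amp = max_amp, t_max = t_max, t_fm = t_fm,
       width = t_hi - t_lo, area = area)
}

safe_ratio <- function(num, den) {
  if (!is.finite(den) || den == 0) {
    warn("ratio denominator is zero; ratio undefined")
    return(NaN)
  }
  num / den
}

#' Compute the full 19-metric panel for one thermogram
#'
#' Peaks are located in the three standard windows, the valley between the
#' detected Peak 1 and Peak 2 positions, six amplitude ratios by division
#' (undefined ratios with a zero denominator are returned as `NaN`), and the
#' whole-profile metrics via [global_metrics()].
#'
#' @param tg A `tlb_thermogram`.
#' @param windows Peak windows, as from [tlb_windows()].
#' @return A one-row tibble with the 19 columns of [tlb_metric_names()]
#'   (plus `sample_id` if the thermogram carries one).
#' @export
compute_panel <- function(tg, windows = tlb_windows()) {
  p1 <- find_peak(tg, windows$peak1)
  p2 <- find_peak(tg, windows$peak2)
  p3 <- find_peak(tg, windows$peak3)
  v <- find_valley(tg, p1$temperature, p2$temperature)
  g <- global_metrics(tg)
  out <- tibble(
    peak1 = p1$amplitude, peak2 = p2$amplitude, peak3 = p3$amplitude,
    t_peak1 = p1$temperature, t_peak2 = p2$temperature,
    t_peak3 = p3$temperature,
    r_p1p2 = safe_ratio(p1$amplitude, p2$amplitude),
    r_p1p3 = safe_ratio(p1$amplitude, p3$amplitude),
    r_p2p3 = safe_ratio(p2$amplitude, p3$amplitude),
    v12 = v$amplitude, t_v12 = v$temperature,
    r_v12p1 = safe_ratio(v$amplitude, p1$amplitude),
    r_v12p2 = safe_ratio(v$amplitude, p2$amplitude),
    r_v12p3 = safe_ratio(v$amplitude, p3$amplitude),
    max_amp = g$max_amp, t_max = g$t_max, t_fm = g$t_fm,
    width = g$width, area = g$area
  )
  sid <- attr(tg, "sample_id")
  if (!is.null(sid)) out <- dplyr::bind_cols(tibble(sample_id = sid), out)
  out
}

#' Compute metric panels for every sample of a cohort
#'
#' @param cohort A `tlb_cohort` (as from [simulate_cohort()]) or any tibble
#'   with a `thermogram` list-column; censored samples are skipped.
#' @param windows Peak windows, as from [tlb_windows()].
#' @return A tibble with one row per non-censored sample: the manifest
#'   columns plus the 19 metrics.
#' @export
compute_panels <- function(cohort, windows = tlb_windows()) {
  stopifnot(is.data.frame(cohort), "thermogram" %in% names(cohort))
  manifest <- dplyr::select(as_tibble(cohort), -"thermogram")
  if ("censored" %in% names(manifest)) {
    keep <- !cohort$censored
  } else {
    keep <- rep(TRUE, nrow(cohort))
  }
  panels <- purrr::map(cohort$thermogram[keep], function(tg) {
    p <- compute_panel(tg, windows)
    dplyr::select(p, -dplyr::any_of("sample_id"))
  })
  dplyr::bind_cols(manifest[keep, , drop = FALSE], dplyr::bind_rows(panels))
}
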