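# Independent brute-force oracles for the 19 thermogram metrics, evaluated
# on a densely oversampled analytic three-Gaussian curve. Deliberately
# shares no code with the package: plain vector arithmetic only.

gauss_mix_fun <- function(centers, sigmas, amps) {
  force(centers); force(sigmas); force(amps)
  function(tt) {
    y <- numeric(length(tt))
    for (i in seq_along(centers)) {
      y <- y + amps[i] * exp(-((tt - centers[i])^2) / (2 * sigmas[i]^2))
    }
    y
  }
}

oracle_panel <- function(f, step = 0.001) {
  tt <- seq(45, 90, by = step)
  y <- f(tt)
  argmax_in <- function(lo, hi, open_hi = TRUE) {
    i <- which(tt >= lo & (if (open_hi) tt < hi else tt <= hi))
    j <- i[which.max(y[i])]
    c(amp = y[j], t = tt[j])
  }
  p1 <- argmax_in(60, 66)
  p2 <- argmax_in(67, 73)
  p3 <- argmax_in(73, 81)
  vi <- which(tt > p1[["t"]] & tt < p2[["t"]])
  vj <- vi[which.min(y[vi])]
  jmax <- which.max(y)
  half <- y[jmax] / 2
  above <- which(y >= half)
  lo_i <- above[1]
  hi_i <- above[length(above)]
  interp_t <- function(i1, i2) {
    tt[i1] + (half - y[i1]) * (tt[i2] - tt[i1]) / (y[i2] - y[i1])
  }
  t_lo <- if (lo_i == 1) tt[1] else interp_t(lo_i - 1, lo_i)
  t_hi <- if (hi_i == length(y)) tt[length(tt)] else interp_t(hi_i + 1, hi_i)
  c(peak1 = p1[["amp"]], peak2 = p2[["amp"]], peak3 = p3[["amp"]],
    t_peak1 = p1[["t"]], t_peak2 = p2[["t"]], t_peak3 = p3[["t"]],
    r_p1p2 = p1[["amp"]] / p2[["amp"]],
    r_p1p3 = p1[["amp"]] / p3[["amp"]],
    r_p2p3 = p2[["amp"]] / p3[["amp"]],
    v12 = y[vj], t_v12 = tt[vj],
    r_v12p1 = y[vj] / p1[["amp"]],
    r_v12p2 = y[vj] / p2[["amp"]],
    r_v12p3 = y[vj] / p3[["amp"]],
    max_amp = y[jmax], t_max = tt[jmax],
    t_fm = sum(tt * y) / sum(y),
    width = t_hi - t_lo,
    area = sum((y[-1] + y[-length(y)]) / 2 * diff(tt)))
}

# Random three-Gaussian profile parameters with one component per standard
# peak window; amplitudes and widths keep the major/smaller/shoulder
# morphology of plasma curves, with enough separation that the Peak 1 and
# Peak 2 window maxima are interior local maxima (so a genuine valley exists
# between them).
random_profile_params <- function() {
  list(centers = c(runif(1, 62.0, 64.0), runif(1, 68.8, 70.8),
                   runif(1, 74.5, 79.0)),
       sigmas = c(runif(1, 1.2, 1.6), runif(1, 1.2, 1.6),
                  runif(1, 1.2, 2.0)),
       amps = c(runif(1, 0.18, 0.35), runif(1, 0.10, 0.20),
                runif(1, 0.04, 0.12)))
}

# Parameters for the shift-equivariance property: components dominant and
# well separated so that each window's maximum is an interior local maximum
# both before and after a +/- 0.5 degree rigid shift (otherwise a
# neighbouring tail can pin the window maximum to the window edge and the
# peak position no longer moves with the curve).
random_shift_params <- function() {
  list(centers = c(runif(1, 62.8, 63.4), runif(1, 69.3, 70.2),
                   runif(1, 76.0, 77.5)),
       sigmas = c(runif(1, 1.2, 1.6), runif(1, 1.2, 1.4),
                  runif(1, 1.2, 1.6)),
       amps = c(runif(1, 0.25, 0.35), runif(1, 0.12, 0.18),
                runif(1, 0.06, 0.10)))
}

analytic_thermogram <- function(f, sample_id = "analytic") {
  new_thermogram(f(tlb_grid()), sample_id = sample_id)
}

# Absolute-difference comparison of a computed panel against the oracle.
# Positions can differ by up to one grid step (the coarse argmax may land on
# the neighbouring grid point of the fine one); amplitudes and area by a
# small relative interpolation error; ratios compound two amplitude errors.
expect_panel_matches_oracle <- function(got, want, context = "") {
  lt <- function(m, tol) {
    testthat::expect_lt(abs(got[[m]] - want[[m]]), tol,
                        label = paste0(m, " ", context, " |got-want|"))
  }
  for (m in c("t_peak1", "t_peak2", "t_peak3", "t_v12", "t_max")) lt(m, 0.101)
  for (m in c("t_fm", "width")) lt(m, 0.05)
  for (m in c("peak1", "peak2", "peak3", "max_amp", "area")) {
    lt(m, 5e-3 * abs(want[[m]]) + 1e-9)
  }
  # the valley can sit arbitrarily close to zero, where a relative bound is
  # ill-posed; the absolute floor is the curvature bound max|f''| step^2 / 8
  lt("v12", 5e-3 * abs(want[["v12"]]) + 5e-4)
  for (m in c("r_p1p2", "r_p1p3", "r_p2p3")) {
    lt(m, 1e-2 * abs(want[[m]]) + 1e-9)
  }
  for (m in c("r_v12p1", "r_v12p2", "r_v12p3")) {
    lt(m, 1e-2 * abs(want[[m]]) + 5e-3)
  }
}
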