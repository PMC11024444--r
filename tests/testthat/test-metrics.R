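test_that("find_peak locates window maxima under the half-open convention", {
  g <- analytic_thermogram(gauss_mix_fun(63, 2, 0.4))
  p <- find_peak(g, c(60, 66))
  expect_equal(p$temperature, 63)
  expect_equal(p$amplitude, 0.4)

  rising <- new_thermogram(seq_len(451) / 451)
  p2 <- find_peak(rising, c(60, 66))
  expect_equal(p2$temperature, 65.9)

  flat <- new_thermogram(rep(0.1, 451))
  expect_equal(find_peak(flat, c(60, 66))$temperature, 60.0)

  # tie between two equal grid maxima resolves to the lower temperature
  cp <- rep(0, 451)
  cp[match(c(61.0, 64.0), tlb_grid())] <- 0.5
  expect_equal(find_peak(new_thermogram(cp), c(60, 66))$temperature, 61.0)
})

test_that("find_valley locates the minimum strictly between two peaks", {
  f <- gauss_mix_fun(c(63, 70), c(1.5, 1.5), c(0.3, 0.3))
  tg <- analytic_thermogram(f)
  v <- find_valley(tg, 63, 70)
  expect_equal(v$temperature, 66.5, tolerance = 0.1)

  rising <- new_thermogram(seq_len(451) / 451)
  expect_equal(find_valley(rising, 60, 66)$temperature, 60.1)

  flat <- new_thermogram(rep(0.2, 451))
  v2 <- find_valley(flat, 60, 66)
  expect_equal(v2$temperature, 60.1)
  expect_equal(v2$amplitude, 0.2)

  expect_error(find_valley(tg, 70, 63), "below")
  expect_error(find_valley(tg, 63, 63.05), "no grid points")
})

test_that("global metrics match Gaussian closed forms", {
  sigma <- 2
  tg <- analytic_thermogram(gauss_mix_fun(63, sigma, 1))
  g <- global_metrics(tg)
  expect_equal(g$max_amp, 1, tolerance = 1e-4)
  expect_equal(g$t_max, 63)
  expect_lt(abs(g$t_fm - 63), 0.05)
  expect_lt(abs(g$width - 2 * sigma * sqrt(2 * log(2))), 0.01)
  expect_lt(abs(g$area - sigma * sqrt(2 * pi)), 0.001 * sigma * sqrt(2 * pi))
})

test_that("t_fm sits at the symmetry point of a symmetric profile", {
  f <- gauss_mix_fun(c(64, 71), c(1.5, 1.5), c(0.3, 0.3))  # symmetric about 67.5
  g <- global_metrics(analytic_thermogram(f))
  expect_equal(g$t_fm, 67.5, tolerance = 1e-6)
})

test_that("t_fm is NaN with a warning when total signal is not positive", {
  neg <- new_thermogram(rep(-0.01, 451))
  w <- capture_warnings(g <- global_metrics(neg))
  expect_match(w, "t_fm|width", all = TRUE)
  expect_true(is.nan(g$t_fm))
  expect_true(is.nan(g$width))
})

test_that("width truncates at the grid boundary with a warning", {
  wide <- analytic_thermogram(gauss_mix_fun(67.5, 30, 1))
  w <- capture_warnings(g <- global_metrics(wide))
  expect_match(w, "truncated", all = TRUE)
  expect_equal(g$width, 45)
})

test_that("compute_panel assembles a consistent 19-metric panel", {
  f <- gauss_mix_fun(c(63, 70, 77), c(1.4, 1.7, 2), c(0.3, 0.15, 0.06))
  p <- compute_panel(analytic_thermogram(f))
  expect_true(all(tlb_metric_names() %in% names(p)))
  expect_equal(p$t_peak1, 63, tolerance = 0.05)
  expect_equal(p$t_peak2, 70, tolerance = 0.05)
  expect_equal(p$t_peak3, 77, tolerance = 0.05)
  expect_lt(p$t_peak1, p$t_v12)
  expect_lt(p$t_v12, p$t_peak2)
  expect_lte(p$v12, min(p$peak1, p$peak2))
  expect_gte(p$max_amp, max(p$peak1, p$peak2, p$peak3))
  expect_equal(p$r_p1p3, p$r_p1p2 * p$r_p2p3, tolerance = 1e-9)
  expect_equal(p$r_v12p2, p$v12 / p$peak2, tolerance = 1e-12)

  # recomputation is bit-identical
  expect_identical(p, compute_panel(analytic_thermogram(f)))
})

test_that("a flat zero profile yields zero amplitudes and undefined ratios", {
  zero <- new_thermogram(rep(0, 451))
  suppressWarnings(p <- compute_panel(zero))
  expect_equal(p$peak1, 0)
  expect_equal(p$area, 0)
  expect_true(is.nan(p$r_p1p2))
  expect_true(is.nan(p$t_fm))
})

test_that("metrics agree with the oversampled brute-force oracle", {
  set.seed(401)
  for (rep in 1:20) {
    pp <- random_profile_params()
    f <- gauss_mix_fun(pp$centers, pp$sigmas, pp$amps)
    got <- compute_panel(analytic_thermogram(f))
    want <- oracle_panel(f)
    expect_panel_matches_oracle(got, want, context = paste("rep", rep))
  }
})

test_that("amplitudes scale and temperatures stay fixed under scaling", {
  set.seed(402)
  for (rep in 1:30) {
    pp <- random_profile_params()
    f <- gauss_mix_fun(pp$centers, pp$sigmas, pp$amps)
    c_scale <- runif(1, 0.2, 5)
    base <- compute_panel(analytic_thermogram(f))
    scaled <- compute_panel(new_thermogram(c_scale * f(tlb_grid())))
    for (m in c("peak1", "peak2", "peak3", "v12", "max_amp", "area")) {
      expect_equal(scaled[[m]], c_scale * base[[m]], tolerance = 1e-12)
    }
    for (m in c("t_peak1", "t_peak2", "t_peak3", "t_v12", "t_max", "t_fm",
                "width", "r_p1p2", "r_p1p3", "r_p2p3", "r_v12p1",
                "r_v12p2", "r_v12p3")) {
      expect_equal(scaled[[m]], base[[m]], tolerance = 1e-9)
    }
  }
})

test_that("small temperature shifts move positions by the shift", {
  set.seed(403)
  for (rep in 1:30) {
    pp <- random_shift_params()
    delta <- runif(1, -0.5, 0.5)
    f0 <- gauss_mix_fun(pp$centers, pp$sigmas, pp$amps)
    f1 <- gauss_mix_fun(pp$centers + delta, pp$sigmas, pp$amps)
    a <- compute_panel(analytic_thermogram(f0))
    b <- compute_panel(analytic_thermogram(f1))
    for (m in c("t_peak1", "t_peak2", "t_peak3", "t_v12", "t_max", "t_fm")) {
      expect_lt(abs((b[[m]] - a[[m]]) - delta), 0.1 + 1e-9)
    }
    for (m in c("peak1", "peak2", "peak3", "max_amp")) {
      expect_lt(abs(b[[m]] - a[[m]]), 0.01 * a[[m]])
    }
  }
})
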