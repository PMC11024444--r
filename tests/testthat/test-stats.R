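random_panels <- function(n_per_group = 10, groups = c("A", "B", "C")) {
  g <- rep(groups, each = n_per_group)
  m <- matrix(rnorm(length(g) * 19), ncol = 19,
              dimnames = list(NULL, tlb_metric_names()))
  dplyr::bind_cols(tibble::tibble(phenotype = g), tibble::as_tibble(m))
}

test_that("kruskal_wallis_panel tests every metric with family adjustment", {
  set.seed(501)
  panels <- random_panels()
  res <- kruskal_wallis_panel(panels)
  expect_equal(nrow(res), 19)
  expect_equal(res$metric, tlb_metric_names())
  expect_true(all(res$p_adjusted >= res$p_unadjusted - 1e-12))
  expect_true(all(res$p_adjusted <= 1 & res$p_unadjusted >= 0))
  # Holm adjustment preserves the ordering of unadjusted p-values
  ord <- order(res$p_unadjusted)
  expect_true(all(diff(res$p_adjusted[ord]) >= -1e-12))
  # per-group summaries carry median and quartiles
  gs <- res$group_summary[[1]]
  expect_setequal(names(gs), c("group", "median", "q1", "q3"))
  expect_equal(nrow(gs), 3)
})

test_that("constant metrics and degenerate groups are handled", {
  set.seed(502)
  panels <- random_panels()
  panels$area <- 1
  expect_warning(res <- kruskal_wallis_panel(panels), "constant")
  expect_equal(res$p_unadjusted[res$metric == "area"], 1)

  tiny <- random_panels(1)
  expect_error(kruskal_wallis_panel(tiny), "at least 2 samples")
  one_group <- random_panels(5, groups = "A")
  expect_error(kruskal_wallis_panel(one_group), "at least 2 groups")
})

test_that("a strongly shifted group is detected after Holm adjustment", {
  set.seed(503)
  hits <- 0
  for (r in 1:20) {
    panels <- random_panels(20)
    panels$peak1[panels$phenotype == "A"] <-
      panels$peak1[panels$phenotype == "A"] + 3
    res <- kruskal_wallis_panel(panels)
    if (res$p_adjusted[res$metric == "peak1"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("rank tests are invariant to strictly monotone transforms", {
  set.seed(504)
  panels <- random_panels(8)
  r1 <- kruskal_wallis_panel(panels)
  trans <- panels
  for (m in tlb_metric_names()) trans[[m]] <- exp(trans[[m]])
  r2 <- kruskal_wallis_panel(trans)
  expect_equal(r1$p_unadjusted, r2$p_unadjusted, tolerance = 1e-12)
})

test_that("pairwise rank-sum p-values match exact enumeration", {
  panels <- tibble::tibble(phenotype = rep(c("A", "B"), each = 3),
                           peak1 = c(1, 2, 3, 4, 5, 6))
  res <- pairwise_wilcoxon(panels, metric = "peak1")
  # 2/20 orderings are as or more extreme in each tail: p = 0.1 two-sided
  expect_equal(res$p_value, 0.1)

  same <- tibble::tibble(phenotype = rep(c("A", "B"), each = 3),
                         peak1 = rep(c(1, 2, 3), 2))
  expect_equal(pairwise_wilcoxon(same, metric = "peak1")$p_value, 1)
})

test_that("paired signed-rank comparisons match by patient", {
  panels <- tibble::tibble(
    phenotype = rep(c("T0", "Tfu"), each = 4),
    patient_id = rep(paste0("p", 1:4), 2),
    peak1 = c(1, 2, 3, 4, 1, 2, 3, 4))
  expect_warning(res <- pairwise_wilcoxon(panels, metric = "peak1",
                                          paired = TRUE), "zero")
  expect_equal(res$p_value, 1)

  unmatched <- tibble::tibble(
    phenotype = c("T0", "T0", "Tfu", "Tfu"),
    patient_id = c("a", "b", "c", "d"),
    peak1 = 1:4)
  expect_error(pairwise_wilcoxon(unmatched, metric = "peak1", paired = TRUE),
               "matched")
})

test_that("delta_metrics computes within-patient follow-up changes", {
  set.seed(505)
  p0 <- random_panels(4, groups = c("TMI"))
  p0$patient_id <- paste0("p", 1:4)
  p1 <- p0
  expect_equal(sum(abs(as.matrix(
    delta_metrics(p0, p1)[, tlb_metric_names()]))), 0)

  p2 <- p0
  for (m in tlb_metric_names()) p2[[m]][1] <- p2[[m]][1] + 1
  d <- delta_metrics(p0, p2)
  expect_true(all(abs(as.matrix(d[d$patient_id == "p1",
                                  tlb_metric_names()]) - 1) < 1e-12))

  p3 <- p1
  p3$patient_id <- paste0("q", 1:4)
  expect_error(delta_metrics(p0, p3), "both timepoints")
  p4 <- p1
  p4$patient_id[1] <- "zzz"
  expect_message(delta_metrics(p0, p4), "dropped")
})

test_that("profile bands are pointwise medians with 95% quantile limits", {
  f <- gauss_mix_fun(63, 2, 0.3)
  single <- profile_band(list(analytic_thermogram(f)))
  expect_equal(single$center, single$lower)
  expect_equal(single$center, single$upper)

  set.seed(506)
  mu <- f(tlb_grid())
  m <- matrix(rnorm(400 * 451, mean = rep(mu, each = 400)), nrow = 400)
  band <- profile_band(m)
  expect_true(all(band$lower <= band$center + 1e-12))
  expect_true(all(band$center <= band$upper + 1e-12))
  # unit normal noise: band half-width concentrates near 1.96
  halfwidth <- (band$upper - band$lower) / 2
  expect_equal(mean(halfwidth), 1.96, tolerance = 0.08)
  expect_equal(band$center, mu, tolerance = 0.25)
})

test_that("mean difference profiles recover the recovery signature", {
  co <- simulate_cohort(c(cCAD = 6, TMI = 10, nTMi = 5),
                        timepoints = c("T0", "Tfu"), seed = 21)
  diffs <- mean_difference_profile(co)
  expect_setequal(unique(diffs$phenotype), c("cCAD", "TMI", "nTMi"))

  tmi <- diffs[diffs$phenotype == "TMI", ]
  in_win <- function(lo, hi) tmi$temperature >= lo & tmi$temperature < hi
  # follow-up regains the major transition and loses the shoulder
  expect_gt(mean(tmi$mean_diff[in_win(60, 66)]), 0)
  expect_lt(mean(tmi$mean_diff[in_win(73, 81)]), 0)

  # identical timepoints give a zero curve; opposite pairs cancel
  base <- co[co$timepoint == "T0", ]
  dup <- base
  dup$timepoint <- "Tfu"
  both <- dplyr::bind_rows(base, dup)
  class(both) <- class(co)
  z <- mean_difference_profile(both)
  expect_equal(max(abs(z$mean_diff)), 0)
})

test_that("band and difference summaries are invariant to sample order", {
  co <- simulate_cohort(c(TMI = 8), timepoints = c("T0", "Tfu"), seed = 31)
  shuffled <- co[sample(nrow(co)), ]
  class(shuffled) <- class(co)
  b1 <- profile_band(co[co$timepoint == "T0", ])
  b2 <- profile_band(shuffled[shuffled$timepoint == "T0", ])
  expect_equal(b1, b2, ignore_attr = TRUE)
  expect_equal(mean_difference_profile(co)$mean_diff,
               mean_difference_profile(shuffled)$mean_diff)
})
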