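#' Censor post-baseline acute samples of flagged cCAD patients
#'
#' Patients in the stable-disease (cCAD) group whose troponin rose above the
#' 99th-percentile threshold after baseline had their acute-phase samples
#' (T2-T48) excluded from analysis; baseline (T0) and follow-up (Tfu)
#' samples are retained. The rule reads a logical manifest column and
#' applies only to cCAD.
#'
#' @param cohort A `tlb_cohort` (or manifest tibble).
#' @param flag_column Name of the logical column marking troponin
#'   exceedance; any flagged row marks the whole patient.
#' @return The cohort with the `censored` column updated; one message per
#'   excluded sample set.
#' @export
apply_censoring <- function(cohort, flag_column = "troponin_flag") {
  df <- cohort
  if (!flag_column %in% names(df)) {
    abort(paste0("censoring rule references missing column: ", flag_column))
  }
  if (!"censored" %in% names(df)) df$censored <- FALSE
  acute_post <- c("T2", "T4", "T24", "T48")
  flagged <- unique(df$patient_id[df$phenotype == "cCAD" &
                                    df[[flag_column]] %in% TRUE])
  hit <- df$patient_id %in% flagged & df$phenotype == "cCAD" &
    df$timepoint %in% acute_post
  if (any(hit)) {
    for (pid in unique(df$patient_id[hit])) {
      inform(paste0("censoring ", sum(hit & df$patient_id == pid),
                    " post-baseline acute sample(s) of ", pid))
    }
  }
  df$censored <- df$censored | hit
  df
}

#' Frequency / summary tables per phenotype group
#'
#' Categorical variables are summarized as count and within-group percentage
#' (denominator = group size minus missing values, which are reported);
#' continuous variables as mean +/- SD, or median (Q1, Q3) when listed as
#' skewed.
#'
#' @param manifest Tibble with a `phenotype` column plus the variables to
#'   summarize (one row per patient).
#' @param categorical,continuous Character vectors of column names.
#' @param skewed Subset of `continuous` to summarize by median (Q1, Q3).
#' @return A tibble with `variable`, `level`, `phenotype`, `n`,
#'   `n_missing`, `pct` (one decimal) for categorical rows, and `variable`,
#'   `phenotype`, `mean`, `sd` or `median`, `q1`, `q3` with a formatted
#'   `label` for continuous rows.
#' @export
summarize_cohort <- function(manifest, categorical = character(),
                             continuous = character(),
                             skewed = character()) {
  missing_cols <- setdiff(c(categorical, continuous), names(manifest))
  if (length(missing_cols) > 0) {
    abort(paste0("unknown column(s): ", paste(missing_cols, collapse = ", ")))
  }
  groups <- unique(manifest$phenotype)
  rows <- list()
  for (v in categorical) {
    for (ph in groups) {
      x <- manifest[[v]][manifest$phenotype == ph]
      n_missing <- sum(is.na(x))
      denom <- length(x) - n_missing
      lv <- unique(stats::na.omit(x))
      if (length(lv) == 0) {
        rows[[length(rows) + 1L]] <- tibble(
          variable = v, level = NA_character_, phenotype = ph, n = 0L,
          n_missing = n_missing, pct = NA_real_,
          label = "0 (undefined)")
        next
      }
      for (l in sort(lv)) {
        cnt <- sum(x == l, na.rm = TRUE)
        pct <- if (denom > 0) round_half_up(100 * cnt / denom, 1) else NA_real_
        rows[[length(rows) + 1L]] <- tibble(
          variable = v, level = as.character(l), phenotype = ph,
          n = cnt, n_missing = n_missing, pct = pct,
          label = if (is.na(pct)) paste0(cnt, " (undefined)")
                  else sprintf("%d (%.1f)", cnt, pct))
      }
    }
  }
  for (v in continuous) {
    for (ph in groups) {
      x <- manifest[[v]][manifest$phenotype == ph]
      n_missing <- sum(is.na(x))
      x <- x[!is.na(x)]
      if (v %in% skewed) {
        q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
        rows[[length(rows) + 1L]] <- tibble(
          variable = v, level = NA_character_, phenotype = ph,
          n = length(x), n_missing = n_missing,
          median = q[[2]], q1 = q[[1]], q3 = q[[3]],
          label = sprintf("%.2f (%.2f, %.2f)", q[[2]], q[[1]], q[[3]]))
      } else {
        rows[[length(rows) + 1L]] <- tibble(
          variable = v, level = NA_character_, phenotype = ph,
          n = length(x), n_missing = n_missing,
          mean = mean(x), sd = sd(x),
          label = sprintf("%.2f ± %.2f", mean(x), sd(x)))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Run the end-to-end analysis pipeline
#'
#' Simulates (or loads) a cohort, applies the censoring rule when the flag
#' column is present, computes metric panels, runs the three statistical
#' families (baseline T0, follow-up Tfu, within-patient delta), clusters
#' baseline profiles, and writes every stage output as plain CSV/JSON to
#' `out_dir`. With the same configuration and seed the numeric outputs are
#' byte-identical across runs.
#'
#' @param config A named list or path to a YAML file. Recognized fields:
#'   `seed` (default 1); `simulate` (list passed to [simulate_cohort()]:
#'   `n_per_group`, `frac_tmi_80c`, ...); `adjust` (p-adjustment method,
#'   default `"holm"`); `k` (clusters at baseline, default 3); `restarts`
#'   (default 50); `censor_flag` (manifest column for the censoring rule,
#'   applied if present); `figures` (write ggplot2 figures, default FALSE).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `cohort`, `panels`, `stats` (per family),
#'   `clusters`, `purity`, `band`, `diff_profiles`, and the output paths.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("tlb_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% 1
  adjust <- config$adjust %||% "holm"
  k <- config$k %||% 3
  restarts <- config$restarts %||% 50
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  sim <- config$simulate %||% list()
  cohort <- do.call(simulate_cohort, c(sim, list(seed = seed)))
  if (!is.null(config$censor_flag) &&
        config$censor_flag %in% names(cohort)) {
    cohort <- apply_censoring(cohort, config$censor_flag)
  }

  manifest <- dplyr::select(as_tibble(cohort), -"thermogram")
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))

  panels <- compute_panels(cohort)
  readr::write_csv(dplyr::select(panels, -dplyr::any_of("thermogram")),
                   file.path(out_dir, "panels.csv"))

  fam <- list()
  flat <- function(kw) dplyr::select(kw, -"group_summary")
  p_t0 <- panels[panels$timepoint == "T0", ]
  p_tfu <- panels[panels$timepoint == "Tfu", ]
  fam$t0 <- kruskal_wallis_panel(p_t0, "phenotype", adjust)
  fam$tfu <- kruskal_wallis_panel(p_tfu, "phenotype", adjust)
  delta <- delta_metrics(p_t0, p_tfu)
  fam$delta <- kruskal_wallis_panel(delta, "phenotype", adjust)
  readr::write_csv(flat(fam$t0), file.path(out_dir, "stats_t0.csv"))
  readr::write_csv(flat(fam$tfu), file.path(out_dir, "stats_tfu.csv"))
  readr::write_csv(flat(fam$delta), file.path(out_dir, "stats_delta.csv"))

  clusters <- kmeans_profiles(cohort, k = k, seed = seed,
                              restarts = restarts, timepoint = "T0")
  purity <- purity_table(clusters,
                         setNames(cohort$phenotype, cohort$sample_id))
  readr::write_csv(tidy(clusters), file.path(out_dir, "cluster_assignments.csv"))
  readr::write_csv(as_tibble(purity), file.path(out_dir, "cluster_purity.csv"))
  centers <- as_tibble(t(clusters$centers))
  names(centers) <- paste0("cluster", seq_len(k))
  readr::write_csv(dplyr::bind_cols(tibble(temperature = tlb_grid()), centers),
                   file.path(out_dir, "cluster_centers.csv"))

  band <- profile_band(cohort[cohort$timepoint == "T0" & !cohort$censored, ])
  readr::write_csv(band, file.path(out_dir, "band_t0.csv"))
  diffs <- mean_difference_profile(cohort)
  readr::write_csv(diffs, file.path(out_dir, "difference_profiles.csv"))

  log <- list(seed = seed, adjust = adjust, k = k, restarts = restarts,
              n_samples = nrow(cohort), n_censored = sum(cohort$censored),
              n_patients = length(unique(cohort$patient_id)))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)

  if (isTRUE(config$figures)) {
    ggplot2::ggsave(file.path(out_dir, "band_t0.png"),
                    plot_profile_band(band), width = 6, height = 4, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "difference_profiles.png"),
                    plot_difference_profiles(diffs),
                    width = 6, height = 4, dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "clusters.png"),
                    autoplot(clusters), width = 8, height = 4, dpi = 150)
  }

  invisible(list(cohort = cohort, panels = panels, stats = fam,
                 clusters = clusters, purity = purity, band = band,
                 diff_profiles = diffs, out_dir = out_dir))
}
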