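metric_cols <- function(panels) {
  present <- intersect(tlb_metric_names(), names(panels))
  if (length(present) == 0) abort("no metric columns found in panels")
  present
}

resolve_groups <- function(panels, groups) {
  if (is.character(groups) && length(groups) == 1 && groups %in% names(panels)) {
    groups <- panels[[groups]]
  }
  if (length(groups) != nrow(panels)) {
    abort("groups must name a column of panels or match its row count")
  }
  factor(groups)
}

#' Kruskal-Wallis tests across groups for every metric
#'
#' One rank-based Kruskal-Wallis test per metric (chi-square reference with
#' groups - 1 degrees of freedom, tie-corrected), with family-wise adjustment
#' across the metric panel. A metric constant across all samples is
#' untestable and reported with p = 1 and a warning.
#'
#' @param panels Tibble with the 19 metric columns (see
#'   [tlb_metric_names()]); extra columns are ignored.
#' @param groups Grouping: either the name of a column of `panels` (e.g.
#'   `"phenotype"`) or a vector with one label per row. At least two groups
#'   with two samples each are required.
#' @param adjust Multiple-comparison method: `"holm"` (default),
#'   `"bonferroni"` or `"BH"`.
#' @return A tibble with one row per metric: `metric`, `p_unadjusted`,
#'   `p_adjusted`, and a `group_summary` list-column of per-group median and
#'   quartiles.
#' @export
kruskal_wallis_panel <- function(panels, groups = "phenotype",
                                 adjust = c("holm", "bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  g <- resolve_groups(panels, groups)
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) < 2)) abort("every group needs at least 2 samples")
  cols <- metric_cols(panels)
  p <- vapply(cols, function(m) {
    x <- panels[[m]]
    ok <- is.finite(x)
    if (length(unique(x[ok])) < 2) {
      warn(paste0("metric ", m, " is constant; p set to 1"))
      return(1)
    }
    kruskal.test(x[ok], g[ok])$p.value
  }, numeric(1))
  summaries <- purrr::map(cols, function(m) {
    dplyr::summarise(
      dplyr::group_by(tibble(value = panels[[m]], group = g), .data$group),
      median = median(.data$value, na.rm = TRUE),
      q1 = quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
      q3 = quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
      .groups = "drop")
  })
  tibble(metric = cols, p_unadjusted = unname(p),
         p_adjusted = p.adjust(unname(p), method = adjust),
         group_summary = summaries)
}

#' Pairwise two-group Wilcoxon tests for one metric
#'
#' Between-group comparisons use the rank-sum (Mann-Whitney) form; paired
#' within-patient comparisons use the signed-rank form with samples matched
#' by patient id. The exact null distribution is used for small samples
#' (n <= 25 per group) without ties, otherwise the normal approximation with
#' continuity correction.
#'
#' @inheritParams kruskal_wallis_panel
#' @param metric Name of the metric column to test.
#' @param paired If `TRUE`, use the signed-rank test on patient-matched
#'   values; requires `patient_id`.
#' @param patient_id Column name or vector of patient ids (for pairing).
#' @return Tibble with one row per group pair: `group1`, `group2`, `n1`,
#'   `n2`, `p_value`.
#' @export
pairwise_wilcoxon <- function(panels, groups = "phenotype", metric,
                              paired = FALSE, patient_id = "patient_id") {
  g <- resolve_groups(panels, groups)
  if (!metric %in% names(panels)) abort(paste0("unknown metric: ", metric))
  x <- panels[[metric]]
  pid <- NULL
  if (paired) {
    pid <- if (is.character(patient_id) && length(patient_id) == 1 &&
                 patient_id %in% names(panels)) {
      panels[[patient_id]]
    } else patient_id
    if (length(pid) != length(x)) abort("patient_id required for paired tests")
  }
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    i1 <- g == pr[[1]]
    i2 <- g == pr[[2]]
    x1 <- x[i1]
    x2 <- x[i2]
    if (paired) {
      common <- intersect(pid[i1], pid[i2])
      if (length(common) == 0) abort("no matched patients for paired test")
      x1 <- x1[match(common, pid[i1])]
      x2 <- x2[match(common, pid[i2])]
      d <- x1 - x2
      if (all(d == 0)) {
        warn("all paired differences are zero; p = 1")
        return(tibble(group1 = pr[[1]], group2 = pr[[2]],
                      n1 = length(x1), n2 = length(x2), p_value = 1))
      }
      exact <- length(d[d != 0]) <= 25 && !any(duplicated(abs(d[d != 0])))
      pv <- suppressWarnings(
        wilcox.test(x1, x2, paired = TRUE, exact = exact,
                    correct = TRUE)$p.value)
    } else {
      if (identical(sort(x1), sort(x2))) {
        return(tibble(group1 = pr[[1]], group2 = pr[[2]],
                      n1 = length(x1), n2 = length(x2), p_value = 1))
      }
      exact <- max(length(x1), length(x2)) <= 25 &&
        !any(duplicated(c(x1, x2)))
      pv <- suppressWarnings(
        wilcox.test(x1, x2, paired = FALSE, exact = exact,
                    correct = TRUE)$p.value)
    }
    tibble(group1 = pr[[1]], group2 = pr[[2]],
           n1 = length(x1), n2 = length(x2), p_value = pv)
  })
}

#' Within-patient metric changes between two timepoints
#'
#' Computes per-patient differences (typically follow-up minus baseline,
#' Tfu - T0) for every metric. Patients missing from either panel are
#' dropped with a message.
#'
#' @param panels_t0,panels_tfu Metric-panel tibbles containing `patient_id`
#'   and the metric columns, one row per patient.
#' @return A tibble of per-patient differences with `patient_id`, any shared
#'   `phenotype` column (from the baseline panel), and the 19 metric columns
#'   holding `tfu - t0` values.
#' @export
delta_metrics <- function(panels_t0, panels_tfu) {
  if (!"patient_id" %in% names(panels_t0) ||
        !"patient_id" %in% names(panels_tfu)) {
    abort("both panels need a patient_id column")
  }
  common <- intersect(panels_t0$patient_id, panels_tfu$patient_id)
  dropped <- setdiff(union(panels_t0$patient_id, panels_tfu$patient_id), common)
  if (length(common) == 0) abort("no patients present at both timepoints")
  if (length(dropped) > 0) {
    inform(paste0(length(dropped),
                  " patient(s) missing a timepoint were dropped"))
  }
  i0 <- match(common, panels_t0$patient_id)
  i1 <- match(common, panels_tfu$patient_id)
  cols <- metric_cols(panels_t0)
  delta <- purrr::map_dfc(cols, function(m) {
    tibble(!!m := panels_tfu[[m]][i1] - panels_t0[[m]][i0])
  })
  meta <- tibble(patient_id = common)
  if ("phenotype" %in% names(panels_t0)) {
    meta$phenotype <- panels_t0$phenotype[i0]
  }
  dplyr::bind_cols(meta, delta)
}

#' Pointwise median profile with a 95% quantile band
#'
#' For a set of thermograms on the standard grid, the pointwise median and
#' the pointwise 2.5% and 97.5% quantiles (linear-interpolation convention).
#'
#' @param thermograms A `tlb_cohort`, a tibble with a `thermogram`
#'   list-column, a list of `tlb_thermogram`s, or a profile matrix.
#' @return A tibble with `temperature`, `center`, `lower`, `upper`; the
#'   sample count is in attribute `n`.
#' @export
profile_band <- function(thermograms) {
  m <- as_profile_matrix(thermograms)
  out <- tibble(
    temperature = tlb_grid(),
    center = apply(m, 2, median),
    lower = apply(m, 2, quantile, probs = 0.025, names = FALSE),
    upper = apply(m, 2, quantile, probs = 0.975, names = FALSE))
  attr(out, "n") <- nrow(m)
  out
}

as_profile_matrix <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) != 451) abort("profile matrix must have 451 columns")
    return(x)
  }
  if (is.data.frame(x) && "thermogram" %in% names(x)) {
    return(profile_matrix(x))
  }
  if (is.data.frame(x) && "cp_excess" %in% names(x)) x <- list(x)
  if (is.list(x) && length(x) > 0) {
    return(t(vapply(x, function(tg) tg$cp_excess, numeric(451))))
  }
  abort("cannot interpret input as thermogram profiles")
}

#' Mean follow-up minus baseline difference profile per phenotype
#'
#' Patients are matched across the two timepoints; within each phenotype the
#' pointwise mean of the (Tfu - T0) curves is returned. Phenotypes with no
#' matched pairs are omitted with a warning.
#'
#' @param cohort A `tlb_cohort` containing both timepoints.
#' @param from,to Timepoint labels; the difference is `from - to`
#'   (default `Tfu - T0`).
#' @return Tibble with `phenotype`, `temperature`, `mean_diff`, `n_pairs`.
#' @export
mean_difference_profile <- function(cohort, from = "Tfu", to = "T0") {
  df <- as_tibble(cohort)
  if ("censored" %in% names(df)) df <- df[!df$censored, ]
  out <- list()
  for (ph in unique(df$phenotype)) {
    a <- df[df$phenotype == ph & df$timepoint == from, ]
    b <- df[df$phenotype == ph & df$timepoint == to, ]
    common <- intersect(a$patient_id, b$patient_id)
    if (length(common) == 0) {
      warn(paste0("no matched pairs for phenotype ", ph, "; omitted"))
      next
    }
    ma <- t(vapply(a$thermogram[match(common, a$patient_id)],
                   function(tg) tg$cp_excess, numeric(451)))
    mb <- t(vapply(b$thermogram[match(common, b$patient_id)],
                   function(tg) tg$cp_excess, numeric(451)))
    out[[ph]] <- tibble(phenotype = ph, temperature = tlb_grid(),
                        mean_diff = colMeans(ma - mb),
                        n_pairs = length(common))
  }
  if (length(out) == 0) abort("no phenotype had matched pairs")
  dplyr::bind_rows(out)
}
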