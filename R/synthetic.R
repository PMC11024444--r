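#' Noise model for simulated thermograms
#'
#' @param pointwise_sd Standard deviation of additive pointwise noise,
#'   cal/(degC g).
#' @param amplitude_cv Coefficient of variation of the per-sample
#'   multiplicative amplitude factor (log-normal).
#' @param shift_sd Standard deviation of the per-sample temperature jitter,
#'   degrees C.
#' @return A `tlb_noise` list.
#' @export
noise_model <- function(pointwise_sd = 0.004, amplitude_cv = 0.06,
                        shift_sd = 0.25) {
  if (pointwise_sd < 0 || amplitude_cv < 0 || shift_sd < 0) {
    abort("noise parameters must be non-negative")
  }
  structure(list(pointwise_sd = pointwise_sd, amplitude_cv = amplitude_cv,
                 shift_sd = shift_sd), class = "tlb_noise")
}

new_template <- function(phenotype, acute, quiescent, lambda) {
  for (comp in list(acute, quiescent)) {
    stopifnot(all(comp$sigma > 0), all(comp$amplitude >= 0),
              all(comp$center >= 50 & comp$center <= 85))
  }
  if (abs(lambda[["T0"]]) > 1e-12 || abs(lambda[["Tfu"]] - 1) > 1e-12) {
    abort("recovery fraction must be 0 at T0 and 1 at Tfu")
  }
  structure(list(phenotype = phenotype, acute = acute,
                 quiescent = quiescent, lambda = lambda),
            class = "tlb_template")
}

gaussians <- function(comp, tt, shift = 0) {
  out <- numeric(length(tt))
  for (i in seq_len(nrow(comp))) {
    out <- out + comp$amplitude[[i]] *
      exp(-((tt - comp$center[[i]] - shift)^2) / (2 * comp$sigma[[i]]^2))
  }
  out
}

#' Default phenotype templates for simulated cohorts
#'
#' Each template mixes an acute and a quiescent three-component Gaussian
#' curve, blended by a recovery fraction lambda that runs from 0 at baseline
#' (T0) to 1 at follow-up (Tfu). The quiescent signature has a dominant
#' major transition near 63 degrees C, a smaller transition near 70 and a
#' small shoulder near 77. Acute signatures: TMI has a strongly diminished
#' major transition and an elevated shoulder region; nTMi a diminished major
#' transition with an elevated 68-75 region; TMI_80C (a TMI subtype) a
#' dominant, well-defined 80 degree component. cCAD is stable, so its acute
#' curve is only slightly below the quiescent one. Recovery is faster for
#' nTMi than for TMI. All constants are package defaults chosen for
#' qualitative realism and testability, not measured values.
#'
#' @return Named list of `tlb_template` objects for `cCAD`, `TMI`, `nTMi`
#'   and `TMI_80C`.
#' @export
default_templates <- function() {
  quiescent <- tibble(center = c(63.2, 70.0, 77.0),
                      sigma = c(1.3, 1.6, 1.9),
                      amplitude = c(0.300, 0.165, 0.055))
  lam <- function(v) setNames(v, c("T0", "T2", "T4", "T24", "T48", "Tfu"))
  list(
    cCAD = new_template(
      "cCAD",
      acute = tibble(center = c(63.2, 70.0, 77.0),
                     sigma = c(1.3, 1.6, 1.9),
                     amplitude = c(0.270, 0.170, 0.060)),
      quiescent = quiescent,
      lambda = lam(c(0, 0.30, 0.50, 0.80, 0.90, 1))),
    TMI = new_template(
      "TMI",
      acute = tibble(center = c(63.6, 70.5, 77.2),
                     sigma = c(1.4, 1.8, 2.0),
                     amplitude = c(0.120, 0.160, 0.145)),
      quiescent = quiescent,
      lambda = lam(c(0, 0.05, 0.12, 0.35, 0.55, 1))),
    nTMi = new_template(
      "nTMi",
      acute = tibble(center = c(63.4, 70.8, 76.5),
                     sigma = c(1.4, 2.3, 1.9),
                     amplitude = c(0.160, 0.190, 0.075)),
      quiescent = quiescent,
      lambda = lam(c(0, 0.10, 0.25, 0.55, 0.75, 1))),
    TMI_80C = new_template(
      "TMI_80C",
      acute = tibble(center = c(63.5, 70.5, 80.0),
                     sigma = c(1.4, 1.8, 1.1),
                     amplitude = c(0.075, 0.100, 0.320)),
      quiescent = quiescent,
      lambda = lam(c(0, 0.05, 0.12, 0.35, 0.55, 1)))
  )
}

template_curve <- function(template, lambda, shift = 0, scale = 1) {
  tt <- tlb_grid()
  mix <- (1 - lambda) * gaussians(template$acute, tt, shift) +
    lambda * gaussians(template$quiescent, tt, shift)
  scale * mix
}

#' Simulate one thermogram from a phenotype template
#'
#' The deterministic mean curve is the lambda-blend of the template's acute
#' and quiescent mixtures on the standard grid; a multiplicative amplitude
#' factor, a small temperature jitter (applied analytically to the component
#' centers) and additive pointwise noise are then drawn under `seed`.
#'
#' @param template A `tlb_template`.
#' @param timepoint One of `"T0"`, `"T2"`, `"T4"`, `"T24"`, `"T48"`, `"Tfu"`.
#' @param noise A `tlb_noise` model; use zero parameters for the noiseless
#'   mean curve.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param sample_id Identifier for the resulting thermogram.
#' @return A `tlb_thermogram`.
#' @export
simulate_thermogram <- function(template, timepoint, noise = noise_model(),
                                seed = NULL, sample_id = NULL) {
  if (!timepoint %in% names(template$lambda)) {
    abort(paste0("unknown timepoint: ", timepoint))
  }
  if (!is.null(seed)) set.seed(seed)
  lambda <- template$lambda[[timepoint]]
  shift <- rnorm(1, 0, noise$shift_sd)
  scale <- exp(rnorm(1, 0, noise$amplitude_cv))
  cp <- template_curve(template, lambda, shift, scale) +
    rnorm(451, 0, noise$pointwise_sd)
  new_thermogram(cp,
                 sample_id = sample_id %||%
                   paste0(template$phenotype, "_", timepoint),
                 provenance = list(simulated = TRUE, lambda = lambda))
}

#' Simulate a longitudinal thermogram cohort
#'
#' Patients are generated per phenotype group with one multiplicative
#' amplitude factor and one temperature jitter per patient, shared across
#' that patient's timepoints (patients serve as their own controls); sample
#' level noise is added on top. A fixed number
#' `round(frac_tmi_80c * n_TMI)` of TMI patients (chosen at random) carry the
#' 80 degree C subtype.
#'
#' @param n_per_group Named vector of patient counts, e.g.
#'   `c(cCAD = 35, TMI = 60, nTMi = 20)` (the study group sizes).
#' @param timepoints Character vector of timepoints to simulate.
#' @param templates Templates as from [default_templates()].
#' @param noise Sample-level `tlb_noise` model.
#' @param seed Integer seed for the whole cohort.
#' @param frac_tmi_80c Fraction of TMI patients carrying the 80 degree
#'   subtype; default 7/60.
#' @param patient_amplitude_cv,patient_shift_sd Patient-level random-effect
#'   scales (shared across timepoints).
#' @return A `tlb_cohort`: a tibble with columns `sample_id`, `patient_id`,
#'   `phenotype`, `subtype`, `timepoint`, `censored` and a `thermogram`
#'   list-column.
#' @export
simulate_cohort <- function(n_per_group = c(cCAD = 35, TMI = 60, nTMi = 20),
                            timepoints = c("T0", "T2", "T4", "T24", "T48", "Tfu"),
                            templates = default_templates(),
                            noise = noise_model(), seed = 1,
                            frac_tmi_80c = 7 / 60,
                            patient_amplitude_cv = 0.08,
                            patient_shift_sd = 0.3) {
  if (length(timepoints) == 0) abort("timepoints must be non-empty")
  if (any(n_per_group <= 0)) abort("n_per_group must be positive")
  if (frac_tmi_80c < 0 || frac_tmi_80c > 1) {
    abort("frac_tmi_80c must be in [0, 1]")
  }
  set.seed(seed)
  rows <- list()
  for (ph in names(n_per_group)) {
    n <- n_per_group[[ph]]
    subtypes <- rep(ph, n)
    if (ph == "TMI" && frac_tmi_80c > 0) {
      n80 <- round(frac_tmi_80c * n)
      if (n80 > 0) subtypes[sample.int(n, n80)] <- "TMI_80C"
    }
    for (i in seq_len(n)) {
      pid <- sprintf("%s_%03d", ph, i)
      tmpl <- templates[[subtypes[[i]]]]
      p_scale <- exp(rnorm(1, 0, patient_amplitude_cv))
      p_shift <- rnorm(1, 0, patient_shift_sd)
      for (tp in timepoints) {
        if (!tp %in% names(tmpl$lambda)) {
          abort(paste0("unknown timepoint: ", tp))
        }
        shift <- p_shift + rnorm(1, 0, noise$shift_sd)
        scale <- p_scale * exp(rnorm(1, 0, noise$amplitude_cv))
        cp <- template_curve(tmpl, tmpl$lambda[[tp]], shift, scale) +
          rnorm(451, 0, noise$pointwise_sd)
        sid <- paste0(pid, "_", tp)
        rows[[length(rows) + 1L]] <- tibble(
          sample_id = sid, patient_id = pid, phenotype = ph,
          subtype = subtypes[[i]], timepoint = tp, censored = FALSE,
          thermogram = list(new_thermogram(cp, sample_id = sid,
                                           provenance = list(simulated = TRUE))))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tlb_cohort", class(out))
  attr(out, "seed") <- seed
  out
}

#' Extract the profile matrix of a cohort
#'
#' @param cohort A `tlb_cohort` or tibble with a `thermogram` list-column.
#' @param timepoint Optional timepoint filter.
#' @return Numeric matrix, one row per (non-censored) sample, 451 columns,
#'   rownames = sample ids.
#' @export
profile_matrix <- function(cohort, timepoint = NULL) {
  df <- as_tibble(cohort)
  if (!is.null(timepoint)) df <- df[df$timepoint %in% timepoint, ]
  if ("censored" %in% names(df)) df <- df[!df$censored, ]
  if (nrow(df) == 0) abort("no samples selected")
  m <- t(vapply(df$thermogram, function(tg) tg$cp_excess, numeric(451)))
  rownames(m) <- df$sample_id
  m
}
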