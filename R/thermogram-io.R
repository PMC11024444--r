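#' Read a raw DSC scan from a delimited text file
#'
#' Raw scans are two-column numeric tables (temperature in degrees Celsius,
#' measured heat signal). Comma- and tab-delimited files are auto-detected;
#' an optional header row is tolerated. Extra columns beyond the first two
#' are ignored.
#'
#' @param path Path to the scan file.
#' @param role Either `"sample"` or `"buffer"`.
#' @param sample_id Identifier for the scan; defaults to the file name.
#' @param scan_rate Scan rate in degrees C per minute (instrument setting).
#' @return A `tlb_scan` tibble with columns `temperature` and `signal`.
#' @export
read_scan <- function(path, role = c("sample", "buffer"), sample_id = NULL,
                      scan_rate = 1) {
  role <- match.arg(role)
  if (!file.exists(path)) abort(paste0("scan file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("empty scan file: ", path))
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  first <- suppressWarnings(as.numeric(fields[[1]][1:2]))
  start <- if (any(is.na(first))) 2L else 1L
  if (start > length(lines)) abort(paste0("no data rows in scan file: ", path))
  temp <- numeric(0)
  sig <- numeric(0)
  for (i in seq(start, length(lines))) {
    f <- fields[[i]]
    if (length(f) < 2) {
      abort(paste0("malformed row at line ", i, " of ", path,
                   ": fewer than 2 fields"))
    }
    v <- suppressWarnings(as.numeric(f[1:2]))
    if (any(is.na(v))) {
      abort(paste0("malformed row at line ", i, " of ", path,
                   ": non-numeric value"))
    }
    temp[length(temp) + 1L] <- v[[1]]
    sig[length(sig) + 1L] <- v[[2]]
  }
  new_scan(temp, sig,
           sample_id = sample_id %||% basename(path),
           role = role, scan_rate = scan_rate)
}

#' Construct a raw scan object from vectors
#'
#' @param temperature Strictly increasing temperatures, degrees C.
#' @param signal Heat signal at each temperature (instrument units).
#' @inheritParams read_scan
#' @return A `tlb_scan` tibble.
#' @export
new_scan <- function(temperature, signal, sample_id = "scan",
                     role = "sample", scan_rate = 1) {
  if (length(temperature) != length(signal)) {
    abort("temperature and signal must have the same length")
  }
  if (any(!is.finite(temperature)) || any(!is.finite(signal))) {
    abort("temperature and signal must be finite")
  }
  if (any(diff(temperature) <= 0)) {
    abort("temperature must be strictly increasing")
  }
  out <- tibble(temperature = as.numeric(temperature),
                signal = as.numeric(signal))
  attr(out, "sample_id") <- sample_id
  attr(out, "role") <- role
  attr(out, "scan_rate") <- scan_rate
  class(out) <- c("tlb_scan", class(out))
  out
}

scan_meta <- function(scan) {
  list(sample_id = attr(scan, "sample_id") %||% "scan",
       role = attr(scan, "role") %||% "sample",
       scan_rate = attr(scan, "scan_rate") %||% 1)
}

rewrap_scan <- function(scan, signal, temperature = scan$temperature,
                        provenance_step = NULL) {
  m <- scan_meta(scan)
  out <- new_scan(temperature, signal, sample_id = m$sample_id,
                  role = m$role, scan_rate = m$scan_rate)
  prov <- c(attr(scan, "provenance") %||% list(), provenance_step)
  attr(out, "provenance") <- prov
  out
}

#' Subtract a buffer reference scan from a sample scan
#'
#' Instrument-baseline correction: the buffer scan is linearly interpolated
#' onto the sample's temperatures and subtracted pointwise. Sample points
#' outside the buffer's range are dropped, but the overlap must cover the
#' 45-90 degree analysis range.
#'
#' @param sample,buffer `tlb_scan` objects.
#' @return A `tlb_scan` with the buffer-corrected signal.
#' @export
subtract_buffer <- function(sample, buffer) {
  brange <- range(buffer$temperature)
  keep <- sample$temperature >= brange[[1]] & sample$temperature <= brange[[2]]
  kept <- sample$temperature[keep]
  if (length(kept) == 0 || min(kept) > 45 + 1e-9 || max(kept) < 90 - 1e-9) {
    abort("buffer scan does not cover the sample's 45-90 degree C range")
  }
  b <- approx(buffer$temperature, buffer$signal, xout = kept,
              method = "linear", ties = "ordered")$y
  rewrap_scan(sample, sample$signal[keep] - b, temperature = kept,
              provenance_step = list(buffer_id = scan_meta(buffer)$sample_id))
}

#' Normalize a scan for protein concentration
#'
#' Converts the buffer-corrected heat signal to heat capacity per gram of
#' protein by dividing by scan rate x concentration x cell volume. With the
#' instrument defaults (0.3 ml sensing volume, 1 degree C/min) this is the
#' standard excess-heat-capacity conversion.
#'
#' @param scan A `tlb_scan`.
#' @param protein_conc Protein concentration, mg/ml. Must be positive.
#' @param cell_volume Calorimeter cell volume, ml. Default 0.3.
#' @param scan_rate Scan rate, degrees C/min; defaults to the scan's own rate.
#' @return A `tlb_scan` whose signal is in heat-capacity-per-gram units.
#' @export
normalize_concentration <- function(scan, protein_conc, cell_volume = 0.3,
                                    scan_rate = NULL) {
  scan_rate <- scan_rate %||% scan_meta(scan)$scan_rate
  if (!is.numeric(protein_conc) || protein_conc <= 0) {
    abort("protein_conc must be positive")
  }
  if (cell_volume <= 0) abort("cell_volume must be positive")
  if (scan_rate <= 0) abort("scan_rate must be positive")
  rewrap_scan(scan, scan$signal / (scan_rate * protein_conc * cell_volume),
              provenance_step = list(protein_conc = protein_conc,
                                     cell_volume = cell_volume,
                                     scan_rate = scan_rate))
}

#' Remove a linear sample baseline
#'
#' Fits the straight line through the (mean temperature, mean signal) points
#' of two anchor windows on the flat flanks of the thermogram and subtracts
#' it. After correction the mean signal within each anchor window is zero by
#' construction.
#'
#' @param scan A `tlb_scan`.
#' @param low_window,high_window Anchor windows `c(low, high)` in degrees C,
#'   inclusive; defaults 45-50 and 85-90, outside the three transition
#'   windows.
#' @return The baseline-corrected `tlb_scan`.
#' @export
linear_baseline_correct <- function(scan, low_window = c(45, 50),
                                    high_window = c(85, 90)) {
  anchor <- function(w) {
    idx <- scan$temperature >= w[[1]] & scan$temperature <= w[[2]]
    if (sum(idx) < 3) {
      abort(sprintf("anchor window [%g, %g] contains fewer than 3 points",
                    w[[1]], w[[2]]))
    }
    c(t = mean(scan$temperature[idx]), s = mean(scan$signal[idx]))
  }
  lo <- anchor(low_window)
  hi <- anchor(high_window)
  slope <- (hi[["s"]] - lo[["s"]]) / (hi[["t"]] - lo[["t"]])
  base <- lo[["s"]] + slope * (scan$temperature - lo[["t"]])
  rewrap_scan(scan, scan$signal - base,
              provenance_step = list(baseline_anchors =
                                       c(low_window, high_window)))
}

#' Interpolate a processed scan onto the standard analysis grid
#'
#' Linear interpolation onto the 451-point 45-90 degree C grid. Input points
#' that coincide with grid points are preserved exactly.
#'
#' @param scan A fully corrected `tlb_scan` covering at least 45-90 degrees C.
#' @param sample_id Optional identifier override.
#' @return A `tlb_thermogram` tibble with columns `temperature`, `cp_excess`.
#' @export
regrid <- function(scan, sample_id = NULL) {
  if (min(scan$temperature) > 45 + 1e-9 || max(scan$temperature) < 90 - 1e-9) {
    abort("scan does not cover the 45-90 degree C analysis range")
  }
  cp <- approx(scan$temperature, scan$signal, xout = tlb_grid(),
               method = "linear", ties = "ordered")$y
  new_thermogram(cp, sample_id = sample_id %||% scan_meta(scan)$sample_id,
                 provenance = attr(scan, "provenance") %||% list())
}

#' Construct a thermogram on the standard grid
#'
#' @param cp_excess Excess specific heat capacity, cal/(degC g), one value
#'   per point of [tlb_grid()].
#' @param sample_id Sample identifier.
#' @param provenance Optional list recording applied corrections.
#' @return A `tlb_thermogram` tibble.
#' @export
new_thermogram <- function(cp_excess, sample_id = "sample",
                           provenance = list()) {
  if (length(cp_excess) != 451L) {
    abort("cp_excess must have 451 values (one per grid point)")
  }
  if (any(!is.finite(cp_excess))) abort("cp_excess must be finite everywhere")
  out <- tibble(temperature = tlb_grid(), cp_excess = as.numeric(cp_excess))
  attr(out, "sample_id") <- sample_id
  attr(out, "provenance") <- provenance
  class(out) <- c("tlb_thermogram", class(out))
  out
}

#' Average replicate thermograms
#'
#' Duplicate scans of the same sample are combined by pointwise mean; the
#' replicate count and the maximum pointwise absolute spread are recorded in
#' the provenance (reported, not thresholded).
#'
#' @param reps List of `tlb_thermogram` objects on identical grids.
#' @return A single averaged `tlb_thermogram`.
#' @export
average_replicates <- function(reps) {
  if (!is.list(reps) || length(reps) == 0) {
    abort("reps must be a non-empty list of thermograms")
  }
  mats <- vapply(reps, function(r) r$cp_excess, numeric(451))
  mats <- matrix(mats, nrow = 451)
  spread <- if (ncol(mats) > 1) {
    max(apply(mats, 1, function(v) diff(range(v))))
  } else 0
  new_thermogram(rowMeans(mats),
                 sample_id = attr(reps[[1]], "sample_id") %||% "sample",
                 provenance = c(attr(reps[[1]], "provenance") %||% list(),
                                list(n_replicates = length(reps),
                                     max_replicate_spread = spread)))
}

#' Run the full preprocessing chain on one sample
#'
#' Buffer subtraction, concentration normalization, linear baseline
#' correction and regridding, in the standard order.
#'
#' @inheritParams subtract_buffer
#' @inheritParams normalize_concentration
#' @inheritParams linear_baseline_correct
#' @return A finalized `tlb_thermogram`.
#' @export
preprocess_scan <- function(sample, buffer, protein_conc, cell_volume = 0.3,
                            scan_rate = NULL, low_window = c(45, 50),
                            high_window = c(85, 90)) {
  sample |>
    subtract_buffer(buffer) |>
    normalize_concentration(protein_conc, cell_volume, scan_rate) |>
    linear_baseline_correct(low_window, high_window) |>
    regrid()
}

#' Write / read a finalized thermogram
#'
#' Thermograms are stored as a 451-row CSV with header
#' `temperature,cp_excess` plus a JSON sidecar (`<path>.json`) carrying the
#' sample id and provenance.
#'
#' @param tg A `tlb_thermogram`.
#' @param path CSV path to write.
#' @return `write_thermogram` returns `path` invisibly; `read_thermogram`
#'   returns the `tlb_thermogram`.
#' @export
write_thermogram <- function(tg, path) {
  readr::write_csv(tibble(temperature = tg$temperature,
                          cp_excess = tg$cp_excess), path)
  meta <- list(sample_id = attr(tg, "sample_id") %||% "sample",
               provenance = attr(tg, "provenance") %||% list())
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_thermogram
#' @export
read_thermogram <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list(sample_id = basename(path), provenance = list())
  if (!is_standard_grid(df$temperature)) {
    abort("thermogram file is not on the standard 45-90 x 0.1 grid")
  }
  new_thermogram(df$cp_excess, sample_id = meta$sample_id,
                 provenance = as.list(meta$provenance))
}
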