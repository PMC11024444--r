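#' The standard thermogram analysis grid
#'
#' All finalized thermograms live on a uniform temperature grid from 45.0 to
#' 90.0 degrees Celsius in steps of 0.1 (451 points). Every downstream stage
#' (metrics, profile bands, clustering) assumes this grid.
#'
#' @return Numeric vector of length 451: 45.0, 45.1, ..., 90.0.
#' @export
#' @examples
#' length(tlb_grid())
tlb_grid <- function() {
  round(seq(45, 90, by = 0.1), 1)
}

#' Default peak-search windows
#'
#' The three transition windows of plasma thermograms: a major transition at
#' 60-66 degrees C (Peak 1), a smaller transition at 67-73 (Peak 2), and a
#' shoulder at 73-81 (Peak 3). Windows are half-open `[low, high)` so the
#' shared 73 degree boundary belongs to Peak 3 only and every grid point falls
#' in at most one window.
#'
#' @return Named list of `c(low, high)` pairs for `peak1`, `peak2`, `peak3`.
#' @export
tlb_windows <- function() {
  list(peak1 = c(60, 66), peak2 = c(67, 73), peak3 = c(73, 81))
}

# Internal: does x equal the standard grid (exactly, up to fp tolerance)?
is_standard_grid <- function(x) {
  length(x) == 451L && max(abs(x - tlb_grid())) < 1e-8
}
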