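#' Synthetic multi-peak validation landscape
#'
#' Generates the benchmark surface used to validate the optimizer against a
#' known answer: a site-attribute surface built from five Gaussian bumps —
#' one tall peak at the grid center and four lower peaks at the corners that
#' act as local-optimum traps. The surface is normalized to `[0, 1]`, the
#' development layer is zero (site quality is carried by a single combined
#' surface) and every cell is configurable.
#'
#' With the default parameters the value at radius 20 from the center
#' (`exp(-20^2 / (2 * 20^2)) = 0.61` of the peak) exceeds the corner
#' amplitude 0.5, so the top-1250 cells by value form the central disk of
#' radius 20 on the default 200 x 200 grid: selecting `Q = 1250` cells makes
#' the central disk the known global optimum, while the corner bumps remain
#' attractive enough to trap purely greedy searches.
#'
#' @param n_rows,n_cols Grid size (default 200 x 200).
#' @param center_amplitude,center_sigma Height and width (in cells) of the
#'   central peak.
#' @param corner_amplitude,corner_sigma Height and width of the four corner
#'   peaks; must be lower than the central peak.
#' @return A [suitability_grid()] whose `eco` layer is the normalized
#'   surface.
#' @examples
#' g <- multipeak_surface(50, 50, center_sigma = 5, corner_sigma = 3)
#' which(g$eco == 1, arr.ind = TRUE)
#' @export
multipeak_surface <- function(n_rows = 200, n_cols = 200,
                              center_amplitude = 1, center_sigma = 20,
                              corner_amplitude = 0.5, corner_sigma = 10) {
  if (center_amplitude <= corner_amplitude || corner_amplitude <= 0)
    stop("need center_amplitude > corner_amplitude > 0", call. = FALSE)
  if (center_sigma <= 0 || corner_sigma <= 0)
    stop("sigmas must be positive", call. = FALSE)
  r <- matrix(seq_len(n_rows), n_rows, n_cols)
  c <- matrix(seq_len(n_cols), n_rows, n_cols, byrow = TRUE)
  bump <- function(amp, sig, r0, c0)
    amp * exp(-((r - r0)^2 + (c - c0)^2) / (2 * sig^2))
  ctr <- c((n_rows + 1) / 2, (n_cols + 1) / 2)
  surf <- bump(center_amplitude, center_sigma, ctr[1], ctr[2]) +
    bump(corner_amplitude, corner_sigma, 1, 1) +
    bump(corner_amplitude, corner_sigma, 1, n_cols) +
    bump(corner_amplitude, corner_sigma, n_rows, 1) +
    bump(corner_amplitude, corner_sigma, n_rows, n_cols)
  surf <- surf / max(surf)
  suitability_grid(eco = surf)
}

#' Circular reference mask
#'
#' Cells whose center lies within `radius` (Euclidean, in cell units) of
#' `center` are `TRUE`. Used as the known-optimum reference on the synthetic
#' landscape: the disk of radius 20 at the center of the default 200 x 200
#' surface.
#'
#' @param n_rows,n_cols Grid size.
#' @param center `(row, col)` of the disk center; defaults to the grid
#'   center `((n_rows + 1) / 2, (n_cols + 1) / 2)`.
#' @param radius Disk radius in cells.
#' @return A logical matrix.
#' @examples
#' sum(circle_mask(200, 200, radius = 20))  # about pi * 20^2
#' @export
circle_mask <- function(n_rows, n_cols, center = NULL, radius) {
  if (is.null(center)) center <- c((n_rows + 1) / 2, (n_cols + 1) / 2)
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  r <- matrix(seq_len(n_rows), n_rows, n_cols)
  c <- matrix(seq_len(n_cols), n_rows, n_cols, byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

#' Random zoning instance for property tests
#'
#' Draws independent uniform `[0, 1]` ecological and development layers and
#' blocks a random fraction of cells (non-configurable), giving an
#' unstructured instance for invariant and property testing.
#'
#' @param n_rows,n_cols Grid size.
#' @param blocked_fraction Expected fraction of non-configurable cells.
#' @return A [suitability_grid()].
#' @export
random_instance <- function(n_rows, n_cols, blocked_fraction = 0.1) {
  n <- n_rows * n_cols
  eco <- matrix(stats::runif(n), n_rows, n_cols)
  dev <- matrix(stats::runif(n), n_rows, n_cols)
  conf <- matrix(stats::runif(n) >= blocked_fraction, n_rows, n_cols)
  if (!any(conf)) conf[sample.int(n, 1)] <- TRUE
  suitability_grid(eco, dev, conf)
}
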