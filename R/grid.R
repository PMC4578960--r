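#' Raster problem instance for protected-area zoning
#'
#' Bundles the two normalized site-attribute layers and the eligibility mask
#' that define a zoning instance: per-cell ecological suitability (`eco`),
#' per-cell urban development potential (`dev`), and a logical `configurable`
#' mask marking the cells that may be allocated to protection at all.
#'
#' All layers must share the same dimensions. Both value layers must be
#' finite and lie in `[0, 1]`; out-of-range values are a hard error rather
#' than being clamped, so upstream normalization bugs surface immediately.
#' Cells with `NA` in either layer are forced non-configurable.
#'
#' Cells are addressed as 1-based `(row, col)` pairs with row 1 at the top of
#' the raster, matching R's matrix indexing.
#'
#' @param eco Numeric matrix of ecological suitability values in `[0, 1]`.
#' @param dev Numeric matrix of urban development potential in `[0, 1]`, same
#'   shape as `eco`. Defaults to all zeros (site quality carried entirely by
#'   `eco`, as on the synthetic validation surface).
#' @param configurable Logical matrix flagging cells eligible for protection.
#'   Defaults to all `TRUE` (minus `NA` cells).
#' @param meta Optional list of georeferencing metadata (`xllcorner`,
#'   `yllcorner`, `cellsize`, `nodata`) carried through to raster output.
#'
#' @return An object of class `"suitability_grid"`: a list with elements
#'   `eco`, `dev`, `configurable`, `n_rows`, `n_cols` and `meta`.
#' @examples
#' g <- suitability_grid(matrix(runif(25), 5, 5))
#' g$n_rows
#' @export
suitability_grid <- function(eco, dev = NULL, configurable = NULL, meta = NULL) {
  if (!is.matrix(eco) || !is.numeric(eco))
    stop("`eco` must be a numeric matrix", call. = FALSE)
  if (is.null(dev)) dev <- array(0, dim(eco))
  if (!is.matrix(dev) || !identical(dim(dev), dim(eco)))
    stop("`dev` must be a numeric matrix with the same shape as `eco`",
         call. = FALSE)
  if (is.null(configurable)) configurable <- array(TRUE, dim(eco))
  if (!identical(dim(configurable), dim(eco)))
    stop("`configurable` must have the same shape as `eco`", call. = FALSE)
  storage.mode(configurable) <- "logical"
  configurable[is.na(configurable)] <- FALSE
  configurable <- configurable & !is.na(eco) & !is.na(dev)

  for (nm in c("eco", "dev")) {
    v <- get(nm)[configurable]
    if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
      stop("`", nm, "` has values outside [0, 1] on configurable cells; ",
           "normalize the layer before building the grid", call. = FALSE)
  }
  # non-configurable cells never enter the objective; keep them finite
  eco[is.na(eco)] <- 0
  dev[is.na(dev)] <- 0

  structure(
    list(eco = eco, dev = dev, configurable = configurable,
         n_rows = nrow(eco), n_cols = ncol(eco),
         meta = meta %||% list(xllcorner = 0, yllcorner = 0,
                               cellsize = 1, nodata = -9999)),
    class = "suitability_grid")
}

#' @export
print.suitability_grid <- function(x, ...) {
  cat("Suitability grid: ", x$n_rows, " x ", x$n_cols, " cells, ",
      sum(x$configurable), " configurable\n", sep = "")
  cat(sprintf("  eco: [%.3f, %.3f]   dev: [%.3f, %.3f]\n",
              min(x$eco[x$configurable]), max(x$eco[x$configurable]),
              min(x$dev[x$configurable]), max(x$dev[x$configurable])))
  invisible(x)
}

#' Scalarization weights for the three zoning sub-objectives
#'
#' The zoning objective is the weighted sum
#' `w1 * Ecological + w2 * (1 - Development) + w3 * Compactness`,
#' with non-negative weights summing to one. `zoning_weights()` validates a
#' weight triple; all fitting functions also accept a plain numeric vector of
#' length 3, which is passed through the same validation.
#'
#' @param ecological Weight on mean ecological suitability of protected cells.
#' @param development Weight on one minus mean development potential.
#' @param compactness Weight on mean neighborhood-density compactness.
#' @return A named numeric vector of class `"zoning_weights"`.
#' @examples
#' zoning_weights(0.34, 0.33, 0.33)
#' @export
zoning_weights <- function(ecological, development, compactness) {
  w <- c(ecological = ecological, development = development,
         compactness = compactness)
  if (any(!is.finite(w)) || any(w < 0))
    stop("weights must be finite and non-negative", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-9)
    stop("weights must sum to 1 (got ", format(sum(w)), ")", call. = FALSE)
  structure(w, class = "zoning_weights")
}

# accept zoning_weights or plain length-3 numeric
check_weights <- function(w) {
  if (inherits(w, "zoning_weights")) return(unclass(w))
  if (!is.numeric(w) || length(w) != 3)
    stop("weights must be a length-3 numeric vector or zoning_weights()",
         call. = FALSE)
  unclass(zoning_weights(w[[1]], w[[2]], w[[3]]))
}

check_window <- function(window) {
  if (length(window) != 1 || window < 3 || window %% 2 != 1)
    stop("`window` must be a single odd integer >= 3", call. = FALSE)
  as.integer(window)
}

check_grid <- function(grid) {
  if (!inherits(grid, "suitability_grid"))
    stop("`grid` must be a suitability_grid", call. = FALSE)
  grid
}

check_solution <- function(solution, grid, Q = NULL, feasible = TRUE) {
  if (!is.matrix(solution) ||
      !identical(dim(solution), c(grid$n_rows, grid$n_cols)))
    stop("solution shape does not match the grid (",
         grid$n_rows, " x ", grid$n_cols, ")", call. = FALSE)
  storage.mode(solution) <- "logical"
  if (anyNA(solution)) stop("solution contains NA", call. = FALSE)
  if (feasible) {
    if (!is.null(Q) && sum(solution) != Q)
      stop("solution protects ", sum(solution), " cells but Q = ", Q,
           call. = FALSE)
    if (any(solution & !grid$configurable))
      stop("solution protects non-configurable cells", call. = FALSE)
  }
  solution
}

check_quota <- function(Q, grid) {
  Q <- as.integer(Q)
  if (length(Q) != 1 || is.na(Q) || Q < 1)
    stop("`Q` must be a positive integer", call. = FALSE)
  nconf <- sum(grid$configurable)
  if (Q > nconf)
    stop("quota Q = ", Q, " exceeds the ", nconf, " configurable cells",
         call. = FALSE)
  Q
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Truncated-window sums: S[i, j] = sum of M over the window x window block
# centered on (i, j), clipped at the borders.  Computed via a padded
# summed-area table, O(N).
window_sum <- function(M, window) {
  h <- (window - 1L) %/% 2L
  nr <- nrow(M); nc <- ncol(M)
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- apply(apply(M, 2L, cumsum), 1L, cumsum) |> t()
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  R2 <- r2 + 1L; C2 <- c2 + 1L
  S[R2, C2, drop = FALSE] - S[r1, C2, drop = FALSE] -
    S[R2, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
}

# row-major rank key for tie-breaking on an nr x nc grid (R matrices are
# column-major, so this is computed explicitly)
rm_order_key <- function(nr, nc) {
  idx <- seq_len(nr * nc)
  r <- (idx - 1L) %% nr
  c <- (idx - 1L) %/% nr
  r * nc + c
}

# site attribute score s_i = (w1*eco + w2*(1 - dev)) / (w1 + w2); the
# pattern-free part of the objective, used by pseudo-random initialization,
# poor-quality regions and the density-slicing baseline.  Falls back to a
# constant score when w1 + w2 = 0.
site_score <- function(grid, w) {
  w <- check_weights(w)
  sw <- w[1] + w[2]
  if (sw <= 0) return(array(1, dim(grid$eco)))
  (w[1] * grid$eco + w[2] * (1 - grid$dev)) / sw
}
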