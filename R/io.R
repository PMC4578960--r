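#' Read and write ESRI ASCII grid rasters
#'
#' Plain-text raster I/O in the ESRI ASCII grid (`.asc`) format: a six-line
#' header (`ncols`, `nrows`, `xllcorner`/`xllcenter`, `yllcorner`/
#' `yllcenter`, `cellsize`, optional `NODATA_value`) followed by rows of
#' values from the top (north) row down. Values equal to the nodata code are
#' returned as `NA`; [suitability_grid()] treats `NA` cells as
#' non-configurable.
#'
#' Matrix row 1 corresponds to the top raster row; indices are 1-based
#' `(row, col)`.
#'
#' @param path File path.
#' @return For `read_ascii_grid()`: a list with `values` (numeric matrix)
#'   and `meta` (list with `xllcorner`, `yllcorner`, `cellsize`, `nodata`).
#' @examples
#' f <- tempfile(fileext = ".asc")
#' write_ascii_grid(matrix(runif(12), 3, 4), f)
#' str(read_ascii_grid(f)$values)
#' @name ascii_grid
NULL

#' @rdname ascii_grid
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path))
    stop("cannot read raster: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows"))
    if (is.null(hdr[[k]]))
      stop("malformed ASCII grid header in ", path, call. = FALSE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ASCII grid ", path, " holds ", length(vals), " values, expected ",
         nr * nc, call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- hdr$nodata_value %||% -9999
  m[m == nodata] <- NA
  xll <- hdr$xllcorner %||% hdr$xllcenter %||% 0
  yll <- hdr$yllcorner %||% hdr$yllcenter %||% 0
  list(values = m,
       meta = list(xllcorner = xll, yllcorner = yll,
                   cellsize = hdr$cellsize %||% 1, nodata = nodata))
}

#' @rdname ascii_grid
#' @param values Numeric or logical matrix (row 1 = top row). `NA` cells are
#'   written as the nodata code.
#' @param meta Optional metadata list (as returned by `read_ascii_grid()`).
#' @param xllcorner,yllcorner,cellsize,nodata Header fields, overridden by
#'   `meta` when given.
#' @export
write_ascii_grid <- function(values, path, meta = NULL, xllcorner = 0,
                             yllcorner = 0, cellsize = 1, nodata = -9999) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (!is.null(meta)) {
    xllcorner <- meta$xllcorner %||% xllcorner
    yllcorner <- meta$yllcorner %||% yllcorner
    cellsize <- meta$cellsize %||% cellsize
    nodata <- meta$nodata %||% nodata
  }
  v <- values + 0  # logical -> numeric
  v[is.na(v)] <- nodata
  hdr <- c(paste("ncols", ncol(values)),
           paste("nrows", nrow(values)),
           paste("xllcorner", format(xllcorner, scientific = FALSE)),
           paste("yllcorner", format(yllcorner, scientific = FALSE)),
           paste("cellsize", format(cellsize, scientific = FALSE)),
           paste("NODATA_value", format(nodata, scientific = FALSE)))
  rows <- apply(v, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a raster layer by format
#'
#' Dispatches on the file extension. Only the plain-text ESRI ASCII grid
#' format (`.asc`, `.txt`) is supported; GeoTIFF input must be converted
#' (e.g. `gdal_translate -of AAIGrid in.tif out.asc`) before use.
#'
#' @param path File path.
#' @return As [read_ascii_grid()].
#' @export
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("asc", "txt", "grd")) return(read_ascii_grid(path))
  if (ext %in% c("tif", "tiff"))
    stop("GeoTIFF is not supported; convert ", path,
         " to ESRI ASCII grid first (gdal_translate -of AAIGrid)",
         call. = FALSE)
  stop("unrecognized raster format: ", path, call. = FALSE)
}

#' Build a zoning instance from raster files
#'
#' Reads the ecological-suitability and development-potential layers (and an
#' optional 0/1 eligibility mask), checks that shapes and georeferencing
#' agree, and assembles a [suitability_grid()]. Nodata cells in any layer
#' are non-configurable.
#'
#' @param eco_path,dev_path,mask_path Raster paths; `dev_path` and
#'   `mask_path` may be `NULL`.
#' @return A [suitability_grid()] carrying the input georeferencing in
#'   `$meta`.
#' @export
grid_from_rasters <- function(eco_path, dev_path = NULL, mask_path = NULL) {
  eco <- read_raster(eco_path)
  dev <- conf <- NULL
  for (p in c(dev_path, mask_path)) {
    lay <- read_raster(p)
    if (!identical(dim(lay$values), dim(eco$values)))
      stop("raster shape mismatch: ", p, " is ",
           paste(dim(lay$values), collapse = "x"), ", expected ",
           paste(dim(eco$values), collapse = "x"), call. = FALSE)
    if (abs(lay$meta$cellsize - eco$meta$cellsize) > 1e-9 ||
        abs(lay$meta$xllcorner - eco$meta$xllcorner) > 1e-6 ||
        abs(lay$meta$yllcorner - eco$meta$yllcorner) > 1e-6)
      stop("raster georeferencing mismatch: ", p, call. = FALSE)
    if (identical(p, dev_path)) dev <- lay$values else conf <- lay$values
  }
  if (!is.null(conf)) conf <- !is.na(conf) & conf != 0
  suitability_grid(eco$values, dev, conf, meta = eco$meta)
}

#' Write a protection solution as a binary raster
#'
#' Protected cells are written as 1, unprotected configurable cells as 0,
#' and (when a grid is supplied) non-configurable cells as the nodata code.
#'
#' @inheritParams objectives
#' @param path Output `.asc` path.
#' @param grid Optional [suitability_grid()] supplying georeferencing and
#'   the non-configurable mask.
#' @export
write_solution <- function(solution, path, grid = NULL) {
  v <- solution + 0
  meta <- NULL
  if (!is.null(grid)) {
    grid <- check_grid(grid)
    v[!grid$configurable] <- NA
    meta <- grid$meta
  }
  write_ascii_grid(v, path, meta = meta)
}

#' Weighted linear summation of normalized factor layers
#'
#' The standard multi-criteria map combiner: given factor layers normalized
#' to `[0, 1]` and non-negative weights summing to one, returns the per-cell
#' weighted sum. Used to rebuild ecological-suitability or
#' development-potential maps from criterion layers and a weight set (for
#' example, weights derived by the analytic hierarchy process).
#'
#' @param layers List of numeric matrices of identical shape with values in
#'   `[0, 1]`.
#' @param weights Numeric vector, one non-negative weight per layer, summing
#'   to 1 (within 1e-9).
#' @return A numeric matrix in `[0, 1]`.
#' @examples
#' a <- matrix(0, 2, 2); b <- matrix(1, 2, 2)
#' weighted_linear_summation(list(a, b), c(0.5, 0.5))
#' @export
weighted_linear_summation <- function(layers, weights) {
  if (!is.list(layers) || length(layers) == 0)
    stop("`layers` must be a non-empty list of matrices", call. = FALSE)
  if (length(weights) != length(layers))
    stop("need one weight per layer", call. = FALSE)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  dims <- dim(layers[[1]])
  out <- array(0, dims)
  for (k in seq_along(layers)) {
    l <- layers[[k]]
    if (!is.matrix(l) || !identical(dim(l), dims))
      stop("layer ", k, " shape mismatch", call. = FALSE)
    if (any(!is.na(l) & (l < 0 | l > 1)))
      stop("layer ", k, " has values outside [0, 1]", call. = FALSE)
    out <- out + weights[k] * l
  }
  out
}

#' Read a run configuration file
#'
#' Flat YAML key-value configuration for command-line runs. Recognized keys
#' mirror [abc_control()] (`SN`, `limit`, `mcn`, `window`,
#' `init_pseudo_prob`, `init_best_fraction`, `swap_range`, `p_rect`,
#' `p_best_alter`) plus `q`, `weights` (length 3), `seed`, `eco`, `dev`,
#' `mask`, `reference`, `out`. Unspecified keys fall back to the
#' [abc_control()] defaults.
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  cfg
}
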