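#' Overlay a solution against a reference mask
#'
#' Counts how many protected cells fall inside and outside a reference
#' protection mask (for instance the known circular optimum of the synthetic
#' landscape), reporting the non-matched share as a percentage of the quota.
#'
#' @inheritParams objectives
#' @param reference Logical matrix of reference cells, same shape as the
#'   solution.
#' @return An object of class `"overlay_report"`: a list with
#'   `matched_count`, `nonmatched_count`, `nonmatched_pct` and `Q`.
#' @examples
#' ref <- circle_mask(20, 20, radius = 5)
#' overlay_match(ref, ref)
#' @export
overlay_match <- function(solution, reference) {
  if (!is.matrix(solution) || !identical(dim(solution), dim(reference)))
    stop("solution and reference must be matrices of identical shape",
         call. = FALSE)
  storage.mode(solution) <- "logical"
  storage.mode(reference) <- "logical"
  Q <- sum(solution)
  if (Q == 0) stop("solution protects no cells", call. = FALSE)
  matched <- sum(solution & reference)
  structure(list(matched_count = matched,
                 nonmatched_count = Q - matched,
                 nonmatched_pct = 100 * (Q - matched) / Q,
                 Q = Q),
            class = "overlay_report")
}

#' @export
print.overlay_report <- function(x, ...) {
  cat(sprintf("Overlay: %d of %d protected cells match the reference (%.2f%% non-matched)\n",
              x$matched_count, x$Q, x$nonmatched_pct))
  invisible(x)
}

#' Overlap stability across repeated runs
#'
#' Measures how consistently repeated stochastic runs protect the same
#' cells: the percentage of the quota protected in *every* run, plus a
#' per-cell overlap-count raster (0 to `length(solutions)`) for mapping
#' partial agreement.
#'
#' Each run protects exactly `Q` cells, so the fully-overlapping area as a
#' fraction of `Q` is well-defined and permutation-invariant in the run
#' order.
#'
#' @param solutions A list of logical solution matrices of identical shape
#'   and quota.
#' @return A list of class `"run_overlap"`: `overlap_pct`, `counts` (integer
#'   matrix), `n_runs`, `Q`.
#' @examples
#' a <- circle_mask(10, 10, radius = 3)
#' run_overlap(list(a, a))$overlap_pct
#' @export
run_overlap <- function(solutions) {
  if (!is.list(solutions) || length(solutions) == 0)
    stop("`solutions` must be a non-empty list of solution matrices",
         call. = FALSE)
  dims <- dim(solutions[[1]])
  qs <- vapply(solutions, sum, 0)
  for (s in solutions)
    if (!is.matrix(s) || !identical(dim(s), dims))
      stop("all solutions must be matrices of identical shape", call. = FALSE)
  if (length(unique(qs)) != 1)
    stop("all solutions must protect the same number of cells", call. = FALSE)
  Q <- qs[[1]]
  counts <- Reduce(`+`, lapply(solutions, function(s) s + 0L))
  structure(list(
    overlap_pct = 100 * sum(counts == length(solutions)) / Q,
    counts = counts,
    n_runs = length(solutions),
    Q = Q), class = "run_overlap")
}

#' @export
print.run_overlap <- function(x, ...) {
  cat(sprintf("Run overlap: %.1f%% of %d cells protected in all %d runs\n",
              x$overlap_pct, x$Q, x$n_runs))
  invisible(x)
}

#' Land-use composition of a protection scheme
#'
#' Cross-tabulates a solution against a categorical land-use raster: for
#' each category the regional cell count, the protected and non-protected
#' counts, the composition of the protected and non-protected areas
#' (column percentages) and the protected share within each category (row
#' percentage).
#'
#' Per category, `protected + nonprotected = regional`, and the protected
#' counts sum to the quota.
#'
#' @inheritParams objectives
#' @param landuse Categorical matrix (factor, character or integer) of the
#'   same shape as the solution.
#' @param categories Optional vector fixing the category order (absent
#'   categories get zero rows).
#' @return A data frame with columns `landuse`, `regional`, `protected`,
#'   `nonprotected`, `pct_of_protected`, `pct_of_nonprotected`,
#'   `pct_protected_within`.
#' @examples
#' lu <- matrix(c("forest", "urban"), 4, 4)
#' sol <- matrix(c(TRUE, FALSE), 4, 4)
#' landuse_stats(sol, lu)
#' @export
landuse_stats <- function(solution, landuse, categories = NULL) {
  if (!is.matrix(solution) || !identical(dim(solution), dim(landuse)))
    stop("solution and landuse must be matrices of identical shape",
         call. = FALSE)
  storage.mode(solution) <- "logical"
  lv <- as.vector(landuse)
  cats <- categories %||% sort(unique(lv))
  f <- factor(lv, levels = cats)
  regional <- as.integer(table(f))
  protected <- as.integer(table(f[as.vector(solution)]))
  nonprot <- regional - protected
  tp <- sum(protected); tn <- sum(nonprot)
  data.frame(
    landuse = cats,
    regional = regional,
    protected = protected,
    nonprotected = nonprot,
    pct_of_protected = if (tp > 0) 100 * protected / tp else 0 * protected,
    pct_of_nonprotected = if (tn > 0) 100 * nonprot / tn else 0 * nonprot,
    pct_protected_within = ifelse(regional > 0, 100 * protected / regional, 0),
    stringsAsFactors = FALSE)
}
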