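# Cranio-caudal depth of the hematoma from its per-slice areas.
# C0 counts every hematoma-bearing slice; C1 weights each bearing slice
# 1, 0.5 or 0 by its area ratio to the reference (largest-area) slice,
# the slice-weighting convention introduced for the ABC/2 method by
# Kothari and colleagues.

#' Bundle per-slice measurements into a series
#'
#' @param slices list of [measure_slice()] results, one per axial slice in
#'   scan order, lesion-free slices included.
#' @param slice_thickness_mm slice thickness in mm (> 0). Values above
#'   5 mm trigger a warning: such scans were excluded from the study
#'   population this tool models.
#' @return An object of class `series_measurement`.
#' @export
series_measurement <- function(slices, slice_thickness_mm) {
  if (!length(slices)) stop("`slices` must be non-empty")
  if (!all(vapply(slices, inherits, logical(1), "slice_measurement")))
    stop("`slices` must be a list of slice_measurement objects")
  if (!is.numeric(slice_thickness_mm) || length(slice_thickness_mm) != 1L ||
      !is.finite(slice_thickness_mm) || slice_thickness_mm <= 0)
    stop("`slice_thickness_mm` must be a single positive number")
  if (slice_thickness_mm > 5)
    warning(sprintf("slice thickness %.3g mm exceeds 5 mm; depth estimates degrade on thick-slice scans",
                    slice_thickness_mm), call. = FALSE)
  structure(list(slices = slices,
                 slice_thickness_mm = as.numeric(slice_thickness_mm)),
            class = "series_measurement")
}

#' @export
print.series_measurement <- function(x, ...) {
  a <- series_areas(x)
  cat(sprintf("<series_measurement> %d slices (%d bearing), thickness %.3g mm\n",
              length(a), sum(a > 0), x$slice_thickness_mm))
  invisible(x)
}

#' Per-slice areas of a series
#' @param series a [series_measurement()].
#' @return numeric vector of areas in mm2, one per slice.
#' @export
series_areas <- function(series) {
  vapply(series$slices, function(s) s$area_mm2, numeric(1))
}

#' Indices of hematoma-bearing slices
#'
#' A slice is hematoma-bearing when its lesion area is positive. A gap
#' (lesion-free slice inside the lesion span) is permitted but flagged
#' with a warning, since it usually indicates segmentation noise.
#'
#' @param series a [series_measurement()].
#' @return integer vector of 1-based slice indices, in scan order.
#' @export
find_bearing_slices <- function(series) {
  stopifnot(inherits(series, "series_measurement"))
  idx <- which(series_areas(series) > 0)
  if (!length(idx))
    stop("no hematoma in volume: every slice is lesion-free", call. = FALSE)
  if (length(idx) > 1L && any(diff(idx) > 1L))
    warning("hematoma-bearing slices are non-contiguous", call. = FALSE)
  idx
}

#' Slice weight from its area ratio
#'
#' Weighting rule for the adjusted depth: a slice whose area exceeds 75%
#' of the reference slice counts as a full bearing slice (weight 1), one
#' in the 25-75% band counts as half (0.5), and one below 25% does not
#' count (0). Both band edges are read inclusively (exactly 0.25 or 0.75
#' gives 0.5); the thresholds are exposed for sensitivity analyses.
#'
#' @param ratio area ratio(s) to the reference slice, >= 0 (vectorised).
#' @param lower,upper band thresholds, defaults 0.25 and 0.75.
#' @return numeric vector of weights in {0, 0.5, 1}.
#' @export
#' @examples
#' weight_for_ratio(c(0.1, 0.5, 0.8))
weight_for_ratio <- function(ratio, lower = 0.25, upper = 0.75) {
  if (!is.numeric(ratio) || anyNA(ratio)) stop("`ratio` must be numeric")
  if (any(ratio < 0)) stop("`ratio` must be non-negative")
  ifelse(ratio > upper, 1, ifelse(ratio >= lower, 0.5, 0))
}

#' Unadjusted (C0) and adjusted (C1) maximum depth
#'
#' C0 is the slice thickness times the number of hematoma-bearing
#' slices. C1 is the thickness times the sum of per-slice weights, where
#' each bearing slice's weight follows [weight_for_ratio()] applied to
#' its area ratio against the reference slice. With the largest-area
#' slice as reference every ratio lies in `[0, 1]` and C1 <= C0.
#'
#' @param series a [series_measurement()].
#' @param reference_index slice index of the reference slice (must have
#'   positive area); defaults to the largest-area slice.
#' @return An object of class `depth_result`: list with
#'   `bearing_indices`, `area_ratios`, `weights` (per bearing slice),
#'   `C0_mm`, `C1_mm`, `reference_index`.
#' @export
#' @examples
#' # areas 3, 8, 10, 8, 2 at 5 mm thickness: C0 = 25 mm, C1 = 17.5 mm
compute_depths <- function(series, reference_index = NULL) {
  stopifnot(inherits(series, "series_measurement"))
  areas <- series_areas(series)
  bearing <- find_bearing_slices(series)
  if (is.null(reference_index)) reference_index <- bearing[which.max(areas[bearing])]
  if (reference_index < 1L || reference_index > length(areas) ||
      areas[reference_index] <= 0)
    stop("reference slice has zero lesion area", call. = FALSE)
  ratios <- areas[bearing] / areas[reference_index]
  w <- weight_for_ratio(ratios)
  th <- series$slice_thickness_mm
  structure(list(bearing_indices = bearing,
                 area_ratios = ratios,
                 weights = w,
                 C0_mm = th * length(bearing),
                 C1_mm = th * sum(w),
                 reference_index = as.integer(reference_index)),
            class = "depth_result")
}

#' @export
print.depth_result <- function(x, ...) {
  cat(sprintf("<depth_result> %d bearing slices, C0 %.2f mm, C1 %.2f mm\n",
              length(x$bearing_indices), x$C0_mm, x$C1_mm))
  invisible(x)
}

# Evaluate f with a private RNG stream; the global .Random.seed is
# restored afterwards.
.with_seed <- function(seed, f) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  f()
}

#' Select the two representative slices
#'
#' The first representative slice (source of A1, B1) is the slice with
#' the largest lesion area (earliest on exact ties). The second (source
#' of A2, B2) is the central hematoma-bearing slice: the middle element
#' of the ordered bearing list when their number is odd; with an even
#' number, the larger-area slice of the two middle ones, and on an exact
#' area tie a random choice between them, reproducible through `seed`.
#'
#' @param series a [series_measurement()].
#' @param seed integer seed used only for the central-slice tie-break;
#'   recorded in the result.
#' @return list with `largest_index`, `central_index`, `rng_seed`,
#'   class `representative_slices`.
#' @export
select_representative_slices <- function(series, seed = 0L) {
  stopifnot(inherits(series, "series_measurement"))
  areas <- series_areas(series)
  bearing <- find_bearing_slices(series)
  largest <- bearing[which.max(areas[bearing])]
  nb <- length(bearing)
  if (nb %% 2L == 1L) {
    central <- bearing[(nb + 1L) %/% 2L]
  } else {
    mid <- bearing[c(nb %/% 2L, nb %/% 2L + 1L)]
    a <- areas[mid]
    central <- if (a[1L] > a[2L]) mid[1L]
      else if (a[2L] > a[1L]) mid[2L]
      else .with_seed(seed, function() sample(mid, 1L))
  }
  structure(list(largest_index = as.integer(largest),
                 central_index = as.integer(central),
                 rng_seed = as.integer(seed)),
            class = "representative_slices")
}

#' @export
print.representative_slices <- function(x, ...) {
  cat(sprintf("<representative_slices> largest %d, central %d (seed %d)\n",
              x$largest_index, x$central_index, x$rng_seed))
  invisible(x)
}
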