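# The ABC/2 estimator family. A variation is a linear form
# a * (A * B * C / 1000) + b in mL, where A and B are the maximum length
# and maximum perpendicular width (mm) on a representative slice and C
# is one of the two depths (mm). Lengths stay in mm internally; the
# product is divided by 1000 so coefficients and intercepts live on the
# mL scale of the planimetry reference.

#' Define an ABC/2 variation
#'
#' @param name label, unique within a registry.
#' @param coefficient dimensionless slope a (> 0).
#' @param intercept_mL additive intercept b in mL.
#' @param length_source `"largest"` (A1, B1 from the largest-area slice)
#'   or `"central"` (A2, B2 from the central bearing slice).
#' @param depth_source `"C0"` (unadjusted) or `"C1"` (adjusted depth).
#' @return An object of class `variation_spec`.
#' @export
variation_spec <- function(name, coefficient, intercept_mL = 0,
                           length_source = c("largest", "central"),
                           depth_source = c("C0", "C1")) {
  if (!is.numeric(coefficient) || coefficient <= 0)
    stop("`coefficient` must be positive")
  structure(list(name = as.character(name),
                 coefficient = as.numeric(coefficient),
                 intercept_mL = as.numeric(intercept_mL),
                 length_source = match.arg(length_source),
                 depth_source = match.arg(depth_source)),
            class = "variation_spec")
}

#' @export
print.variation_spec <- function(x, ...) {
  src <- if (x$length_source == "largest") "A1*B1" else "A2*B2"
  b <- if (x$intercept_mL == 0) "" else sprintf(" %+.2f", x$intercept_mL)
  cat(sprintf("<variation_spec> %s: %.2f x %s*%s%s mL\n",
              x$name, x$coefficient, src, x$depth_source, b))
  invisible(x)
}

#' The eight study variations
#'
#' Variations 1-4 are the traditional half-product forms
#' (coefficient 0.5, no intercept) over the four length/depth source
#' combinations; 1'-4' are their regression-calibrated counterparts
#' (slopes 0.37, 0.65, 0.39, 0.65; intercepts -0.75, -1.04, -0.04,
#' -0.17 mL).
#'
#' @return Named list of [variation_spec()] objects in the order
#'   1, 2, 3, 4, 1p, 2p, 3p, 4p.
#' @export
variation_registry <- function() {
  list(
    `1`  = variation_spec("1",  0.5,  0,     "largest", "C0"),
    `2`  = variation_spec("2",  0.5,  0,     "largest", "C1"),
    `3`  = variation_spec("3",  0.5,  0,     "central", "C0"),
    `4`  = variation_spec("4",  0.5,  0,     "central", "C1"),
    `1p` = variation_spec("1p", 0.37, -0.75, "largest", "C0"),
    `2p` = variation_spec("2p", 0.65, -1.04, "largest", "C1"),
    `3p` = variation_spec("3p", 0.39, -0.04, "central", "C0"),
    `4p` = variation_spec("4p", 0.65, -0.17, "central", "C1"))
}

#' Simplified zero-intercept clinical forms
#'
#' The calibrated variations 2' and 4' have intercepts close to zero and
#' are often quoted without them for bedside use. These forms are
#' approximations of the fitted variations, not fits of their own.
#'
#' @return Named list of two [variation_spec()] objects.
#' @export
simplified_variations <- function() {
  list(`2s` = variation_spec("2s", 0.65, 0, "largest", "C1"),
       `4s` = variation_spec("4s", 0.65, 0, "central", "C1"))
}

#' Planimetry volume of a measured series
#'
#' The reference-standard volume: segmented lesion area summed over
#' slices, times the slice thickness (voxel counting), in mL.
#'
#' @param series a [series_measurement()].
#' @return volume in mL.
#' @export
planimetry_volume <- function(series) {
  stopifnot(inherits(series, "series_measurement"))
  find_bearing_slices(series)  # errors when the volume holds no lesion
  sum(series_areas(series)) * series$slice_thickness_mm / 1000
}

#' Evaluate one ABC/2 variation
#'
#' @param A,B in-plane length and width in mm (>= 0).
#' @param C depth in mm (>= 0).
#' @param spec a [variation_spec()]; defaults to the traditional ABC/2
#'   (coefficient 0.5, no intercept).
#' @return estimated volume in mL: `a * (A*B*C/1000) + b`.
#' @export
#' @examples
#' abc_estimate(20, 20, 20)  # 4 mL
abc_estimate <- function(A, B, C, spec = variation_spec("abc2", 0.5)) {
  stopifnot(inherits(spec, "variation_spec"))
  if (any(c(A, B, C) < 0) || anyNA(c(A, B, C)))
    stop("A, B and C must be non-negative")
  spec$coefficient * (A * B * C / 1000) + spec$intercept_mL
}

# Build a series_measurement by measuring every axial slice of a 3-D
# binary mask array (dims: row x col x slice).
.measure_series <- function(mask_volume, spacing, thickness) {
  if (length(dim(mask_volume)) != 3L) stop("`mask_volume` must be 3-D")
  slices <- lapply(seq_len(dim(mask_volume)[3L]), function(k) {
    measure_slice(slice_mask(mask_volume[, , k], spacing, slice_index = k))
  })
  series_measurement(slices, thickness)
}

#' Measure a case end to end
#'
#' Runs the whole measurement chain on a 3-D binary mask: per-slice
#' geometry, bearing-slice detection, representative-slice selection,
#' C0/C1 depths, the planimetry reference, the four A.B.C products and
#' every requested variation estimate.
#'
#' @param mask_volume 3-D logical/0-1 array (row x col x slice).
#' @param spacing in-plane mm per pixel, length 2 (row, col).
#' @param thickness slice thickness in mm.
#' @param variations list of [variation_spec()]; defaults to
#'   [variation_registry()].
#' @param seed seed for the central-slice tie-break.
#' @param case_id optional identifier carried into reports.
#' @return An object of class `case_record`: list with `case_id`,
#'   `planimetry_mL`, `A1_mm`, `B1_mm`, `A2_mm`, `B2_mm`, `C0_mm`,
#'   `C1_mm`, `products_mL` (named: A1B1C0, A1B1C1, A2B2C0, A2B2C1) and
#'   `estimates_mL` (named per variation).
#' @export
measure_case <- function(mask_volume, spacing, thickness,
                         variations = variation_registry(), seed = 0L,
                         case_id = NA) {
  series <- .measure_series(mask_volume, spacing, thickness)
  rep_slices <- select_representative_slices(series, seed = seed)
  depths <- compute_depths(series, reference_index = rep_slices$largest_index)
  s1 <- series$slices[[rep_slices$largest_index]]
  s2 <- series$slices[[rep_slices$central_index]]
  case_record(case_id = case_id,
              planimetry_mL = planimetry_volume(series),
              A1_mm = s1$max_length_mm, B1_mm = s1$max_width_mm,
              A2_mm = s2$max_length_mm, B2_mm = s2$max_width_mm,
              C0_mm = depths$C0_mm, C1_mm = depths$C1_mm,
              variations = variations,
              representative = rep_slices)
}

#' Assemble a case record from measured parameters
#'
#' Lower-level constructor used by [measure_case()] and by table-driven
#' workflows: given the six measured lengths it forms the four products
#' (in mL units, mm3/1000) and applies every variation.
#'
#' @param case_id identifier.
#' @param planimetry_mL reference volume in mL.
#' @param A1_mm,B1_mm,A2_mm,B2_mm,C0_mm,C1_mm measured lengths in mm.
#' @param variations list of [variation_spec()].
#' @param representative optional `representative_slices` echo.
#' @return object of class `case_record`.
#' @export
case_record <- function(case_id, planimetry_mL, A1_mm, B1_mm, A2_mm, B2_mm,
                        C0_mm, C1_mm, variations = variation_registry(),
                        representative = NULL) {
  lens <- c(A1_mm, B1_mm, A2_mm, B2_mm, C0_mm, C1_mm)
  if (any(lens < 0) || anyNA(lens)) stop("lengths must be non-negative")
  products <- c(A1B1C0 = A1_mm * B1_mm * C0_mm,
                A1B1C1 = A1_mm * B1_mm * C1_mm,
                A2B2C0 = A2_mm * B2_mm * C0_mm,
                A2B2C1 = A2_mm * B2_mm * C1_mm) / 1000
  est <- vapply(variations, function(sp) {
    p <- products[[paste0(if (sp$length_source == "largest") "A1B1" else "A2B2",
                          sp$depth_source)]]
    sp$coefficient * p + sp$intercept_mL
  }, numeric(1))
  names(est) <- vapply(variations, `[[`, character(1), "name")
  structure(list(case_id = case_id, planimetry_mL = planimetry_mL,
                 A1_mm = A1_mm, B1_mm = B1_mm, A2_mm = A2_mm, B2_mm = B2_mm,
                 C0_mm = C0_mm, C1_mm = C1_mm,
                 products_mL = products, estimates_mL = est,
                 representative = representative),
            class = "case_record")
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf("<case_record> %s: planimetry %.2f mL, A1 %.1f B1 %.1f A2 %.1f B2 %.1f C0 %.1f C1 %.1f mm\n",
              as.character(x$case_id), x$planimetry_mL,
              x$A1_mm, x$B1_mm, x$A2_mm, x$B2_mm, x$C0_mm, x$C1_mm))
  print(round(x$estimates_mL, 2))
  invisible(x)
}

#' @export
as.data.frame.case_record <- function(x, ...) {
  d <- data.frame(case_id = as.character(x$case_id),
                  planimetry = x$planimetry_mL,
                  A1_mm = x$A1_mm, B1_mm = x$B1_mm,
                  A2_mm = x$A2_mm, B2_mm = x$B2_mm,
                  C0_mm = x$C0_mm, C1_mm = x$C1_mm,
                  stringsAsFactors = FALSE)
  for (nm in names(x$products_mL)) d[[paste0("p_", nm)]] <- x$products_mL[[nm]]
  for (nm in names(x$estimates_mL)) d[[paste0("v", nm)]] <- x$estimates_mL[[nm]]
  d
}
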