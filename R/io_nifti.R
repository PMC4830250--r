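# Minimal NIfTI-1 mask I/O. Only what a binary segmentation carrier
# needs: single-file .nii or .nii.gz, 3-D volumes, the common integer /
# float datatypes, both endiannesses. Array convention throughout the
# package: [row, col, slice] = NIfTI dims 1..3, with pixdim 1..3 as
# (row spacing, col spacing, slice thickness) in mm.

.nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "numeric", size = 4L, signed = TRUE),
  `64`  = list(what = "numeric", size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE))

.open_conn <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a binary mask from a NIfTI-1 file
#'
#' Reads a 3-D (or trailing-singleton 4-D) NIfTI-1 volume and binarises
#' it: any voxel different from zero — or equal to `label` when one is
#' given — is lesion. Spacing and slice thickness come from the header
#' `pixdim` unless overridden. A thickness above 5 mm triggers a
#' warning (the thick-slice exclusion rule of the study population this
#' tool models).
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param spacing_override optional length-2 in-plane spacing (mm).
#' @param thickness_override optional slice thickness (mm).
#' @param label optional numeric label to select; default any non-zero.
#' @return list with `mask` (logical row x col x slice array), `spacing`
#'   (length 2, mm) and `thickness` (mm).
#' @export
read_mask_volume <- function(path, spacing_override = NULL,
                             thickness_override = NULL, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- .open_conn(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("not a NIfTI-1 file: header truncated")
  endian <- "little"
  if (readBin(hdr[1:4], "integer", 1L, 4L, endian = endian) != 348L) {
    endian <- "big"
    if (readBin(hdr[1:4], "integer", 1L, 4L, endian = endian) != 348L)
      stop("not a NIfTI-1 file: bad sizeof_hdr")
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file: bad magic")
  if (magic == "ni1") stop("two-file (.hdr/.img) NIfTI is not supported")
  dims <- readBin(hdr[41:56], "integer", 8L, 2L, endian = endian)
  ndim <- dims[1L]
  extra <- if (ndim > 3L) dims[5:(ndim + 1L)] else integer(0)
  if (ndim < 3L || any(extra > 1L))
    stop("volume is not 3-D (dim = ", paste(dims[2:(ndim + 1)], collapse = "x"), ")")
  d <- dims[2:4]
  datatype <- readBin(hdr[71:72], "integer", 1L, 2L, endian = endian)
  dt <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  pixdim <- readBin(hdr[77:108], "numeric", 8L, 4L, endian = endian)
  vox_offset <- readBin(hdr[109:112], "numeric", 1L, 4L, endian = endian)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(d)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop("NIfTI data truncated")
  vol <- array(vals, dim = d)
  mask <- if (is.null(label)) vol != 0 else vol == label
  spacing <- abs(pixdim[2:3])
  thickness <- abs(pixdim[4L])
  if (!is.null(spacing_override))
    spacing <- rep(as.numeric(spacing_override), length.out = 2L)
  if (!is.null(thickness_override)) {
    if (thickness > 0 && !isTRUE(all.equal(thickness_override, thickness)))
      warning(sprintf("overriding header thickness %.3g mm with %.3g mm",
                      thickness, thickness_override), call. = FALSE)
    thickness <- as.numeric(thickness_override)
  }
  if (any(spacing <= 0) || thickness <= 0)
    stop("non-positive voxel spacing; supply overrides")
  if (thickness > 5)
    warning(sprintf("slice thickness %.3g mm exceeds 5 mm", thickness),
            call. = FALSE)
  list(mask = mask, spacing = spacing, thickness = thickness)
}

#' Write a binary mask to a NIfTI-1 file
#'
#' Single-file NIfTI-1, uint8 data, gzip-compressed when the path ends
#' in `.gz`.
#'
#' @param mask 3-D logical/0-1 array (row x col x slice).
#' @param spacing in-plane mm per pixel (scalar or length 2).
#' @param thickness slice thickness in mm.
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask_volume <- function(mask, spacing, thickness, path) {
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3-D array")
  spacing <- rep(as.numeric(spacing), length.out = 2L)
  hdr <- raw(348L)
  put <- function(h, off, x, what, size) {
    b <- writeBin(x, raw(), size = size, endian = "little")
    h[(off + 1):(off + length(b))] <- b
    h
  }
  hdr <- put(hdr, 0L, 348L, "integer", 4L)
  hdr <- put(hdr, 40L, as.integer(c(3L, dim(mask), 1L, 1L, 1L, 1L)),
             "integer", 2L)
  hdr <- put(hdr, 70L, 2L, "integer", 2L)          # datatype uint8
  hdr <- put(hdr, 72L, 8L, "integer", 2L)          # bitpix
  hdr <- put(hdr, 76L, c(1, spacing, thickness, 0, 0, 0, 0), "numeric", 4L)
  hdr <- put(hdr, 108L, 352, "numeric", 4L)        # vox_offset
  hdr <- put(hdr, 112L, c(1, 0), "numeric", 4L)    # scl_slope/inter
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0L))
  con <- .open_conn(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con)                           # pad to vox_offset 352
  writeBin(as.integer(mask != 0), con, size = 1L, endian = "little")
  invisible(path)
}

#' Write a phantom as NIfTI mask plus JSON sidecar
#'
#' @param phantom a `phantom` (see [make_ellipsoid_phantom()]).
#' @param path output `.nii`/`.nii.gz`; the sidecar replaces the
#'   extension with `.json` and records the true volume and generator
#'   parameters.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom"))
  write_mask_volume(phantom$mask, phantom$spacing, phantom$thickness, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(true_volume_mL = phantom$true_volume_mL,
         spacing = phantom$spacing, thickness = phantom$thickness,
         spec = phantom$spec),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-case and summary reports
#'
#' The per-case table mirrors the study's cohort-table layout (one row
#' per case: planimetry then the variation estimates, plus measured
#' lengths and products when available); the summary mirrors its
#' per-variation accuracy table. Output is bit-stable for identical
#' inputs.
#'
#' @param records list of `case_record`s or a cohort data frame.
#' @param summary optional [summarize_cohort()] result.
#' @param dir output directory (created when absent).
#' @param format `"csv"` (always written) and/or `"json"`.
#' @return named character vector of the files written, invisibly.
#' @export
write_case_report <- function(records, summary = NULL, dir,
                              format = c("csv", "json")) {
  format <- match.arg(format, several.ok = TRUE)
  if (is.null(records) || (is.data.frame(records) && !nrow(records)) ||
      (!is.data.frame(records) && !length(records)))
    stop("`records` must be non-empty")
  tab <- if (is.data.frame(records)) records else cases_to_table(records)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- c(cases = file.path(dir, "cases.csv"))
  utils::write.csv(tab, out[["cases"]], row.names = FALSE)
  if (!is.null(summary)) {
    stopifnot(inherits(summary, "evaluation_summary"))
    out[["summary"]] <- file.path(dir, "summary.csv")
    utils::write.csv(summary$table, out[["summary"]], row.names = FALSE)
    if ("json" %in% format) {
      out[["summary_json"]] <- file.path(dir, "summary.json")
      jsonlite::write_json(
        list(n = summary$n, tie_policy = summary$tie_policy,
             table = summary$table,
             agreement = lapply(summary$agreement, function(a)
               a[c("mean_difference_mL", "sd_difference_mL",
                   "loa_low_mL", "loa_high_mL", "proportion_within_loa")])),
        out[["summary_json"]], auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(out)
}
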