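# Shape fixtures built in code: voxelized disks/ellipses, random blobs,
# and series stubs with prescribed per-slice areas.

disk_mask <- function(radius_px, n = 2 * radius_px + 5) {
  ctr <- (n + 1) / 2
  outer(1:n, 1:n, function(r, c) (r - ctr)^2 + (c - ctr)^2 <= radius_px^2)
}

# axis-aligned ellipse with semi-axes (a_row, a_col) in mm at `sp` mm/px
ellipse_mask <- function(a_row, a_col, sp) {
  n_r <- 2L * ceiling(a_row / sp) + 5L
  n_c <- 2L * ceiling(a_col / sp) + 5L
  cr <- (n_r + 1) / 2; cc <- (n_c + 1) / 2
  outer(1:n_r, 1:n_c, function(r, c)
    (((r - cr) * sp) / a_row)^2 + (((c - cc) * sp) / a_col)^2 <= 1)
}

# connected random blob: scattered seeds plus a few 4-neighbour dilations,
# largest component kept
random_blob <- function(n = 40, n_seeds = 50, n_dilate = 3) {
  m <- matrix(FALSE, n, n)
  lo <- ceiling(n * 0.3); hi <- floor(n * 0.7)
  m[cbind(sample(lo:hi, n_seeds, TRUE), sample(lo:hi, n_seeds, TRUE))] <- TRUE
  for (k in seq_len(n_dilate))
    m <- m | rbind(m[-1, ], FALSE) | rbind(FALSE, m[-n, ]) |
      cbind(m[, -1], FALSE) | cbind(FALSE, m[, -n])
  edhvol:::.largest_component(m)$mask
}

# series_measurement stub with prescribed areas (no geometry involved)
series_from_areas <- function(areas, thickness = 5) {
  slices <- lapply(seq_along(areas), function(i) {
    structure(list(area_mm2 = areas[i], max_length_mm = 0, max_width_mm = 0,
                   length_endpoints = NULL, width_anchor = NULL,
                   lesion_free = areas[i] == 0, slice_index = i),
              class = "slice_measurement")
  })
  series_measurement(slices, thickness)
}

# brute-force max pairwise distance over ALL foreground pixels (oracle)
brute_feret <- function(px, spacing) {
  fg <- which(px, arr.ind = TRUE)
  mm <- cbind(fg[, 1] * spacing[1], fg[, 2] * spacing[2])
  if (nrow(mm) < 2) return(0)
  max(stats::dist(mm))
}
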