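test_that("contour handles degenerate masks", {
  m <- matrix(FALSE, 5, 5)
  expect_error(extract_contour(slice_mask(m)), "no lesion")
  m[3, 3] <- TRUE
  expect_equal(unname(extract_contour(slice_mask(m))), matrix(c(3L, 3L), 1))
  sq <- matrix(FALSE, 5, 5); sq[2:4, 2:4] <- TRUE
  ct <- extract_contour(slice_mask(sq))
  expect_equal(nrow(ct), 8L)             # 3x3 square: center excluded
  expect_false(any(ct[, 1] == 3 & ct[, 2] == 3))
})

test_that("contour set equals the background-8-neighbour scan", {
  px <- disk_mask(20)
  ct <- extract_contour(slice_mask(px))
  bf <- which(edhvol:::.contour_set(px), arr.ind = TRUE)
  expect_setequal(paste(ct[, 1], ct[, 2]), paste(bf[, 1], bf[, 2]))
  # every contour pixel is foreground with a background 8-neighbour
  expect_true(all(px[ct]))
  set.seed(101)
  for (i in 1:10) {
    b <- random_blob()
    ct <- extract_contour(slice_mask(b))
    bf <- which(edhvol:::.contour_set(b), arr.ind = TRUE)
    expect_setequal(paste(ct[, 1], ct[, 2]), paste(bf[, 1], bf[, 2]))
  }
})

test_that("multiple components: largest wins with a warning", {
  m <- matrix(FALSE, 12, 12)
  m[2:7, 2:7] <- TRUE        # 36 px
  m[10:11, 10:11] <- TRUE    # 4 px island
  expect_warning(ct <- extract_contour(slice_mask(m)), "largest")
  expect_true(all(ct[, 1] <= 7))
  expect_warning(ms <- measure_slice(slice_mask(m)), "largest")
  expect_equal(ms$area_mm2, 36)          # island excluded from area too
})

test_that("max_length matches the exhaustive all-pixel oracle on random blobs", {
  set.seed(42)
  for (i in 1:50) {
    b <- random_blob(n = 36, n_seeds = sample(20:60, 1),
                     n_dilate = sample(1:3, 1))
    sp <- runif(2, 0.4, 1.5)
    ct <- extract_contour(slice_mask(b, sp))
    hull <- max_length(ct, sp)
    expect_identical(hull$length_mm, max_length(ct, sp, method = "brute")$length_mm)
    expect_equal(hull$length_mm, brute_feret(b, sp))
    # endpoints attain the reported distance
    e <- hull$endpoints
    d <- sqrt(sum((((e[1, ] - e[2, ]) * sp))^2))
    expect_equal(d, hull$length_mm)
  }
})

test_that("max_length degenerate cases", {
  one <- matrix(c(3L, 3L), 1)
  expect_equal(max_length(one, c(1, 1))$length_mm, 0)
  # disk radius 10 mm at 0.5 mm/px: diameter 20 mm within a pixel diagonal
  ct <- extract_contour(slice_mask(disk_mask(20), c(0.5, 0.5)))
  expect_lt(abs(max_length(ct, c(0.5, 0.5))$length_mm - 20), sqrt(2) * 0.5)
})

test_that("perpendicular width: disk, ellipse, segment", {
  sp <- c(0.5, 0.5)
  ct <- extract_contour(slice_mask(disk_mask(20), sp))
  ml <- max_length(ct, sp)
  w <- max_perpendicular_width(ct, ml$endpoints, sp)
  expect_lt(abs(w$width_mm - 20), sqrt(2) * 0.5)
  # ellipse semi-axes 20 x 10 mm: length about 40, width about 20.
  # Oracle: densely scan chords of the analytic ellipse perpendicular to
  # the major axis; the longest is twice the minor semi-axis.
  xs <- seq(-20, 20, by = 0.01)
  chord <- 2 * 10 * sqrt(pmax(0, 1 - (xs / 20)^2))
  expect_equal(max(chord), 20)
  spe <- 0.25
  me <- measure_slice(slice_mask(ellipse_mask(10, 20, spe), c(spe, spe)))
  expect_lt(abs(me$max_length_mm - 40), sqrt(2) * spe)
  expect_lt(abs(me$max_width_mm - max(chord)), sqrt(2) * spe)
  # 1-pixel-wide straight segment has no transverse extent
  seg <- matrix(FALSE, 5, 9); seg[3, 2:8] <- TRUE
  ms <- measure_slice(slice_mask(seg))
  expect_equal(ms$max_width_mm, 0)
  expect_equal(ms$max_length_mm, 6)
})

test_that("measure_slice: area, empty and single-pixel rules", {
  sq <- matrix(TRUE, 10, 10)
  expect_equal(measure_slice(slice_mask(sq, c(1, 1)))$area_mm2, 100)
  me <- measure_slice(slice_mask(matrix(FALSE, 4, 4)))
  expect_true(me$lesion_free)
  expect_equal(me$area_mm2, 0)
  one <- matrix(FALSE, 3, 3); one[2, 2] <- TRUE
  m1 <- measure_slice(slice_mask(one, c(0.7, 0.9)))
  expect_equal(m1$area_mm2, 0.63)
  expect_equal(m1$max_length_mm, 0)
  expect_equal(m1$max_width_mm, 0)
  # ellipse area approaches the analytic value at fine spacing
  spe <- 0.25
  me2 <- measure_slice(slice_mask(ellipse_mask(10, 20, spe), c(spe, spe)))
  expect_lt(abs(me2$area_mm2 - pi * 20 * 10) / (pi * 20 * 10), 0.01)
})

test_that("width never exceeds length; rotations/flips and spacing scale", {
  set.seed(7)
  for (i in 1:20) {
    b <- random_blob()
    sp <- runif(2, 0.5, 1.2)
    ms <- measure_slice(slice_mask(b, sp))
    expect_lte(ms$max_width_mm, ms$max_length_mm)
  }
  b <- random_blob()
  sp <- c(0.8, 0.5)
  ms <- measure_slice(slice_mask(b, sp))
  tol <- sqrt(sum(sp^2))
  rot <- t(b)[, nrow(b):1]                     # 90 degrees
  mr <- measure_slice(slice_mask(rot, rev(sp)))
  expect_equal(mr$area_mm2, ms$area_mm2)
  expect_lt(abs(mr$max_length_mm - ms$max_length_mm), 1e-9)
  expect_lt(abs(mr$max_width_mm - ms$max_width_mm), tol)
  fl <- b[nrow(b):1, ]                         # row flip
  mf <- measure_slice(slice_mask(fl, sp))
  expect_lt(abs(mf$max_length_mm - ms$max_length_mm), 1e-9)
  expect_lt(abs(mf$max_width_mm - ms$max_width_mm), tol)
  # spacing scaling: lengths scale by k, area by k^2, exactly
  k <- 3.5
  mk <- measure_slice(slice_mask(b, sp * k))
  expect_equal(mk$max_length_mm, k * ms$max_length_mm)
  expect_equal(mk$max_width_mm, k * ms$max_width_mm)
  expect_equal(mk$area_mm2, k^2 * ms$area_mm2)
})
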