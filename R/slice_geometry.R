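# Per-slice shape measurement on binary hematoma masks: area, maximum
# length (largest pixel-center distance, the maximum Feret diameter) and
# maximum perpendicular width (longest chord at right angles to the
# length axis). All distances are between pixel centers in physical mm;
# anisotropic in-plane spacing is supported.

#' Construct a single-slice binary mask
#'
#' Wraps one axial slice of a segmentation together with its in-plane
#' pixel spacing. Any non-zero / `TRUE` entry is treated as lesion.
#'
#' @param pixels logical or 0/1 numeric matrix (rows x cols).
#' @param spacing numeric length-2, mm per pixel along (row, col). Both
#'   must be strictly positive.
#' @param slice_index optional ordinal position of the slice in its
#'   axial stack (1-based).
#' @return An object of class `slice_mask`.
#' @export
#' @examples
#' m <- slice_mask(matrix(1, 3, 3), spacing = c(0.5, 0.5))
#' measure_slice(m)
slice_mask <- function(pixels, spacing = c(1, 1), slice_index = NA_integer_) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (anyNA(pixels)) stop("`pixels` must not contain NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 2L)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be two strictly positive values (mm/pixel)")
  structure(
    list(pixels = pixels != 0,
         spacing_row = spacing[1L], spacing_col = spacing[2L],
         slice_index = as.integer(slice_index)),
    class = "slice_mask")
}

#' @export
print.slice_mask <- function(x, ...) {
  cat(sprintf("<slice_mask> %d x %d px, spacing %.3g x %.3g mm, %d foreground\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing_row, x$spacing_col,
              sum(x$pixels)))
  invisible(x)
}

# 8-neighbour offsets, clockwise starting west (used by the Moore trace)
.moore_dirs <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                     c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))

# Label the 8-connected foreground components by frontier BFS; returns the
# logical mask of the largest component and the component count.
.largest_component <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  lab <- integer(length(px))
  ncomp <- 0L
  for (seed in which(px)) {
    if (lab[seed] != 0L) next
    ncomp <- ncomp + 1L
    lab[seed] <- ncomp
    frontier <- seed
    while (length(frontier)) {
      r <- ((frontier - 1L) %% nr) + 1L
      co <- ((frontier - 1L) %/% nr) + 1L
      nxt <- integer(0)
      for (d in seq_len(8L)) {
        dr <- .moore_dirs[d, 1L]; dc <- .moore_dirs[d, 2L]
        ok <- r + dr >= 1L & r + dr <= nr & co + dc >= 1L & co + dc <= nc
        nb <- frontier[ok] + dr + dc * nr
        nxt <- c(nxt, nb[px[nb] & lab[nb] == 0L])
      }
      nxt <- unique(nxt)
      lab[nxt] <- ncomp
      frontier <- nxt
    }
  }
  keep <- px
  if (ncomp > 1L) {
    sizes <- tabulate(lab, ncomp)
    keep[] <- FALSE
    keep[lab == which.max(sizes)] <- TRUE
  }
  list(mask = keep, n_components = ncomp)
}

# Foreground pixels with at least one background 8-neighbour (grid edge
# counts as background). Vectorised via a padded matrix.
.contour_set <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- px
  interior <- pad[2:(nr + 1L), 2:(nc + 1L)]
  for (d in seq_len(8L)) {
    dr <- .moore_dirs[d, 1L]; dc <- .moore_dirs[d, 2L]
    interior <- interior & pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  px & !interior
}

# Moore-neighbour boundary tracing with Jacob's stopping criterion
# (terminate on re-entering the start pixel in the starting state).
# Returns an n x 2 integer matrix of (row, col), ordered along the outer
# boundary, duplicates removed (first visit kept).
.trace_boundary <- function(px) {
  nr <- nrow(px); nc <- ncol(px)
  fg <- which(px, arr.ind = TRUE)
  fg <- fg[order(fg[, 1L], fg[, 2L]), , drop = FALSE]
  s <- as.integer(fg[1L, ])
  if (nrow(fg) == 1L)
    return(matrix(s, 1L, 2L, dimnames = NULL))
  path <- matrix(0L, 8L * nrow(fg) + 8L, 2L)
  path[1L, ] <- s
  np <- 1L
  cur <- s
  bdir <- 1L  # direction from cur to its backtrack pixel; west of the
              # scan-order start pixel is background by construction
  seen <- new.env(hash = TRUE, parent = emptyenv())
  repeat {
    # the walk is deterministic in (pixel, backtrack direction): a
    # repeated state closes the boundary loop
    skey <- paste0(cur[1L], ",", cur[2L], ",", bdir)
    if (!is.null(seen[[skey]])) break
    seen[[skey]] <- TRUE
    hit <- 0L
    for (k in seq_len(8L)) {       # clockwise, starting after backtrack
      d <- ((bdir - 1L + k) %% 8L) + 1L
      r <- cur[1L] + .moore_dirs[d, 1L]
      cc <- cur[2L] + .moore_dirs[d, 2L]
      if (r >= 1L && r <= nr && cc >= 1L && cc <= nc && px[r, cc]) {
        hit <- d
        break
      }
    }
    if (hit == 0L) break           # isolated pixel; handled above
    prev <- ((hit - 2L) %% 8L) + 1L        # background pixel just before
    pr <- cur[1L] + .moore_dirs[prev, 1L]
    pc <- cur[2L] + .moore_dirs[prev, 2L]
    cur <- c(cur[1L] + .moore_dirs[hit, 1L], cur[2L] + .moore_dirs[hit, 2L])
    bdir <- .dir_index(cur, c(pr, pc))
    if (np >= nrow(path)) break    # safety cap
    np <- np + 1L
    path[np, ] <- cur
  }
  path <- path[seq_len(np), , drop = FALSE]
  path[!duplicated(path), , drop = FALSE]
}

.dir_index <- function(from, to) {
  d <- c(to[1L] - from[1L], to[2L] - from[2L])
  for (k in seq_len(8L)) if (all(.moore_dirs[k, ] == d)) return(k)
  stop("pixels are not 8-adjacent")  # internal invariant
}

#' Extract the ordered outer contour of a mask slice
#'
#' Contour pixels are foreground pixels with at least one background
#' 8-neighbour (the grid edge counts as background); they are returned in
#' order along the outer boundary (Moore-neighbour tracing). When the
#' slice holds several 8-connected components only the largest is traced
#' and a warning is raised: a detached island is treated as segmentation
#' noise.
#'
#' @param mask a [slice_mask()].
#' @return Integer matrix with columns `row`, `col`, one contour pixel
#'   per row, ordered along the boundary.
#' @export
extract_contour <- function(mask) {
  stopifnot(inherits(mask, "slice_mask"))
  px <- mask$pixels
  if (!any(px)) stop("no lesion on slice: mask has no foreground pixel",
                     call. = FALSE)
  comp <- .largest_component(px)
  if (comp$n_components > 1L)
    warning(sprintf("slice has %d foreground components; measuring the largest only",
                    comp$n_components), call. = FALSE)
  px <- comp$mask
  .ordered_contour(px)$contour
}

# Traced boundary polygon plus the full contour set spliced into its
# order; `polygon` is the raw Moore path (a clean closed curve),
# `contour` the complete set of boundary pixels in boundary order.
.ordered_contour <- function(px) {
  poly <- .trace_boundary(px)
  ord <- poly
  # The Moore walk can skip pixels whose only background contact is
  # diagonal (inner step corners). Splice them into the traced order next
  # to an adjacent traced pixel so the returned set matches the full
  # "foreground with a background 8-neighbour" definition.
  set <- which(.contour_set(px), arr.ind = TRUE)
  key <- function(m) paste(m[, 1L], m[, 2L])
  extra <- set[!(key(set) %in% key(ord)), , drop = FALSE]
  if (nrow(extra)) {
    pos <- seq_len(nrow(ord))
    epos <- numeric(nrow(extra))
    for (j in seq_len(nrow(extra))) {
      p <- extra[j, ]
      adj <- which(abs(ord[, 1L] - p[1L]) <= 1L & abs(ord[, 2L] - p[2L]) <= 1L)
      if (!length(adj)) { epos[j] <- nrow(ord) + j; next }
      # prefer a gap whose successor is also adjacent to p
      nxt <- (adj %% nrow(ord)) + 1L
      both <- adj[abs(ord[nxt, 1L] - p[1L]) <= 1L & abs(ord[nxt, 2L] - p[2L]) <= 1L]
      i <- if (length(both)) both[1L] else adj[1L]
      epos[j] <- i + 0.5 + j * 1e-6
    }
    o <- order(c(pos, epos))
    ord <- rbind(ord, extra)[o, , drop = FALSE]
  }
  ord <- ord[!duplicated(ord), , drop = FALSE]
  dimnames(ord) <- list(NULL, c("row", "col"))
  dimnames(poly) <- list(NULL, c("row", "col"))
  list(contour = ord, polygon = poly)
}

# contour pixel centers in physical mm; column 1 = row axis, 2 = col axis
.to_mm <- function(coords, spacing) {
  cbind(coords[, 1L] * spacing[1L], coords[, 2L] * spacing[2L])
}

#' Maximum length (Feret diameter) of a contour
#'
#' The largest Euclidean distance, in physical mm, between any two
#' contour pixel centers. The farthest pair of a point set lies on its
#' convex hull, so the default path computes the hull first; a
#' brute-force path over all pairs is available and bit-identical.
#'
#' @param contour integer matrix of contour pixels (`row`, `col`), as
#'   returned by [extract_contour()].
#' @param spacing mm per pixel along (row, col).
#' @param method `"hull"` (default) or `"brute"`; both produce identical
#'   results, the hull path is faster.
#' @return list with `length_mm` and `endpoints` (2 x 2 matrix of pixel
#'   coordinates; on exact ties the lexicographically smallest pair).
#' @export
max_length <- function(contour, spacing = c(1, 1), method = c("hull", "brute")) {
  method <- match.arg(method)
  stopifnot(is.matrix(contour), nrow(contour) >= 1L)
  spacing <- rep(as.numeric(spacing), length.out = 2L)
  if (nrow(contour) == 1L)
    return(list(length_mm = 0,
                endpoints = contour[c(1L, 1L), , drop = FALSE]))
  pts <- contour
  if (method == "hull" && nrow(contour) > 3L) {
    mm <- .to_mm(contour, spacing)
    h <- tryCatch(grDevices::chull(mm[, 1L], mm[, 2L]), error = function(e) NULL)
    if (!is.null(h) && length(h) >= 2L) pts <- contour[h, , drop = FALSE]
  }
  mm <- .to_mm(pts, spacing)
  n <- nrow(mm)
  dx <- outer(mm[, 1L], mm[, 1L], "-")
  dy <- outer(mm[, 2L], mm[, 2L], "-")
  d <- sqrt(dx * dx + dy * dy)
  best <- max(d)
  hits <- which(d == best, arr.ind = TRUE)
  # order each pair, then pick the lexicographically smallest pair
  pairs <- t(apply(hits, 1L, function(ij) {
    a <- pts[ij[1L], ]; b <- pts[ij[2L], ]
    if (a[1L] > b[1L] || (a[1L] == b[1L] && a[2L] > b[2L])) c(b, a) else c(a, b)
  }))
  pairs <- unique(pairs)
  o <- order(pairs[, 1L], pairs[, 2L], pairs[, 3L], pairs[, 4L])
  p <- pairs[o[1L], ]
  ep <- rbind(p[1:2], p[3:4])
  storage.mode(ep) <- "integer"
  colnames(ep) <- c("row", "col")
  list(length_mm = best, endpoints = ep)
}

#' Maximum width perpendicular to the length axis
#'
#' For every contour pixel, the full line through its center and
#' perpendicular (in physical coordinates) to the maximum-length
#' direction is intersected with the closed polygon through the ordered
#' contour pixel centers; the farthest intersection from the pixel gives
#' that pixel's chord. The maximum over all contour pixels is the width.
#' On concave outlines the farthest of multiple crossings is used, which
#' maximises the chord.
#'
#' @inheritParams max_length
#' @param endpoints 2 x 2 matrix of the length-axis endpoints (pixel
#'   coordinates), from [max_length()].
#' @param polygon optional ordered pixel matrix defining the closed
#'   boundary polygon the cast lines are intersected with; defaults to
#'   `contour`. [measure_slice()] passes the raw traced boundary here,
#'   which keeps the width exactly invariant under grid rotations.
#' @return list with `width_mm` and `anchor` (pixel coordinate attaining
#'   the width).
#' @export
max_perpendicular_width <- function(contour, endpoints, spacing = c(1, 1),
                                    polygon = contour) {
  stopifnot(is.matrix(contour), nrow(contour) >= 1L)
  spacing <- rep(as.numeric(spacing), length.out = 2L)
  if (nrow(contour) < 3L || nrow(polygon) < 3L)
    return(list(width_mm = 0, anchor = contour[1L, ]))
  e <- .to_mm(endpoints, spacing)
  u <- e[2L, ] - e[1L, ]
  nu <- sqrt(sum(u^2))
  if (nu == 0) return(list(width_mm = 0, anchor = contour[1L, ]))
  v <- c(-u[2L], u[1L]) / nu  # unit perpendicular
  anchors <- .to_mm(contour, spacing)
  poly <- .to_mm(polygon, spacing)
  p1 <- poly
  p2 <- poly[c(seq_len(nrow(poly))[-1L], 1L), , drop = FALSE]
  ex <- p2[, 1L] - p1[, 1L]
  ey <- p2[, 2L] - p1[, 2L]
  cv <- v[1L] * ey - v[2L] * ex          # cross(v, edge)
  eps <- 1e-12 * max(1, nu)
  best <- 0; anchor <- 1L
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    wx <- p1[, 1L] - a[1L]
    wy <- p1[, 2L] - a[2L]
    # line: a + t v ; edge: p1 + s (p2 - p1)
    num_t <- wx * ey - wy * ex
    num_s <- wx * v[2L] - wy * v[1L]
    par <- abs(cv) < eps
    t <- num_t / cv
    s <- -num_s / cv
    ok <- !par & s >= -1e-9 & s <= 1 + 1e-9
    tmax <- if (any(ok)) max(abs(t[ok])) else 0
    # edges collinear with the cast line contribute their endpoints
    col_edges <- par & abs(wx * v[2L] - wy * v[1L]) < eps
    if (any(col_edges)) {
      tt <- c(wx[col_edges] * v[1L] + wy[col_edges] * v[2L],
              (p2[col_edges, 1L] - a[1L]) * v[1L] +
              (p2[col_edges, 2L] - a[2L]) * v[2L])
      tmax <- max(tmax, abs(tt))
    }
    if (tmax > best) { best <- tmax; anchor <- i }
  }
  list(width_mm = best, anchor = contour[anchor, ])
}

#' Measure one slice: area, maximum length, maximum perpendicular width
#'
#' The slice-level primitives combined: area is the foreground pixel
#' count times the pixel area; the length and width are measured on the
#' ordered outer contour. An empty slice yields a lesion-free record with
#' all measurements zero; a single-pixel lesion has positive area but
#' zero lengths.
#'
#' @param mask a [slice_mask()].
#' @return An object of class `slice_measurement`: list with `area_mm2`,
#'   `max_length_mm`, `max_width_mm`, `length_endpoints`, `width_anchor`,
#'   `lesion_free`, `slice_index`.
#' @export
measure_slice <- function(mask) {
  stopifnot(inherits(mask, "slice_mask"))
  sp <- c(mask$spacing_row, mask$spacing_col)
  n_fg <- sum(mask$pixels)
  if (n_fg == 0L) {
    return(structure(list(area_mm2 = 0, max_length_mm = 0, max_width_mm = 0,
                          length_endpoints = NULL, width_anchor = NULL,
                          lesion_free = TRUE, slice_index = mask$slice_index),
                     class = "slice_measurement"))
  }
  comp <- .largest_component(mask$pixels)
  if (comp$n_components > 1L) {
    warning(sprintf("slice has %d foreground components; measuring the largest only",
                    comp$n_components), call. = FALSE)
    # area counts the measured component only, consistent with the lengths
    n_fg <- sum(comp$mask)
  }
  pieces <- .ordered_contour(comp$mask)
  len <- max_length(pieces$contour, sp)
  wid <- max_perpendicular_width(pieces$contour, len$endpoints, sp,
                                 polygon = pieces$polygon)
  w <- min(wid$width_mm, len$length_mm)  # guard numeric eps on the invariant
  structure(list(area_mm2 = n_fg * sp[1L] * sp[2L],
                 max_length_mm = len$length_mm,
                 max_width_mm = w,
                 length_endpoints = len$endpoints,
                 width_anchor = wid$anchor,
                 lesion_free = FALSE,
                 slice_index = mask$slice_index),
            class = "slice_measurement")
}

#' @export
print.slice_measurement <- function(x, ...) {
  if (x$lesion_free) cat("<slice_measurement> lesion-free\n")
  else cat(sprintf("<slice_measurement> area %.2f mm2, A %.2f mm, B %.2f mm\n",
                   x$area_mm2, x$max_length_mm, x$max_width_mm))
  invisible(x)
}
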