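# Geometry model for synthetic scenes and small polygon utilities.
#
# Coordinate conventions (package-wide): 0-based pixel indices, pixel-center
# convention, x = column, y = row, origin at the top-left pixel center.
# Polygons are closed implicitly (last vertex != first).

#' Geometry constants of the synthetic scene model
#'
#' Desk-scale geometry used by [build_scene()]: SEM pixel size 50 nm (a
#' 1024 px frame spans ~51 um so the SEM:NanoSIMS resolution ratio is ~4x),
#' elliptical cell bodies ~9-12 um across, a concentric nucleus at half the
#' cell axes, and organelle counts/sizes typical of a soma section. The same
#' constants drive the preset calibration (expected compartment area
#' fractions), so ground-truth compartment means and the area-weighted
#' whole-cell target stay mutually consistent.
#'
#' @param pixel_size_nm SEM pixel size in nm.
#' @return Named list of geometry parameters (sizes in SEM pixels).
#' @export
scene_geometry <- function(pixel_size_nm = 50) {
  list(
    pixel_size_nm = pixel_size_nm,
    cell_semi_axis_a = c(100, 120),   # uniform range, px
    cell_semi_axis_b = c(80, 100),
    nucleus_scale = 0.5,              # nucleus semi-axes / cell semi-axes
    nucleus_offset_frac = 0.12,       # max nucleus center offset / cell a
    nucleolus_radius = c(13, 1.5),    # mean, sd (px)
    n_mitochondria = 12L,
    mito_area = c(250, 40),           # mean, sd (px^2); area independent of aspect
    n_golgi = 3L,
    golgi_radius = c(16, 26),         # uniform range of arc radius (px)
    golgi_thickness = 10,             # px (~0.5 um ribbon width)
    golgi_span_deg = c(90, 150),      # uniform range of arc span
    n_lysosomes = 12L,
    lysosome_radius = c(7, 1),        # mean, sd (px)
    n_er = 8L,
    er_length = c(40, 8),             # mean, sd (px)
    er_width = 3,                     # px
    cell_margin_px = 30,              # clearance from the SEM frame edge
    min_cell_gap_px = 12
  )
}

# Expected compartment area fractions of a cell body under the geometry
# model; used to calibrate preset compartment means against the whole-cell
# target. `nucleolus_prob` enters because only a fraction of sections show
# the nucleolus.
design_area_fractions <- function(geom = scene_geometry(), nucleolus_prob = 0.3) {
  a_cell <- pi * mean(geom$cell_semi_axis_a) * mean(geom$cell_semi_axis_b)
  f_nuc_gross <- geom$nucleus_scale^2
  f_nll <- nucleolus_prob * pi * (geom$nucleolus_radius[1]^2 + geom$nucleolus_radius[2]^2) / a_cell
  f_mito <- geom$n_mitochondria * geom$mito_area[1] / a_cell
  span <- mean(geom$golgi_span_deg) * pi / 180
  f_golgi <- geom$n_golgi * geom$golgi_thickness * mean(geom$golgi_radius) * span / a_cell
  f_lys <- geom$n_lysosomes * pi * (geom$lysosome_radius[1]^2 + geom$lysosome_radius[2]^2) / a_cell
  f_er <- geom$n_er * geom$er_length[1] * geom$er_width / a_cell
  f_nuc <- f_nuc_gross - f_nll
  f_cyt <- 1 - f_nuc - f_nll - f_mito - f_golgi - f_lys - f_er
  c(cytoplasm = f_cyt, nucleus = f_nuc, nucleolus = f_nll,
    mitochondrion = f_mito, golgi = f_golgi, lysosome = f_lys, ER = f_er)
}

# Pixel-center coordinates (0-based) of an ellipse interior within an
# integer grid. Returns a two-column matrix of (row, col) 1-based indices.
ellipse_pixels <- function(cx, cy, a, b, theta, nrow, ncol) {
  half_w <- max(a, b)
  x0 <- max(0L, floor(cx - half_w)); x1 <- min(ncol - 1L, ceiling(cx + half_w))
  y0 <- max(0L, floor(cy - half_w)); y1 <- min(nrow - 1L, ceiling(cy + half_w))
  if (x1 < x0 || y1 < y0) return(cbind(row = integer(), col = integer()))
  xs <- x0:x1; ys <- y0:y1
  gx <- rep(xs, each = length(ys)) - cx
  gy <- rep(ys, times = length(xs)) - cy
  ct <- cos(theta); st <- sin(theta)
  u <- gx * ct + gy * st
  v <- -gx * st + gy * ct
  inside <- (u / a)^2 + (v / b)^2 <= 1
  cbind(row = rep(ys, times = length(xs))[inside] + 1L,
        col = rep(xs, each = length(ys))[inside] + 1L)
}

# Thick circular-arc ("ribbon") pixels: radius band [r - w/2, r + w/2],
# angular span `span` centered on `phi`.
arc_pixels <- function(cx, cy, r, w, phi, span, nrow, ncol) {
  half <- r + w / 2 + 1
  x0 <- max(0L, floor(cx - half)); x1 <- min(ncol - 1L, ceiling(cx + half))
  y0 <- max(0L, floor(cy - half)); y1 <- min(nrow - 1L, ceiling(cy + half))
  if (x1 < x0 || y1 < y0) return(cbind(row = integer(), col = integer()))
  xs <- x0:x1; ys <- y0:y1
  gx <- rep(xs, each = length(ys)) - cx
  gy <- rep(ys, times = length(xs)) - cy
  rad <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx)
  dang <- atan2(sin(ang - phi), cos(ang - phi))
  inside <- rad >= r - w / 2 & rad <= r + w / 2 & abs(dang) <= span / 2
  cbind(row = rep(ys, times = length(xs))[inside] + 1L,
        col = rep(xs, each = length(ys))[inside] + 1L)
}

# Rotated-rectangle pixels (length L along direction theta, width w).
rect_pixels <- function(cx, cy, L, w, theta, nrow, ncol) {
  half <- sqrt(L^2 + w^2) / 2 + 1
  x0 <- max(0L, floor(cx - half)); x1 <- min(ncol - 1L, ceiling(cx + half))
  y0 <- max(0L, floor(cy - half)); y1 <- min(nrow - 1L, ceiling(cy + half))
  if (x1 < x0 || y1 < y0) return(cbind(row = integer(), col = integer()))
  xs <- x0:x1; ys <- y0:y1
  gx <- rep(xs, each = length(ys)) - cx
  gy <- rep(ys, times = length(xs)) - cy
  ct <- cos(theta); st <- sin(theta)
  u <- gx * ct + gy * st
  v <- -gx * st + gy * ct
  inside <- abs(u) <= L / 2 & abs(v) <= w / 2
  cbind(row = rep(ys, times = length(xs))[inside] + 1L,
        col = rep(xs, each = length(ys))[inside] + 1L)
}

#' Test points against a simple polygon
#'
#' Even-odd crossing test with the package's boundary convention: points
#' exactly on a lower or left edge are inside, points on an upper or right
#' edge are outside, so abutting polygons tile the grid without double
#' counting.
#'
#' @param px,py Point coordinates (0-based pixel-center convention).
#' @param verts Two-column matrix of polygon vertices (x, y), implicitly
#'   closed.
#' @return Logical vector.
#' @export
point_in_polygon <- function(px, py, verts) {
  stopifnot(is.matrix(verts), ncol(verts) == 2, nrow(verts) >= 3)
  n <- nrow(verts)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- verts[j, 1]; y1 <- verts[j, 2]
    x2 <- verts[i, 1]; y2 <- verts[i, 2]
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xint <- (x2 - x1) * (py[crosses] - y1) / (y2 - y1) + x1
      hit <- px[crosses] < xint
      inside[crosses] <- xor(inside[crosses], hit)
    }
    j <- i
  }
  inside
}

# TRUE when any two non-adjacent polygon edges properly intersect or overlap
# (self-intersecting ring). O(n^2); polygons here are small.
polygon_self_intersects <- function(verts) {
  n <- nrow(verts)
  if (n < 4) return(FALSE)
  seg <- function(i) rbind(verts[i, ], verts[if (i == n) 1 else i + 1, ])
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through closure
      if (segments_intersect(seg(i), seg(j))) return(TRUE)
    }
  }
  FALSE
}

segments_intersect <- function(s1, s2) {
  d1 <- cross2(s2[1, ], s2[2, ], s1[1, ])
  d2 <- cross2(s2[1, ], s2[2, ], s1[2, ])
  d3 <- cross2(s1[1, ], s1[2, ], s2[1, ])
  d4 <- cross2(s1[1, ], s1[2, ], s2[2, ])
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(p, q, r) {
    min(p[1], q[1]) <= r[1] && r[1] <= max(p[1], q[1]) &&
      min(p[2], q[2]) <= r[2] && r[2] <= max(p[2], q[2])
  }
  (d1 == 0 && on_seg(s2[1, ], s2[2, ], s1[1, ])) ||
    (d2 == 0 && on_seg(s2[1, ], s2[2, ], s1[2, ])) ||
    (d3 == 0 && on_seg(s1[1, ], s1[2, ], s2[1, ])) ||
    (d4 == 0 && on_seg(s1[1, ], s1[2, ], s2[2, ]))
}

cross2 <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
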