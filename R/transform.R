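# Planar (affine) mapping between the SEM frame and the NanoSIMS raster.
#
# The NanoSIMS image is rotated relative to the SEM image and slightly
# stretched or squeezed by stage drift during the long acquisition; an
# affine transform (rotation + anisotropic scale + shear + translation,
# 6 dof) captures exactly this family. ROIs drawn on the SEM image are
# transported onto the native NanoSIMS grid; ion counts are never
# interpolated.

new_planar_transform <- function(M, rmse = 0, n_points = NA_integer_) {
  stopifnot(is.matrix(M), nrow(M) == 2, ncol(M) == 3)
  det <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  if (abs(det) < 1e-12) abort("transform is singular (|det| < 1e-12).")
  structure(list(M = M, rmse = rmse, n_points = n_points), class = "planar_transform")
}

#' @export
print.planar_transform <- function(x, ...) {
  cat("<planar_transform> SEM -> NanoSIMS\n")
  print(round(x$M, 6))
  cat(sprintf("  rmse = %.4g NanoSIMS px over %s points\n", x$rmse, x$n_points))
  invisible(x)
}

#' Apply a planar transform to points
#'
#' @param transform A `planar_transform`.
#' @param xy Two-column matrix (x, y), 0-based pixel-center coordinates.
#' @return Transformed coordinates, same shape.
#' @export
transform_points <- function(transform, xy) {
  stopifnot(inherits(transform, "planar_transform"))
  xy <- matrix(as.numeric(xy), ncol = 2)
  out <- xy %*% t(transform$M[, 1:2, drop = FALSE])
  out[, 1] <- out[, 1] + transform$M[1, 3]
  out[, 2] <- out[, 2] + transform$M[2, 3]
  out
}

#' Invert a planar transform
#'
#' @param transform A `planar_transform`.
#' @return The inverse `planar_transform` (NanoSIMS -> SEM).
#' @export
invert_transform <- function(transform) {
  L <- transform$M[, 1:2, drop = FALSE]
  t <- transform$M[, 3]
  Li <- solve(L)
  new_planar_transform(cbind(Li, -Li %*% t),
                       rmse = transform$rmse, n_points = transform$n_points)
}

#' Fit the SEM-to-NanoSIMS affine transform from landmarks
#'
#' Least-squares affine fit to user-matched reference points, minimizing the
#' summed squared residuals in the NanoSIMS frame. Requires at least three
#' non-collinear pairs; with exactly three the fit is exact (zero residual).
#'
#' @param points Data frame with columns `x_sem`, `y_sem`, `x_sims`,
#'   `y_sims` (0-based pixel coordinates), e.g. from
#'   [read_control_points()].
#' @return A `planar_transform` carrying the 2x3 coefficient matrix, the
#'   fit RMSE (NanoSIMS px) and the number of points used.
#' @export
fit_affine <- function(points) {
  points <- as.data.frame(points)
  need <- c("x_sem", "y_sem", "x_sims", "y_sims")
  missing <- setdiff(need, names(points))
  if (length(missing)) {
    abort(paste("control points lack columns:", paste(missing, collapse = ", ")))
  }
  n <- nrow(points)
  if (n < 3) abort("at least 3 control-point pairs are required to fit an affine transform.")
  X <- cbind(points$x_sem, points$y_sem, 1)
  qrX <- qr(X)
  if (qrX$rank < 3) {
    abort("control points are collinear (rank-deficient design); spread the landmarks.")
  }
  bx <- qr.coef(qrX, points$x_sims)
  by <- qr.coef(qrX, points$y_sims)
  M <- rbind(bx, by)
  dimnames(M) <- NULL
  pred <- X %*% t(M)
  res2 <- (points$x_sims - pred[, 1])^2 + (points$y_sims - pred[, 2])^2
  new_planar_transform(M, rmse = sqrt(mean(res2)), n_points = n)
}

#' Simulate user-clicked landmarks for a synthetic scene
#'
#' Draws reference points spread across the SEM frame, maps them through the
#' scene's true transform, and perturbs the SEM-side coordinates with
#' Gaussian jitter emulating manual localization error.
#'
#' @param transform_true True SEM -> NanoSIMS `planar_transform`.
#' @param sem_dim SEM frame dimension `c(nrow, ncol)`.
#' @param n Number of landmark pairs.
#' @param jitter_sem_px SD of the localization jitter, SEM pixels.
#' @return Tibble with `x_sem`, `y_sem`, `x_sims`, `y_sims`.
#' @export
make_landmarks <- function(transform_true, sem_dim, n = 12, jitter_sem_px = 0.25) {
  stopifnot(n >= 3)
  # stratified placement: reference points are deliberately spread across the
  # field, as a user matching recognizable structures would choose them
  margin <- 0.08
  k <- ceiling(sqrt(n))
  cells <- expand.grid(ix = seq_len(k), iy = seq_len(k))
  cells <- cells[sample.int(nrow(cells), n), , drop = FALSE]
  w <- (1 - 2 * margin) / k
  xs <- (margin + (cells$ix - runif(n)) * w) * sem_dim[2]
  ys <- (margin + (cells$iy - runif(n)) * w) * sem_dim[1]
  sims <- transform_points(transform_true, cbind(xs, ys))
  tibble(
    x_sem = xs + rnorm(n, 0, jitter_sem_px),
    y_sem = ys + rnorm(n, 0, jitter_sem_px),
    x_sims = sims[, 1], y_sims = sims[, 2]
  )
}

#' Transport an ROI onto the NanoSIMS grid
#'
#' Maps an SEM-frame ROI into the NanoSIMS frame and returns its pixel
#' footprint. Polygon ROIs are transformed vertex-wise and rasterized by the
#' pixel-center rule (lower/left boundary ties included); label-mask ROIs
#' are resolved by pulling every NanoSIMS pixel center back to the SEM frame
#' and testing membership in the referenced mask, which keeps the footprint
#' exactly consistent with how the instrument samples the scene.
#'
#' @param transform SEM -> NanoSIMS `planar_transform`.
#' @param roi A single ROI: a list with `class`, `cell_id` and `geometry`,
#'   where geometry is `list(type = "polygon", vertices = <n x 2 matrix>)`
#'   or `list(type = "label", organelle_id = <int or NA>)` (see
#'   [scene_rois()]).
#' @param grid_dim NanoSIMS grid `c(nrow, ncol)`.
#' @param scene Required for label-mask ROIs: the `silksims_scene` whose
#'   label images the ROI references.
#' @param interior_only For label-mask ROIs: restrict the footprint to
#'   interior mask pixels (4-neighbourhood uniform), so that sub-pixel
#'   registration error cannot misassign boundary pixels between adjacent
#'   compartments. On by default; boundary pixels carry mixed signal in any
#'   real acquisition and are excluded from quantification.
#' @return List with `pixels` (two-column matrix of 1-based (row, col)
#'   NanoSIMS indices), `outside_fraction` (fraction of the ROI mapping
#'   outside the grid) and `empty`.
#' @export
map_roi <- function(transform, roi, grid_dim, scene = NULL, interior_only = TRUE) {
  geom <- roi$geometry
  # a row taken from an ROI tibble wraps the geometry in a one-element list
  if (is.null(geom$type) && is.list(geom) && length(geom) == 1) geom <- geom[[1]]
  if (identical(geom$type, "polygon")) {
    verts <- geom$vertices
    vs <- transform_points(transform, verts)
    # candidate pixel centers over the transformed bbox (unclipped, so the
    # outside fraction can be measured)
    x0 <- floor(min(vs[, 1])); x1 <- ceiling(max(vs[, 1]))
    y0 <- floor(min(vs[, 2])); y1 <- ceiling(max(vs[, 2]))
    xs <- x0:x1; ys <- y0:y1
    px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
    inside <- point_in_polygon(px, py, vs)
    px <- px[inside]; py <- py[inside]
    ingrid <- px >= 0 & px <= grid_dim[2] - 1 & py >= 0 & py <= grid_dim[1] - 1
    n_tot <- length(px)
    pixels <- cbind(row = py[ingrid] + 1L, col = px[ingrid] + 1L)
    outside <- if (n_tot == 0) 1 else 1 - sum(ingrid) / n_tot
  } else if (identical(geom$type, "label")) {
    if (is.null(scene)) abort("label-mask ROIs need the `scene` that defines them.")
    sam <- sims_to_sem_index(transform, grid_dim, dim(scene$label_image))
    interior <- if (interior_only) {
      scene_interior_mask(scene,
                          if (identical(roi$class, "cell_body")) "cell" else "full")
    } else {
      NULL
    }
    sel <- roi_mask_select(scene, roi, sam$index, interior = interior)
    sel[is.na(sel)] <- FALSE
    pixels <- cbind(row = sam$row[sel], col = sam$col[sel])
    # forward-map the SEM mask pixels to estimate how much of the ROI falls
    # outside the raster
    mask_idx <- roi_mask_pixels(scene, roi)
    if (nrow(mask_idx) == 0) {
      outside <- 1
    } else {
      fwd <- transform_points(transform, cbind(mask_idx[, "col"] - 1, mask_idx[, "row"] - 1))
      out <- fwd[, 1] < -0.5 | fwd[, 1] > grid_dim[2] - 0.5 |
        fwd[, 2] < -0.5 | fwd[, 2] > grid_dim[1] - 0.5
      outside <- mean(out)
    }
  } else {
    abort("unknown ROI geometry type; expected 'polygon' or 'label'.")
  }
  list(pixels = pixels, outside_fraction = outside, empty = nrow(pixels) == 0)
}

# Pull every NanoSIMS pixel center back into the SEM frame; returns the
# rounded SEM linear index (NA outside the frame) plus the grid row/col.
sims_to_sem_index <- function(transform, grid_dim, sem_dim) {
  inv <- invert_transform(transform)
  nr <- grid_dim[1]; nc <- grid_dim[2]
  xs <- rep(0:(nc - 1), each = nr)
  ys <- rep(0:(nr - 1), times = nc)
  sem <- transform_points(inv, cbind(xs, ys))
  sc <- as.integer(round(sem[, 1])); sr <- as.integer(round(sem[, 2]))
  ok <- sc >= 0 & sc < sem_dim[2] & sr >= 0 & sr < sem_dim[1]
  idx <- rep(NA_integer_, length(xs))
  idx[ok] <- sr[ok] + 1L + sc[ok] * sem_dim[1]
  list(index = idx, row = rep(1:nr, times = nc), col = rep(1:nc, each = nr))
}

# Logical selector over the pulled-back SEM indices for a label-mask ROI.
roi_mask_select <- function(scene, roi, sem_index, interior = NULL) {
  cls <- roi$class
  geom <- roi$geometry
  if (is.null(geom$type) && is.list(geom) && length(geom) == 1) geom <- geom[[1]]
  cid <- roi$cell_id
  lab <- scene$label_image[sem_index]
  cell <- scene$cell_id_image[sem_index]
  oid <- geom$organelle_id %||% NA
  sel <- if (identical(cls, "cell_body")) {
    cell == cid
  } else if (!is.na(oid)) {
    scene$organelle_id_image[sem_index] == oid
  } else {
    lab == COMPARTMENT_CLASSES[[cls]] & cell == cid
  }
  if (!is.null(interior)) sel <- sel & interior[sem_index]
  sel
}

# Interior pixels of the scene's segmentation: a pixel whose 4-neighbours
# all carry the same assignment. Mask-ROI footprints are restricted to
# interior pixels so that small registration errors cannot misassign
# boundary pixels between adjacent structures (edge avoidance; the excluded
# rim is < 1 SEM px wide). `type = "full"` erodes at every compartment and
# organelle boundary (for compartment/organelle ROIs); `type = "cell"`
# erodes only at cell outlines, so whole-cell ROIs keep their internal
# compartment weighting intact.
scene_interior_mask <- function(scene, type = c("full", "cell")) {
  type <- match.arg(type)
  key <- if (type == "cell") {
    scene$cell_id_image * 1.0
  } else {
    scene$label_image * 1e9 + scene$cell_id_image * 1e4 +
      scene$organelle_id_image
  }
  nr <- nrow(key); nc <- ncol(key)
  interior <- matrix(FALSE, nr, nc)
  ctr <- key[2:(nr - 1), 2:(nc - 1)]
  interior[2:(nr - 1), 2:(nc - 1)] <-
    ctr == key[1:(nr - 2), 2:(nc - 1)] &
    ctr == key[3:nr, 2:(nc - 1)] &
    ctr == key[2:(nr - 1), 1:(nc - 2)] &
    ctr == key[2:(nr - 1), 3:nc]
  interior
}

# (row, col) SEM pixels of a label-mask ROI.
roi_mask_pixels <- function(scene, roi) {
  cls <- roi$class
  cid <- roi$cell_id
  oid <- roi$geometry$organelle_id %||% NA
  sel <- if (identical(cls, "cell_body")) {
    scene$cell_id_image == cid
  } else if (!is.na(oid)) {
    scene$organelle_id_image == oid
  } else {
    scene$label_image == COMPARTMENT_CLASSES[[cls]] & scene$cell_id_image == cid
  }
  which(sel, arr.ind = TRUE)[, c("row", "col"), drop = FALSE]
}

#' Resample a delta map into the SEM frame (visualization only)
#'
#' Nearest-neighbour pull-back of the per-mil map onto the SEM grid so it
#' can be overlaid on the ultrastructure image. Quantification never uses
#' this resampled image; ROI statistics are always computed from summed
#' counts on the native NanoSIMS grid.
#'
#' @param dmap A `delta_map` (see [delta_map()]).
#' @param transform SEM -> NanoSIMS `planar_transform`.
#' @param sem_dim Output dimension `c(nrow, ncol)`.
#' @return Numeric matrix of delta-13C (per mil), `NA` where the source
#'   pixel is invalid or outside the raster.
#' @export
resample_to_sem <- function(dmap, transform, sem_dim) {
  stopifnot(inherits(dmap, "silksims_delta_map"))
  nr <- sem_dim[1]; nc <- sem_dim[2]
  xs <- rep(0:(nc - 1), each = nr)
  ys <- rep(0:(nr - 1), times = nc)
  sims <- transform_points(transform, cbind(xs, ys))
  c_ <- as.integer(round(sims[, 1])); r_ <- as.integer(round(sims[, 2]))
  gd <- dim(dmap$delta)
  ok <- c_ >= 0 & c_ < gd[2] & r_ >= 0 & r_ < gd[1]
  out <- rep(NA_real_, nr * nc)
  src <- r_[ok] + 1L + c_[ok] * gd[1]
  val <- dmap$delta[src]
  val[!dmap$valid[src]] <- NA_real_
  out[ok] <- val
  matrix(out, nr, nc)
}
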