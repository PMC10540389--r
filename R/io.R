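# Readers and writers for every artifact the pipeline touches.
#
# On-disk conventions:
#  * ion-count stacks: one multi-page 32-bit TIFF per species plus a JSON
#    sidecar. Integer counts are encoded as v / 2^24 in the float payload,
#    which is bit-exact for integers below 2^24 (the tiff package stores
#    32-bit floats only inside [0, 1]).
#  * delta maps: 32-bit float TIFF with an offset/scale recorded in the
#    sidecar (float32 precision), plus a validity-mask page.
#  * control points and measurement tables: CSV; ROIs: JSON polygons
#    (primary) or label-image TIFF (secondary); transforms/presets/metadata:
#    JSON at full double precision.
# All readers validate and reject malformed input rather than coercing.

COUNT_SCALE <- 2^24

write_count_pages <- function(mats, path) {
  if (any(vapply(mats, max, numeric(1)) >= COUNT_SCALE)) {
    abort("counts >= 2^24 cannot be stored losslessly in the TIFF encoding.")
  }
  tiff::writeTIFF(lapply(mats, function(m) m / COUNT_SCALE), path,
                  bits.per.sample = 32L, compression = "none")
  invisible(path)
}

read_count_pages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  lapply(pages, function(m) round(m * COUNT_SCALE))
}

#' Write / read an ion-count stack
#'
#' A stack directory holds `12C14N.tiff`, `13C14N.tiff` (one page per raster
#' plane) and `stack.json` with pixel size, dwell time and metadata. The
#' round trip is lossless: counts bit-exact, metadata field-by-field.
#'
#' @param stack A `sims_stack`.
#' @param dir Directory (created if missing).
#' @return `write_stack()` returns `dir` invisibly; `read_stack()` returns
#'   the `sims_stack`.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "sims_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in names(stack$counts)) {
    arr <- stack$counts[[sp]]
    mats <- lapply(seq_len(dim(arr)[3]), function(p) arr[, , p])
    write_count_pages(mats, file.path(dir, paste0(sp, ".tiff")))
  }
  meta <- list(
    species = names(stack$counts),
    dim = dim(stack$counts[[1]]),
    pixel_size_um = stack$pixel_size_um,
    dwell_ms = stack$dwell_ms,
    metadata = stack$metadata
  )
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  jpath <- file.path(dir, "stack.json")
  if (!file.exists(jpath)) abort(paste("no stack.json in", dir))
  meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  arrays <- list()
  for (sp in c(SPECIES_12, SPECIES_13)) {
    tpath <- file.path(dir, paste0(sp, ".tiff"))
    if (!file.exists(tpath)) {
      abort(sprintf("stack format error: species %s is missing (%s not found).", sp, tpath))
    }
    pages <- read_count_pages(tpath)
    arrays[[sp]] <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  }
  if (!identical(dim(arrays[[SPECIES_12]]), dim(arrays[[SPECIES_13]]))) {
    abort("stack format error: species shapes differ.")
  }
  md <- meta$metadata
  if (is.null(md)) md <- list()
  ion_count_stack(arrays[[SPECIES_12]], arrays[[SPECIES_13]],
                  pixel_size_um = meta$pixel_size_um,
                  dwell_ms = meta$dwell_ms, metadata = as.list(md))
}

#' Write / read an accumulated image
#'
#' Summed counts for both species, the validity mask and the applied shifts;
#' counts round-trip bit-exact.
#'
#' @param acc A `silksims_accumulated`.
#' @param dir Directory.
#' @return `dir` invisibly / the `silksims_accumulated`.
#' @export
write_accumulated <- function(acc, dir) {
  stopifnot(inherits(acc, "silksims_accumulated"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_pages(list(acc$n12, acc$n13, acc$mask * 1), file.path(dir, "accumulated.tiff"))
  meta <- list(shifts = unclass(acc$shifts), pixel_size_um = acc$pixel_size_um,
               dwell_ms = acc$dwell_ms, n_planes = acc$n_planes,
               metadata = acc$metadata)
  jsonlite::write_json(meta, file.path(dir, "accumulated.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_accumulated
#' @export
read_accumulated <- function(dir) {
  jpath <- file.path(dir, "accumulated.json")
  if (!file.exists(jpath)) abort(paste("no accumulated.json in", dir))
  meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  pages <- read_count_pages(file.path(dir, "accumulated.tiff"))
  if (length(pages) != 3) abort("accumulated image must have 3 pages (n12, n13, mask).")
  shifts <- matrix(as.integer(meta$shifts), ncol = 2,
                   dimnames = list(NULL, c("dy", "dx")))
  md <- meta$metadata
  if (is.null(md)) md <- list()
  structure(list(
    n12 = pages[[1]], n13 = pages[[2]], mask = pages[[3]] > 0,
    shifts = shifts, pixel_size_um = meta$pixel_size_um,
    dwell_ms = meta$dwell_ms, n_planes = meta$n_planes, metadata = as.list(md)
  ), class = "silksims_accumulated")
}

#' Write / read a delta map
#'
#' 32-bit float TIFF (values rescaled into [0, 1] with the offset/scale in
#' the sidecar, so precision is float32, ~1e-7 relative) plus a mask page;
#' `r_nat` and `min_counts` round-trip exactly through the sidecar.
#'
#' @param dmap A `silksims_delta_map`.
#' @param dir Directory.
#' @return `dir` invisibly / the `silksims_delta_map`.
#' @export
write_delta_map <- function(dmap, dir) {
  stopifnot(inherits(dmap, "silksims_delta_map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- dmap$delta
  rng <- if (any(dmap$valid)) range(v[dmap$valid]) else c(0, 1)
  scale <- max(rng[2] - rng[1], 1e-9)
  enc <- matrix(0, nrow(v), ncol(v))
  enc[dmap$valid] <- (v[dmap$valid] - rng[1]) / scale
  tiff::writeTIFF(list(enc, dmap$valid * 1), file.path(dir, "delta.tiff"),
                  bits.per.sample = 32L, compression = "none")
  meta <- list(offset = rng[1], scale = scale, r_nat = dmap$r_nat,
               min_counts = dmap$min_counts, pixel_size_um = dmap$pixel_size_um)
  jsonlite::write_json(meta, file.path(dir, "delta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_delta_map
#' @export
read_delta_map <- function(dir) {
  jpath <- file.path(dir, "delta.json")
  if (!file.exists(jpath)) abort(paste("no delta.json in", dir))
  meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dir, "delta.tiff"), all = TRUE)
  if (length(pages) != 2) abort("delta map must have 2 pages (delta, mask).")
  valid <- pages[[2]] > 0
  delta <- matrix(NA_real_, nrow(valid), ncol(valid))
  delta[valid] <- pages[[1]][valid] * meta$scale + meta$offset
  structure(list(delta = delta, valid = valid, r_nat = meta$r_nat,
                 min_counts = meta$min_counts, pixel_size_um = meta$pixel_size_um),
            class = "silksims_delta_map")
}

#' Read user-matched control points from CSV
#'
#' Expects columns `x_sem`, `y_sem`, `x_sims`, `y_sims` (0-based pixel
#' coordinates) and optionally `label`. Malformed rows are rejected with the
#' offending line number.
#'
#' @param path CSV file.
#' @return Tibble of control points.
#' @export
read_control_points <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  lines <- readLines(path)
  if (length(lines) < 2) abort("control-point file needs a header and at least one row.")
  header <- trimws(strsplit(lines[1], ",")[[1]])
  need <- c("x_sem", "y_sem", "x_sims", "y_sims")
  missing <- setdiff(need, header)
  if (length(missing)) {
    abort(paste("control-point file lacks columns:", paste(missing, collapse = ", ")))
  }
  rows <- lapply(seq_along(lines[-1]), function(i) {
    fields <- trimws(strsplit(lines[i + 1], ",")[[1]])
    if (length(fields) < length(header)) {
      abort(sprintf("parse error at line %d: expected %d fields, found %d.",
                    i + 1, length(header), length(fields)))
    }
    vals <- suppressWarnings(as.numeric(fields[match(need, header)]))
    if (anyNA(vals)) {
      abort(sprintf("parse error at line %d: non-numeric coordinate.", i + 1))
    }
    if (any(vals < 0)) {
      abort(sprintf("parse error at line %d: negative coordinate.", i + 1))
    }
    setNames(as.list(vals), need)
  })
  dplyr::bind_rows(rows)
}

#' Write control points to CSV
#'
#' @param points Tibble with `x_sem`, `y_sem`, `x_sims`, `y_sims`.
#' @param path Output CSV.
#' @return `path` invisibly.
#' @export
write_control_points <- function(points, path) {
  readr::write_csv(points[, c("x_sem", "y_sem", "x_sims", "y_sims")], path)
  invisible(path)
}

#' Read ROIs from a JSON polygon file
#'
#' Each entry carries `id`, `cell_id`, `class` (from
#' [compartment_classes()]) and `polygon`, an array of [x, y] vertices in
#' SEM pixel coordinates (implicitly closed; last vertex must differ from
#' the first). Self-intersecting rings and unknown classes are rejected.
#'
#' @param path JSON file.
#' @return ROI tibble with columns `region_id`, `cell_id`, `class` and a
#'   `geometry` list-column.
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- purrr::imap(raw, function(r, i) {
    cls <- r$class
    if (is.null(cls) || !cls %in% ROI_CLASSES) {
      abort(sprintf("ROI %d: unknown class '%s'.", i, cls %||% "<missing>"))
    }
    verts <- do.call(rbind, lapply(r$polygon, function(v) as.numeric(unlist(v))))
    if (is.null(verts) || nrow(verts) < 3 || ncol(verts) != 2 || anyNA(verts)) {
      abort(sprintf("ROI %d: polygon needs >= 3 numeric [x, y] vertices.", i))
    }
    if (all(verts[1, ] == verts[nrow(verts), ])) {
      abort(sprintf("ROI %d: polygons are implicitly closed; drop the repeated last vertex.", i))
    }
    if (polygon_self_intersects(verts)) {
      abort(sprintf("ROI %d: polygon ring is self-intersecting.", i))
    }
    tibble(
      region_id = as.character(r$id %||% i),
      cell_id = as.integer(r$cell_id %||% NA),
      class = cls,
      geometry = list(list(type = "polygon", vertices = verts))
    )
  })
  dplyr::bind_rows(rows)
}

#' Write polygon ROIs to JSON
#'
#' @param rois ROI tibble (polygon geometries only).
#' @param path Output JSON file.
#' @return `path` invisibly.
#' @export
write_rois <- function(rois, path) {
  entries <- purrr::pmap(rois, function(region_id, cell_id, class, geometry, ...) {
    if (!identical(geometry$type, "polygon")) {
      abort("write_rois() handles polygon ROIs; label-mask ROIs live in the scene bundle.")
    }
    list(id = region_id, cell_id = cell_id, class = class,
         polygon = lapply(seq_len(nrow(geometry$vertices)),
                          function(i) as.numeric(geometry$vertices[i, ])))
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Build label-mask ROIs from a label image
#'
#' Secondary ROI exchange format: a compartment-label image (and optional
#' cell-id image) defines one mask ROI per (cell, class) present.
#'
#' @param label_image Integer matrix with the [compartment_classes()] codes.
#' @param cell_id_image Optional congruent integer matrix of cell indices.
#' @return ROI tibble with label-mask geometries plus a minimal scene-like
#'   container in the `scene` attribute for use with [map_roi()].
#' @export
label_image_rois <- function(label_image, cell_id_image = NULL) {
  if (is.null(cell_id_image)) {
    cell_id_image <- matrix(as.integer(label_image != COMPARTMENT_CLASSES[["background"]]),
                            nrow(label_image), ncol(label_image))
  }
  if (!identical(dim(label_image), dim(cell_id_image))) {
    abort("label and cell-id images must be congruent.")
  }
  combos <- unique(data.frame(
    code = as.vector(label_image), cell = as.vector(cell_id_image)
  ))
  combos <- combos[combos$code != COMPARTMENT_CLASSES[["background"]] & combos$cell > 0, ]
  rows <- purrr::pmap(combos, function(code, cell) {
    cls <- names(COMPARTMENT_CLASSES)[match(code, COMPARTMENT_CLASSES)]
    tibble(region_id = paste0("cell", cell, "_", cls), cell_id = as.integer(cell),
           class = cls, geometry = list(list(type = "label", organelle_id = NA)))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "scene") <- structure(list(
    label_image = label_image, cell_id_image = cell_id_image,
    organelle_id_image = matrix(0L, nrow(label_image), ncol(label_image))
  ), class = "silksims_scene")
  out
}

#' Write a measurement table to CSV
#'
#' One row per measurement with a stable column order (as given); doubles
#' are written at full precision so a re-read reproduces the table.
#'
#' @param records Tibble/data frame.
#' @param path Output CSV.
#' @return `path` invisibly.
#' @export
write_table <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Write / read a planar transform as JSON
#'
#' @param transform A `planar_transform`.
#' @param path JSON file.
#' @return `path` invisibly / the `planar_transform`.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "planar_transform"))
  jsonlite::write_json(
    list(matrix = transform$M, rmse = transform$rmse, n_points = transform$n_points),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) abort(paste("file not found:", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_planar_transform(matrix(unlist(raw$matrix), 2, 3),
                       rmse = raw$rmse, n_points = raw$n_points)
}

#' Write / read a scene bundle
#'
#' Directory with the SEM image (16-bit TIFF), label / cell-id /
#' organelle-id images, the true delta field (32-bit float TIFF with sidecar
#' scale), the ground-truth tables (CSV) and the acquisition + preset
#' parameters (JSON, including the true transform).
#'
#' @param scene A `silksims_scene`.
#' @param dir Directory.
#' @return `dir` invisibly / the `silksims_scene`.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "silksims_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(scene$sem_image, file.path(dir, "sem.tiff"), bits.per.sample = 16L)
  write_count_pages(list(scene$label_image, scene$cell_id_image, scene$organelle_id_image),
                    file.path(dir, "labels.tiff"))
  v <- scene$true_delta_field
  rng <- range(v); scale <- max(rng[2] - rng[1], 1e-9)
  tiff::writeTIFF((v - rng[1]) / scale, file.path(dir, "true_delta.tiff"),
                  bits.per.sample = 32L, compression = "none")
  write_table(scene$cells, file.path(dir, "cells.csv"))
  write_table(scene$organelles, file.path(dir, "organelles.csv"))
  acq <- scene$acquisition
  meta <- list(
    delta_offset = rng[1], delta_scale = scale,
    acquisition = list(grid = acq$grid, n_planes = acq$n_planes,
                       fov_um = acq$fov_um, pixel_size_um = acq$pixel_size_um,
                       transform = acq$transform_true$M,
                       drift_per_plane = unclass(acq$drift_per_plane),
                       lambda_total = as.list(acq$lambda_total),
                       r_nat = acq$r_nat,
                       sem_pixel_size_nm = acq$sem_pixel_size_nm),
    preset = preset_to_json(scene$preset),
    provenance = scene$provenance
  )
  jsonlite::write_json(meta, file.path(dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_scene
#' @export
read_scene <- function(dir) {
  jpath <- file.path(dir, "scene.json")
  if (!file.exists(jpath)) abort(paste("no scene.json in", dir))
  meta <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  labels <- read_count_pages(file.path(dir, "labels.tiff"))
  enc <- tiff::readTIFF(file.path(dir, "true_delta.tiff"))
  acq <- meta$acquisition
  drift <- matrix(as.integer(unlist(acq$drift_per_plane)), ncol = 2,
                  dimnames = list(NULL, c("dy", "dx")))
  raw_preset <- jsonlite::read_json(jpath, simplifyVector = FALSE)$preset
  preset <- preset_from_json(raw_preset)
  structure(list(
    label_image = matrix(as.integer(labels[[1]]), nrow(labels[[1]])),
    cell_id_image = matrix(as.integer(labels[[2]]), nrow(labels[[2]])),
    organelle_id_image = matrix(as.integer(labels[[3]]), nrow(labels[[3]])),
    true_delta_field = enc * meta$delta_scale + meta$delta_offset,
    sem_image = tiff::readTIFF(file.path(dir, "sem.tiff")),
    cells = readr::read_csv(file.path(dir, "cells.csv"), show_col_types = FALSE),
    organelles = readr::read_csv(file.path(dir, "organelles.csv"), show_col_types = FALSE),
    acquisition = list(grid = acq$grid, n_planes = acq$n_planes, fov_um = acq$fov_um,
                       pixel_size_um = acq$pixel_size_um,
                       transform_true = new_planar_transform(matrix(unlist(acq$transform), 2, 3)),
                       drift_per_plane = drift,
                       lambda_total = unlist(acq$lambda_total),
                       r_nat = acq$r_nat,
                       sem_pixel_size_nm = acq$sem_pixel_size_nm),
    preset = preset,
    provenance = meta$provenance
  ), class = "silksims_scene")
}
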