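# End-to-end orchestration: synthetic cohorts and configuration-driven runs.

#' ROI set of a synthetic scene
#'
#' One label-mask ROI per compartment and organelle of every cell: the
#' whole cell body, cytoplasm (organelle footprints excluded by
#' construction, since organelle pixels carry their own labels), nucleus,
#' nucleolus when present, and each organelle instance.
#'
#' @param scene A `silksims_scene`.
#' @return ROI tibble (`region_id`, `cell_id`, `class`, `geometry`).
#' @export
scene_rois <- function(scene) {
  rows <- list()
  for (i in scene$cells$cell_id) {
    present <- scene$cells$nucleolus_present[scene$cells$cell_id == i]
    classes <- c("cell_body", "cytoplasm", "nucleus", if (present) "nucleolus")
    for (cl in classes) {
      rows[[length(rows) + 1]] <- tibble(
        region_id = paste0("cell", i, "_", cl), cell_id = i, class = cl,
        geometry = list(list(type = "label", organelle_id = NA)))
    }
  }
  org <- scene$organelles
  for (j in seq_len(nrow(org))) {
    rows[[length(rows) + 1]] <- tibble(
      region_id = paste0("org", org$organelle_id[j]),
      cell_id = org$cell_id[j], class = org$class[j],
      geometry = list(list(type = "label", organelle_id = org$organelle_id[j])))
  }
  dplyr::bind_rows(rows)
}

#' Quantify a set of ROIs against an accumulated image
#'
#' Transports every ROI to the NanoSIMS grid through the fitted transform
#' and measures it with [measure_roi()]. Label-mask ROIs share one
#' pull-back of the raster grid, so large ROI sets stay fast. ROIs with
#' more than `max_outside` of their area outside the raster are excluded
#' with a warning.
#'
#' @param acc A `silksims_accumulated`.
#' @param rois ROI tibble ([scene_rois()] or [read_rois()]).
#' @param transform Fitted SEM -> NanoSIMS `planar_transform`.
#' @param r_nat Reference ratio.
#' @param scene Scene defining label-mask ROIs (omit for polygon ROIs).
#' @param max_outside Exclusion threshold on the outside fraction.
#' @return Measurement tibble, one row per ROI.
#' @export
quantify_rois <- function(acc, rois, transform, r_nat, scene = NULL,
                          max_outside = 0.5) {
  grid_dim <- dim(acc$n12)
  has_label <- any(vapply(rois$geometry, function(g) identical(g$type, "label"), TRUE))
  sam <- NULL
  if (has_label) {
    if (is.null(scene)) abort("label-mask ROIs need `scene`.")
    sam <- sims_to_sem_index(transform, grid_dim, dim(scene$label_image))
    lab_s <- scene$label_image[sam$index]
    cell_s <- scene$cell_id_image[sam$index]
    org_s <- scene$organelle_id_image[sam$index]
    int_full_s <- scene_interior_mask(scene, "full")[sam$index]
    int_full_s[is.na(int_full_s)] <- FALSE
    int_cell_s <- scene_interior_mask(scene, "cell")[sam$index]
    int_cell_s[is.na(int_cell_s)] <- FALSE
    out_frac_cell <- cell_outside_fractions(scene, transform, grid_dim)
  }
  rows <- vector("list", nrow(rois))
  for (j in seq_len(nrow(rois))) {
    g <- rois$geometry[[j]]
    if (identical(g$type, "label")) {
      cid <- rois$cell_id[j]
      cls <- rois$class[j]
      oid <- g$organelle_id %||% NA
      sel <- if (!is.na(oid)) {
        org_s == oid
      } else if (identical(cls, "cell_body")) {
        cell_s == cid
      } else {
        lab_s == COMPARTMENT_CLASSES[[cls]] & cell_s == cid
      }
      sel[is.na(sel)] <- FALSE
      sel <- sel & (if (identical(cls, "cell_body")) int_cell_s else int_full_s)
      fp <- list(pixels = cbind(row = sam$row[sel], col = sam$col[sel]),
                 outside_fraction = out_frac_cell[as.character(cid)][[1]] %||% 0)
    } else {
      fp <- map_roi(transform, as.list(rois[j, ]), grid_dim, scene = scene)
    }
    m <- measure_roi(acc, fp, r_nat)
    m$region_id <- rois$region_id[j]
    m$cell_id <- rois$cell_id[j]
    m$class <- rois$class[j]
    rows[[j]] <- m
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::relocate(out, "region_id", "cell_id", "class")
  excl <- out$outside_fraction > max_outside
  if (any(excl)) {
    warn(sprintf("excluding %d ROI(s) with more than %.0f%% of their area outside the raster.",
                 sum(excl), 100 * max_outside))
    out <- out[!excl, , drop = FALSE]
  }
  out
}

# Fraction of each cell's boundary samples mapping outside the raster
# (cells are placed fully inside by construction, so this is normally 0).
cell_outside_fractions <- function(scene, transform, grid_dim) {
  out <- list()
  ang <- seq(0, 2 * pi, length.out = 33)[-33]
  for (i in scene$cells$cell_id) {
    ci <- scene$cells[scene$cells$cell_id == i, ]
    if (!all(c("cx", "a") %in% names(ci))) { out[[as.character(i)]] <- 0; next }
    bnd <- cbind(ci$cx + ci$a * cos(ang) * cos(ci$theta) - ci$b * sin(ang) * sin(ci$theta),
                 ci$cy + ci$a * cos(ang) * sin(ci$theta) + ci$b * sin(ang) * cos(ci$theta))
    mp <- transform_points(transform, bnd)
    outside <- mp[, 1] < -0.5 | mp[, 1] > grid_dim[2] - 0.5 |
      mp[, 2] < -0.5 | mp[, 2] > grid_dim[1] - 0.5
    out[[as.character(i)]] <- mean(outside)
  }
  out
}

#' Run the full analysis chain on one synthetic scene
#'
#' Render -> drift-correct -> accumulate -> register (from simulated
#' landmarks) -> quantify -> summarize, plus SEM-frame morphometry.
#'
#' @param scene A `silksims_scene`.
#' @param n_landmarks,landmark_jitter Landmark simulation parameters
#'   (SEM-frame localization jitter in SEM px).
#' @param max_shift Drift-search radius for plane alignment.
#' @param r_nat Reference ratio (defaults to the scene's acquisition value).
#' @param max_outside ROI exclusion threshold.
#' @param morphometry Run the SEM-frame morphometry stage.
#' @return List with `cells`, `organelles`, `measurements`, `transform`,
#'   `shifts`, `morpho`.
#' @export
process_scene <- function(scene, n_landmarks = 16, landmark_jitter = 0.15,
                          max_shift = 4, r_nat = NULL, max_outside = 0.5,
                          morphometry = TRUE) {
  stopifnot(inherits(scene, "silksims_scene"))
  r_nat <- r_nat %||% scene$acquisition$r_nat
  stack <- render_nanosims(scene)
  shifts <- estimate_plane_shifts(stack, max_shift = max_shift)
  acc <- accumulate(stack, shifts, max_shift = max_shift)
  landmarks <- make_landmarks(scene$acquisition$transform_true,
                              dim(scene$label_image),
                              n = n_landmarks, jitter_sem_px = landmark_jitter)
  tf <- fit_affine(landmarks)
  rois <- scene_rois(scene)
  meas <- quantify_rois(acc, rois, tf, r_nat, scene = scene,
                        max_outside = max_outside)
  summ <- summarize_cells(meas)

  cells <- dplyr::left_join(
    summ$cells,
    dplyr::select(scene$cells, "cell_id", "whole_cell_delta_true",
                  "cytoplasm_delta_true", "nucleus_delta_true",
                  "nuc_minus_cyt_true", "merc_planted"),
    by = "cell_id")
  organelles <- dplyr::left_join(
    summ$organelles |>
      dplyr::mutate(organelle_id = suppressWarnings(as.integer(sub("^org", "", .data$region_id)))),
    dplyr::select(scene$organelles, "organelle_id", "true_delta"),
    by = "organelle_id")

  morpho <- if (morphometry) morphometry_scene(scene) else NULL
  list(cells = cells, organelles = organelles, measurements = meas,
       transform = tf, shifts = shifts,
       shifts_true = scene$acquisition$drift_per_plane, morpho = morpho)
}

#' Simulate and analyze a cohort of neurons
#'
#' Builds as many scenes as needed to host `n_cells` cells of the given
#' preset, runs the full chain on each, and returns pooled per-cell and
#' per-organelle tables. Scene seeds derive deterministically from `seed`,
#' so the whole cohort is reproducible bit for bit. Scenes are assigned
#' round-robin to three synthetic animals, matching the 3-4 animals per
#' group of the labeling design.
#'
#' @param preset A `silksims_preset` (or preset name).
#' @param n_cells Cohort size.
#' @param seed Cohort seed.
#' @param cells_per_scene Cells per rendered field.
#' @param sem_size,grid,n_planes Scene/acquisition dimensions.
#' @param ... Passed to [process_scene()].
#' @return List with `cells`, `organelles`, `morpho_mitochondria`,
#'   `morpho_cells`, `registration` (per-scene fit RMSE), `shift_recovery`
#'   (estimated vs true drift).
#' @export
simulate_cohort <- function(preset, n_cells = 50, seed = 1,
                            cells_per_scene = 5, sem_size = 1024,
                            grid = 256, n_planes = 6, ...) {
  if (is.character(preset)) preset <- default_preset(preset)
  n_scenes <- ceiling(n_cells / cells_per_scene)
  set.seed(seed)
  scene_seeds <- sample.int(.Machine$integer.max - 1, n_scenes)
  cells <- list(); orgs <- list(); mmito <- list(); mcell <- list()
  reg <- list(); shifts <- list()
  done <- 0L
  for (s in seq_len(n_scenes)) {
    n_here <- min(cells_per_scene, n_cells - done)
    scene <- build_scene(preset, n_cells = n_here, sem_size = sem_size,
                         seed = scene_seeds[s], grid = grid, n_planes = n_planes)
    res <- process_scene(scene, ...)
    animal <- ((s - 1L) %% 3L) + 1L
    ctab <- res$cells
    ctab$scene <- s; ctab$animal <- animal
    ctab$condition <- preset$condition; ctab$timepoint_h <- preset$timepoint_h
    ctab$region <- preset$region
    ctab$cell_uid <- paste0("s", s, "c", ctab$cell_id)
    otab <- res$organelles
    otab$scene <- s; otab$animal <- animal
    otab$condition <- preset$condition; otab$timepoint_h <- preset$timepoint_h
    otab$cell_uid <- paste0("s", s, "c", otab$cell_id)
    cells[[s]] <- ctab; orgs[[s]] <- otab
    if (!is.null(res$morpho)) {
      mm <- res$morpho$mitochondria; mm$scene <- s
      mm$condition <- preset$condition; mm$timepoint_h <- preset$timepoint_h
      mc <- res$morpho$cells; mc$scene <- s
      mc$condition <- preset$condition; mc$timepoint_h <- preset$timepoint_h
      mmito[[s]] <- mm; mcell[[s]] <- mc
    }
    reg[[s]] <- tibble(scene = s, rmse = res$transform$rmse,
                       n_points = res$transform$n_points)
    shifts[[s]] <- tibble(scene = s,
                          plane = seq_len(nrow(res$shifts)),
                          dy_est = res$shifts[, 1], dx_est = res$shifts[, 2],
                          dy_true = res$shifts_true[, 1], dx_true = res$shifts_true[, 2])
    done <- done + n_here
  }
  list(
    preset = preset$name,
    cells = dplyr::bind_rows(cells),
    organelles = dplyr::bind_rows(orgs),
    morpho_mitochondria = dplyr::bind_rows(mmito),
    morpho_cells = dplyr::bind_rows(mcell),
    registration = dplyr::bind_rows(reg),
    shift_recovery = dplyr::bind_rows(shifts)
  )
}

RUN_CONFIG_KEYS <- c("mode", "presets", "n_cells", "cells_per_scene", "seed",
                     "sem_size", "grid", "n_planes", "r_nat", "max_shift",
                     "min_counts", "d_contact_nm", "max_outside",
                     "n_landmarks", "landmark_jitter", "out_dir",
                     "stack_dir", "points_csv", "rois_json", "transform_json")

#' Validate a run configuration
#'
#' Fail-fast validation: unknown keys are rejected, thresholds must lie in
#' their documented ranges.
#'
#' @param config Named list (e.g. from a YAML file).
#' @return The validated config with defaults filled in.
#' @export
validate_run_config <- function(config) {
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    abort(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  }
  config$mode <- config$mode %||% "synthetic"
  if (!config$mode %in% c("synthetic", "files")) abort("mode must be 'synthetic' or 'files'.")
  config$seed <- config$seed %||% 1L
  config$out_dir <- config$out_dir %||% "silksims-run"
  config$max_shift <- config$max_shift %||% 4
  config$min_counts <- config$min_counts %||% 100
  config$d_contact_nm <- config$d_contact_nm %||% 30
  config$max_outside <- config$max_outside %||% 0.5
  config$n_landmarks <- config$n_landmarks %||% 16
  config$landmark_jitter <- config$landmark_jitter %||% 0.15
  if (config$max_shift < 0 || config$max_shift > 32) abort("max_shift out of range [0, 32].")
  if (config$min_counts < 1) abort("min_counts must be >= 1.")
  if (config$d_contact_nm <= 0) abort("d_contact_nm must be > 0.")
  if (config$max_outside < 0 || config$max_outside > 1) abort("max_outside out of range [0, 1].")
  if (config$mode == "synthetic") {
    config$presets <- config$presets %||% c("snpc-control-48h")
    config$n_cells <- config$n_cells %||% 10
    config$cells_per_scene <- config$cells_per_scene %||% 5
    config$sem_size <- config$sem_size %||% 1024
    config$grid <- config$grid %||% 256
    config$n_planes <- config$n_planes %||% 6
  }
  config
}

#' Run the configured pipeline end to end
#'
#' Synthetic mode simulates the configured presets and writes per-cell,
#' per-organelle and morphometry tables, group summaries, condition
#' comparisons (Mann-Whitney with BH adjustment, when both conditions are
#' present at a time point), pulse/chase kinetics fits of the control cohort
#' means, and a provenance record (config, seeds, package version). Files
#' mode processes a measured stack: accumulate -> delta map -> register
#' (from control points) -> quantify user ROIs. Outputs are byte-stable for
#' a fixed config and seed.
#'
#' @param config Named list or path to a YAML config file.
#' @return Invisibly, the list of result tables; files are written to
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (config$mode == "synthetic") {
    run_synthetic_mode(config)
  } else {
    run_files_mode(config)
  }
}

run_synthetic_mode <- function(config) {
  cohorts <- list()
  for (i in seq_along(config$presets)) {
    nm <- config$presets[[i]]
    message("silksims: simulating preset ", nm)
    cohorts[[nm]] <- simulate_cohort(
      nm, n_cells = config$n_cells, seed = config$seed + i - 1L,
      cells_per_scene = config$cells_per_scene, sem_size = config$sem_size,
      grid = config$grid, n_planes = config$n_planes,
      n_landmarks = config$n_landmarks, landmark_jitter = config$landmark_jitter,
      max_shift = config$max_shift, max_outside = config$max_outside
    )
  }
  cells <- purrr::map_dfr(cohorts, "cells")
  organelles <- purrr::map_dfr(cohorts, "organelles")
  morpho <- purrr::map_dfr(cohorts, "morpho_cells")
  mito <- purrr::map_dfr(cohorts, "morpho_mitochondria")

  write_table(cells, file.path(config$out_dir, "cells.csv"))
  write_table(organelles, file.path(config$out_dir, "organelles.csv"))
  write_table(morpho, file.path(config$out_dir, "morphometry_cells.csv"))
  write_table(mito, file.path(config$out_dir, "morphometry_mitochondria.csv"))
  groups <- group_table(cells, .data$whole_cell_delta,
                        .data$condition, .data$timepoint_h)
  write_table(groups, file.path(config$out_dir, "group_summary.csv"))

  stats_tbl <- NULL
  both <- cells |>
    dplyr::distinct(.data$condition, .data$timepoint_h) |>
    dplyr::count(.data$timepoint_h) |>
    dplyr::filter(.data$n == 2)
  if (nrow(both) > 0) {
    stats_tbl <- compare_groups(
      dplyr::filter(cells, .data$timepoint_h %in% both$timepoint_h),
      .data$whole_cell_delta, .data$condition, .data$timepoint_h,
      test = "mann_whitney")
    write_table(stats_tbl, file.path(config$out_dir, "stats.csv"))
  }

  fits <- list()
  ctrl <- dplyr::filter(groups, .data$condition == "control")
  pulse_pts <- dplyr::filter(ctrl, .data$timepoint_h <= 48)
  if (nrow(pulse_pts) >= 2) {
    f <- fit_pulse(pulse_pts$timepoint_h, pulse_pts$mean)
    fits$pulse <- list(parameters = as.list(f$par), rss = f$rss, n_points = f$n_points)
  }
  chase_pts <- dplyr::filter(ctrl, .data$timepoint_h >= 48)
  if (nrow(chase_pts) >= 2) {
    f <- fit_chase(chase_pts$timepoint_h, chase_pts$mean)
    fits$chase <- list(parameters = as.list(f$par), rss = f$rss, n_points = f$n_points,
                       half_life_h = log(2) / f$par[["k_c"]])
  }
  if (length(fits)) {
    jsonlite::write_json(fits, file.path(config$out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  provenance <- list(config = config,
                     package_version = as.character(utils::packageVersion("silksims")))
  jsonlite::write_json(provenance, file.path(config$out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(cells = cells, organelles = organelles, morpho = morpho,
                 groups = groups, stats = stats_tbl, fits = fits))
}

run_files_mode <- function(config) {
  if (is.null(config$stack_dir)) {
    abort("accumulation stage: config lacks `stack_dir`.")
  }
  stack <- read_stack(config$stack_dir)
  shifts <- estimate_plane_shifts(stack, max_shift = config$max_shift)
  acc <- accumulate(stack, shifts, max_shift = config$max_shift)
  if (is.null(config$r_nat)) abort("delta stage: config lacks `r_nat`.")
  dmap <- delta_map(acc, config$r_nat, config$min_counts)
  write_accumulated(acc, file.path(config$out_dir, "accumulated"))
  write_delta_map(dmap, file.path(config$out_dir, "delta"))

  tf <- if (!is.null(config$transform_json)) {
    read_transform(config$transform_json)
  } else if (!is.null(config$points_csv)) {
    fit_affine(read_control_points(config$points_csv))
  } else {
    abort("registration stage: config lacks `points_csv` or `transform_json`.")
  }
  write_transform(tf, file.path(config$out_dir, "transform.json"))

  if (is.null(config$rois_json)) abort("quantification stage: config lacks `rois_json`.")
  rois <- read_rois(config$rois_json)
  meas <- quantify_rois(acc, rois, tf, config$r_nat, max_outside = config$max_outside)
  write_table(meas, file.path(config$out_dir, "roi_measurements.csv"))
  cells_out <- NULL
  if (any(meas$class == "cell_body")) {
    summ <- summarize_cells(meas)
    cells_out <- summ$cells
    write_table(summ$cells, file.path(config$out_dir, "cells.csv"))
    write_table(summ$organelles, file.path(config$out_dir, "organelle_measurements.csv"))
  }
  provenance <- list(config = config,
                     package_version = as.character(utils::packageVersion("silksims")))
  jsonlite::write_json(provenance, file.path(config$out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(measurements = meas, cells = cells_out, transform = tf,
                 shifts = shifts))
}
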