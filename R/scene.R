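# Ground-truth scene construction: the SEM-frame forward model.
#
# A scene is a high-resolution labeled field (background resin plus
# elliptical neuronal cell bodies with nucleus, optional nucleolus,
# mitochondria, Golgi ribbons, lysosomes and ER segments) together with a
# per-pixel true delta-13C field drawn from the preset's compartment
# parameters. Cells carry a multiplicative between-cell enrichment factor;
# the nucleus adds the preset nucleus-minus-cytoplasm difference; organelle
# instances scatter around their cytoplasm-normalized ratios. Compartments
# are internally uniform: the model is a piecewise-constant field observed
# through Poisson counting, not a texture model.

#' Random SEM-to-NanoSIMS acquisition transform
#'
#' Draws a plausible instrument mapping: the nominal grid/sem scale with a
#' small random rotation, per-axis stretch and shear, mapping the SEM frame
#' center onto the raster center ("rotated and slightly stretched or
#' squeezed").
#'
#' @param sem_size SEM frame size (pixels, square).
#' @param grid NanoSIMS raster size (pixels, square).
#' @param max_rotation_deg,max_stretch,max_shear Ranges of the random draws.
#' @return A `planar_transform`.
#' @export
random_scene_transform <- function(sem_size, grid, max_rotation_deg = 8,
                                   max_stretch = 0.03, max_shear = 0.02) {
  s0 <- grid / sem_size
  th <- runif(1, -max_rotation_deg, max_rotation_deg) * pi / 180
  sx <- s0 * (1 + runif(1, -max_stretch, max_stretch))
  sy <- s0 * (1 + runif(1, -max_stretch, max_stretch))
  h <- runif(1, -max_shear, max_shear)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  L <- R %*% matrix(c(sx, 0, h * sy, sy), 2, 2)
  c_sem <- (sem_size - 1) / 2
  c_sims <- (grid - 1) / 2
  t <- c(c_sims, c_sims) - L %*% c(c_sem, c_sem)
  new_planar_transform(cbind(L, t))
}

#' Build a ground-truth scene
#'
#' Places `n_cells` non-overlapping cell bodies (entirely inside both the
#' SEM frame and the mapped NanoSIMS raster), populates each with nucleus,
#' optional nucleolus, mitochondria (aspect ratios from the preset),
#' Golgi ribbons, lysosomes and ER segments (a subset planted as
#' mitochondria-ER contacts at the preset contact rate), and paints the true
#' delta-13C field from the preset's compartment parameters.
#'
#' @param preset A `silksims_preset`.
#' @param n_cells Number of cells (>= 1).
#' @param sem_size SEM frame size in pixels (square, >= 256).
#' @param seed Optional RNG seed; fixed seeds give bit-identical scenes.
#' @param grid NanoSIMS raster size (default 256).
#' @param n_planes Raster repetitions (<= 15).
#' @param transform True SEM -> NanoSIMS transform; random if `NULL`.
#' @param drift_step Per-plane stage-drift step amplitude (px); the drift is
#'   a clipped integer random walk starting at (0, 0).
#' @param max_drift Clip for the cumulative drift (px).
#' @return A `silksims_scene`: label/cell-id/organelle-id images, the true
#'   delta field, a rendered SEM image, per-cell and per-organelle ground
#'   truth tibbles, and the acquisition parameters.
#' @export
build_scene <- function(preset, n_cells, sem_size = 1024, seed = NULL,
                        grid = 256, n_planes = 6, transform = NULL,
                        drift_step = 1, max_drift = 3) {
  stopifnot(inherits(preset, "silksims_preset"), n_cells >= 1, sem_size >= 256,
            grid >= 32, n_planes >= 1, n_planes <= 15)
  if (!is.null(seed)) set.seed(seed)
  geom <- preset$geometry
  nr <- sem_size; nc <- sem_size

  label <- matrix(COMPARTMENT_CLASSES[["background"]], nr, nc)
  cellid <- matrix(0L, nr, nc)
  orgid <- matrix(0L, nr, nc)
  dfield <- matrix(0, nr, nc)

  if (is.null(transform)) transform <- random_scene_transform(sem_size, grid)

  cells <- place_cells(n_cells, geom, sem_size, transform, grid)

  cd <- preset$compartment_delta
  cv <- preset$whole_cell[["sd"]] / max(preset$whole_cell[["mean"]], 1e-9)
  org_counter <- 0L
  org_rows <- list()
  cell_rows <- list()

  for (i in seq_len(n_cells)) {
    ci <- cells[[i]]
    g_i <- max(0.05, 1 + rnorm(1, 0, cv))
    c_i <- cd$cytoplasm[["mean"]] * g_i
    nuc_i <- c_i + preset$nuc_minus_cyt[["mean"]] + rnorm(1, 0, preset$nuc_minus_cyt[["sd"]])

    px <- ellipse_pixels(ci$cx, ci$cy, ci$a, ci$b, ci$theta, nr, nc)
    label[px] <- COMPARTMENT_CLASSES[["cytoplasm"]]
    cellid[px] <- i
    dfield[px] <- c_i

    # nucleus: concentric ellipse at half the cell axes, slightly offset
    off <- runif(1, 0, geom$nucleus_offset_frac * ci$a)
    ang <- runif(1, 0, 2 * pi)
    ncx <- ci$cx + off * cos(ang); ncy <- ci$cy + off * sin(ang)
    na_ <- geom$nucleus_scale * ci$a; nb_ <- geom$nucleus_scale * ci$b
    npx <- ellipse_pixels(ncx, ncy, na_, nb_, ci$theta, nr, nc)
    label[npx] <- COMPARTMENT_CLASSES[["nucleus"]]
    dfield[npx] <- nuc_i

    nucleolus_present <- runif(1) < preset$nucleolus_prob
    if (nucleolus_present) {
      rn <- max(4, rnorm(1, geom$nucleolus_radius[1], geom$nucleolus_radius[2]))
      lim <- max(0, min(na_, nb_) - rn - 2)
      d0 <- runif(1, 0, 0.6 * lim); a0 <- runif(1, 0, 2 * pi)
      qpx <- ellipse_pixels(ncx + d0 * cos(a0), ncy + d0 * sin(a0), rn, rn, 0, nr, nc)
      label[qpx] <- COMPARTMENT_CLASSES[["nucleolus"]]
      dfield[qpx] <- max(-999, (preset$nucleolus_ratio + rnorm(1, 0, preset$nucleolus_sd)) * c_i)
    }

    # organelles live in the cytoplasm; candidates must land entirely on
    # unclaimed cytoplasm of this cell
    free_ok <- function(px_) {
      nrow(px_) > 0 &&
        all(label[px_] == COMPARTMENT_CLASSES[["cytoplasm"]] & cellid[px_] == i)
    }

    # place the large ribbon-shaped Golgi first, while the cytoplasm is clear
    for (k in seq_len(geom$n_golgi)) {
      for (try in 1:150) {
        r <- runif(1, geom$golgi_radius[1], geom$golgi_radius[2])
        span <- runif(1, geom$golgi_span_deg[1], geom$golgi_span_deg[2]) * pi / 180
        phi <- runif(1, 0, 2 * pi)
        pos <- random_point_in_ellipse(ci, margin = r + geom$golgi_thickness / 2 + 2)
        cand <- arc_pixels(pos[1], pos[2], r, geom$golgi_thickness, phi, span, nr, nc)
        if (free_ok(cand)) {
          org_counter <- org_counter + 1L
          dv <- organelle_delta(preset, "golgi", c_i)
          label[cand] <- COMPARTMENT_CLASSES[["golgi"]]
          orgid[cand] <- org_counter
          dfield[cand] <- dv
          org_rows[[org_counter]] <- tibble(
            organelle_id = org_counter, cell_id = i, class = "golgi",
            true_delta = dv, true_aspect = NA_real_, n_px = nrow(cand))
          break
        }
      }
    }

    mitos <- list()
    for (k in seq_len(geom$n_mitochondria)) {
      for (try in 1:150) {
        A <- max(120, rnorm(1, geom$mito_area[1], geom$mito_area[2]))
        rho <- max(1.05, rnorm(1, preset$mito_aspect[["mean"]], preset$mito_aspect[["sd"]]))
        sa <- sqrt(A * rho / pi); sb <- sqrt(A / (rho * pi))
        th <- runif(1, 0, pi)
        pos <- random_point_in_ellipse(ci, margin = sa + 2)
        cand <- ellipse_pixels(pos[1], pos[2], sa, sb, th, nr, nc)
        if (free_ok(cand)) {
          org_counter <- org_counter + 1L
          dv <- organelle_delta(preset, "mitochondrion", c_i)
          label[cand] <- COMPARTMENT_CLASSES[["mitochondrion"]]
          orgid[cand] <- org_counter
          dfield[cand] <- dv
          mitos[[length(mitos) + 1]] <- list(id = org_counter, cx = pos[1], cy = pos[2],
                                             a = sa, b = sb, theta = th, px = cand)
          org_rows[[org_counter]] <- tibble(
            organelle_id = org_counter, cell_id = i, class = "mitochondrion",
            true_delta = dv, true_aspect = rho, n_px = nrow(cand))
          break
        }
      }
    }

    for (k in seq_len(geom$n_lysosomes)) {
      for (try in 1:150) {
        r <- max(4, rnorm(1, geom$lysosome_radius[1], geom$lysosome_radius[2]))
        pos <- random_point_in_ellipse(ci, margin = r + 2)
        cand <- ellipse_pixels(pos[1], pos[2], r, r, 0, nr, nc)
        if (free_ok(cand)) {
          org_counter <- org_counter + 1L
          mix <- preset$lysosome_mixture
          high <- runif(1) < mix$fraction_high
          ratio <- rnorm(1, if (high) mix$ratio_high else mix$ratio_low,
                         if (high) mix$sd_high else mix$sd_low)
          dv <- max(-999, ratio * c_i)
          label[cand] <- COMPARTMENT_CLASSES[["lysosome"]]
          orgid[cand] <- org_counter
          dfield[cand] <- dv
          org_rows[[org_counter]] <- tibble(
            organelle_id = org_counter, cell_id = i, class = "lysosome",
            true_delta = dv, true_aspect = NA_real_, n_px = nrow(cand))
          break
        }
      }
    }

    # ER segments: plant contacts at the preset rate, keep the rest clear of
    # mitochondria so detected contacts are exactly the planted ones
    mito_perim_um <- sum(vapply(mitos, function(m) {
      ellipse_perimeter(m$a, m$b) * geom$pixel_size_nm / 1000
    }, numeric(1)))
    n_plant <- min(geom$n_er, rpois(1, preset$merc_rate * mito_perim_um))
    planted <- 0L
    if (length(mitos) > 0 && n_plant > 0) {
      # a planted contact must put ER pixels directly adjacent (8-neighbour)
      # to the mitochondrial outer boundary, i.e. zero membrane-gap pixels
      touches <- function(cand, mito_px) {
        if (nrow(cand) == 0) return(FALSE)
        for (i in seq_len(nrow(cand))) {
          if (any(abs(mito_px[, 1] - cand[i, 1]) <= 1 &
                  abs(mito_px[, 2] - cand[i, 2]) <= 1)) return(TRUE)
        }
        FALSE
      }
      for (k in seq_len(n_plant)) {
        for (try in 1:40) {
          m <- mitos[[sample.int(length(mitos), 1)]]
          tpar <- runif(1, 0, 2 * pi)
          bx <- m$cx + cos(m$theta) * m$a * cos(tpar) - sin(m$theta) * m$b * sin(tpar)
          by <- m$cy + sin(m$theta) * m$a * cos(tpar) + cos(m$theta) * m$b * sin(tpar)
          nvec <- c(cos(m$theta) * cos(tpar) / m$a - sin(m$theta) * sin(tpar) / m$b,
                    sin(m$theta) * cos(tpar) / m$a + cos(m$theta) * sin(tpar) / m$b)
          nvec <- nvec / sqrt(sum(nvec^2))
          tang <- atan2(-nvec[1], nvec[2])
          L <- max(12, rnorm(1, 22, 4))
          cand <- NULL
          for (off in c(1.2 + geom$er_width / 2, 0.8 + geom$er_width / 2,
                        1.6 + geom$er_width / 2)) {
            trial <- rect_pixels(bx + nvec[1] * off, by + nvec[2] * off,
                                 L, geom$er_width, tang, nr, nc)
            if (free_ok(trial) && touches(trial, m$px)) { cand <- trial; break }
          }
          if (!is.null(cand)) {
            org_counter <- org_counter + 1L
            dv <- organelle_delta(preset, "ER", c_i)
            label[cand] <- COMPARTMENT_CLASSES[["ER"]]
            orgid[cand] <- org_counter
            dfield[cand] <- dv
            org_rows[[org_counter]] <- tibble(
              organelle_id = org_counter, cell_id = i, class = "ER",
              true_delta = dv, true_aspect = NA_real_, n_px = nrow(cand))
            planted <- planted + 1L
            break
          }
        }
      }
    }
    n_free_er <- geom$n_er - planted
    if (n_free_er > 0) {
      mito_clear <- mito_clearance_mask(mitos, ci, nr, nc, clearance = 4)
      for (k in seq_len(n_free_er)) {
        for (try in 1:150) {
          L <- max(15, rnorm(1, geom$er_length[1], geom$er_length[2]))
          th <- runif(1, 0, pi)
          pos <- random_point_in_ellipse(ci, margin = L / 2 + 2)
          cand <- rect_pixels(pos[1], pos[2], L, geom$er_width, th, nr, nc)
          if (free_ok(cand) && !any(mito_clear[cand])) {
            org_counter <- org_counter + 1L
            dv <- organelle_delta(preset, "ER", c_i)
            label[cand] <- COMPARTMENT_CLASSES[["ER"]]
            orgid[cand] <- org_counter
            dfield[cand] <- dv
            org_rows[[org_counter]] <- tibble(
              organelle_id = org_counter, cell_id = i, class = "ER",
              true_delta = dv, true_aspect = NA_real_, n_px = nrow(cand))
            break
          }
        }
      }
    }

    cell_rows[[i]] <- tibble(
      cell_id = i, cx = ci$cx, cy = ci$cy, a = ci$a, b = ci$b, theta = ci$theta,
      cytoplasm_delta_true = c_i, nucleus_delta_true = nuc_i,
      nuc_minus_cyt_true = nuc_i - c_i,
      nucleolus_present = nucleolus_present, merc_planted = planted
    )
  }

  cells_tbl <- dplyr::bind_rows(cell_rows)
  # realized whole-cell ground truth (area-weighted over all painted pixels)
  cells_tbl$whole_cell_delta_true <- vapply(seq_len(n_cells), function(i) {
    mean(dfield[cellid == i])
  }, numeric(1))

  drift <- drift_walk(n_planes, drift_step, max_drift)
  fov_um <- sem_size * geom$pixel_size_nm / 1000
  acquisition <- list(
    grid = grid, n_planes = n_planes, fov_um = fov_um,
    pixel_size_um = fov_um / grid,
    transform_true = transform, drift_per_plane = drift,
    lambda_total = c(background = preset$lambda_background, cell = preset$lambda_cell),
    r_nat = preset$r_nat, sem_pixel_size_nm = geom$pixel_size_nm
  )

  scene <- structure(list(
    label_image = label, cell_id_image = cellid, organelle_id_image = orgid,
    true_delta_field = dfield, sem_image = NULL,
    cells = cells_tbl,
    organelles = dplyr::bind_rows(org_rows),
    acquisition = acquisition,
    preset = preset,
    provenance = list(preset = preset$name, seed = seed, n_cells = n_cells)
  ), class = "silksims_scene")
  scene$sem_image <- render_sem(scene, noise_sd = 0.02)
  scene
}

#' @export
print.silksims_scene <- function(x, ...) {
  cat(sprintf("<silksims_scene> %s: %d cell(s), %d organelle(s), %d x %d px SEM, %d px raster\n",
              x$provenance$preset, nrow(x$cells), nrow(x$organelles),
              nrow(x$label_image), ncol(x$label_image), x$acquisition$grid))
  invisible(x)
}

# Rejection-sample non-overlapping cell placements that stay inside both the
# SEM frame and the mapped raster; aborts with a placement count if the
# field cannot host the requested cells.
place_cells <- function(n_cells, geom, sem_size, transform, grid) {
  cells <- list()
  for (i in seq_len(n_cells)) {
    placed <- FALSE
    for (try in 1:300) {
      a <- runif(1, geom$cell_semi_axis_a[1], geom$cell_semi_axis_a[2])
      b <- runif(1, geom$cell_semi_axis_b[1], geom$cell_semi_axis_b[2])
      th <- runif(1, 0, pi)
      rmax <- max(a, b)
      lo <- geom$cell_margin_px + rmax
      hi <- sem_size - 1 - geom$cell_margin_px - rmax
      if (hi <= lo) abort("SEM frame too small for the cell geometry.")
      cx <- runif(1, lo, hi); cy <- runif(1, lo, hi)
      ok <- TRUE
      for (cj in cells) {
        if (sqrt((cx - cj$cx)^2 + (cy - cj$cy)^2) <
            rmax + max(cj$a, cj$b) + geom$min_cell_gap_px) { ok <- FALSE; break }
      }
      if (ok) {
        # the whole cell must land inside the raster
        ang <- seq(0, 2 * pi, length.out = 17)[-17]
        bnd <- cbind(cx + rmax * cos(ang), cy + rmax * sin(ang))
        mapped <- transform_points(transform, bnd)
        if (any(mapped < 1) || any(mapped > grid - 2)) ok <- FALSE
      }
      if (ok) {
        cells[[i]] <- list(cx = cx, cy = cy, a = a, b = b, theta = th)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort(sprintf("could only place %d of %d cells without overlap; reduce n_cells or enlarge the frame.",
                    i - 1L, n_cells))
    }
  }
  cells
}

random_point_in_ellipse <- function(cell, margin = 0) {
  # uniform in the shrunken ellipse so the shape fits with `margin` clearance
  fa <- max(0.05, 1 - margin / cell$a)
  fb <- max(0.05, 1 - margin / cell$b)
  u <- sqrt(runif(1)); v <- runif(1, 0, 2 * pi)
  ex <- cell$a * fa * u * cos(v); ey <- cell$b * fb * u * sin(v)
  c(cell$cx + ex * cos(cell$theta) - ey * sin(cell$theta),
    cell$cy + ex * sin(cell$theta) + ey * cos(cell$theta))
}

organelle_delta <- function(preset, class, c_i) {
  mode <- (preset$organelle_modes %||% c())[class]
  if (identical(unname(mode), "diff")) {
    return(max(-999, c_i + preset$organelle_diffs[[class]] +
                 rnorm(1, 0, preset$organelle_diff_sds[[class]])))
  }
  r <- preset$organelle_ratios[[class]] +
    rnorm(1, 0, preset$organelle_ratio_sds[[class]])
  max(-999, r * c_i)
}

ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

mito_clearance_mask <- function(mitos, cell, nr, nc, clearance = 4) {
  m <- matrix(FALSE, nr, nc)
  for (mt in mitos) {
    px <- ellipse_pixels(mt$cx, mt$cy, mt$a + clearance, mt$b + clearance,
                         mt$theta, nr, nc)
    m[px] <- TRUE
  }
  m
}

drift_walk <- function(n_planes, step, max_drift) {
  d <- matrix(0L, n_planes, 2, dimnames = list(NULL, c("dy", "dx")))
  if (n_planes > 1 && step > 0) {
    for (p in 2:n_planes) {
      d[p, ] <- as.integer(pmin(max_drift, pmax(-max_drift,
                                                d[p - 1, ] + sample((-step):step, 2, replace = TRUE))))
    }
  }
  d
}

#' Render the SEM backscatter image of a scene
#'
#' Class-dependent gray levels (inverted-contrast backscatter look: osmium-
#' dense organelles dark, resin bright) plus Gaussian noise. Deterministic
#' for a fixed RNG state.
#'
#' @param scene A `silksims_scene`.
#' @param noise_sd Gaussian noise SD on the [0, 1] gray scale.
#' @return Numeric matrix in [0, 1].
#' @export
render_sem <- function(scene, noise_sd = 0.02) {
  levels <- c(background = 0.85, cytoplasm = 0.55, nucleus = 0.65,
              nucleolus = 0.30, mitochondrion = 0.35, golgi = 0.45,
              lysosome = 0.22, ER = 0.50)
  code2level <- numeric(length(COMPARTMENT_CLASSES))
  code2level[COMPARTMENT_CLASSES + 1] <- levels[names(COMPARTMENT_CLASSES)]
  img <- matrix(code2level[scene$label_image + 1L],
                nrow(scene$label_image), ncol(scene$label_image))
  if (noise_sd > 0) {
    img <- img + matrix(rnorm(length(img), 0, noise_sd), nrow(img), ncol(img))
  }
  matrix(pmin(1, pmax(0, img)), nrow(img), ncol(img))
}
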