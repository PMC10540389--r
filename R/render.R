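# Simulated NanoSIMS acquisition of a ground-truth scene.
#
# Each raster plane samples the scene through the true SEM->NanoSIMS
# transform (plus that plane's integer stage drift). The expected total CN-
# rate lambda of the underlying tissue class is split between the two
# isotopologues by the local enrichment:
#   R = R_nat * (1 + delta/1000),  lambda13 = lambda R/(1+R),
#   lambda12 = lambda/(1+R),
# and counts are independent Poisson draws per pixel, plane and species.
# No dead-time, quasi-simultaneous-arrival or topographic effects are
# modeled; shot noise is the only detection noise.

#' Render a simulated NanoSIMS ion-count stack
#'
#' @param scene A `silksims_scene`.
#' @param n_planes Override for the number of raster planes (default from
#'   the scene's acquisition parameters).
#' @param metadata Extra metadata merged into the stack metadata.
#' @return A `sims_stack` with `12C14N` and `13C14N` count arrays.
#' @export
render_nanosims <- function(scene, n_planes = NULL, metadata = list()) {
  stopifnot(inherits(scene, "silksims_scene"))
  acq <- scene$acquisition
  np <- n_planes %||% acq$n_planes
  grid <- acq$grid
  drift <- acq$drift_per_plane
  if (nrow(drift) < np) {
    drift <- rbind(drift, matrix(rep(drift[nrow(drift), ], np - nrow(drift)),
                                 ncol = 2, byrow = TRUE))
  }
  inv <- invert_transform(acq$transform_true)
  sem_dim <- dim(scene$label_image)
  r_nat <- acq$r_nat
  lam_bg <- acq$lambda_total[["background"]]
  lam_cell <- acq$lambda_total[["cell"]]

  nrg <- grid; ncg <- grid
  xs <- rep(0:(ncg - 1), each = nrg)   # column-major order
  ys <- rep(0:(nrg - 1), times = ncg)

  c12 <- array(0L, c(nrg, ncg, np))
  c13 <- array(0L, c(nrg, ncg, np))
  any_inside <- FALSE
  for (p in seq_len(np)) {
    sem <- transform_points(inv, cbind(xs - drift[p, "dx"], ys - drift[p, "dy"]))
    sc <- as.integer(round(sem[, 1])); sr <- as.integer(round(sem[, 2]))
    ok <- sc >= 0 & sc < sem_dim[2] & sr >= 0 & sr < sem_dim[1]
    any_inside <- any_inside || any(ok)
    lam <- rep(lam_bg, length(xs))
    dlt <- numeric(length(xs))
    if (any(ok)) {
      idx <- sr[ok] + 1L + sc[ok] * sem_dim[1]
      inside_cell <- scene$cell_id_image[idx] > 0L
      lam[ok][inside_cell] <- lam_cell
      dlt[ok] <- scene$true_delta_field[idx]
    }
    R <- r_nat * (1 + dlt / 1000)
    l13 <- lam * R / (1 + R)
    l12 <- lam - l13
    c12[, , p] <- rpois(length(l12), l12)
    c13[, , p] <- rpois(length(l13), l13)
  }
  if (!any_inside) {
    abort("acquisition transform maps the raster entirely outside the scene.")
  }

  ion_count_stack(
    c12, c13, pixel_size_um = acq$pixel_size_um, dwell_ms = 5,
    metadata = c(list(preset = scene$provenance$preset,
                      condition = scene$preset$condition,
                      timepoint_h = scene$preset$timepoint_h,
                      seed = scene$provenance$seed), metadata)
  )
}
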