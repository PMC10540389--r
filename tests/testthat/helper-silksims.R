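# Shared fixtures and independent oracles for the test suite.

# Desk-scale geometry for fast tests: smaller cells and fewer organelles.
small_geometry <- function() {
  g <- scene_geometry()
  g$cell_semi_axis_a <- c(46, 54)
  g$cell_semi_axis_b <- c(38, 46)
  g$n_mitochondria <- 5L
  g$mito_area <- c(200, 25)
  g$n_golgi <- 2L
  g$golgi_radius <- c(11, 15)
  g$golgi_thickness <- 8
  g$n_lysosomes <- 4L
  g$lysosome_radius <- c(6, 0.8)
  g$n_er <- 4L
  g$er_length <- c(28, 5)
  g$cell_margin_px <- 14
  g$min_cell_gap_px <- 8
  g
}

small_preset <- function(name = "test-control-48h", ...) {
  defaults <- list(
    name = name, region = "SNpc", condition = "control", timepoint_h = 48,
    whole_cell = 259, whole_cell_sd = 48, nuc_minus_cyt = 25,
    geometry = small_geometry()
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(scene_preset, args)
}

# All compartments at exactly 0 permil, no variability anywhere.
zero_preset <- function(lambda_cell = 1500, lambda_background = 300) {
  scene_preset(
    name = "test-null", region = "SNpc", condition = "control", timepoint_h = 48,
    whole_cell = 0, whole_cell_sd = 0, nuc_minus_cyt = 0, nuc_minus_cyt_sd = 0,
    organelle_ratio_sds = c(mitochondrion = 0, golgi = 0, ER = 0),
    lysosome_mixture = list(fraction_high = 0.5, ratio_high = 1, ratio_low = 1,
                            sd_high = 0, sd_low = 0),
    nucleolus_sd = 0,
    lambda_cell = lambda_cell, lambda_background = lambda_background,
    geometry = small_geometry()
  )
}

make_test_scene <- function(preset = small_preset(), n_cells = 2, seed = 42,
                            sem_size = 256, grid = 128, n_planes = 3, ...) {
  build_scene(preset, n_cells = n_cells, sem_size = sem_size, seed = seed,
              grid = grid, n_planes = n_planes, ...)
}

# --- Mann-Whitney enumeration oracle -----------------------------------------
# Exact two-sided p by enumerating every assignment of the pooled values to
# the two groups (valid when there are no ties).
mw_enum <- function(x, y) {
  pooled <- c(x, y)
  n_x <- length(x)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  combos <- utils::combn(length(pooled), n_x)
  us <- apply(combos, 2, u_of)
  u_obs <- u_of(seq_len(n_x))
  mu <- n_x * (length(pooled) - n_x) / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  list(U = u_obs, p = min(1, p))
}

# --- Direct (brute force) normalized cross-correlation oracle ----------------
ncc_brute <- function(ref, plane, m) {
  nr <- nrow(ref); nc <- ncol(ref)
  cand <- expand.grid(dy = -m:m, dx = -m:m)
  cand <- cand[order(abs(cand$dy) + abs(cand$dx), cand$dy, cand$dx), ]
  best <- -Inf; best_s <- c(0L, 0L)
  for (i in seq_len(nrow(cand))) {
    dy <- cand$dy[i]; dx <- cand$dx[i]
    rr <- max(1, 1 - dy):min(nr, nr - dy)
    cc <- max(1, 1 - dx):min(nc, nc - dx)
    a <- as.vector(ref[rr, cc]); b <- as.vector(plane[rr + dy, cc + dx])
    if (sd(a) == 0 || sd(b) == 0) next
    v <- stats::cor(a, b)
    if (v > best + 1e-10) { best <- v; best_s <- c(dy, dx) }
  }
  as.integer(best_s)
}

# Handcrafted drifting stack: a fixed smooth intensity pattern observed with
# per-plane content displacement `shifts` (rows of dy, dx) and Poisson noise.
drift_stack <- function(shifts, lambda = 20, n = 64, r_nat = 0.011, seed = 1) {
  set.seed(seed)
  gx <- outer(seq_len(n), seq_len(n), function(r, c) {
    1 + 0.9 * sin(2 * pi * r / 17) * cos(2 * pi * c / 23) +
      0.5 * sin(2 * pi * (r + c) / 31)
  })
  base <- lambda * (gx - min(gx) + 0.2) / mean(gx - min(gx) + 0.2)
  wrap_shift <- function(m, dy, dx) {
    m[((seq_len(n) - 1 - dy) %% n) + 1, ((seq_len(n) - 1 - dx) %% n) + 1]
  }
  np <- nrow(shifts)
  c12 <- array(0L, c(n, n, np)); c13 <- array(0L, c(n, n, np))
  for (p in seq_len(np)) {
    lam <- wrap_shift(base, shifts[p, 1], shifts[p, 2])
    c12[, , p] <- rpois(n * n, lam / (1 + r_nat))
    c13[, , p] <- rpois(n * n, lam * r_nat / (1 + r_nat))
  }
  ion_count_stack(c12, c13, pixel_size_um = 0.2)
}

# Accumulated-image constructor for handcrafted count matrices.
acc_from_counts <- function(n12, n13, pixel_size_um = 0.2) {
  structure(list(
    n12 = n12, n13 = n13, mask = matrix(TRUE, nrow(n12), ncol(n12)),
    shifts = matrix(0L, 1, 2, dimnames = list(NULL, c("dy", "dx"))),
    pixel_size_um = pixel_size_um, dwell_ms = 5, n_planes = 1, metadata = list()
  ), class = "silksims_accumulated")
}

identity_transform <- function() {
  silksims:::new_planar_transform(cbind(diag(2), c(0, 0)))
}

expect_scene_consistent <- function(scene) {
  lab <- scene$label_image
  cid <- scene$cell_id_image
  testthat::expect_identical(dim(lab), dim(cid))
  testthat::expect_identical(dim(lab), dim(scene$true_delta_field))
  # intracellular labels only inside cells; background only outside
  inside <- lab != 0
  testthat::expect_true(all(cid[inside] > 0))
  testthat::expect_true(all(cid[!inside] == 0))
  testthat::expect_true(all(scene$true_delta_field >= -1000))
  org <- scene$organelle_id_image
  testthat::expect_true(all(lab[org > 0] %in% c(4L, 5L, 6L, 7L)))
}
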