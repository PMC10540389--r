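# Landmark registration and ROI transport.

test_that("identity landmarks give the identity transform with zero residual", {
  pts <- tibble::tibble(x_sem = c(0, 10, 3), y_sem = c(0, 0, 7),
                        x_sims = c(0, 10, 3), y_sims = c(0, 0, 7))
  tf <- fit_affine(pts)
  expect_equal(tf$M, cbind(diag(2), c(0, 0)), tolerance = 1e-12)
  expect_equal(tf$rmse, 0, tolerance = 1e-9)
  expect_identical(tf$n_points, 3L)
})

test_that("a pure 90-degree rotation is recovered exactly from 3 pairs", {
  pts <- tibble::tibble(x_sem = c(0, 1, 0), y_sem = c(0, 0, 1),
                        x_sims = c(0, 0, -1), y_sims = c(0, 1, 0))
  tf <- fit_affine(pts)
  expect_equal(tf$M[, 1:2], matrix(c(0, 1, -1, 0), 2, 2), tolerance = 1e-12)
  expect_equal(tf$rmse, 0, tolerance = 1e-9)
})

test_that("degenerate landmark sets are rejected", {
  expect_error(fit_affine(tibble::tibble(x_sem = c(0, 1), y_sem = c(0, 1),
                                         x_sims = c(0, 1), y_sims = c(0, 1))),
               "at least 3")
  coll <- tibble::tibble(x_sem = c(0, 1, 2, 3), y_sem = c(0, 1, 2, 3),
                         x_sims = c(0, 1, 2, 3), y_sims = c(0, 1, 2, 3))
  expect_error(fit_affine(coll), "collinear")
  expect_error(fit_affine(tibble::tibble(a = 1)), "lack columns")
})

test_that("jittered landmarks recover a known affine within 0.5 NanoSIMS px RMS", {
  rms <- vapply(1:25, function(s) {
    set.seed(s)
    tf_true <- random_scene_transform(1024, 256)
    lm <- make_landmarks(tf_true, c(1024, 1024), n = 6, jitter_sem_px = 0.5)
    tf_fit <- fit_affine(lm)
    test_pts <- cbind(runif(200, 0, 1023), runif(200, 0, 1023))
    d <- transform_points(tf_fit, test_pts) - transform_points(tf_true, test_pts)
    sqrt(mean(rowSums(d^2)))
  }, numeric(1))
  expect_true(all(rms <= 0.5))
})

test_that("transform inversion composes to the identity", {
  set.seed(11)
  tf <- random_scene_transform(1024, 256)
  inv <- invert_transform(tf)
  pts <- cbind(runif(50, 0, 1000), runif(50, 0, 1000))
  back <- transform_points(inv, transform_points(tf, pts))
  expect_equal(back, pts, tolerance = 1e-9)
})

test_that("pixel-center rasterization honors the lower/left boundary rule", {
  # unit square through the crossing test directly
  sq <- rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4))
  expect_true(point_in_polygon(0, 2, sq))    # left edge in
  expect_false(point_in_polygon(4, 2, sq))   # right edge out
  expect_true(point_in_polygon(2, 0, sq))    # bottom edge in
  expect_false(point_in_polygon(2, 4, sq))   # top edge out
  expect_true(point_in_polygon(0, 0, sq))    # lower-left corner in
  expect_false(point_in_polygon(4, 4, sq))   # upper-right corner out
})

test_that("an axis-aligned square with corners on pixel centers maps to a 4x4 footprint", {
  roi <- list(class = "mitochondrion", cell_id = 1L,
              geometry = list(type = "polygon",
                              vertices = rbind(c(2, 2), c(6, 2), c(6, 6), c(2, 6))))
  fp <- map_roi(identity_transform(), roi, grid_dim = c(12, 12))
  expect_identical(nrow(fp$pixels), 16L)
  expect_equal(fp$outside_fraction, 0)
  # brute-force oracle: every grid pixel center tested independently
  centers <- expand.grid(x = 0:11, y = 0:11)
  inside <- point_in_polygon(centers$x, centers$y, roi$geometry$vertices)
  oracle <- centers[inside, ]
  expect_setequal(paste(fp$pixels[, "row"], fp$pixels[, "col"]),
                  paste(oracle$y + 1, oracle$x + 1))
})

test_that("polygons fully outside the grid give an empty flagged footprint", {
  roi <- list(class = "golgi", cell_id = 1L,
              geometry = list(type = "polygon",
                              vertices = rbind(c(50, 50), c(60, 50), c(55, 60))))
  fp <- map_roi(identity_transform(), roi, grid_dim = c(20, 20))
  expect_true(fp$empty)
  expect_equal(fp$outside_fraction, 1)
})

test_that("polygon vertices survive a forward/inverse round trip", {
  set.seed(3)
  tf <- random_scene_transform(512, 128)
  verts <- rbind(c(100, 120), c(200, 130), c(220, 240), c(120, 260))
  back <- transform_points(invert_transform(tf), transform_points(tf, verts))
  expect_equal(back, verts, tolerance = 1e-9)
})

test_that("resample_to_sem pulls the map back unchanged under the identity", {
  n12 <- matrix(1000, 16, 16); n13 <- matrix(11, 16, 16)
  dmap <- delta_map(acc_from_counts(n12, n13), r_nat = 0.011, min_counts = 10)
  out <- resample_to_sem(dmap, identity_transform(), c(16, 16))
  expect_equal(out, dmap$delta, tolerance = 1e-12)
  # uniform enrichment stays uniform inside the footprint
  dmap2 <- delta_map(acc_from_counts(n12, matrix(16.5, 16, 16)), 0.011, 10)
  out2 <- resample_to_sem(dmap2, identity_transform(), c(16, 16))
  expect_true(all(abs(out2 - 500) < 1e-9))
})

test_that("resampled class boundaries agree with the label image near edges", {
  scene <- make_test_scene(zero_preset(), n_cells = 1, seed = 7)
  # a delta map carrying the pulled-back cell-id signal via lambda contrast:
  # use the true transform to resample the (0-enrichment) map and check the
  # footprint of valid pixels covers the cell interior
  stack <- render_nanosims(scene)
  acc <- accumulate(stack, estimate_plane_shifts(stack, max_shift = 3))
  dmap <- delta_map(acc, 0.011, min_counts = 50)
  res <- resample_to_sem(dmap, scene$acquisition$transform_true, dim(scene$label_image))
  # interior cell pixels (eroded by a few px) must be covered by valid values
  ci <- scene$cells[1, ]
  inner <- silksims:::ellipse_pixels(ci$cx, ci$cy, ci$a - 6, ci$b - 6, ci$theta,
                                     nrow(res), ncol(res))
  expect_lt(mean(is.na(res[inner])), 0.01)
})

test_that("self-intersection detection separates bowties from simple rings", {
  bowtie <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  square <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  expect_true(silksims:::polygon_self_intersects(bowtie))
  expect_false(silksims:::polygon_self_intersects(square))
})
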