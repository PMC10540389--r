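# Ground-truth scene construction.

test_that("scenes satisfy the structural invariants", {
  scene <- make_test_scene(n_cells = 2, seed = 21)
  expect_scene_consistent(scene)
  expect_identical(nrow(scene$cells), 2L)
  expect_gt(nrow(scene$organelles), 0L)
  expect_true(all(scene$organelles$class %in%
                    c("mitochondrion", "golgi", "lysosome", "ER")))
})

test_that("an all-zero preset paints an identically zero delta field", {
  scene <- make_test_scene(zero_preset(), n_cells = 1, seed = 5)
  expect_true(all(scene$true_delta_field == 0))
})

test_that("compartment ground truth is exact when between-cell SDs are zero", {
  p <- small_preset(whole_cell_sd = 0, nuc_minus_cyt_sd = 0,
                    organelle_ratio_sds = c(mitochondrion = 0, golgi = 0, ER = 0),
                    lysosome_mixture = list(fraction_high = 1, ratio_high = 1.79,
                                            ratio_low = 1, sd_high = 0, sd_low = 0),
                    nucleolus_sd = 0)
  scene <- make_test_scene(p, n_cells = 2, seed = 9)
  lab <- scene$label_image; d <- scene$true_delta_field
  cyt <- unique(d[lab == 1])
  expect_equal(cyt, p$compartment_delta$cytoplasm[["mean"]], tolerance = 1e-9)
  expect_equal(unique(d[lab == 2]), p$compartment_delta$nucleus[["mean"]],
               tolerance = 1e-9)
  expect_equal(sort(unique(d[lab == 4])),
               sort(unique(p$organelle_ratios[["mitochondrion"]] *
                             scene$cells$cytoplasm_delta_true)), tolerance = 1e-9)
  # per-cell nucleus - cytoplasm equals the preset difference exactly
  expect_equal(scene$cells$nuc_minus_cyt_true, rep(25, 2), tolerance = 1e-9)
})

test_that("whole-cell ground truth tracks the preset target across cells", {
  p <- small_preset(whole_cell_sd = 0, nuc_minus_cyt_sd = 0,
                    organelle_ratio_sds = c(mitochondrion = 0, golgi = 0, ER = 0))
  scene <- make_test_scene(p, n_cells = 3, seed = 31, sem_size = 360)
  # realized areas differ from the design fractions, so allow a small
  # geometric tolerance around the calibration target
  expect_equal(mean(scene$cells$whole_cell_delta_true), 259, tolerance = 0.04)
})

test_that("mitochondrial aspect ratios separate the conditions", {
  ctrl <- make_test_scene(small_preset(), n_cells = 3, seed = 12)
  asyn <- make_test_scene(small_preset(condition = "asyn",
                                       mito_aspect = c(mean = 1.6, sd = 0.4)),
                          n_cells = 3, seed = 12)
  a_c <- ctrl$organelles$true_aspect[ctrl$organelles$class == "mitochondrion"]
  a_a <- asyn$organelles$true_aspect[asyn$organelles$class == "mitochondrion"]
  expect_gt(mean(a_c), mean(a_a))
})

test_that("scene construction is reproducible bit for bit", {
  s1 <- make_test_scene(n_cells = 2, seed = 77)
  s2 <- make_test_scene(n_cells = 2, seed = 77)
  expect_identical(s1$label_image, s2$label_image)
  expect_identical(s1$true_delta_field, s2$true_delta_field)
  expect_identical(s1$sem_image, s2$sem_image)
  expect_equal(s1$cells, s2$cells)
})

test_that("impossible cell packings fail with a placement report", {
  expect_error(make_test_scene(n_cells = 30, seed = 2, sem_size = 256),
               "place")
})

test_that("the SEM rendering is piecewise constant without noise and bimodal with it", {
  scene <- make_test_scene(n_cells = 1, seed = 4)
  img0 <- render_sem(scene, noise_sd = 0)
  # noiseless image is a deterministic function of the label image
  expect_identical(dim(img0), dim(scene$label_image))
  for (code in unique(as.vector(scene$label_image))) {
    expect_identical(length(unique(img0[scene$label_image == code])), 1L)
  }
  set.seed(1); img1 <- render_sem(scene, noise_sd = 0.02)
  set.seed(1); img2 <- render_sem(scene, noise_sd = 0.02)
  expect_identical(img1, img2)
  # gray histogram splits into background and cytoplasm modes
  h <- hist(img1, breaks = seq(0, 1, by = 0.05), plot = FALSE)
  mids <- h$mids; cnt <- h$counts
  bg_mode <- sum(cnt[mids > 0.80 & mids < 0.90])
  cyt_mode <- sum(cnt[mids > 0.50 & mids < 0.60])
  valley <- sum(cnt[mids > 0.70 & mids < 0.75])
  expect_gt(bg_mode, 10 * max(valley, 1))
  expect_gt(cyt_mode, 10 * max(valley, 1))
})
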