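# ROI quantification and per-cell summaries.

test_that("a uniform-ratio region yields the per-pixel delta", {
  n12 <- matrix(2000, 6, 6); n13 <- matrix(2000 * 0.011 * 1.2, 6, 6)
  acc <- acc_from_counts(n12, n13)
  m <- measure_roi(acc, cbind(row = c(1, 2, 3), col = c(1, 1, 2)), 0.011)
  expect_equal(m$delta, 200, tolerance = 1e-9)
  expect_equal(m$area_px, 3L)
})

test_that("ratio-of-sums differs from mean-of-ratios as documented", {
  # two pixels (N12, N13) = (100, 1) and (300, 9)
  n12 <- matrix(c(100, 300), 1); n13 <- matrix(c(1, 9), 1)
  acc <- acc_from_counts(n12, n13)
  m <- measure_roi(acc, cbind(row = c(1, 1), col = c(1, 2)), 0.011)
  d_sums <- (10 / 400 / 0.011 - 1) * 1000
  d_mean <- mean((c(1 / 100, 9 / 300) / 0.011 - 1) * 1000)
  expect_equal(m$delta, d_sums, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(d_sums, d_mean)))
  expect_equal(d_sums, 1272.727, tolerance = 1e-4)
  expect_equal(d_mean, 818.182, tolerance = 1e-4)
})

test_that("empty or fully masked footprints are flagged invalid", {
  acc <- acc_from_counts(matrix(10, 4, 4), matrix(1, 4, 4))
  m0 <- measure_roi(acc, cbind(row = integer(), col = integer()), 0.011)
  expect_false(m0$valid)
  acc$mask[1, 1] <- FALSE
  m1 <- measure_roi(acc, cbind(row = 1L, col = 1L), 0.011)
  expect_false(m1$valid)
})

test_that("ROI delta equals brute-force recomputation from raw plane counts", {
  scene <- make_test_scene(n_cells = 1, seed = 23)
  set.seed(23)
  stack <- render_nanosims(scene)
  shifts <- estimate_plane_shifts(stack, max_shift = 3)
  acc <- accumulate(stack, shifts)
  tf <- scene$acquisition$transform_true
  roi <- list(class = "nucleus", cell_id = 1L,
              geometry = list(type = "label", organelle_id = NA))
  fp <- map_roi(tf, roi, dim(acc$n12), scene = scene)
  m <- measure_roi(acc, fp, 0.011)
  # oracle: sum the raw plane counts shifted pixel-by-pixel over the footprint
  px <- fp$pixels[acc$mask[fp$pixels], , drop = FALSE]
  tot12 <- 0; tot13 <- 0
  for (p in seq_len(dim(stack$counts[[1]])[3])) {
    for (i in seq_len(nrow(px))) {
      tot12 <- tot12 + stack$counts[["12C14N"]][px[i, 1] + shifts[p, 1],
                                                px[i, 2] + shifts[p, 2], p]
      tot13 <- tot13 + stack$counts[["13C14N"]][px[i, 1] + shifts[p, 1],
                                                px[i, 2] + shifts[p, 2], p]
    }
  }
  expect_identical(m$N12, as.numeric(tot12))
  expect_identical(m$N13, as.numeric(tot13))
  expect_equal(m$delta, (tot13 / tot12 / 0.011 - 1) * 1000, tolerance = 1e-12)
})

test_that("the counting SE matches Monte-Carlo spread and covers the truth", {
  lam12 <- 30000; lam13 <- lam12 * 0.011 * 1.259
  true_delta <- 259
  set.seed(31)
  n12 <- rpois(2000, lam12); n13 <- rpois(2000, lam13)
  deltas <- (n13 / n12 / 0.011 - 1) * 1000
  ses <- (1000 / 0.011) * (n13 / n12) * sqrt(1 / n13 + 1 / n12)
  expect_lt(abs(sd(deltas) / mean(ses) - 1), 0.15)
  coverage <- mean(abs(deltas - true_delta) < 3 * ses)
  expect_gte(coverage, 0.99)
})

test_that("cell summaries implement the organelle normalizations and exclusions", {
  meas <- tibble::tibble(
    region_id = c("w", "cy", "nu", "g1", "m1"),
    cell_id = 1L,
    class = c("cell_body", "cytoplasm", "nucleus", "golgi", "mitochondrion"),
    N12 = 1e5, N13 = 1e3, area_px = 100L, area_um2 = 4,
    delta = c(120, 100, 100, 169, 132), delta_se = 5,
    outside_fraction = 0, valid = TRUE)
  cs <- cell_summary(meas)
  expect_equal(cs$nuc_minus_cyt, 0)
  expect_false(cs$nucleolus_present)
  orgs <- cs$organelles[[1]]
  g <- orgs[orgs$class == "golgi", ]
  expect_equal(g$ratio_to_cytoplasm, 1.69)
  expect_equal(g$diff_from_cytoplasm, 69)
  # ratio and difference encodings stay mutually consistent
  expect_equal(orgs$diff_from_cytoplasm,
               (orgs$ratio_to_cytoplasm - 1) * orgs$cytoplasm_delta,
               tolerance = 1e-9)

  withnll <- dplyr::bind_rows(meas, tibble::tibble(
    region_id = "nll", cell_id = 1L, class = "nucleolus", N12 = 1e4, N13 = 300,
    area_px = 10L, area_um2 = 0.4, delta = 320, delta_se = 10,
    outside_fraction = 0, valid = TRUE))
  cs2 <- cell_summary(withnll)
  expect_true(cs2$nucleolus_present)
  both <- dplyr::bind_rows(cs, cs2)
  both$cell_id <- c(1L, 2L)
  expect_identical(nuclear_analysis_set(both)$cell_id, 1L)
})

test_that("non-positive cytoplasm delta voids ratios but keeps differences", {
  meas <- tibble::tibble(
    region_id = c("w", "cy", "m1"), cell_id = 1L,
    class = c("cell_body", "cytoplasm", "mitochondrion"),
    N12 = 1e5, N13 = 1e3, area_px = 100L, area_um2 = 4,
    delta = c(-5, -10, 30), delta_se = 5, outside_fraction = 0, valid = TRUE)
  orgs <- cell_summary(meas)$organelles[[1]]
  expect_true(is.na(orgs$ratio_to_cytoplasm))
  expect_equal(orgs$diff_from_cytoplasm, 40)
})

test_that("cell_summary requires a whole-cell ROI and a single cell", {
  meas <- tibble::tibble(region_id = "cy", cell_id = 1L, class = "cytoplasm",
                         N12 = 10, N13 = 1, area_px = 1L, area_um2 = 1,
                         delta = 0, delta_se = 1, outside_fraction = 0, valid = TRUE)
  expect_error(cell_summary(meas), "cell_body")
})

test_that("percent_change matches the printed pulse-to-chase declines", {
  expect_equal(percent_change(259, 156), -39.768, tolerance = 1e-4)
  expect_identical(round(percent_change(259, 156)), -40)
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(259, 136), -47.49, tolerance = 1e-3)
  expect_error(percent_change(0, 10), "undefined")
})

test_that("group_table uses the linear-interpolation quartile convention", {
  df <- tibble::tibble(g = "a", v = c(1, 2, 3, 4))
  gt <- group_table(df, v, g)
  expect_equal(gt$median, 2.5)
  expect_equal(gt$q25, 1.75)
  expect_equal(gt$q75, 3.25)
  single <- group_table(tibble::tibble(g = "a", v = 5), v, g)
  expect_equal(single$mean, 5)
  expect_equal(single$median, 5)
  expect_equal(single$sd, 0)
  expect_warning(
    gt2 <- group_table(tibble::tibble(g = c("a", "b"), v = c(1, NA)), v, g),
    "dropping")
  expect_identical(gt2$g, "a")
})
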