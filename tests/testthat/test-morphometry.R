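# Mitochondrial shape and mitochondria-ER contact quantification.

disk_mask <- function(r, pad = 3) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  outer(1:n, 1:n, function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
}

test_that("a disk has aspect ratio 1 and a rectangle its side ratio", {
  expect_equal(aspect_ratio(disk_mask(9)), 1, tolerance = 0.05)
  rect <- matrix(FALSE, 50, 20)
  rect[6:45, 6:15] <- TRUE  # 40 x 10 px
  # hand oracle: uniform-rectangle second moments ((L^2-1)/12 + 1/12 per axis,
  # with the sample-covariance n/(n-1) factor on the pixel spread)
  expect_equal(aspect_ratio(rect), 4, tolerance = 1e-3)
})

test_that("aspect ratio is rotation invariant within discretization tolerance", {
  base <- silksims:::ellipse_pixels(31, 31, 24, 9, 0, 63, 63)
  m0 <- matrix(FALSE, 63, 63); m0[base] <- TRUE
  a0 <- aspect_ratio(m0)
  for (th in c(pi / 6, pi / 4, 1.2)) {
    px <- silksims:::ellipse_pixels(31, 31, 24, 9, th, 63, 63)
    m <- matrix(FALSE, 63, 63); m[px] <- TRUE
    expect_equal(aspect_ratio(m), a0, tolerance = 0.05)
  }
})

test_that("degenerate thin regions are capped at their length and flagged", {
  m <- matrix(FALSE, 10, 30)
  m[5, 3:22] <- TRUE  # 1 px wide, 20 px long
  a <- aspect_ratio(m)
  expect_equal(as.numeric(a), 20)
  expect_true(isTRUE(attr(a, "degenerate")))
  expect_error(aspect_ratio(matrix(TRUE, 2, 2)), ">= 9")
})

test_that("moment aspect agrees with the EBImage implementation on a blob", {
  set.seed(41)
  px <- silksims:::ellipse_pixels(40, 38, 21, 9, 0.7, 81, 81)
  m <- matrix(FALSE, 81, 81); m[px] <- TRUE
  ft <- EBImage::computeFeatures.moment(matrix(as.integer(m), 81, 81))
  # independent implementation: aspect from eccentricity, a = 1/sqrt(1 - e^2)
  aspect_eb <- 1 / sqrt(1 - ft[1, "m.eccentricity"]^2)
  expect_equal(aspect_ratio(m), unname(aspect_eb), tolerance = 0.02)
})

test_that("boundary tracing yields rectangle perimeters within 5%", {
  rect <- matrix(FALSE, 40, 24)
  rect[6:35, 6:17] <- TRUE  # 30 x 12
  chain <- silksims:::trace_boundary(rect)
  per <- silksims:::chain_perimeter_px(chain)
  expect_equal(per, 2 * (29 + 11), tolerance = 1e-9)
  expect_lt(abs(per - 2 * (30 + 12)) / (2 * 42), 0.05)
})

test_that("a single flanking ER segment counts as exactly one contact", {
  mito <- matrix(FALSE, 30, 30); mito[10:20, 10:16] <- TRUE
  er <- matrix(FALSE, 30, 30); er[10:20, 17] <- TRUE  # adjacent: zero membrane gap
  res <- merc_quantify(list(mito), er, pixel_size_nm = 50, d_contact_nm = 30)
  expect_identical(res$merc_count, 1L)
  expect_equal(res$merc_frequency, 1 / res$perimeter_um)
  # ER beyond the cutoff: no contact
  er_far <- matrix(FALSE, 30, 30); er_far[10:20, 19] <- TRUE  # 100 nm gap
  expect_identical(merc_quantify(list(mito), er_far, 50, 30)$merc_count, 0L)
  # no ER at all: frequency 0
  none <- merc_quantify(list(mito), matrix(FALSE, 30, 30), 50, 30)
  expect_identical(none$merc_count, 0L)
  expect_equal(none$merc_frequency, 0)
})

test_that("two ER segments on opposite sides are two contacts, merged runs one", {
  mito <- matrix(FALSE, 32, 32); mito[12:22, 12:18] <- TRUE
  er2 <- matrix(FALSE, 32, 32)
  er2[12:22, 19] <- TRUE; er2[12:22, 11] <- TRUE
  expect_identical(merc_quantify(list(mito), er2, 50, 30)$merc_count, 2L)
  # a gap of a single boundary pixel inside one apposition merges into one run
  er_gap <- matrix(FALSE, 32, 32)
  er_gap[12:15, 19] <- TRUE; er_gap[17:22, 19] <- TRUE
  expect_identical(merc_quantify(list(mito), er_gap, 50, 30,
                                 merge_gap_px = 3)$merc_count, 1L)
})

test_that("planted contacts are recovered within one per cell", {
  scene <- make_test_scene(n_cells = 2, seed = 33)
  morpho <- morphometry_scene(scene)
  expect_identical(nrow(morpho$cells), 2L)
  expect_true(all(abs(morpho$cells$merc_count - morpho$cells$merc_planted) <= 1))
  expect_true(all(morpho$mitochondria$aspect_ratio >= 1))
  # measured aspect tracks the generating draw
  expect_equal(mean(morpho$mitochondria$aspect_ratio),
               mean(morpho$mitochondria$true_aspect), tolerance = 0.12)
})

test_that("synthetic condition cohorts reproduce the aspect-ratio direction", {
  ctrl <- morphometry_scene(make_test_scene(small_preset(), n_cells = 2, seed = 51))
  asyn <- morphometry_scene(make_test_scene(
    small_preset(condition = "asyn", mito_aspect = c(mean = 1.6, sd = 0.4),
                 merc_rate = 0.07), n_cells = 2, seed = 51))
  expect_gt(mean(ctrl$mitochondria$aspect_ratio),
            mean(asyn$mitochondria$aspect_ratio))
})
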