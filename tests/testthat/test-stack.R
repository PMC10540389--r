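# Plane alignment, accumulation and delta maps.

test_that("stack construction validates shapes and integrality", {
  a <- array(1L, c(4, 4, 2))
  expect_s3_class(ion_count_stack(a, a, 0.2), "sims_stack")
  expect_error(ion_count_stack(a, array(1L, c(4, 4, 3)), 0.2), "shape")
  expect_error(ion_count_stack(array(1.5, c(4, 4, 1)), array(1, c(4, 4, 1)), 0.2),
               "integer")
  expect_error(ion_count_stack(array(-1, c(4, 4, 1)), array(1, c(4, 4, 1)), 0.2),
               "non-negative")
})

test_that("zero-drift stacks estimate all-zero shifts and single planes are trivial", {
  st <- drift_stack(matrix(0L, 3, 2), lambda = 50, seed = 2)
  sh <- estimate_plane_shifts(st, max_shift = 4)
  expect_identical(sh, matrix(0L, 3, 2, dimnames = list(NULL, c("dy", "dx"))))
  st1 <- drift_stack(matrix(0L, 1, 2), lambda = 50, seed = 2)
  expect_identical(estimate_plane_shifts(st1, max_shift = 4)[1, ],
                   c(dy = 0L, dx = 0L))
})

test_that("planted drifts are recovered exactly", {
  shifts <- rbind(c(0L, 0L), c(2L, -1L))
  st <- drift_stack(shifts, lambda = 60, seed = 4)
  expect_identical(unname(estimate_plane_shifts(st, max_shift = 4)),
                   unname(shifts))
})

test_that("an empty plane yields a zero shift with a warning", {
  st <- drift_stack(matrix(0L, 2, 2), lambda = 50, seed = 6)
  st$counts[["12C14N"]][, , 2] <- 0L
  expect_warning(sh <- estimate_plane_shifts(st, max_shift = 3), "no counts")
  expect_identical(unname(sh[2, ]), c(0L, 0L))
})

test_that("the FFT-based NCC search matches the brute-force oracle", {
  for (s in 1:10) {
    set.seed(s)
    n <- 16
    ref <- matrix(rpois(n * n, 8 + 6 * runif(n * n)), n)
    pl <- matrix(rpois(n * n, 8 + 6 * runif(n * n)), n)
    m <- 3
    expect_identical(silksims:::best_ncc_shift(ref, pl, m), ncc_brute(ref, pl, m))
  }
})

test_that("drift recovery succeeds in at least 95% of low-count replicates", {
  hits <- vapply(1:20, function(s) {
    true <- rbind(c(0L, 0L), c(1L, 2L), c(-2L, 1L), c(3L, -1L))
    st <- drift_stack(true, lambda = 20, seed = 400 + s)
    identical(unname(estimate_plane_shifts(st, max_shift = 4)), unname(true))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("accumulation doubles identical planes and keeps the full mask", {
  a <- array(rep(matrix(1:16, 4), 2), c(4, 4, 2))
  st <- ion_count_stack(a, a, 0.2)
  acc <- accumulate(st, matrix(0L, 2, 2))
  expect_equal(acc$n12, 2 * matrix(1:16, 4))
  expect_true(all(acc$mask))
})

test_that("a one-column shift trims the mask and conserves masked totals", {
  p1 <- matrix(1:16, 4); p2 <- matrix(17:32, 4)
  st <- ion_count_stack(array(c(p1, p2), c(4, 4, 2)),
                        array(c(p1, p2), c(4, 4, 2)), 0.2)
  shifts <- rbind(c(0L, 0L), c(0L, 1L))
  acc <- accumulate(st, shifts)
  # hand oracle: plane 2 is read from column c+1, so the last column is invalid
  expect_identical(acc$mask[, 4], rep(FALSE, 4))
  expect_identical(acc$mask[, 1:3], matrix(TRUE, 4, 3))
  expect_equal(acc$n12[, 1:3], p1[, 1:3] + p2[, 2:4])
  expect_equal(sum(acc$n12[acc$mask]), sum(p1[, 1:3]) + sum(p2[, 2:4]))
})

test_that("accumulate validates its shift table", {
  a <- array(1L, c(4, 4, 2))
  st <- ion_count_stack(a, a, 0.2)
  expect_error(accumulate(st, matrix(0L, 0, 2)), "empty")
  expect_error(accumulate(st, matrix(0L, 3, 2)), "one row per plane")
  expect_error(accumulate(st, rbind(c(0L, 0L), c(0L, 99L))), "max_shift")
})

test_that("count conservation holds exactly for random stacks and shifts", {
  for (s in 1:5) {
    set.seed(s)
    a12 <- array(rpois(64 * 3, 10), c(8, 8, 3))
    a13 <- array(rpois(64 * 3, 3), c(8, 8, 3))
    st <- ion_count_stack(a12, a13, 0.2)
    sh <- matrix(sample(-2:2, 6, replace = TRUE), 3, 2); sh[1, ] <- 0L
    acc <- accumulate(st, sh)
    # brute-force recomputation over the masked region
    tot12 <- 0
    for (p in 1:3) {
      for (r in 1:8) for (cc in 1:8) {
        if (acc$mask[r, cc]) tot12 <- tot12 + a12[r + sh[p, 1], cc + sh[p, 2], p]
      }
    }
    expect_identical(sum(acc$n12[acc$mask]), as.numeric(tot12))
    expect_true(all(acc$n12 == round(acc$n12)))
  }
})

test_that("delta_map implements the per-mil equation and the count threshold", {
  n12 <- matrix(c(100000, 1000, 50, 100000), 2, 2)
  n13 <- matrix(c(1385, 11, 1, 1650), 2, 2)
  dm <- delta_map(acc_from_counts(n12, n13), r_nat = 0.0110, min_counts = 100)
  expect_equal(dm$delta[1, 1], (0.01385 / 0.011 - 1) * 1000, tolerance = 1e-12)
  expect_equal(dm$delta[1, 1], 259.09, tolerance = 1e-4)
  expect_equal(dm$delta[2, 1], 0, tolerance = 1e-9)        # exactly R_nat
  expect_true(is.na(dm$delta[1, 2]))                        # below min_counts
  expect_false(dm$valid[1, 2])
  expect_equal(dm$delta[2, 2], 500, tolerance = 1e-9)       # 1.5 x R_nat
  expect_error(delta_map(acc_from_counts(n12, n13), r_nat = 0), "r_nat")
  expect_error(delta_map(acc_from_counts(n12, n13), 0.011, min_counts = 0), "min_counts")
})

test_that("inverting the delta formula returns the measured ratio to 1e-12", {
  set.seed(9)
  n12 <- matrix(rpois(64, 5000), 8); n13 <- matrix(rpois(64, 60), 8)
  dm <- delta_map(acc_from_counts(n12, n13), 0.011, min_counts = 1)
  r_back <- (dm$delta / 1000 + 1) * 0.011
  expect_equal(r_back[dm$valid], (n13 / n12)[dm$valid], tolerance = 1e-12)
})

test_that("a rendered null scene has a field-wide mean delta near zero", {
  scene <- make_test_scene(zero_preset(), n_cells = 1, seed = 17)
  set.seed(17)
  stack <- render_nanosims(scene)
  sh <- estimate_plane_shifts(stack, max_shift = 3)
  acc <- accumulate(stack, sh)
  m <- measure_roi(acc, which(acc$mask, arr.ind = TRUE), r_nat = 0.011)
  expect_lt(abs(m$delta), 3 * m$delta_se)
})
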