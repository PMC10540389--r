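# Preset catalog calibration and invariants.

test_that("catalog presets satisfy the declared invariants", {
  cat <- preset_catalog()
  expect_setequal(names(cat), c(
    "snpc-control-24h", "snpc-control-48h", "snpc-control-96h",
    "snpc-asyn-24h", "snpc-asyn-48h", "snpc-asyn-96h", "striatum-control-48h"))
  for (p in cat) {
    means <- vapply(p$compartment_delta, function(x) x[["mean"]], numeric(1))
    expect_true(all(means >= -1000))
    expect_gte(p$whole_cell[["sd"]], 0)
    expect_gte(p$nuc_minus_cyt[["sd"]], 0)
    fh <- p$lysosome_mixture$fraction_high
    expect_true(fh >= 0 && fh <= 1)
    expect_gt(p$pulse_params[["k"]], 0)
    expect_gt(p$chase_params[["k_c"]], 0)
    expect_gte(p$mito_aspect[["mean"]], 1)
    expect_gt(p$r_nat, 0)
  }
})

test_that("area-weighted compartment means reproduce the whole-cell target exactly", {
  for (p in preset_catalog()) {
    f <- p$area_fractions
    cd <- vapply(p$compartment_delta, function(x) x[["mean"]], numeric(1))
    w <- sum(f[names(cd)[names(cd) != "lysosome"]] * cd[names(cd) != "lysosome"]) +
      f[["lysosome"]] * cd[["lysosome"]]
    expect_equal(unname(w), p$whole_cell[["mean"]], tolerance = 1e-9)
  }
})

test_that("preset whole-cell means follow the pulse/chase kinetics", {
  cat <- preset_catalog()
  pp <- silk_pulse_params()
  expect_equal(cat[["snpc-control-24h"]]$whole_cell[["mean"]],
               pulse_delta(24, pp[["A"]], pp[["k"]]))
  expect_equal(cat[["snpc-control-48h"]]$whole_cell[["mean"]], 259, tolerance = 1e-9)
  expect_equal(cat[["snpc-control-96h"]]$whole_cell[["mean"]], 156, tolerance = 1e-9)
  expect_equal(cat[["snpc-asyn-96h"]]$whole_cell[["mean"]], 136, tolerance = 1e-9)
  # pulse behaviour identical across conditions; only the chase rate differs
  expect_equal(cat[["snpc-asyn-48h"]]$whole_cell[["mean"]],
               cat[["snpc-control-48h"]]$whole_cell[["mean"]])
  expect_gt(cat[["snpc-asyn-96h"]]$chase_params[["k_c"]],
            cat[["snpc-control-96h"]]$chase_params[["k_c"]])
})

test_that("diff-parameterized organelles hit their difference targets exactly", {
  a48 <- default_preset("snpc-asyn-48h")
  expect_identical(unname(a48$organelle_modes["mitochondrion"]), "diff")
  expect_equal(unname(a48$organelle_diffs["mitochondrion"]), 56)
  expect_equal((a48$organelle_ratios[["mitochondrion"]] - 1) * a48$cytoplasm_delta,
               56, tolerance = 1e-9)
  a96 <- default_preset("snpc-asyn-96h")
  expect_equal((a96$organelle_ratios[["golgi"]] - 1) * a96$cytoplasm_delta,
               63, tolerance = 1e-9)
})

test_that("lysosome mixture averages to the calibrated ratio", {
  p <- default_preset("snpc-control-48h")
  mix <- p$lysosome_mixture
  mean_ratio <- mix$fraction_high * mix$ratio_high + (1 - mix$fraction_high) * mix$ratio_low
  expect_equal(mean_ratio, 1.79, tolerance = 1e-12)
  expect_equal(p$compartment_delta$lysosome[["mean"]], 1.79 * p$cytoplasm_delta,
               tolerance = 1e-9)
})

test_that("striatum preset confines enrichment to the nucleus at a lower level", {
  st <- default_preset("striatum-control-48h")
  sn <- default_preset("snpc-control-48h")
  expect_equal(st$whole_cell[["mean"]] * 1.8, sn$whole_cell[["mean"]], tolerance = 1e-9)
  expect_gt(st$compartment_delta$nucleus[["mean"]] - st$compartment_delta$cytoplasm[["mean"]],
            50)
})

test_that("shipped preset catalog matches the in-memory catalog", {
  path <- system.file("extdata", "presets.json", package = "silksims")
  skip_if(path == "", "catalog not installed")
  disk <- read_presets(path)
  mem <- preset_catalog()
  expect_setequal(names(disk), names(mem))
  for (nm in names(mem)) {
    expect_equal(disk[[nm]]$compartment_delta, mem[[nm]]$compartment_delta,
                 tolerance = 1e-12)
    expect_equal(disk[[nm]]$organelle_ratios, mem[[nm]]$organelle_ratios,
                 tolerance = 1e-12)
    expect_equal(unname(disk[[nm]]$whole_cell), unname(mem[[nm]]$whole_cell),
                 tolerance = 1e-12)
  }
})

test_that("preset JSON round-trips through a temp file", {
  cat <- preset_catalog()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_presets(cat, tmp)
  back <- read_presets(tmp)
  expect_equal(back[["snpc-control-48h"]]$cytoplasm_delta,
               cat[["snpc-control-48h"]]$cytoplasm_delta, tolerance = 1e-12)
  expect_identical(back[["snpc-asyn-48h"]]$organelle_modes[["mitochondrion"]], "diff")
})

test_that("sample_cohort draws the between-cell whole-cell distribution", {
  p <- default_preset("snpc-control-48h")
  set.seed(99)
  co <- sample_cohort(p, 4000)
  expect_identical(nrow(co), 4000L)
  expect_equal(mean(co$whole_cell_delta), 259, tolerance = 0.02)
  expect_equal(sd(co$whole_cell_delta), 48, tolerance = 0.05)
  expect_identical(unique(co$condition), "control")
})

test_that("impossible calibrations are rejected", {
  expect_error(small_preset(whole_cell = -50, nuc_minus_cyt = 0), "cytoplasm")
  expect_error(scene_preset("bad", "SNpc", "control", 48, whole_cell = 100,
                            whole_cell_sd = 10, nuc_minus_cyt = 0,
                            organelle_ratios = c(mitochondrion = 1, golgi = 1)),
               "organelle_ratios")
})
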