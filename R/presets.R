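# Condition/time-point presets for the synthetic forward model.
#
# Each preset pins the population-level quantities the analysis is meant to
# recover: whole-cell delta-13C (mean and between-cell SD), the
# nucleus-minus-cytoplasm difference, organelle enrichment relative to the
# cytoplasm, the bimodal lysosome population, mitochondrial aspect ratio and
# the mitochondria-ER contact rate. Absolute compartment means are derived
# from those targets so that the *area-weighted* whole-cell mean under the
# scene geometry equals the whole-cell target: the generator and the
# quantification stages share one consistent parameterization.

#' Pulse kinetics constants implied by the cohort means
#'
#' Closed-form exponential-plateau parameters that pass exactly through
#' 156 per mil at 24 h and 259 per mil at 48 h: with x = exp(-24 k),
#' 1 + x = 259/156 gives x = 103/156, hence k = log(156/103)/24 per hour
#' and A = 156^2/53 per mil.
#'
#' @return Named vector with `A` (per mil) and `k` (1/h).
#' @export
silk_pulse_params <- function() {
  c(A = 156^2 / 53, k = log(156 / 103) / 24)
}

#' Chase decay constants implied by the cohort means
#'
#' One-phase decay from 259 per mil at 48 h to the observed 96 h mean:
#' k_c = log(259/156)/48 for the control condition and
#' k_c = log(259/136)/48 for the alpha-synuclein condition.
#'
#' @param condition `"control"` or `"asyn"`.
#' @return Named vector with `delta48` (per mil) and `k_c` (1/h).
#' @export
silk_chase_params <- function(condition = c("control", "asyn")) {
  condition <- match.arg(condition)
  end <- if (condition == "control") 156 else 136
  c(delta48 = 259, k_c = log(259 / end) / 48)
}

#' Construct a synthetic-scene preset
#'
#' Defines one (region, condition, time point) cell population. Organelle
#' enrichment can be given either as a ratio to the cytoplasm
#' (`organelle_ratios`, the Fig.-5-style normalization) or as an absolute
#' difference in per mil (`organelle_diffs`, the Fig.-7-style quantity);
#' differences are converted to ratios during calibration. The cytoplasm
#' level is solved from the whole-cell target using the expected compartment
#' area fractions of the scene geometry:
#' `c = (W - f_nuc * D - sum(f_i * d_i)) / (f_cyt + f_nuc + sum(f_i) + sum(f_j * r_j))`
#' where the sums run over diff- and ratio-parameterized classes.
#'
#' @param name Preset identifier.
#' @param region `"SNpc"` or `"striatum"`.
#' @param condition `"control"` or `"asyn"`.
#' @param timepoint_h Hours since pulse start.
#' @param whole_cell,whole_cell_sd Whole-cell delta-13C mean and between-cell
#'   SD, per mil.
#' @param nuc_minus_cyt,nuc_minus_cyt_sd Nucleus-minus-cytoplasm difference
#'   mean and between-cell SD, per mil.
#' @param organelle_ratios Named vector of cytoplasm-normalized ratios for a
#'   subset of `c("mitochondrion", "golgi", "ER")`.
#' @param organelle_ratio_sds Named vector of between-organelle SDs on the
#'   ratio scale (same names).
#' @param organelle_diffs Named vector of organelle-minus-cytoplasm targets
#'   in per mil; takes precedence over `organelle_ratios` for those classes.
#' @param lysosome_mixture List with `fraction_high` and the two component
#'   ratios/SDs (`ratio_high`, `ratio_low`, `sd_high`, `sd_low`) describing
#'   the 13C-rich / 13C-poor lysosome populations.
#' @param nucleolus_ratio,nucleolus_sd Nucleolus enrichment relative to the
#'   cytoplasm (the nucleolus is strongly enriched, which motivates the
#'   exclusion rule in the nuclear analysis).
#' @param nucleolus_prob Fraction of cell sections in which a nucleolus is
#'   visible.
#' @param pulse_params,chase_params Kinetics constants (see
#'   [silk_pulse_params()], [silk_chase_params()]).
#' @param mito_aspect Mean and SD of the mitochondrial length-to-width ratio.
#' @param merc_rate Mitochondria-ER contacts per um of mitochondrial
#'   perimeter.
#' @param lambda_background,lambda_cell Expected total CN- counts per pixel
#'   per raster plane in resin and intracellular classes.
#' @param r_nat Natural-abundance 13C14N-/12C14N- reference ratio.
#' @param geometry Scene geometry constants ([scene_geometry()]); presets
#'   built with a different geometry are recalibrated against its area
#'   fractions.
#' @return A `silksims_preset` object.
#' @export
scene_preset <- function(name, region = c("SNpc", "striatum"),
                         condition = c("control", "asyn"),
                         timepoint_h,
                         whole_cell, whole_cell_sd,
                         nuc_minus_cyt, nuc_minus_cyt_sd = 10,
                         organelle_ratios = c(mitochondrion = 1.32, golgi = 1.69, ER = 1.2),
                         organelle_ratio_sds = c(mitochondrion = 0.22, golgi = 0.17, ER = 0.1),
                         organelle_diffs = NULL,
                         lysosome_mixture = list(fraction_high = 0.5,
                                                 ratio_high = 2.65, ratio_low = 0.93,
                                                 sd_high = 0.30, sd_low = 0.25),
                         nucleolus_ratio = 3.0, nucleolus_sd = 0.4,
                         nucleolus_prob = 0.3,
                         pulse_params = silk_pulse_params(),
                         chase_params = silk_chase_params("control"),
                         mito_aspect = c(mean = 2.2, sd = 0.6),
                         merc_rate = 0.15,
                         lambda_background = 300, lambda_cell = 1500,
                         r_nat = 0.0110,
                         geometry = scene_geometry()) {
  region <- match.arg(region)
  condition <- match.arg(condition)
  stopifnot(timepoint_h >= 0, whole_cell >= -1000, whole_cell_sd >= 0,
            nuc_minus_cyt_sd >= 0, nucleolus_prob >= 0, nucleolus_prob <= 1,
            r_nat > 0, lambda_background >= 0, lambda_cell >= 0)
  fh <- lysosome_mixture$fraction_high
  stopifnot(fh >= 0, fh <= 1, pulse_params[["k"]] > 0, chase_params[["k_c"]] > 0)

  f <- design_area_fractions(geometry, nucleolus_prob)
  lys_mean_ratio <- fh * lysosome_mixture$ratio_high + (1 - fh) * lysosome_mixture$ratio_low

  ratio_classes <- c("mitochondrion", "golgi", "ER")
  ratios <- organelle_ratios[ratio_classes]
  names(ratios) <- ratio_classes
  if (anyNA(ratios)) abort("organelle_ratios must name mitochondrion, golgi and ER.")
  diff_classes <- intersect(names(organelle_diffs %||% numeric()), ratio_classes)

  # Solve the cytoplasm level from the whole-cell target (linear; diffs enter
  # additively, ratios multiplicatively).
  num <- whole_cell - f[["nucleus"]] * nuc_minus_cyt
  den <- f[["cytoplasm"]] + f[["nucleus"]] + f[["nucleolus"]] * nucleolus_ratio +
    f[["lysosome"]] * lys_mean_ratio
  for (cl in ratio_classes) {
    if (cl %in% diff_classes) {
      num <- num - f[[cl]] * organelle_diffs[[cl]]
      den <- den + f[[cl]]
    } else {
      den <- den + f[[cl]] * ratios[[cl]]
    }
  }
  cytoplasm_delta <- num / den
  zero_ok <- whole_cell == 0 && nuc_minus_cyt == 0 && length(diff_classes) == 0
  if (!is.finite(cytoplasm_delta) || cytoplasm_delta < 0 ||
      (cytoplasm_delta == 0 && !zero_ok)) {
    abort("preset calibration produced a non-positive cytoplasm delta; check targets.")
  }
  # diff-parameterized classes: the organelle level is cytoplasm + d with
  # additive between-organelle scatter, so the population median of the
  # organelle-minus-cytoplasm difference equals d exactly (the printed
  # organelle comparisons are medians). Ratio-parameterized classes scatter
  # multiplicatively and recover the printed mean ratio instead.
  modes <- setNames(rep("ratio", length(ratio_classes)), ratio_classes)
  diffs <- setNames(rep(NA_real_, length(ratio_classes)), ratio_classes)
  diff_sds <- setNames(rep(NA_real_, length(ratio_classes)), ratio_classes)
  for (cl in diff_classes) {
    modes[[cl]] <- "diff"
    diffs[[cl]] <- organelle_diffs[[cl]]
    diff_sds[[cl]] <- organelle_ratio_sds[[cl]] * cytoplasm_delta
    ratios[[cl]] <- if (cytoplasm_delta > 0) 1 + organelle_diffs[[cl]] / cytoplasm_delta else NA_real_
  }

  cv <- whole_cell_sd / max(whole_cell, 1e-9)
  compartment_delta <- list(
    cytoplasm = c(mean = cytoplasm_delta, sd = cytoplasm_delta * cv),
    nucleus = c(mean = cytoplasm_delta + nuc_minus_cyt,
                sd = sqrt((cytoplasm_delta * cv)^2 + nuc_minus_cyt_sd^2)),
    nucleolus = c(mean = nucleolus_ratio * cytoplasm_delta,
                  sd = nucleolus_ratio * cytoplasm_delta * cv),
    mitochondrion = c(mean = ratios[["mitochondrion"]] * cytoplasm_delta,
                      sd = organelle_ratio_sds[["mitochondrion"]] * cytoplasm_delta),
    golgi = c(mean = ratios[["golgi"]] * cytoplasm_delta,
              sd = organelle_ratio_sds[["golgi"]] * cytoplasm_delta),
    lysosome = c(mean = lys_mean_ratio * cytoplasm_delta, sd = NA_real_),
    ER = c(mean = ratios[["ER"]] * cytoplasm_delta,
           sd = organelle_ratio_sds[["ER"]] * cytoplasm_delta)
  )
  if (any(vapply(compartment_delta, function(x) x[["mean"]], 1) < -1000)) {
    abort("compartment means below -1000 per mil are not physical.")
  }

  structure(list(
    name = name, region = region, condition = condition,
    timepoint_h = timepoint_h,
    whole_cell = c(mean = whole_cell, sd = whole_cell_sd),
    nuc_minus_cyt = c(mean = nuc_minus_cyt, sd = nuc_minus_cyt_sd),
    organelle_ratios = ratios,
    organelle_ratio_sds = organelle_ratio_sds[ratio_classes],
    organelle_modes = modes,
    organelle_diffs = diffs,
    organelle_diff_sds = diff_sds,
    lysosome_mixture = lysosome_mixture,
    nucleolus_ratio = nucleolus_ratio, nucleolus_sd = nucleolus_sd,
    nucleolus_prob = nucleolus_prob,
    cytoplasm_delta = cytoplasm_delta,
    compartment_delta = compartment_delta,
    area_fractions = f,
    pulse_params = pulse_params, chase_params = chase_params,
    mito_aspect = c(mean = unname(mito_aspect[1]), sd = unname(mito_aspect[2])),
    merc_rate = merc_rate,
    lambda_background = lambda_background, lambda_cell = lambda_cell,
    r_nat = r_nat, geometry = geometry
  ), class = "silksims_preset")
}

#' @export
print.silksims_preset <- function(x, ...) {
  cat(sprintf("<silksims_preset> %s: %s %s at %g h\n",
              x$name, x$region, x$condition, x$timepoint_h))
  cat(sprintf("  whole cell %g +/- %g permil; nucleus - cytoplasm %g permil\n",
              x$whole_cell[["mean"]], x$whole_cell[["sd"]], x$nuc_minus_cyt[["mean"]]))
  cat(sprintf("  cytoplasm %0.1f permil; ratios: mito %.3f, golgi %.3f, ER %.3f\n",
              x$cytoplasm_delta, x$organelle_ratios[["mitochondrion"]],
              x$organelle_ratios[["golgi"]], x$organelle_ratios[["ER"]]))
  invisible(x)
}

#' Catalog of calibrated presets
#'
#' One preset per studied (region, condition, time point). Whole-cell means
#' follow the pulse/chase kinetics exactly (156 and 259 per mil during the
#' pulse; 156 and 136 per mil at 96 h for control and alpha-synuclein).
#' Organelle parameters: control 48 h ratios 1.69 (Golgi), 1.32
#' (mitochondria) and a bimodal lysosome population averaging 1.79; control
#' 96 h ratios 1.36 and 1.23; the alpha-synuclein 48 h mitochondrial and
#' 96 h Golgi levels are calibrated to organelle-minus-cytoplasm targets of
#' +56 and +63 per mil. The striatum preset confines enrichment mainly to
#' the nucleus at roughly 1/1.8 of the nigral whole-cell level.
#'
#' @param geometry Scene geometry passed to every preset.
#' @return Named list of `silksims_preset` objects.
#' @export
preset_catalog <- function(geometry = scene_geometry()) {
  pp <- silk_pulse_params()
  ch_ctrl <- silk_chase_params("control")
  ch_asyn <- silk_chase_params("asyn")
  w24 <- pulse_delta(24, pp[["A"]], pp[["k"]])
  w48 <- pulse_delta(48, pp[["A"]], pp[["k"]])
  w96_ctrl <- chase_delta(96, ch_ctrl[["delta48"]], ch_ctrl[["k_c"]])
  w96_asyn <- chase_delta(96, ch_asyn[["delta48"]], ch_asyn[["k_c"]])
  ratios_pulse <- c(mitochondrion = 1.32, golgi = 1.69, ER = 1.2)
  sds_pulse <- c(mitochondrion = 0.22, golgi = 0.17, ER = 0.1)
  ratios_96 <- c(mitochondrion = 1.23, golgi = 1.36, ER = 1.1)
  sds_96 <- c(mitochondrion = 0.32, golgi = 0.18, ER = 0.1)
  ctrl_aspect <- c(mean = 2.2, sd = 0.6)
  asyn_aspect <- c(mean = 1.6, sd = 0.4)

  presets <- list(
    scene_preset("snpc-control-24h", "SNpc", "control", 24,
                 whole_cell = w24, whole_cell_sd = 22,
                 nuc_minus_cyt = 15,
                 organelle_ratios = ratios_pulse, organelle_ratio_sds = sds_pulse,
                 pulse_params = pp, chase_params = ch_ctrl,
                 mito_aspect = ctrl_aspect, merc_rate = 0.15, geometry = geometry),
    scene_preset("snpc-control-48h", "SNpc", "control", 48,
                 whole_cell = w48, whole_cell_sd = 48,
                 nuc_minus_cyt = 25,
                 organelle_ratios = ratios_pulse, organelle_ratio_sds = sds_pulse,
                 pulse_params = pp, chase_params = ch_ctrl,
                 mito_aspect = ctrl_aspect, merc_rate = 0.15, geometry = geometry),
    scene_preset("snpc-control-96h", "SNpc", "control", 96,
                 whole_cell = w96_ctrl, whole_cell_sd = 25,
                 nuc_minus_cyt = 2,
                 organelle_ratios = ratios_96, organelle_ratio_sds = sds_96,
                 pulse_params = pp, chase_params = ch_ctrl,
                 mito_aspect = ctrl_aspect, merc_rate = 0.15, geometry = geometry),
    scene_preset("snpc-asyn-24h", "SNpc", "asyn", 24,
                 whole_cell = w24, whole_cell_sd = 22,
                 nuc_minus_cyt = 2,
                 organelle_ratios = ratios_pulse, organelle_ratio_sds = sds_pulse,
                 pulse_params = pp, chase_params = ch_asyn,
                 mito_aspect = asyn_aspect, merc_rate = 0.07, geometry = geometry),
    scene_preset("snpc-asyn-48h", "SNpc", "asyn", 48,
                 whole_cell = w48, whole_cell_sd = 48,
                 nuc_minus_cyt = 2,
                 organelle_ratios = ratios_pulse, organelle_ratio_sds = sds_pulse,
                 organelle_diffs = c(mitochondrion = 56),
                 pulse_params = pp, chase_params = ch_asyn,
                 mito_aspect = asyn_aspect, merc_rate = 0.07, geometry = geometry),
    scene_preset("snpc-asyn-96h", "SNpc", "asyn", 96,
                 whole_cell = w96_asyn, whole_cell_sd = 25,
                 nuc_minus_cyt = 2,
                 organelle_ratios = ratios_96, organelle_ratio_sds = sds_96,
                 organelle_diffs = c(golgi = 63),
                 pulse_params = pp, chase_params = ch_asyn,
                 mito_aspect = asyn_aspect, merc_rate = 0.07, geometry = geometry),
    scene_preset("striatum-control-48h", "striatum", "control", 48,
                 whole_cell = w48 / 1.8, whole_cell_sd = 30,
                 nuc_minus_cyt = 80, nuc_minus_cyt_sd = 20,
                 organelle_ratios = c(mitochondrion = 1.2, golgi = 1.3, ER = 1.1),
                 organelle_ratio_sds = c(mitochondrion = 0.2, golgi = 0.15, ER = 0.1),
                 lysosome_mixture = list(fraction_high = 0.5, ratio_high = 2.0,
                                         ratio_low = 0.9, sd_high = 0.3, sd_low = 0.25),
                 pulse_params = pp, chase_params = ch_ctrl,
                 mito_aspect = ctrl_aspect, merc_rate = 0.15, geometry = geometry)
  )
  names(presets) <- vapply(presets, function(p) p$name, character(1))
  presets
}

#' Fetch one preset by name
#'
#' @param name Preset name, e.g. `"snpc-control-48h"`.
#' @param geometry Scene geometry constants.
#' @return A `silksims_preset`.
#' @export
default_preset <- function(name = "snpc-control-48h", geometry = scene_geometry()) {
  cat <- preset_catalog(geometry)
  if (!name %in% names(cat)) {
    abort(sprintf("unknown preset '%s'; available: %s", name,
                  paste(names(cat), collapse = ", ")))
  }
  cat[[name]]
}

#' Preset catalog as a tibble
#'
#' @param catalog Output of [preset_catalog()].
#' @return One row per preset with the headline population parameters.
#' @export
preset_table <- function(catalog = preset_catalog()) {
  purrr::map_dfr(catalog, function(p) {
    tibble(
      name = p$name, region = p$region, condition = p$condition,
      timepoint_h = p$timepoint_h,
      whole_cell = p$whole_cell[["mean"]], whole_cell_sd = p$whole_cell[["sd"]],
      nuc_minus_cyt = p$nuc_minus_cyt[["mean"]],
      cytoplasm = p$cytoplasm_delta,
      ratio_mito = p$organelle_ratios[["mitochondrion"]],
      ratio_golgi = p$organelle_ratios[["golgi"]],
      lysosome_mean_ratio = with(p$lysosome_mixture,
                                 fraction_high * ratio_high + (1 - fraction_high) * ratio_low),
      mito_aspect = p$mito_aspect[["mean"]],
      merc_rate = p$merc_rate
    )
  })
}

#' Draw per-cell whole-body enrichment values for a preset
#'
#' Samples the between-cell distribution of whole-cell delta-13C directly
#' (no imaging noise); this is the distributional layer of the forward model
#' used for power analyses of the group comparisons, where rendering full
#' image stacks for every replicate would add nothing but counting noise that
#' is negligible at the whole-cell scale.
#'
#' @param preset A `silksims_preset`.
#' @param n Number of cells.
#' @return Tibble with `cell`, `condition`, `timepoint_h`,
#'   `whole_cell_delta`.
#' @export
sample_cohort <- function(preset, n) {
  stopifnot(inherits(preset, "silksims_preset"), n >= 1)
  tibble(
    cell = seq_len(n),
    condition = preset$condition,
    timepoint_h = preset$timepoint_h,
    whole_cell_delta = pmax(-1000, rnorm(n, preset$whole_cell[["mean"]],
                                         preset$whole_cell[["sd"]]))
  )
}

#' Write / read a preset catalog as JSON
#'
#' The on-disk catalog stores every derived field at full double precision,
#' so a written-then-read catalog reproduces the in-memory one.
#'
#' @param catalog Named list of presets.
#' @param path JSON file path.
#' @return `write_presets()` returns `path` invisibly; `read_presets()`
#'   returns the catalog.
#' @export
write_presets <- function(catalog, path) {
  payload <- purrr::map(catalog, preset_to_json)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

# Named vectors are serialized as JSON objects so names survive the round
# trip (jsonlite drops names of atomic vectors).
preset_to_json <- function(p) {
  p <- unclass(p)
  vec_fields <- c("whole_cell", "nuc_minus_cyt", "organelle_ratios",
                  "organelle_ratio_sds", "organelle_modes", "organelle_diffs",
                  "organelle_diff_sds", "area_fractions", "pulse_params",
                  "chase_params", "mito_aspect")
  for (f in intersect(vec_fields, names(p))) p[[f]] <- as.list(p[[f]])
  p$compartment_delta <- purrr::map(p$compartment_delta, as.list)
  p
}

# Inverse of preset_to_json(); NULLs (JSON nulls) become NAs so names and
# length are preserved.
preset_from_json <- function(p) {
  unlist_na <- function(x) {
    if (is.null(x)) return(NULL)
    x[vapply(x, is.null, logical(1))] <- NA
    unlist(x)
  }
  vec_fields <- c("whole_cell", "nuc_minus_cyt", "organelle_ratios",
                  "organelle_ratio_sds", "organelle_modes", "organelle_diffs",
                  "organelle_diff_sds", "area_fractions", "pulse_params",
                  "chase_params", "mito_aspect")
  for (f in intersect(vec_fields, names(p))) p[[f]] <- unlist_na(p[[f]])
  p$compartment_delta <- purrr::map(p$compartment_delta, unlist_na)
  p$geometry <- purrr::map(p$geometry, unlist)
  structure(p, class = "silksims_preset")
}

#' @rdname write_presets
#' @export
read_presets <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  purrr::map(raw, preset_from_json)
}
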