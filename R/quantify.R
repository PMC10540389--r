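# ROI quantification: delta-13C and counting precision per region, then the
# per-cell derived quantities (whole-cell enrichment, nucleus-minus-cytoplasm
# difference with the nucleolus exclusion rule, and organelle-vs-cytoplasm
# normalization).

#' Measure delta-13C in one ROI footprint
#'
#' The ROI value is computed from the ratio of summed counts,
#' `R_mes = sum(N13) / sum(N12)`, not the mean of per-pixel ratios: summing
#' first keeps the estimator unbiased at low per-pixel counts and follows
#' ion-counting practice. The counting standard error uses first-order
#' propagation of the Poisson ratio:
#' `se(delta) = (1000 / R_nat) * R_mes * sqrt(1/N13 + 1/N12)`,
#' accurate above ~100 counts per species.
#'
#' @param acc A `silksims_accumulated`.
#' @param footprint Output of [map_roi()] (or a two-column (row, col) index
#'   matrix on the accumulation grid). Pixels outside the accumulation
#'   validity mask are dropped.
#' @param r_nat Natural-abundance reference ratio.
#' @return One-row tibble: summed `N12`, `N13`, `area_px`, `area_um2`,
#'   `delta`, `delta_se` (per mil), `outside_fraction`, `valid`.
#' @export
measure_roi <- function(acc, footprint, r_nat) {
  stopifnot(inherits(acc, "silksims_accumulated"))
  if (is.matrix(footprint)) footprint <- list(pixels = footprint, outside_fraction = 0)
  px <- footprint$pixels
  if (nrow(px) > 0) {
    keep <- acc$mask[px]
    px <- px[keep, , drop = FALSE]
  }
  n <- nrow(px)
  if (n == 0) {
    return(tibble(N12 = 0, N13 = 0, area_px = 0L, area_um2 = 0,
                  delta = NA_real_, delta_se = NA_real_,
                  outside_fraction = footprint$outside_fraction, valid = FALSE))
  }
  N12 <- sum(acc$n12[px]); N13 <- sum(acc$n13[px])
  if (N12 > 0) {
    R_mes <- N13 / N12
    delta <- (R_mes / r_nat - 1) * 1000
    delta_se <- if (N13 > 0) (1000 / r_nat) * R_mes * sqrt(1 / N13 + 1 / N12) else NA_real_
  } else {
    delta <- NA_real_; delta_se <- NA_real_
  }
  tibble(N12 = N12, N13 = N13, area_px = n,
         area_um2 = n * acc$pixel_size_um^2,
         delta = delta, delta_se = delta_se,
         outside_fraction = footprint$outside_fraction,
         valid = N12 > 0)
}

#' Summarize the measurements of one cell
#'
#' Builds the per-cell record from its ROI measurements: whole-cell,
#' cytoplasm and nucleus delta-13C, the nucleus-minus-cytoplasm difference
#' (the within-cell quantity that normalizes away between-neuron variation),
#' the nucleolus flag (cells showing the strongly enriched nucleolus are
#' excluded from nuclear-compartment analyses), and per-organelle
#' enrichment relative to the cell's whole-cytoplasm value, both as a ratio
#' `delta_org / delta_cyt` and as a difference `delta_org - delta_cyt`
#' (per mil). Ratios are undefined (NA) when the cytoplasm delta is not
#' positive; differences are still reported.
#'
#' @param measurements Tibble of ROI measurements for one cell, with columns
#'   `class`, `delta`, plus the [measure_roi()] columns.
#' @return One-row tibble with an `organelles` list-column.
#' @export
cell_summary <- function(measurements) {
  m <- measurements
  stopifnot(all(c("class", "delta") %in% names(m)))
  if (length(unique(m$cell_id %||% 1)) > 1) abort("cell_summary() expects one cell.")
  if (!"cell_id" %in% names(m)) m$cell_id <- 1L
  pick <- function(cl) {
    v <- m$delta[m$class == cl & m$valid]
    if (length(v)) v[1] else NA_real_
  }
  if (!any(m$class == "cell_body")) abort("a whole-cell (cell_body) ROI is required.")
  whole <- pick("cell_body")
  cyt <- pick("cytoplasm")
  nuc <- pick("nucleus")
  orgs <- organelle_table_one(m, cyt)
  tibble(
    cell_id = m$cell_id[1],
    whole_cell_delta = whole,
    cytoplasm_delta = cyt,
    nucleus_delta = nuc,
    nuc_minus_cyt = nuc - cyt,
    nucleolus_present = any(m$class == "nucleolus"),
    n_organelles = nrow(orgs),
    organelles = list(orgs)
  )
}

organelle_table_one <- function(m, cyt) {
  org_classes <- c("mitochondrion", "golgi", "lysosome", "ER")
  o <- m[m$class %in% org_classes & m$valid, , drop = FALSE]
  if (nrow(o) == 0) {
    return(tibble(region_id = character(), cell_id = integer(), class = character(),
                  delta = numeric(), delta_se = numeric(),
                  cytoplasm_delta = numeric(), ratio_to_cytoplasm = numeric(),
                  diff_from_cytoplasm = numeric()))
  }
  tibble(
    region_id = as.character(o$region_id %||% seq_len(nrow(o))),
    cell_id = o$cell_id,
    class = o$class,
    delta = o$delta,
    delta_se = o$delta_se,
    cytoplasm_delta = cyt,
    ratio_to_cytoplasm = if (is.na(cyt) || cyt <= 0) NA_real_ else o$delta / cyt,
    diff_from_cytoplasm = o$delta - cyt
  )
}

#' Summarize all cells in a measurement table
#'
#' @param measurements ROI measurement tibble covering one or more cells
#'   (column `cell_id` required).
#' @return List with `cells` (one row per cell, no list-columns) and
#'   `organelles` (one row per organelle ROI with cytoplasm normalization).
#' @export
summarize_cells <- function(measurements) {
  stopifnot("cell_id" %in% names(measurements))
  recs <- measurements |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_split() |>
    purrr::map(cell_summary)
  cells <- purrr::map_dfr(recs, ~ dplyr::select(.x, -"organelles"))
  organelles <- purrr::map_dfr(recs, ~ .x$organelles[[1]])
  list(cells = cells, organelles = organelles)
}

#' Cells eligible for nuclear-compartment analyses
#'
#' Applies the exclusion rule: cells whose section shows the strongly
#' 13C-enriched nucleolus are removed, because the nucleolus inflates the
#' nuclear average.
#'
#' @param cells Cell record tibble from [summarize_cells()].
#' @return Filtered tibble.
#' @export
nuclear_analysis_set <- function(cells) {
  dplyr::filter(cells, !.data$nucleolus_present, !is.na(.data$nuc_minus_cyt))
}

#' Percent change between two values
#'
#' `(after - before) / before * 100`; used for the pulse-to-chase decline of
#' cohort means.
#'
#' @param before,after Values in the same units; `before` must be non-zero.
#' @return Percent change.
#' @examples
#' percent_change(259, 156)  # about -40%
#' @export
percent_change <- function(before, after) {
  stopifnot(length(before) == length(after))
  if (any(before == 0)) abort("percent change is undefined for before = 0.")
  (after - before) / before * 100
}

#' Group summary table
#'
#' Per-group n, mean, SD, median and quartiles (linear-interpolation
#' convention) of a measurement column; the summary behind the violin-plot
#' panels. Groups whose values are all missing are dropped with a warning;
#' a single observation reports SD 0 by convention.
#'
#' @param data Tibble of records.
#' @param value Column to summarize (tidy-eval).
#' @param ... Grouping columns (tidy-eval).
#' @return Tibble with `n`, `mean`, `sd`, `median`, `q25`, `q75` per group.
#' @export
group_table <- function(data, value, ...) {
  val <- rlang::enquo(value)
  out <- data |>
    dplyr::group_by(...) |>
    dplyr::summarize(
      n = sum(!is.na(!!val)),
      mean = mean(!!val, na.rm = TRUE),
      sd = ifelse(sum(!is.na(!!val)) > 1, sd(!!val, na.rm = TRUE), 0),
      median = median(!!val, na.rm = TRUE),
      q25 = quantile(!!val, 0.25, na.rm = TRUE, names = FALSE),
      q75 = quantile(!!val, 0.75, na.rm = TRUE, names = FALSE),
      .groups = "drop"
    )
  if (any(out$n == 0)) {
    warn("dropping group(s) with no non-missing values.")
    out <- dplyr::filter(out, .data$n > 0)
  }
  out
}
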