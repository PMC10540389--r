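# Group statistics: Mann-Whitney and Welch tests with Benjamini-Hochberg
# false-discovery-rate adjustment across the time-point comparisons.

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided rank-sum comparison with the U statistic (midranks for ties).
#' The p-value is exact by enumeration when both samples have at most 8
#' observations and there are no ties, and otherwise uses the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Numeric samples (non-empty).
#' @return One-row tibble: `test`, `statistic` (U), `p_raw`, `n_x`, `n_y`,
#'   `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) abort("both samples must be non-empty.")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- max(length(x), length(y)) <= 8 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  tibble(
    test = "mann_whitney",
    statistic = unname(res$statistic),   # R's W equals U for sample x
    p_raw = min(1, res$p.value),
    n_x = length(x), n_y = length(y),
    method = if (exact) "exact" else "normal_approx"
  )
}

#' Unpaired two-tailed t-test (Welch)
#'
#' Welch's t-test with Satterthwaite degrees of freedom (group variances are
#' not assumed equal). Degenerate inputs are guarded: two constant samples
#' with equal means give p = 1; with different means the separation is
#' infinitely significant and p = 0 is returned with a flag.
#'
#' @param x,y Numeric samples with at least 2 observations each.
#' @return One-row tibble: `test`, `statistic` (t), `p_raw`, `n_x`, `n_y`,
#'   `method`.
#' @export
t_unpaired <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) abort("both samples need >= 2 observations.")
  if (sd(x) == 0 && sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(tibble(test = "t_unpaired", statistic = 0, p_raw = 1,
                    n_x = length(x), n_y = length(y), method = "degenerate"))
    }
    return(tibble(test = "t_unpaired", statistic = Inf, p_raw = 0,
                  n_x = length(x), n_y = length(y), method = "degenerate"))
  }
  res <- stats::t.test(x, y, alternative = "two.sided", var.equal = FALSE)
  tibble(test = "t_unpaired", statistic = unname(res$statistic),
         p_raw = res$p.value, n_x = length(x), n_y = length(y),
         method = "welch")
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `p * m / rank` with monotonicity enforcement; order
#' preserving and never below the raw p-values.
#'
#' @param p_values Vector of p-values in [0, 1].
#' @return Adjusted p-values, same order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Compare two conditions across groups with FDR adjustment
#'
#' Runs the chosen test per group (typically per time point) and adjusts
#' the p-values across groups with Benjamini-Hochberg.
#'
#' @param data Tibble of per-cell (or per-organelle) records.
#' @param value Measurement column (tidy-eval).
#' @param condition Column holding the two condition labels (tidy-eval).
#' @param group Grouping column, e.g. time point (tidy-eval).
#' @param test `"mann_whitney"` or `"t_unpaired"`.
#' @return Tibble with one row per group: test output plus `p_adjusted`.
#' @export
compare_groups <- function(data, value, condition, group,
                           test = c("mann_whitney", "t_unpaired")) {
  test <- match.arg(test)
  fn <- if (test == "mann_whitney") mann_whitney else t_unpaired
  val <- rlang::enquo(value); cond <- rlang::enquo(condition); grp <- rlang::enquo(group)
  splits <- data |>
    dplyr::group_by(!!grp) |>
    dplyr::group_split()
  out <- purrr::map_dfr(splits, function(d) {
    levels <- sort(unique(dplyr::pull(d, !!cond)))
    if (length(levels) != 2) {
      abort("each group must contain exactly two condition levels.")
    }
    xv <- dplyr::pull(dplyr::filter(d, !!cond == levels[1]), !!val)
    yv <- dplyr::pull(dplyr::filter(d, !!cond == levels[2]), !!val)
    res <- fn(xv[!is.na(xv)], yv[!is.na(yv)])
    res$group <- dplyr::pull(d, !!grp)[1]
    res$level_x <- levels[1]; res$level_y <- levels[2]
    res
  })
  out$p_adjusted <- bh_fdr(out$p_raw)
  dplyr::relocate(out, "group")
}
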