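# Multi-plane ion-count stacks: drift alignment, accumulation and delta maps.
#
# The NanoSIMS rasters the same field up to 15 times; planes are aligned by
# integer-pixel shifts (no interpolation, so Poisson integrality and summed
# counts are preserved) and accumulated to raise counting precision, then
# the per-mil 13C enrichment is computed from the accumulated count ratio.

SPECIES_12 <- "12C14N"
SPECIES_13 <- "13C14N"

#' Construct an ion-count stack
#'
#' @param counts12,counts13 Integer arrays `nrow x ncol x n_planes` of
#'   12C14N- and 13C14N- counts per pixel per raster plane.
#' @param pixel_size_um NanoSIMS pixel size, micrometres.
#' @param dwell_ms Pixel dwell time, milliseconds.
#' @param metadata Named list (field id, condition, time point, ...).
#' @return A `sims_stack` object.
#' @export
ion_count_stack <- function(counts12, counts13, pixel_size_um, dwell_ms = 5,
                            metadata = list()) {
  if (length(dim(counts12)) == 2) counts12 <- array(counts12, c(dim(counts12), 1))
  if (length(dim(counts13)) == 2) counts13 <- array(counts13, c(dim(counts13), 1))
  if (!identical(dim(counts12), dim(counts13))) {
    abort("species count arrays differ in shape; both species must share plane count and grid.")
  }
  for (a in list(counts12, counts13)) {
    if (any(a < 0) || any(a != round(a))) abort("ion counts must be non-negative integers.")
  }
  structure(list(
    counts = setNames(list(counts12, counts13), c(SPECIES_12, SPECIES_13)),
    pixel_size_um = pixel_size_um, dwell_ms = dwell_ms, metadata = metadata
  ), class = "sims_stack")
}

#' @export
print.sims_stack <- function(x, ...) {
  d <- dim(x$counts[[1]])
  cat(sprintf("<sims_stack> %d x %d px, %d plane(s), species %s\n",
              d[1], d[2], d[3], paste(names(x$counts), collapse = " + ")))
  invisible(x)
}

n_planes <- function(stack) dim(stack$counts[[1]])[3]

#' Estimate per-plane drift shifts
#'
#' Aligns each raster plane to the running accumulation of the already
#' aligned planes by maximizing the normalized cross-correlation over integer
#' shifts within `±max_shift`. A shift of (dy, dx) means the plane's content
#' is displaced by (dy, dx) relative to the first plane, i.e. aligned values
#' are read from `plane[r + dy, c + dx]`. Ties are broken by smallest
#' |dy| + |dx|, then smallest dy, then dx. The first plane's shift is (0, 0)
#' by definition.
#'
#' @param stack A `sims_stack`.
#' @param reference_species Species used for alignment (the 12C14N- image,
#'   which carries the structural contrast).
#' @param max_shift Search radius in pixels.
#' @return Integer matrix `n_planes x 2` with columns `dy`, `dx`.
#' @export
estimate_plane_shifts <- function(stack, reference_species = SPECIES_12,
                                  max_shift = 10) {
  stopifnot(inherits(stack, "sims_stack"), max_shift >= 0)
  planes <- stack$counts[[reference_species]]
  if (is.null(planes)) abort(paste("species", reference_species, "not present in stack."))
  np <- dim(planes)[3]
  shifts <- matrix(0L, np, 2, dimnames = list(NULL, c("dy", "dx")))
  acc <- planes[, , 1] * 1.0
  if (np == 1) return(shifts)
  for (p in 2:np) {
    pl <- planes[, , p] * 1.0
    if (all(pl == 0)) {
      warn(sprintf("plane %d contains no counts; assuming zero shift.", p))
      s <- c(0L, 0L)
    } else {
      s <- best_ncc_shift(acc, pl, max_shift)
    }
    shifts[p, ] <- s
    # fold the aligned plane into the running reference
    src_r <- (1 + max(0, s[1])):(nrow(pl) + min(0, s[1]))
    dst_r <- src_r - s[1]
    src_c <- (1 + max(0, s[2])):(ncol(pl) + min(0, s[2]))
    dst_c <- src_c - s[2]
    acc[dst_r, dst_c] <- acc[dst_r, dst_c] + pl[src_r, src_c]
  }
  shifts
}

# Exact normalized cross-correlation over all |dy|,|dx| <= m, computed with
# summed-area tables for the marginal moments and an FFT-based linear
# cross-correlation for the cross term (zero padding prevents wraparound).
best_ncc_shift <- function(ref, plane, m) {
  nr <- nrow(ref); nc <- ncol(ref)
  if (m == 0) return(c(0L, 0L))
  P1 <- stats::nextn(nr + m, 2); P2 <- stats::nextn(nc + m, 2)
  A <- matrix(0, P1, P2); A[1:nr, 1:nc] <- ref
  B <- matrix(0, P1, P2); B[1:nr, 1:nc] <- plane
  D <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE)) / (P1 * P2)

  sat_ref <- sat(ref); sat_ref2 <- sat(ref^2)
  sat_pl <- sat(plane); sat_pl2 <- sat(plane^2)

  cand <- expand.grid(dy = -m:m, dx = -m:m)
  cand <- cand[order(abs(cand$dy) + abs(cand$dx), cand$dy, cand$dx), ]
  best <- -Inf; best_s <- c(0L, 0L)
  for (i in seq_len(nrow(cand))) {
    dy <- cand$dy[i]; dx <- cand$dx[i]
    rr0 <- max(1, 1 - dy); rr1 <- min(nr, nr - dy)
    cc0 <- max(1, 1 - dx); cc1 <- min(nc, nc - dx)
    n <- (rr1 - rr0 + 1) * (cc1 - cc0 + 1)
    if (n <= 1) next
    sr <- sat_rect(sat_ref, rr0, rr1, cc0, cc1)
    sr2 <- sat_rect(sat_ref2, rr0, rr1, cc0, cc1)
    sp <- sat_rect(sat_pl, rr0 + dy, rr1 + dy, cc0 + dx, cc1 + dx)
    sp2 <- sat_rect(sat_pl2, rr0 + dy, rr1 + dy, cc0 + dx, cc1 + dx)
    cross <- D[(dy %% P1) + 1, (dx %% P2) + 1]
    vr <- sr2 - sr^2 / n
    vp <- sp2 - sp^2 / n
    if (vr <= 0 || vp <= 0) next
    ncc <- (cross - sr * sp / n) / sqrt(vr * vp)
    if (ncc > best + 1e-10) {  # candidates visited in tie-break order
      best <- ncc; best_s <- c(dy, dx)
    }
  }
  as.integer(best_s)
}

sat <- function(x) {
  s <- apply(x, 2, cumsum)
  t(apply(s, 1, cumsum))
}

sat_rect <- function(s, r0, r1, c0, c1) {
  v <- s[r1, c1]
  if (r0 > 1) v <- v - s[r0 - 1, c1]
  if (c0 > 1) v <- v - s[r1, c0 - 1]
  if (r0 > 1 && c0 > 1) v <- v + s[r0 - 1, c0 - 1]
  v
}

#' Accumulate aligned raster planes
#'
#' Applies the same integer shifts to both species and sums the planes.
#' The validity mask is the intersection of the shifted plane footprints:
#' only pixels covered by every plane are valid, so summed counts over the
#' mask conserve the per-plane totals over that region exactly.
#'
#' @param stack A `sims_stack`.
#' @param shifts Integer matrix `n_planes x 2` (columns dy, dx), e.g. from
#'   [estimate_plane_shifts()].
#' @param max_shift Largest allowed |shift| component; larger values are an
#'   error (they indicate a failed alignment).
#' @return A `silksims_accumulated` object with summed `n12`, `n13`,
#'   logical `mask`, and the applied `shifts`.
#' @export
accumulate <- function(stack, shifts, max_shift = 10) {
  stopifnot(inherits(stack, "sims_stack"))
  shifts <- as.matrix(shifts)
  if (nrow(shifts) == 0) abort("empty shift list; one (dy, dx) pair per plane is required.")
  if (nrow(shifts) != n_planes(stack) || ncol(shifts) != 2) {
    abort(sprintf("shifts must be %d x 2 (one row per plane).", n_planes(stack)))
  }
  if (any(abs(shifts) > max_shift)) {
    abort(sprintf("|shift| exceeds max_shift = %d.", max_shift))
  }
  d <- dim(stack$counts[[1]])
  nr <- d[1]; nc <- d[2]; np <- d[3]
  mask <- matrix(TRUE, nr, nc)
  sums <- list(matrix(0, nr, nc), matrix(0, nr, nc))
  for (p in seq_len(np)) {
    dy <- shifts[p, 1]; dx <- shifts[p, 2]
    dst_r <- max(1, 1 - dy):min(nr, nr - dy)
    dst_c <- max(1, 1 - dx):min(nc, nc - dx)
    cov <- matrix(FALSE, nr, nc)
    cov[dst_r, dst_c] <- TRUE
    mask <- mask & cov
    for (s in 1:2) {
      pl <- stack$counts[[s]][, , p]
      sums[[s]][dst_r, dst_c] <- sums[[s]][dst_r, dst_c] + pl[dst_r + dy, dst_c + dx]
    }
  }
  structure(list(
    n12 = sums[[1]], n13 = sums[[2]], mask = mask, shifts = shifts,
    pixel_size_um = stack$pixel_size_um, dwell_ms = stack$dwell_ms,
    n_planes = np, metadata = stack$metadata
  ), class = "silksims_accumulated")
}

#' @export
print.silksims_accumulated <- function(x, ...) {
  cat(sprintf("<silksims_accumulated> %d x %d px from %d plane(s); %.1f%% valid\n",
              nrow(x$n12), ncol(x$n12), x$n_planes, 100 * mean(x$mask)))
  invisible(x)
}

#' Per-pixel delta-13C map
#'
#' Computes the per-mil 13C enrichment
#' `delta13C = (R_mes / R_nat - 1) * 1000` from the accumulated count
#' ratio `R_mes = N13 / N12` at each pixel. Pixels whose accumulated 12C14N-
#' count falls below `min_counts` (or that lie outside the accumulation
#' validity mask) are masked, not errors: the per-pixel ratio is meaningless
#' at very low counts, while ROI statistics use raw summed counts and apply
#' no per-pixel threshold.
#'
#' @param acc A `silksims_accumulated`.
#' @param r_nat Reference 13C14N-/12C14N- ratio measured on isotopically
#'   natural tissue (> 0).
#' @param min_counts Minimum accumulated 12C14N- counts per pixel (>= 1).
#' @return A `silksims_delta_map` with `delta` (per mil, NA where invalid),
#'   logical `valid`, `r_nat`, `min_counts`.
#' @export
delta_map <- function(acc, r_nat, min_counts = 100) {
  stopifnot(inherits(acc, "silksims_accumulated"))
  if (r_nat <= 0) abort("`r_nat` must be > 0.")
  if (min_counts < 1) abort("`min_counts` must be >= 1.")
  valid <- acc$mask & acc$n12 >= min_counts
  delta <- matrix(NA_real_, nrow(acc$n12), ncol(acc$n12))
  delta[valid] <- (acc$n13[valid] / acc$n12[valid] / r_nat - 1) * 1000
  structure(list(delta = delta, valid = valid, r_nat = r_nat,
                 min_counts = min_counts, pixel_size_um = acc$pixel_size_um),
            class = "silksims_delta_map")
}

#' @export
print.silksims_delta_map <- function(x, ...) {
  cat(sprintf("<silksims_delta_map> %d x %d px, %.1f%% valid, R_nat = %g\n",
              nrow(x$delta), ncol(x$delta), 100 * mean(x$valid), x$r_nat))
  if (any(x$valid)) {
    cat(sprintf("  delta range %.1f .. %.1f permil\n",
                min(x$delta, na.rm = TRUE), max(x$delta, na.rm = TRUE)))
  }
  invisible(x)
}
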