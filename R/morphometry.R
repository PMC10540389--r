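# SEM-frame morphometry: mitochondrial shape and mitochondria-ER contacts.
#
# Shape uses the second-moment equivalent ellipse; perimeters come from the
# traced 8-connected boundary chain (edge step = pixel_size, diagonal step
# = sqrt(2) * pixel_size). A mitochondria-ER contact (MERC) is a maximal
# run of boundary pixels whose membrane gap to the nearest ER pixel is at
# most d_contact; the gap is measured as (center distance - 1 px) *
# pixel_size so that directly adjacent pixels count as zero apposition
# distance.

#' Length-to-width ratio of a mask region
#'
#' Major/minor axis ratio of the second-moment equivalent ellipse of the
#' region (pixel-center covariance plus the 1/12-per-axis pixel term), the
#' standard moment-based shape descriptor. Degenerate one-pixel-wide
#' regions are capped at the region length and flagged via the
#' `"degenerate"` attribute.
#'
#' @param mask Logical matrix with a single connected region of >= 9 px.
#' @return Aspect ratio (>= 1).
#' @export
aspect_ratio <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  if (nrow(px) < 9) abort("region too small for a moment-based aspect ratio (need >= 9 px).")
  cv <- stats::cov(px) + diag(2) / 12
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  len_major <- 4 * sqrt(ev[1])
  len_minor <- 4 * sqrt(ev[2])
  if (len_minor < 1.2) {  # ~single-pixel-wide: the minor moment is pure discretization
    out <- max(diff(range(px[, 1])), diff(range(px[, 2]))) + 1
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  max(1, len_major / len_minor)
}

# Moore boundary tracing of the (single) 8-connected region in `mask`.
# Returns an n x 2 matrix of (row, col) boundary pixels in traversal order
# (first-visit order along the clockwise walk). The walk terminates when a
# (pixel, backtrack-direction) state repeats, which is robust for any
# 8-connected region.
trace_boundary <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  if (nrow(px) == 0) return(cbind(row = integer(), col = integer()))
  if (nrow(px) == 1) {
    out <- px
    colnames(out) <- c("row", "col")
    return(out)
  }
  # pad so neighbour lookups never leave the matrix
  nrp <- nrow(mask) + 2L; ncp <- ncol(mask) + 2L
  m <- matrix(FALSE, nrp, ncp)
  m[2:(nrp - 1L), 2:(ncp - 1L)] <- mask
  # first foreground pixel in row-major scan; its west neighbour is background
  start <- as.integer(px[order(px[, 1], px[, 2]), , drop = FALSE][1, ] + 1L)
  # clockwise neighbourhood starting west (rows grow downward)
  dirs <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L,
                   0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L), ncol = 2, byrow = TRUE)
  dir_index <- matrix(0L, 3, 3)
  for (k in 1:8) dir_index[dirs[k, 1] + 2L, dirs[k, 2] + 2L] <- k

  seen <- new.env(hash = TRUE, size = 256)
  chain <- vector("list", 4L * nrow(px) + 8L)
  nchain <- 0L
  cur <- start; back <- 1L
  add_pixel <- function(p) {
    key <- paste0("p", p[1], "_", p[2])
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      nchain <<- nchain + 1L
      chain[[nchain]] <<- p
    }
  }
  add_pixel(cur)
  states <- new.env(hash = TRUE, size = 256)
  repeat {
    skey <- paste0(cur[1], "_", cur[2], "_", back)
    if (!is.null(states[[skey]])) break
    states[[skey]] <- TRUE
    moved <- FALSE
    for (j in 0:7) {
      k <- ((back - 1L + j) %% 8L) + 1L
      cand <- cur + dirs[k, ]
      if (m[cand[1], cand[2]]) {
        prev_k <- ((k - 2L) %% 8L) + 1L
        prev <- cur + dirs[prev_k, ]
        d <- prev - cand
        back <- dir_index[d[1] + 2L, d[2] + 2L]
        cur <- cand
        add_pixel(cur)
        moved <- TRUE
        break
      }
    }
    if (!moved) break  # no foreground neighbour: isolated start
  }
  out <- do.call(rbind, chain[seq_len(nchain)])
  colnames(out) <- c("row", "col")
  out - 1L
}

# Perimeter of a traced chain: edge steps count 1, diagonal steps sqrt(2);
# the closing step is included.
chain_perimeter_px <- function(chain) {
  n <- nrow(chain)
  if (n < 2) return(4)  # lone pixel: its own boundary
  nxt <- rbind(chain[-1, , drop = FALSE], chain[1, , drop = FALSE])
  steps <- sqrt(rowSums((nxt - chain)^2))
  sum(pmin(steps, sqrt(2)))
}

#' Quantify mitochondria-ER contacts for one cell
#'
#' Traces each mitochondrion's boundary, marks boundary pixels whose
#' membrane gap to the nearest ER pixel is within `d_contact_nm`, merges
#' runs separated by fewer than `merge_gap_px` boundary pixels (so
#' discretization does not split one apposition into several), and counts
#' the maximal runs. The contact frequency is the total count divided by the
#' summed mitochondrial boundary length.
#'
#' @param mito_masks List of logical matrices (one per mitochondrion) or a
#'   single integer-labeled matrix (`> 0` identifies mitochondria).
#' @param er_mask Logical matrix of ER pixels, congruent with the masks.
#' @param pixel_size_nm Pixel size in nm.
#' @param d_contact_nm Apposition cutoff in nm (default 30, the usual EM
#'   scale for ER-mitochondria appositions).
#' @param merge_gap_px Boundary-pixel gap below which two contact runs merge.
#' @return One-row tibble: `merc_count`, `n_mitochondria`, `perimeter_um`,
#'   `merc_frequency` (contacts per um of mitochondrial perimeter).
#' @export
merc_quantify <- function(mito_masks, er_mask, pixel_size_nm,
                          d_contact_nm = 30, merge_gap_px = 3) {
  stopifnot(d_contact_nm > 0)
  if (is.matrix(mito_masks) && !is.logical(mito_masks)) {
    ids <- setdiff(unique(as.vector(mito_masks)), 0)
    mito_masks <- lapply(ids, function(k) mito_masks == k)
  }
  if (is.matrix(mito_masks)) mito_masks <- list(mito_masks)
  for (mm in mito_masks) {
    if (!identical(dim(mm), dim(er_mask))) abort("masks must be congruent.")
  }
  have_er <- any(er_mask)
  if (have_er) {
    d_er <- as.matrix(EBImage::distmap(matrix(as.numeric(!er_mask),
                                              nrow(er_mask), ncol(er_mask))))
  }
  total_count <- 0L
  total_perim_px <- 0
  for (mm in mito_masks) {
    chain <- trace_boundary(mm)
    total_perim_px <- total_perim_px + chain_perimeter_px(chain)
    if (!have_er || nrow(chain) == 0) next
    gap_nm <- (d_er[chain] - 1) * pixel_size_nm
    total_count <- total_count + count_runs(gap_nm <= d_contact_nm, merge_gap_px)
  }
  perimeter_um <- total_perim_px * pixel_size_nm / 1000
  tibble(
    merc_count = total_count,
    n_mitochondria = length(mito_masks),
    perimeter_um = perimeter_um,
    merc_frequency = if (perimeter_um > 0) total_count / perimeter_um else 0
  )
}

# Count maximal TRUE runs on a cyclic sequence, merging FALSE gaps shorter
# than `merge_gap`.
count_runs <- function(flag, merge_gap) {
  n <- length(flag)
  if (n == 0 || !any(flag)) return(0L)
  if (all(flag)) return(1L)
  r <- rle(flag)
  # cyclically merge short FALSE gaps
  vals <- r$values; lens <- r$lengths
  keep_false <- vals == FALSE & lens >= merge_gap
  vals[vals == FALSE & !keep_false] <- TRUE
  r2 <- rle(rep.int(vals, lens))
  runs <- sum(r2$values)
  # wrap-around: if the sequence both starts and ends inside a TRUE run,
  # they are the same run
  if (r2$values[1] && r2$values[length(r2$values)] && length(r2$values) > 1) {
    runs <- runs - 1L
  }
  max(runs, 1L)
}

#' Morphometry of a synthetic scene
#'
#' Runs [aspect_ratio()] and [merc_quantify()] on the SEM-frame label masks
#' of every cell, mirroring how the shape analysis is done on the SEM image
#' rather than the ion images.
#'
#' @param scene A `silksims_scene`.
#' @param d_contact_nm,merge_gap_px See [merc_quantify()].
#' @return List with `mitochondria` (per-mitochondrion aspect ratios) and
#'   `cells` (per-cell MERC counts, planted truth, and frequency).
#' @export
morphometry_scene <- function(scene, d_contact_nm = 30, merge_gap_px = 3) {
  ps <- scene$acquisition$sem_pixel_size_nm
  mito_rows <- list(); cell_rows <- list()
  for (i in scene$cells$cell_id) {
    ci <- scene$cells[scene$cells$cell_id == i, ]
    rmax <- ceiling(max(ci$a, ci$b)) + 12
    r0 <- max(1, floor(ci$cy) - rmax); r1 <- min(nrow(scene$label_image), ceiling(ci$cy) + rmax)
    c0 <- max(1, floor(ci$cx) - rmax); c1 <- min(ncol(scene$label_image), ceiling(ci$cx) + rmax)
    lab <- scene$label_image[r0:r1, c0:c1]
    cid <- scene$cell_id_image[r0:r1, c0:c1]
    oid <- scene$organelle_id_image[r0:r1, c0:c1]
    er <- lab == COMPARTMENT_CLASSES[["ER"]] & cid == i
    mito_ids <- scene$organelles$organelle_id[
      scene$organelles$class == "mitochondrion" & scene$organelles$cell_id == i]
    masks <- lapply(mito_ids, function(k) oid == k)
    for (j in seq_along(mito_ids)) {
      mito_rows[[length(mito_rows) + 1]] <- tibble(
        cell_id = i, organelle_id = mito_ids[j],
        aspect_ratio = as.numeric(aspect_ratio(masks[[j]])),
        true_aspect = scene$organelles$true_aspect[
          scene$organelles$organelle_id == mito_ids[j]]
      )
    }
    mq <- if (length(masks)) {
      merc_quantify(masks, er, ps, d_contact_nm, merge_gap_px)
    } else {
      tibble(merc_count = 0L, n_mitochondria = 0L, perimeter_um = 0, merc_frequency = 0)
    }
    mq$cell_id <- i
    mq$merc_planted <- ci$merc_planted
    cell_rows[[length(cell_rows) + 1]] <- mq
  }
  list(mitochondria = dplyr::bind_rows(mito_rows),
       cells = dplyr::relocate(dplyr::bind_rows(cell_rows), "cell_id"))
}
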