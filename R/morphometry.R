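#' Label connected components of a 3D mask
#'
#' Breadth-first labelling under 6-connectivity (face-adjacent voxels), the
#' conservative choice that splits touching vesicles; 26-connectivity is
#' available for completeness.
#'
#' @param mask logical 3D array.
#' @param connectivity 6 (default) or 26.
#' @return integer array of the same shape; 0 = background, components
#'   numbered from 1 in first-voxel order.
#' @export
label_components <- function(mask, connectivity = 6) {
  stopifnot(length(dim(mask)) == 3L, connectivity %in% c(6, 26))
  d <- dim(mask)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  labels <- array(0L, dim = d)
  fg <- which(mask)
  if (length(fg) == 0L) return(labels)
  if (connectivity == 6) {
    offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                  c(0, 0, -1), c(0, 0, 1))
  } else {
    offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  }
  off_lin <- offs[, 1] + offs[, 2] * nz + offs[, 3] * nz * ny
  in_mask <- mask
  lab <- 0L
  for (seed_vox in fg) {
    if (labels[seed_vox] != 0L) next
    lab <- lab + 1L
    frontier <- seed_vox
    labels[seed_vox] <- lab
    while (length(frontier)) {
      sub <- arrayInd(frontier, d)
      nxt <- integer(0)
      for (k in seq_len(nrow(offs))) {
        nb_sub <- sub + matrix(offs[k, ], nrow(sub), 3, byrow = TRUE)
        ok <- nb_sub[, 1] >= 1 & nb_sub[, 1] <= nz &
          nb_sub[, 2] >= 1 & nb_sub[, 2] <= ny &
          nb_sub[, 3] >= 1 & nb_sub[, 3] <= nx
        if (!any(ok)) next
        nb <- frontier[ok] + off_lin[k]
        nb <- nb[in_mask[nb] & labels[nb] == 0L]
        if (length(nb)) {
          labels[nb] <- lab
          nxt <- c(nxt, nb)
        }
      }
      frontier <- unique(nxt)
    }
  }
  labels
}

#' Detect vesicles and apply the enlarged (>2 um) rule
#'
#' Connected components of a lysosome-marker mask are measured: volume equals
#' voxel count times voxel volume, the equivalent diameter is the diameter of
#' a sphere of the same volume, and a component is called enlarged iff its
#' equivalent diameter is strictly greater than the threshold (default 2 um,
#' the rule used for abnormally enlarged lysosome aggregates).
#'
#' @param mask logical 3D array (or `segmentation_mask`).
#' @param voxel_size `(z, y, x)` micrometres.
#' @param diameter_threshold_um strict threshold for the enlarged call.
#' @param connectivity passed to [label_components()].
#' @return data.frame of class `vesicle_calls`: component, centroid_z/y/x_um,
#'   voxels, volume_um3, eq_diam_um, enlarged. Empty mask gives zero rows.
#' @export
detect_vesicles <- function(mask, voxel_size, diameter_threshold_um = 2.0,
                            connectivity = 6) {
  stopifnot(all(voxel_size > 0))
  labels <- label_components(mask, connectivity)
  k <- max(labels)
  vox_vol <- prod(voxel_size)
  out <- data.frame(component = integer(0), centroid_z_um = numeric(0),
                    centroid_y_um = numeric(0), centroid_x_um = numeric(0),
                    voxels = integer(0), volume_um3 = numeric(0),
                    eq_diam_um = numeric(0), enlarged = logical(0))
  if (k == 0L) { class(out) <- c("vesicle_calls", class(out)); return(out) }
  d <- dim(mask)
  for (i in seq_len(k)) {
    idx <- which(labels == i)
    cen <- .index_centroid_um(idx, d, voxel_size)
    vol <- length(idx) * vox_vol
    eqd <- (6 * vol / pi)^(1 / 3)
    out <- rbind(out, data.frame(component = i, centroid_z_um = cen[1],
                                 centroid_y_um = cen[2], centroid_x_um = cen[3],
                                 voxels = length(idx), volume_um3 = vol,
                                 eq_diam_um = eqd,
                                 enlarged = eqd > diameter_threshold_um))
  }
  class(out) <- c("vesicle_calls", class(out))
  out
}

#' Assign vesicles to cells and build enlarged-cell contingency counts
#'
#' A cell is flagged iff at least one enlarged vesicle's centroid voxel lies in
#' its mask. Vesicles whose centroid falls in no cell are recorded as
#' unassigned and excluded from the counts. With a two-level `groups` factor
#' the per-group flagged/unflagged counts are assembled into a 2x2 table with
#' rows = groups and columns = (flagged, not flagged), mirroring
#' group-comparison reporting such as 39/184 wild-type versus 134/236 mutant
#' cells carrying enlarged lysosomal structures.
#'
#' @param vesicles a `vesicle_calls` data.frame.
#' @param cell_masks list of pairwise-disjoint logical arrays (or voxel index
#'   vectors), one per cell.
#' @param voxel_size `(z, y, x)` micrometres (to locate centroid voxels).
#' @param dim3 stack dimensions when `cell_masks` are index vectors.
#' @param groups optional factor of length `length(cell_masks)`.
#' @return list with `cell_flagged` (logical per cell), `vesicle_cell`
#'   (integer per vesicle, NA = unassigned), and `table` (2x2 matrix when two
#'   groups are given).
#' @export
assign_and_flag_cells <- function(vesicles, cell_masks, voxel_size,
                                  dim3 = NULL, groups = NULL) {
  n_cells <- length(cell_masks)
  as_idx <- function(m) if (is.logical(m) || is.array(m)) which(m != 0) else
    as.integer(m)
  idx_sets <- lapply(cell_masks, as_idx)
  if (n_cells > 1) {
    all_idx <- unlist(idx_sets)
    if (anyDuplicated(all_idx)) stop("cell masks must be pairwise disjoint")
  }
  if (is.null(dim3)) {
    first_arr <- Filter(function(m) is.array(m), cell_masks)
    if (!length(first_arr)) stop("supply dim3 when cell masks are index sets")
    dim3 <- dim(first_arr[[1]])
  }
  v_cell <- rep(NA_integer_, nrow(vesicles))
  if (nrow(vesicles)) {
    sub <- cbind(pmin(pmax(ceiling(vesicles$centroid_z_um / voxel_size[1]), 1),
                      dim3[1]),
                 pmin(pmax(ceiling(vesicles$centroid_y_um / voxel_size[2]), 1),
                      dim3[2]),
                 pmin(pmax(ceiling(vesicles$centroid_x_um / voxel_size[3]), 1),
                      dim3[3]))
    lin <- sub[, 1] + (sub[, 2] - 1) * dim3[1] + (sub[, 3] - 1) * dim3[1] * dim3[2]
    for (ci in seq_len(n_cells))
      v_cell[lin %in% idx_sets[[ci]]] <- ci
  }
  flagged <- vapply(seq_len(n_cells), function(ci)
    any(vesicles$enlarged & !is.na(v_cell) & v_cell == ci), FALSE)
  tab <- NULL
  if (!is.null(groups)) {
    stopifnot(length(groups) == n_cells)
    tab <- contingency_2x2(flagged, groups)
  }
  list(cell_flagged = flagged, vesicle_cell = v_cell, table = tab)
}

#' 2x2 contingency table from per-cell flags and groups
#'
#' Rows are the two groups (factor level order), columns are
#' (flagged, not flagged): e.g. 39 of 184 wild-type and 134 of 236 mutant
#' flagged cells form `rbind(c(39, 145), c(134, 102))`.
#'
#' @param flagged logical vector, one entry per cell.
#' @param groups two-level factor of the same length.
#' @return 2x2 integer matrix with dimnames.
#' @export
contingency_2x2 <- function(flagged, groups) {
  groups <- as.factor(groups)
  lv <- levels(groups)
  if (length(lv) != 2) stop("exactly two groups are required")
  tab <- rbind(c(sum(flagged[groups == lv[1]]), sum(!flagged[groups == lv[1]])),
               c(sum(flagged[groups == lv[2]]), sum(!flagged[groups == lv[2]])))
  dimnames(tab) <- list(group = lv, outcome = c("flagged", "not_flagged"))
  tab
}

#' Hair-bundle length and width from a 2D mask
#'
#' The bundle's principal axis is taken from the second-moment (inertia)
#' tensor of the pixel centers. Extents are moment-based: `sqrt(12)` times the
#' standard deviation of the pixel-center projections plus the per-pixel
#' variance, which is exact for axis-aligned rectangles and rotation-stable
#' (jagged staircase edges do not inflate it). Length uses the whole mask;
#' width is measured within a one-pixel band at mid-length, a declared
#' convention recorded in the result.
#'
#' @param mask logical 2D matrix (rows = y, cols = x), one connected component.
#' @param pixel_size `(y, x)` micrometres.
#' @return list of class `bundle_measure`: `length_um`, `width_um`,
#'   `orientation_deg` (principal axis versus the x axis), `convention`.
#' @export
measure_bundle <- function(mask, pixel_size) {
  stopifnot(length(dim(mask)) == 2L, length(pixel_size) == 2)
  m3 <- array(mask, dim = c(1L, dim(mask)))
  ncomp <- max(label_components(m3, 6))
  if (ncomp == 0L) stop("empty bundle mask")
  if (ncomp > 1L)
    stop("bundle mask has ", ncomp,
         " components; label bundles and measure them one at a time")
  w <- which(mask, arr.ind = TRUE)
  pts <- cbind(y = (w[, 1] - 0.5) * pixel_size[1],
               x = (w[, 2] - 0.5) * pixel_size[2])
  ctr <- colMeans(pts)
  cen <- sweep(pts, 2, ctr)
  ev <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)
  v1 <- ev$vectors[, 1]  # principal axis (largest variance)
  v2 <- ev$vectors[, 2]
  # moment extent: sqrt(12) * sd, corrected for the within-pixel variance
  pixvar <- function(v) (pixel_size[1]^2 * v[1]^2 + pixel_size[2]^2 * v[2]^2) / 12
  extent <- function(p, v) sqrt(12 * (mean((p - mean(p))^2) + pixvar(v)))
  p1 <- cen %*% v1
  len <- extent(p1, v1)
  band <- max(pixel_size)
  mid <- (max(p1) + min(p1)) / 2
  in_band <- abs(p1 - mid) <= band
  if (!any(in_band)) in_band <- abs(p1 - mid) <= min(abs(p1 - mid)) + 1e-9
  p2 <- (cen %*% v2)[in_band]
  wid <- extent(p2, v2)
  structure(list(length_um = len, width_um = wid,
                 orientation_deg = atan2(v1[1], v1[2]) * 180 / pi,
                 convention = "moment extents; width in a mid-length band"),
            class = "bundle_measure")
}

#' Count labelled cells whose centroid falls inside a region
#'
#' Deterministic stand-in for manual multi-point counting: a label is counted
#' iff its pixel centroid lies inside the region (inclusive bounds), e.g. a
#' 50 x 50 um box centered on the field.
#'
#' @param labels integer 2D matrix of cell labels (0 = background).
#' @param pixel_size `(y, x)` micrometres.
#' @param origin_um region origin `(y, x)` in micrometres.
#' @param extent_um region extent `(y, x)` in micrometres; default a 50 x 50
#'   um box.
#' @return integer count.
#' @export
count_cells <- function(labels, pixel_size, origin_um,
                        extent_um = c(50, 50)) {
  stopifnot(length(dim(labels)) == 2L)
  field <- dim(labels) * pixel_size
  if (any(origin_um < 0) || any(origin_um + extent_um > field + 1e-9))
    stop("counting region lies outside the image (field ",
         paste(round(field, 2), collapse = " x "), " um)")
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) return(0L)
  inside <- vapply(ids, function(i) {
    w <- which(labels == i, arr.ind = TRUE)
    cy <- (mean(w[, 1]) - 0.5) * pixel_size[1]
    cx <- (mean(w[, 2]) - 0.5) * pixel_size[2]
    cy >= origin_um[1] && cy <= origin_um[1] + extent_um[1] &&
      cx >= origin_um[2] && cx <= origin_um[2] + extent_um[2]
  }, FALSE)
  sum(inside)
}
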