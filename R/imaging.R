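#' Adaptive-threshold segmentation of one channel
#'
#' A voxel enters the foreground iff its intensity exceeds the local mean over
#' a window of physical size `window_um`, multiplied by `1 + offset_frac`. By
#' default windows are two-dimensional within each optical section (z-slice),
#' matching slice-wise confocal quantification; full 3D windows are available
#' via `mode = "3d"`. The method and parameters are recorded on the mask as
#' provenance.
#'
#' @param stack a [volume_stack()].
#' @param channel channel name or index.
#' @param window_um window edge length in micrometres (must cover at least one
#'   voxel in every windowed axis).
#' @param offset_frac non-negative multiplicative offset on the local mean.
#' @param mode `"slice"` (2D windows per z-slice, default) or `"3d"`.
#' @return A logical 3D array of class `segmentation_mask` with a
#'   `provenance` attribute.
#' @export
segment_adaptive <- function(stack, channel = 1, window_um = 5,
                             offset_frac = 0.1, mode = c("slice", "3d")) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "volume_stack"), offset_frac >= 0)
  if (window_um <= 0) stop("window_um must be positive")
  vs <- stack$voxel_size
  axes <- if (mode == "slice") 2:3 else 1:3
  if (any(window_um < vs[axes]))
    stop("window_um (", window_um, ") is smaller than one voxel (",
         paste(round(vs[axes], 3), collapse = ", "), " um)")
  half <- c(0L, 0L, 0L)
  half[axes] <- pmax(0L, as.integer(floor(window_um / (2 * vs[axes]))))
  a <- .stack_channel(stack, channel)
  lm <- .local_mean(a, half)
  mask <- a > lm * (1 + offset_frac)
  structure(mask, class = "segmentation_mask",
            provenance = list(method = "local_mean_adaptive",
                              channel = channel, window_um = window_um,
                              offset_frac = offset_frac, mode = mode,
                              half_window_vox = half))
}

#' Rectangular region of interest in physical coordinates
#'
#' @param origin_um box origin `(z, y, x)` in micrometres.
#' @param extent_um box extent `(z, y, x)` in micrometres; all positive.
#' @param channel optional channel selector attached to the ROI.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(origin_um, extent_um, channel = NULL) {
  stopifnot(length(origin_um) == 3, length(extent_um) == 3,
            all(extent_um > 0), all(origin_um >= 0))
  structure(list(origin_um = as.numeric(origin_um),
                 extent_um = as.numeric(extent_um), channel = channel),
            class = "roi_box")
}

# um box -> 0-based half-open voxel bounds, rounded outward; errors when the
# box does not fit in the stack.
.roi_voxels <- function(roi, stack) {
  vs <- stack$voxel_size
  d <- dim(stack$voxels)[1:3]
  lo <- floor(roi$origin_um / vs)
  hi <- ceiling((roi$origin_um + roi$extent_um) / vs)
  if (any(lo < 0) || any(hi > d))
    stop("ROI [", paste(roi$origin_um, collapse = ","), "] + [",
         paste(roi$extent_um, collapse = ","), "] um lies outside the stack")
  list(lo = as.integer(lo), hi = as.integer(hi))
}

#' Intensity summary over a region of interest
#'
#' Sums and means are computed over the ROI voxels of one channel, optionally
#' intersected with a segmentation mask. A selection containing zero voxels
#' returns sum 0 with the mean flagged undefined (`mean = NA`,
#' `mean_defined = FALSE`) rather than silently zero.
#'
#' @param stack a [volume_stack()].
#' @param roi a [roi_box()], or `NULL` for the whole field.
#' @param mask optional logical array aligned to the stack.
#' @param channel channel name or index; defaults to the ROI's channel or 1.
#' @return A list of class `intensity_summary` with `voxel_count`, `sum`,
#'   `mean`, `mean_defined` and `per_slice_sums`.
#' @export
quantify_roi <- function(stack, roi = NULL, mask = NULL, channel = NULL) {
  stopifnot(inherits(stack, "volume_stack"))
  channel <- channel %||% (if (!is.null(roi)) roi$channel else NULL) %||% 1L
  a <- .stack_channel(stack, channel)
  d <- dim(a)
  sel <- array(TRUE, dim = d)
  if (!is.null(roi)) {
    b <- .roi_voxels(roi, stack)
    sel[] <- FALSE
    sel[(b$lo[1] + 1L):b$hi[1], (b$lo[2] + 1L):b$hi[2],
        (b$lo[3] + 1L):b$hi[3]] <- TRUE
  }
  if (!is.null(mask)) {
    if (!all(dim(mask) == d)) stop("mask shape does not match the stack")
    sel <- sel & mask
  }
  n <- sum(sel)
  total <- sum(a[sel])
  per_slice <- vapply(seq_len(d[1]), function(z) sum(a[z, , ][sel[z, , ]]), 0)
  structure(list(voxel_count = n, sum = total,
                 mean = if (n > 0) total / n else NA_real_,
                 mean_defined = n > 0,
                 per_slice_sums = per_slice),
            class = "intensity_summary")
}

#' @export
print.intensity_summary <- function(x, ...) {
  cat("intensity_summary: n =", x$voxel_count, " sum =", format(x$sum),
      " mean =", if (x$mean_defined) format(x$mean) else "undefined", "\n")
  invisible(x)
}

#' Total and recruited signal quantification
#'
#' Total signal is the sum of all voxel values of the signal channel over the
#' whole field; recruited signal is the mean of the signal channel within the
#' marker-positive mask (the convention used for total versus recruited
#' filipin-cholesterol quantification relative to a GFP-positive area). When
#' no mask is supplied the marker channel is segmented adaptively.
#'
#' @param stack a [volume_stack()].
#' @param signal_channel,marker_channel channel names or indices.
#' @param marker_mask optional logical array; overrides segmentation.
#' @param ... passed to [segment_adaptive()] when the mask is derived.
#' @return list with `total_sum`, `recruited_mean`, `recruited_defined`,
#'   `marker_voxels`.
#' @export
total_and_recruited <- function(stack, signal_channel, marker_channel = NULL,
                                marker_mask = NULL, ...) {
  if (is.null(marker_mask)) {
    if (is.null(marker_channel))
      stop("supply marker_mask or marker_channel")
    marker_mask <- segment_adaptive(stack, marker_channel, ...)
  }
  sig <- .stack_channel(stack, signal_channel)
  if (!all(dim(marker_mask) == dim(sig)))
    stop("marker mask shape does not match the stack")
  n <- sum(marker_mask)
  list(total_sum = sum(sig),
       recruited_mean = if (n > 0) mean(sig[marker_mask]) else NA_real_,
       recruited_defined = n > 0,
       marker_voxels = n)
}

#' Stereocilium versus basolateral compartment enrichment
#'
#' For each of two channels, measures compartment volumes and mean
#' fluorescence over the stereocilium and basolateral masks, expresses the
#' within-channel stereocilium/basolateral mean-fluorescence ratio as a
#' percentage, and reports the cross-channel ratio of ratios (probe of
#' interest over reference membrane probe) as a fold change.
#'
#' @param stack a [volume_stack()].
#' @param stereocilia_mask,basolateral_mask disjoint, non-empty logical arrays
#'   aligned to the stack.
#' @param channels length-2 vector `(probe, reference)` of names or indices.
#' @return An object of class `enrichment_result`: per-channel table plus
#'   `ratio_of_ratios`.
#' @export
compartment_enrichment <- function(stack, stereocilia_mask, basolateral_mask,
                                   channels) {
  stopifnot(inherits(stack, "volume_stack"), length(channels) == 2)
  d <- dim(stack$voxels)[1:3]
  if (!all(dim(stereocilia_mask) == d) || !all(dim(basolateral_mask) == d))
    stop("mask shapes do not match the stack")
  if (sum(stereocilia_mask) == 0 || sum(basolateral_mask) == 0)
    stop("compartment masks must be non-empty")
  if (any(stereocilia_mask & basolateral_mask))
    stop("stereocilia and basolateral masks overlap")
  vox_vol <- prod(stack$voxel_size)
  per_channel <- lapply(channels, function(ch) {
    a <- .stack_channel(stack, ch)
    sm <- mean(a[stereocilia_mask])
    bm <- mean(a[basolateral_mask])
    list(channel = ch,
         stereocilia_volume_um3 = sum(stereocilia_mask) * vox_vol,
         basolateral_volume_um3 = sum(basolateral_mask) * vox_vol,
         stereocilia_mean = sm, basolateral_mean = bm,
         ratio_pct = 100 * sm / bm)
  })
  names(per_channel) <- c("probe", "reference")
  structure(list(channels = per_channel,
                 ratio_of_ratios = per_channel$probe$ratio_pct /
                   per_channel$reference$ratio_pct),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  for (nm in names(x$channels)) {
    c_ <- x$channels[[nm]]
    cat(sprintf("%-9s channel %-6s stereocilia/basolateral = %.1f%%\n",
                nm, as.character(c_$channel), c_$ratio_pct))
  }
  cat(sprintf("ratio of ratios: %.1f-fold\n", x$ratio_of_ratios))
  invisible(x)
}

#' Split a mask at an apical z-plane
#'
#' Utility for turning one segmented cell into stereocilium (above the plane)
#' and basolateral (at or below the plane) compartments.
#'
#' Because the apical cell surface is curved, voxels just under the plane mix
#' stereocilia bases with cell-body membrane; an optional exclusion slab of
#' thickness `exclude_um` below the plane is dropped from both compartments.
#'
#' @param mask logical 3D array.
#' @param voxel_size `(z, y, x)` micrometres.
#' @param z_um apical plane height in micrometres.
#' @param exclude_um transition-slab thickness excluded below the plane.
#' @return list with logical arrays `above` and `below` (disjoint).
#' @export
split_mask_at_z <- function(mask, voxel_size, z_um, exclude_um = 0) {
  d <- dim(mask)
  zc <- (seq_len(d[1]) - 0.5) * voxel_size[1]
  above <- mask; above[zc <= z_um, , ] <- FALSE
  below <- mask; below[zc > z_um - exclude_um, , ] <- FALSE
  list(above = above, below = below)
}

#' Batch ROI quantification over a group of stacks
#'
#' @param stacks named list of [volume_stack()] objects (names become sample
#'   ids) or a character vector of TIFF paths.
#' @param roi a [roi_box()] applied to every stack, or `NULL` for whole field.
#' @param channel channel name present in every stack.
#' @param groups optional group label per stack (recycled if length 1).
#' @param mask_fun optional function `stack -> logical mask`, e.g. a
#'   [segment_adaptive()] wrapper.
#' @return data.frame with columns sample_id, group, channel, voxel_count,
#'   sum, mean; rows in input order. An empty input yields an empty table.
#' @export
quantify_group_stacks <- function(stacks, roi = NULL, channel = 1,
                                  groups = NULL, mask_fun = NULL) {
  if (is.character(stacks)) {
    nm <- basename(stacks)
    stacks <- stats::setNames(lapply(stacks, read_stack), nm)
  }
  n <- length(stacks)
  empty <- data.frame(sample_id = character(0), group = character(0),
                      channel = character(0), voxel_count = integer(0),
                      sum = numeric(0), mean = numeric(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  ids <- names(stacks) %||% paste0("sample", seq_len(n))
  if (is.null(groups)) groups <- rep("all", n)
  if (length(groups) == 1L) groups <- rep(groups, n)
  rows <- lapply(seq_len(n), function(i) {
    st <- stacks[[i]]
    if (is.character(channel) && !(channel %in% st$channel_names))
      stop("channel '", channel, "' missing in stack '", ids[i], "'")
    mask <- if (!is.null(mask_fun)) mask_fun(st) else NULL
    s <- quantify_roi(st, roi = roi, mask = mask, channel = channel)
    data.frame(sample_id = ids[i], group = groups[i],
               channel = as.character(channel),
               voxel_count = s$voxel_count, sum = s$sum, mean = s$mean,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
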