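#' Multi-channel 3D fluorescence stack
#'
#' A `volume_stack` holds non-negative voxel intensities for one or more
#' channels together with the physical voxel size. Voxels are indexed
#' `[z, y, x, channel]`; the voxel size is given in micrometres in `(z, y, x)`
#' order, matching confocal acquisition conventions (coarse axial step, fine
#' lateral sampling).
#'
#' @param voxels numeric array, either 3D `(z, y, x)` for a single channel or
#'   4D `(z, y, x, channel)`.
#' @param voxel_size numeric length-3, micrometres per voxel in `(z, y, x)`
#'   order; all components must be positive.
#' @param channel_names character vector naming the channels, one per channel.
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(voxels, voxel_size, channel_names = NULL) {
  if (length(dim(voxels)) == 3L) dim(voxels) <- c(dim(voxels), 1L)
  stopifnot(length(dim(voxels)) == 4L)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be three positive numbers (z, y, x) in micrometres")
  nc <- dim(voxels)[4]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    stop("channel count (", nc, ") does not match length of channel_names (",
         length(channel_names), ")")
  if (any(voxels < 0, na.rm = TRUE)) stop("voxel intensities must be non-negative")
  structure(list(voxels = voxels,
                 voxel_size = stats::setNames(voxel_size, c("z", "y", "x")),
                 channel_names = as.character(channel_names)),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat("volume_stack: ", d[1], " x ", d[2], " x ", d[3], " voxels (z,y,x), ",
      d[4], " channel(s)\n", sep = "")
  cat("  voxel size (um): z=", x$voxel_size[1], " y=", x$voxel_size[2],
      " x=", x$voxel_size[3], "\n", sep = "")
  cat("  channels: ", paste(x$channel_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.volume_stack <- function(x) dim(x$voxels)

.stack_channel <- function(stack, channel) {
  if (is.character(channel)) {
    i <- match(channel, stack$channel_names)
    if (is.na(i)) stop("channel '", channel, "' not found; available: ",
                       paste(stack$channel_names, collapse = ", "))
    channel <- i
  }
  a <- stack$voxels[, , , channel, drop = FALSE]
  dim(a) <- dim(stack$voxels)[1:3]
  a
}

.sidecar_path <- function(path) paste0(path, ".json")

#' Write a stack to multi-page TIFF with JSON metadata
#'
#' Pages are written channel-major (all z-slices of channel 1, then channel 2,
#' ...) as 32-bit float, scaled into `[0, 1]`. Physical voxel size, channel
#' names, stack shape and the intensity scale are stored in a JSON sidecar
#' (`<path>.json`) so the round trip through [read_stack()] restores
#' intensities to 32-bit float precision.
#'
#' @param stack a [volume_stack()].
#' @param path output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "volume_stack"))
  d <- dim(stack$voxels)
  scale <- max(stack$voxels, 1e-12)
  pages <- vector("list", d[1] * d[4])
  k <- 1L
  for (ch in seq_len(d[4])) for (z in seq_len(d[1])) {
    pages[[k]] <- stack$voxels[z, , , ch] / scale
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- list(shape_zyx = d[1:3], n_channels = d[4],
               voxel_size_um = as.numeric(stack$voxel_size),
               channel_names = stack$channel_names,
               intensity_scale = scale)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a stack written by [write_stack()]
#'
#' @param path TIFF path.
#' @param voxel_size optional `(z, y, x)` micrometre override, required when no
#'   metadata sidecar is present.
#' @param channel_names optional override for channel names.
#' @param n_channels number of channels when reading a bare TIFF without
#'   metadata (pages are split evenly, channel-major).
#' @return A [volume_stack()].
#' @export
read_stack <- function(path, voxel_size = NULL, channel_names = NULL,
                       n_channels = NULL) {
  if (!file.exists(path)) stop("stack file not found: ", path)
  meta <- NULL
  if (file.exists(.sidecar_path(path)))
    meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  if (is.null(voxel_size)) {
    if (is.null(meta))
      stop("missing voxel size: no metadata sidecar for '", path,
           "' and no voxel_size override supplied (field: voxel_size_um)")
    voxel_size <- meta$voxel_size_um
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz_total <- length(pages)
  nc <- n_channels %||% (if (!is.null(meta)) meta$n_channels else 1L)
  if (nz_total %% nc != 0L)
    stop("page count ", nz_total, " is not divisible by channel count ", nc)
  nz <- nz_total %/% nc
  scale <- if (!is.null(meta)) meta$intensity_scale else 1
  d2 <- dim(pages[[1]])
  vox <- array(0, dim = c(nz, d2[1], d2[2], nc))
  k <- 1L
  for (ch in seq_len(nc)) for (z in seq_len(nz)) {
    vox[z, , , ch] <- pages[[k]] * scale
    k <- k + 1L
  }
  if (is.null(channel_names))
    channel_names <- if (!is.null(meta)) meta$channel_names else NULL
  volume_stack(vox, voxel_size, channel_names)
}

#' Write ground-truth compartment masks as run-length-encoded JSON
#'
#' @param truth a `ground_truth` object from [simulate_stack()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  enc_cell <- function(cell) {
    list(center_um = cell$center_um, apex_um = cell$apex_um,
         enlarged = cell$enlarged,
         stereocilia = .rle_encode(cell$stereocilia),
         membrane = .rle_encode(cell$membrane),
         cytoplasm = .rle_encode(cell$cytoplasm),
         kinocilium = .rle_encode(cell$kinocilium),
         lysosomes = lapply(cell$lysosomes, function(l)
           list(diameter_um = l$diameter_um, center_um = l$center_um,
                idx = .rle_encode(l$idx))))
  }
  out <- list(dim_zyx = truth$dim, voxel_size_um = as.numeric(truth$voxel_size),
              cells = lapply(truth$cells, enc_cell))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read ground truth written by [write_ground_truth()]
#' @param path JSON path.
#' @return A `ground_truth` object.
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  dec_rle <- function(r) .rle_decode(list(starts = unlist(r$starts),
                                          lengths = unlist(r$lengths)))
  dec_cell <- function(cell) {
    list(center_um = unlist(cell$center_um), apex_um = cell$apex_um,
         enlarged = isTRUE(cell$enlarged),
         stereocilia = dec_rle(cell$stereocilia),
         membrane = dec_rle(cell$membrane),
         cytoplasm = dec_rle(cell$cytoplasm),
         kinocilium = dec_rle(cell$kinocilium),
         lysosomes = lapply(cell$lysosomes, function(l)
           list(diameter_um = l$diameter_um, center_um = unlist(l$center_um),
                idx = dec_rle(l$idx))))
  }
  structure(list(dim = unlist(x$dim_zyx), voxel_size = unlist(x$voxel_size_um),
                 cells = lapply(x$cells, dec_cell)),
            class = "ground_truth")
}

#' Logical mask for a ground-truth compartment
#'
#' @param truth `ground_truth` object.
#' @param compartment one of `"stereocilia"`, `"membrane"`, `"cytoplasm"`,
#'   `"kinocilium"`, `"lysosomes"`.
#' @param cells integer indices of cells to include (default all).
#' @return logical 3D array aligned to the phantom stack.
#' @export
truth_mask <- function(truth, compartment = c("stereocilia", "membrane",
                                              "cytoplasm", "kinocilium",
                                              "lysosomes"),
                       cells = seq_along(truth$cells)) {
  compartment <- match.arg(compartment)
  m <- array(FALSE, dim = truth$dim)
  for (i in cells) {
    cell <- truth$cells[[i]]
    idx <- if (compartment == "lysosomes")
      unlist(lapply(cell$lysosomes, `[[`, "idx"), use.names = FALSE)
    else cell[[compartment]]
    m[idx] <- TRUE
  }
  m
}
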