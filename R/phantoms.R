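#' Specification of a synthetic hair-cell imaging phantom
#'
#' Builds the parameter set for [simulate_stack()]. The phantom emulates the
#' specimens behind two-channel confocal quantification of sensory hair cells:
#' an ellipsoidal cell body with a membrane shell, a bundle of apical
#' stereocilia cylinders (optionally a single longer kinocilium), apically
#' biased lysosome vesicles, and per-channel membrane-probe models in which the
#' stereocilia membrane density is the cell-body membrane density multiplied by
#' an enrichment factor. All geometric parameters are generative choices of
#' this package, not measurements: hair-cell proportions are realistic for
#' larval zebrafish (cell body ~5 x 8 um, bundle a few micrometres tall) but
#' stereocilia are rendered thicker than real stereocilia so that they are
#' resolvable on the voxel grid.
#'
#' @param n_cells number of cells, laid out on a y-x grid.
#' @param cell_semiaxes_um ellipsoid semi-axes `(z, y, x)` of the cell body.
#' @param membrane_um thickness of the membrane shell.
#' @param stereocilia_count cylinders per bundle.
#' @param stereocilia_radius_um,stereocilia_length_um cylinder dimensions.
#' @param kinocilium logical; add one cylinder twice the stereocilia length.
#' @param probes list of per-channel probe models, each a list with fields
#'   `name`, `membrane_density` (intensity density per membrane voxel),
#'   `enrichment` (dimensionless multiplier on stereocilia-membrane density),
#'   `cyto_density`, `lysosome_density`.
#' @param lysosome_count small vesicles per cell.
#' @param lysosome_diam_um range (min, max) of normal vesicle diameters.
#' @param enlarged_fraction fraction of cells receiving one enlarged vesicle.
#' @param enlarged_diam_um range of enlarged vesicle diameters; must exceed
#'   2 um so that enlarged calls are well defined.
#' @param gain photon gain, detector counts per unit density (Poisson stage).
#' @param read_sd Gaussian read-noise standard deviation in counts.
#' @param poisson logical; apply Poisson photon noise.
#' @param psf_sigma_um isotropic Gaussian PSF sigma in micrometres (0 = none).
#' @param voxel_size_um voxel size `(z, y, x)` in micrometres.
#' @param stack_shape stack dimensions `(z, y, x)` in voxels.
#' @param seed integer seed; phantoms are pure functions of (spec, seed).
#' @return A `phantom_spec` list, validated.
#' @export
phantom_spec <- function(n_cells = 1,
                         cell_semiaxes_um = c(4, 2.5, 2.5),
                         membrane_um = 0.4,
                         stereocilia_count = 12,
                         stereocilia_radius_um = 0.3,
                         stereocilia_length_um = 4,
                         kinocilium = FALSE,
                         probes = list(
                           list(name = "PM", membrane_density = 1,
                                enrichment = 1, cyto_density = 0.05,
                                lysosome_density = 0),
                           list(name = "D4H", membrane_density = 1,
                                enrichment = 8, cyto_density = 0.05,
                                lysosome_density = 0)),
                         lysosome_count = 3,
                         lysosome_diam_um = c(0.6, 1.2),
                         enlarged_fraction = 0,
                         enlarged_diam_um = c(2.2, 3.2),
                         gain = 50,
                         read_sd = 2,
                         poisson = TRUE,
                         psf_sigma_um = 0.1,
                         voxel_size_um = c(0.15, 0.1, 0.1),
                         stack_shape = c(96, 80, 80),
                         seed = 1) {
  spec <- list(n_cells = as.integer(n_cells),
               cell_semiaxes_um = cell_semiaxes_um,
               membrane_um = membrane_um,
               stereocilia_count = as.integer(stereocilia_count),
               stereocilia_radius_um = stereocilia_radius_um,
               stereocilia_length_um = stereocilia_length_um,
               kinocilium = isTRUE(kinocilium),
               probes = probes,
               lysosome_count = as.integer(lysosome_count),
               lysosome_diam_um = lysosome_diam_um,
               enlarged_fraction = enlarged_fraction,
               enlarged_diam_um = enlarged_diam_um,
               gain = gain, read_sd = read_sd, poisson = isTRUE(poisson),
               psf_sigma_um = psf_sigma_um,
               voxel_size_um = voxel_size_um,
               stack_shape = as.integer(stack_shape),
               seed = as.integer(seed))
  .validate_phantom_spec(spec)
  class(spec) <- "phantom_spec"
  spec
}

.validate_phantom_spec <- function(s) {
  stopifnot(s$n_cells >= 1, s$membrane_um > 0,
            all(s$cell_semiaxes_um > 0), s$stereocilia_count >= 0,
            s$stereocilia_radius_um > 0, s$stereocilia_length_um > 0,
            s$lysosome_count >= 0, all(s$lysosome_diam_um > 0),
            s$gain > 0, s$read_sd >= 0, s$psf_sigma_um >= 0,
            all(s$voxel_size_um > 0), all(s$stack_shape >= 4))
  if (s$enlarged_fraction < 0 || s$enlarged_fraction > 1)
    stop("enlarged_fraction must lie in [0, 1]")
  if (s$enlarged_fraction > 0 && s$enlarged_diam_um[1] <= 2)
    stop("enlarged_diam_um must exceed the 2 um rule")
  for (p in s$probes) {
    if (p$membrane_density <= 0) stop("probe membrane_density must be > 0")
    if (p$enrichment < 0) stop("probe enrichment must be >= 0")
  }
  invisible(TRUE)
}

# Voxel-center coordinate vectors (um) for a stack geometry.
.vox_centers <- function(shape, voxel_size)
  lapply(1:3, function(a) (seq_len(shape[a]) - 0.5) * voxel_size[a])

# Linear indices of voxels whose centers lie inside an ellipsoid.
# Restricted to a bounding box for speed.
.ellipsoid_idx <- function(shape, vs, center, semi) {
  ax <- .vox_centers(shape, vs)
  rng <- lapply(1:3, function(a) which(abs(ax[[a]] - center[a]) <= semi[a]))
  if (any(vapply(rng, length, 0L) == 0L)) return(integer(0))
  g <- expand.grid(z = rng[[1]], y = rng[[2]], x = rng[[3]])
  dz <- (ax[[1]][g$z] - center[1]) / semi[1]
  dy <- (ax[[2]][g$y] - center[2]) / semi[2]
  dx <- (ax[[3]][g$x] - center[3]) / semi[3]
  inside <- dz * dz + dy * dy + dx * dx <= 1
  g <- g[inside, , drop = FALSE]
  g$z + (g$y - 1L) * shape[1] + (g$x - 1L) * shape[1] * shape[2]
}

# Linear indices of a z-aligned cylinder: center (y,x), radius r, z in (z0, z1].
.cylinder_idx <- function(shape, vs, yx, r, z0, z1) {
  ax <- .vox_centers(shape, vs)
  zr <- which(ax[[1]] > z0 & ax[[1]] <= z1)
  yr <- which(abs(ax[[2]] - yx[1]) <= r)
  xr <- which(abs(ax[[3]] - yx[2]) <= r)
  if (!length(zr) || !length(yr) || !length(xr)) return(integer(0))
  g <- expand.grid(z = zr, y = yr, x = xr)
  dy <- ax[[2]][g$y] - yx[1]
  dx <- ax[[3]][g$x] - yx[2]
  g <- g[dy * dy + dx * dx <= r * r, , drop = FALSE]
  g$z + (g$y - 1L) * shape[1] + (g$x - 1L) * shape[1] * shape[2]
}

#' Render a synthetic hair-cell stack with ground truth
#'
#' Renders geometry on the voxel grid by center-of-voxel inclusion, assigns
#' per-compartment intensity densities from each probe model, optionally blurs
#' with a Gaussian PSF (optics precede detection), then applies Poisson photon
#' noise and Gaussian read noise. With noise disabled the rendered intensity
#' at a voxel equals its compartment density times the gain exactly.
#'
#' Per-cell geometry (stereocilia placement, lysosome sizes and positions,
#' enlarged-vesicle assignment) is drawn from a per-cell substream seeded from
#' `(spec$seed, cell index)`, so cell `i` is unchanged when `n_cells` grows.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `stack` (a [volume_stack()]) and `truth`
#'   (a `ground_truth` object: per-cell disjoint compartment masks as voxel
#'   index sets, true lysosome diameters, and the spec).
#' @export
simulate_stack <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  .validate_phantom_spec(spec)
  shape <- spec$stack_shape
  vs <- spec$voxel_size_um
  ext <- shape * vs
  semi <- spec$cell_semiaxes_um
  st_len <- spec$stereocilia_length_um
  kin_len <- if (spec$kinocilium) 2 * st_len else 0
  apical_len <- max(if (spec$stereocilia_count > 0) st_len else 0, kin_len)
  need_z <- 2 * semi[1] + apical_len + 2 * vs[1]
  if (need_z > ext[1])
    stop("cell body plus stereocilia (", round(need_z, 2),
         " um) exceed stack z extent (", round(ext[1], 2), " um)")
  # grid layout in y-x
  ncol_g <- ceiling(sqrt(spec$n_cells))
  nrow_g <- ceiling(spec$n_cells / ncol_g)
  pitch_y <- ext[2] / nrow_g
  pitch_x <- ext[3] / ncol_g
  if (pitch_y < 2 * semi[2] + 2 * vs[2] || pitch_x < 2 * semi[3] + 2 * vs[3])
    stop("cells do not fit in the stack cross-section; enlarge stack_shape ",
         "or reduce n_cells/cell_semiaxes_um")
  cz <- semi[1] + vs[1]   # cell center z; apical direction = +z
  n_probes <- length(spec$probes)
  occupied <- integer(0)  # guard against inter-cell overlap
  cells <- vector("list", spec$n_cells)
  dens <- lapply(seq_len(n_probes), function(i) array(0, dim = shape))

  for (ci in seq_len(spec$n_cells)) {
    set.seed((spec$seed * 7919 + ci * 104729) %% 2147483629L)
    gy <- ((ci - 1L) %/% ncol_g) + 1L
    gx <- ((ci - 1L) %% ncol_g) + 1L
    center <- c(cz, (gy - 0.5) * pitch_y, (gx - 0.5) * pitch_x)
    body <- .ellipsoid_idx(shape, vs, center, semi)
    inner <- .ellipsoid_idx(shape, vs, center, pmax(semi - spec$membrane_um,
                                                    vs / 2))
    membrane <- setdiff(body, inner)
    cytoplasm <- inner

    # stereocilia: sunflower-spiral placement within 55% of the apical radius
    st_idx <- integer(0)
    kin_idx <- integer(0)
    nst <- spec$stereocilia_count
    if (nst > 0) {
      golden <- pi * (3 - sqrt(5))
      kmax <- nst
      rad_max <- 0.55 * min(semi[2], semi[3])
      for (k in seq_len(nst)) {
        rr <- rad_max * sqrt(k / kmax)
        th <- k * golden
        sy <- center[2] + rr * sin(th)
        sx <- center[3] + rr * cos(th)
        # attach at the local ellipsoid surface height
        h2 <- 1 - ((sy - center[2]) / semi[2])^2 - ((sx - center[3]) / semi[3])^2
        z_surf <- center[1] + semi[1] * sqrt(max(h2, 0))
        if (z_surf + st_len > ext[1])
          stop("stereocilium exceeds stack bounds in z")
        st_idx <- c(st_idx, .cylinder_idx(shape, vs, c(sy, sx),
                                          spec$stereocilia_radius_um,
                                          z_surf, z_surf + st_len))
      }
      st_idx <- setdiff(unique(st_idx), body)  # cylinders attach at the curved surface
    }
    if (spec$kinocilium) {
      z_surf <- center[1] + semi[1]
      if (z_surf + kin_len > ext[1]) stop("kinocilium exceeds stack bounds in z")
      kin_idx <- setdiff(.cylinder_idx(shape, vs, center[2:3],
                                       spec$stereocilia_radius_um,
                                       z_surf, z_surf + kin_len),
                         c(st_idx, body))
    }

    # lysosomes: apically biased spheres inside the cytoplasm, non-overlapping
    enlarged <- stats::runif(1) < spec$enlarged_fraction
    d_ums <- stats::runif(spec$lysosome_count, spec$lysosome_diam_um[1],
                          spec$lysosome_diam_um[2])
    if (enlarged)
      d_ums <- c(d_ums, stats::runif(1, spec$enlarged_diam_um[1],
                                     spec$enlarged_diam_um[2]))
    d_ums <- sort(d_ums, decreasing = TRUE)  # place big vesicles first
    lys <- list()
    placed <- matrix(numeric(0), ncol = 4)  # z, y, x, r
    for (d_um in d_ums) {
      r <- d_um / 2
      ok <- FALSE
      for (try in 1:80) {
        # apical bias: upper half of the cell interior
        zc <- center[1] + stats::runif(1, 0.05, 0.95) * (semi[1] - r -
                                                           spec$membrane_um)
        u <- stats::runif(1, 0, 2 * pi)
        rho <- sqrt(stats::runif(1))
        margin <- 1 - (r + spec$membrane_um) / min(semi[2:3])
        if (margin <= 0) break
        h2 <- 1 - ((zc - center[1]) / semi[1])^2
        if (h2 <= 0) next
        yc <- center[2] + rho * sqrt(h2) * margin * semi[2] * sin(u)
        xc <- center[3] + rho * sqrt(h2) * margin * semi[3] * cos(u)
        cand <- c(zc, yc, xc)
        sep <- if (nrow(placed) == 0) TRUE else
          all(sqrt(colSums((t(placed[, 1:3, drop = FALSE]) - cand)^2)) >
                placed[, 4] + r + max(vs))
        if (sep) { ok <- TRUE; break }
      }
      if (!ok) next
      idx <- intersect(.ellipsoid_idx(shape, vs, cand, rep(r, 3)), cytoplasm)
      placed <- rbind(placed, c(cand, r))
      lys[[length(lys) + 1L]] <- list(diameter_um = d_um, center_um = cand,
                                      idx = idx)
    }
    lys_idx <- unlist(lapply(lys, `[[`, "idx"), use.names = FALSE)
    cytoplasm <- setdiff(cytoplasm, lys_idx)
    # truth records what was actually rendered, not the sampling intent
    enlarged <- any(vapply(lys, `[[`, 0, "diameter_um") > 2)

    all_idx <- c(st_idx, kin_idx, membrane, cytoplasm, lys_idx)
    if (anyDuplicated(all_idx))
      stop("internal error: compartments of cell ", ci, " are not disjoint")
    if (length(intersect(all_idx, occupied)))
      stop("cells overlap; enlarge the stack or reduce n_cells")
    occupied <- c(occupied, all_idx)

    for (pi_ in seq_len(n_probes)) {
      p <- spec$probes[[pi_]]
      a <- dens[[pi_]]
      a[cytoplasm] <- p$cyto_density
      a[membrane] <- p$membrane_density
      a[st_idx] <- p$membrane_density * p$enrichment
      a[kin_idx] <- p$membrane_density * (p$kinocilium_factor %||% 1)
      if ((p$lysosome_density %||% 0) > 0) a[lys_idx] <- p$lysosome_density
      dens[[pi_]] <- a
    }
    cells[[ci]] <- list(center_um = center, apex_um = center[1] + semi[1],
                        enlarged = enlarged,
                        stereocilia = sort(st_idx), membrane = sort(membrane),
                        cytoplasm = sort(cytoplasm), kinocilium = sort(kin_idx),
                        lysosomes = lys)
  }

  # detection: PSF blur, then Poisson photon noise, then Gaussian read noise
  set.seed(spec$seed)
  vox <- array(0, dim = c(shape, n_probes))
  sigma_vox <- spec$psf_sigma_um / vs
  for (pi_ in seq_len(n_probes)) {
    expected <- dens[[pi_]] * spec$gain
    if (spec$psf_sigma_um > 0) expected <- .gaussian_blur(expected, sigma_vox)
    out <- expected
    if (spec$poisson) out <- array(stats::rpois(length(expected),
                                                pmax(expected, 0)),
                                   dim = shape)
    if (spec$read_sd > 0) out <- out + array(stats::rnorm(length(out), 0,
                                                          spec$read_sd),
                                             dim = shape)
    vox[, , , pi_] <- pmax(out, 0)
  }
  stack <- volume_stack(vox, vs, vapply(spec$probes, `[[`, "", "name"))
  truth <- structure(list(dim = shape, voxel_size = vs, cells = cells,
                          spec = spec),
                     class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", length(x$cells), "cell(s),",
      sum(vapply(x$cells, function(c) length(c$lysosomes), 0L)),
      "lysosome(s)\n")
  invisible(x)
}
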