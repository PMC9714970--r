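test_that("voxelised spheres are measured and classified by the >2 um rule", {
  for (case in list(list(d = 3.0, enlarged = TRUE),
                    list(d = 1.0, enlarged = FALSE),
                    list(d = 1.9, enlarged = FALSE),
                    list(d = 2.1, enlarged = TRUE))) {
    m <- sphere_mask(case$d, 0.1)
    calls <- detect_vesicles(m, c(0.1, 0.1, 0.1))
    expect_equal(nrow(calls), 1)
    expect_lt(abs(calls$eq_diam_um - case$d), 0.1)
    expect_identical(calls$enlarged, case$enlarged)
  }
})

test_that("separated spheres are distinct components and volumes conserve", {
  m1 <- sphere_mask(1.0, 0.1, pad_vox = 3)
  n <- dim(m1)[1]
  m <- array(FALSE, dim = c(n, n, 3 * n))
  m[, , 1:n] <- m1
  m[, , (2 * n + 1):(3 * n)] <- m1
  calls <- detect_vesicles(m, c(0.1, 0.1, 0.1))
  expect_equal(nrow(calls), 2)
  expect_equal(sum(calls$voxels), sum(m))
  # touching along a face merges under 6-connectivity; diagonal does not
  touch <- array(FALSE, c(1, 2, 2))
  touch[1, 1, 1] <- TRUE; touch[1, 2, 2] <- TRUE
  expect_equal(max(label_components(touch, 6)), 2)
  expect_equal(max(label_components(touch, 26)), 1)
})

test_that("raising the diameter threshold never adds enlarged calls", {
  m <- sphere_mask(2.5, 0.1, pad_vox = 3)
  n_enl <- vapply(c(1, 2, 2.4, 3), function(th)
    sum(detect_vesicles(m, rep(0.1, 3), th)$enlarged), 0L)
  expect_true(all(diff(n_enl) <= 0))
})

test_that("equivalent diameter converges as voxel size shrinks", {
  err <- vapply(c(0.2, 0.1, 0.05), function(vx) {
    calls <- detect_vesicles(sphere_mask(2.4, vx), rep(vx, 3))
    abs(calls$eq_diam_um - 2.4)
  }, 0)
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.05)
})

test_that("per-cell enlarged flags follow the generative fraction", {
  spec <- phantom_spec(n_cells = 40, cell_semiaxes_um = c(2.6, 2, 2),
                       membrane_um = 0.3, stereocilia_count = 0,
                       lysosome_count = 1, lysosome_diam_um = c(0.8, 1.2),
                       enlarged_fraction = 0.5,
                       enlarged_diam_um = c(2.3, 2.7),
                       probes = list(list(name = "Lamp1",
                                          membrane_density = 0.05,
                                          enrichment = 1, cyto_density = 0.02,
                                          lysosome_density = 2)),
                       poisson = FALSE, read_sd = 0, psf_sigma_um = 0,
                       voxel_size_um = c(0.2, 0.2, 0.2),
                       stack_shape = c(32, 132, 154), seed = 21)
  sim <- simulate_stack(spec)
  truth <- sim$truth
  mask <- truth_mask(truth, "lysosomes")
  calls <- detect_vesicles(mask, truth$voxel_size)
  cell_masks <- lapply(truth$cells, function(cell)
    c(cell$membrane, cell$cytoplasm,
      unlist(lapply(cell$lysosomes, `[[`, "idx"))))
  res <- assign_and_flag_cells(calls, cell_masks, truth$voxel_size,
                               dim3 = truth$dim)
  # pipeline flags agree with the generator's own assignment
  expect_identical(res$cell_flagged,
                   vapply(truth$cells, `[[`, FALSE, "enlarged"))
  # flagged fraction within binomial 95% bounds of 0.5 for n = 40
  expect_true(sum(res$cell_flagged) >= qbinom(0.025, 40, 0.5) &&
                sum(res$cell_flagged) <= qbinom(0.975, 40, 0.5))
})

test_that("contingency layout mirrors grouped flagged/unflagged reporting", {
  flagged <- c(rep(TRUE, 39), rep(FALSE, 145), rep(TRUE, 134), rep(FALSE, 102))
  groups <- factor(rep(c("wild_type", "mutant"), c(184, 236)),
                   levels = c("wild_type", "mutant"))
  tab <- contingency_2x2(flagged, groups)
  expect_equal(unname(tab), rbind(c(39, 145), c(134, 102)))
})

test_that("no vesicles means no flags and a zero flagged column", {
  empty <- detect_vesicles(array(FALSE, c(4, 4, 4)), rep(1, 3))
  expect_equal(nrow(empty), 0)
  masks <- list(array(c(TRUE, rep(FALSE, 63)), c(4, 4, 4)))
  res <- assign_and_flag_cells(empty, masks, rep(1, 3))
  expect_false(any(res$cell_flagged))
})

test_that("bundle morphometry matches analytic rectangles", {
  px <- c(0.1, 0.1)
  rect <- matrix(FALSE, 40, 70)
  rect[11:25, 11:60] <- TRUE   # 1.5 um x 5.0 um
  b <- measure_bundle(rect, px)
  expect_equal(b$length_um, 5.0, tolerance = 1e-9)
  expect_equal(b$width_um, 1.5, tolerance = 1e-9)
  # square: symmetric, so length equals width
  sq <- matrix(FALSE, 30, 30)
  sq[6:25, 6:25] <- TRUE
  bs <- measure_bundle(sq, px)
  expect_equal(bs$length_um, bs$width_um, tolerance = 5e-3)
  # rotation invariance within 5%
  th <- 30 * pi / 180
  n <- 120
  ctr <- n / 2 * 0.1
  coords <- expand.grid(y = ((1:n) - 0.5) * 0.1, x = ((1:n) - 0.5) * 0.1)
  u <- (coords$x - ctr) * cos(th) + (coords$y - ctr) * sin(th)
  v <- -(coords$x - ctr) * sin(th) + (coords$y - ctr) * cos(th)
  rot <- matrix(abs(u) <= 2.5 & abs(v) <= 0.75, n, n)
  br <- measure_bundle(rot, px)
  expect_lt(abs(br$length_um - 5.0) / 5.0, 0.05)
  expect_lt(abs(br$width_um - 1.5) / 1.5, 0.05)
  # translation invariance
  rect2 <- matrix(FALSE, 40, 70)
  rect2[16:30, 6:55] <- TRUE
  b2 <- measure_bundle(rect2, px)
  expect_equal(b2$length_um, b$length_um)
  expect_equal(b2$width_um, b$width_um)
  # multi-component masks are rejected with guidance
  multi <- matrix(FALSE, 10, 10)
  multi[1:2, 1:2] <- TRUE; multi[8:9, 8:9] <- TRUE
  expect_error(measure_bundle(multi, px), "label")
})

test_that("cell counting uses the centroid-in-region rule", {
  labels <- matrix(0L, 100, 100)          # 0.6 um pixels -> 60 x 60 um field
  labels[10:14, 10:14] <- 1L              # centroid ~ (7.0, 7.0) um
  labels[40:44, 40:44] <- 2L
  labels[60:64, 60:64] <- 3L
  labels[2:18, 95:100] <- 4L              # straddles the right edge, centroid out
  px <- c(0.6, 0.6)
  n <- count_cells(labels, px, origin_um = c(3, 3), extent_um = c(50, 50))
  expect_equal(n, 3)
  # blob 4 overlaps the region column-wise but its centroid lies outside
  n2 <- count_cells(labels, px, origin_um = c(0, 5), extent_um = c(50, 50))
  expect_equal(n2, 3)
  expect_error(count_cells(labels, px, c(30, 30), c(50, 50)), "outside")
  # full-field region recovers every planted blob
  expect_equal(count_cells(labels, px, c(0, 0), c(60, 60)), 4)
})
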