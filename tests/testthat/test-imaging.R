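make_stack <- function(values, voxel = c(1, 1, 1), names = NULL) {
  volume_stack(values, voxel, names)
}

test_that("stack write/read round trip preserves voxels and metadata", {
  sim <- simulate_stack(small_quiet_spec())
  path <- file.path(tempdir(), "rt.tif")
  write_stack(sim$stack, path)
  back <- read_stack(path)
  expect_equal(back$voxels, sim$stack$voxels, tolerance = 1e-6)
  expect_equal(back$voxel_size, sim$stack$voxel_size)
  expect_identical(back$channel_names, sim$stack$channel_names)
})

test_that("missing voxel-size metadata is a named error, override recovers", {
  sim <- simulate_stack(small_quiet_spec())
  path <- file.path(tempdir(), "bare.tif")
  write_stack(sim$stack, path)
  file.remove(paste0(path, ".json"))
  expect_error(read_stack(path), "voxel size")
  back <- read_stack(path, voxel_size = c(0.12, 0.1, 0.1), n_channels = 2)
  expect_equal(dim(back$voxels)[4], 2L)
})

test_that("adaptive threshold honours its contract on flat and noisy fields", {
  flat <- make_stack(array(5, dim = c(4, 20, 20)))
  m <- segment_adaptive(flat, 1, window_um = 5, offset_frac = 0.1)
  expect_equal(sum(m), 0L)
  expect_error(segment_adaptive(flat, 1, window_um = 0.5), "smaller than one voxel")
  # monotonicity: larger offsets never add voxels
  set.seed(4)
  noisy <- make_stack(array(stats::runif(4 * 30 * 30, 0, 10), c(4, 30, 30)))
  offs <- c(0, 0.05, 0.1, 0.3)
  masks <- lapply(offs, function(o) segment_adaptive(noisy, 1, 5, o))
  for (i in seq_len(length(offs) - 1))
    expect_true(all(masks[[i]][masks[[i + 1]]])) # mask(i+1) subset of mask(i)
})

test_that("noise-free sphere segmentation overlaps ground truth", {
  truth <- sphere_mask(2.0, 0.1, pad_vox = 15)
  st <- make_stack(array(ifelse(truth, 100, 0), dim(truth)),
                   voxel = c(0.1, 0.1, 0.1))
  m <- segment_adaptive(st, 1, window_um = 3, offset_frac = 0.1)
  jac <- sum(m & truth) / sum(m | truth)
  expect_gte(jac, 0.9)
})

test_that("thresholding a thin binarised field reproduces its foreground", {
  sim <- simulate_stack(quiet_spec())
  m1 <- segment_adaptive(sim$stack, "PM", 5, 0.1)
  bin <- make_stack(array(as.numeric(m1), dim(m1)),
                    voxel = sim$stack$voxel_size)
  m2 <- segment_adaptive(bin, 1, 5, 0.1)
  expect_equal(unclass(m2), unclass(m1) == TRUE, ignore_attr = TRUE)
})

test_that("ROI quantification matches hand and brute-force sums", {
  a <- array(1, dim = c(1, 2, 5))
  st <- make_stack(a)
  s <- quantify_roi(st, roi_box(c(0, 0, 0), c(1, 2, 5)))
  expect_equal(s$voxel_count, 10)
  expect_equal(s$sum, 10)
  expect_equal(s$mean, 1)
  # empty mask intersection: sum 0, mean flagged undefined
  s0 <- quantify_roi(st, mask = array(FALSE, dim(a)))
  expect_equal(s0$sum, 0)
  expect_false(s0$mean_defined)
  expect_true(is.na(s0$mean))
  # brute-force oracle on a phantom sub-box
  sim <- simulate_stack(small_noisy_spec(seed = 8))
  roi <- roi_box(c(1.5, 1, 1), c(3, 2, 2))
  got <- quantify_roi(sim$stack, roi, channel = "PM")
  vs <- sim$stack$voxel_size
  lo <- floor(c(1.5, 1, 1) / vs); hi <- ceiling((c(1.5, 1, 1) + c(3, 2, 2)) / vs)
  oracle <- sum(sim$stack$voxels[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2],
                                 (lo[3] + 1):hi[3], 1])
  expect_equal(got$sum, oracle)
  expect_error(quantify_roi(st, roi_box(c(0, 0, 0), c(5, 5, 50))), "outside")
})

test_that("masking monotonicity holds for nested masks", {
  sim <- simulate_stack(small_noisy_spec(seed = 2))
  d <- dim(sim$stack$voxels)[1:3]
  set.seed(1)
  m2 <- array(stats::runif(prod(d)) < 0.5, d)
  m1 <- m2 & array(stats::runif(prod(d)) < 0.5, d)
  s1 <- quantify_roi(sim$stack, mask = m1, channel = 1)
  s2 <- quantify_roi(sim$stack, mask = m2, channel = 1)
  expect_lte(s1$sum, s2$sum)
})

test_that("total and recruited quantification follows the marker mask", {
  vals <- array(0, dim = c(1, 3, 3))
  vals[1, , ] <- matrix(1:9, 3, 3)  # column-major: cells hold 1..9
  marker <- array(FALSE, dim = c(1, 3, 3))
  marker[vals %in% c(2, 4, 6)] <- TRUE
  st <- volume_stack(array(c(vals, vals), c(1, 3, 3, 2)), c(1, 1, 1),
                     c("sig", "marker"))
  r <- total_and_recruited(st, "sig", marker_mask = marker)
  expect_equal(r$total_sum, 45)
  expect_equal(r$recruited_mean, 4)
  # marker covering the whole field equals the global mean
  rall <- total_and_recruited(st, "sig", marker_mask = array(TRUE, c(1, 3, 3)))
  expect_equal(rall$recruited_mean, mean(vals))
  # all-zero signal
  z <- volume_stack(array(0, c(1, 3, 3, 1)), c(1, 1, 1))
  rz <- total_and_recruited(z, 1, marker_mask = marker)
  expect_equal(rz$total_sum, 0)
  expect_equal(rz$recruited_mean, 0)
  # empty marker flags the mean undefined
  re <- total_and_recruited(st, "sig", marker_mask = array(FALSE, c(1, 3, 3)))
  expect_false(re$recruited_defined)
})

test_that("compartment enrichment ratios behave under scaling and swapping", {
  sim <- simulate_stack(quiet_spec(E = 4))
  stereo <- truth_mask(sim$truth, "stereocilia")
  baso <- truth_mask(sim$truth, "membrane")
  e <- compartment_enrichment(sim$stack, stereo, baso, c("D4H", "PM"))
  # equal compartment means give 100%
  expect_equal(e$channels$reference$ratio_pct, 100, tolerance = 1e-10)
  # per-channel scale invariance
  scaled <- sim$stack
  scaled$voxels[, , , 2] <- scaled$voxels[, , , 2] * 37
  e2 <- compartment_enrichment(scaled, stereo, baso, c("D4H", "PM"))
  expect_equal(e2$channels$probe$ratio_pct, e$channels$probe$ratio_pct)
  # exchange antisymmetry
  esw <- compartment_enrichment(sim$stack, stereo, baso, c("PM", "D4H"))
  expect_equal(esw$ratio_of_ratios, 1 / e$ratio_of_ratios, tolerance = 1e-12)
  # degenerate masks are rejected
  expect_error(compartment_enrichment(sim$stack, stereo, stereo, c(1, 2)),
               "overlap")
  empty <- array(FALSE, dim(stereo))
  expect_error(compartment_enrichment(sim$stack, empty, baso, c(1, 2)),
               "non-empty")
})

test_that("apical split produces disjoint compartments", {
  sim <- simulate_stack(quiet_spec())
  m <- segment_adaptive(sim$stack, "PM", 5, 0.1)
  sp <- split_mask_at_z(unclass(m), sim$stack$voxel_size,
                        sim$truth$cells[[1]]$apex_um, exclude_um = 0.9)
  expect_false(any(sp$above & sp$below))
})

test_that("batch quantification is deterministic and validates channels", {
  sim <- simulate_stack(small_quiet_spec())
  st <- sim$stack
  tab <- quantify_group_stacks(list(a = st, b = st), channel = "PM")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$sum[1], tab$sum[2])
  expect_equal(tab$mean[1], tab$mean[2])
  expect_error(quantify_group_stacks(list(a = st), channel = "nope"),
               "missing in stack 'a'")
  empty <- quantify_group_stacks(list(), channel = "PM")
  expect_s3_class(empty, "data.frame")
  expect_equal(nrow(empty), 0)
})

test_that("group batches recover a planted density ratio", {
  mk <- function(mult, seed) {
    probes <- list(list(name = "PM", membrane_density = mult, enrichment = 1,
                        cyto_density = 0.05 * mult, lysosome_density = 0))
    args <- utils::modifyList(small_geom, list(probes = probes, seed = seed))
    simulate_stack(do.call(phantom_spec, args))$stack
  }
  stacks <- c(lapply(1:3, function(s) mk(1, s)), lapply(4:6, function(s) mk(0.5, s)))
  names(stacks) <- paste0("s", 1:6)
  tab <- quantify_group_stacks(stacks, channel = "PM",
                               groups = rep(c("A", "B"), each = 3))
  ratio <- mean(tab$sum[tab$group == "B"]) / mean(tab$sum[tab$group == "A"])
  expect_lt(abs(ratio - 0.5), 0.05)
})
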