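test_that("endosteal segmentation recovers the disc area", {
  p <- trabecular_params(endosteal_radius = 9.2, seed = 31)
  s <- generate_slice(p)
  em <- segment_endosteal(s$grey, p$voxel_inplane)
  expect_lt(abs(em$area_mm2 - pi * 9.2^2) / (pi * 9.2^2), 0.05)
  # scale emulation: a typical distal-radius endosteal area
  expect_gt(em$area_mm2, 230)
  expect_lt(em$area_mm2, 300)
  # single connected region strictly inside the bounds
  lab <- trabmorph:::.label_components(em$mask, 4)
  expect_identical(max(lab), 1L)
  expect_false(any(em$mask[1, ]) || any(em$mask[, 1]))
})

test_that("segmentation fails without a closed rim", {
  flat <- matrix(0.8, 64, 64)
  expect_error(segment_endosteal(flat, 0.195), "degenerate|rim")
  noise <- matrix(runif(64 * 64), 64, 64)
  expect_error(segment_endosteal(noise, 0.195), "rim")
})

test_that("binarization is exact on separable classes and robust at noise", {
  p0 <- trabecular_params(noise_sd = 0, psf_fwhm = 0, seed = 32)
  s0 <- generate_slice(p0)
  mask <- structure(list(mask = s0$mask,
                         area_mm2 = sum(s0$mask) * p0$voxel_inplane^2,
                         threshold = NA, voxel_inplane = p0$voxel_inplane),
                    class = "endosteal_mask")
  bm0 <- binarize(s0$grey, mask)
  expect_identical(unname(bm0$bone[s0$mask]), unname(s0$bone[s0$mask]))

  p1 <- trabecular_params(seed = 32)          # default PSF and noise
  s1 <- generate_slice(p1)
  em <- segment_endosteal(s1$grey, p1$voxel_inplane)
  bm1 <- binarize(s1$grey, em)
  agree <- mean((bm1$bone == s1$bone)[s1$mask & em$mask])
  expect_gte(agree, 0.95)

  # inverted contrast with the flag set reproduces the same map
  bm_inv <- binarize(1 - s1$grey, em, invert = TRUE)
  expect_identical(bm_inv$bone, bm1$bone)

  expect_error(binarize(matrix(0.5, 10, 10), matrix(TRUE, 10, 10)),
               "degenerate")
})

test_that("hole growing matches the constructed three-square fixture", {
  bone <- matrix(TRUE, 16, 16)
  put <- function(m, r, c) { m[r:(r + 1), c:(c + 1)] <- FALSE; m }
  bone <- put(bone, 2, 2); bone <- put(bone, 2, 10); bone <- put(bone, 10, 5)
  bm <- as_binary(bone)
  h <- grow_holes(bm, voxel_inplane = 0.195)
  expect_identical(h$count, 3L)
  expect_equal(h$areas_mm2, rep(4 * 0.195^2, 3), tolerance = 1e-12)
  expect_equal(h$mean_area_mm2, 0.1521, tolerance = 1e-9)
})

test_that("region growing equals independent component labeling on random maps", {
  set.seed(41)
  for (k in 1:100) {
    fg <- matrix(runif(64 * 64) < runif(1, 0.2, 0.8), 64, 64)
    bm <- as_binary(!fg)          # fg here is marrow
    h <- grow_holes(bm, voxel_inplane = 1)
    ora <- oracle_label(fg, connectivity = 4)
    expect_identical(h$count, max(ora))
    expect_identical(sort(as.integer(h$areas_mm2)),
                     sort(as.integer(tabulate(ora[ora > 0]))))
  }
})

test_that("hole accounting is exact and boundary exclusion is reported", {
  s <- generate_slice(trabecular_params(seed = 33))
  bm <- as_binary(s$bone, s$mask)
  h_all <- grow_holes(bm, voxel_inplane = 0.195)
  # partition identity: hole area + bone area = mask area
  expect_equal(sum(h_all$areas_mm2) + sum(bm$bone) * 0.195^2,
               sum(bm$mask) * 0.195^2, tolerance = 1e-9)
  h_ex <- grow_holes(bm, voxel_inplane = 0.195, exclude_boundary = TRUE)
  expect_lte(h_ex$count, h_all$count)
  expect_equal(sum(h_ex$areas_mm2) + h_ex$boundary_area_mm2,
               sum(h_all$areas_mm2), tolerance = 1e-9)
})

test_that("removing bone monotonically grows holes; merging drops the count by one", {
  set.seed(42)
  for (k in 1:20) {
    fg <- random_binary_map(40, p = 0.5)
    bm <- as_binary(fg)
    h0 <- grow_holes(bm, voxel_inplane = 1)
    bone_px <- which(fg & !trabmorph:::.erode_mask(fg))
    if (!length(bone_px)) next
    fg2 <- fg; fg2[bone_px[1]] <- FALSE
    h1 <- grow_holes(as_binary(fg2), voxel_inplane = 1)
    expect_gte(sum(h1$areas_mm2), sum(h0$areas_mm2))
  }
  # two marrow squares separated by a single-pixel trabecula
  bone <- matrix(TRUE, 10, 12)
  bone[4:7, 3:5] <- FALSE
  bone[4:7, 7:9] <- FALSE
  h2 <- grow_holes(as_binary(bone), voxel_inplane = 1)
  expect_identical(h2$count, 2L)
  bone[4:7, 6] <- FALSE
  h1 <- grow_holes(as_binary(bone), voxel_inplane = 1)
  expect_identical(h1$count, 1L)
})

test_that("solid bone yields a flagged empty hole set, never 0/0", {
  bm <- as_binary(matrix(TRUE, 8, 8))
  h <- grow_holes(bm, voxel_inplane = 1)
  expect_identical(h$count, 0L)
  expect_true(h$empty)
  expect_true(is.na(h$mean_area_mm2))
})

test_that("noise-free measurement reproduces the ground-truth hole count", {
  p <- trabecular_params(noise_sd = 0, psf_fwhm = 0, seed = 34)
  s <- generate_slice(p)
  mask <- structure(list(mask = s$mask,
                         area_mm2 = sum(s$mask) * p$voxel_inplane^2,
                         threshold = NA, voxel_inplane = p$voxel_inplane),
                    class = "endosteal_mask")
  bm <- binarize(s$grey, mask)
  h <- grow_holes(bm)
  expect_identical(h$count, s$holes$count)
})
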