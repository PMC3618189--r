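make_stack <- function(n = 8, nr = 24, seed = 1, subject = "S01",
                       visit = "baseline") {
  set.seed(seed)
  image_stack(replicate(n, matrix(runif(nr * nr), nr, nr), simplify = FALSE),
              voxel_inplane = 0.195, voxel_thickness = 1,
              subject_id = subject, visit = visit)
}

test_that("TIFF stacks round-trip through disk", {
  st <- make_stack()
  # quantize to the 16-bit grid that TIFF storage imposes
  st$slices <- lapply(st$slices, function(m) round(m * 65535) / 65535)
  path <- tempfile(fileext = ".tif")
  write_stack(st, path)
  back <- read_stack(path, voxel_inplane = 0.195, voxel_thickness = 1)
  expect_length(back$slices, 8)
  for (i in 1:8)
    expect_equal(back$slices[[i]], st$slices[[i]], tolerance = 1e-7)
})

test_that("NIfTI stacks carry voxel geometry in pixdim", {
  st <- make_stack()
  path <- tempfile(fileext = ".nii.gz")
  write_stack(st, path)
  back <- read_stack(path)
  expect_equal(back$voxel_inplane, 0.195, tolerance = 1e-6)
  expect_equal(back$voxel_thickness, 1, tolerance = 1e-6)
})

test_that("stack invariants are enforced", {
  expect_error(image_stack(replicate(7, matrix(0, 4, 4), simplify = FALSE),
                           0.195, 1), "at least 8")
  expect_error(image_stack(c(replicate(7, matrix(0, 4, 4), simplify = FALSE),
                             list(matrix(0, 5, 4))), 0.195, 1),
               "same dimensions")
  st <- make_stack()
  path <- tempfile(fileext = ".tif")
  write_stack(st, path)
  expect_error(read_stack(path), "voxel_inplane")
  expect_error(read_stack(path, voxel_inplane = 0.195), "voxel_thickness")
})

test_that("registration of an identical pair is the identity", {
  p <- trabecular_params(seed = 21)
  bl <- generate_stack(p, n_slices = 8)
  fu <- bl
  fu$image$visit <- "followup"
  pair <- register_pair(bl$image, fu$image)
  expect_identical(pair$slice_offset, 0L)
  expect_identical(pair$shift, c(0L, 0L))
  expect_identical(pair$rotation, 0)
  expect_equal(pair$match_score, 1, tolerance = 1e-10)
})

test_that("planted slice offsets and in-plane shifts are recovered", {
  p <- trabecular_params(seed = 22)
  bl <- generate_stack(p, n_slices = 11)
  fu <- generate_followup(bl, bone_loss_fraction = 0.02, shift = c(3, 2),
                          rotation = 0, slice_offset = 2)
  pair <- register_pair(bl$image, fu$image)
  expect_identical(pair$slice_offset, 2L)
  expect_identical(oracle_slice_offset(bl$image, fu$image), 2L)
  expect_lte(max(abs(pair$shift - c(3, 2))), 1)

  # robustness: extra i.i.d. noise at the generator level must not move the
  # recovered integer offset
  fu_noisy <- fu
  set.seed(99)
  fu_noisy$image$slices <- lapply(fu$image$slices, function(m)
    m + matrix(rnorm(length(m), 0, p$noise_sd), nrow(m)))
  pair2 <- register_pair(bl$image, fu_noisy$image)
  expect_identical(pair2$slice_offset, 2L)
})

test_that("registration is symmetric up to inversion", {
  p <- trabecular_params(seed = 23)
  bl <- generate_stack(p, n_slices = 10)
  fu <- generate_followup(bl, bone_loss_fraction = 0.02, shift = c(2, -3),
                          rotation = 0, slice_offset = 1)
  ab <- register_pair(bl$image, fu$image)
  ba <- register_pair(fu$image, bl$image)
  expect_lte(abs(ab$slice_offset + ba$slice_offset), 1)
  expect_lte(max(abs(ab$shift + ba$shift)), 1)
})

test_that("unrelated stacks are flagged unmatchable", {
  a <- make_stack(seed = 1)
  b <- make_stack(seed = 2, visit = "followup")
  expect_error(register_pair(a, b), "unmatchable")
})

test_that("analysis volume selection follows the indexing contract", {
  st <- make_stack(n = 20)
  fu <- st; fu$visit <- "followup"
  pair <- register_pair(st, fu)
  vol <- select_analysis_volume(pair, 5)
  expect_identical(vol$baseline_index, 5:12)
  expect_identical(vol$followup_index, 5:12)
  expect_length(vol$baseline_volume, 8)
  expect_identical(vol$baseline_volume[[1]], st$slices[[5]])
  expect_error(select_analysis_volume(pair, 15), "6")
})

test_that("automatic distal reference detection matches the marked band", {
  p <- trabecular_params(seed = 25)
  st <- generate_stack(p, n_slices = 10, growth_plate_slices = 2)
  expect_identical(st$reference_slice, 3L)
  expect_identical(detect_reference_slice(st$image), 3L)
})
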