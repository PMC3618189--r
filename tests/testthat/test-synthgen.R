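test_that("generated slice hits the BVTV target and is reproducible", {
  p <- trabecular_params(target_bvtv = 0.477, seed = 1)
  s <- generate_slice(p)
  frac <- mean(s$bone[s$mask])
  expect_gte(frac, 0.447)
  expect_lte(frac, 0.507)

  s2 <- generate_slice(p)
  expect_identical(s$grey, s2$grey)
  expect_identical(s$bone, s2$bone)
  expect_identical(s$holes$areas_px, s2$holes$areas_px)

  s7a <- generate_slice(trabecular_params(seed = 7))
  s7b <- generate_slice(trabecular_params(seed = 7))
  expect_identical(s7a, s7b)
})

test_that("noise-free, PSF-free rendering is an intensity scaling of the truth", {
  p <- trabecular_params(noise_sd = 0, psf_fwhm = 0, seed = 3)
  s <- generate_slice(p)
  # inside the field of view the scene is two-class: grey is an affine map
  # of the bone indicator
  expect_setequal(unique(as.vector(s$grey)), c(0.25, 0.80))
  in_disc <- s$mask
  expect_identical(unname(s$grey[in_disc] == 0.25), unname(s$bone[in_disc]))
})

test_that("ground-truth hole areas partition the marrow exactly", {
  s <- generate_slice(trabecular_params(seed = 4))
  marrow_px <- sum(s$mask & !s$bone)
  expect_identical(sum(s$holes$areas_px), as.integer(marrow_px))
  expect_equal(sum(s$holes$areas_px),
               round((1 - mean(s$bone[s$mask])) * sum(s$mask)))
  expect_true(all(s$holes$areas_px > 0))
})

test_that("infeasible parameter combinations fail loudly", {
  expect_error(trabecular_params(target_bvtv = 0.1), "target_bvtv")
  expect_error(trabecular_params(target_bvtv = 0.85), "target_bvtv")
  expect_error(trabecular_params(hole_count_target = 5000L), "infeasible")
  expect_error(trabecular_params(target_tbth = 0.1), "voxel")
})

test_that("follow-up with no perturbation is the baseline", {
  p <- trabecular_params(seed = 5, noise_sd = 0)
  bl <- generate_stack(p, n_slices = 8)
  fu <- generate_followup(bl, bone_loss_fraction = 0, shift = c(0, 0),
                          rotation = 0, slice_offset = 0)
  for (i in seq_along(bl$slices)) {
    expect_identical(fu$slices[[i]]$bone, bl$slices[[i]]$bone)
    expect_identical(fu$slices[[i]]$mask, bl$slices[[i]]$mask)
  }
})

test_that("bone loss removes the stated fraction and is monotone in BVTV", {
  p <- trabecular_params(seed = 6)
  bl <- generate_stack(p, n_slices = 8)
  base_px <- sum(bl$slices[[1]]$bone & bl$slices[[1]]$mask)
  fu <- generate_followup(bl, bone_loss_fraction = 0.05, slice_offset = 0)
  fu_px <- sum(fu$slices[[1]]$bone & fu$slices[[1]]$mask)
  expect_lt(abs(fu_px - 0.95 * base_px) / base_px, 0.01)

  # increasing loss never increases ground-truth BVTV
  losses <- c(0, 0.03, 0.08, 0.15)
  bv <- sapply(losses, function(f) {
    fx <- generate_followup(bl, bone_loss_fraction = f, slice_offset = 0)
    mean(fx$slices[[1]]$bone[fx$slices[[1]]$mask])
  })
  expect_true(all(diff(bv) <= 0))
})

test_that("perturbations that leave the field of view are refused", {
  bl <- generate_stack(trabecular_params(seed = 8), n_slices = 8)
  expect_error(generate_followup(bl, shift = c(50, 0)), "field of view")
  expect_error(generate_followup(bl, slice_offset = 5L), "8")
})

test_that("cohort generation is reproducible and validates group sizes", {
  spec <- cohort_spec(n_diabetes = 5, n_control = 6, seed = 11)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$cohort, b$cohort)
  expect_identical(sort(unique(a$cohort$group)), c("control", "diabetes"))
  expect_identical(nrow(a$cohort), 2L * 11L)

  expect_error(generate_cohort(cohort_spec(n_diabetes = 2, n_control = 8,
                                           seed = 1)),
               "3 subjects per group")
})

test_that("planted group effects are recovered without bias under the null", {
  # null cohort: no group offsets; adjusted difference should be unbiased
  est <- sapply(500 + seq_len(200), function(seed) {
    spec <- cohort_spec(n_diabetes = 8, n_control = 8,
                        effect_pct_change = setNames(rep(0, 9),
                                                     trab_variables()),
                        ethnicity_shift = 0, seed = seed)
    ch <- cohort_changes(generate_cohort(spec))
    fit <- adjusted_group_comparison(ch, "pct_hole_size", "group")
    fit$difference
  })
  bias <- mean(est)
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(bias), 2 * se + 1e-12)
})

test_that("a degenerate ethnicity covariate is dropped with a warning", {
  spec <- cohort_spec(n_diabetes = 6, n_control = 6,
                      ethnicity_prob = c(diabetes = 1, control = 1),
                      seed = 13)
  ch <- cohort_changes(generate_cohort(spec))
  expect_warning(
    fit <- adjusted_group_comparison(ch, "pct_hole_size", "group",
                                     covariates = "ethnicity"),
    "constant")
  expect_length(fit$covariates, 0)
})
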