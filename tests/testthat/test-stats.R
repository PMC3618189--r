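test_that("descriptive t-test handles identical groups and printed summaries", {
  x <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  res <- descriptive_test(x, g)
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, 0)

  # printed-summary mode at the BMI scale: 34.6 (7.6) vs 27.9 (5.5), n 30/30
  sm <- descriptive_test_summary(34.6, 7.6, 30, 27.9, 5.5, 30)
  expect_lt(sm$p_value, 0.001)

  expect_error(descriptive_test(rep(1, 6), g), "constant")
})

test_that("descriptive t-test holds its nominal type-I error", {
  set.seed(81)
  n <- 1000
  rej <- logical(n)
  x <- rnorm(30)
  for (i in seq_len(n)) {
    g <- sample(rep(c("a", "b"), each = 15))
    rej[i] <- descriptive_test(x, g)$p_value < 0.05
  }
  mc_se <- sqrt(0.05 * 0.95 / n)
  expect_lt(mean(rej), 0.05 + 3 * mc_se)
  expect_gt(mean(rej), 0.05 - 3 * mc_se)
})

test_that("chi-square test runs on categorical tables", {
  g <- rep(c("a", "b"), each = 30)
  x <- c(rep("yes", 23), rep("no", 7), rep("yes", 30))
  res <- descriptive_test(x, g, type = "categorical")
  expect_lt(res$p_value, 0.05)
  expect_match(res$summaries[["a"]], "23")
})

test_that("covariate screening recovers planted correlations and degeneracy", {
  y <- rnorm(40)
  scr <- screen_covariate(y, y, name = "self")
  expect_equal(scr$correlation_r, 1, tolerance = 1e-12)
  expect_true(scr$included)

  set.seed(82)
  hits <- replicate(500, {
    screen_covariate(rnorm(35), rnorm(35), name = "x")$included
  })
  expect_gte(mean(!hits), 0.90)

  expect_warning(scr0 <- screen_covariate(rep(1, 20), rnorm(20), name = "flat"),
                 "zero variance")
  expect_false(scr0$included)

  # cohort built with an ethnicity-outcome association: the planted
  # correlation averages to about -0.36 (sampling tolerance +/- 0.15)
  r <- sapply(100 + seq_len(30), function(seed) {
    ch <- cohort_changes(generate_cohort(
      cohort_spec(n_diabetes = 14, n_control = 21, seed = seed)))
    suppressWarnings(screen_covariate(
      as.numeric(ch$ethnicity == "Caucasian"),
      ch$pct_hole_size, name = "ethnicity"))$correlation_r
  })
  r <- r[!is.na(r)]   # a rare all-Caucasian draw degenerates the covariate
  expect_gt(length(r), 20)
  expect_lt(abs(mean(r) - (-0.364)), 0.15)
  expect_lt(mean(r), 0)
})

test_that("with no covariates the adjusted comparison is the pooled t-test", {
  set.seed(84)
  d <- data.frame(y = rnorm(30), g = rep(c("a", "b"), each = 15))
  fit <- adjusted_group_comparison(d, "y", "g")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_lt(abs(fit$raw_p - tt$p.value), 1e-10)
  means <- tapply(d$y, d$g, mean)
  expect_lt(max(abs(fit$adjusted_means - means)), 1e-10)
})

test_that("a balanced covariate leaves the group difference unchanged", {
  set.seed(85)
  cov_half <- rnorm(15)
  d <- data.frame(y = rnorm(30) + rep(c(0, 1), each = 15),
                  g = rep(c("a", "b"), each = 15),
                  z = rep(cov_half, 2))     # identical distribution per group
  fit0 <- adjusted_group_comparison(d, "y", "g")
  fit1 <- adjusted_group_comparison(d, "y", "g", covariates = "z")
  expect_lt(abs(fit0$difference - fit1$difference), 1e-10)
})

test_that("planted group effects are recovered by the adjusted comparison", {
  delta <- 17.2   # planted diabetes-minus-control offset on hole count (%)
  est <- sapply(900 + seq_len(200), function(seed) {
    spec <- cohort_spec(n_diabetes = 14, n_control = 21,
                        effect_pct_change = c(hole_count = delta),
                        seed = seed)
    ch <- cohort_changes(generate_cohort(spec))
    fit <- suppressWarnings(adjusted_group_comparison(
      ch, "pct_hole_count", "group", covariates = "ethnicity"))
    # sign: difference is the coefficient of the second factor level
    # (diabetes) relative to control
    fit$difference
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - delta), 2 * se)
})

test_that("collinear covariates are refused by name", {
  d <- data.frame(y = rnorm(20), g = rep(c("a", "b"), each = 10),
                  z1 = 1:20)
  d$z2 <- 2 * d$z1
  expect_error(adjusted_group_comparison(d, "y", "g", c("z1", "z2")),
               "collinear")
})

test_that("Holm adjustment reproduces the printed nine-variable family", {
  p <- c(hole_size = 0.172, hole_count = 0.010, endosteal_area = 0.225,
         bvtv = 0.263, tbth = 0.661, tbsp = 0.206, tbn = 0.119,
         nodal_density = 0.221, branch_density = 0.566)
  adj <- holm_adjust(p, m = 9)
  expect_equal(unname(adj[["hole_count"]]), 0.090, tolerance = 1e-12)
  expect_equal(round(adj[["tbn"]], 3), 0.952)
  expect_true(all(adj[setdiff(names(p), c("hole_count", "tbn"))] >= 0.999))

  expect_equal(holm_adjust(0.031), 0.031)
  expect_error(holm_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("Holm matches the brute-force step-down definition", {
  set.seed(86)
  for (k in 1:50) {
    p <- runif(sample(2:12, 1))
    adj <- holm_adjust(p)
    expect_equal(unname(adj), oracle_holm(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("the Holm-corrected battery controls family-wise error", {
  fwe <- sapply(3000 + seq_len(1000), function(seed) {
    spec <- cohort_spec(n_diabetes = 14, n_control = 21,
                        effect_pct_change = setNames(rep(0, 9),
                                                     trab_variables()),
                        seed = seed)
    ch <- cohort_changes(generate_cohort(spec))
    cmp <- suppressWarnings(compare_groups(ch, covariates = "ethnicity"))
    any(cmp$holm_p < 0.05)
  })
  mc_se <- sqrt(mean(fwe) * (1 - mean(fwe)) / length(fwe))
  expect_lte(mean(fwe), 0.05 + 2 * max(mc_se, sqrt(0.05 * 0.95 / 1000)))
})
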