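#' Canonical microarchitecture variable names
#'
#' The nine apparent outcome variables, in their fixed reporting order:
#' mean hole size (mm^2), hole count (per slice), endosteal area (mm^2),
#' bone volume fraction BVTV (%), trabecular thickness Tb.Th (mm), trabecular
#' separation Tb.Sp (mm), trabecular number Tb.N (/mm), nodal density (/mm^2)
#' and branch density (/mm^2).
#'
#' @return Character vector of length nine.
#' @export
trab_variables <- function() {
  c("hole_size", "hole_count", "endosteal_area", "bvtv",
    "tbth", "tbsp", "tbn", "nodal_density", "branch_density")
}

# Study-scale distributional defaults for the synthetic cohort generator
# (baseline means/SDs on the distal-radius 1 T MRI scale; per-visit percent
# change means/SDs for the control condition; diabetes-minus-control offsets).
.study_scale <- function() {
  v <- trab_variables()
  list(
    baseline_mean = setNames(
      c(2.08, 70, 268, 47.7, 0.515, 0.545, 0.925, 0.16, 0.41), v),
    baseline_sd = setNames(
      c(0.44, 16, 55, 1.1, 0.01, 0.015, 0.03, 0.01, 0.055), v),
    change_pct_mean = setNames(
      c(5.0, -7.1, -4.5, 0.1, -0.3, -0.2, 0.3, -3.8, 3.3), v),
    change_pct_sd = setNames(
      c(17.9, 20.2, 16.0, 1.8, 1.8, 1.4, 1.8, 6.4, 13.3), v),
    effect_pct = setNames(
      c(-9.1, 17.2, 7.3, 0.6, -0.3, -0.8, 1.0, 3.0, -2.8), v)
  )
}

#' Parameters for one synthetic trabecular slice
#'
#' Defines the target microarchitecture of a synthetic axial slice of the
#' distal radius: a Voronoi-edge trabecular lattice inside an endosteal disc
#' surrounded by a cortical rim, imaged as a two-class scene (bone dark,
#' marrow bright) degraded by a Gaussian point-spread function and additive
#' Gaussian noise.
#'
#' @param target_bvtv Target bone volume fraction inside the endosteal disc,
#'   as a fraction in (0.2, 0.8). Default 0.477.
#' @param target_tbth Nominal trabecular strut thickness in mm; must exceed
#'   the in-plane voxel size. Used for feasibility checking (the realized
#'   thickness is set by `target_bvtv` and `hole_count_target`).
#' @param hole_count_target Number of marrow cells (holes) per slice.
#' @param endosteal_radius Radius of the endosteal disc in mm.
#' @param cortical_thickness Thickness of the cortical rim in mm.
#' @param voxel_inplane In-plane voxel size in mm (default 0.195, the 1 T
#'   protocol scale).
#' @param voxel_thickness Slice thickness in mm (default 1.0).
#' @param noise_sd Additive Gaussian noise SD in grey-level units (the scene
#'   spans roughly 0.25--0.80).
#' @param psf_fwhm Full width at half maximum of the Gaussian PSF in mm.
#' @param seed Integer seed; the generator is bit-reproducible given the seed.
#' @return An object of class `trabecular_params`.
#' @export
trabecular_params <- function(target_bvtv = 0.477,
                              target_tbth = 0.52,
                              hole_count_target = 68L,
                              endosteal_radius = 9.2,
                              cortical_thickness = 1.0,
                              voxel_inplane = 0.195,
                              voxel_thickness = 1.0,
                              noise_sd = 0.06,
                              psf_fwhm = 0.35,
                              seed = 1L) {
  stopifnot(.is_num1(target_bvtv), .is_num1(target_tbth),
            .is_count(hole_count_target), hole_count_target > 0,
            .is_num1(endosteal_radius), endosteal_radius > 0,
            .is_num1(cortical_thickness), cortical_thickness > 0,
            .is_num1(voxel_inplane), voxel_inplane > 0,
            .is_num1(voxel_thickness), voxel_thickness > 0,
            .is_num1(noise_sd), noise_sd >= 0,
            .is_num1(psf_fwhm), psf_fwhm >= 0,
            .is_count(seed))
  if (target_bvtv <= 0.2 || target_bvtv >= 0.8)
    stop("target_bvtv must lie in (0.2, 0.8), got ", target_bvtv)
  if (target_tbth <= voxel_inplane)
    stop("target_tbth (", target_tbth,
         " mm) must exceed the in-plane voxel size (", voxel_inplane, " mm)")
  # feasibility: each marrow cell must be resolvable, and the implied strut
  # width must span at least one voxel -- otherwise the lattice degenerates.
  area <- pi * endosteal_radius^2
  mean_hole_mm2 <- (1 - target_bvtv) * area / hole_count_target
  if (mean_hole_mm2 < 9 * voxel_inplane^2)
    stop("infeasible parameters: hole_count_target ", hole_count_target,
         " at target_bvtv ", target_bvtv, " implies mean hole area ",
         signif(mean_hole_mm2, 3), " mm^2, below the resolvable minimum of ",
         signif(9 * voxel_inplane^2, 3), " mm^2")
  cell <- sqrt(area / hole_count_target)
  strut <- target_bvtv * area / (2 * sqrt(hole_count_target * area))
  if (strut < voxel_inplane)
    stop("infeasible parameters: implied strut width ", signif(strut, 3),
         " mm is below one voxel (", voxel_inplane, " mm)")
  out <- list(target_bvtv = target_bvtv, target_tbth = target_tbth,
              hole_count_target = as.integer(hole_count_target),
              endosteal_radius = endosteal_radius,
              cortical_thickness = cortical_thickness,
              voxel_inplane = voxel_inplane,
              voxel_thickness = voxel_thickness,
              noise_sd = noise_sd, psf_fwhm = psf_fwhm,
              seed = as.integer(seed), cell_pitch = cell)
  class(out) <- "trabecular_params"
  out
}

#' @export
print.trabecular_params <- function(x, ...) {
  cat("Synthetic trabecular slice parameters\n")
  cat(sprintf("  target BVTV       : %.1f %%\n", 100 * x$target_bvtv))
  cat(sprintf("  holes per slice   : %d\n", x$hole_count_target))
  cat(sprintf("  endosteal radius  : %.2f mm (area %.1f mm^2)\n",
              x$endosteal_radius, pi * x$endosteal_radius^2))
  cat(sprintf("  voxel             : %.3f x %.3f x %.3f mm\n",
              x$voxel_inplane, x$voxel_inplane, x$voxel_thickness))
  cat(sprintf("  PSF FWHM / noise  : %.2f mm / %.3f\n", x$psf_fwhm, x$noise_sd))
  cat(sprintf("  seed              : %d\n", x$seed))
  invisible(x)
}

#' Specification of a synthetic two-group longitudinal cohort
#'
#' Describes a two-group (diabetes vs control) cohort with a baseline and one
#' follow-up visit about two years later. Group differences in percent change
#' are planted per variable through `effect_pct_change`; ethnicity (Caucasian
#' indicator) is assigned per group and may shift the primary outcome so that
#' the covariate-outcome correlation of the emulated study is reproduced.
#'
#' @param n_diabetes,n_control Group sizes (each at least 2; the inference
#'   stage additionally requires at least 3 per group).
#' @param effect_pct_change Named numeric vector of diabetes-minus-control
#'   offsets on the percent-change scale, names among [trab_variables()].
#'   Defaults to the study-scale offsets.
#' @param ethnicity_prob Length-2 named vector, probability of Caucasian
#'   ethnicity per group (`diabetes`, `control`).
#' @param ethnicity_shift Additive shift (percent-change units) on the
#'   primary outcome (`hole_size`) for Caucasian subjects. The default -34
#'   is calibrated (by simulation, accounting for the variance the shift
#'   itself adds and for partial cancellation through the group offset) so
#'   the covariate-outcome correlation averages about -0.36 at n = 35.
#' @param followup_months_mean,followup_months_sd Follow-up interval in
#'   months (default 25.4 and 1.9).
#' @param seed Integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_diabetes = 14L, n_control = 21L,
                        effect_pct_change = NULL,
                        ethnicity_prob = c(diabetes = 0.80, control = 1.00),
                        ethnicity_shift = -34,
                        followup_months_mean = 25.4,
                        followup_months_sd = 1.9,
                        seed = 1L) {
  stopifnot(.is_count(n_diabetes), .is_count(n_control), .is_count(seed),
            .is_num1(ethnicity_shift),
            .is_num1(followup_months_mean), followup_months_mean > 0,
            .is_num1(followup_months_sd), followup_months_sd >= 0)
  if (n_diabetes < 2 || n_control < 2)
    stop("group sizes must be at least 2")
  if (any(ethnicity_prob < 0) || any(ethnicity_prob > 1))
    stop("ethnicity_prob entries must lie in [0, 1]")
  ethnicity_prob <- ethnicity_prob[c("diabetes", "control")]
  if (anyNA(ethnicity_prob))
    stop("ethnicity_prob must be named with 'diabetes' and 'control'")
  eff <- setNames(rep(0, 9), trab_variables())
  if (is.null(effect_pct_change)) {
    eff <- .study_scale()$effect_pct
  } else {
    stopifnot(is.numeric(effect_pct_change))
    bad <- setdiff(names(effect_pct_change), trab_variables())
    if (length(bad)) stop("unknown variables in effect_pct_change: ",
                          paste(bad, collapse = ", "))
    eff[names(effect_pct_change)] <- effect_pct_change
  }
  out <- list(n_diabetes = as.integer(n_diabetes),
              n_control = as.integer(n_control),
              effect_pct_change = eff,
              ethnicity_prob = ethnicity_prob,
              ethnicity_shift = ethnicity_shift,
              followup_months_mean = followup_months_mean,
              followup_months_sd = followup_months_sd,
              seed = as.integer(seed))
  class(out) <- "cohort_spec"
  out
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  n: %d diabetes / %d control; seed %d\n",
              x$n_diabetes, x$n_control, x$seed))
  cat(sprintf("  follow-up interval: %.1f (%.1f) months\n",
              x$followup_months_mean, x$followup_months_sd))
  cat(sprintf("  P(Caucasian): %.2f / %.2f; ethnicity shift %.1f%% on hole_size\n",
              x$ethnicity_prob[["diabetes"]], x$ethnicity_prob[["control"]],
              x$ethnicity_shift))
  nz <- x$effect_pct_change[x$effect_pct_change != 0]
  if (length(nz)) {
    cat("  planted group offsets (%):\n")
    for (v in names(nz)) cat(sprintf("    %-15s %+.1f\n", v, nz[[v]]))
  } else cat("  no planted group offsets (global null)\n")
  invisible(x)
}
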