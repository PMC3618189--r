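# Synthetic trabecular slice/stack/cohort generator.
#
# A slice is a Voronoi-edge lattice: marrow cells are Voronoi cells of a
# jittered point process inside the endosteal disc, trabeculae are the cell
# boundaries drawn with a calibrated width, and a cortical rim surrounds the
# disc. This gives independent control of hole count (number of seed points),
# BVTV (boundary-band width, calibrated exactly by order statistics of the
# distance-difference field) and, implicitly, strut thickness.

.slice_geometry <- function(params) {
  half_fov <- params$endosteal_radius + params$cortical_thickness + 0.6
  n <- 2L * as.integer(ceiling(half_fov / params$voxel_inplane))
  ctr <- (n + 1) / 2
  ax <- (seq_len(n) - ctr) * params$voxel_inplane
  rr <- sqrt(outer(ax^2, ax^2, "+"))
  list(n = n, ax = ax, rr = rr)
}

.voronoi_seeds <- function(params) {
  R <- params$endosteal_radius
  s <- params$cell_pitch
  N <- params$hole_count_target
  xs <- seq(-R, R, by = s)
  ys <- seq(-R, R, by = s * sqrt(3) / 2)
  pts <- do.call(rbind, lapply(seq_along(ys), function(j) {
    off <- if (j %% 2 == 0) s / 2 else 0
    cbind(xs + off, ys[j])
  }))
  pts <- pts + matrix(runif(2 * nrow(pts), -0.25 * s, 0.25 * s), ncol = 2)
  keep <- sqrt(rowSums(pts^2)) <= R - 0.40 * s
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) > N) {
    pts <- pts[sort(sample.int(nrow(pts), N)), , drop = FALSE]
  } else while (nrow(pts) < N) {
    cand <- matrix(runif(2, -R + 0.4 * s, R - 0.4 * s), ncol = 2)
    if (sqrt(sum(cand^2)) > R - 0.40 * s) next
    if (min(sqrt(rowSums((pts - matrix(cand, nrow(pts), 2, byrow = TRUE))^2))) >
        0.5 * s) pts <- rbind(pts, cand)
  }
  pts
}

.render_grey <- function(bone_full, in_fov, params) {
  g <- matrix(0.25, nrow(bone_full), ncol(bone_full))
  g[in_fov & !bone_full] <- 0.80
  if (params$psf_fwhm > 0) {
    sigma_px <- params$psf_fwhm / (2 * sqrt(2 * log(2))) / params$voxel_inplane
    g <- matrix(as.numeric(EBImage::imageData(
      EBImage::gblur(g, sigma = sigma_px))), nrow(g), ncol(g))
  }
  if (params$noise_sd > 0)
    g <- g + matrix(rnorm(length(g), 0, params$noise_sd), nrow(g), ncol(g))
  g
}

.holes_from_truth <- function(marrow_in_mask, voxel_inplane) {
  lab <- .label_components(marrow_in_mask, connectivity = 4)
  n <- max(lab)
  areas_px <- if (n > 0) tabulate(lab[lab > 0L], nbins = n) else integer(0)
  list(labels = lab, count = n, areas_px = areas_px,
       areas_mm2 = areas_px * voxel_inplane^2,
       mean_area_mm2 = if (n > 0) mean(areas_px) * voxel_inplane^2 else NA_real_)
}

#' Generate one synthetic trabecular slice with ground truth
#'
#' Draws a Voronoi-edge trabecular lattice inside an endosteal disc with a
#' cortical rim, then renders a grey-level image (bone dark at 0.25, marrow
#' bright at 0.80) degraded by the Gaussian PSF and additive noise given in
#' `params`. The trabecular band width is calibrated so the ground-truth bone
#' fraction inside the disc matches `target_bvtv` to within one pixel's worth.
#'
#' @param params A [trabecular_params()] object.
#' @param slice_seed Optional integer overriding `params$seed` (used by
#'   [generate_stack()] to decorrelate slices).
#' @return A list of class `trab_slice` with elements `grey` (matrix),
#'   `bone` (logical ground-truth bone map, trabeculae plus cortex), `mask`
#'   (logical endosteal disc), `holes` (ground-truth hole set: labels, count,
#'   exact pixel areas), `band_width` (calibrated lattice band width, mm) and
#'   `params`.
#' @export
generate_slice <- function(params, slice_seed = NULL) {
  stopifnot(inherits(params, "trabecular_params"))
  seed <- if (is.null(slice_seed)) params$seed else as.integer(slice_seed)
  .with_seed(seed, {
    geo <- .slice_geometry(params)
    n <- geo$n; rr <- geo$rr
    R <- params$endosteal_radius
    mask <- rr <= R
    cortex <- rr > R & rr <= R + params$cortical_thickness
    in_fov <- rr <= R + params$cortical_thickness

    pts <- .voronoi_seeds(params)
    idx <- which(mask)
    px <- geo$ax[(idx - 1L) %% n + 1L]
    py <- geo$ax[(idx - 1L) %/% n + 1L]
    # two smallest seed distances per in-disc pixel
    d1 <- rep(Inf, length(idx)); d2 <- rep(Inf, length(idx))
    for (k in seq_len(nrow(pts))) {
      dk <- sqrt((px - pts[k, 1])^2 + (py - pts[k, 2])^2)
      closer <- dk < d1
      d2[closer] <- d1[closer]; d1[closer] <- dk[closer]
      mid <- !closer & dk < d2
      d2[mid] <- dk[mid]
    }
    v <- d2 - d1
    k_bone <- round(params$target_bvtv * length(idx))
    t_band <- sort(v, partial = k_bone)[k_bone]
    bone_trab <- v <= t_band

    bone_full <- cortex
    bone_full[idx[bone_trab]] <- TRUE

    achieved <- sum(bone_trab) / length(idx)
    if (abs(achieved - params$target_bvtv) > 0.03)
      stop("infeasible parameter combination: achieved bone fraction ",
           signif(achieved, 3), " misses target ", params$target_bvtv)

    marrow_in_mask <- mask & !bone_full
    holes <- .holes_from_truth(marrow_in_mask, params$voxel_inplane)
    if (abs(holes$count - params$hole_count_target) >
        max(3, 0.15 * params$hole_count_target))
      stop("infeasible parameter combination: lattice produced ",
           holes$count, " holes against a target of ",
           params$hole_count_target)

    grey <- .render_grey(bone_full, in_fov, params)
    structure(list(grey = grey, bone = bone_full, mask = mask,
                   holes = holes, band_width = t_band, seeds = pts,
                   params = params, seed = seed),
              class = "trab_slice")
  })
}

#' Generate a synthetic axial stack
#'
#' Slices are generated independently (slice thickness is several times the
#' in-plane voxel, so through-plane texture correlation is not modeled). An
#' optional densified band at the distal end of the stack stands in for the
#' growth-plate region and is recorded in the ground truth so automatic
#' distal-reference detection can be validated.
#'
#' @param params A [trabecular_params()] object.
#' @param n_slices Number of slices (at least 8).
#' @param growth_plate_slices Number of leading dense (growth-plate band)
#'   slices, 0 for none.
#' @param subject_id,visit Labels carried into the [image_stack()].
#' @return A list of class `trab_stack`: `slices` (list of `trab_slice`),
#'   `image` (an [image_stack()]), `growth_plate_slices`, `reference_slice`
#'   (first slice past the band), `params`.
#' @export
generate_stack <- function(params, n_slices = 10L, growth_plate_slices = 0L,
                           subject_id = "S01", visit = "baseline") {
  stopifnot(inherits(params, "trabecular_params"),
            .is_count(n_slices), .is_count(growth_plate_slices),
            growth_plate_slices >= 0)
  if (n_slices < 8) stop("a stack needs at least 8 slices, got ", n_slices)
  if (growth_plate_slices > n_slices - 8)
    stop("growth-plate band leaves fewer than 8 analyzable slices")
  dense <- if (growth_plate_slices > 0)
    trabecular_params(target_bvtv = 0.75,
                      target_tbth = params$target_tbth,
                      hole_count_target = params$hole_count_target,
                      endosteal_radius = params$endosteal_radius,
                      cortical_thickness = params$cortical_thickness,
                      voxel_inplane = params$voxel_inplane,
                      voxel_thickness = params$voxel_thickness,
                      noise_sd = params$noise_sd, psf_fwhm = params$psf_fwhm,
                      seed = params$seed)
  slices <- vector("list", n_slices)
  for (i in seq_len(n_slices)) {
    p_i <- if (i <= growth_plate_slices) dense else params
    slices[[i]] <- generate_slice(p_i, slice_seed = params$seed + 7919L * i)
  }
  img <- image_stack(lapply(slices, `[[`, "grey"),
                     voxel_inplane = params$voxel_inplane,
                     voxel_thickness = params$voxel_thickness,
                     subject_id = subject_id, visit = visit)
  structure(list(slices = slices, image = img,
                 growth_plate_slices = as.integer(growth_plate_slices),
                 reference_slice = as.integer(growth_plate_slices + 1L),
                 params = params, seed = params$seed),
            class = "trab_stack")
}

#' @export
print.trab_stack <- function(x, ...) {
  cat(sprintf("Synthetic trabecular stack: %d slices, %s/%s\n",
              length(x$slices), x$image$subject_id, x$image$visit))
  cat(sprintf("  image %d x %d px, voxel %.3f mm; seed %d\n",
              nrow(x$slices[[1]]$grey), ncol(x$slices[[1]]$grey),
              x$params$voxel_inplane, x$seed))
  if (x$growth_plate_slices > 0)
    cat(sprintf("  growth-plate band: slices 1..%d (reference slice %d)\n",
                x$growth_plate_slices, x$reference_slice))
  invisible(x)
}

# Rigid transform of a slice: rotate about image center, then translate by
# `shift` = c(row, col) pixels. `filter` "bilinear" for grey, "none" for masks.
.rigid_transform <- function(m, shift = c(0, 0), rotation = 0,
                             filter = "bilinear", bg = 0) {
  out <- m
  if (rotation != 0) {
    img <- EBImage::rotate(out, angle = rotation, filter = filter,
                           output.dim = dim(m), bg.col = bg)
    out <- matrix(as.numeric(EBImage::imageData(img)), nrow(m), ncol(m))
  }
  if (any(shift != 0)) {
    img <- EBImage::translate(out, v = shift, filter = filter, bg.col = bg)
    out <- matrix(as.numeric(EBImage::imageData(img)), nrow(m), ncol(m))
  }
  out
}

#' Derive a follow-up stack from a baseline by controlled perturbation
#'
#' Bone loss is applied as surface thinning: the stated fraction of
#' trabecular bone pixels is removed in order of increasing distance to the
#' marrow boundary (ties broken reproducibly). The perturbed scene is then
#' re-rendered with fresh noise and rigidly transformed (rotation about the
#' image center, then translation); a positive `slice_offset` drops the most
#' distal baseline slices so that follow-up slice i corresponds to baseline
#' slice i + offset. All perturbation parameters are recorded as ground truth.
#'
#' @param baseline A `trab_stack` from [generate_stack()].
#' @param bone_loss_fraction Fraction of trabecular bone pixels removed,
#'   in \[0, 1).
#' @param shift Length-2 numeric, in-plane shift in voxels (row, col).
#' @param rotation In-plane rotation in degrees.
#' @param slice_offset Non-negative integer through-plane offset.
#' @param seed Integer seed for thinning tie-breaks and rendering noise.
#' @return A `trab_stack` with a `transform` element recording the planted
#'   perturbation.
#' @export
generate_followup <- function(baseline, bone_loss_fraction = 0.03,
                              shift = c(0, 0), rotation = 0,
                              slice_offset = 0L, seed = baseline$seed + 1L) {
  stopifnot(inherits(baseline, "trab_stack"),
            .is_num1(bone_loss_fraction),
            is.numeric(shift), length(shift) == 2,
            .is_num1(rotation), .is_count(slice_offset), .is_count(seed))
  if (bone_loss_fraction < 0 || bone_loss_fraction >= 1)
    stop("bone_loss_fraction must lie in [0, 1)")
  if (slice_offset < 0)
    stop("slice_offset must be non-negative; swap the roles of the stacks ",
         "to probe negative offsets")
  params <- baseline$params
  geo_n <- nrow(baseline$slices[[1]]$grey)
  margin_px <- (geo_n * params$voxel_inplane / 2 -
    (params$endosteal_radius + params$cortical_thickness)) / params$voxel_inplane
  if (max(abs(shift)) > margin_px)
    stop("perturbation pushes structure outside the field of view ",
         "(|shift| > ", signif(margin_px, 3), " voxels)")
  if (abs(rotation) > 45)
    stop("rotation beyond +/-45 degrees is outside the rigid-misalignment model")
  n <- length(baseline$slices)
  m <- n - slice_offset
  if (m < 8)
    stop("slice_offset ", slice_offset, " leaves only ", m,
         " slices; at least 8 required")
  out_slices <- vector("list", m)
  for (i in seq_len(m)) {
    src <- baseline$slices[[i + slice_offset]]
    .with_seed(seed + 7919L * i, {
      bone_full <- src$bone
      trab <- bone_full & src$mask
      if (bone_loss_fraction > 0 && any(trab)) {
        d <- .distmap(bone_full)
        cand <- which(trab)
        k <- round(bone_loss_fraction * length(cand))
        if (k > 0) {
          ord <- order(d[cand] + runif(length(cand), 0, 1e-3))
          bone_full[cand[ord[seq_len(k)]]] <- FALSE
        }
      }
      in_fov <- .slice_geometry(params)$rr <=
        params$endosteal_radius + params$cortical_thickness
      grey <- .render_grey(bone_full, in_fov, params)
      grey_t <- .rigid_transform(grey, shift, rotation,
                                 filter = "bilinear", bg = 0.25)
      bone_t <- .rigid_transform(bone_full * 1, shift, rotation,
                                 filter = "none", bg = 0) > 0.5
      mask_t <- .rigid_transform(src$mask * 1, shift, rotation,
                                 filter = "none", bg = 0) > 0.5
      holes <- .holes_from_truth(mask_t & !bone_t, params$voxel_inplane)
      out_slices[[i]] <- structure(
        list(grey = grey_t, bone = bone_t, mask = mask_t, holes = holes,
             band_width = src$band_width, seeds = src$seeds,
             params = params, seed = seed + 7919L * i,
             bone_unshifted = bone_full, mask_unshifted = src$mask),
        class = "trab_slice")
    })
  }
  img <- image_stack(lapply(out_slices, `[[`, "grey"),
                     voxel_inplane = params$voxel_inplane,
                     voxel_thickness = params$voxel_thickness,
                     subject_id = baseline$image$subject_id,
                     visit = "followup")
  structure(list(slices = out_slices, image = img,
                 growth_plate_slices = max(0L, baseline$growth_plate_slices -
                                             as.integer(slice_offset)),
                 reference_slice = max(1L, baseline$reference_slice -
                                         as.integer(slice_offset)),
                 params = params, seed = as.integer(seed),
                 transform = list(slice_offset = as.integer(slice_offset),
                                  shift = shift, rotation = rotation,
                                  bone_loss_fraction = bone_loss_fraction)),
            class = "trab_stack")
}

#' Generate a synthetic two-group longitudinal cohort
#'
#' In `render = "values"` mode, per-subject baseline profiles and per-variable
#' percent changes are drawn from the study-scale distributions (group offsets
#' from `spec$effect_pct_change`; an ethnicity shift on the primary outcome
#' plants the covariate-outcome correlation); this mode backs the Monte-Carlo
#' statistical validation. In `render = "stacks"` mode, full baseline and
#' follow-up image stacks are generated per subject with subject-level
#' parameter jitter and group-dependent bone loss, for validating the imaging
#' chain end to end.
#'
#' @param spec A [cohort_spec()].
#' @param render `"values"` or `"stacks"`.
#' @param params Base [trabecular_params()] for `"stacks"` mode.
#' @param n_slices Slices per stack in `"stacks"` mode.
#' @param bone_loss_mean Named length-2 vector (`diabetes`, `control`): mean
#'   trabecular bone-loss fraction at follow-up in `"stacks"` mode.
#' @return A list of class `trab_cohort` with elements `cohort` (long-format
#'   data frame: subject_id, group, ethnicity, visit, months_since_baseline,
#'   and in values mode the nine variable columns), `truth` (planted effects
#'   and per-subject ground truth), `spec`, `render`, and in stacks mode
#'   `stacks` (per subject: `baseline`, `followup`).
#' @export
generate_cohort <- function(spec, render = c("values", "stacks"),
                            params = trabecular_params(seed = spec$seed),
                            n_slices = 10L,
                            bone_loss_mean = c(diabetes = 0.04, control = 0.02)) {
  stopifnot(inherits(spec, "cohort_spec"))
  render <- match.arg(render)
  if (spec$n_diabetes < 3 || spec$n_control < 3)
    stop("fewer than 3 subjects per group: the covariate-adjusted ",
         "regression stage is not estimable")
  vars <- trab_variables()
  sc <- .study_scale()
  .with_seed(spec$seed, {
    grp <- c(rep("diabetes", spec$n_diabetes), rep("control", spec$n_control))
    ids <- c(sprintf("D%02d", seq_len(spec$n_diabetes)),
             sprintf("C%02d", seq_len(spec$n_control)))
    eth <- rbinom(length(grp), 1L, spec$ethnicity_prob[grp])
    months <- rnorm(length(grp), spec$followup_months_mean,
                    spec$followup_months_sd)

    base <- sapply(vars, function(v)
      rnorm(length(grp), sc$baseline_mean[[v]], sc$baseline_sd[[v]]))
    base[, "hole_count"] <- round(base[, "hole_count"])
    pct <- sapply(vars, function(v)
      rnorm(length(grp),
            sc$change_pct_mean[[v]] +
              (grp == "diabetes") * spec$effect_pct_change[[v]],
            sc$change_pct_sd[[v]]))
    pct[, "hole_size"] <- pct[, "hole_size"] + spec$ethnicity_shift * eth
    fup <- base * (1 + pct / 100)
    fup[, "hole_count"] <- round(fup[, "hole_count"])

    mk <- function(visit, vals, mo) {
      data.frame(subject_id = ids, group = grp,
                 ethnicity = ifelse(eth == 1L, "Caucasian", "Other"),
                 visit = visit, months_since_baseline = mo,
                 as.data.frame(vals), check.names = FALSE)
    }
    cohort <- rbind(mk("baseline", base, 0), mk("followup", fup, months))
    cohort <- cohort[order(cohort$subject_id, cohort$visit), ]
    rownames(cohort) <- NULL

    truth <- list(effect_pct_change = spec$effect_pct_change,
                  ethnicity_shift = spec$ethnicity_shift,
                  pct_change = data.frame(subject_id = ids, group = grp,
                                          ethnicity = eth, pct,
                                          check.names = FALSE))
    stacks <- NULL
    if (render == "stacks") {
      if (!all(c("diabetes", "control") %in% names(bone_loss_mean)))
        stop("bone_loss_mean must be named with 'diabetes' and 'control'")
      stacks <- vector("list", length(ids))
      names(stacks) <- ids
      subj_seed <- spec$seed + 104729L * seq_along(ids)
      bvtv_i <- rnorm(length(ids), params$target_bvtv, 0.01)
      holes_i <- round(rnorm(length(ids), params$hole_count_target, 6))
      rad_i <- rnorm(length(ids), params$endosteal_radius, 0.7)
      loss_i <- pmin(0.25, pmax(0, rnorm(length(ids),
                                         bone_loss_mean[grp], 0.01)))
      shift_i <- matrix(runif(2 * length(ids), -3, 3), ncol = 2)
      rot_i <- runif(length(ids), -1.5, 1.5)
      max_off <- min(2L, n_slices - 8L)
      off_i <- sample(0:max_off, length(ids), replace = TRUE)
      for (j in seq_along(ids)) {
        p_j <- trabecular_params(
          target_bvtv = min(0.79, max(0.21, bvtv_i[j])),
          target_tbth = params$target_tbth,
          hole_count_target = max(20L, holes_i[j]),
          endosteal_radius = max(5, rad_i[j]),
          cortical_thickness = params$cortical_thickness,
          voxel_inplane = params$voxel_inplane,
          voxel_thickness = params$voxel_thickness,
          noise_sd = params$noise_sd, psf_fwhm = params$psf_fwhm,
          seed = subj_seed[j])
        bl <- generate_stack(p_j, n_slices = n_slices,
                             subject_id = ids[j], visit = "baseline")
        fu <- generate_followup(bl, bone_loss_fraction = loss_i[j],
                                shift = round(shift_i[j, ]),
                                rotation = rot_i[j],
                                slice_offset = off_i[j],
                                seed = subj_seed[j] + 1L)
        stacks[[j]] <- list(baseline = bl, followup = fu)
      }
      truth$bone_loss <- setNames(loss_i, ids)
      truth$transforms <- data.frame(subject_id = ids,
                                     shift_row = round(shift_i[, 1]),
                                     shift_col = round(shift_i[, 2]),
                                     rotation = rot_i,
                                     slice_offset = off_i)
    }
    structure(list(cohort = cohort, truth = truth, spec = spec,
                   render = render, stacks = stacks),
              class = "trab_cohort")
  })
}

#' @export
print.trab_cohort <- function(x, ...) {
  n <- table(x$cohort$group[x$cohort$visit == "baseline"])
  cat(sprintf("Synthetic cohort (%s mode): %d diabetes / %d control\n",
              x$render, n[["diabetes"]], n[["control"]]))
  cat(sprintf("  seed %d; %d rows (two visits per subject)\n",
              x$spec$seed, nrow(x$cohort)))
  invisible(x)
}
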