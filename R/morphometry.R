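# Apparent structural metrics. All metrics are 2D per slice and averaged over
# the 8-slice analysis volume: with ~5x anisotropic voxels (0.195 mm in-plane
# vs 1 mm through-plane) 3D spheres would be dominated by slice thickness, so
# "maximal spheres" becomes maximal inscribed discs in-plane.

#' Bone volume fraction (BVTV, %)
#'
#' 100 x bone pixels / endosteal mask pixels.
#'
#' @param binary A [binarize()] result (or logical bone matrix with `mask`).
#' @param mask Optional logical mask when `binary` is a plain matrix.
#' @return Percent in \[0, 100\].
#' @export
compute_bvtv <- function(binary, mask = NULL) {
  if (inherits(binary, "trab_binary")) {
    mask <- binary$mask
    bone <- binary$bone
  } else {
    stopifnot(is.logical(binary), is.logical(mask))
    bone <- binary & mask
  }
  if (!any(mask)) stop("empty endosteal mask")
  100 * sum(bone) / sum(mask)
}

# Local thickness map by maximal inscribed discs. For every phase pixel q the
# inscribed radius is r(q) = EDT(q) - 0.5 (center-to-center distance to the
# nearest background pixel, less half a pixel to the inter-pixel boundary).
# The thickness at pixel p is the diameter of the largest disc that contains
# p and fits in the phase: discs are painted in decreasing radius order, each
# covering the pixels within r(q) - 0.5 of its center.
.local_thickness <- function(phase) {
  stopifnot(is.matrix(phase), is.logical(phase))
  nr <- nrow(phase); nc <- ncol(phase)
  th <- matrix(0, nr, nc)
  if (!any(phase)) return(th)
  d <- .distmap(phase)
  idx <- which(phase)
  r <- d[idx] - 0.5
  ord <- order(r, decreasing = TRUE)
  for (j in ord) {
    i <- idx[j]
    ri <- r[j]
    diam <- 2 * ri
    pr <- (i - 1L) %% nr + 1L
    pc <- (i - 1L) %/% nr + 1L
    reach <- ri - 0.5
    if (reach < 1) {
      if (th[i] == 0) th[i] <- diam
      next
    }
    w <- floor(reach)
    rows <- max(1L, pr - w):min(nr, pr + w)
    cols <- max(1L, pc - w):min(nc, pc + w)
    dr <- rows - pr; dc <- cols - pc
    inside <- outer(dr^2, dc^2, "+") <= reach^2
    cells <- as.vector(outer(rows, (cols - 1L) * nr, "+"))[as.vector(inside)]
    cells <- cells[th[cells] == 0]
    if (length(cells)) th[cells] <- diam
  }
  th
}

#' Apparent trabecular thickness (Tb.Th, mm)
#'
#' Model-independent maximal-inscribed-disc estimate on the bone phase: the
#' mean, over bone pixels, of the diameter of the largest disc containing the
#' pixel and fitting in the bone phase.
#'
#' @param binary A [binarize()] result.
#' @param voxel_inplane In-plane voxel size in mm.
#' @return Thickness in mm.
#' @export
compute_tbth <- function(binary, voxel_inplane = binary$voxel_inplane) {
  stopifnot(inherits(binary, "trab_binary"))
  if (is.null(voxel_inplane)) stop("voxel_inplane is required")
  bone <- binary$bone
  if (!any(bone)) stop("bone phase is empty: Tb.Th undefined")
  if (all(bone)) stop("image is single-phase bone: no reference background")
  th <- .local_thickness(bone)
  mean(th[bone]) * voxel_inplane
}

#' Apparent trabecular separation (Tb.Sp, mm)
#'
#' The same maximal-disc estimator applied to the marrow phase inside the
#' endosteal mask: marrow spaces are filled with maximal discs and Tb.Sp is
#' the mean diameter over marrow pixels.
#'
#' @inheritParams compute_tbth
#' @return Separation in mm.
#' @export
compute_tbsp <- function(binary, voxel_inplane = binary$voxel_inplane) {
  stopifnot(inherits(binary, "trab_binary"))
  if (is.null(voxel_inplane)) stop("voxel_inplane is required")
  marrow <- binary$mask & !binary$bone
  if (!any(marrow)) stop("marrow phase is empty: Tb.Sp undefined")
  th <- .local_thickness(marrow)
  mean(th[marrow]) * voxel_inplane
}

#' Trabecular number (Tb.N, /mm)
#'
#' Standard histomorphometric derivation Tb.N = BVTV / Tb.Th, with BVTV
#' supplied in percent.
#'
#' @param bvtv Bone volume fraction in percent.
#' @param tbth Trabecular thickness in mm, strictly positive.
#' @return Trabecular number in /mm.
#' @export
compute_tbn <- function(bvtv, tbth) {
  stopifnot(.is_num1(bvtv), .is_num1(tbth))
  if (bvtv < 0 || bvtv > 100) stop("bvtv must be a percent in [0, 100]")
  if (tbth <= 0) stop("tbth must be positive, got ", tbth)
  (bvtv / 100) / tbth
}

#' Measure one slice
#'
#' Runs the full per-slice chain: endosteal segmentation (unless a mask is
#' supplied), within-mask binarization, hole growing, BVTV, Tb.Th, Tb.Sp,
#' skeletonization and network densities.
#'
#' @param slice Grey-level matrix.
#' @param voxel_inplane Voxel size in mm.
#' @param mask Optional precomputed [segment_endosteal()] result.
#' @param invert Contrast flag passed to [binarize()].
#' @return One-row data frame of slice-level metrics plus QC columns
#'   (`threshold`).
#' @export
measure_slice <- function(slice, voxel_inplane, mask = NULL, invert = FALSE) {
  if (is.null(mask)) mask <- segment_endosteal(slice, voxel_inplane,
                                               invert = invert)
  bm <- binarize(slice, mask, invert = invert)
  holes <- grow_holes(bm, voxel_inplane)
  bvtv <- compute_bvtv(bm)
  tbth <- compute_tbth(bm, voxel_inplane)
  tbsp <- compute_tbsp(bm, voxel_inplane)
  sk <- skeletonize(bm)
  dens <- network_densities(sk, reference_area_mm2 = mask$area_mm2)
  data.frame(hole_size = holes$mean_area_mm2,
             hole_count = holes$count,
             endosteal_area = mask$area_mm2,
             bvtv = bvtv, tbth = tbth, tbsp = tbsp,
             tbn = compute_tbn(bvtv, tbth),
             nodal_density = dens[["nodal_density"]],
             branch_density = dens[["branch_density"]],
             threshold = bm$threshold)
}

#' Assemble the per-visit microarchitecture profile
#'
#' Averages slice-level metrics over the analysis volume (unweighted mean per
#' variable; hole count as mean per-slice count) and recomputes Tb.N from the
#' averaged BVTV and Tb.Th.
#'
#' @param slice_metrics Data frame with one row per slice and the nine
#'   variable columns of [trab_variables()].
#' @param n_slices Required number of slices (protocol default 8).
#' @return Named numeric of class `microarch_profile` with attribute
#'   `n_slices_averaged`.
#' @export
build_profile <- function(slice_metrics, n_slices = 8L) {
  stopifnot(is.data.frame(slice_metrics), .is_count(n_slices))
  if (nrow(slice_metrics) != n_slices)
    stop("expected ", n_slices, " slice-level records, got ",
         nrow(slice_metrics))
  vars <- trab_variables()
  missing_vars <- setdiff(vars, names(slice_metrics))
  if (length(missing_vars))
    stop("missing slice metrics: ", paste(missing_vars, collapse = ", "))
  for (v in vars) {
    bad <- which(!is.finite(slice_metrics[[v]]))
    if (length(bad))
      stop("missing value for variable '", v, "' on slice(s) ",
           paste(bad, collapse = ", "))
  }
  prof <- vapply(vars, function(v) mean(slice_metrics[[v]]), numeric(1))
  prof[["tbn"]] <- compute_tbn(prof[["bvtv"]], prof[["tbth"]])
  structure(prof, n_slices_averaged = as.integer(n_slices),
            class = "microarch_profile")
}

#' Measure a matched analysis volume or stack
#'
#' @param volume A `matched_volume` side (`"baseline"` or `"followup"`), an
#'   [image_stack()] (first 8 slices unless `slices` given), or a plain list
#'   of matrices.
#' @param voxel_inplane Voxel size in mm (taken from the object when present).
#' @param side For `matched_volume` input: which side to measure.
#' @param slices Optional integer indices of slices to measure.
#' @param invert Contrast flag.
#' @return A `microarch_profile`.
#' @export
measure_volume <- function(volume, voxel_inplane = NULL,
                           side = c("baseline", "followup"),
                           slices = NULL, invert = FALSE) {
  side <- match.arg(side)
  if (inherits(volume, "trab_stack")) volume <- volume$image
  if (inherits(volume, "matched_volume")) {
    voxel_inplane <- volume$voxel_inplane
    volume <- if (side == "baseline") volume$baseline_volume
    else volume$followup_volume
  } else if (inherits(volume, "image_stack")) {
    voxel_inplane <- volume$voxel_inplane
    volume <- volume$slices
  }
  stopifnot(is.list(volume), .is_num1(voxel_inplane))
  if (!is.null(slices)) volume <- volume[slices]
  rows <- lapply(volume, measure_slice, voxel_inplane = voxel_inplane,
                 invert = invert)
  build_profile(do.call(rbind, rows), n_slices = length(volume))
}

#' @export
print.microarch_profile <- function(x, ...) {
  cat("Trabecular microarchitecture profile (",
      attr(x, "n_slices_averaged"), "-slice mean)\n", sep = "")
  fmt <- c(hole_size = "%.2f mm^2", hole_count = "%.0f",
           endosteal_area = "%.1f mm^2", bvtv = "%.1f %%", tbth = "%.2f mm",
           tbsp = "%.2f mm", tbn = "%.2f /mm", nodal_density = "%.2f /mm^2",
           branch_density = "%.2f /mm^2")
  lab <- c(hole_size = "Hole size", hole_count = "Number of holes",
           endosteal_area = "Endosteal area", bvtv = "BVTV",
           tbth = "Tb.Th", tbsp = "Tb.Sp", tbn = "Tb.N",
           nodal_density = "Nodal density", branch_density = "Branch density")
  for (v in trab_variables())
    cat(sprintf("  %-16s %s\n", lab[[v]], sprintf(fmt[[v]], x[[v]])))
  invisible(x)
}
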