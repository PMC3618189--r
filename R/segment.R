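# Endosteal delineation, bone/marrow binarization and hole quantification.

# Otsu threshold on a vector of intensities (256-bin histogram between the
# observed range): maximizes between-class variance; deterministic.
.otsu <- function(v, nbins = 256L) {
  rng <- range(v)
  if (diff(rng) == 0) stop("degenerate intensity histogram: constant values")
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  bc <- (mu_t * w - mu)^2 / (w * (1 - w))
  bc[!is.finite(bc)] <- -Inf
  mids[which.max(bc)]
}

#' Delineate the endosteal region of a slice
#'
#' Finds the region enclosed by the cortical rim: the slice is thresholded
#' (Otsu), bright (marrow-class) components touching the image border are
#' discarded, the interior marrow is morphologically closed to bridge
#' trabeculae, holes are filled, and the largest connected component is kept.
#' The closing element (default radius 2 mm) must exceed half the typical
#' marrow cell diameter so that the closed marrow envelope reaches the
#' endosteal border.
#'
#' @param slice Grey-level matrix with bone dark and marrow bright (use
#'   `invert = TRUE` otherwise).
#' @param voxel_inplane In-plane voxel size in mm.
#' @param closing_radius_mm Radius of the closing element; should exceed half
#'   the typical marrow cell diameter. Default 2 mm.
#' @param invert Set when contrast is inverted (bone bright).
#' @return An object of class `endosteal_mask`: `mask` (logical), `area_mm2`,
#'   `threshold` used.
#' @export
segment_endosteal <- function(slice, voxel_inplane, closing_radius_mm = 2,
                              invert = FALSE) {
  stopifnot(is.matrix(slice), .is_num1(voxel_inplane), voxel_inplane > 0)
  if (invert) slice <- -slice
  thr <- .otsu(as.vector(slice))
  bright <- slice > thr
  if (!any(bright) || all(bright))
    stop("no closed cortical rim found: thresholding yields a single class")
  lab <- .label_components(bright, connectivity = 4)
  border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labs <- border_labs[border_labs > 0L]
  interior <- lab > 0L & !(lab %in% border_labs)
  if (!any(interior))
    stop("no closed cortical rim found: no interior marrow region")
  r_px <- max(1L, as.integer(round(closing_radius_mm / voxel_inplane)))
  kern <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  # pad before closing so the structuring element never clips at the border
  pad <- r_px + 1L
  padded <- matrix(0, nrow(slice) + 2L * pad, ncol(slice) + 2L * pad)
  padded[pad + seq_len(nrow(slice)), pad + seq_len(ncol(slice))] <- interior * 1
  closed <- EBImage::closing(padded, kern)
  closed <- EBImage::fillHull(closed)
  closed <- matrix(as.numeric(EBImage::imageData(closed)),
                   nrow(padded))[pad + seq_len(nrow(slice)),
                                 pad + seq_len(ncol(slice))] > 0.5
  lab2 <- .label_components(closed, connectivity = 4)
  if (max(lab2) == 0L)
    stop("no closed cortical rim found: closing produced an empty region")
  sizes <- tabulate(lab2[lab2 > 0L])
  mask <- lab2 == which.max(sizes)
  # verify the rim: the ring just outside the mask must be predominantly
  # dark (cortical bone); otherwise there is no closed cortical boundary
  ring_kern <- EBImage::makeBrush(5L, shape = "disc")
  ring <- (matrix(as.numeric(EBImage::imageData(
    EBImage::dilate(mask * 1, ring_kern))), nrow(slice)) > 0.5) & !mask
  if (any(ring) && mean(bright[ring]) > 0.35)
    stop("no closed cortical rim found: region boundary is not bone")
  if (any(mask[1, ]) || any(mask[nrow(mask), ]) ||
      any(mask[, 1]) || any(mask[, ncol(mask)]))
    stop("endosteal region touches the image border: rim not closed")
  structure(list(mask = mask,
                 area_mm2 = sum(mask) * voxel_inplane^2,
                 threshold = if (invert) -thr else thr,
                 voxel_inplane = voxel_inplane),
            class = "endosteal_mask")
}

#' @export
print.endosteal_mask <- function(x, ...) {
  cat(sprintf("Endosteal mask: %d px, %.1f mm^2 (threshold %.4f)\n",
              sum(x$mask), x$area_mm2, x$threshold))
  invisible(x)
}

#' Binarize bone vs marrow within the endosteal mask
#'
#' The threshold is computed by Otsu's rule from the intensity histogram
#' inside the mask only, and recorded for audit. Bone is the dark class
#' (gradient-echo MRI contrast); set `invert = TRUE` for bone-bright inputs.
#'
#' @param slice Grey-level matrix.
#' @param mask An [segment_endosteal()] result (or logical matrix).
#' @param invert Contrast flag.
#' @return Object of class `trab_binary`: `bone` (logical, FALSE outside the
#'   mask), `mask`, `threshold`, `voxel_inplane` (when available).
#' @export
binarize <- function(slice, mask, invert = FALSE) {
  voxel <- NULL
  if (inherits(mask, "endosteal_mask")) {
    voxel <- mask$voxel_inplane
    mask <- mask$mask
  }
  stopifnot(is.matrix(slice), is.logical(mask), all(dim(slice) == dim(mask)))
  if (!any(mask)) stop("empty endosteal mask")
  v <- slice[mask]
  if (invert) v <- -v
  thr <- .otsu(v)
  inside <- if (invert) -slice <= thr else slice <= thr
  bone <- mask & inside
  structure(list(bone = bone, mask = mask,
                 threshold = if (invert) -thr else thr,
                 voxel_inplane = voxel),
            class = "trab_binary")
}

#' @export
print.trab_binary <- function(x, ...) {
  cat(sprintf("Binary trabecular map: %.1f%% bone of %d mask px (threshold %.4f)\n",
              100 * sum(x$bone) / sum(x$mask), sum(x$mask), x$threshold))
  invisible(x)
}

#' Quantify trabecular holes by region growing
#'
#' Marrow (intertrabecular) regions inside the endosteal mask are grown from
#' seed pixels by flood fill: each unvisited marrow pixel seeds a region that
#' expands to its connected component. The number of regions grown is the
#' hole count; per-hole pixel areas times the squared voxel size give hole
#' areas, and mean hole size is total hole area over the count.
#'
#' Marrow is 4-connected by default (bone 8-connected downstream), the
#' standard duality preventing both phases from crossing at pixel corners.
#' Marrow components touching the endosteal rim are counted as holes by
#' default; `exclude_boundary = TRUE` reports them separately.
#'
#' @param binary A [binarize()] result.
#' @param voxel_inplane In-plane voxel size in mm (defaults to the one
#'   recorded in `binary`).
#' @param connectivity 4 (default) or 8, for the marrow phase.
#' @param exclude_boundary Exclude rim-touching marrow components from the
#'   hole count (they are still reported in `boundary_area_mm2`).
#' @return Object of class `hole_set`: `labels` (integer matrix), `count`,
#'   `areas_mm2` (per hole), `mean_area_mm2` (`NA` with `empty = TRUE` when no
#'   holes exist -- never 0/0), `boundary_area_mm2`.
#' @export
grow_holes <- function(binary, voxel_inplane = binary$voxel_inplane,
                       connectivity = 4, exclude_boundary = FALSE) {
  stopifnot(inherits(binary, "trab_binary"))
  if (is.null(voxel_inplane))
    stop("voxel_inplane is required (not recorded in the binary map)")
  marrow <- binary$mask & !binary$bone
  lab <- .label_components(marrow, connectivity = connectivity)
  n <- max(lab)
  boundary_area <- 0
  if (n > 0L && exclude_boundary) {
    # rim-touching components: marrow pixels 8-adjacent to outside-mask pixels
    rim <- binary$mask & !.erode_mask(binary$mask)
    rim_labs <- unique(lab[rim & marrow])
    rim_labs <- rim_labs[rim_labs > 0L]
    if (length(rim_labs)) {
      boundary_area <- sum(lab %in% rim_labs) * voxel_inplane^2
      lab[lab %in% rim_labs] <- 0L
      keep <- setdiff(seq_len(n), rim_labs)
      relab <- integer(n); relab[keep] <- seq_along(keep)
      lab[lab > 0L] <- relab[lab[lab > 0L]]
      n <- length(keep)
    }
  }
  areas_px <- if (n > 0L) tabulate(lab[lab > 0L], nbins = n) else integer(0)
  structure(list(labels = lab, count = n,
                 areas_mm2 = areas_px * voxel_inplane^2,
                 mean_area_mm2 = if (n > 0L)
                   sum(areas_px) * voxel_inplane^2 / n else NA_real_,
                 empty = n == 0L,
                 boundary_area_mm2 = boundary_area,
                 voxel_inplane = voxel_inplane,
                 connectivity = connectivity),
            class = "hole_set")
}

# one-pixel erosion of a logical mask (4-neighborhood)
.erode_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  p[2:(nr + 1L), 2:(nc + 1L)] &
    p[1:nr, 2:(nc + 1L)] & p[3:(nr + 2L), 2:(nc + 1L)] &
    p[2:(nr + 1L), 1:nc] & p[2:(nr + 1L), 3:(nc + 2L)]
}

#' @export
print.hole_set <- function(x, ...) {
  if (x$empty) {
    cat("Hole set: no holes (solid bone); mean hole area undefined\n")
  } else {
    cat(sprintf("Hole set: %d holes, mean area %.3f mm^2 (total %.1f mm^2)\n",
                x$count, x$mean_area_mm2, sum(x$areas_mm2)))
  }
  invisible(x)
}
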