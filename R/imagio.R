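#' Construct an image stack
#'
#' An ordered set of axial grey-level slices with voxel geometry. At least 8
#' slices are required (the longitudinal protocol analyzes 8 matched slices),
#' all with identical dimensions.
#'
#' @param slices List of numeric matrices (ordered distal to proximal).
#' @param voxel_inplane,voxel_thickness Voxel geometry in mm, both positive.
#' @param subject_id,visit Labels.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(slices, voxel_inplane, voxel_thickness,
                        subject_id = "S01", visit = "baseline") {
  stopifnot(is.list(slices))
  if (length(slices) < 8)
    stop("an image stack requires at least 8 slices, got ", length(slices))
  if (!all(vapply(slices, is.matrix, logical(1))))
    stop("all slices must be numeric matrices")
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all slices must share the same dimensions")
  if (!.is_num1(voxel_inplane) || voxel_inplane <= 0)
    stop("voxel_inplane must be a positive length in mm")
  if (!.is_num1(voxel_thickness) || voxel_thickness <= 0)
    stop("voxel_thickness must be a positive length in mm")
  structure(list(slices = slices, voxel_inplane = voxel_inplane,
                 voxel_thickness = voxel_thickness,
                 subject_id = subject_id, visit = visit),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("Image stack %s/%s: %d slices of %d x %d px, voxel %.3f x %.3f x %.3f mm\n",
              x$subject_id, x$visit, length(x$slices),
              nrow(x$slices[[1]]), ncol(x$slices[[1]]),
              x$voxel_inplane, x$voxel_inplane, x$voxel_thickness))
  invisible(x)
}

#' Write an image stack to disk
#'
#' Multi-page TIFF (grey values clipped to \[0, 1\]; voxel geometry is not
#' representable and must be re-supplied on read) or NIfTI (voxel geometry
#' stored in pixdim).
#'
#' @param stack An [image_stack()].
#' @param path Output path; format inferred from extension unless given.
#' @param format `"auto"`, `"tiff"` or `"nifti"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, format = c("auto", "tiff", "nifti")) {
  stopifnot(inherits(stack, "image_stack"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff"
    else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
    else stop("cannot infer format from extension of ", path)
  }
  if (format == "tiff") {
    pages <- lapply(stack$slices, function(m) pmin(pmax(m, 0), 1))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    arr <- simplify2array(stack$slices)
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(stack$voxel_inplane, stack$voxel_inplane,
                             stack$voxel_thickness)
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

#' Read an image stack from disk
#'
#' @param path TIFF or NIfTI file.
#' @param format `"auto"`, `"tiff"` or `"nifti"`.
#' @param voxel_inplane,voxel_thickness Overrides in mm. Mandatory for TIFF
#'   (which carries no voxel metadata); optional for NIfTI where they
#'   override pixdim.
#' @param subject_id,visit Labels attached to the stack.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, format = c("auto", "tiff", "nifti"),
                       voxel_inplane = NULL, voxel_thickness = NULL,
                       subject_id = "S01", visit = "baseline") {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff"
    else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) "nifti"
    else stop("cannot infer format from extension of ", path)
  }
  if (format == "tiff") {
    if (is.null(voxel_inplane))
      stop("TIFF carries no voxel metadata: 'voxel_inplane' must be supplied")
    if (is.null(voxel_thickness))
      stop("TIFF carries no voxel metadata: 'voxel_thickness' must be supplied")
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    slices <- lapply(pages, function(p) {
      if (length(dim(p)) == 3) p <- p[, , 1]
      matrix(as.numeric(p), nrow(p), ncol(p))
    })
  } else {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)
    if (is.null(voxel_inplane)) {
      if (length(pd) < 2 || !is.finite(pd[1]) || pd[1] <= 0)
        stop("NIfTI pixdim lacks a usable in-plane size: ",
             "'voxel_inplane' must be supplied")
      voxel_inplane <- pd[1]
    }
    if (is.null(voxel_thickness)) {
      if (length(pd) < 3 || !is.finite(pd[3]) || pd[3] <= 0)
        stop("NIfTI pixdim lacks a usable slice thickness: ",
             "'voxel_thickness' must be supplied")
      voxel_thickness <- pd[3]
    }
    arr <- as.array(img)
    slices <- lapply(seq_len(dim(arr)[3]), function(i)
      matrix(as.numeric(arr[, , i]), dim(arr)[1], dim(arr)[2]))
  }
  image_stack(slices, voxel_inplane = voxel_inplane,
              voxel_thickness = voxel_thickness,
              subject_id = subject_id, visit = visit)
}

# Cross-correlation via FFT between equally sized matrices (zero-mean), with
# the integer shift restricted to +/- max_shift. Returns the shift s = (row,
# col) such that moving `b` by s best aligns it to `a`, and the normalized
# correlation at that shift.
.best_shift <- function(a, b, max_shift = 8L) {
  stopifnot(all(dim(a) == dim(b)))
  a0 <- a - mean(a); b0 <- b - mean(b)
  cc <- Re(fft(fft(a0) * Conj(fft(b0)), inverse = TRUE))
  nr <- nrow(a); nc <- ncol(a)
  sh <- -max_shift:max_shift
  rows <- ((sh %% nr) + nr) %% nr + 1L
  cols <- ((sh %% nc) + nc) %% nc + 1L
  sub <- cc[rows, cols, drop = FALSE]
  k <- which.max(sub)
  i <- (k - 1L) %% length(sh) + 1L
  j <- (k - 1L) %/% length(sh) + 1L
  shift <- c(sh[i], sh[j])
  # exact normalized cross-correlation on the overlap at the chosen shift
  score <- .ncc_at(a, b, shift)
  list(shift = shift, score = score)
}

# Exact NCC between a and b after shifting b by `shift`, on the overlap.
.ncc_at <- function(a, b, shift) {
  nr <- nrow(a); nc <- ncol(a)
  dr <- shift[1]; dc <- shift[2]
  ra <- max(1, 1 + dr):min(nr, nr + dr)
  ca <- max(1, 1 + dc):min(nc, nc + dc)
  rb <- ra - dr; cb <- ca - dc
  va <- as.vector(a[ra, ca]); vb <- as.vector(b[rb, cb])
  if (sd(va) == 0 || sd(vb) == 0) return(0)
  cor(va, vb)
}

#' Register a follow-up stack to its baseline
#'
#' Through-plane matching searches integer slice offsets (no through-plane
#' interpolation: slice thickness far exceeds the in-plane voxel); in-plane
#' alignment estimates a rigid transform (rotation over a fixed grid, then
#' integer translation by FFT cross-correlation), both scored by normalized
#' cross-correlation on the central matched slice pair. An offset k means
#' follow-up slice i corresponds to baseline slice i + k.
#'
#' @param baseline,followup [image_stack()] objects from the same subject
#'   with identical voxel geometry.
#' @param max_slice_offset Through-plane search range (integer slices).
#' @param max_shift In-plane translation search range (voxels).
#' @param rotations Rotation search grid in degrees.
#' @param score_floor Minimum acceptable match score; below it the pair is
#'   flagged unmatchable (an error), mirroring exclusion of motion-degraded
#'   scans.
#' @return An object of class `matched_pair`: `slice_offset`, `shift`
#'   (row, col voxels) and `rotation` (degrees) -- the displacement of the
#'   follow-up relative to the baseline -- `match_score`, plus both stacks.
#' @export
register_pair <- function(baseline, followup, max_slice_offset = 3L,
                          max_shift = 8L, rotations = seq(-3, 3, by = 0.75),
                          score_floor = 0.35) {
  stopifnot(inherits(baseline, "image_stack"), inherits(followup, "image_stack"))
  if (baseline$subject_id != followup$subject_id)
    stop("stacks are from different subjects: ",
         baseline$subject_id, " vs ", followup$subject_id)
  if (abs(baseline$voxel_inplane - followup$voxel_inplane) > 1e-9 ||
      abs(baseline$voxel_thickness - followup$voxel_thickness) > 1e-9)
    stop("voxel geometry differs between the stacks")
  nb <- length(baseline$slices); nf <- length(followup$slices)
  best <- list(score = -Inf)
  for (off in -max_slice_offset:max_slice_offset) {
    # follow-up slice i corresponds to baseline slice i + off
    i_f <- seq_len(nf)
    i_b <- i_f + off
    ok <- i_b >= 1 & i_b <= nb
    if (sum(ok) < 1) next
    mid <- which(ok)[ceiling(sum(ok) / 2)]
    a <- baseline$slices[[i_b[mid]]]
    b <- followup$slices[[mid]]
    for (rot in rotations) {
      b_r <- if (rot != 0) .rigid_transform(b, rotation = rot,
                                            filter = "bilinear",
                                            bg = median(b)) else b
      cand <- .best_shift(a, b_r, max_shift = max_shift)
      if (cand$score > best$score)
        best <- list(score = cand$score, shift = cand$shift,
                     rotation = rot, slice_offset = off, n_matched = sum(ok))
    }
  }
  if (!is.finite(best$score) || best$score < score_floor)
    stop("stacks are unmatchable: best match score ",
         signif(best$score, 3), " is below the floor ", score_floor,
         " (scan flagged for exclusion)")
  # report the displacement of the follow-up relative to the baseline (the
  # inverse of the transform that aligns it), matching the convention in
  # which misalignments are planted by the generator
  structure(list(baseline = baseline, followup = followup,
                 slice_offset = best$slice_offset,
                 shift = as.integer(-best$shift), rotation = -best$rotation,
                 match_score = best$score, n_matched = best$n_matched),
            class = "matched_pair")
}

#' @export
print.matched_pair <- function(x, ...) {
  cat(sprintf("Matched pair %s: slice offset %+d, shift (%+d, %+d) vx, rotation %+.2f deg, NCC %.3f\n",
              x$baseline$subject_id, x$slice_offset,
              x$shift[1], x$shift[2], x$rotation, x$match_score))
  invisible(x)
}

#' Detect the distal reference slice of a synthetic stack
#'
#' Scans the stack from its distal end and returns the first slice past the
#' dense growth-plate band (per-slice trabecular bone fraction below the
#' given cutoff). Intended for generator-produced stacks where the band is
#' part of the recorded ground truth; clinical use supplies the reference
#' manually.
#'
#' @param stack An [image_stack()].
#' @param dense_cutoff Bone-fraction (0-1) above which a slice is considered
#'   part of the dense band.
#' @return Integer slice index.
#' @export
detect_reference_slice <- function(stack, dense_cutoff = 0.60) {
  stopifnot(inherits(stack, "image_stack"))
  frac <- vapply(stack$slices, function(g) {
    em <- segment_endosteal(g, stack$voxel_inplane)
    bm <- binarize(g, em)
    mean(bm$bone[em$mask])
  }, numeric(1))
  dense <- frac > dense_cutoff
  if (!any(dense)) return(1L)
  last_dense <- max(which(dense))
  if (last_dense >= length(stack$slices))
    stop("entire stack is dense bone: no analyzable reference slice")
  last_dense + 1L
}

#' Restrict a matched pair to the 8-slice analysis volume
#'
#' Selects exactly 8 contiguous matched slices beginning at the distal
#' reference slice (baseline indexing).
#'
#' @param pair A [register_pair()] result.
#' @param distal_reference_slice Baseline index of the most distal slice to
#'   analyze.
#' @param n_slices Number of contiguous slices (default 8).
#' @return A `matched_volume`: `baseline_volume` and `followup_volume` (lists
#'   of `n_slices` matrices in 1:1 order), the slice index maps, and the
#'   in-plane transform inherited from the pair.
#' @export
select_analysis_volume <- function(pair, distal_reference_slice, n_slices = 8L) {
  stopifnot(inherits(pair, "matched_pair"), .is_count(distal_reference_slice),
            .is_count(n_slices), n_slices >= 1)
  nb <- length(pair$baseline$slices); nf <- length(pair$followup$slices)
  i_b <- as.integer(distal_reference_slice) + seq_len(n_slices) - 1L
  i_f <- i_b - pair$slice_offset
  ok <- i_b >= 1 & i_b <= nb & i_f >= 1 & i_f <= nf
  if (!all(ok))
    stop("insufficient contiguous matched slices from reference ",
         distal_reference_slice, ": only ", sum(ok), " of ", n_slices,
         " available")
  structure(list(baseline_volume = pair$baseline$slices[i_b],
                 followup_volume = pair$followup$slices[i_f],
                 baseline_index = i_b, followup_index = i_f,
                 slice_offset = pair$slice_offset, shift = pair$shift,
                 rotation = pair$rotation, match_score = pair$match_score,
                 voxel_inplane = pair$baseline$voxel_inplane,
                 subject_id = pair$baseline$subject_id),
            class = "matched_volume")
}
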