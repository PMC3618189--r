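# Internal raster helpers shared across modules. All matrices are indexed
# [row, col]; linear indices are column-major as in base R.

.neighbor_offsets <- function(connectivity) {
  if (connectivity == 4) {
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  } else if (connectivity == 8) {
    cbind(dr = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
          dc = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
  } else {
    stop("connectivity must be 4 or 8")
  }
}

# Flood-fill (seed-and-grow) connected-component labeling. Seeds are taken in
# raster (column-major) order; each seed grows a breadth-first frontier until
# its component is exhausted. Used both for hole quantification (the region
# growing step of the measurement chain) and for ground-truth bookkeeping.
.label_components <- function(fg, connectivity = 4) {
  stopifnot(is.matrix(fg))
  nr <- nrow(fg); nc <- ncol(fg)
  lab <- matrix(0L, nr, nc)
  offs <- .neighbor_offsets(connectivity)
  nlab <- 0L
  for (s in which(fg)) {
    if (lab[s] != 0L) next
    nlab <- nlab + 1L
    lab[s] <- nlab
    frontier <- s
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      cc <- (frontier - 1L) %/% nr + 1L
      nxt <- integer(0)
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1L]
        c2 <- cc + offs[k, 2L]
        ok <- rr >= 1L & rr <= nr & c2 >= 1L & c2 <= nc
        if (!any(ok)) next
        idx <- (c2[ok] - 1L) * nr + rr[ok]
        idx <- idx[fg[idx] & lab[idx] == 0L]
        if (length(idx)) {
          lab[idx] <- nlab
          nxt <- c(nxt, idx)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

# Euclidean distance transform: per foreground pixel, the center-to-center
# distance to the nearest background pixel. The image border is not treated
# as background (EBImage convention, relied upon throughout).
.distmap <- function(fg) {
  stopifnot(is.matrix(fg))
  if (!any(fg)) return(matrix(0, nrow(fg), ncol(fg)))
  if (all(fg)) stop("distance transform undefined: no background pixels")
  d <- EBImage::distmap(matrix(as.numeric(fg), nrow(fg)), metric = "euclidean")
  matrix(as.numeric(EBImage::imageData(d)), nrow(fg), ncol(fg))
}

# Count of foreground neighbors (8-neighborhood) for every pixel.
.neighbor_count <- function(fg) {
  nr <- nrow(fg); nc <- ncol(fg)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- as.integer(fg)
  acc <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    acc <- acc + p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  }
  acc
}

# Deterministic local RNG scope: evaluates expr under a seed without
# clobbering the caller's RNG stream.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)

.is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
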