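# Independent oracles and fixture builders. These deliberately avoid the
# package's own algorithms: labeling via igraph graph components, thickness
# via the exhaustive all-centers definition with a brute-force EDT, Holm via
# a literal transcription of the step-down definition.

# connected components through igraph: pixels are vertices, adjacent pixels
# share an edge
oracle_label <- function(fg, connectivity = 4) {
  idx <- which(fg)
  lab <- matrix(0L, nrow(fg), ncol(fg))
  if (!length(idx)) return(lab)
  nr <- nrow(fg)
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  key <- setNames(seq_along(idx), idx)
  offs <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  }
  edges <- NULL
  for (k in seq_len(nrow(offs))) {
    rr <- r + offs[k, 1]; c2 <- cc + offs[k, 2]
    ok <- rr >= 1 & rr <= nr & c2 >= 1 & c2 <= ncol(fg)
    nb <- (c2[ok] - 1L) * nr + rr[ok]
    src <- idx[ok]
    good <- fg[nb]
    if (any(good)) edges <- rbind(edges, cbind(src[good], nb[good]))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[, 1]), to = as.character(edges[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(idx)))
  comp <- igraph::components(g)$membership
  lab[as.integer(names(comp))] <- as.integer(comp)
  lab
}

# exhaustive maximal-disc thickness: for every phase pixel, the diameter of
# the largest disc (over all centers, all radii) containing it and fitting
# in the phase; EDT by brute-force minimum over background pixels
oracle_thickness <- function(phase) {
  nr <- nrow(phase); nc <- ncol(phase)
  th <- matrix(0, nr, nc)
  fgi <- which(phase, arr.ind = TRUE)
  bgi <- which(!phase, arr.ind = TRUE)
  if (!nrow(fgi)) return(th)
  stopifnot(nrow(bgi) > 0)
  d <- apply(fgi, 1, function(p)
    sqrt(min((bgi[, 1] - p[1])^2 + (bgi[, 2] - p[2])^2)))
  r <- d - 0.5                       # inscribed radius per center
  n <- nrow(fgi)
  dd <- as.matrix(stats::dist(fgi))  # center-to-center distances
  for (i in seq_len(n)) {
    covered <- dd[i, ] <= r - 0.5    # centers whose disc covers pixel i
    covered[i] <- TRUE               # every center covers itself
    th[fgi[i, 1], fgi[i, 2]] <- 2 * max(r[covered])
  }
  th
}

# literal step-down definition: sort ascending, multiply the i-th smallest by
# (m - i + 1), enforce running maxima, cap at 1
oracle_holm <- function(p, m = length(p)) {
  ord <- order(p)
  adj <- numeric(length(p))
  run <- 0
  for (i in seq_along(ord)) {
    run <- max(run, (m - i + 1) * p[ord[i]])
    adj[ord[i]] <- min(1, run)
  }
  adj
}

# exhaustive through-plane offset search scored by plain correlation
oracle_slice_offset <- function(baseline, followup, max_offset = 3) {
  scores <- sapply(-max_offset:max_offset, function(off) {
    i_f <- seq_along(followup$slices)
    i_b <- i_f + off
    ok <- i_b >= 1 & i_b <= length(baseline$slices)
    if (!sum(ok)) return(-Inf)
    mean(mapply(function(ib, jf)
      cor(as.vector(baseline$slices[[ib]]), as.vector(followup$slices[[jf]])),
      i_b[ok], i_f[ok]))
  })
  (-max_offset:max_offset)[which.max(scores)]
}

# smoothed random binary map with both phases present
random_binary_map <- function(n = 64, p = 0.5, smooth = 1.2) {
  g <- matrix(rnorm(n * n), n, n)
  g <- matrix(as.numeric(EBImage::imageData(EBImage::gblur(g, smooth))), n, n)
  fg <- g > quantile(g, 1 - p)
  if (!any(fg)) fg[1, 1] <- TRUE
  if (all(fg)) fg[1, 1] <- FALSE
  fg
}

# wrap a logical bone map (full-image mask) as a binary trabecular map
as_binary <- function(bone, mask = NULL, voxel = 0.195) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(bone), ncol(bone))
  structure(list(bone = bone & mask, mask = mask, threshold = NA_real_,
                 voxel_inplane = voxel),
            class = "trab_binary")
}

# per-subject percent-change table from a values-mode cohort
cohort_changes <- function(coh) {
  cc <- coh$cohort
  b <- cc[cc$visit == "baseline", ]
  f <- cc[cc$visit == "followup", ]
  stopifnot(identical(b$subject_id, f$subject_id))
  ch <- data.frame(subject_id = b$subject_id, group = b$group,
                   ethnicity = b$ethnicity)
  for (v in trab_variables())
    ch[[paste0("pct_", v)]] <- 100 * (f[[v]] - b[[v]]) / b[[v]]
  ch
}
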