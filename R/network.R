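# Skeletonization and network analysis of the trabecular phase.
#
# Thinning is sequential simple-point deletion: a foreground pixel is deleted
# only if deletion preserves the topology of its 3x3 neighborhood (one
# 8-connected foreground component, one 4-connected background component
# adjacent to the pixel). Deleting simple points one at a time preserves the
# homotopy of the whole image by construction, so the skeleton has exactly
# the component and hole counts of the input. Endpoints are preserved to
# retain branch geometry; four directional subcycles per pass keep the result
# near-medial.

# neighbor offsets, bit order fixed: NW N NE W E SW S SE
.n8_offsets <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
                     dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

# 256-entry lookup: is a pixel with this 8-neighborhood pattern simple?
.simple_lut_env <- new.env(parent = emptyenv())

.simple_lut <- function() {
  if (!is.null(.simple_lut_env$lut)) return(.simple_lut_env$lut)
  offs <- .n8_offsets
  count_components <- function(cells, four_only) {
    if (!length(cells)) return(0L)
    n <- length(cells)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i >= j) next
      ddr <- abs(offs[cells[i], 1] - offs[cells[j], 1])
      ddc <- abs(offs[cells[i], 2] - offs[cells[j], 2])
      adj <- if (four_only) (ddr + ddc) == 1L else max(ddr, ddc) == 1L
      if (adj) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
    length(unique(vapply(seq_len(n), find, integer(1))))
  }
  lut <- logical(256)
  four_nbrs <- which(abs(.n8_offsets[, 1]) + abs(.n8_offsets[, 2]) == 1L)
  for (pat in 0:255) {
    bits <- bitwAnd(pat, 2L^(0:7)) > 0
    fg <- which(bits)
    bg <- which(!bits)
    n_fg <- count_components(fg, four_only = FALSE)
    # background components must touch a 4-neighbor of the center
    n_bg <- 0L
    if (length(bg)) {
      # label bg components under 4-adjacency, count those containing a
      # 4-neighbor of the center
      n <- length(bg)
      parent <- seq_len(n)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i >= j) next
        ddr <- abs(offs[bg[i], 1] - offs[bg[j], 1])
        ddc <- abs(offs[bg[i], 2] - offs[bg[j], 2])
        if ((ddr + ddc) == 1L) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
      roots <- vapply(seq_len(n), find, integer(1))
      n_bg <- length(unique(roots[bg %in% four_nbrs]))
    }
    lut[pat + 1L] <- (n_fg == 1L) && (n_bg == 1L)
  }
  .simple_lut_env$lut <- lut
  lut
}

# neighborhood pattern code of pixel (r, c) in padded logical matrix
.pattern_at <- function(img, r, c) {
  offs <- .n8_offsets
  code <- 0L
  for (k in 1:8) if (img[r + offs[k, 1], c + offs[k, 2]]) {
    code <- code + 2L^(k - 1L)
  }
  code
}

#' Skeletonize the trabecular bone phase
#'
#' Topology-preserving sequential thinning to a one-pixel-wide medial
#' representation: the skeleton has the same number of connected components
#' and holes as the bone phase. Junction pixels (3 or more skeleton
#' neighbors) are clustered (8-adjacent junction pixels form one node) and
#' branches are the maximal skeleton segments between nodes and endpoints.
#'
#' @param binary A [binarize()] result, or a logical bone matrix.
#' @return Object of class `skeleton_graph`: `skeleton` (logical matrix),
#'   `n_nodes` (merged junction clusters), `n_branches`, `n_endpoints`,
#'   `node_labels`, `branch_labels`.
#' @export
skeletonize <- function(binary) {
  bone <- if (inherits(binary, "trab_binary")) binary$bone else binary
  stopifnot(is.matrix(bone), is.logical(bone))
  if (!any(bone)) stop("bone phase is empty: nothing to skeletonize")
  lut <- .simple_lut()
  nr <- nrow(bone); nc <- ncol(bone)
  img <- matrix(FALSE, nr + 2L, nc + 2L)
  img[2:(nr + 1L), 2:(nc + 1L)] <- bone
  dirs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  repeat {
    changed <- FALSE
    for (d in dirs) {
      fg <- which(img)
      if (!length(fg)) break
      rr <- (fg - 1L) %% (nr + 2L) + 1L
      cc <- (fg - 1L) %/% (nr + 2L) + 1L
      open_side <- !img[cbind(rr + d[1], cc + d[2])]
      cand <- fg[open_side]
      rr <- rr[open_side]; cc <- cc[open_side]
      for (k in seq_along(cand)) {
        pat <- .pattern_at(img, rr[k], cc[k])
        nn <- sum(bitwAnd(pat, 2L^(0:7)) > 0)
        if (nn > 1L && lut[pat + 1L]) {
          img[cand[k]] <- FALSE
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  skel <- img[2:(nr + 1L), 2:(nc + 1L)]
  .skeleton_graph(skel)
}

.skeleton_graph <- function(skel) {
  nbr <- .neighbor_count(skel)
  junction <- skel & nbr >= 3L
  endpoint <- skel & nbr == 1L
  node_labels <- .label_components(junction, connectivity = 8)
  branch_labels <- .label_components(skel & !junction, connectivity = 8)
  structure(list(skeleton = skel,
                 n_nodes = max(node_labels),
                 n_branches = max(branch_labels),
                 n_endpoints = sum(endpoint),
                 node_labels = node_labels,
                 branch_labels = branch_labels),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("Skeleton graph: %d px, %d nodes, %d branches, %d endpoints\n",
              sum(x$skeleton), x$n_nodes, x$n_branches, x$n_endpoints))
  invisible(x)
}

#' Nodal and branch density
#'
#' Junction clusters and branch segments per mm^2 of endosteal area.
#'
#' @param graph A [skeletonize()] result.
#' @param reference_area_mm2 Endosteal area in mm^2, strictly positive.
#' @return Named numeric: `nodal_density`, `branch_density` (/mm^2).
#' @export
network_densities <- function(graph, reference_area_mm2) {
  stopifnot(inherits(graph, "skeleton_graph"), .is_num1(reference_area_mm2))
  if (reference_area_mm2 <= 0)
    stop("reference area must be positive, got ", reference_area_mm2)
  c(nodal_density = graph$n_nodes / reference_area_mm2,
    branch_density = graph$n_branches / reference_area_mm2)
}

# Euler number (components minus holes) of a binary image under the standard
# duality: foreground 8-connected, holes = interior background 4-components.
.euler_number <- function(fg) {
  comps <- max(.label_components(fg, connectivity = 8))
  bg <- !fg
  lab <- .label_components(bg, connectivity = 4)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  holes <- length(setdiff(unique(lab[lab > 0L]), border))
  comps - holes
}
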