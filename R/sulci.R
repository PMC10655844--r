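#' Laplacian mesh smoothing
#'
#' Classic umbrella-operator smoothing: each vertex moves toward the mean of
#' its one-ring neighbours with weight `lambda` per iteration. Repeated
#' application yields the "super-smoothed" hull used to derive sulcal bases.
#'
#' @param mesh a `seeg_mesh`.
#' @param iterations number of smoothing passes.
#' @param lambda neighbour-averaging weight in (0, 1].
#' @param preserve_scale counteract the systematic shrinkage of umbrella
#'   smoothing by rescaling the result about its centroid so the mean
#'   vertex-to-centroid distance is preserved (the behaviour of
#'   shrink-compensated smoothing filters). Without it, heavy smoothing
#'   pulls a closed surface entirely inside the folds it is meant to
#'   average.
#' @return smoothed `seeg_mesh` (same triangulation).
#' @export
laplacian_smooth <- function(mesh, iterations = 100, lambda = 0.5,
                             preserve_scale = FALSE) {
  if (iterations == 0) return(mesh)
  F <- mesh$triangles
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)],
             F[, c(2, 1)], F[, c(3, 2)], F[, c(1, 3)])
  e <- unique(e)
  nv <- nrow(mesh$vertices)
  A <- Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1, dims = c(nv, nv))
  deg <- Matrix::rowSums(A)
  if (any(deg == 0)) stop("isolated vertices cannot be smoothed")
  W <- Matrix::Diagonal(x = 1 / deg) %*% A
  V <- mesh$vertices
  for (i in seq_len(iterations))
    V <- (1 - lambda) * V + lambda * as.matrix(W %*% V)
  if (preserve_scale) {
    ctr <- colMeans(mesh$vertices)
    r0 <- mean(sqrt(rowSums(sweep(mesh$vertices, 2, ctr)^2)))
    ctr1 <- colMeans(V)
    r1 <- mean(sqrt(rowSums(sweep(V, 2, ctr1)^2)))
    V <- sweep(sweep(V, 2, ctr1) * (r0 / r1), 2, ctr, `+`)
  }
  out <- surface_mesh(V, F)
  if (mean(out$areas == 0) > 0.5)
    stop("smoothing collapsed the mesh (more than half of the triangles degenerate)")
  out
}

#' Derive the sulci surface of a cortex mesh
#'
#' Smooths a copy of the cortex heavily (scale-preserving, so the hull
#' averages the folds instead of shrinking inside them) and returns the
#' sub-mesh of cortex triangles lying at least `depth_clearance` below the
#' smoothed hull — the bases of the sulci. Membership uses a winding-number
#' inside test on the element centroid pushed `depth_clearance` mm along its
#' outward normal; the clearance makes the rule robust to facet depression
#' and residual smoothing anisotropy, so a convex (or unsmoothed) cortex
#' yields an empty sulci surface.
#'
#' @param cortex closed `seeg_mesh`.
#' @param smooth_iters smoothing iterations for the hull (default 100).
#' @param lambda smoothing weight per iteration.
#' @param depth_clearance minimum depth (mm) below the hull for an element
#'   to count as sulcal.
#' @return a `seeg_mesh` containing only the sulcal triangles (possibly with
#'   0 triangles); attribute `element_ids` holds their indices in `cortex`.
#' @export
derive_sulci_surface <- function(cortex, smooth_iters = 100, lambda = 0.5,
                                 depth_clearance = 2.5) {
  if (smooth_iters == 0) {
    keep <- logical(nrow(cortex$triangles))
  } else {
    hull <- laplacian_smooth(cortex, smooth_iters, lambda, preserve_scale = TRUE)
    keep <- points_inside(hull, cortex$centroids +
                                  depth_clearance * cortex$normals)
  }
  sub <- submesh(cortex, which(keep))
  attr(sub, "element_ids") <- which(keep)
  sub
}

#' Extract the sub-mesh spanned by a set of triangles
#'
#' @param mesh a `seeg_mesh`.
#' @param triangle_ids triangle indices to keep.
#' @return a `seeg_mesh` with re-indexed vertices.
#' @export
submesh <- function(mesh, triangle_ids) {
  F <- mesh$triangles[triangle_ids, , drop = FALSE]
  used <- sort(unique(as.vector(F)))
  if (length(used) == 0L)
    return(surface_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3)))
  remap <- integer(nrow(mesh$vertices))
  remap[used] <- seq_along(used)
  surface_mesh(mesh$vertices[used, , drop = FALSE],
               matrix(remap[F], ncol = 3))
}
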