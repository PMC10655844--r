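#' Grow a fixed-area cortical patch around a centre element
#'
#' Accretes whole rings of edge-adjacent triangles breadth-first around the
#' centre element, stopping at the first ring whose inclusion brings the
#' cumulative area to at least `target_area`. The returned area is therefore
#' at least the target, and the area minus the last ring is below the target.
#'
#' @param mesh a `seeg_mesh` (the cortex).
#' @param center triangle index of the patch centre element.
#' @param target_area target patch area in cm^2.
#' @param adjacency optional precomputed [triangle_adjacency()] matrix.
#' @return a `seeg_patch`: list with `center`, `members` (triangle indices),
#'   `area` (cm^2) and `extent` (cm, filled by [patch_extent()]; NA here).
#' @export
grow_patch <- function(mesh, center, target_area, adjacency = NULL) {
  target_mm2 <- target_area * 100
  if (target_mm2 < mesh$areas[center])
    stop("target_area smaller than the centre element")
  if (target_mm2 > sum(mesh$areas) + 1e-9)
    stop("target_area exceeds total mesh area")
  if (is.null(adjacency)) adjacency <- triangle_adjacency(mesh)
  members <- cpp_grow_patches(adjacency, mesh$areas, as.integer(center),
                              target_mm2)[[1]]
  structure(list(center = as.integer(center), members = members,
                 area = sum(mesh$areas[members]) / 100, extent = NA_real_),
            class = "seeg_patch")
}

#' Grow one patch around every requested centre element
#'
#' Vectorized version of [grow_patch()] used to build a patch source per
#' cortical element (one patch model per element of the surface).
#'
#' @param mesh a `seeg_mesh`.
#' @param target_area patch area in cm^2 (6, 10 or 20 in the standard grid).
#' @param centers integer vector of centre elements (default: all).
#' @param adjacency optional precomputed adjacency.
#' @return a `seeg_patch_set`: list with `centers`, `members` (list of
#'   integer vectors), `areas` (cm^2) and `target_area`.
#' @export
grow_patches <- function(mesh, target_area,
                         centers = seq_len(nrow(mesh$triangles)),
                         adjacency = NULL) {
  target_mm2 <- target_area * 100
  if (target_mm2 > sum(mesh$areas) + 1e-9)
    stop("target_area exceeds total mesh area")
  if (is.null(adjacency)) adjacency <- triangle_adjacency(mesh)
  members <- cpp_grow_patches(adjacency, mesh$areas, as.integer(centers),
                              target_mm2)
  areas <- vapply(members, function(m) sum(mesh$areas[m]), numeric(1)) / 100
  structure(list(centers = as.integer(centers), members = members,
                 areas = areas, target_area = target_area),
            class = "seeg_patch_set")
}

#' @export
print.seeg_patch_set <- function(x, ...) {
  cat(sprintf("seeg_patch_set: %d patches of target area %g cm^2 (mean %0.2f cm^2, mean %0.0f elements)\n",
              length(x$centers), x$target_area, mean(x$areas),
              mean(lengths(x$members))))
  invisible(x)
}

#' Boundary vertices of a patch
#'
#' Vertices lying on edges shared with non-member triangles (or on the mesh
#' boundary).
#'
#' @keywords internal
patch_boundary_vertices <- function(mesh, members) {
  F <- mesh$triangles[members, , drop = FALSE]
  inpatch <- logical(nrow(mesh$triangles))
  inpatch[members] <- TRUE
  adj <- attr(mesh, "adjacency")
  if (is.null(adj)) adj <- triangle_adjacency(mesh)
  bnd <- integer(0)
  slots <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  for (k in 1:3) {
    nb <- adj[members, k]
    open_ <- nb == 0L | !inpatch[pmax(nb, 1L)]
    if (any(open_))
      bnd <- c(bnd, as.vector(F[open_, slots[[k]]]))
  }
  unique(bnd)
}

#' Spatial extent of a patch
#'
#' Mean Euclidean distance from the area-weighted centroid of the member
#' triangles to the boundary vertices of the patch, in cm.
#'
#' @param mesh a `seeg_mesh`.
#' @param patch a `seeg_patch`, or an integer vector of member triangles.
#' @return extent in cm.
#' @export
patch_extent <- function(mesh, patch) {
  members <- if (inherits(patch, "seeg_patch")) patch$members else as.integer(patch)
  bnd <- patch_boundary_vertices(mesh, members)
  if (length(bnd) == 0L)
    stop("patch covers a closed mesh: no boundary to measure extent against")
  w <- mesh$areas[members]
  com <- colSums(mesh$centroids[members, , drop = FALSE] * w) / sum(w)
  d <- sqrt(rowSums((mesh$vertices[bnd, , drop = FALSE] -
                       matrix(com, length(bnd), 3, byrow = TRUE))^2))
  mean(d) / 10
}

#' Mean patch extent per area class
#'
#' @param mesh a `seeg_mesh`.
#' @param patch_sets list of `seeg_patch_set` objects (e.g. the 6/10/20 cm^2
#'   classes), or a single set.
#' @return named numeric vector of mean extents (cm), one per area class.
#' @export
patch_extent_summary <- function(mesh, patch_sets) {
  if (inherits(patch_sets, "seeg_patch_set")) patch_sets <- list(patch_sets)
  adj <- triangle_adjacency(mesh)
  attr(mesh, "adjacency") <- adj
  out <- vapply(patch_sets, function(ps) {
    mean(vapply(ps$members, function(m) patch_extent(mesh, m), numeric(1)))
  }, numeric(1))
  names(out) <- vapply(patch_sets, function(ps) paste0(ps$target_area, "cm2"),
                       character(1))
  out
}
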