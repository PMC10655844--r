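#' Bounding-volume-hierarchy distance index over a triangle mesh
#'
#' Builds an axis-aligned-box binary tree over the mesh triangles for fast
#' minimum-distance queries (the binary-tree search used for the safety
#' clearance filters).
#'
#' @param mesh a `seeg_mesh` with at least one triangle.
#' @return an object of class `seeg_distance_index`.
#' @export
distance_index <- function(mesh) {
  if (is.null(mesh$triangles) || nrow(mesh$triangles) == 0L)
    stop("cannot index an empty mesh")
  structure(list(mesh = mesh,
                 tree = cpp_bvh_build(mesh$vertices, mesh$triangles)),
            class = "seeg_distance_index")
}

#' Minimum Euclidean distance from query points to a mesh
#'
#' Exact point-to-triangle minima found by branch-and-bound descent of the
#' bounding-volume hierarchy. Segments should be sampled to a finite point
#' set first (see [trajectory_shaft_points()] for the electrode convention).
#'
#' @param index a `seeg_distance_index` (or a `seeg_mesh`, indexed on the fly).
#' @param query numeric matrix n x 3 of points (mm), or a length-3 vector.
#' @return numeric vector of distances (mm), one per query point.
#' @export
min_distance <- function(index, query) {
  if (inherits(index, "seeg_mesh")) index <- distance_index(index)
  if (!inherits(index, "seeg_distance_index")) stop("not a distance index")
  if (is.null(dim(query))) query <- matrix(query, ncol = 3, byrow = TRUE)
  query <- as.matrix(query)
  storage.mode(query) <- "double"
  tree <- index$tree
  # external pointers do not survive serialization; rebuild lazily
  if (is.null(tree) || cpp_xptr_is_null(tree))
    tree <- cpp_bvh_build(index$mesh$vertices, index$mesh$triangles)
  cpp_bvh_min_distance(tree, query)
}

#' Signed-region inside test via generalized winding number
#'
#' @param mesh closed `seeg_mesh`.
#' @param points n x 3 matrix (mm).
#' @param threshold winding-number cutoff; points well inside score ~1,
#'   outside ~0, exactly on the surface ~0.5.
#' @return logical vector.
#' @export
points_inside <- function(mesh, points, threshold = 0.75) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  wn <- cpp_winding_number(mesh$vertices, mesh$triangles, as.matrix(points))
  wn > threshold
}
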