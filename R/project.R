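#' Radial projection of a cortical patch onto the inner skull
#'
#' Casts rays from `head_center` through the vertices of each member
#' triangle onto the inner-skull mesh and sums the areas of the projected
#' triangles: the patch area "as seen" on the inside of the skull.
#'
#' @param patch a `seeg_patch` or integer vector of member triangle indices.
#' @param cortex cortical `seeg_mesh` (encloses the patch).
#' @param skull inner-skull `seeg_mesh` (encloses the cortex).
#' @param head_center interior projection centre (mm), default the skull
#'   vertex centroid.
#' @return projected area in cm^2.
#' @export
projected_area_on_skull <- function(patch, cortex, skull,
                                    head_center = colMeans(skull$vertices)) {
  members <- if (inherits(patch, "seeg_patch")) patch$members else as.integer(patch)
  if (length(members) == 0L) return(0)
  F <- cortex$triangles[members, , drop = FALSE]
  used <- sort(unique(as.vector(F)))
  P <- cortex$vertices[used, , drop = FALSE]
  O <- matrix(head_center, nrow(P), 3, byrow = TRUE)
  D <- P - O
  hits <- cpp_ray_mesh(skull$vertices, skull$triangles, O, D)
  if (anyNA(hits[, 1]))
    stop("projection ray missed the skull mesh")
  remap <- integer(nrow(cortex$vertices))
  remap[used] <- seq_along(used)
  Fp <- matrix(remap[F], ncol = 3)
  proj <- surface_mesh(hits[, 2:4, drop = FALSE], Fp, validate = FALSE)
  sum(proj$areas) / 100
}
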