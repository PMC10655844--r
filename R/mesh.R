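#' Triangulated surface mesh
#'
#' Constructs a `seeg_mesh`: a closed or open triangle mesh with cached
#' per-triangle areas, unit normals and centroids. Coordinates are in
#' millimetres.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates (mm).
#' @param triangles integer matrix, m x 3, 1-based vertex indices.
#' @param validate check invariants (finite coordinates, indices in range).
#' @return An object of class `seeg_mesh` with elements `vertices`,
#'   `triangles`, `areas` (mm^2), `normals` (unit), `centroids` (mm).
#' @export
surface_mesh <- function(vertices, triangles, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  if (validate) {
    if (ncol(vertices) != 3L || ncol(triangles) != 3L)
      stop("vertices and triangles must have 3 columns")
    if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
    if (nrow(triangles) > 0L &&
        (min(triangles) < 1L || max(triangles) > nrow(vertices)))
      stop("triangle indices out of range")
  }
  tm <- triangle_metrics(list(vertices = vertices, triangles = triangles))
  structure(list(vertices = vertices, triangles = triangles,
                 areas = tm$areas, normals = tm$normals,
                 centroids = tm$centroids),
            class = "seeg_mesh")
}

#' Per-triangle areas, unit normals and centroids
#'
#' Area is half the norm of the edge cross product; degenerate (collinear)
#' triangles get area 0 and an NA normal.
#'
#' @param mesh a `seeg_mesh`, or a list with `vertices` and `triangles`.
#' @return list with `areas` (mm^2), `normals` (m x 3), `centroids` (m x 3 mm).
#' @export
triangle_metrics <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$triangles
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c_ - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm2 <- sqrt(rowSums(cr^2))
  areas <- nrm2 / 2
  normals <- cr / ifelse(nrm2 > 0, nrm2, NA_real_)
  list(areas = areas, normals = normals, centroids = (a + b + c_) / 3)
}

#' @export
print.seeg_mesh <- function(x, ...) {
  closed <- tryCatch(is_closed_mesh(x), error = function(e) NA)
  cat(sprintf("seeg_mesh: %d vertices, %d triangles, area %.1f cm^2%s\n",
              nrow(x$vertices), nrow(x$triangles), sum(x$areas) / 100,
              if (isTRUE(closed)) ", closed" else ""))
  invisible(x)
}

#' Edge-adjacent triangle neighbours
#'
#' For each triangle, the (up to three) triangles sharing an edge with it.
#' Used for ring-wise patch growth and boundary detection.
#'
#' @param mesh a `seeg_mesh`.
#' @return integer matrix m x 3; 0 marks a boundary edge (no neighbour).
#' @export
triangle_adjacency <- function(mesh) {
  F <- mesh$triangles
  m <- nrow(F)
  # edges in fixed per-triangle slots 1..3: (1,2), (2,3), (3,1)
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tri <- rep(seq_len(m), 3L)
  ord <- order(key)
  key <- key[ord]
  tri <- tri[ord]
  adj <- matrix(0L, m, 3L)
  slot <- rep(1:3, each = m)[ord]
  same <- which(key[-1] == key[-length(key)])
  for (i in same) {
    t1 <- tri[i]; t2 <- tri[i + 1]
    adj[t1, slot[i]] <- t2
    adj[t2, slot[i + 1]] <- t1
  }
  adj
}

#' Test whether every edge is shared by exactly two triangles
#' @param mesh a `seeg_mesh`.
#' @return logical scalar.
#' @export
is_closed_mesh <- function(mesh) {
  F <- mesh$triangles
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Orient all triangles outward for a star-shaped closed mesh
#'
#' Flips triangles whose normal points toward `center` (default: the
#' vertex centroid).
#'
#' @param mesh a `seeg_mesh`.
#' @param center interior reference point (length-3).
#' @return re-oriented `seeg_mesh`.
#' @export
orient_outward <- function(mesh, center = colMeans(mesh$vertices)) {
  out <- mesh$centroids - matrix(center, nrow(mesh$centroids), 3, byrow = TRUE)
  flip <- rowSums(out * mesh$normals) < 0
  F <- mesh$triangles
  F[flip, c(2, 3)] <- F[flip, c(3, 2)]
  surface_mesh(mesh$vertices, F)
}

#' Subdivided icosahedral sphere mesh
#'
#' Starts from a regular icosahedron and applies `subdivision` rounds of
#' 1-to-4 edge-midpoint subdivision, projecting vertices to the sphere.
#'
#' @param radius sphere radius (mm).
#' @param subdivision number of subdivision rounds (>= 0);
#'   20 * 4^subdivision triangles.
#' @return a `seeg_mesh`, closed and outward-oriented.
#' @export
icosphere <- function(radius = 1, subdivision = 3) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivision)) {
    m <- nrow(F)
    e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    uk <- unique(key)
    mididx <- match(key, uk) + nrow(V)
    ue <- e[match(uk, key), , drop = FALSE]
    mid <- (V[ue[, 1], , drop = FALSE] + V[ue[, 2], , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    V <- rbind(V, mid)
    m12 <- mididx[seq_len(m)]
    m23 <- mididx[m + seq_len(m)]
    m31 <- mididx[2 * m + seq_len(m)]
    F <- rbind(cbind(F[, 1], m12, m31),
               cbind(m12, F[, 2], m23),
               cbind(m31, m23, F[, 3]),
               cbind(m12, m23, m31))
  }
  orient_outward(surface_mesh(V * radius, F))
}
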