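# Pure-R brute-force oracles, independent of the compiled kernels.

# distance from one point to every triangle of a mesh (projection +
# edge-clamping, vectorized over triangles)
r_point_mesh_distances <- function(mesh, p) {
  V <- mesh$vertices
  F <- mesh$triangles
  A <- V[F[, 1], , drop = FALSE]
  B <- V[F[, 2], , drop = FALSE]
  C <- V[F[, 3], , drop = FALSE]
  e1 <- B - A; e2 <- C - A
  d <- matrix(p, nrow(A), 3, byrow = TRUE) - A
  a <- rowSums(e1 * e1); b <- rowSums(e1 * e2); cc <- rowSums(e2 * e2)
  pp <- rowSums(e1 * d); qq <- rowSums(e2 * d)
  det <- a * cc - b * b
  u <- (cc * pp - b * qq) / det
  v <- (a * qq - b * pp) / det
  inside <- is.finite(u) & is.finite(v) & u >= 0 & v >= 0 & (u + v) <= 1
  face <- rep(Inf, nrow(A))
  if (any(inside)) {
    resid <- d[inside, , drop = FALSE] -
      u[inside] * e1[inside, , drop = FALSE] -
      v[inside] * e2[inside, , drop = FALSE]
    face[inside] <- sqrt(rowSums(resid^2))
  }
  seg_dist <- function(P0, E, d0) {
    t <- rowSums(E * d0) / rowSums(E * E)
    t <- pmin(pmax(t, 0), 1)
    sqrt(rowSums((d0 - t * E)^2))
  }
  dAB <- seg_dist(A, e1, d)
  dAC <- seg_dist(A, e2, d)
  dBC <- seg_dist(B, C - B, matrix(p, nrow(B), 3, byrow = TRUE) - B)
  pmin(face, dAB, dAC, dBC)
}

r_min_distance <- function(mesh, points) {
  apply(points, 1, function(p) min(r_point_mesh_distances(mesh, p)))
}

# distances along a unit ray from the origin to every hull triangle it hits
# (plain-R Moller-Trumbore, vectorized over triangles)
r_ray_mesh_radius <- function(mesh, dir) {
  V <- mesh$vertices
  F <- mesh$triangles
  A <- V[F[, 1], , drop = FALSE]
  B <- V[F[, 2], , drop = FALSE]
  C <- V[F[, 3], , drop = FALSE]
  e1 <- B - A; e2 <- C - A
  cross_rows <- function(X, Y)
    cbind(X[, 2] * Y[, 3] - X[, 3] * Y[, 2],
          X[, 3] * Y[, 1] - X[, 1] * Y[, 3],
          X[, 1] * Y[, 2] - X[, 2] * Y[, 1])
  pv <- cross_rows(matrix(dir, nrow(A), 3, byrow = TRUE), e2)
  det <- rowSums(e1 * pv)
  tv <- -A
  u <- rowSums(tv * pv) / det
  qv <- cross_rows(tv, e1)
  v <- rowSums(matrix(dir, nrow(A), 3, byrow = TRUE) * qv) / det
  t <- rowSums(e2 * qv) / det
  ok <- is.finite(t) & abs(det) > 1e-12 & u >= -1e-9 & v >= -1e-9 &
    (u + v) <= 1 + 1e-9 & t > 1e-9
  t[ok]
}

# minimum distance between two point sets (plain R)
r_pointset_min_dist <- function(P, Q) {
  m <- Inf
  for (i in seq_len(nrow(P)))
    m <- min(m, sqrt(min(colSums((t(Q) - P[i, ])^2))))
  m
}

# planar grid mesh in the z = 0 plane (nx x ny cells of size `spacing` mm)
flat_grid_mesh <- function(nx = 40, ny = 40, spacing = 1) {
  xs <- seq(0, nx) * spacing
  ys <- seq(0, ny) * spacing
  V <- as.matrix(expand.grid(x = xs, y = ys))
  V <- cbind(V, 0)
  idx <- function(i, j) (j - 1) * (nx + 1) + i
  tri <- list()
  k <- 0
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      k <- k + 1
      tri[[k]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
      k <- k + 1
      tri[[k]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
    }
  }
  surface_mesh(V, do.call(rbind, tri))
}

# equilateral-triangle grid in the z = 0 plane: edge-adjacency rings grow as
# hexagons, so fixed-area patches are close to planar disks
tri_grid_mesh <- function(nx = 50, ny = 50, spacing = 1) {
  h <- spacing * sqrt(3) / 2
  rows <- lapply(seq(0, ny), function(j)
    cbind(seq(0, nx) * spacing + (j %% 2) * spacing / 2, j * h, 0))
  V <- do.call(rbind, rows)
  idx <- function(i, j) (j - 1) * (nx + 1) + i
  tri <- list(); k <- 0
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      if (j %% 2 == 1) {
        k <- k + 1; tri[[k]] <- c(idx(i, j), idx(i + 1, j), idx(i, j + 1))
        k <- k + 1; tri[[k]] <- c(idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1))
      } else {
        k <- k + 1; tri[[k]] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
        k <- k + 1; tri[[k]] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
      }
    }
  }
  surface_mesh(V, do.call(rbind, tri))
}

# shared medium-size fixtures, built once per test run
.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

fixture_head3 <- function() fixture("head3", function()
  make_synthetic_head(synthetic_head_spec(mesh_subdivision = 3)))

fixture_sulci3 <- function() fixture("sulci3", function()
  derive_sulci_surface(fixture_head3()$cortex))

# step decay law: strong voltage inside 20 mm, weak beyond
step_law_20mm <- function(d) ifelse(d < 20, 600, 100)

# toy optimizer instance: 3 electrodes x 10 patches with known coverage
# (A covers patches 1-6, B 5-8, C 7-10 at >= 2 contacts and 600 uV)
toy_abc_patch_lf <- function() {
  M <- matrix(0, 6, 10)   # 3 electrodes x 2 contacts each
  cover <- list(A = 1:6, B = 5:8, C = 7:10)
  for (e in seq_along(cover)) {
    rows <- (2 * e - 1):(2 * e)
    M[rows, cover[[e]]] <- 600
  }
  list(
    plf = structure(list(matrix = M, patch_area = NA, moment_density = NA,
                         patch_centers = 1:10,
                         patch_center_positions = cbind(1:10, 0, 0),
                         contact_positions = matrix(0, 6, 3)),
                    class = "seeg_patch_lead_field"),
    contact_rows = rbind(c(1, 2), c(3, 4), c(5, 6)))
}

# minimal trajectory-set wrapper around explicit contact rows (no geometry)
toy_trajectory_set <- function(n, collision = NULL) {
  traj <- data.frame(line_id = seq_len(n), entry_x = 0, entry_y = 0,
                     entry_z = 0, dir_x = 0, dir_y = 0, dir_z = 1,
                     tip_depth = 52.5, length = 52.5)
  if (is.null(collision)) collision <- matrix(FALSE, n, n)
  structure(list(trajectories = traj, collision = collision,
                 validity_log = NULL, electrode = electrode_spec(2, 2, 1.5),
                 shaft_samples = 8),
            class = "seeg_trajectory_set")
}
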