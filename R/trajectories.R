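#' Depth-electrode geometry
#'
#' A 16-contact depth electrode with 2 mm contacts and 1.5 mm insulators
#' (3.5 mm centre-to-centre pitch); each contact is reduced to a single
#' recording point at its centre.
#'
#' @param n_contacts number of contacts (>= 2).
#' @param contact_length contact length (mm).
#' @param insulator_length insulator length (mm).
#' @return object of class `seeg_electrode_spec` with derived `pitch` and
#'   `span` (distance from first to last contact centre).
#' @export
electrode_spec <- function(n_contacts = 16, contact_length = 2,
                           insulator_length = 1.5) {
  if (n_contacts < 2) stop("n_contacts must be >= 2")
  pitch <- contact_length + insulator_length
  structure(list(n_contacts = as.integer(n_contacts),
                 contact_length = contact_length,
                 insulator_length = insulator_length,
                 pitch = pitch, span = (n_contacts - 1) * pitch),
            class = "seeg_electrode_spec")
}

#' Sample electrode insertion points on the scalp
#'
#' Area-weighted random sample of points on the scalp triangles whose
#' centroid direction lies inside the entry cap, with the inward surface
#' normal attached.
#'
#' @param scalp scalp `seeg_mesh`.
#' @param entry_cap list with `axis` and `half_angle` (degrees).
#' @param n number of entries (default 800).
#' @param seed RNG seed.
#' @param center head centre (mm).
#' @return list with `points` (n x 3), `normals` (inward, n x 3),
#'   `triangle` indices.
#' @export
sample_entries <- function(scalp, entry_cap, n = 800, seed = 1L,
                           center = c(0, 0, 0)) {
  d <- scalp$centroids - matrix(center, nrow(scalp$centroids), 3, byrow = TRUE)
  d <- d / sqrt(rowSums(d^2))
  cap <- as.vector(d %*% unit(entry_cap$axis)) >= cos(deg2rad(entry_cap$half_angle))
  if (!any(cap)) stop("entry cap does not intersect the scalp")
  idx <- which(cap)
  with_seed(seed, {
    tri <- idx[sample.int(length(idx), n, replace = TRUE,
                          prob = scalp$areas[idx])]
    # uniform point in each triangle (sqrt trick on barycentric coords)
    r1 <- sqrt(runif(n)); r2 <- runif(n)
    a <- scalp$vertices[scalp$triangles[tri, 1], , drop = FALSE]
    b <- scalp$vertices[scalp$triangles[tri, 2], , drop = FALSE]
    c_ <- scalp$vertices[scalp$triangles[tri, 3], , drop = FALSE]
    pts <- (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * c_
    list(points = pts, normals = -scalp$normals[tri, , drop = FALSE],
         triangle = tri)
  })
}

#' Sample insertion directions within a cone about the inward normal
#'
#' Deterministic Fibonacci spiral covering the spherical cap of half-angle
#' `max_angle` about `normal`, with an optional seeded random rotation of
#' the spiral about the axis.
#'
#' @param normal inward scalp normal (unit).
#' @param max_angle cone half-angle in degrees (default 10).
#' @param n number of directions (default 366).
#' @param seed optional seed for the spiral rotation; NULL keeps the pure
#'   spiral.
#' @return n x 3 matrix of unit vectors.
#' @export
sample_directions <- function(normal, max_angle = 10, n = 366, seed = NULL) {
  normal <- unit(normal)
  if (max_angle == 0) return(matrix(normal, n, 3, byrow = TRUE))
  cmin <- cos(deg2rad(max_angle))
  k <- seq_len(n)
  z <- 1 - (k - 0.5) / n * (1 - cmin)
  golden <- pi * (3 - sqrt(5))
  rot <- if (is.null(seed)) 0 else with_seed(seed, runif(1, 0, 2 * pi))
  phi <- k * golden + rot
  s <- sqrt(pmax(1 - z^2, 0))
  b <- plane_basis(normal)
  t(vapply(k, function(i)
    z[i] * normal + s[i] * (cos(phi[i]) * b$u + sin(phi[i]) * b$v),
    numeric(3)))
}

#' Discretize an electrode line into insertion depths
#'
#' Along a line (entry + direction), tip depths are the multiples of the
#' contact pitch from the electrode span up to `max_length`; consecutive
#' depths therefore share all but one contact point on a common 3.5 mm
#' lattice. Contacts are placed tip-first: the deepest contact centre sits
#' at the tip.
#'
#' @param entry entry point (mm).
#' @param direction unit insertion direction (into the head).
#' @param electrode an [electrode_spec()].
#' @param max_length maximum entry-to-tip length (mm, default 100).
#' @param step depth step (mm; default the contact pitch).
#' @param line_id integer id shared by all depths of this line.
#' @return data.frame with one row per trajectory: `line_id`, `entry_*`,
#'   `dir_*`, `tip_depth`, `length`.
#' @export
discretize_depths <- function(entry, direction, electrode = electrode_spec(),
                              max_length = 100, step = electrode$pitch,
                              line_id = 1L) {
  direction <- unit(direction)
  if (max_length < electrode$span)
    return(data.frame(line_id = integer(0), entry_x = numeric(0),
                      entry_y = numeric(0), entry_z = numeric(0),
                      dir_x = numeric(0), dir_y = numeric(0),
                      dir_z = numeric(0), tip_depth = numeric(0),
                      length = numeric(0)))
  depths <- seq(electrode$span, max_length, by = step)
  data.frame(line_id = as.integer(line_id), entry_x = entry[1],
             entry_y = entry[2], entry_z = entry[3],
             dir_x = direction[1], dir_y = direction[2], dir_z = direction[3],
             tip_depth = depths, length = depths)
}

#' Contact centre points of trajectories
#'
#' @param traj data.frame of trajectories (rows from [discretize_depths()]).
#' @param electrode an [electrode_spec()].
#' @return 3-d array n_traj x n_contacts x 3 (mm); contacts ordered from
#'   tip outward.
#' @export
trajectory_contacts <- function(traj, electrode = electrode_spec()) {
  offs <- traj$tip_depth
  n <- nrow(traj)
  out <- array(NA_real_, c(n, electrode$n_contacts, 3))
  E <- as.matrix(traj[, c("entry_x", "entry_y", "entry_z")])
  D <- as.matrix(traj[, c("dir_x", "dir_y", "dir_z")])
  for (k in seq_len(electrode$n_contacts)) {
    depth <- offs - (k - 1) * electrode$pitch
    out[, k, ] <- E + D * depth
  }
  out
}

#' Shaft sample points of trajectories
#'
#' The 128-point representation of each electrode shaft (evenly spaced from
#' entry to tip) used by the clearance filters and collision tests.
#'
#' @param traj trajectory data.frame.
#' @param n_samples points per shaft (default 128).
#' @return 3-d array n_traj x n_samples x 3 (mm).
#' @export
trajectory_shaft_points <- function(traj, n_samples = 128) {
  n <- nrow(traj)
  out <- array(NA_real_, c(n, n_samples, 3))
  E <- as.matrix(traj[, c("entry_x", "entry_y", "entry_z")])
  D <- as.matrix(traj[, c("dir_x", "dir_y", "dir_z")])
  frac <- seq(0, 1, length.out = n_samples)
  for (k in seq_len(n_samples))
    out[, k, ] <- E + D * (traj$tip_depth * frac[k])
  out
}

#' Generate candidate trajectories on a head model
#'
#' Entries are sampled in the head's entry cap, directions within the
#' insertion cone about each inward normal, and each line is discretized
#' into pitch-spaced insertion depths.
#'
#' @param head a `seeg_head`.
#' @param n_entries number of scalp entry points.
#' @param n_angles insertion directions per entry (366 at full scale).
#' @param max_angle insertion cone half-angle (degrees, default 10).
#' @param electrode an [electrode_spec()].
#' @param max_length maximum trajectory length (mm).
#' @param seed RNG seed.
#' @return trajectory data.frame (one row per candidate).
#' @export
candidate_trajectories <- function(head, n_entries = 800, n_angles = 366,
                                   max_angle = 10,
                                   electrode = electrode_spec(),
                                   max_length = 100, seed = 1L) {
  entries <- sample_entries(head$scalp, head$entry_cap, n_entries, seed = seed)
  out <- vector("list", n_entries * n_angles)
  line <- 0L
  for (i in seq_len(n_entries)) {
    dirs <- sample_directions(entries$normals[i, ], max_angle, n_angles,
                              seed = seed + i)
    for (j in seq_len(n_angles)) {
      line <- line + 1L
      out[[line]] <- discretize_depths(entries$points[i, ], dirs[j, ],
                                       electrode, max_length,
                                       line_id = line)
    }
  }
  do.call(rbind, out)
}

#' Apply the safety filters to candidate trajectories
#'
#' Rejects trajectories whose 128-point shaft passes within
#' `sulci_clearance` of the sulci surface, within `skull_clearance` of the
#' inner skull (evaluated away from the insertion site, i.e. for shaft
#' points deeper than `skull_skip` from the entry), or within
#' `midline_clearance` of the midline plane.
#'
#' @param traj trajectory data.frame.
#' @param sulci sulci `seeg_mesh` (may have zero triangles).
#' @param skull inner-skull `seeg_mesh`.
#' @param midline a [plane()].
#' @param sulci_clearance,skull_clearance,midline_clearance clearances (mm).
#' @param skull_skip entry-region depth excluded from the skull test (mm).
#' @param shaft_samples shaft points per electrode (default 128).
#' @param electrode an [electrode_spec()].
#' @return object of class `seeg_trajectory_set`: `trajectories` (kept
#'   rows), `collision` (NULL until [collision_matrix()]), `validity_log`
#'   (data.frame with the rejection reason per candidate), `electrode`,
#'   `shaft_samples`.
#' @export
filter_valid <- function(traj, sulci, skull, midline,
                         sulci_clearance = 1.5, skull_clearance = 4,
                         midline_clearance = 4, skull_skip = 10,
                         shaft_samples = 128, electrode = electrode_spec()) {
  n <- nrow(traj)
  pts <- trajectory_shaft_points(traj, shaft_samples)
  # row order: all shaft samples of trajectory 1, then trajectory 2, ...
  flat <- matrix(aperm(pts, c(2, 1, 3)), n * shaft_samples, 3)
  depth <- rep(seq(0, 1, length.out = shaft_samples), times = n) *
    rep(traj$tip_depth, each = shaft_samples)
  per_traj_any <- function(flag)
    colSums(matrix(flag, shaft_samples, n)) > 0

  reason <- rep(NA_character_, n)
  if (nrow(sulci$triangles) > 0) {
    ds <- min_distance(distance_index(sulci), flat)
    reason[is.na(reason) & per_traj_any(ds < sulci_clearance)] <- "sulci"
  }
  dk <- min_distance(distance_index(skull), flat)
  dk[depth <= skull_skip] <- Inf
  reason[is.na(reason) & per_traj_any(dk < skull_clearance)] <- "skull"
  dm <- plane_distance(midline, flat)
  reason[is.na(reason) & per_traj_any(dm < midline_clearance)] <- "midline"

  keep <- is.na(reason)
  structure(list(trajectories = traj[keep, , drop = FALSE],
                 collision = NULL,
                 validity_log = data.frame(line_id = traj$line_id,
                                           tip_depth = traj$tip_depth,
                                           reason = reason),
                 electrode = electrode, shaft_samples = shaft_samples),
            class = "seeg_trajectory_set")
}

#' @export
print.seeg_trajectory_set <- function(x, ...) {
  cat(sprintf("seeg_trajectory_set: %d valid trajectories on %d lines%s\n",
              nrow(x$trajectories), length(unique(x$trajectories$line_id)),
              if (!is.null(x$collision))
                sprintf(", %d colliding pairs", sum(x$collision) / 2) else ""))
  invisible(x)
}

#' Pairwise collision matrix of a trajectory set
#'
#' Two electrodes collide when the minimum distance between their 128-point
#' shaft representations is below the threshold (4 mm). The exact
#' segment-segment distance is used as a lower bound to skip pairs that
#' cannot collide; flagged pairs are confirmed point-by-point, so the result
#' equals the brute-force all-pairs computation.
#'
#' @param ts a `seeg_trajectory_set` (or trajectory data.frame).
#' @param threshold collision distance (mm, default 4).
#' @param samples_per_electrode shaft points per electrode (default 128).
#' @return the trajectory set with `collision` filled (symmetric logical
#'   matrix, FALSE diagonal); for a data.frame input, the matrix itself.
#' @export
collision_matrix <- function(ts, threshold = 4, samples_per_electrode = 128) {
  traj <- if (inherits(ts, "seeg_trajectory_set")) ts$trajectories else ts
  if (nrow(traj) < 2) stop("need at least two trajectories")
  pts <- trajectory_shaft_points(traj, samples_per_electrode)
  # one electrode per row as x,y,z triples per shaft sample
  flat <- matrix(NA_real_, nrow(traj), samples_per_electrode * 3)
  for (k in seq_len(samples_per_electrode))
    flat[, (3 * (k - 1) + 1):(3 * k)] <- pts[, k, ]
  cm <- cpp_collision_matrix(flat, threshold)
  if (inherits(ts, "seeg_trajectory_set")) { ts$collision <- cm; ts } else cm
}

#' Randomly thin a trajectory set to a target size, whole lines at a time
#'
#' @param ts a `seeg_trajectory_set`.
#' @param target maximum number of trajectories to keep.
#' @param seed RNG seed.
#' @return thinned `seeg_trajectory_set` (collision matrix subset
#'   accordingly).
#' @export
downsample_lines <- function(ts, target, seed = 1L) {
  traj <- ts$trajectories
  if (nrow(traj) <= target) return(ts)
  with_seed(seed, {
    lines <- unique(traj$line_id)
    drop <- character(0)
    count <- nrow(traj)
    lines <- lines[sample.int(length(lines))]
    li <- 1L
    keep_mask <- rep(TRUE, nrow(traj))
    while (count > target && li <= length(lines)) {
      sel <- traj$line_id == lines[li]
      keep_mask[sel] <- FALSE
      count <- count - sum(sel)
      li <- li + 1L
    }
    ts$trajectories <- traj[keep_mask, , drop = FALSE]
    if (!is.null(ts$collision))
      ts$collision <- ts$collision[keep_mask, keep_mask, drop = FALSE]
    ts
  })
}

#' Unique contact lattice of a trajectory set
#'
#' Trajectories on the same line share pitch-lattice contact points; this
#' collapses all contacts to the unique point set and records, per
#' trajectory, the row of each of its contacts.
#'
#' @param ts a `seeg_trajectory_set` (or trajectory data.frame).
#' @param electrode an [electrode_spec()].
#' @param digits rounding used to identify shared lattice points (decimal
#'   mm digits).
#' @return list with `points` (m x 3 unique contacts) and `rows`
#'   (n_traj x n_contacts matrix of indices into `points`).
#' @export
contact_table <- function(ts, electrode = NULL, digits = 6) {
  traj <- if (inherits(ts, "seeg_trajectory_set")) ts$trajectories else ts
  if (is.null(electrode))
    electrode <- if (inherits(ts, "seeg_trajectory_set")) ts$electrode
                 else electrode_spec()
  cp <- trajectory_contacts(traj, electrode)
  n <- nrow(traj); k <- electrode$n_contacts
  flat <- matrix(cp, n * k, 3)   # row (i + n*(j-1)) = traj i, contact j
  key <- paste(round(flat[, 1], digits), round(flat[, 2], digits),
               round(flat[, 3], digits))
  uk <- unique(key)
  rows <- matrix(match(key, uk), n, k)
  list(points = flat[match(uk, key), , drop = FALSE], rows = rows)
}
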