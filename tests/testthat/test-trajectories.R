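test_that("electrode geometry: pitch is contact plus insulator length", {
  el <- electrode_spec()
  expect_equal(el$pitch, 3.5)
  expect_equal(el$span, 52.5)
  expect_equal(el$n_contacts, 16L)
  expect_error(electrode_spec(n_contacts = 1))
})

test_that("entry sampling stays in the cap and is reproducible", {
  scalp <- icosphere(92, 3)
  cap <- list(axis = c(1, 0, 0), half_angle = 40)
  e1 <- sample_entries(scalp, cap, n = 50, seed = 3)
  e2 <- sample_entries(scalp, cap, n = 50, seed = 3)
  expect_identical(e1$points, e2$points)
  dirs <- e1$points / sqrt(rowSums(e1$points^2))
  ang <- acos(pmin(dirs %*% c(1, 0, 0), 1)) * 180 / pi
  expect_true(all(ang <= 40 + 3))   # cap membership up to one facet size
  expect_equal(nrow(sample_entries(scalp, cap, n = 1, seed = 1)$points), 1L)
  # inward normals point toward the head centre
  expect_true(all(rowSums(e1$points * e1$normals) < 0))
  expect_error(sample_entries(scalp, list(axis = c(1, 0, 0), half_angle = 40),
                              n = 5, center = c(500, 0, 0)))
})

test_that("direction sampling covers the insertion cone", {
  n <- c(0, 0, -1)
  d0 <- sample_directions(n, max_angle = 0, n = 10)
  expect_equal(d0, matrix(n, 10, 3, byrow = TRUE))
  d <- sample_directions(n, max_angle = 10, n = 366, seed = 4)
  expect_equal(nrow(d), 366L)
  expect_equal(rowSums(d^2), rep(1, 366), tolerance = 1e-12)
  ang <- acos(pmin(d %*% n, 1)) * 180 / pi
  expect_true(all(ang <= 10 + 1e-9))
  expect_gt(max(ang), 8)   # the spiral reaches the cone boundary
})

test_that("depth discretization lies on the 3.5 mm lattice", {
  el <- electrode_spec()
  tr <- discretize_depths(c(92, 0, 0), c(-1, 0, 0), el, max_length = 100)
  expect_equal(nrow(tr), 14L)    # floor((100 - 52.5)/3.5) + 1
  expect_equal(tr$tip_depth, seq(52.5, 98, by = 3.5))
  expect_true(all(tr$length < 100))
  cp <- trajectory_contacts(tr, el)
  # contact pitch is exactly 3.5 mm along the shaft
  gaps <- sqrt(rowSums((cp[1, -1, ] - cp[1, -16, ])^2))
  expect_equal(gaps, rep(3.5, 15), tolerance = 1e-12)
  # consecutive depths share 15 of 16 contact points
  shared <- sum(apply(cp[1, , ], 1, function(p)
    any(sqrt(rowSums((cp[2, , , drop = TRUE] -
      matrix(p, 16, 3, byrow = TRUE))^2)) < 1e-9)))
  expect_equal(shared, 15L)
  expect_equal(nrow(discretize_depths(c(92, 0, 0), c(-1, 0, 0), el,
                                      max_length = 52.5)), 1L)
  expect_equal(nrow(discretize_depths(c(92, 0, 0), c(-1, 0, 0), el,
                                      max_length = 50)), 0L)
})

test_that("safety filters reject the right trajectories for the right reason", {
  skull <- icosphere(87, 2)
  midline <- plane(c(0, 0, 0), c(1, 0, 0))
  el <- electrode_spec()
  # a small sulci wall at x = 30 crossing one trajectory's path
  sulci <- surface_mesh(rbind(c(30, -20, -20), c(30, 20, -20), c(30, 0, 25)),
                        rbind(1:3))
  hit <- discretize_depths(c(92, 0, 0), c(-1, 0, 0), el, 100)[10, ]  # deep
  e2 <- 92 * unit(c(1, 0.9, 0))    # radial entry passing wide of the wall
  miss <- discretize_depths(e2, -unit(e2), el, 100)[1, ]
  ts <- filter_valid(rbind(hit, miss), sulci, skull, midline)
  expect_equal(ts$validity_log$reason, c("sulci", NA))
  expect_equal(nrow(ts$trajectories), 1L)

  # parallel to the midline at 10 mm: retained; crossing within 4 mm: rejected
  par10 <- discretize_depths(c(10, 90, 0), c(0, -1, 0), el, 100)[1, ]
  par2 <- discretize_depths(c(2, 90, 0), c(0, -1, 0), el, 100)[1, ]
  empty_sulci <- surface_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  ts2 <- filter_valid(rbind(par10, par2), empty_sulci, skull, midline)
  expect_equal(ts2$validity_log$reason, c(NA, "midline"))

  # zero clearances retain everything interior
  ts3 <- filter_valid(rbind(hit, miss, par10, par2), sulci, skull, midline,
                      sulci_clearance = 0, skull_clearance = 0,
                      midline_clearance = 0)
  expect_equal(nrow(ts3$trajectories), 4L)
})

test_that("collision matrix equals brute-force over the same 128 points", {
  el <- electrode_spec()
  mk <- function(entry, dir) discretize_depths(entry, dir, el, 100)[5, ]
  same <- mk(c(92, 0, 0), c(-1, 0, 0))
  near3 <- mk(c(92, 3, 0), c(-1, 0, 0))
  far5 <- mk(c(92, 5, 0), c(-1, 0, 0))
  cm <- collision_matrix(rbind(same, same, near3, far5))
  expect_true(cm[1, 2])              # identical shafts collide
  expect_true(cm[1, 3])              # 3 mm parallel offset collides
  expect_false(cm[1, 4])             # 5 mm does not
  expect_true(isSymmetric(cm))
  expect_true(all(diag(cm) == FALSE))

  # randomized audit against a plain-R all-pairs computation
  set.seed(6)
  rows <- lapply(1:30, function(i) {
    entry <- c(92, runif(1, -30, 30), runif(1, -30, 30))
    dir <- unit(c(-1, runif(2, -0.2, 0.2)))
    discretize_depths(entry, dir, el, 100, line_id = i)[sample(1:14, 1), ]
  })
  traj <- do.call(rbind, rows)
  cm2 <- collision_matrix(traj)
  pts <- trajectory_shaft_points(traj, 128)
  for (i in 1:29) for (j in (i + 1):30) {
    ref <- r_pointset_min_dist(pts[i, , ], pts[j, , ]) < 4
    expect_identical(cm2[i, j], ref)
  }
})

test_that("line downsampling is seeded, line-atomic and size-bounded", {
  el <- electrode_spec()
  traj <- do.call(rbind, lapply(1:10, function(i)
    discretize_depths(c(92, 2 * i, 0), c(-1, 0, 0), el, 100, line_id = i)))
  ts <- structure(list(trajectories = traj, collision = NULL,
                       validity_log = NULL, electrode = el,
                       shaft_samples = 128),
                  class = "seeg_trajectory_set")
  expect_identical(downsample_lines(ts, 1000, seed = 1), ts)  # no-op
  a <- downsample_lines(ts, 60, seed = 5)
  b <- downsample_lines(ts, 60, seed = 5)
  expect_identical(a$trajectories, b$trajectories)
  expect_lte(nrow(a$trajectories), 60)
  # whole lines removed together: surviving lines keep all 14 depths
  expect_true(all(table(a$trajectories$line_id) == 14L))
})

test_that("every emitted valid trajectory independently re-passes the constraints", {
  head <- fixture_head3()
  sul <- fixture_sulci3()
  cand <- candidate_trajectories(head, n_entries = 10, n_angles = 4, seed = 2)
  ts <- filter_valid(cand, sul, head$skull, head$midline)
  traj <- ts$trajectories
  expect_gt(nrow(traj), 0)
  # angle <= 10 degrees from the inward normal of the entry's scalp facet
  for (i in seq_len(min(nrow(traj), 50))) {
    entry <- as.numeric(traj[i, c("entry_x", "entry_y", "entry_z")])
    dirv <- as.numeric(traj[i, c("dir_x", "dir_y", "dir_z")])
    tri <- which.min(r_point_mesh_distances(head$scalp, entry))
    inward <- -head$scalp$normals[tri, ]
    expect_lte(acos(min(sum(dirv * inward), 1)) * 180 / pi, 10 + 1e-6)
  }
  expect_true(all(traj$length < 100))
  pts <- trajectory_shaft_points(traj, 128)
  flat <- matrix(aperm(pts, c(2, 1, 3)), ncol = 3)
  expect_true(all(min_distance(distance_index(sul), flat) >= 1.5))
  expect_true(all(abs(flat[, 1]) >= 4))     # midline x = 0 clearance
})
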