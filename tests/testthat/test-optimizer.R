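test_that("greedy search solves the three-electrode covering toy exactly", {
  toy <- toy_abc_patch_lf()
  ts <- toy_trajectory_set(3)
  cfg <- next_best_search(ts, toy$plf, roi(1:10), toy$contact_rows,
                          priority = c(500, 200, 1000), seed = 1)
  expect_identical(cfg$electrodes, c(1L, 3L))   # A (gain 6) then C (gain 4)
  expect_equal(unname(cfg$cost_curve[, "500"]), c(4, 0))
  # full coverage after two electrodes
  expect_equal(unname(cfg$rs_report$rs_by_count[2, "500"]), 100)
})

test_that("best ordering of a fixed set follows greedy gains", {
  toy <- toy_abc_patch_lf()
  bo <- best_order(toy$contact_rows, toy$plf, roi(1:10), thr = 500, seed = 1)
  expect_identical(bo$order, c(1L, 3L, 2L))   # A, C, then B adds nothing
  expect_equal(bo$rs_curve, c(60, 100, 100))
  # ordering does not change the final RS of the set
  expect_equal(bo$rs_curve[3], 100)
  single <- best_order(toy$contact_rows[2, , drop = FALSE], toy$plf,
                       roi(1:10), 500)
  expect_identical(single$order, 1L)
  expect_error(best_order(toy$contact_rows[0, , drop = FALSE], toy$plf,
                          roi(1:10), 500), "empty")
})

test_that("the first greedy pick equals the exhaustive best single electrode", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 8; p <- 30
    M <- matrix(rexp(2 * n * p, 1 / 400), 2 * n, p)
    plf <- structure(list(matrix = M, patch_centers = seq_len(p),
                          patch_center_positions = cbind(seq_len(p), 0, 0),
                          contact_positions = matrix(0, 2 * n, 3)),
                     class = "seeg_patch_lead_field")
    rows <- matrix(seq_len(2 * n), n, 2, byrow = TRUE)
    ts <- toy_trajectory_set(n)
    cfg <- next_best_search(ts, plf, roi(seq_len(p)), rows,
                            priority = c(500, 200, 1000), seed = rep)
    cover <- vapply(seq_len(n), function(i)
      sum(colSums(M[rows[i, ], , drop = FALSE] >= 500) >= 2), integer(1))
    if (max(cover) == 0) {
      expect_length(cfg$electrodes, 0L)
    } else {
      expect_equal(cover[cfg$electrodes[1]], max(cover))
    }
  }
})

test_that("greedy never beats but stays close to the exhaustive optimum", {
  set.seed(33)
  gaps <- numeric(0)
  for (rep in 1:4) {
    n <- 10; p <- 40
    M <- matrix(rexp(2 * n * p, 1 / 350), 2 * n, p)
    plf <- structure(list(matrix = M, patch_centers = seq_len(p),
                          patch_center_positions = cbind(seq_len(p), 0, 0),
                          contact_positions = matrix(0, 2 * n, 3)),
                     class = "seeg_patch_lead_field")
    rows <- matrix(seq_len(2 * n), n, 2, byrow = TRUE)
    ts <- toy_trajectory_set(n)
    cfg <- next_best_search(ts, plf, roi(seq_len(p)), rows,
                            priority = c(500, 200, 1000),
                            max_electrodes = 3, seed = rep)
    k <- min(3, max(1, length(cfg$electrodes)))
    greedy_cost <- if (length(cfg$electrodes))
      cfg$cost_curve[length(cfg$electrodes), "500"] else p
    R <- vapply(seq_len(n), function(i)
      colSums(M[rows[i, ], , drop = FALSE] >= 500) >= 2, logical(p))
    combos <- combn(n, k)
    best <- min(apply(combos, 2, function(cc)
      p - sum(rowSums(R[, cc, drop = FALSE]) > 0)))
    expect_gte(greedy_cost, best)     # greedy is not better than optimal
    gaps <- c(gaps, greedy_cost - best)
  }
  # report the optimality gap observed on these instances
  expect_true(all(gaps >= 0))
  message(sprintf("greedy vs exhaustive cost gaps over 4 instances: %s",
                  paste(gaps, collapse = ", ")))
})

test_that("configurations never contain colliding pairs", {
  set.seed(44)
  n <- 12; p <- 50
  M <- matrix(rexp(2 * n * p, 1 / 500), 2 * n, p)
  plf <- structure(list(matrix = M, patch_centers = seq_len(p),
                        patch_center_positions = cbind(seq_len(p), 0, 0),
                        contact_positions = matrix(0, 2 * n, 3)),
                   class = "seeg_patch_lead_field")
  rows <- matrix(seq_len(2 * n), n, 2, byrow = TRUE)
  collide <- matrix(FALSE, n, n)
  for (i in seq(1, n - 1, by = 2)) collide[i, i + 1] <- collide[i + 1, i] <- TRUE
  ts <- toy_trajectory_set(n, collision = collide)
  cfg <- next_best_search(ts, plf, roi(seq_len(p)), rows, seed = 2)
  for (a in cfg$electrodes) for (b in cfg$electrodes)
    expect_false(collide[a, b])
  # cost strictly decreases at the primary threshold until termination
  costs <- cfg$cost_curve[, 1]
  if (length(costs) > 1) expect_true(all(diff(costs) < 0))
})

test_that("RS curves are monotone with correctly ordered thresholds", {
  set.seed(55)
  n <- 8; p <- 60
  M <- matrix(rexp(2 * n * p, 1 / 450), 2 * n, p)
  plf <- structure(list(matrix = M, patch_centers = seq_len(p),
                        patch_center_positions = cbind(seq_len(p), 0, 0),
                        contact_positions = matrix(0, 2 * n, 3)),
                   class = "seeg_patch_lead_field")
  rows <- matrix(seq_len(2 * n), n, 2, byrow = TRUE)
  cfg <- next_best_search(toy_trajectory_set(n), plf, roi(seq_len(p)), rows,
                          seed = 3)
  rs <- cfg$rs_report$rs_by_count
  expect_gt(nrow(rs), 0)
  for (j in seq_len(ncol(rs)))
    expect_true(all(diff(rs[, j]) >= 0))
  expect_true(all(rs[, "200"] >= rs[, "500"]))
  expect_true(all(rs[, "500"] >= rs[, "1000"]))
  # the curve endpoint equals the module-level RS of the full set
  electrodes <- lapply(seq_len(nrow(cfg$contact_rows)), function(i)
    cfg$contact_rows[i, ])
  expect_equal(unname(rs[nrow(rs), "500"]),
               recording_sensitivity(plf, electrodes, roi(seq_len(p)), 500))
})

test_that("electrode-in-ROI uses the near-contact and half-of-contacts rules", {
  surf <- icosphere(30, 2)
  el <- electrode_spec()
  on_surface <- discretize_depths(c(30, 0, 0), c(-1, 0, 0), el, 100)[1, ]
  cp_on <- trajectory_contacts(on_surface, el)[1, , ]
  expect_true(electrode_in_roi(cp_on, surf))
  # nearest contact 5 mm away fails the 3 mm clause
  cp_far <- cp_on + matrix(c(0, 0, 35.2), 16, 3, byrow = TRUE)
  d <- min_distance(surf, cp_far)
  expect_gt(min(d), 3)
  expect_false(electrode_in_roi(cp_far, surf))
  # half rule: 1 contact near but fewer than 8 within `far`
  cp_half <- cp_on
  cp_half[2:10, ] <- cp_half[2:10, ] + 150   # 9 contacts pushed beyond 100 mm
  expect_false(electrode_in_roi(cp_half, surf, near = 3, far = 100))
})

test_that("identity transfers reproduce the matched RS exactly", {
  head <- make_synthetic_head(synthetic_head_spec(mesh_subdivision = 2,
                                                  fold_amplitude = 6))
  ctx <- head_context(head, patch_area = 10, smooth_iters = 50)
  # build a small optimized configuration on this head
  cand <- candidate_trajectories(head, n_entries = 8, n_angles = 3, seed = 5)
  ts <- filter_valid(cand, ctx$sulci, head$skull, head$midline)
  ts <- collision_matrix(ts)
  ct <- contact_table(ts)
  lf <- build_lead_field(ctx$sources, ct$points)
  plf <- build_patch_lead_field(lf, ctx$patches, 0.465)
  r <- cap_roi(head$cortex, c(1, 0, 0), 60)
  cfg <- next_best_search(ts, plf, r, ct$rows, max_electrodes = 5, seed = 1)
  expect_gt(length(cfg$electrodes), 0)

  ident <- list(R = diag(3), t = c(0, 0, 0))
  tr <- transfer_configuration(cfg, ident, ctx, r, thr = 500, rs_target = 1)
  expect_equal(tr$rs_transferred, tr$rs_matched, tolerance = 1e-9)
  expect_equal(tr$percent_reduction, 0, tolerance = 1e-9)
  expect_length(tr$electrode_valid, tr$n_at)

  # the n_at rule: smallest prefix reaching the RS target
  rs_curve <- cfg$rs_report$rs_by_count[, "500"]
  tgt <- rs_curve[1] + 1e-9
  tr2 <- transfer_configuration(cfg, ident, ctx, r, thr = 500, rs_target = tgt)
  expect_equal(tr2$n_at,
               min(which(rs_curve >= tgt)))

  # scaled and reflected transforms are rejected
  expect_error(transfer_configuration(cfg, list(R = 2 * diag(3), t = rep(0, 3)),
                                      ctx, r), "rotation")
  refl <- diag(c(-1, 1, 1))
  expect_error(transfer_configuration(cfg, list(R = refl, t = rep(0, 3)),
                                      ctx, r), "rotation")
})

test_that("a rotated transfer is evaluated on the target head's forward model", {
  head <- make_synthetic_head(synthetic_head_spec(mesh_subdivision = 2,
                                                  fold_amplitude = 6))
  ctx <- head_context(head, smooth_iters = 50)
  cand <- candidate_trajectories(head, n_entries = 8, n_angles = 3, seed = 5)
  ts <- collision_matrix(filter_valid(cand, ctx$sulci, head$skull, head$midline))
  ct <- contact_table(ts)
  plf <- build_patch_lead_field(build_lead_field(ctx$sources, ct$points),
                                ctx$patches, 0.465)
  r <- cap_roi(head$cortex, c(1, 0, 0), 60)
  cfg <- next_best_search(ts, plf, r, ct$rows, max_electrodes = 4, seed = 1)
  th <- 10 * pi / 180
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- transfer_configuration(cfg, list(R = rot, t = c(1, -2, 0)), ctx, r,
                               rs_target = 1)
  expect_true(is.finite(tr$rs_transferred))
  expect_length(tr$electrode_valid, tr$n_at)
  expect_type(tr$config_valid, "logical")
})
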