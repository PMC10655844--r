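toy_plf <- function(M, pos = NULL) {
  structure(list(matrix = M, patch_area = NA, moment_density = NA,
                 patch_centers = seq_len(ncol(M)),
                 patch_center_positions = if (is.null(pos))
                   cbind(seq_len(ncol(M)), 0, 0) else pos,
                 contact_positions = matrix(0, nrow(M), 3)),
            class = "seeg_patch_lead_field")
}

test_that("two-contact recordability counts inclusive threshold crossings", {
  plf <- toy_plf(cbind(c(600, 550, 100), c(700, 100, 100), c(500, 500, 499)))
  expect_identical(recordable_by_electrode(plf, 1:3, 500),
                   c(TRUE, FALSE, TRUE))   # third: >= is inclusive
  # negative voltages count by magnitude
  plf2 <- toy_plf(cbind(c(-600, 550, 0)))
  expect_true(recordable_by_electrode(plf2, 1:3, 500))
  expect_error(recordable_by_electrode(plf, c(1, 9), 500), "contact rows")
})

test_that("recording strength counts electrodes and doubles with duplicates", {
  plf <- toy_plf(matrix(c(600, 600, 0, 0,
                          600, 600, 600, 600), 4, 2))
  one <- list(1:2, 3:4)
  expect_identical(recording_strength(plf, one, 500), c(1L, 2L))
  expect_identical(recording_strength(plf, list(), 500), c(0L, 0L))
  expect_identical(recording_strength(plf, c(one, one), 500), c(2L, 4L))
  # brute-force per-electrode enumeration
  set.seed(9)
  M <- matrix(runif(60, 0, 1200), 6, 10)
  plf3 <- toy_plf(M)
  config <- list(1:2, 3:4, 5:6)
  ref <- rowSums(vapply(config, function(el)
    colSums(M[el, , drop = FALSE] >= 500) >= 2, logical(10)))
  expect_equal(recording_strength(plf3, config, 500), as.integer(ref))
})

test_that("RS and cost obey the exact complementarity identity", {
  set.seed(4)
  M <- matrix(runif(160, 0, 1500), 8, 20)
  plf <- toy_plf(M)
  config <- list(1:4, 5:8)
  r <- roi(1:20)
  for (thr in c(200, 500, 1000)) {
    rs <- recording_sensitivity(plf, config, r, thr)
    cc <- rs_cost(plf, config, r, thr)
    expect_equal(rs * 20 / 100 + cc, 20)
  }
  # arithmetic spot checks
  M2 <- matrix(0, 2, 10); M2[, 1:4] <- 600
  plf2 <- toy_plf(M2)
  expect_equal(recording_sensitivity(plf2, list(1:2), roi(1:10), 500), 40)
  expect_equal(rs_cost(plf2, list(1:2), roi(1:10), 500), 6)
  expect_equal(recording_sensitivity(plf2, list(1:2), roi(1:4), 500), 100)
  expect_equal(rs_cost(plf2, list(1:2), roi(1:4), 500), 0)
  expect_equal(recording_sensitivity(plf2, list(), roi(1:10), 500), 0)
  expect_error(recording_sensitivity(plf2, list(1:2), roi(400), 500))
})

test_that("threshold monotonicity: higher thresholds never increase RS", {
  set.seed(5)
  M <- matrix(rexp(200, 1 / 400), 10, 20)
  plf <- toy_plf(M)
  config <- list(1:3, 4:6, 7:10)
  r <- roi(1:20)
  rs <- vapply(c(200, 500, 1000), function(thr)
    recording_sensitivity(plf, config, r, thr), numeric(1))
  expect_true(rs[1] >= rs[2] && rs[2] >= rs[3])
})

test_that("recording radius recovers the step-law fixture exactly", {
  step <- make_toy_leadfield(5, 16, step_law_20mm)
  r <- estimate_recording_radius(step, thr = 500)
  expect_equal(as.numeric(r), 2.0)
  expect_false(attr(r, "no_bin_passed"))
  # all voltages below threshold: radius 0 with a flag
  low <- make_toy_leadfield(3, 8, function(d) rep(100, length(d)))
  r0 <- estimate_recording_radius(low, thr = 500)
  expect_equal(as.numeric(r0), 0)
  expect_true(attr(r0, "no_bin_passed"))
  # all voltages above: radius = right edge of the farthest occupied bin
  hi <- make_toy_leadfield(3, 8, function(d) rep(900, length(d)))
  rh <- estimate_recording_radius(hi, thr = 500)
  d_max <- max(hi$patch_center_positions[, 1]) / 10
  expect_equal(as.numeric(rh), (floor(d_max / 0.25) + 1) * 0.25)
})

test_that("recording radius matches the analytic crossing on smooth decay", {
  law <- function(d) 500 * (15 / d)^2     # crosses 500 µV at exactly 15 mm
  lf <- make_toy_leadfield(4, 40, law)
  r <- estimate_recording_radius(lf, thr = 500)
  # independent computation: last half-open 0.25 cm bin whose sources are
  # >= 20% recordable at the median contact (all contacts identical here)
  d <- lf$patch_center_positions[, 1] / 10
  bins <- floor(d / 0.25) + 1
  rec <- tapply(lf$matrix[1, ] >= 500, bins, function(z) 100 * mean(z))
  expected <- max(as.integer(names(rec))[rec >= 20]) * 0.25
  expect_equal(as.numeric(r), expected)
})

test_that("contact sampling returns 105 points per hemisphere, reproducibly", {
  head <- fixture_head3()
  labels <- atlas_labels(head$cortex)
  expect_true(all(table(labels$hemisphere, labels$region) > 0))
  pts <- contact_sampling(head$cortex, labels, per_region = 3, seed = 2)
  expect_equal(nrow(pts), 210)
  expect_equal(as.vector(table(attr(pts, "hemisphere"))), c(105L, 105L))
  expect_identical(pts, contact_sampling(head$cortex, labels, 3, seed = 2))
  one <- contact_sampling(head$cortex, labels, per_region = 1, seed = 2)
  expect_equal(nrow(one), 70)
  # a region with no elements is an error
  bad <- labels
  bad$region[bad$region == 5] <- 6
  expect_error(contact_sampling(head$cortex, bad), "no elements")
})

test_that("common average referencing zeroes the channel mean per sample", {
  V <- rbind(a = c(10, -4, 2), b = c(2, 6, -2))
  car <- common_average_reference(V)
  expect_equal(car[1, ], (V[1, ] - V[2, ]) / 2)
  expect_equal(car[2, ], (V[2, ] - V[1, ]) / 2)
  expect_lt(max(abs(colSums(car))), 1e-12)
  same <- matrix(5, 3, 4)
  expect_true(all(common_average_reference(same) == 0))
  expect_error(common_average_reference(matrix(1, 1, 5)), "2 channels")
})

test_that("the noise threshold is four spike-free SDs", {
  zero <- make_trace(trace_spec(n_channels = 2, n_samples = 100, noise_sd = 0))
  expect_equal(noise_threshold(zero), 0)
  tr <- make_trace(trace_spec(n_channels = 2, n_samples = 5e5, noise_sd = 50,
                              seed = 8))
  expect_lt(abs(noise_threshold(tr) - 200) / 200, 0.02)
  tr2 <- tr
  tr2$voltages <- tr$voltages * -3
  expect_equal(noise_threshold(tr2), 3 * noise_threshold(tr))
  tr3 <- tr
  tr3$spike_free_mask <- rep(FALSE, ncol(tr$voltages))
  expect_error(noise_threshold(tr3), "empty")
})

test_that("spike amplitude statistics summarize window maxima", {
  V <- matrix(0, 2, 40)
  V[1, c(3, 13, 23, 33)] <- c(100, -200, 300, 400)
  wins <- list(c(1, 10), c(11, 20), c(21, 30), c(31, 40))
  st <- spike_amplitude_stats(V, wins)
  expect_equal(st$max_per_spike, c(100, 200, 300, 400))
  expect_equal(st$mean_max, 250)
  expect_equal(st$p25_max, as.numeric(quantile(c(100, 200, 300, 400), 0.25)))
  single <- spike_amplitude_stats(V, wins[3])
  expect_equal(single$p25_max, 300)
  expect_equal(single$mean_max, 300)
  expect_error(spike_amplitude_stats(V, list(c(35, 45))), "outside")
  # planted spikes are recovered within the noise bound after referencing
  spec <- trace_spec(n_channels = 4, n_samples = 5000, noise_sd = 20,
                     spike_amplitudes = c(800, 1200), spike_times = c(1000, 3000),
                     spike_channels = c(2, 3), seed = 13)
  tr <- common_average_reference(make_trace(spec))
  st2 <- spike_amplitude_stats(tr)
  planted <- c(800, 1200) * (1 - 1 / 4)   # CAR shrinks a single-channel spike
  expect_true(all(abs(st2$max_per_spike - planted) <= 4 * 20))
})
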