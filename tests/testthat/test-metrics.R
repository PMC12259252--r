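# Independent brute-force oracle: net-over-total ratio of an n-step unit
# walk is |sum of unit steps| / n, computed with raw arithmetic only.
mc_unit_walk_ratio <- function(n_steps, n_rep, seed) {
  withr::with_seed(seed, {
    th <- matrix(runif(n_steps * n_rep, 0, 2 * pi), n_rep, n_steps)
    sx <- rowSums(cos(th)); sy <- rowSums(sin(th))
    sqrt(sx^2 + sy^2) / n_steps
  })
}

test_that("window construction follows the earliest-window rule", {
  tr7 <- manual_track(0:6, rep(0, 7))
  w <- make_window(tr7)
  expect_equal(w$positions, cbind(0:6, rep(0, 7)))

  tr12 <- manual_track(c(0:6, 100, 101, 102, 103, 104), rep(0, 12))
  w12 <- make_window(tr12)
  expect_equal(w12$positions[, 1], as.numeric(0:6))  # first 7 frames only

  expect_error(make_window(manual_track(0:5, rep(0, 6))), "6 frames")

  # gappy imported track: window comes from the longest consecutive run
  gappy <- manual_track(c(0, 1, 2, 10:17), rep(0, 11),
                        frames = c(0L, 1L, 2L, 10:17))
  wg <- make_window(gappy)
  expect_equal(wg$positions[, 1], as.numeric(10:16))
})

test_that("window frames are consecutive and 7 long over simulated tracks", {
  acq <- acquisition_spec(n_beads = 500, n_frames = 20, dropout_prob = 0.2,
                          seed = 21)
  gt <- simulate_tracks(flow_field_spec(), acq)
  tr <- truth_tracks(gt)
  elig <- eligible_tracks(tr)
  ids <- unique(elig$track_id)
  expect_gt(length(ids), 100)
  for (id in ids[seq_len(min(200, length(ids)))]) {
    sub <- elig[elig$track_id == id, ]
    w <- make_window(sub)
    expect_equal(nrow(w$positions), 7)
    expect_equal(w$alpha, sqrt(sum(w$phi^2)))
    expect_lte(w$alpha, w$beta + 1e-12)
  }
})

test_that("traveling linearity matches hand arithmetic", {
  straight <- make_window(manual_track(0:6, rep(0, 7)))
  expect_identical(traveling_linearity(straight), 1)
  expect_equal(straight$alpha, 6)
  expect_equal(straight$beta, 6)

  backtrack <- make_window(manual_track(c(0, 1, 2, 1, 2, 3, 4), rep(0, 7)))
  expect_equal(backtrack$alpha, 4)
  expect_equal(backtrack$beta, 6)
  expect_equal(traveling_linearity(backtrack), 2 / 3)

  stationary <- make_window(manual_track(rep(1, 7), rep(2, 7)))
  expect_true(is.na(traveling_linearity(stationary)))
})

test_that("mean linearity of isotropic unit walks matches the Monte-Carlo oracle", {
  n_rep <- 10000
  oracle <- mc_unit_walk_ratio(6, n_rep, seed = 100)
  lin <- withr::with_seed(200, {
    vapply(seq_len(n_rep), function(i) {
      th <- runif(6, 0, 2 * pi)
      pos <- rbind(c(0, 0), cbind(cumsum(cos(th)), cumsum(sin(th))))
      w <- make_window(data.frame(track_id = 1, frame = 0:6,
                                  x_um = pos[, 1], y_um = pos[, 2]))
      traveling_linearity(w)
    }, numeric(1))
  })
  se <- sqrt(var(oracle) / n_rep + var(lin) / n_rep)
  expect_lt(abs(mean(lin) - mean(oracle)), 2 * se)
})

test_that("directional uniformity bounds, limits and invariances hold", {
  ten_same <- matrix(c(1, 0), 10, 2, byrow = TRUE)
  expect_identical(directional_uniformity(ten_same), 1)
  cancel <- rbind(matrix(c(1, 0), 5, 2, byrow = TRUE),
                  matrix(c(-1, 0), 5, 2, byrow = TRUE))
  expect_identical(directional_uniformity(cancel), 0)
  expect_error(directional_uniformity(matrix(0, 3, 2)), "zero")
  expect_error(directional_uniformity(matrix(numeric(), 0, 2)), "empty")

  # rotation and positive-scale invariance; bounds over random sets
  withr::with_seed(31, {
    for (i in 1:50) {
      phis <- matrix(rnorm(20), 10, 2)
      u <- directional_uniformity(phis)
      expect_gte(u, 0); expect_lte(u, 1)
      a <- runif(1, 0, 2 * pi)
      R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
      expect_equal(directional_uniformity(phis %*% R), u, tolerance = 1e-9)
      expect_equal(directional_uniformity(phis * runif(1, 0.1, 7)), u,
                   tolerance = 1e-9)
    }
  })
})

test_that("record metrics exclude stationary beads with a message", {
  mk <- function(id, dx) manual_track((0:6) * dx, rep(id, 7), id = id)
  tracks <- do.call(rbind, c(lapply(1:9, mk, dx = 1),
                             list(manual_track(rep(0, 7), rep(0, 7), id = 10))))
  expect_message(rm <- record_metrics(track_table(tracks)), "excluded 1")
  expect_equal(rm$n_used, 9)
  expect_equal(rm$n_excluded, 1)
  expect_equal(length(rm$linearity), 9)
  expect_equal(nrow(rm$phi), 9)
})

test_that("ten co-directional noise-free beads give uniformity and linearity 1", {
  acq <- quiet_acq(n_beads = 30, n_frames = 10, seed = 2)
  gt <- simulate_tracks(noisefree_flow(), acq)
  rm <- record_metrics(select_beads(eligible_tracks(truth_tracks(gt)),
                                    selection_spec(seed = 1)))
  expect_identical(rm$uniformity, 1)
  expect_identical(unname(rm$linearity), rep(1, 10))
})

test_that("erratic patchwork flow lowers uniformity relative to coherent flow", {
  worse <- 0L
  for (s in 1:20) {
    acq <- acquisition_spec(n_beads = 300, n_frames = 12, dropout_prob = 0,
                            seed = s)
    coh <- simulate_tracks(flow_field_spec(patch_direction_sd = 0.1,
                                           patch_size = 20), acq)
    err <- simulate_tracks(flow_field_spec(patch_direction_sd = pi / 2,
                                           patch_size = 20), acq)
    u <- function(gt) record_metrics(select_beads(
      eligible_tracks(truth_tracks(gt)), selection_spec(seed = s)))$uniformity
    if (u(err) < u(coh)) worse <- worse + 1L
  }
  expect_gte(worse, 19)
})

test_that("sample aggregation averages records and pools linearities", {
  mk_rm <- function(u, id) {
    tracks <- do.call(rbind, lapply(1:10, function(i)
      manual_track((0:6) * i, rep(i, 7), id = i)))
    rm <- record_metrics(track_table(tracks), record_id = id)
    rm$uniformity <- u   # fix the uniformity to test the aggregation rule
    rm
  }
  sm <- aggregate_sample(list(mk_rm(0.8, "r1"), mk_rm(0.6, "r2")), "m1")
  expect_equal(sm$uniformity, 0.7)
  expect_equal(length(sm$linearity), 20)

  one <- aggregate_sample(list(mk_rm(0.5, "r1")), "m2")
  expect_equal(one$uniformity, 0.5)
  expect_error(aggregate_sample(list()), "at least one")
})

test_that("the analysis window spans 0.816 s at the protocol frame interval", {
  expect_equal(window_duration(), 6 * 0.136)
  expect_equal(window_duration(), 0.816)
  rm <- record_metrics(track_table(do.call(rbind, lapply(1:2, function(i)
    manual_track(0:6 + i, rep(i, 7), id = i)))))
  expect_equal(rm$window_duration_s, 0.816)
})
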