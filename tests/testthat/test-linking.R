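test_that("well-separated beads link into exactly their ground-truth tracks", {
  init <- cbind(c(50, 200), c(20, 50))
  acq <- quiet_acq(n_beads = 2, n_frames = 10, seed = 1)
  gt <- simulate_tracks(noisefree_flow(speed = 5), acq, init_positions = init)
  det <- data.frame(frame = gt$frame, x_um = gt$x_um, y_um = gt$y_um,
                    intensity = 1)
  tr <- link_detections(det, max_disp = 2)
  expect_equal(length(unique(tr$track_id)), 2)
  expect_true(all(table(tr$track_id) == 10))
  # identities match ground truth: each track stays on one bead's path
  for (id in unique(tr$track_id)) {
    sub <- tr[tr$track_id == id, ]
    beads <- gt$bead_id[match(paste(sub$frame, sub$x_um),
                              paste(gt$frame, gt$x_um))]
    expect_equal(length(unique(beads)), 1)
  }
})

test_that("dropout splits a track because there is no gap closing", {
  det <- data.frame(frame = setdiff(0:9, 5L), x_um = (0:8) * 0.5, y_um = 0,
                    intensity = 1)
  tr <- link_detections(det, max_disp = 2)
  expect_equal(length(unique(tr$track_id)), 2)
  lens <- as.integer(table(tr$track_id))
  expect_setequal(lens, c(5L, 4L))
  expect_equal(sort(unique(tr$frame[tr$track_id == 1])), 0:4)
  expect_equal(sort(unique(tr$frame[tr$track_id == 2])), 6:9)
})

test_that("every detection lands in exactly one track and links respect the gate", {
  acq <- acquisition_spec(n_beads = 150, n_frames = 15, dropout_prob = 0.15,
                          seed = 6)
  gt <- simulate_tracks(flow_field_spec(patch_direction_sd = 1.0), acq)
  det <- truth_detections(gt)
  tr <- link_detections(det, max_disp = 4)
  expect_equal(nrow(tr), nrow(det))             # detections conserved
  key <- paste(tr$frame, sprintf("%.12f", tr$x_um), sprintf("%.12f", tr$y_um))
  expect_false(anyDuplicated(key) > 0)
  # no within-track consecutive displacement exceeds max_disp
  for (id in unique(tr$track_id)) {
    sub <- tr[tr$track_id == id, ]
    if (nrow(sub) < 2) next
    d <- sqrt(diff(sub$x_um)^2 + diff(sub$y_um)^2)
    expect_true(all(d[diff(sub$frame) == 1] < 4))
  }
})

test_that("linking recovers ground-truth identities on a separated field", {
  # per-frame displacement: 10 um/s * 0.136 s = 1.36 um advective plus
  # diffusion (sd 0.23 um/axis); 99th percentile ~ 2.1 um. Grid min distance
  # 7 - 2 = 5 um > 2 x that.
  n <- 300
  init <- grid_positions(n, 258.33, 64.20, pitch = 7, jitter = 1, margin = 3,
                         seed = 4)
  acq <- quiet_acq(n_beads = n, n_frames = 15, seed = 4)
  fl <- flow_field_spec(base_speed = 10, angular_jitter_sd = 0.05,
                        patch_direction_sd = 0, diffusion_coeff = 0.2)
  gt <- simulate_tracks(fl, acq, init_positions = init)
  vis <- gt[gt$visible, ]
  det <- data.frame(frame = vis$frame, x_um = vis$x_um, y_um = vis$y_um,
                    intensity = 1, true_id = vis$bead_id)
  tr <- link_detections(det[, 1:4], max_disp = 4)
  acc <- link_accuracy(tr, det)
  expect_gte(acc, 0.999)
})

test_that("eligibility keeps exactly the tracks with >= 7 consecutive frames", {
  expect_equal(nrow(eligible_tracks(track_table(manual_track(0:6, rep(0, 7))),
                                    selection_spec())), 7)
  expect_equal(nrow(eligible_tracks(track_table(manual_track(0:5, rep(0, 6))),
                                    selection_spec())), 0)
  # brute-force audit over simulated broken tracks
  acq <- acquisition_spec(n_beads = 100, n_frames = 20, dropout_prob = 0.25,
                          seed = 12)
  gt <- simulate_tracks(flow_field_spec(), acq)
  tr <- link_detections(truth_detections(gt), max_disp = 4)
  elig <- eligible_tracks(tr, selection_spec())
  brute <- Filter(function(id) {
    f <- sort(tr$frame[tr$track_id == id])
    if (length(f) < 7) return(FALSE)
    r <- rle(diff(f) == 1)
    runs <- r$lengths[r$values]
    length(runs) > 0 && max(runs) + 1 >= 7
  }, unique(tr$track_id))
  expect_setequal(unique(elig$track_id), brute)
})

test_that("bead selection is seeded, uniform, and error-checked", {
  tracks <- do.call(rbind, lapply(1:10, function(i)
    manual_track(0:6 + i, rep(i, 7), id = i)))
  sel10 <- select_beads(track_table(tracks), selection_spec(n_select = 10))
  expect_equal(sort(unique(sel10$track_id)), 1:10)

  big <- do.call(rbind, lapply(1:500, function(i)
    manual_track(0:6 + i, rep(i, 7), id = i)))
  big <- track_table(big)
  s1 <- select_beads(big, selection_spec(seed = 77))
  s2 <- select_beads(big, selection_spec(seed = 77))
  expect_identical(s1, s2)

  counts <- integer(500)
  for (r in 1:10000) {
    sel <- select_beads(big, selection_spec(seed = r))
    counts[unique(sel$track_id)] <- counts[unique(sel$track_id)] + 1L
  }
  p <- 10 / 500
  sd1 <- sqrt(p * (1 - p) / 10000)
  dev <- abs(counts / 10000 - p)
  # per-track frequencies are ~ Binomial(10000, 0.02)/10000: ~99.7% should
  # sit within 3 sd; jointly, none should stray beyond 5 sd
  expect_gte(mean(dev < 3 * sd1), 0.99)
  expect_true(all(dev < 5 * sd1))

  expect_error(select_beads(track_table(manual_track(0:6, rep(0, 7))),
                            selection_spec(n_select = 10)),
               "1 eligible tracks but n_select = 10")
})

test_that("TrackMate CSV round trip is lossless for (id, frame, x, y)", {
  acq <- acquisition_spec(n_beads = 40, n_frames = 12, seed = 5)
  gt <- simulate_tracks(flow_field_spec(), acq)
  tr <- link_detections(truth_detections(gt), max_disp = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trackmate_csv(tr, path)
  back <- read_trackmate_csv(path)
  expect_equal(back$track_id, tr$track_id)
  expect_equal(back$frame, tr$frame)
  expect_equal(back$x_um, tr$x_um, tolerance = 1e-12)
  expect_equal(back$y_um, tr$y_um, tolerance = 1e-12)
})

test_that("TrackMate-style extra header rows and unit scaling are handled", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("TRACK_ID,FRAME,POSITION_X,POSITION_Y",
               "Track ID,Frame,X,Y",
               "Track ID,Frame,X (micron),Y (micron)",
               "1,0,1.5,2.5", "1,1,1.6,2.6"), path)
  tr <- read_trackmate_csv(path, unit_scale = 2)
  expect_equal(nrow(tr), 2)
  expect_equal(tr$x_um, c(3.0, 3.2))
})

test_that("empty detection input yields an empty track table", {
  tr <- link_detections(data.frame(frame = integer(), x_um = numeric(),
                                   y_um = numeric()), max_disp = 2)
  expect_equal(nrow(tr), 0)
})
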