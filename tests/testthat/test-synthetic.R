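test_that("noise-free advection produces collinear steps of speed * dt", {
  acq <- quiet_acq(n_beads = 25, n_frames = 12, seed = 4)
  gt <- simulate_tracks(noisefree_flow(speed = 10), acq)
  step <- 10 * 0.136
  for (id in unique(gt$bead_id)) {
    tr <- gt[gt$bead_id == id, ]
    expect_equal(diff(tr$x_um), rep(step, 11), tolerance = 1e-12)
    expect_equal(diff(tr$y_um), rep(0, 11), tolerance = 1e-12)
  }
})

test_that("pure-diffusion displacements match the Brownian closed form", {
  # 500 beads x 20 steps = 10,000 bead-steps; variance 2 D dt per axis
  D <- 0.5
  acq <- quiet_acq(n_beads = 500, n_frames = 21, seed = 9,
                   field_width = 1e5, field_height = 1e5)
  fl <- flow_field_spec(base_speed = 0, diffusion_coeff = D,
                        angular_jitter_sd = 0, patch_direction_sd = 0)
  gt <- simulate_tracks(fl, acq)
  dx <- unlist(tapply(gt$x_um, gt$bead_id, diff))
  dy <- unlist(tapply(gt$y_um, gt$bead_id, diff))
  expect_equal(var(dx), 2 * D * 0.136, tolerance = 0.05)
  expect_equal(var(dy), 2 * D * 0.136, tolerance = 0.05)

  # MSD grows linearly in lag with slope 4 D dt (2D), within 5%
  msd <- sapply(1:5, function(k) {
    d2 <- unlist(lapply(split(gt, gt$bead_id), function(tr) {
      n <- nrow(tr)
      (tr$x_um[(1 + k):n] - tr$x_um[1:(n - k)])^2 +
        (tr$y_um[(1 + k):n] - tr$y_um[1:(n - k)])^2
    }))
    mean(d2)
  })
  slope <- sum(msd * (1:5)) / sum((1:5)^2)  # through-origin fit
  expect_equal(slope, 4 * D * 0.136, tolerance = 0.05)
})

test_that("dropout hides the expected fraction of frames", {
  acq <- acquisition_spec(n_beads = 400, n_frames = 30, dropout_prob = 0.3,
                          seed = 2, field_width = 1e4, field_height = 1e4)
  gt <- simulate_tracks(flow_field_spec(base_speed = 0, diffusion_coeff = 0),
                        acq)
  frac <- mean(gt$visible)
  n <- nrow(gt)
  sd3 <- 3 * sqrt(0.7 * 0.3 / n)
  expect_lt(abs(frac - 0.7), sd3)
})

test_that("bead identities are conserved for every parameterization", {
  for (s in 1:3) {
    acq <- acquisition_spec(n_beads = 50 + s, n_frames = 10, seed = s)
    gt <- simulate_tracks(flow_field_spec(patch_direction_sd = s / 2,
                                          immobile_fraction = 0.3), acq)
    expect_identical(sort(unique(gt$bead_id)), 1:(50 + s))
    expect_equal(nrow(gt), (50 + s) * 10)
  }
  # drawn bead counts stay in the protocol range
  acq <- acquisition_spec(n_beads = NA, n_frames = 7, seed = 5)
  gt <- simulate_tracks(flow_field_spec(), acq)
  expect_gte(length(unique(gt$bead_id)), 300)
  expect_lte(length(unique(gt$bead_id)), 600)
})

test_that("identical seeds reproduce bit-identical trajectories", {
  acq <- acquisition_spec(n_beads = 30, n_frames = 10, seed = 42)
  fl <- flow_field_spec(patch_direction_sd = 0.8, immobile_fraction = 0.1)
  a <- simulate_tracks(fl, acq)
  b <- simulate_tracks(fl, acq)
  expect_identical(as.data.frame(a), as.data.frame(b))
  z1 <- simulate_zstack(n_cells = 9, seed = 7)
  z2 <- simulate_zstack(n_cells = 9, seed = 7)
  expect_identical(z1$cilia, z2$cilia)
  expect_identical(z1$cells, z2$cells)
})

test_that("beads leaving the field are censored permanently", {
  init <- cbind(c(257, 5), c(32, 32))   # first bead exits almost immediately
  acq <- quiet_acq(n_beads = 2, n_frames = 10, seed = 1)
  gt <- simulate_tracks(noisefree_flow(speed = 20), acq, init_positions = init)
  b1 <- gt[gt$bead_id == 1, ]
  exit <- which(!b1$visible)[1]
  expect_false(any(b1$visible[exit:length(b1$visible)]))
  expect_true(all(gt$x_um[gt$visible] >= 0 & gt$x_um[gt$visible] <= 258.33))
})

test_that("invalid spec values are reported with the offending field", {
  expect_error(flow_field_spec(base_speed = -1), "base_speed")
  expect_error(flow_field_spec(immobile_fraction = 1.2), "immobile_fraction")
  expect_error(acquisition_spec(n_frames = 5), "n_frames")
  expect_error(acquisition_spec(dropout_prob = 1), "dropout_prob")
  expect_error(acquisition_spec(pixel_size = 0), "pixel_size")
})

test_that("z-stack generator returns the requested cells and height stats", {
  zs <- simulate_zstack(n_cells = 25, height_mean = 5, height_sd = 0,
                        z_step = 1, seed = 3)
  expect_equal(nrow(zs$cells), 25)
  expect_equal(zs$cells$true_height_um, rep(5, 25))

  zs2 <- simulate_zstack(n_cells = 200, height_mean = 5, height_sd = 1,
                         z_step = 0.5, seed = 11, field_size = 300)
  m <- mean(zs2$cells$true_height_um)
  expect_lt(abs(m - 5), 3 * 1 / sqrt(200))
  # sub-resolution cells are flagged, not dropped
  zs3 <- simulate_zstack(n_cells = 9, height_mean = 0.3, height_sd = 0,
                         z_step = 0.5, seed = 1)
  expect_true(all(zs3$cells$sub_resolution))
  expect_equal(nrow(zs3$cells), 9)
})

test_that("epithelial trace allocation hits the target ciliated share", {
  tr1 <- simulate_epithelial_trace(500, 1, 60, seed = 1)
  expect_true(all(tr1$ciliated))
  tr0 <- simulate_epithelial_trace(500, 0, 60, seed = 1)
  expect_false(any(tr0$ciliated))
  tr <- simulate_epithelial_trace(500, 0.5, 100, seed = 5)
  expect_equal(sum(tr$ciliated), 50)   # equal segments: exact allocation
  # fractional targets land within one segment's length
  tr2 <- simulate_epithelial_trace(500, 0.333, 100, seed = 5)
  expect_lt(abs(sum(tr2$ciliated) / 100 - 0.333), 1 / 100)
})
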