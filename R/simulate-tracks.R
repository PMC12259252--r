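#' Simulate ground-truthed bead trajectories
#'
#' Generates bead trajectories under patchwise advection plus Brownian
#' diffusion:
#' `x[t+1] = x[t] + v(x[t]) * dt + eta`, where `v` has magnitude
#' `base_speed` (zero for immobile beads) and direction equal to the fixed
#' direction of the flow patch containing the bead plus per-step jitter
#' `Normal(0, angular_jitter_sd)`, and `eta ~ Normal(0, 2 * D * dt)` per axis.
#' Beads that leave the field are censored: marked invisible from the first
#' frame outside and never re-enter the visible set. Independently of
#' censoring, each visible bead is hidden with probability `dropout_prob` per
#' frame (missed detection), which breaks tracks.
#'
#' @param flow A [flow_field_spec()].
#' @param acq An [acquisition_spec()]; `acq$seed` drives all randomness via
#'   named sub-streams (patches, motion, dropout).
#' @param init_positions Optional n x 2 matrix of initial positions (um). By
#'   default beads start uniformly in the field; supply positions to enforce
#'   e.g. a minimum-distance layout.
#' @return A `ground_truth` object: a data.frame with columns `bead_id`,
#'   `frame` (0-based), `x_um`, `y_um`, `visible`, carrying the generating
#'   specs as attributes (`flow`, `acq`, `patch_directions`).
#' @export
#' @examples
#' gt <- simulate_tracks(flow_field_spec(), acquisition_spec(n_beads = 50))
#' head(gt)
simulate_tracks <- function(flow, acq, init_positions = NULL) {
  stopifnot(inherits(flow, "flow_field_spec"), inherits(acq, "acquisition_spec"))
  dt <- acq$frame_interval
  nf <- acq$n_frames

  n_beads <- acq$n_beads
  if (is.na(n_beads)) {
    n_beads <- with_seed(derive_seed(acq$seed, "motion", 999L),
                         sample(300:600, 1L))
  }

  # Patch directions: fixed once per simulation, on a grid covering the field.
  npx <- max(1L, ceiling(acq$field_width / flow$patch_size))
  npy <- max(1L, ceiling(acq$field_height / flow$patch_size))
  patch_dir <- with_seed(derive_seed(acq$seed, "patches"),
    matrix(flow$base_direction +
             stats::rnorm(npx * npy, 0, flow$patch_direction_sd),
           nrow = npy, ncol = npx))

  patch_of <- function(x, y) {
    cx <- pmin(pmax(floor(x / flow$patch_size) + 1L, 1L), npx)
    cy <- pmin(pmax(floor(y / flow$patch_size) + 1L, 1L), npy)
    patch_dir[cbind(cy, cx)]
  }

  pos <- array(NA_real_, dim = c(n_beads, 2L, nf))
  with_seed(derive_seed(acq$seed, "motion"), {
    if (is.null(init_positions)) {
      pos[, 1L, 1L] <- stats::runif(n_beads, 0, acq$field_width)
      pos[, 2L, 1L] <- stats::runif(n_beads, 0, acq$field_height)
    } else {
      init_positions <- as.matrix(init_positions)
      if (nrow(init_positions) != n_beads || ncol(init_positions) != 2L)
        stop_field("init_positions",
                   sprintf("must be a %d x 2 matrix", n_beads))
      pos[, , 1L] <- init_positions
    }
    immobile <- stats::runif(n_beads) < flow$immobile_fraction
    sd_diff <- sqrt(2 * flow$diffusion_coeff * dt)
    for (t in seq_len(nf - 1L)) {
      theta <- patch_of(pos[, 1L, t], pos[, 2L, t]) +
        stats::rnorm(n_beads, 0, flow$angular_jitter_sd)
      speed <- ifelse(immobile, 0, flow$base_speed)
      pos[, 1L, t + 1L] <- pos[, 1L, t] + speed * cos(theta) * dt +
        stats::rnorm(n_beads, 0, sd_diff)
      pos[, 2L, t + 1L] <- pos[, 2L, t] + speed * sin(theta) * dt +
        stats::rnorm(n_beads, 0, sd_diff)
    }
  })

  inside <- pos[, 1L, ] >= 0 & pos[, 1L, ] <= acq$field_width &
            pos[, 2L, ] >= 0 & pos[, 2L, ] <= acq$field_height
  inside <- matrix(inside, nrow = n_beads)
  # censor permanently after first exit
  visible <- t(apply(inside, 1L, cumprod)) > 0

  if (acq$dropout_prob > 0) {
    drop <- with_seed(derive_seed(acq$seed, "dropout"),
      matrix(stats::runif(n_beads * nf) < acq$dropout_prob,
             nrow = n_beads))
    visible <- visible & !drop
  }

  df <- data.frame(
    bead_id = rep(seq_len(n_beads), times = nf),
    frame = rep(0:(nf - 1L), each = n_beads),
    x_um = as.vector(pos[, 1L, ]),
    y_um = as.vector(pos[, 2L, ]),
    visible = as.vector(visible)
  )
  df <- df[order(df$bead_id, df$frame), ]
  rownames(df) <- NULL
  ground_truth(df, flow = flow, acq = acq, patch_directions = patch_dir)
}

#' Construct a ground-truth trajectory set
#'
#' Wraps a per-bead, per-frame position table into the container used
#' throughout the simulator and the audits against it. Mostly called by
#' [simulate_tracks()]; exposed so tests and users can build bespoke layouts.
#'
#' @param df data.frame with columns `bead_id`, `frame`, `x_um`, `y_um`,
#'   `visible`.
#' @param flow,acq The generating specs.
#' @param patch_directions Optional matrix of fixed patch flow directions.
#' @return A `ground_truth` data.frame.
#' @export
ground_truth <- function(df, flow, acq, patch_directions = NULL) {
  need <- c("bead_id", "frame", "x_um", "y_um", "visible")
  if (!all(need %in% names(df)))
    stop_field("df", paste("must have columns", paste(need, collapse = ", ")))
  structure(df, flow = flow, acq = acq, patch_directions = patch_directions,
            class = c("ground_truth", "data.frame"))
}

#' @export
print.ground_truth <- function(x, ...) {
  acq <- attr(x, "acq")
  cat("Ground-truth bead set:", length(unique(x$bead_id)), "beads,",
      length(unique(x$frame)), "frames,",
      sum(x$visible), "visible detections\n")
  cat("Field:", acq$field_width, "x", acq$field_height, "um @",
      acq$frame_interval, "s/frame\n")
  NextMethod()
}

#' Observed detections from a ground-truth set
#'
#' The "direct tracks" entry into the pipeline: visible ground-truth
#' positions with localization noise applied, formatted as a detection table
#' (what a spot detector would emit). Intensities are drawn around the
#' nominal bead amplitude.
#'
#' @param truth A `ground_truth` object.
#' @param localization_noise_sd Localization error in um; defaults to the
#'   acquisition spec's value.
#' @return data.frame with columns `frame`, `x_um`, `y_um`, `intensity`,
#'   ordered by frame then descending intensity.
#' @export
truth_detections <- function(truth, localization_noise_sd = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  acq <- attr(truth, "acq")
  if (is.null(localization_noise_sd))
    localization_noise_sd <- acq$localization_noise_sd
  vis <- truth[truth$visible, , drop = FALSE]
  det <- with_seed(derive_seed(acq$seed, "motion", 17L), data.frame(
    frame = vis$frame,
    x_um = vis$x_um + stats::rnorm(nrow(vis), 0, localization_noise_sd),
    y_um = vis$y_um + stats::rnorm(nrow(vis), 0, localization_noise_sd),
    intensity = acq$bead_amplitude * stats::runif(nrow(vis), 0.8, 1.2)
  ))
  det <- det[order(det$frame, -det$intensity), ]
  rownames(det) <- NULL
  det
}

#' Write / read ground truth or detection tables as CSV
#'
#' Positions are written in um with full double precision (15 significant
#' digits), so a write-then-read round trip is exact to well below 1e-9 um.
#'
#' @param x data.frame to write.
#' @param path File path.
#' @return `write_table_csv` returns `path` invisibly; `read_table_csv`
#'   returns a data.frame.
#' @export
write_table_csv <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 15, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Ground-truth identity tracks
#'
#' Converts the visible detections of a ground-truth set into a track table
#' using the true bead identities — the reference assignment that linking
#' audits compare against, and a direct route into the transport metrics
#' that bypasses detection and linking.
#'
#' @param truth A `ground_truth` object.
#' @return A `track_table` with `track_id` equal to the true `bead_id`.
#' @export
truth_tracks <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  vis <- truth[truth$visible, , drop = FALSE]
  out <- data.frame(track_id = vis$bead_id, frame = vis$frame,
                    x_um = vis$x_um, y_um = vis$y_um, intensity = 0)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  track_table(out)
}
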