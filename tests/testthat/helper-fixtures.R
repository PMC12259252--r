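# Shared fixture builders. Everything is generated in code at test time.

# Deterministic noise-free flow: pure advection along +x.
noisefree_flow <- function(speed = 15) {
  flow_field_spec(base_speed = speed, base_direction = 0,
                  angular_jitter_sd = 0, patch_size = 30,
                  patch_direction_sd = 0, diffusion_coeff = 0,
                  immobile_fraction = 0)
}

quiet_acq <- function(n_beads, seed = 1L, ...) {
  acquisition_spec(n_beads = n_beads, dropout_prob = 0,
                   localization_noise_sd = 0, seed = seed, ...)
}

# Jittered-grid initial positions with a guaranteed minimum pairwise
# distance of (pitch - 2 * jitter); enforces the separation conditions the
# detection and linking oracles require.
grid_positions <- function(n, width, height, pitch, jitter, margin = 2,
                           seed = 1L) {
  xs <- seq(margin, width - margin, by = pitch)
  ys <- seq(margin, height - margin, by = pitch)
  g <- expand.grid(x = xs, y = ys)
  stopifnot(nrow(g) >= n)
  withr::with_seed(seed, {
    g <- g[sample.int(nrow(g), n), ]
    as.matrix(g) + matrix(stats::runif(2 * n, -jitter, jitter), n, 2)
  })
}

# A hand-built single track as a track_table-compatible data.frame.
manual_track <- function(x, y, frames = seq_along(x) - 1L, id = 1L) {
  data.frame(track_id = id, frame = frames, x_um = x, y_um = y,
             intensity = 0)
}

# Match detections to true positions within a radius; returns recall and
# precision (greedy nearest-neighbour matching per frame).
detection_prf <- function(det, truth, radius = 1) {
  vis <- truth[truth$visible, ]
  tp <- 0L
  for (f in unique(vis$frame)) {
    tv <- vis[vis$frame == f, ]
    dv <- det[det$frame == f, ]
    if (nrow(dv) == 0) next
    used <- logical(nrow(dv))
    for (i in seq_len(nrow(tv))) {
      d <- sqrt((dv$x_um - tv$x_um[i])^2 + (dv$y_um - tv$y_um[i])^2)
      d[used] <- Inf
      j <- which.min(d)
      if (length(j) && d[j] <= radius) {
        tp <- tp + 1L
        used[j] <- TRUE
      }
    }
  }
  c(recall = tp / nrow(vis), precision = tp / nrow(det))
}

# Fraction of frame-to-frame links connecting detections of the same true
# bead. `det` must carry a `true_id` column (dropped before linking); linked
# rows are re-identified by exact (frame, x_um, y_um) values, which the
# linker passes through unchanged.
link_accuracy <- function(tracks, det) {
  key <- function(d) paste(d$frame, sprintf("%.12f", d$x_um),
                           sprintf("%.12f", d$y_um))
  tid <- det$true_id[match(key(tracks), key(det))]
  stopifnot(!anyNA(tid))
  correct <- 0L; total <- 0L
  ord <- order(tracks$track_id, tracks$frame)
  id <- tracks$track_id[ord]; tv <- tid[ord]
  same_track <- id[-1] == id[-length(id)]
  total <- sum(same_track)
  correct <- sum(same_track & tv[-1] == tv[-length(tv)])
  if (total == 0L) return(NA_real_)
  correct / total
}
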