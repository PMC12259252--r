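#' Build the seven-frame analysis window of a track
#'
#' Takes the first 7 frames of the track's longest consecutive-frame run
#' (earliest-window rule: deterministic, and avoids biasing towards fast
#' late segments) and derives the per-bead quantities: displacement `alpha`
#' (straight-line distance from the window's first to last position), path
#' length `beta` (sum of the 6 segment lengths), and the trajectory vector
#' `phi` (last position minus first position, so `|phi| = alpha`).
#'
#' @param track One track: a data.frame with columns `frame`, `x_um`, `y_um`
#'   (a single-track subset of a `track_table`).
#' @return A `track_window` with elements `positions` (7 x 2 matrix),
#'   `alpha`, `beta`, `phi`.
#' @export
#' @examples
#' tr <- data.frame(frame = 0:6, x_um = 0:6, y_um = 0)
#' w <- make_window(tr)
#' traveling_linearity(w)  # 1: perfectly straight path
make_window <- function(track) {
  track <- as.data.frame(track)
  if (length(unique(track$track_id)) > 1)
    stop("make_window() expects a single track", call. = FALSE)
  track <- track[order(track$frame), ]
  f <- track$frame
  grp <- cumsum(c(1L, as.integer(diff(f) != 1L)))
  lens <- tabulate(grp)
  if (max(lens) < 7L)
    stop(sprintf(
      "track is not eligible: longest consecutive run is %d frames (< 7)",
      max(lens)), call. = FALSE)
  run <- which(grp == which.max(lens))  # longest run, earliest on ties
  idx <- run[1:7]
  pos <- as.matrix(track[idx, c("x_um", "y_um")])
  dimnames(pos) <- NULL
  seg <- diff(pos)
  phi <- pos[7L, ] - pos[1L, ]
  structure(list(positions = pos,
                 alpha = sqrt(sum(phi^2)),
                 beta = sum(sqrt(rowSums(seg^2))),
                 phi = phi),
            class = "track_window")
}

#' Traveling linearity of a bead (net displacement over path length)
#'
#' The ratio `alpha / beta` of the straight-line displacement over the total
#' travelled distance within the seven-frame window. 1 means perfectly
#' straight motion; values near 0 indicate wandering or oscillation. For a
#' perfectly stationary bead `beta = 0` and the ratio is undefined: `NA` is
#' returned and such beads are excluded (with a count) by
#' [record_metrics()].
#'
#' @param w A [make_window()] result.
#' @return Dimensionless value in `[0, 1]`, or `NA` when `beta = 0`.
#' @export
traveling_linearity <- function(w) {
  stopifnot(inherits(w, "track_window"))
  if (w$beta == 0) return(NA_real_)
  min(w$alpha / w$beta, 1)
}

#' Directional uniformity of a set of trajectory vectors
#'
#' The length of the mean trajectory vector divided by the mean length of
#' the individual trajectory vectors: `|mean(phi)| / mean(|phi|)`. Equals 1
#' when all beads move in the same direction and 0 under exact cancellation;
#' invariant under global rotation and positive rescaling of all vectors.
#' The result is clipped to `[0, 1]` only to absorb floating-point round-off
#' (<= 1e-12).
#'
#' @param phis n x 2 matrix (or list of length-2 vectors) of trajectory
#'   vectors in um.
#' @return Dimensionless value in `[0, 1]`.
#' @export
#' @examples
#' directional_uniformity(matrix(c(1, 0), 10, 2, byrow = TRUE))  # 1
directional_uniformity <- function(phis) {
  if (is.list(phis)) phis <- do.call(rbind, phis)
  phis <- as.matrix(phis)
  if (nrow(phis) == 0) stop("empty set of trajectory vectors", call. = FALSE)
  lens <- sqrt(rowSums(phis^2))
  if (all(lens == 0))
    stop("directional uniformity undefined: all trajectory vectors are zero",
         call. = FALSE)
  u <- sqrt(sum(colMeans(phis)^2)) / mean(lens)
  min(max(u, 0), 1)
}

#' Per-recording transport metrics
#'
#' Builds the seven-frame window for each selected bead, computes the
#' per-bead traveling linearity and trajectory vector, and the recording's
#' directional uniformity from the set of trajectory vectors. Stationary
#' beads (`beta = 0`, trajectory undefined) are excluded from both
#' statistics and the exclusion is counted and messaged.
#'
#' @param tracks A `track_table` of the selected beads (normally 10).
#' @param frame_interval Frame interval in seconds (metadata, carried into
#'   the result).
#' @param record_id Identifier for the recording.
#' @return A `record_metrics` object: list with `record_id`, `linearity`
#'   (named per-track vector), `phi` (matrix), `Phi` (mean trajectory
#'   vector), `uniformity`, `n_used`, `n_excluded`, `window_duration_s`.
#' @export
record_metrics <- function(tracks, frame_interval = 0.136, record_id = "record") {
  ids <- sort(unique(tracks$track_id))
  if (length(ids) < 2) stop("need at least 2 tracks", call. = FALSE)
  wins <- lapply(ids, function(id) make_window(tracks[tracks$track_id == id, ]))
  lin <- vapply(wins, traveling_linearity, numeric(1))
  phi <- do.call(rbind, lapply(wins, `[[`, "phi"))
  usable <- !is.na(lin)
  n_excluded <- sum(!usable)
  if (n_excluded > 0)
    message(record_id, ": excluded ", n_excluded,
            " stationary bead(s) with zero path length")
  if (sum(usable) < 2)
    stop("fewer than 2 usable beads after excluding stationary beads",
         call. = FALSE)
  lin <- lin[usable]
  names(lin) <- ids[usable]
  phi <- phi[usable, , drop = FALSE]
  structure(list(record_id = record_id,
                 linearity = lin,
                 phi = phi,
                 Phi = colMeans(phi),
                 uniformity = directional_uniformity(phi),
                 n_used = sum(usable),
                 n_excluded = n_excluded,
                 window_duration_s = 6 * frame_interval),
            class = "record_metrics")
}

#' @export
print.record_metrics <- function(x, ...) {
  cat("Recording", x$record_id, "-", x$n_used, "beads",
      if (x$n_excluded) paste0("(", x$n_excluded, " excluded)") else "", "\n")
  cat("  directional uniformity:", signif(x$uniformity, 4), "\n")
  cat("  traveling linearity: mean", signif(mean(x$linearity), 4),
      "range", paste(signif(range(x$linearity), 3), collapse = "-"), "\n")
  invisible(x)
}

#' Aggregate recordings into per-animal metrics
#'
#' The assay performs two recordings per trachea; the animal-level
#' directional uniformity is the unweighted mean of the record uniformities,
#' and per-bead linearities are pooled across records (both the per-record
#' and pooled layouts are retained so either convention can be plotted).
#'
#' @param records List of [record_metrics()] objects (>= 1).
#' @param animal_id Identifier for the animal.
#' @return A `sample_metrics` object with `uniformity` (animal-level mean),
#'   `record_uniformity` (per record), `linearity` (pooled), and the record
#'   list.
#' @export
aggregate_sample <- function(records, animal_id = "animal") {
  if (length(records) < 1) stop("need at least one record", call. = FALSE)
  stopifnot(all(vapply(records, inherits, logical(1), "record_metrics")))
  ru <- vapply(records, `[[`, numeric(1), "uniformity")
  names(ru) <- vapply(records, `[[`, character(1), "record_id")
  structure(list(animal_id = animal_id,
                 uniformity = mean(ru),
                 record_uniformity = ru,
                 linearity = unlist(lapply(records, `[[`, "linearity")),
                 records = records),
            class = "sample_metrics")
}

#' @export
print.sample_metrics <- function(x, ...) {
  cat("Animal", x$animal_id, "-", length(x$records), "recording(s)\n")
  cat("  directional uniformity (mean of records):",
      signif(x$uniformity, 4), "\n")
  cat("  pooled traveling linearity: mean", signif(mean(x$linearity), 4),
      "over", length(x$linearity), "beads\n")
  invisible(x)
}
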