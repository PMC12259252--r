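#' Link detections across frames into tracks
#'
#' Frame-to-frame linking with no gap closing, splitting or merging: for each
#' consecutive frame pair, detections are assigned one-to-one so as to
#' minimize the total squared displacement among candidate pairs closer than
#' `max_disp`, with "no link" always available at the equivalent cost of
#' `max_disp^2 / 2` per endpoint (so a candidate link is made exactly when it
#' lowers the total cost). The gated linear assignment problem is solved as a
#' maximum-weight bipartite matching with weight `max_disp^2 - d^2` per
#' allowed pair. Unmatched detections start new tracks; a track ends at the
#' first frame with no match. Track ids are assigned in order of track birth;
#' within a frame, ties are broken by descending intensity then ascending x.
#'
#' @param detections data.frame with columns `frame` (0-based), `x_um`,
#'   `y_um` and optionally `intensity`, sorted by frame.
#' @param max_disp Maximum linking displacement in um (> 0).
#' @return A `track_table`: data.frame with columns `track_id`, `frame`,
#'   `x_um`, `y_um`, `intensity`, ordered by track then frame.
#' @export
link_detections <- function(detections, max_disp) {
  check_num(max_disp, "max_disp")
  if (max_disp <= 0) stop_field("max_disp", "must be > 0")
  det <- as.data.frame(detections)
  if (nrow(det) == 0)
    return(track_table(data.frame(track_id = integer(), frame = integer(),
                                  x_um = numeric(), y_um = numeric(),
                                  intensity = numeric())))
  if (is.null(det$intensity)) det$intensity <- 0
  if (is.unsorted(det$frame)) det <- det[order(det$frame), ]

  frames <- sort(unique(det$frame))
  by_frame <- split(seq_len(nrow(det)), det$frame)

  track_of <- integer(nrow(det))   # track id per detection row
  next_id <- 1L

  new_tracks <- function(rows) {
    # birth order within a frame: descending intensity, then ascending x
    ord <- rows[order(-det$intensity[rows], det$x_um[rows])]
    ids <- seq.int(next_id, length.out = length(ord))
    track_of[ord] <<- ids
    next_id <<- next_id + length(ord)
  }

  active <- by_frame[[as.character(frames[1])]]
  new_tracks(active)

  for (i in seq_along(frames)[-1]) {
    f_prev <- frames[i - 1L]; f_cur <- frames[i]
    cur <- by_frame[[as.character(f_cur)]]
    if (f_cur != f_prev + 1L || length(active) == 0L) {
      new_tracks(cur)          # gap in frames: everything starts fresh
      active <- cur
      next
    }
    m <- match_frame_pair(cbind(det$x_um[active], det$y_um[active]),
                          cbind(det$x_um[cur], det$y_um[cur]),
                          max_disp)
    linked <- which(!is.na(m))       # indices into `cur`
    track_of[cur[linked]] <- track_of[active[m[linked]]]
    unmatched <- setdiff(seq_along(cur), linked)
    if (length(unmatched)) new_tracks(cur[unmatched])
    active <- cur
  }

  out <- data.frame(track_id = track_of, frame = det$frame,
                    x_um = det$x_um, y_um = det$y_um,
                    intensity = det$intensity)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  track_table(out)
}

# Gated min-total-squared-displacement assignment between two point sets,
# via maximum-weight bipartite matching on weights max_disp^2 - d^2 (> 0 for
# allowed pairs only). Returns, for each row of p2, the matched row index of
# p1 (NA if the point starts a new track).
match_frame_pair <- function(p1, p2, max_disp) {
  n1 <- nrow(p1); n2 <- nrow(p2)
  res <- rep(NA_integer_, n2)
  if (n1 == 0L || n2 == 0L) return(res)
  d2 <- outer(p1[, 1L], p2[, 1L], "-")^2 + outer(p1[, 2L], p2[, 2L], "-")^2
  allowed <- which(d2 < max_disp^2, arr.ind = TRUE)
  if (nrow(allowed) == 0L) return(res)
  w <- max_disp^2 - d2[allowed]
  g <- igraph::make_bipartite_graph(
    c(rep(TRUE, n1), rep(FALSE, n2)),
    as.vector(t(cbind(allowed[, 1L], n1 + allowed[, 2L]))))
  mm <- igraph::max_bipartite_match(g, weights = w)$matching
  for (j in seq_len(n2)) {
    mj <- mm[n1 + j]
    if (!is.na(mj)) res[j] <- as.integer(mj)
  }
  res
}

#' Track table container
#'
#' @param df data.frame with columns `track_id`, `frame`, `x_um`, `y_um` and
#'   optionally `intensity`. Frames within a track must be consecutive.
#' @return A `track_table` data.frame.
#' @export
track_table <- function(df) {
  need <- c("track_id", "frame", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop_field("df", paste("must have columns", paste(need, collapse = ", ")))
  structure(as.data.frame(df), class = c("track_table", "data.frame"))
}

#' @export
print.track_table <- function(x, ...) {
  cat("Tracks:", length(unique(x$track_id)), "tracks,",
      nrow(x), "detections\n")
  NextMethod()
}

#' Plot bead tracks
#'
#' Diagnostic figure: each track drawn as a polyline in um coordinates, y
#' axis flipped to match image orientation.
#'
#' @param x A `track_table`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.track_table <- function(x, ...) {
  graphics::plot(NA, xlim = range(x$x_um), ylim = rev(range(x$y_um)),
                 xlab = "x (um)", ylab = "y (um)", asp = 1, ...)
  cols <- grDevices::hcl.colors(max(32L, length(unique(x$track_id))),
                                "Dark 3")
  for (id in unique(x$track_id)) {
    tr <- x[x$track_id == id, ]
    graphics::lines(tr$x_um, tr$y_um, col = cols[(id %% length(cols)) + 1L])
  }
  invisible(x)
}

#' Filter tracks by the continuous-frames eligibility rule
#'
#' A track is eligible when its consecutive-frame run spans at least
#' `min_intervals + 1` detections — with the defaults, more than 6 continuous
#' inter-frame intervals, i.e. at least 7 frame observations (0.816 s at
#' 136 ms per interval).
#'
#' @param tracks A `track_table`.
#' @param spec A [selection_spec()].
#' @return The eligible subset, as a `track_table`.
#' @export
eligible_tracks <- function(tracks, spec = selection_spec()) {
  stopifnot(inherits(spec, "selection_spec"))
  runs <- vapply(split(tracks$frame, tracks$track_id),
                 longest_consecutive_run, numeric(1))
  keep <- as.integer(names(runs))[runs >= spec$min_intervals + 1L]
  out <- tracks[tracks$track_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  track_table(out)
}

# length (in observations) of the longest run of consecutive frame indices
longest_consecutive_run <- function(frames) {
  f <- sort(unique(frames))
  if (length(f) == 0L) return(0)
  grp <- cumsum(c(1L, as.integer(diff(f) != 1L)))
  max(tabulate(grp))
}

#' Randomly select beads for metric calculation
#'
#' Uniform sample without replacement of `n_select` eligible tracks, driven
#' by `spec$seed` (deterministic given the seed). Selected tracks are
#' returned in ascending track-id order.
#'
#' @param eligible A `track_table` of eligible tracks.
#' @param spec A [selection_spec()].
#' @return A `track_table` containing the selected tracks.
#' @export
select_beads <- function(eligible, spec = selection_spec()) {
  stopifnot(inherits(spec, "selection_spec"))
  ids <- sort(unique(eligible$track_id))
  if (length(ids) < spec$n_select)
    stop(sprintf("only %d eligible tracks but n_select = %d",
                 length(ids), spec$n_select), call. = FALSE)
  sel <- sort(with_seed(spec$seed, sample(ids, spec$n_select)))
  out <- eligible[eligible$track_id %in% sel, , drop = FALSE]
  rownames(out) <- NULL
  track_table(out)
}

#' Read and write TrackMate-compatible track tables
#'
#' Reads CSV exports in the TrackMate spots-in-tracks layout (columns
#' `TRACK_ID`, `FRAME`, `POSITION_X`, `POSITION_Y`; the up to three
#' non-numeric header rows below the column names that TrackMate emits are
#' skipped automatically). Positions are converted to um via `unit_scale`
#' (1 if the export is already in um). The round trip through
#' `write_trackmate_csv` / `read_trackmate_csv` is lossless for
#' (id, frame, x, y).
#'
#' @param path CSV path.
#' @param unit_scale Factor converting exported position units to um.
#' @return A `track_table`.
#' @export
read_trackmate_csv <- function(path, unit_scale = 1) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y")
  if (!all(need %in% names(raw)))
    stop("TrackMate CSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  drop <- is.na(suppressWarnings(as.numeric(raw$FRAME)))
  raw <- raw[!drop, , drop = FALSE]
  out <- data.frame(
    track_id = as.integer(raw$TRACK_ID),
    frame = as.integer(raw$FRAME),
    x_um = as.numeric(raw$POSITION_X) * unit_scale,
    y_um = as.numeric(raw$POSITION_Y) * unit_scale,
    intensity = if ("QUALITY" %in% names(raw))
      suppressWarnings(as.numeric(raw$QUALITY)) else 0
  )
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  track_table(out)
}

#' @rdname read_trackmate_csv
#' @param tracks A `track_table` to export.
#' @export
write_trackmate_csv <- function(tracks, path) {
  df <- data.frame(TRACK_ID = tracks$track_id, FRAME = tracks$frame,
                   POSITION_X = formatC(tracks$x_um, digits = 15, format = "g"),
                   POSITION_Y = formatC(tracks$y_um, digits = 15, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
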