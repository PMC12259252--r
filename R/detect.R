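#' Detect bead spots in a frame stack
#'
#' Band-pass detection in the style of standard particle-tracking spot
#' detectors: each frame is filtered with a difference of Gaussians (centre
#' sigma = expected spot sigma, surround sigma = twice that), local maxima of
#' the filtered image exceeding the robust background threshold
#' (median + `threshold_sd` x scaled MAD of the filtered frame) are kept,
#' and each is localized to sub-pixel precision by an intensity-weighted
#' centroid over a `(2*ceil(psf_sigma_px) + 1)^2` window of the
#' background-subtracted frame. Positions are returned in um (origin
#' top-left, y increasing downward).
#'
#' @param stack A [frame_stack()] with `pixel_size_um` metadata.
#' @param threshold_sd Detection threshold in robust-sd units above
#'   background (default 5).
#' @param psf_sigma_hint Expected spot sigma in um; defaults to the stack's
#'   `psf_sigma_um` metadata, or 2 pixels if absent.
#' @return data.frame with columns `frame` (0-based), `x_um`, `y_um`,
#'   `intensity`, ordered by frame then descending intensity.
#' @export
detect_beads <- function(stack, threshold_sd = 5, psf_sigma_hint = NULL) {
  if (is.null(attr(stack, "pixel_size_um")))
    stop("stack is missing field: pixel_size_um", call. = FALSE)
  ps <- attr(stack, "pixel_size_um")
  if (is.null(psf_sigma_hint)) {
    psf_sigma_hint <- attr(stack, "psf_sigma_um")
    if (is.null(psf_sigma_hint) || is.na(psf_sigma_hint))
      psf_sigma_hint <- 2 * ps
  }
  sig_px <- max(psf_sigma_hint / ps, 0.5)
  half <- ceiling(sig_px)
  a <- unclass(stack)
  if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
  nf <- dim(a)[3]

  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    img <- a[, , f]
    dog <- EBImage::gblur(img, sigma = sig_px) -
           EBImage::gblur(img, sigma = 2 * sig_px)
    thr <- robust_threshold(as.vector(dog), threshold_sd)
    mx <- local_maxima(dog)
    keep <- which(mx & dog > thr, arr.ind = TRUE)
    if (nrow(keep) == 0) next
    bg <- stats::median(img)
    sub <- img - bg
    sub[sub < 0] <- 0
    h <- dim(img)[1]; w <- dim(img)[2]
    res <- matrix(NA_real_, nrow = nrow(keep), ncol = 3L)
    for (k in seq_len(nrow(keep))) {
      r <- keep[k, 1L]; c <- keep[k, 2L]
      r0 <- max(1L, r - half); r1 <- min(h, r + half)
      c0 <- max(1L, c - half); c1 <- min(w, c + half)
      win <- sub[r0:r1, c0:c1, drop = FALSE]
      tot <- sum(win)
      if (tot <= 0) next
      rc <- sum(rowSums(win) * (r0:r1)) / tot
      cc <- sum(colSums(win) * (c0:c1)) / tot
      res[k, ] <- c((cc - 0.5) * ps, (rc - 0.5) * ps, tot)
    }
    res <- res[!is.na(res[, 3L]), , drop = FALSE]
    if (nrow(res) == 0) next
    out[[f]] <- data.frame(frame = f - 1L, x_um = res[, 1L],
                           y_um = res[, 2L], intensity = res[, 3L])
  }
  det <- do.call(rbind, out)
  if (is.null(det))
    return(data.frame(frame = integer(), x_um = numeric(),
                      y_um = numeric(), intensity = numeric()))
  det <- det[order(det$frame, -det$intensity), ]
  rownames(det) <- NULL
  det
}

# strict local maxima over the 8-neighbourhood, computed by shifted
# comparisons; border pixels are excluded
local_maxima <- function(m) {
  h <- nrow(m); w <- ncol(m)
  if (h < 3L || w < 3L) return(matrix(FALSE, h, w))
  pad <- matrix(-Inf, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- m
  res <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    res <- res & (m > pad[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc])
  }
  res[c(1L, h), ] <- FALSE
  res[, c(1L, w)] <- FALSE
  res
}
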