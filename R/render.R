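#' Render a ground-truth bead set into a time-lapse frame stack
#'
#' Produces one 2D image per frame. Each visible bead is rendered as an
#' isotropic Gaussian spot of standard deviation `psf_sigma` centred at its
#' true position, on a constant background with additive Gaussian readout
#' noise; pixel values are rounded to integer counts (camera digitization)
#' and clipped to `[0, 65535]`. Image dimensions are the field size divided
#' by the pixel size, rounded down. Pixel `(r, c)` (1-based, row = y) covers
#' `[(c-1)*pixel_size, c*pixel_size) x [(r-1)*pixel_size, r*pixel_size)` in
#' um, origin at the top-left corner with y increasing downward.
#'
#' @param truth A [ground_truth()] object (carries the acquisition spec).
#' @return A `frame_stack`: numeric array `[rows, cols, frames]` with
#'   attributes `pixel_size_um`, `frame_interval_s`, `psf_sigma_um`.
#' @export
render_frames <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  acq <- attr(truth, "acq")
  ps <- acq$pixel_size
  sigma <- acq$psf_sigma
  if (sigma < ps)
    warning("psf_sigma (", sigma, " um) is smaller than one pixel (", ps,
            " um); spots render essentially on the nearest pixel")
  w <- floor(acq$field_width / ps)
  h <- floor(acq$field_height / ps)
  nf <- acq$n_frames
  stack <- array(acq$background_level, dim = c(h, w, nf))

  half <- max(1L, ceiling(4 * sigma / ps))
  vis <- truth[truth$visible, , drop = FALSE]
  if (nrow(vis) > 0) {
    for (k in seq_len(nrow(vis))) {
      f <- vis$frame[k] + 1L
      # continuous pixel coordinates of the bead centre
      cx <- vis$x_um[k] / ps + 0.5
      cy <- vis$y_um[k] / ps + 0.5
      c0 <- max(1L, floor(cx) - half); c1 <- min(w, floor(cx) + half)
      r0 <- max(1L, floor(cy) - half); r1 <- min(h, floor(cy) + half)
      if (c0 > c1 || r0 > r1) next
      xs <- (c0:c1) - cx
      ys <- (r0:r1) - cy
      spot <- acq$bead_amplitude *
        outer(exp(-ys^2 / (2 * (sigma / ps)^2)),
              exp(-xs^2 / (2 * (sigma / ps)^2)))
      stack[r0:r1, c0:c1, f] <- stack[r0:r1, c0:c1, f] + spot
    }
  }
  if (acq$noise_sd > 0) {
    stack <- stack + with_seed(derive_seed(acq$seed, "render"),
      array(stats::rnorm(length(stack), 0, acq$noise_sd), dim = dim(stack)))
  }
  stack <- round(stack)
  stack[stack < 0] <- 0
  stack[stack > 65535] <- 65535
  frame_stack(stack, pixel_size = ps, frame_interval = acq$frame_interval,
              psf_sigma = sigma)
}

#' Construct a frame stack with geometry metadata
#'
#' @param a Numeric array `[rows, cols, frames]` (a single matrix is treated
#'   as a one-frame stack).
#' @param pixel_size Pixel size in um/px.
#' @param frame_interval Frame interval in seconds (optional).
#' @param psf_sigma Spot sigma in um (optional hint for detection).
#' @return A `frame_stack` object.
#' @export
frame_stack <- function(a, pixel_size, frame_interval = NA_real_,
                        psf_sigma = NA_real_) {
  if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
  stopifnot(length(dim(a)) == 3L)
  check_num(pixel_size, "pixel_size")
  if (pixel_size <= 0) stop_field("pixel_size", "must be > 0")
  structure(a, pixel_size_um = pixel_size, frame_interval_s = frame_interval,
            psf_sigma_um = psf_sigma, class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x)
  cat("Frame stack:", d[3], "frames of", d[1], "x", d[2], "px @",
      attr(x, "pixel_size_um"), "um/px\n")
  invisible(x)
}

#' Write and read image stacks as multi-page TIFF with metadata sidecar
#'
#' Images are stored as 16-bit multi-page TIFF. Geometry metadata (pixel
#' size, frame interval or z-step) that baseline TIFF writers cannot embed as
#' custom tags is carried in a JSON sidecar file (`<path>.meta.json`) written
#' and read by this pair, so a write-then-read round trip reproduces both the
#' pixel values (integer counts) and the metadata exactly.
#'
#' @param stack A [frame_stack()] (or any array with values in
#'   `[0, 65535]`).
#' @param path Output TIFF path.
#' @return `write_stack_tiff` returns `path` invisibly; `read_stack_tiff`
#'   returns a `frame_stack`.
#' @export
write_stack_tiff <- function(stack, path) {
  a <- unclass(stack)
  if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
  pages <- lapply(seq_len(dim(a)[3]), function(i) a[, , i] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  meta <- list(pixel_size_um = attr(stack, "pixel_size_um"),
               frame_interval_s = attr(stack, "frame_interval_s"),
               psf_sigma_um = attr(stack, "psf_sigma_um"),
               z_step_um = attr(stack, "z_step_um"))
  meta <- meta[!vapply(meta, function(v) is.null(v) || all(is.na(v)),
                       logical(1))]
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  a <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (i in seq_along(pages)) a[, , i] <- round(pages[[i]] * 65535)
  mpath <- paste0(path, ".meta.json")
  if (!file.exists(mpath))
    stop("stack metadata sidecar not found (missing field: pixel_size_um): ",
         mpath, call. = FALSE)
  meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (is.null(meta$pixel_size_um))
    stop("stack metadata missing field: pixel_size_um", call. = FALSE)
  out <- frame_stack(a, pixel_size = meta$pixel_size_um,
                     frame_interval = meta$frame_interval_s %||% NA_real_,
                     psf_sigma = meta$psf_sigma_um %||% NA_real_)
  if (!is.null(meta$z_step_um)) attr(out, "z_step_um") <- meta$z_step_um
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
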