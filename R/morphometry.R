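#' Ciliated fraction of an epithelial trace
#'
#' Percentage of the epithelial surface covered by ciliated segments:
#' `100 * sum(ciliated segment lengths) / total polyline length`. Invariant
#' under re-parameterization (splitting a segment into two with the same
#' label leaves the result unchanged).
#'
#' @param trace An [epithelial_trace()].
#' @return Percentage in `[0, 100]`.
#' @export
ciliated_fraction <- function(trace) {
  stopifnot(inherits(trace, "epithelial_trace"))
  seg_len <- sqrt(rowSums(diff(trace$vertices)^2))
  total <- sum(seg_len)
  if (total == 0) stop("trace has zero total length", call. = FALSE)
  100 * sum(seg_len[trace$ciliated]) / total
}

#' Per-cell cilia height from a two-channel z-stack
#'
#' For each labelled cell footprint, the apical reference plane
#' (`junction_z`) is the z-plane of maximal junction-marker signal within
#' the footprint, and the cilia top (`cilia_top_z`) is the highest z-plane
#' whose cilia-marker signal in the footprint exceeds the channel's robust
#' background threshold (median + `intensity_threshold_sd` x scaled MAD).
#' Height is the difference, floored at zero; heights are quantized to the
#' z-step of the source volume. Cells with no supra-threshold cilia signal
#' are reported with height 0 and flagged.
#'
#' @param volume A [simulate_zstack()] result, or any list with `junction`
#'   and `cilia` 3D arrays, `labels` matrix, and `z_step_um`.
#' @param intensity_threshold_sd Threshold in robust-sd units (default 3).
#' @return data.frame with columns `cell_id`, `junction_z_um`,
#'   `cilia_top_z_um`, `height_um`, `no_signal`.
#' @export
cilia_heights <- function(volume, intensity_threshold_sd = 3) {
  if (is.null(volume$z_step_um))
    stop("volume is missing field: z_step_um", call. = FALSE)
  if (is.null(volume$junction) || is.null(volume$cilia))
    stop("volume must carry 'junction' and 'cilia' channels", call. = FALSE)
  z_step <- volume$z_step_um
  nz <- dim(volume$cilia)[3]
  z_centers <- (seq_len(nz) - 0.5) * z_step
  thr <- robust_threshold(as.vector(volume$cilia), intensity_threshold_sd)

  ids <- sort(setdiff(unique(as.vector(volume$labels)), 0L))
  out <- lapply(ids, function(id) {
    mask <- volume$labels == id
    jprof <- vapply(seq_len(nz),
                    function(z) sum(volume$junction[, , z][mask]), numeric(1))
    jz <- which.max(jprof)
    # mean footprint intensity per plane, compared to the voxel threshold
    cprof <- vapply(seq_len(nz),
                    function(z) mean(volume$cilia[, , z][mask]), numeric(1))
    supra <- which(cprof > thr)
    if (length(supra) == 0) {
      data.frame(cell_id = id, junction_z_um = z_centers[jz],
                 cilia_top_z_um = z_centers[jz], height_um = 0,
                 no_signal = TRUE)
    } else {
      top <- max(supra)
      data.frame(cell_id = id, junction_z_um = z_centers[jz],
                 cilia_top_z_um = z_centers[top],
                 height_um = max((top - jz) * z_step, 0),
                 no_signal = FALSE)
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Positive-area fraction of a projection image
#'
#' Percentage of pixels above the robust background threshold
#' (median + `threshold_sd` x scaled MAD): the quantification used for
#' stain-positive area on merged grayscale z-stack projections. Monotone
#' non-increasing in `threshold_sd`.
#'
#' @param img A [simulate_projection()] result or any numeric matrix; an
#'   optional `pixel_size_um` attribute is carried but not required.
#' @param threshold_sd Threshold in robust-sd units (default 3).
#' @return Percentage in `[0, 100]`.
#' @export
positive_area_fraction <- function(img, threshold_sd = 3) {
  m <- as.matrix(img)
  if (any(m < 0)) stop_field("img", "intensities must be non-negative")
  if (stats::mad(as.vector(m)) == 0 &&
      length(unique(as.vector(m))) == 1L) {
    warning("constant image: positive area reported as 0%")
    return(0)
  }
  thr <- robust_threshold(as.vector(m), threshold_sd)
  100 * mean(m > thr)
}

#' Positive-cell density per reference area
#'
#' Scales a raw cell count in a square counting region to the assay's
#' reference area of a 200 x 200 um square (40,000 um^2):
#' `count * 40000 / region_side^2`.
#'
#' @param count Number of positive cells counted.
#' @param region_side Side of the square counting region, um (> 0).
#' @return Cells per 40,000 um^2.
#' @export
#' @examples
#' positive_cell_density(10, 200)  # 10
#' positive_cell_density(10, 100)  # 40
positive_cell_density <- function(count, region_side) {
  check_num(count, "count", lower = 0)
  check_num(region_side, "region_side")
  if (region_side <= 0) stop_field("region_side", "must be > 0")
  count * 40000 / region_side^2
}

#' Total flux within a rectangular region of interest
#'
#' Sum of pixel values inside the rectangle — the whole-animal imaging
#' readout of retained fluorescent particles. Use [roi_flux_table()] when
#' comparing across images: it enforces identical ROI dimensions.
#'
#' @param image Numeric matrix.
#' @param roi Rectangle `c(row0, col0, height, width)` (1-based, inside the
#'   image, area > 0).
#' @return Summed intensity.
#' @export
roi_total_flux <- function(image, roi) {
  image <- as.matrix(image)
  if (length(roi) != 4) stop_field("roi", "need c(row0, col0, height, width)")
  r0 <- roi[1]; c0 <- roi[2]; h <- roi[3]; w <- roi[4]
  if (h <= 0 || w <= 0) stop_field("roi", "area must be > 0")
  if (r0 < 1 || c0 < 1 || r0 + h - 1 > nrow(image) || c0 + w - 1 > ncol(image))
    stop_field("roi", "must lie inside the image")
  sum(image[r0:(r0 + h - 1), c0:(c0 + w - 1)])
}

#' @rdname roi_total_flux
#' @param images List of numeric matrices to compare.
#' @param rois List of rectangles, one per image; all must have identical
#'   height and width (equally sized ROIs), or an error is raised.
#' @export
roi_flux_table <- function(images, rois) {
  stopifnot(length(images) == length(rois))
  dims <- vapply(rois, function(r) r[3:4], numeric(2))
  if (length(rois) > 1 && (length(unique(dims[1, ])) > 1 ||
                           length(unique(dims[2, ])) > 1))
    stop("ROI sizes differ across the comparison set; ",
         "all rectangles must have identical dimensions", call. = FALSE)
  data.frame(image = seq_along(images),
             total_flux = mapply(roi_total_flux, images, rois))
}
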