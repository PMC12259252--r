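#' Simulate a two-channel confocal z-stack of ciliated cells
#'
#' Generates the measurement substrate for per-cell cilia-height
#' quantification: cells are laid out as square footprints on a grid (the
#' label mask); the tight-junction channel concentrates at a single z-plane
#' per cell (the apical reference plane), and the cilia channel occupies the
#' z-range from the junction plane up to `junction + height`, with per-cell
#' heights drawn from `Normal(height_mean, height_sd)` truncated at a small
#' positive floor. Gaussian noise is added to both channels. Cells whose
#' true height is below one z-step are generated but flagged sub-resolution.
#'
#' @param n_cells Number of cells.
#' @param height_mean,height_sd Cilia height distribution, um.
#' @param z_step Axial sampling, um (> 0).
#' @param seed Integer seed.
#' @param pixel_size Lateral pixel size, um/px.
#' @param field_size Lateral field size, um (square; default 96.88, two of
#'   which hold the typical 20-30 ciliated cells each at the default cell
#'   pitch).
#' @param signal,background,noise_sd Channel intensity parameters (counts).
#' @return A `cilia_zstack`: list with `junction` and `cilia` (3D arrays
#'   `[y, x, z]`), `labels` (integer matrix), `z_step_um`, `pixel_size_um`,
#'   `cells` (data.frame: `cell_id`, `junction_z_um`, `true_height_um`,
#'   `sub_resolution`).
#' @export
simulate_zstack <- function(n_cells = 25, height_mean = 5, height_sd = 1,
                            z_step = 0.5, seed = 1L, pixel_size = 1,
                            field_size = 96.88, signal = 200,
                            background = 20, noise_sd = 4) {
  check_num(n_cells, "n_cells", lower = 1)
  check_num(z_step, "z_step")
  if (z_step <= 0) stop_field("z_step", "must be > 0")
  check_num(height_mean, "height_mean")
  if (height_mean <= 0) stop_field("height_mean", "heights must be positive")
  check_num(height_sd, "height_sd", lower = 0)

  npx <- floor(field_size / pixel_size)
  ncol_cells <- ceiling(sqrt(n_cells))
  nrow_cells <- ceiling(n_cells / ncol_cells)
  cw <- npx %/% ncol_cells
  ch <- npx %/% nrow_cells
  if (cw < 3 || ch < 3)
    stop_field("n_cells", "too many cells for the field size")

  res <- with_seed(derive_seed(seed, "zstack"), {
    heights <- pmax(stats::rnorm(n_cells, height_mean, height_sd), 0.25)
    junction_z <- stats::runif(n_cells, 0.5, 2.5)
    list(heights = heights, junction_z = junction_z)
  })
  heights <- res$heights
  # the junction reference is an acquired plane: snap to the nearest plane
  # centre so recovered heights are quantized to the z-step, not to 1.5 steps
  junction_z <- (round(res$junction_z / z_step + 0.5) - 0.5) * z_step

  nz <- ceiling((max(junction_z + heights) + 2) / z_step)
  labels <- matrix(0L, npx, npx)
  junction <- array(0, dim = c(npx, npx, nz))
  cilia <- array(0, dim = c(npx, npx, nz))
  z_centers <- (seq_len(nz) - 0.5) * z_step

  for (i in seq_len(n_cells)) {
    r <- (i - 1L) %/% ncol_cells
    c <- (i - 1L) %% ncol_cells
    rows <- (r * ch + 2L):min((r + 1L) * ch - 1L, npx)
    cols <- (c * cw + 2L):min((c + 1L) * cw - 1L, npx)
    labels[rows, cols] <- i
    jz <- which.min(abs(z_centers - junction_z[i]))
    junction[rows, cols, jz] <- junction[rows, cols, jz] + signal
    top <- junction_z[i] + heights[i]
    zin <- which(z_centers >= z_centers[jz] & z_centers <= top)
    if (length(zin)) cilia[rows, cols, zin] <- cilia[rows, cols, zin] + signal
  }

  if (noise_sd > 0 || background > 0) {
    noise <- with_seed(derive_seed(seed, "zstack", 1L), list(
      j = array(stats::rnorm(length(junction), background, noise_sd),
                dim = dim(junction)),
      c = array(stats::rnorm(length(cilia), background, noise_sd),
                dim = dim(cilia))))
    junction <- pmax(junction + noise$j, 0)
    cilia <- pmax(cilia + noise$c, 0)
  }

  cells <- data.frame(cell_id = seq_len(n_cells),
                      junction_z_um = junction_z,
                      true_height_um = heights,
                      sub_resolution = heights < z_step)
  structure(list(junction = junction, cilia = cilia, labels = labels,
                 z_step_um = z_step, pixel_size_um = pixel_size,
                 cells = cells),
            class = "cilia_zstack")
}

#' @export
print.cilia_zstack <- function(x, ...) {
  d <- dim(x$junction)
  cat("Ciliated-cell z-stack:", nrow(x$cells), "cells,",
      d[1], "x", d[2], "px x", d[3], "planes @", x$z_step_um, "um\n")
  invisible(x)
}

#' Simulate an epithelial surface trace with ciliated segments
#'
#' Emulates the manual line-tool measurement of epithelial and ciliated
#' surface length: a gently undulating polyline of `n_segments` equal-length
#' segments, each labelled ciliated or not. Labels are allocated in a seeded
#' random order by a deterministic largest-remainder rule so the
#' length-weighted ciliated share matches `ciliated_fraction` to within one
#' segment's length (exactly, when the target is a whole number of
#' segments).
#'
#' @param total_length Total polyline length, um.
#' @param ciliated_fraction Target ciliated share of the length, `[0, 1]`.
#' @param n_segments Number of segments (>= 1).
#' @param seed Integer seed for the allocation order and undulation.
#' @return An `epithelial_trace`: list with `vertices`
#'   (`(n_segments + 1) x 2` matrix, um) and `ciliated` (logical per
#'   segment).
#' @export
simulate_epithelial_trace <- function(total_length = 500,
                                      ciliated_fraction = 0.5,
                                      n_segments = 100, seed = 1L) {
  check_num(n_segments, "n_segments", lower = 1)
  check_num(ciliated_fraction, "ciliated_fraction", lower = 0, upper = 1)
  check_num(total_length, "total_length")
  if (total_length <= 0) stop_field("total_length", "must be > 0")
  n_segments <- as.integer(n_segments)
  seg_len <- total_length / n_segments

  res <- with_seed(derive_seed(seed, "trace"), {
    ang <- cumsum(stats::rnorm(n_segments, 0, 0.15))  # gentle undulation
    ord <- sample.int(n_segments)
    list(ang = ang, ord = ord)
  })
  steps <- cbind(seg_len * cos(res$ang), seg_len * sin(res$ang))
  vertices <- rbind(c(0, 0), apply(steps, 2, cumsum))

  target <- ciliated_fraction * total_length
  ciliated <- logical(n_segments)
  acc <- 0
  for (i in res$ord) {
    # add the segment only if that lands closer to the target than stopping
    if (abs(acc + seg_len - target) < abs(acc - target)) {
      ciliated[i] <- TRUE
      acc <- acc + seg_len
    }
  }
  epithelial_trace(vertices, ciliated)
}

#' Construct an epithelial trace
#'
#' @param vertices `(n + 1) x 2` matrix of polyline vertices in um.
#' @param ciliated Logical vector of length n: per-segment ciliated flag.
#' @return An `epithelial_trace` object.
#' @export
epithelial_trace <- function(vertices, ciliated) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2 || ncol(vertices) != 2)
    stop_field("vertices", "need an (n+1) x 2 matrix with n >= 1")
  if (length(ciliated) != nrow(vertices) - 1L)
    stop_field("ciliated", "need one flag per segment")
  seg_len <- sqrt(rowSums(diff(vertices)^2))
  if (any(seg_len <= 0)) stop_field("vertices", "segment lengths must be > 0")
  structure(list(vertices = vertices, ciliated = as.logical(ciliated)),
            class = "epithelial_trace")
}

#' Read and write epithelial traces as CSV polylines
#'
#' Columns `x_um`, `y_um`, `ciliated_flag`; the flag on row i labels the
#' segment ending at vertex i (first row carries `NA`).
#'
#' @param trace An `epithelial_trace`.
#' @param path CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(x_um = trace$vertices[, 1], y_um = trace$vertices[, 2],
                   ciliated_flag = c(NA, as.integer(trace$ciliated)))
  write_table_csv(df, path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  epithelial_trace(cbind(df$x_um, df$y_um), df$ciliated_flag[-1] > 0)
}

#' Simulate a merged-projection image with a known positive-area fraction
#'
#' Paints a contiguous block of pixels at `frac_positive` of the image area
#' to a plateau `snr` robust-sd units above a noisy background — the ground
#' truth for validating positive-area quantification on merged z-stack
#' projections.
#'
#' @param frac_positive True positive-area fraction, `[0, 1]`.
#' @param snr Plateau height in units of the background noise sd.
#' @param dim Image dimensions `c(rows, cols)`.
#' @param pixel_size Pixel size, um/px.
#' @param background,noise_sd Background mean and sd (counts).
#' @param seed Integer seed.
#' @return A `projection_image`: matrix with attributes `pixel_size_um` and
#'   `true_fraction`.
#' @export
simulate_projection <- function(frac_positive = 0.125, snr = 10,
                                dim = c(256, 256), pixel_size = 0.5,
                                background = 50, noise_sd = 5, seed = 1L) {
  check_num(frac_positive, "frac_positive", lower = 0, upper = 1)
  img <- with_seed(derive_seed(seed, "projection"),
    matrix(stats::rnorm(prod(dim), background, noise_sd), dim[1], dim[2]))
  n_pos <- round(frac_positive * prod(dim))
  if (n_pos > 0) {
    idx <- seq_len(n_pos)  # contiguous column-major block
    img[idx] <- img[idx] + snr * noise_sd
  }
  img <- pmax(img, 0)
  structure(img, pixel_size_um = pixel_size,
            true_fraction = n_pos / prod(dim),
            class = c("projection_image", "matrix", "array"))
}
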