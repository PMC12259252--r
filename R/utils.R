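#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a named sub-stream seed from a master seed; keeps results < 2^31 and
# makes the motion / dropout / rendering streams independently reproducible.
derive_seed <- function(seed, stream, index = 0L) {
  offsets <- c(motion = 1L, patches = 2L, dropout = 3L, render = 4L,
               zstack = 5L, trace = 6L, projection = 7L, selection = 8L,
               pipeline = 9L)
  if (!stream %in% names(offsets)) stop("unknown RNG stream: ", stream)
  (as.integer(seed) + 1000L * offsets[[stream]] + as.integer(index)) %%
    2147483587L
}

# Robust background threshold: median + k * MAD (scaled). Shared by the bead
# detector and every morphometry thresholding rule.
robust_threshold <- function(x, threshold_sd) {
  med <- stats::median(x)
  s <- stats::mad(x, center = med)
  med + threshold_sd * s
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

check_num <- function(x, field, lower = -Inf, upper = Inf, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(!is.finite(x)))
    stop_field(field, "must be a finite numeric value")
  if (any(x < lower)) stop_field(field, paste("must be >=", lower))
  if (any(x > upper)) stop_field(field, paste("must be <=", upper))
  invisible(x)
}

euclid <- function(p, q) sqrt(sum((p - q)^2))
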