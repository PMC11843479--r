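#' Time series of complex B-scans
#'
#' @param data 3-D complex array `(m_z, n_x, n_t)` or list of [oct_image]s.
#' @param system The [oct_system] (required for arrays).
#' @param times Optional frame timestamps (seconds); default frame index.
#' @return An `oct_stack`.
#' @export
oct_stack <- function(data, system = NULL, times = NULL) {
  if (is.list(data) && length(data) && inherits(data[[1L]], "oct_image")) {
    v <- .as_volume(data)
    data <- v$data; system <- v$system
  }
  stopifnot(is.array(data), length(dim(data)) == 3L,
            inherits(system, "oct_system"))
  if (!identical(dim(data)[1:2], c(system$m_z, system$n_x))) {
    stop("stack frame dimensions must be (m_z, n_x)")
  }
  n_t <- dim(data)[3L]
  if (is.null(times)) times <- seq_len(n_t) - 1
  stopifnot(length(times) == n_t)
  structure(list(data = data, system = system, times = as.numeric(times)),
            class = "oct_stack")
}

#' @export
print.oct_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<oct_stack> %d frames of %d x %d px\n", d[3L], d[1L], d[2L]))
  invisible(x)
}

#' Extract a stack frame as an image
#' @param stack An [oct_stack].
#' @param i Frame index.
#' @return An [oct_image].
#' @export
stack_frame <- function(stack, i) {
  stopifnot(inherits(stack, "oct_stack"))
  oct_image(stack$data[, , i], stack$system)
}

#' Per-pixel phase trace container
#'
#' Holds per-pixel phase traces over frames as an `n_pixels` x `n_frames`
#' matrix (radians), with the linear pixel indices into the source frame,
#' the frame dimensions, the center wavenumber for OPL conversion, and a
#' wrapped/unwrapped flag. Wrapped values lie in `(-pi, pi]`.
#'
#' @param phase Numeric matrix `n_pixels` x `n_frames` (radians).
#' @param pixels Integer vector of linear pixel indices into the frame.
#' @param dims Frame dimensions `c(m_z, n_x)`.
#' @param k0 Center wavenumber (rad/um) for [phase_to_opl].
#' @param times Frame timestamps.
#' @param wrapped Logical: are values wrapped to `(-pi, pi]`?
#' @return A `phase_series`.
#' @export
phase_series <- function(phase, pixels, dims, k0, times = NULL,
                         wrapped = TRUE) {
  stopifnot(is.matrix(phase), length(pixels) == nrow(phase))
  if (is.null(times)) times <- seq_len(ncol(phase)) - 1
  structure(list(phase = phase, pixels = as.integer(pixels),
                 dims = as.integer(dims), k0 = k0,
                 times = as.numeric(times), wrapped = isTRUE(wrapped)),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> %d pixels x %d frames (%s)\n",
              nrow(x$phase), ncol(x$phase),
              if (x$wrapped) "wrapped" else "unwrapped"))
  invisible(x)
}

#' Per-pixel phase differences against a reference frame
#'
#' For every frame computes the wrapped per-pixel phase of
#' `A_t * conj(A_ref)`; the reference frame's own column is identically
#' zero. Multiplying a frame by a global phase `exp(i theta)` adds `theta`
#' to that frame's column everywhere.
#'
#' @param stack An [oct_stack].
#' @param reference_index Index of the reference frame (default 1).
#' @param pixels Optional logical mask matrix or integer linear indices
#'   restricting the traced pixels (default all).
#' @return A wrapped [phase_series].
#' @export
phase_difference_series <- function(stack, reference_index = 1L,
                                    pixels = NULL) {
  stopifnot(inherits(stack, "oct_stack"))
  d <- dim(stack$data)
  idx <- .pixel_indices(pixels, d[1:2])
  n_t <- d[3L]
  refv <- Conj(stack$data[, , reference_index][idx])
  ph <- matrix(0, length(idx), n_t)
  for (t in seq_len(n_t)) {
    ph[, t] <- Arg(stack$data[, , t][idx] * refv)
  }
  phase_series(ph, idx, d[1:2], stack$system$k0, stack$times, wrapped = TRUE)
}

.pixel_indices <- function(pixels, dims) {
  if (is.null(pixels)) return(seq_len(prod(dims)))
  if (is.logical(pixels)) {
    stopifnot(identical(dim(pixels), as.integer(dims)))
    return(which(pixels))
  }
  if (is.matrix(pixels) && ncol(pixels) == 2L) {
    return(as.integer((pixels[, 2L] - 1L) * dims[1L] + pixels[, 1L]))
  }
  as.integer(pixels)
}

#' Temporal phase unwrapping
#'
#' Removes 2-pi jumps along time independently for every pixel by wrapping
#' each per-step increment into `(-pi, pi]` and accumulating. Correct when
#' the true per-step change is below pi; pixels with any near-pi wrapped
#' step (> 0.9 pi by default) are flagged in the `"suspect"` attribute as
#' potentially aliased. Applying the operation to an already-unwrapped
#' series with sub-pi steps is a no-op.
#'
#' @param series A [phase_series].
#' @param suspect_threshold Wrapped-step magnitude (radians) above which a
#'   pixel is flagged.
#' @return The unwrapped [phase_series] (attribute `suspect`: logical per
#'   pixel).
#' @export
unwrap_temporal <- function(series, suspect_threshold = 0.9 * pi) {
  stopifnot(inherits(series, "phase_series"))
  ph <- series$phase
  if (ncol(ph) > 1L) {
    dp <- .wrap_phase(ph[, -1L, drop = FALSE] - ph[, -ncol(ph), drop = FALSE])
    suspect <- apply(abs(dp), 1L, max) > suspect_threshold
    cum <- if (ncol(dp) > 1L) t(apply(dp, 1L, cumsum)) else dp
    ph <- cbind(ph[, 1L], ph[, 1L] + cum, deparse.level = 0L)
  } else {
    suspect <- rep(FALSE, nrow(ph))
  }
  out <- phase_series(ph, series$pixels, series$dims, series$k0,
                      series$times, wrapped = FALSE)
  attr(out, "suspect") <- suspect
  out
}

#' Convert phase to optical path length
#'
#' `OPL = phase / (2 k0)`, returned in nanometres for `k0` in rad/um.
#'
#' @param phase_rad Phase in radians (any numeric shape).
#' @param k0 Center wavenumber in rad/um.
#' @return OPL in nm, same shape as `phase_rad`.
#' @examples
#' phase_to_opl(pi, 2 * pi / 0.84)   # 210 nm
#' @export
phase_to_opl <- function(phase_rad, k0) {
  phase_rad / (2 * k0) * 1e3
}

#' Spatial standard deviation of the measured OPL change
#'
#' Motion-detection accuracy metric: the population standard deviation,
#' across pixels, of the per-pixel OPL change at one frame.
#'
#' @param series A [phase_series].
#' @param frame Frame index.
#' @param mask Optional logical vector over the series' pixels.
#' @return Standard deviation in nm.
#' @export
spatial_sd <- function(series, frame, mask = NULL) {
  stopifnot(inherits(series, "phase_series"))
  v <- series$phase[, frame]
  if (!is.null(mask)) v <- v[mask]
  .pop_sd(phase_to_opl(v, series$k0))
}

#' Temporal standard deviation of the measured OPL change
#'
#' Motion-detection sensitivity metric: the population standard deviation
#' over frames of each pixel's OPL trace.
#'
#' @param series A [phase_series].
#' @param pixel Optional pixel row index (or vector); default all pixels.
#' @return Standard deviation(s) in nm.
#' @export
temporal_sd <- function(series, pixel = NULL) {
  stopifnot(inherits(series, "phase_series"))
  ph <- series$phase
  if (!is.null(pixel)) ph <- ph[pixel, , drop = FALSE]
  apply(phase_to_opl(ph, series$k0), 1L, .pop_sd)
}

.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' SNR-limited phase sensitivity
#'
#' The phase-noise floor set by image SNR: `sigma_phi = 1/sqrt(SNR)` radians
#' for a single pixel, and `sqrt(1/SNR_1 + 1/SNR_2)` for a self-referenced
#' difference between two pixels; converted to OPL nm via [phase_to_opl].
#'
#' SNR here is the pixel's signal power over the noise variance per
#' quadrature (half the complex noise variance). Under this convention
#' `1/sqrt(SNR)` is the exact high-SNR phase noise of a single pixel; under
#' the total-complex-variance convention the same expression instead gives
#' the floor of an equal-SNR two-pixel difference.
#'
#' @param snr_linear Linear (not dB) intensity SNR (per-quadrature
#'   convention, see above); for `self_referenced = TRUE` a length-2 vector
#'   or 2-column matrix of the two pixels' SNRs.
#' @param k0 Center wavenumber (rad/um).
#' @param self_referenced Two-pixel difference?
#' @return Sensitivity floor in nm.
#' @examples
#' snr_limited_sensitivity(100, 2 * pi / 0.84)   # 6.68 nm
#' @export
snr_limited_sensitivity <- function(snr_linear, k0, self_referenced = FALSE) {
  if (self_referenced) {
    m <- if (is.matrix(snr_linear)) snr_linear else matrix(snr_linear, ncol = 2L)
    sigma_phi <- sqrt(1 / m[, 1L] + 1 / m[, 2L])
  } else {
    sigma_phi <- 1 / sqrt(snr_linear)
  }
  phase_to_opl(sigma_phi, k0)
}

#' Self-referenced phase traces
#'
#' For each frame, the phase of each measurement pixel relative to the
#' amplitude-weighted mean of a reference pixel set (their complex sum), so
#' that any per-frame global phase drift common to both cancels. This is
#' the standard depth self-referencing used to read local deformation
#' (e.g. outer-segment OPL change between two retinal layers) from a moving
#' sample.
#'
#' @param stack An [oct_stack].
#' @param pixels_a Reference pixel set (logical mask, linear indices, or
#'   two-column row/col matrix).
#' @param pixels_b Measurement pixel set (same conventions).
#' @return A wrapped [phase_series] over `pixels_b`.
#' @export
self_referenced_phase <- function(stack, pixels_a, pixels_b) {
  stopifnot(inherits(stack, "oct_stack"))
  d <- dim(stack$data)
  ia <- .pixel_indices(pixels_a, d[1:2])
  ib <- .pixel_indices(pixels_b, d[1:2])
  if (!length(ia)) stop("empty reference pixel set")
  ph <- matrix(0, length(ib), d[3L])
  for (t in seq_len(d[3L])) {
    fr <- stack$data[, , t]
    ph[, t] <- Arg(fr[ib] * Conj(sum(fr[ia])))
  }
  phase_series(ph, ib, d[1:2], stack$system$k0, stack$times, wrapped = TRUE)
}

#' Outlier pixel mask for phase analysis
#'
#' Excludes pixels that are unreliable for phase metrics: those whose
#' time-averaged amplitude SNR falls below a threshold (when a noise floor
#' is supplied), and those whose OPL trace deviates from the per-frame
#' spatial median trace by more than a multiple of the per-frame median
#' absolute deviation.
#'
#' @param stack An [oct_stack].
#' @param series A [phase_series] over a subset of the stack's pixels.
#' @param snr_db_threshold Minimum amplitude SNR in dB (intensity ratio);
#'   used only when `noise_floor` is given.
#' @param mad_multiplier Deviation threshold in per-frame MAD units.
#' @param noise_floor Amplitude of the noise floor (same units as the image
#'   modulus), or `NULL` to skip the SNR criterion.
#' @return Logical vector over the series' pixels: `TRUE` = keep.
#' @export
outlier_mask <- function(stack, series, snr_db_threshold = 10,
                         mad_multiplier = 5, noise_floor = NULL) {
  stopifnot(inherits(stack, "oct_stack"), inherits(series, "phase_series"))
  keep <- rep(TRUE, nrow(series$phase))
  if (!is.null(noise_floor)) {
    n_t <- dim(stack$data)[3L]
    amp <- rowMeans(vapply(seq_len(n_t),
                           function(t) Mod(stack$data[, , t][series$pixels]),
                           numeric(length(series$pixels))))
    snr_db <- 10 * log10((amp / noise_floor)^2)
    keep <- keep & snr_db >= snr_db_threshold
  }
  opl <- phase_to_opl(series$phase, series$k0)
  med <- apply(opl, 2L, stats::median)
  dev <- abs(sweep(opl, 2L, med))
  scale <- apply(opl, 2L, stats::mad)
  scale[scale == 0] <- .Machine$double.eps
  keep & !apply(sweep(dev, 2L, mad_multiplier * scale, `>`), 1L, any)
}
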