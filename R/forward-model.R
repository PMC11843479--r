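#' Spectral interferogram container
#'
#' A complex matrix indexed (A-line x, wavenumber k) together with the system
#' it was sampled on and a detector flag: `"analytic"` frames hold the
#' complex-valued interferogram; `"real"` frames hold the real-valued
#' detector signal (zero imaginary part).
#'
#' @param data Complex matrix `n_x` x `n_k`.
#' @param system The [oct_system] the frame was sampled on.
#' @param detector `"analytic"` or `"real"`.
#' @return A `spectral_frame` object.
#' @export
spectral_frame <- function(data, system, detector = "analytic") {
  stopifnot(inherits(system, "oct_system"), is.matrix(data))
  if (!identical(dim(data), c(system$n_x, system$n_k))) {
    stop("frame dimensions must be (n_x, n_k)")
  }
  detector <- match.arg(detector, c("analytic", "real"))
  if (detector == "real" && any(Im(data) != 0)) {
    stop("real-detector frames must have zero imaginary part")
  }
  structure(list(data = data, system = system, detector = detector),
            class = "spectral_frame")
}

#' @export
print.spectral_frame <- function(x, ...) {
  cat(sprintf("<spectral_frame> %d A-lines x %d wavenumbers (%s detector)\n",
              nrow(x$data), ncol(x$data), x$detector))
  invisible(x)
}

#' Complex OCT image container
#'
#' A complex matrix indexed (depth z, A-line x) holding the reconstructed
#' positive-OPD half of a B-scan, plus the system geometry and a lateral
#' validity mask (columns invalidated by circular lateral shifts).
#'
#' @param data Complex matrix `m_z` x `n_x`.
#' @param system The [oct_system].
#' @param valid_cols Logical vector of length `n_x`; defaults to all valid.
#' @return An `oct_image` object.
#' @export
oct_image <- function(data, system, valid_cols = NULL) {
  stopifnot(inherits(system, "oct_system"), is.matrix(data))
  if (!identical(dim(data), c(system$m_z, system$n_x))) {
    stop("image dimensions must be (m_z, n_x)")
  }
  if (is.null(valid_cols)) valid_cols <- rep(TRUE, system$n_x)
  stopifnot(length(valid_cols) == system$n_x)
  structure(list(data = data, system = system,
                 valid_cols = as.logical(valid_cols)),
            class = "oct_image")
}

#' @export
print.oct_image <- function(x, ...) {
  cat(sprintf("<oct_image> %d x %d px (dz = %.3g um, dx = %.3g um), %d/%d columns valid\n",
              nrow(x$data), ncol(x$data), x$system$dz_um, x$system$dx_um,
              sum(x$valid_cols), length(x$valid_cols)))
  invisible(x)
}

#' @export
plot.oct_image <- function(x, log_floor_db = -40, ...) {
  a <- Mod(x$data)
  a <- a / max(a, .Machine$double.eps)
  db <- pmax(20 * log10(pmax(a, .Machine$double.xmin)), log_floor_db)
  graphics::image(
    x = seq_len(ncol(db)) * x$system$dx_um,
    y = seq_len(nrow(db)) * x$system$dz_um,
    z = t(db)[, rev(seq_len(nrow(db))), drop = FALSE],
    col = grDevices::grey.colors(256, start = 0, end = 1),
    xlab = "x (um)", ylab = "z (um, OPL)", ...)
  invisible(x)
}

#' Simulate a spectral interferogram from a scatterer field
#'
#' Evaluates the discrete FD-OCT forward model on the system's wavenumber
#' grid: for A-line position `x` and wavenumber `k`,
#' `I(x, k) = S(k) * sum_j r_j exp(-2 (x - x_j)^2 / w_l^2) exp(i 2 k z_j)`.
#' The real-detector mode returns `2 * Re` of the analytic frame. Detector
#' noise, when requested, is i.i.d. circular complex Gaussian in the
#' spectral domain, scaled so the reconstructed-image peak intensity SNR of
#' a unit calibration reflector at an A-line center equals `noise_snr_db`;
#' in real mode the noisy analytic frame is formed first and then projected.
#'
#' @param field A [scatterer_field] inside the system's guarded axial span.
#' @param system An [oct_system].
#' @param detector `"analytic"` (default) or `"real"`.
#' @param noise_snr_db Optional image-domain peak SNR (dB) of a unit
#'   reflector; `NULL` for noise-free.
#' @param seed Optional integer seed for the noise draw.
#' @param periodic_lateral If `TRUE`, beam profiles wrap at the image width
#'   (the scatterer field tiles laterally); this makes lateral translation
#'   exactly equivalent to a circular Fourier shift along x and is the mode
#'   used by the sweep experiments.
#' @return A [spectral_frame].
#' @export
simulate_interferogram <- function(field, system,
                                   detector = c("analytic", "real"),
                                   noise_snr_db = NULL, seed = NULL,
                                   periodic_lateral = FALSE) {
  stopifnot(inherits(field, "scatterer_field"), inherits(system, "oct_system"))
  detector <- match.arg(detector)
  span <- guarded_axial_span(system)
  if (nrow(field) &&
      (min(field$z_um) < span[1] || max(field$z_um) > span[2])) {
    stop("field outside the guarded axial span of the system")
  }
  n_x <- system$n_x; n_k <- system$n_k
  frame <- matrix(0i, n_x, n_k)
  if (nrow(field)) {
    xs <- (seq_len(n_x) - 1L) * system$dx_um
    g <- .beam_matrix(xs, field$x_um, system$w_l_um,
                      periodic = periodic_lateral,
                      period = n_x * system$dx_um)
    g <- sweep(g, 2L, field$r, `*`)       # fold reflectivity into the weights
    # chunk over k to bound the (n_scatterer x n_k) phasor memory
    chunk <- max(1L, min(n_k, as.integer(ceiling(2^24 / max(1L, nrow(field))))))
    for (i0 in seq.int(1L, n_k, by = chunk)) {
      idx <- i0:min(n_k, i0 + chunk - 1L)
      ph <- outer(field$z_um, 2 * system$k[idx])
      re <- g %*% cos(ph)
      im <- g %*% sin(ph)
      frame[, idx] <- complex(real = re, imaginary = im)
    }
    frame <- sweep(frame, 2L, system$spectrum, `*`)
  }
  if (!is.null(noise_snr_db)) {
    sigma <- sum(system$spectrum) / sqrt(n_k * 10^(noise_snr_db / 10))
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    if (!is.null(seed)) set.seed(as.integer(seed))
    frame <- frame + complex(
      real = stats::rnorm(n_x * n_k, sd = sigma / sqrt(2)),
      imaginary = stats::rnorm(n_x * n_k, sd = sigma / sqrt(2)))
  }
  if (detector == "real") frame <- 2 * Re(frame) + 0i
  spectral_frame(frame, system, detector)
}

# lateral Gaussian amplitude weights, optionally wrapped on a period
.beam_matrix <- function(xs, xj, w_l, periodic = FALSE, period = NULL) {
  d <- outer(xs, xj, `-`)
  if (periodic) {
    d <- (d + period / 2) %% period - period / 2
    g <- exp(-2 * d^2 / w_l^2) +
      exp(-2 * (d - period)^2 / w_l^2) +
      exp(-2 * (d + period)^2 / w_l^2)
  } else {
    g <- exp(-2 * d^2 / w_l^2)
  }
  g
}

#' Reconstruct the complex OCT image from a spectral frame
#'
#' Applies, per A-line, the uniform-grid transform
#' `A(x, z_m) = sum_n I(x, k_n) exp(-i 2 k_n z_m)` over depth pixels
#' `z_m = m * dz`, `m = 0..n_k-1`, then keeps the positive-OPD half
#' (rows `0..m_z-1`). With this sign convention a single scatterer at a
#' pixel-centred `z_j` yields peak phase 0 at `z = z_j` and a local axial
#' phase slope of `-2 k0`.
#'
#' @param frame A [spectral_frame].
#' @return An [oct_image] of `m_z` x `n_x` pixels.
#' @export
reconstruct_image <- function(frame) {
  stopifnot(inherits(frame, "spectral_frame"))
  sys <- frame$system
  # A(:, z_m) = exp(-i 2 k_min z_m) * DFT_n[I(:, k_n)] with the standard
  # forward FFT kernel exp(-2 pi i n m / n_k)
  full <- stats::mvfft(t(frame$data))              # n_k x n_x, transform over k
  z_full <- (seq_len(sys$n_k) - 1L) * sys$dz_um
  carrier <- exp(-2i * sys$k[1L] * z_full)
  full <- full * carrier                           # recycles down columns
  oct_image(full[seq_len(sys$m_z), , drop = FALSE], sys)
}

#' Analytic superposition oracle for the reconstructed image
#'
#' Computes the complex image directly as the per-scatterer superposition
#' `A(x, z) = sum_j r_j G(x - x_j) Gamma(z - z_j)` where `G` is the lateral
#' beam weight and `Gamma(zeta) = sum_n S(k_n) exp(-i 2 k_n zeta)` is the
#' coherence envelope (with its `-2 k0` carrier) evaluated on the same
#' discrete wavenumber grid the DFT pipeline uses, so the two routes agree
#' to numerical round-off. Intended as an independent check of
#' [simulate_interferogram] + [reconstruct_image] on small fields.
#'
#' @inheritParams simulate_interferogram
#' @return An [oct_image].
#' @export
analytic_image <- function(field, system, periodic_lateral = FALSE) {
  stopifnot(inherits(field, "scatterer_field"), inherits(system, "oct_system"))
  span <- guarded_axial_span(system)
  if (nrow(field) &&
      (min(field$z_um) < span[1] || max(field$z_um) > span[2])) {
    stop("field outside the guarded axial span of the system")
  }
  m_z <- system$m_z; n_x <- system$n_x
  img <- matrix(0i, m_z, n_x)
  if (nrow(field)) {
    xs <- (seq_len(n_x) - 1L) * system$dx_um
    zs <- (seq_len(m_z) - 1L) * system$dz_um
    g <- .beam_matrix(xs, field$x_um, system$w_l_um,
                      periodic = periodic_lateral,
                      period = n_x * system$dx_um)
    g <- sweep(g, 2L, field$r, `*`)
    # Gamma on the (m_z x n_scatterer) grid of zeta = z_m - z_j
    zeta <- outer(zs, field$z_um, `-`)
    gam <- matrix(0i, m_z, nrow(field))
    for (n in seq_len(system$n_k)) {
      gam <- gam + system$spectrum[n] * exp(-2i * system$k[n] * zeta)
    }
    img <- gam %*% t(g)
  }
  oct_image(img, system)
}
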