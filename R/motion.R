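#' Single-step DFT subpixel shift estimation between two B-scans
#'
#' Estimates the translational displacement of `target` relative to
#' `reference` by upsampled normalized cross-correlation. Stage one finds
#' the peak of the 2x upsampled correlation map, obtained by zero-padding
#' the cross-power spectrum. Stage two refines it on a `1.5 x 1.5` pixel
#' neighbourhood sampled at `1/kappa` pixel steps, computed by explicit
#' matrix-multiply DFT kernels rather than a full-size FFT.
#'
#' @param reference,target [oct_image]s of identical dimensions.
#' @param kappa Integer local upsampling factor (default 1000, i.e. a
#'   0.001-px grid).
#' @param use `"complex"` (default) correlates the complex-valued images;
#'   `"amplitude"` correlates their moduli.
#' @return A `shift_estimate`: list with `dz_px`, `dx_px` (reference-to-
#'   target displacement, pixels), `dz_um`, `dx_um`, `ncc_peak` (in
#'   \[0, 1\]), `kappa`, and `use`.
#' @examples
#' sys <- oct_system(n_k = 128, n_x = 48)
#' f <- generate_scatterer_field(sys, z_range_um = c(15, 30), seed = 3)
#' img <- reconstruct_image(simulate_interferogram(f, sys))
#' est <- estimate_shift_2d(img, img, kappa = 100)
#' c(est$dz_px, est$dx_px, est$ncc_peak)   # 0, 0, 1
#' @export
estimate_shift_2d <- function(reference, target, kappa = 1000L,
                              use = c("complex", "amplitude")) {
  stopifnot(inherits(reference, "oct_image"), inherits(target, "oct_image"))
  .assert_same_geometry(reference$data, target$data)
  use <- match.arg(use)
  kappa <- as.integer(kappa)
  if (kappa < 1L) stop("'kappa' must be a positive integer")
  a <- if (use == "complex") reference$data else Mod(reference$data) + 0i
  b <- if (use == "complex") target$data else Mod(target$data) + 0i
  if (stats::sd(Mod(a)) == 0 || stats::sd(Mod(b)) == 0) {
    stop("flat (zero-variance) image: correlation undefined")
  }
  m_z <- nrow(a); n_x <- ncol(a)
  cp <- .fft2(b) * Conj(.fft2(a))          # cross-power spectrum
  denom <- sqrt(sum(Mod(a)^2) * sum(Mod(b)^2))

  # stage 1: 2x upsampled correlation by spectral zero-padding
  up <- .ifft2(.ifftshift2(.embed_center(.fftshift2(cp), 2L * m_z, 2L * n_x)))
  pk <- arrayInd(which.max(Mod(up)), dim(up))
  dz0 <- .wrap_shift((pk[1L] - 1L) / 2, m_z)
  dx0 <- .wrap_shift((pk[2L] - 1L) / 2, n_x)

  # stage 2: kappa-fold matrix-multiply DFT on a 1.5 x 1.5 px neighbourhood
  nor <- as.integer(ceiling(1.5 * kappa))
  off <- (seq_len(nor) - 1L - nor %/% 2L) / kappa
  sz <- dz0 + off
  sx <- dx0 + off
  fz <- .fftfreq(m_z)
  fx <- .fftfreq(n_x)
  kz <- exp(2i * pi * outer(sz, fz))       # nor x m_z
  kx <- exp(2i * pi * outer(fx, sx))       # n_x x nor
  cc <- (kz %*% cp) %*% kx / (m_z * n_x)
  pk2 <- arrayInd(which.max(Mod(cc)), dim(cc))
  dz <- sz[pk2[1L]]
  dx <- sx[pk2[2L]]
  sys <- reference$system
  structure(list(dz_px = dz, dx_px = dx,
                 dz_um = dz * sys$dz_um, dx_um = dx * sys$dx_um,
                 ncc_peak = min(Mod(cc[pk2[1L], pk2[2L]]) / denom, 1),
                 kappa = kappa, use = use),
            class = "shift_estimate")
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat(sprintf("<shift_estimate> dz = %.4f px (%.4f um), dx = %.4f px (%.4f um), ncc = %.4f (kappa = %d, %s)\n",
              x$dz_px, x$dz_um, x$dx_px, x$dx_um, x$ncc_peak, x$kappa, x$use))
  invisible(x)
}

# embed a centred (fftshifted) spectrum into a larger zero array, centred
.embed_center <- function(m, nr, nc) {
  out <- matrix(0i, nr, nc)
  r0 <- nr %/% 2L - nrow(m) %/% 2L
  c0 <- nc %/% 2L - ncol(m) %/% 2L
  out[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m))] <- m
  out
}

#' Brute-force registration-based correlation map
#'
#' Independent oracle for [estimate_shift_2d]: for every candidate shift,
#' registers the target with [presir_register] (full mode) and computes the
#' magnitude of the normalized complex correlation with the reference over
#' the jointly valid columns.
#'
#' @param reference,target [oct_image]s of identical dimensions.
#' @param dz_px,dx_px Numeric vectors of candidate shifts in pixels
#'   (reference-to-target displacement).
#' @return Numeric matrix `length(dz_px)` x `length(dx_px)` of correlation
#'   magnitudes, with the candidate shifts as dimnames.
#' @export
ncc_map_bruteforce <- function(reference, target, dz_px, dx_px) {
  stopifnot(inherits(reference, "oct_image"), inherits(target, "oct_image"))
  .assert_same_geometry(reference$data, target$data)
  sys <- reference$system
  out <- matrix(NA_real_, length(dz_px), length(dx_px),
                dimnames = list(format(dz_px), format(dx_px)))
  for (i in seq_along(dz_px)) {
    for (j in seq_along(dx_px)) {
      reg <- presir_register(target, dx_um = dx_px[j] * sys$dx_um,
                             dz_um = dz_px[i] * sys$dz_um, mode = "full")
      keep <- reg$valid_cols & reference$valid_cols
      x <- reg$data[, keep, drop = FALSE]
      y <- reference$data[, keep, drop = FALSE]
      out[i, j] <- Mod(sum(x * Conj(y))) /
        sqrt(sum(Mod(x)^2) * sum(Mod(y)^2))
    }
  }
  out
}

#' Subpixel axial displacement from surface phase
#'
#' Estimates the axial bulk displacement between two frames from the phase
#' change over a bright surface region: the amplitude-weighted circular
#' mean `arg(sum_surface A_T conj(A_R)) / (2 k0)`. Valid per step for
#' displacements below a quarter wavelength; larger motions are recovered by
#' accumulating per-step estimates over a time series.
#'
#' @param reference,target [oct_image]s of identical dimensions.
#' @param surface_pixels Logical mask matrix (same dimensions) or two-column
#'   index matrix selecting the surface pixels.
#' @return Estimated axial displacement in OPL um.
#' @export
estimate_axial_from_surface <- function(reference, target, surface_pixels) {
  stopifnot(inherits(reference, "oct_image"), inherits(target, "oct_image"))
  .assert_same_geometry(reference$data, target$data)
  r <- reference$data[surface_pixels]
  t <- target$data[surface_pixels]
  if (!length(r)) stop("empty surface mask")
  Arg(sum(t * Conj(r))) / (2 * reference$system$k0)
}

#' Coarse-to-fine registration of repeated volumes
#'
#' Registers every B-scan of a target volume against a reference volume.
#' Coarse stage: sub-volumes of consecutive target B-scans are located in
#' the reference volume by three-dimensional NCC on amplitudes, giving
#' integer scan-direction (y) shifts that are linearly interpolated to every
#' B-scan. Fine stage: each target B-scan is compared by
#' [estimate_shift_2d] against each reference B-scan of the sub-volume
#' around its interpolated position, and the `(dx, dy, dz)` with the highest
#' correlation peak is kept.
#'
#' @param reference,target Volumes: 3-D complex arrays `(m_z, n_x, n_y)`, or
#'   lists of [oct_image]s sharing one system.
#' @param system The [oct_system] (required when volumes are arrays; taken
#'   from the images otherwise).
#' @param subvolume_size Number of consecutive B-scans per coarse sub-volume
#'   and size of the fine search window.
#' @param stride Spacing (in B-scans) between coarse sub-volume starts.
#' @param kappa Upsampling factor passed to [estimate_shift_2d].
#' @param use Correlation mode passed to [estimate_shift_2d].
#' @return A data frame with one row per target B-scan: `scan`, `dy_scans`
#'   (integer y displacement), `dz_px`, `dx_px`, `dz_um`, `dx_um`, `ncc`.
#' @export
register_volume_coarse_to_fine <- function(reference, target, system = NULL,
                                           subvolume_size = 20L,
                                           stride = 50L, kappa = 1000L,
                                           use = "complex") {
  vol <- .as_volume(reference, system)
  ref <- vol$data; system <- vol$system
  tar <- .as_volume(target, system)$data
  if (!identical(dim(ref), dim(tar))) stop("volumes must share geometry")
  n_y <- dim(ref)[3L]
  subvolume_size <- min(as.integer(subvolume_size), n_y)
  if (subvolume_size < 1L) stop("sub-volume larger than volume")
  stride <- max(1L, as.integer(stride))

  # coarse: integer y-shift of each target sub-volume by 3-D amplitude NCC
  starts <- unique(pmin(seq.int(1L, n_y, by = stride),
                        n_y - subvolume_size + 1L))
  # subtract the mean depth profile before correlating: the layered
  # amplitude envelope is common to every scan and would otherwise swamp
  # the speckle term that actually localizes the sub-volume
  amp_ref <- .remove_depth_profile(Mod(ref))
  fa <- .fftn3(amp_ref + 0i)
  coarse <- vapply(starts, function(s) {
    a <- .remove_depth_profile(
      Mod(tar[, , s + seq_len(subvolume_size) - 1L, drop = FALSE]))
    sub <- array(0, dim(ref))
    sub[, , s + seq_len(subvolume_size) - 1L] <- a
    cc <- .ifftn3(.fftn3(sub + 0i) * Conj(fa))
    pk <- arrayInd(which.max(Mod(cc)), dim(cc))
    .wrap_shift(pk[3L] - 1L, n_y)
  }, numeric(1L))
  centers <- starts + (subvolume_size - 1L) / 2
  dy_interp <- if (length(starts) > 1L) {
    stats::approx(centers, coarse, xout = seq_len(n_y), rule = 2L)$y
  } else rep(coarse, n_y)

  # fine: per-B-scan subpixel estimate against the local reference window
  half <- subvolume_size %/% 2L
  res <- lapply(seq_len(n_y), function(iy) {
    jc <- as.integer(round(iy - dy_interp[iy]))
    jc <- min(max(jc, 1L), n_y)
    cand <- seq.int(max(1L, jc - half), min(n_y, jc + half))
    best <- NULL; best_j <- NA_integer_
    t_img <- oct_image(tar[, , iy], system)
    for (j in cand) {
      est <- estimate_shift_2d(oct_image(ref[, , j], system), t_img,
                               kappa = kappa, use = use)
      if (is.null(best) || est$ncc_peak > best$ncc_peak) {
        best <- est; best_j <- j
      }
    }
    data.frame(scan = iy, dy_scans = iy - best_j,
               dz_px = best$dz_px, dx_px = best$dx_px,
               dz_um = best$dz_um, dx_um = best$dx_um,
               ncc = best$ncc_peak)
  })
  do.call(rbind, res)
}

.as_volume <- function(v, system = NULL) {
  if (is.list(v) && length(v) && inherits(v[[1L]], "oct_image")) {
    system <- v[[1L]]$system
    data <- array(0i, c(system$m_z, system$n_x, length(v)))
    for (i in seq_along(v)) data[, , i] <- v[[i]]$data
    return(list(data = data, system = system))
  }
  if (is.array(v) && length(dim(v)) == 3L) {
    if (is.null(system)) stop("'system' required for array volumes")
    return(list(data = v, system = system))
  }
  stop("volume must be a 3-D array or a list of oct_image objects")
}

# n-dimensional FFT helpers (stats::fft handles arrays natively)
.fftn3 <- function(a) stats::fft(a)
.ifftn3 <- function(a) stats::fft(a, inverse = TRUE) / length(a)

# subtract each depth row's mean amplitude (over A-lines and scans)
.remove_depth_profile <- function(a) {
  a - array(rowMeans(a, dims = 1L), dim(a))
}
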