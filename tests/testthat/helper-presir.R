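# shared fixtures: small systems and speckle scenes built in code

test_system <- function(n_k = 256L, n_x = 48L, ...) {
  oct_system(n_k = n_k, n_x = n_x, ...)
}

# wide system with a laterally inset field: beam tails die off before the
# image edges, so circular lateral shifts agree with true translations
test_scene <- function(seed = 7L, n_k = 256L, n_x = 96L,
                       density = 5, inset_um = 48, z_range_um = c(20, 45),
                       periodic = FALSE) {
  sys <- oct_system(n_k = n_k, n_x = n_x)
  width <- sys$n_x * sys$dx_um
  xr <- if (periodic) c(0, width) else c(inset_um, width - inset_um)
  field <- generate_scatterer_field(
    sys, x_range_um = xr, z_range_um = z_range_um,
    density_per_coherence_length = density, seed = seed)
  list(system = sys, field = field,
       image = reconstruct_image(
         simulate_interferogram(field, sys, periodic_lateral = periodic)))
}

# image of the scene's field translated by (dx, dz) um
scene_translated <- function(scene, dx_um = 0, dz_um = 0) {
  periodic <- isTRUE(all.equal(attr(scene$field, "x_range_um"),
                               c(0, scene$system$n_x * scene$system$dx_um)))
  f <- scene$field
  if (periodic) {
    # keep the stored extent inside the image; positions wrap physically
    f$x_um <- (f$x_um + dx_um) %% (scene$system$n_x * scene$system$dx_um)
    f$z_um <- f$z_um + dz_um
    f <- scatterer_field(f$x_um, f$z_um, f$r,
                         z_limits_um = attr(scene$field, "z_limits_um"))
    reconstruct_image(simulate_interferogram(f, scene$system,
                                             periodic_lateral = TRUE))
  } else {
    reconstruct_image(simulate_interferogram(
      translate_field(scene$field, dx_um, dz_um), scene$system))
  }
}

max_rel_err <- function(a, b, cols = NULL) {
  if (is.null(cols)) cols <- seq_len(ncol(a))
  max(Mod(a[, cols, drop = FALSE] - b[, cols, drop = FALSE])) / max(Mod(b))
}

# wrap any angle into (-pi, pi]
.wrapd <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# linear-interpolated intensity FWHM of a sampled profile
interp_fwhm <- function(x, y) {
  imax <- which.max(y)
  half <- y[imax] / 2
  i1 <- max(which(y[seq_len(imax)] <= half))
  i2 <- min(which(y[seq(imax, length(y))] <= half)) + imax - 1L
  lo <- x[i1] + (half - y[i1]) / (y[i1 + 1] - y[i1]) * (x[i1 + 1] - x[i1])
  hi <- x[i2 - 1] + (half - y[i2 - 1]) / (y[i2] - y[i2 - 1]) * (x[i2] - x[i2 - 1])
  hi - lo
}

# circular integer roll (positive = towards larger indices)
.roll_ref <- function(m, by_row, by_col) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1L - by_row) %% nr) + 1L,
    ((seq_len(nc) - 1L - by_col) %% nc) + 1L, drop = FALSE]
}
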