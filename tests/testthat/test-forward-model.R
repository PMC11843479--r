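test_that("scatterer field generation follows the density law and the seed", {
  sys <- test_system()
  lc <- sys$coherence_length_um
  # extent sized for an expected count of exactly 500
  width <- 500 / 5 * lc^2 / 25
  f <- generate_scatterer_field(sys, x_range_um = c(10, 10 + width),
                                z_range_um = c(20, 45), seed = 1)
  expect_equal(nrow(f), 500L)
  expect_true(all(f$x_um >= 10 & f$x_um <= 10 + width))
  expect_true(all(f$z_um >= 20 & f$z_um <= 45))
  expect_true(all(f$r == 1))

  f_again <- generate_scatterer_field(sys, x_range_um = c(10, 10 + width),
                                      z_range_um = c(20, 45), seed = 1)
  expect_identical(f$x_um, f_again$x_um)
  expect_identical(f$z_um, f_again$z_um)

  f2 <- generate_scatterer_field(sys, x_range_um = c(10, 10 + width),
                                 z_range_um = c(20, 45), seed = 2)
  expect_equal(nrow(f2), nrow(f))
  expect_false(isTRUE(all.equal(f$x_um, f2$x_um)))

  expect_error(generate_scatterer_field(sys, x_range_um = c(10, 10),
                                        z_range_um = c(20, 45)),
               "extent")
  expect_error(generate_scatterer_field(sys, density_per_coherence_length = 0),
               "density")
  expect_error(generate_scatterer_field(sys, z_range_um = c(0, 30)),
               "guarded")
})

test_that("field translation is exact, invertible, and range-checked", {
  sys <- test_system()
  f <- generate_scatterer_field(sys, z_range_um = c(20, 40), seed = 3)
  expect_identical(translate_field(f, 0, 0)$z_um, f$z_um)

  g <- translate_field(translate_field(f, 0.7, -0.3), -0.7, 0.3)
  expect_equal(g$x_um, f$x_um, tolerance = 1e-12)
  expect_equal(g$z_um, f$z_um, tolerance = 1e-12)

  h <- translate_field(f, 0, 3.0)
  expect_equal(h$z_um, f$z_um + 3.0)
  expect_identical(h$r, f$r)

  span <- guarded_axial_span(sys)
  expect_error(translate_field(f, 0, span[2]), "guarded")
})

test_that("the interferogram matches the analytic signal model", {
  sys <- test_system()
  xc <- 24 * sys$dx_um  # beam-centred A-line (column 25)
  f1 <- scatterer_field(xc, 30, 1, z_limits_um = guarded_axial_span(sys))
  fr <- simulate_interferogram(f1, sys)
  # modulus at the centred A-line is exactly S(k)
  expect_equal(Mod(fr$data[25L, ]), sys$spectrum, tolerance = 1e-12)

  empty <- scatterer_field(numeric(0), numeric(0), numeric(0))
  expect_true(all(simulate_interferogram(empty, sys)$data == 0))

  # linearity: two half-reflectivity scatterers at one point = one unit one
  f2 <- scatterer_field(c(xc, xc), c(30, 30), c(0.5, 0.5),
                        z_limits_um = guarded_axial_span(sys))
  expect_equal(simulate_interferogram(f2, sys)$data, fr$data,
               tolerance = 1e-12)

  # image linearity: union of fields vs sum of images
  fa <- generate_scatterer_field(sys, z_range_um = c(15, 25), seed = 4)
  fb <- generate_scatterer_field(sys, z_range_um = c(30, 40), seed = 5)
  fab <- scatterer_field(c(fa$x_um, fb$x_um), c(fa$z_um, fb$z_um),
                         c(fa$r, fb$r))
  ia <- reconstruct_image(simulate_interferogram(fa, sys))
  ib <- reconstruct_image(simulate_interferogram(fb, sys))
  iab <- reconstruct_image(simulate_interferogram(fab, sys))
  expect_lt(max(Mod(iab$data - ia$data - ib$data)) / max(Mod(iab$data)),
            1e-12)

  expect_error(simulate_interferogram(
    scatterer_field(10, 1, 1), sys), "guarded")
})

test_that("reconstruction peaks at the scatterer with zero phase and -2k0 slope", {
  sys <- test_system()
  zc <- round(30 / sys$dz_um) * sys$dz_um   # pixel-centred depth
  f1 <- scatterer_field(24 * sys$dx_um, zc, 1,
                        z_limits_um = guarded_axial_span(sys))
  img <- reconstruct_image(simulate_interferogram(f1, sys))
  pk <- arrayInd(which.max(Mod(img$data)), dim(img$data))
  expect_identical(pk[1L], as.integer(round(zc / sys$dz_um)) + 1L)
  expect_lt(abs(Arg(img$data[pk[1L], pk[2L]])), 1e-9)

  # unwrapped axial phase slope near the peak: -2 k0 within 0.1%
  up <- axial_upsample(img, 8L)
  pku <- arrayInd(which.max(Mod(up$data)), dim(up$data))
  col <- up$data[, pku[2L]]
  d <- diff(Arg(col[(pku[1L] - 2L):(pku[1L] + 2L)]))
  d <- (d + pi) %% (2 * pi) - pi
  slope <- mean(d) / (sys$dz_um / 8)
  expect_lt(abs(slope + 2 * sys$k0) / (2 * sys$k0), 1e-3)

  # axial intensity FWHM around the peak equals the configured resolution
  prof <- Mod(up$data[, pku[2L]])^2
  zz <- (seq_along(prof) - 1) * sys$dz_um / 8
  fwhm <- interp_fwhm(zz, prof)
  expect_lt(abs(fwhm - sys$axial_fwhm_um) / sys$axial_fwhm_um, 0.01)
})

test_that("real-detector frames reconstruct like analytic ones for guarded fields", {
  scn <- test_scene(seed = 9)
  fr_r <- simulate_interferogram(scn$field, scn$system, detector = "real")
  expect_true(all(Im(fr_r$data) == 0))
  img_r <- reconstruct_image(fr_r)
  expect_lt(max_rel_err(img_r$data, scn$image$data), 1e-9)
})

test_that("the DFT pipeline agrees with the analytic superposition oracle", {
  scn <- test_scene(seed = 7, density = 2)
  oracle <- analytic_image(scn$field, scn$system)
  expect_lt(max_rel_err(scn$image$data, oracle$data), 1e-6)

  sys <- scn$system
  empty <- scatterer_field(numeric(0), numeric(0), numeric(0))
  expect_true(all(analytic_image(empty, sys)$data == 0))

  dbl <- scatterer_field(scn$field$x_um, scn$field$z_um, 2 * scn$field$r)
  expect_equal(analytic_image(dbl, sys)$data, 2 * oracle$data,
               tolerance = 1e-12)
})

test_that("axial translation obeys the spectral shift theorem exactly", {
  scn <- test_scene(seed = 13, n_x = 48, inset_um = 0, periodic = TRUE)
  sys <- scn$system
  dz <- 1.23
  fr0 <- simulate_interferogram(scn$field, sys, periodic_lateral = TRUE)
  f2 <- scatterer_field(scn$field$x_um, scn$field$z_um + dz, scn$field$r,
                        z_limits_um = attr(scn$field, "z_limits_um"))
  fr1 <- simulate_interferogram(f2, sys, periodic_lateral = TRUE)
  ramp <- matrix(exp(2i * sys$k * dz), sys$n_x, sys$n_k, byrow = TRUE)
  expect_lt(max(Mod(fr1$data - fr0$data * ramp)) / max(Mod(fr0$data)), 1e-12)
})

test_that("system PSF widths match the configuration and Fourier scaling", {
  sys <- test_system()
  w <- system_psf_fwhm(sys)
  expect_equal(unname(w["axial"]), 1.9, tolerance = 0.01)
  expect_equal(unname(w["lateral"]), 19.5, tolerance = 0.01)

  # halving the axial resolution parameter doubles the spectral width and
  # halves the measured axial FWHM
  sys2 <- oct_system(n_k = 256, n_x = 48, axial_fwhm_um = 0.95)
  expect_equal(unname(system_psf_fwhm(sys2)["axial"]), 0.95,
               tolerance = 0.01)
  expect_equal(sys2$sigma_k, 2 * sys$sigma_k, tolerance = 1e-12)

  # lateral width verified against a simulated point target
  f1 <- scatterer_field(24 * sys$dx_um, 30, 1,
                        z_limits_um = guarded_axial_span(sys))
  img <- reconstruct_image(simulate_interferogram(f1, sys))
  prow <- Mod(img$data[round(30 / sys$dz_um) + 1L, ])^2
  xs <- (seq_len(sys$n_x) - 1) * sys$dx_um
  expect_equal(interp_fwhm(xs, prow), 19.5, tolerance = 0.01)
})

test_that("seeded noise draws are reproducible and SNR-calibrated", {
  sys <- test_system()
  f1 <- scatterer_field(24 * sys$dx_um, 30, 1,
                        z_limits_um = guarded_axial_span(sys))
  a <- simulate_interferogram(f1, sys, noise_snr_db = 20, seed = 42)
  b <- simulate_interferogram(f1, sys, noise_snr_db = 20, seed = 42)
  expect_identical(a$data, b$data)
  c <- simulate_interferogram(f1, sys, noise_snr_db = 20, seed = 43)
  expect_false(identical(a$data, c$data))

  # peak SNR of the unit reflector ~ 20 dB: average over many draws
  empty <- scatterer_field(numeric(0), numeric(0), numeric(0))
  peak <- max(Mod(reconstruct_image(
    simulate_interferogram(f1, sys))$data))
  nv <- mean(vapply(1:8, function(s) {
    n <- reconstruct_image(simulate_interferogram(empty, sys,
                                                  noise_snr_db = 20,
                                                  seed = s))$data
    mean(Mod(n)^2)
  }, numeric(1)))
  snr_db <- 10 * log10(peak^2 / nv)
  expect_equal(snr_db, 20, tolerance = 0.5)
})
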