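test_that("phase differences are zero against the reference frame and track
           global phases", {
  scn <- test_scene(seed = 7, n_k = 128, n_x = 48, inset_um = 0,
                    periodic = TRUE, z_range_um = c(8, 20))
  sys <- scn$system
  a <- scn$image$data
  stack <- oct_stack(array(c(a, a * exp(0.3i), a * exp(-2.9i)),
                           c(sys$m_z, sys$n_x, 3)), sys)
  ser <- phase_difference_series(stack, 1L)
  expect_true(all(ser$phase[, 1] == 0))
  expect_equal(max(abs(ser$phase[, 2] - 0.3)), 0, tolerance = 1e-12)
  expect_equal(max(abs(ser$phase[, 3] + 2.9)), 0, tolerance = 1e-12)
})

test_that("an error-only corrected stack reads out exactly the bulk OPL ramp", {
  scn <- test_scene(seed = 7, n_k = 128, n_x = 48, inset_um = 0,
                    periodic = TRUE, z_range_um = c(8, 20))
  sys <- scn$system
  steps <- c(0, 0.12, 0.24, 0.36)
  imgs <- lapply(steps, function(dz) {
    tgt <- scene_translated(scn, 0, dz)
    presir_register(tgt, 0, dz, "error_only")
  })
  stack <- oct_stack(imgs, times = steps)
  bright <- Mod(scn$image$data) > 1e-3 * max(Mod(scn$image$data))
  ser <- phase_difference_series(stack, 1L, pixels = bright)
  for (i in seq_along(steps)) {
    want <- .wrapd(2 * sys$k0 * steps[i])
    expect_lt(max(abs(ser$phase[, i] - want)), 1e-6)
  }
})

test_that("temporal unwrapping recovers ramps, is idempotent, and flags
           aliased traces", {
  k0 <- 2 * pi / 0.84
  ramp <- seq(0, 6, by = 0.2)
  wrapped <- .wrapd(ramp)
  ser <- phase_series(rbind(wrapped, rep(1, length(ramp))),
                      pixels = 1:2, dims = c(2L, 1L), k0 = k0)
  un <- unwrap_temporal(ser)
  expect_equal(un$phase[1, ], ramp, tolerance = 1e-12)
  expect_equal(un$phase[2, ], rep(1, length(ramp)))
  expect_false(un$wrapped)
  expect_false(any(attr(un, "suspect")))

  # unwrapping an already-unwrapped sub-pi-step series changes nothing
  un2 <- unwrap_temporal(un)
  expect_equal(un2$phase, un$phase)

  # per-step jumps beyond pi alias and are flagged
  bad <- .wrapd(seq(0, 30, by = 0.9 * pi + 0.05))
  serb <- unwrap_temporal(phase_series(matrix(bad, 1), 1L, c(1L, 1L), k0))
  expect_true(attr(serb, "suspect")[1])
})

test_that("phase-to-OPL conversion and its inverse are exact", {
  k0 <- 2 * pi / 0.84
  expect_identical(phase_to_opl(0, k0), 0)
  expect_equal(phase_to_opl(2 * k0 * 0.1, k0), 100, tolerance = 1e-12)
  expect_equal(phase_to_opl(pi, k0), 210, tolerance = 1e-12)
})

test_that("spatial and temporal standard deviations use the population
           convention in nm", {
  k0 <- 2 * pi / 0.84
  two <- phase_series(matrix(c(0, 2) * 2 * k0 / 1e3, 2, 1),
                      1:2, c(2L, 1L), k0)
  expect_equal(spatial_sd(two, 1L), 1, tolerance = 1e-12)
  expect_equal(spatial_sd(phase_series(matrix(0.7, 5, 1), 1:5, c(5L, 1L), k0),
                          1L), 0)

  alt <- phase_series(matrix(rep(c(-1, 1) * 2 * k0 / 1e3, 10), 1, 20),
                      1L, c(1L, 1L), k0)
  expect_equal(unname(temporal_sd(alt)), 1, tolerance = 1e-12)

  set.seed(8)
  noise <- stats::rnorm(600, sd = 2 * k0 * 5 / 1e3)  # 5 nm OPL noise
  ser <- phase_series(matrix(noise, 1), 1L, c(1L, 1L), k0)
  expect_equal(unname(temporal_sd(ser)), 5, tolerance = 0.15)
})

test_that("SNR-limited sensitivity follows 1/sqrt(SNR) and is met by
           simulated noisy statics", {
  k0 <- 2 * pi / 0.84
  expect_lt(snr_limited_sensitivity(1e12, k0), 1e-3)
  expect_equal(snr_limited_sensitivity(100, k0), 6.68, tolerance = 0.01)
  expect_equal(snr_limited_sensitivity(c(100, 100), k0,
                                       self_referenced = TRUE),
               sqrt(2) * 6.68, tolerance = 0.01)

  # Monte-Carlo: static stack at known SNR, sigma_t matches the prediction
  sys <- oct_system(n_k = 128, n_x = 48)
  f <- generate_scatterer_field(sys, z_range_um = c(8, 20), seed = 3)
  base <- simulate_interferogram(f, sys, periodic_lateral = TRUE)
  sigma <- sum(sys$spectrum) / sqrt(sys$n_k * 10^(35 / 10))
  n_t <- 80L
  arr <- array(0i, c(sys$m_z, sys$n_x, n_t))
  set.seed(9)
  for (t in seq_len(n_t)) {
    d <- base$data + complex(
      real = stats::rnorm(length(base$data), sd = sigma / sqrt(2)),
      imaginary = stats::rnorm(length(base$data), sd = sigma / sqrt(2)))
    arr[, , t] <- reconstruct_image(spectral_frame(d, sys, "analytic"))$data
  }
  stack <- oct_stack(arr, sys)
  amp <- Mod(apply(arr, c(1, 2), mean))
  # noise amplitude in the image domain after the unnormalized depth DFT
  noise_amp <- sigma * sqrt(sys$n_k)
  bright <- which(amp > 30 * noise_amp)
  set.seed(10)
  px <- sample(bright, 50L)
  ser <- unwrap_temporal(phase_difference_series(stack, 1L, pixels = px))
  measured <- temporal_sd(ser)
  # the reference frame's noise is a constant offset per trace, so the
  # temporal spread is the single-pixel floor; per-quadrature SNR is twice
  # the power ratio against the total complex noise variance
  predicted <- snr_limited_sensitivity(2 * (amp[px] / noise_amp)^2, sys$k0)
  expect_lt(abs(mean(measured / predicted) - 1), 0.15)
})

test_that("self-referencing cancels common-mode drift down to the rigid
           bulk-motion case", {
  scn <- test_scene(seed = 7, n_k = 128, n_x = 48, inset_um = 0,
                    periodic = TRUE, z_range_um = c(8, 20))
  sys <- scn$system
  a <- scn$image$data
  amp <- Mod(a)
  ia <- which(amp > stats::quantile(amp, 0.95))[1:20]
  ib <- which(amp > stats::quantile(amp, 0.90))[41:60]

  stack <- oct_stack(array(c(a, a, a), c(sys$m_z, sys$n_x, 3)), sys)
  # referencing a pixel against itself gives identically zero phase
  self0 <- self_referenced_phase(stack, ia[1], ia[1])
  expect_true(all(self0$phase == 0))

  # adding a global per-frame phase leaves the series unchanged
  drift <- c(0, 0.8, -1.9)
  arr2 <- array(c(a, a * exp(1i * drift[2]), a * exp(1i * drift[3])),
                c(sys$m_z, sys$n_x, 3))
  ser1 <- self_referenced_phase(stack, ia, ib)
  ser2 <- self_referenced_phase(oct_stack(arr2, sys), ia, ib)
  expect_equal(ser2$phase, ser1$phase, tolerance = 1e-9)

  # rigid bulk motion, full-mode corrected: series flat at numerical zero
  steps <- c(0, 0.31, 0.62)
  imgs <- lapply(steps, function(dz) {
    presir_register(scene_translated(scn, 0, dz), 0, dz, "full")
  })
  ser3 <- self_referenced_phase(oct_stack(imgs, times = steps), ia, ib)
  spread <- apply(ser3$phase, 1, function(p) max(p) - min(p))
  expect_lt(max(spread), 1e-6)
})

test_that("outlier masking removes dark and phase-unstable pixels", {
  k0 <- 2 * pi / 0.84
  sys <- oct_system(n_k = 128, n_x = 48)
  n_px <- 60L; n_t <- 30L
  set.seed(4)
  amp <- matrix(1, sys$m_z, sys$n_x)
  arr <- array(complex(modulus = amp, argument = 0),
               c(sys$m_z, sys$n_x, n_t))
  stack <- oct_stack(arr, sys)
  px <- seq_len(n_px)
  ph <- matrix(stats::rnorm(n_px * n_t, sd = 0.02), n_px, n_t)
  ser <- phase_series(ph, px, c(sys$m_z, sys$n_x), k0)

  keep <- outlier_mask(stack, ser, noise_floor = 0.01)
  expect_true(all(keep))

  # planted dark pixel fails the SNR criterion
  dark <- arr; dark[1, 1, ] <- 0.02 + 0i
  keep2 <- outlier_mask(oct_stack(dark, sys), ser, noise_floor = 0.01)
  expect_false(keep2[1])
  expect_true(all(keep2[-1]))

  # planted high-phase-noise pixel fails the MAD criterion
  ph3 <- ph; ph3[5, ] <- stats::rnorm(n_t, sd = 0.4)
  ser3 <- phase_series(ph3, px, c(sys$m_z, sys$n_x), k0)
  keep3 <- outlier_mask(stack, ser3, noise_floor = 0.01)
  expect_false(keep3[5])
  expect_gt(mean(keep3[-5]), 0.9)
})
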