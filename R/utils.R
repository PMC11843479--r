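# internal numerics helpers

# DFT sample frequencies in cycles per sample, numpy-style ordering:
# 0, 1/n, ..., then negative frequencies
.fftfreq <- function(n) {
  f <- c(seq.int(0L, n - n %/% 2L - 1L), seq.int(-(n %/% 2L), -1L))
  f / n
}

# 2-D FFT / inverse FFT of a plain matrix
.fft2 <- function(m) stats::fft(m)
.ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

# circular shift of a matrix by integer amounts (positive = towards larger
# indices), like numpy.roll
.roll2 <- function(m, by_row = 0L, by_col = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- ((seq_len(nr) - 1L - by_row) %% nr) + 1L
  ci <- ((seq_len(nc) - 1L - by_col) %% nc) + 1L
  m[ri, ci, drop = FALSE]
}

# round half away from zero (pixel-level baseline tie rule)
.round_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# fftshift / ifftshift for matrices
.fftshift2 <- function(m) .roll2(m, nrow(m) %/% 2L, ncol(m) %/% 2L)
.ifftshift2 <- function(m) .roll2(m, -(nrow(m) %/% 2L), -(ncol(m) %/% 2L))

# wrap a phase (or any angle) into (-pi, pi]
.wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# wrap an index shift on an n-periodic grid into (-n/2, n/2]
.wrap_shift <- function(s, n) {
  w <- (s + n / 2) %% n - n / 2
  if (w == -n / 2) w <- n / 2
  w
}

.assert_same_geometry <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("images must share the same dimensions")
  }
  invisible(TRUE)
}
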