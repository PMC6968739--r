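# Internal FFT helpers. All spectra in this package use the convention
#   forward:  S = fft2(x)            (unnormalised, zero frequency at [1,1])
#   inverse:  x = ifft2(S) = fft(S, inverse)/length(S)
# Centred ("fftshifted") layouts put the zero frequency at floor(N/2)+1.

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# DFT sample frequencies in cycles per unit, zero first (corner layout)
fft_freq <- function(n, d = 1) {
  stopifnot(n >= 1, d > 0)
  k <- c(seq.int(0L, ceiling(n / 2) - 1L), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

# Move zero frequency from corner to centre index floor(n/2)+1 (and back)
fftshift2 <- function(x) {
  d <- dim(x)
  i <- c(seq.int(floor(d[1] / 2) + 1L, d[1]), seq.int(1L, floor(d[1] / 2)))
  j <- c(seq.int(floor(d[2] / 2) + 1L, d[2]), seq.int(1L, floor(d[2] / 2)))
  x[i, j, drop = FALSE]
}

ifftshift2 <- function(x) {
  d <- dim(x)
  i <- c(seq.int(ceiling(d[1] / 2) + 1L, d[1]), seq.int(1L, ceiling(d[1] / 2)))
  j <- c(seq.int(ceiling(d[2] / 2) + 1L, d[2]), seq.int(1L, ceiling(d[2] / 2)))
  x[i, j, drop = FALSE]
}

# Circular shift of a matrix by integer amounts (positive = toward higher index)
circshift2 <- function(x, s) {
  d <- dim(x)
  s <- as.integer(round(s)) %% d
  i <- if (s[1] == 0) seq_len(d[1]) else c(seq.int(d[1] - s[1] + 1L, d[1]), seq_len(d[1] - s[1]))
  j <- if (s[2] == 0) seq_len(d[2]) else c(seq.int(d[2] - s[2] + 1L, d[2]), seq_len(d[2] - s[2]))
  x[i, j, drop = FALSE]
}

# Standard FLOP estimate for one complex 2D FFT of n points (5 n log2 n);
# used for the relative PRR/IPM cost accounting, not wall-clock prediction.
fft_flops <- function(n) 5 * n * log2(n)
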