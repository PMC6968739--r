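#' Two-dimensional phase unwrapping
#'
#' Least-squares phase unwrapping: wrapped phase differences are integrated
#' by solving the discrete Poisson equation with Neumann boundary
#' conditions (via a mirror-extended FFT solve), then the result is snapped
#' to the nearest 2-pi-congruent surface so that the output differs from the
#' raw phase by an integer multiple of 2 pi at every pixel. Exact (up to a
#' global 2-pi multiple) for residue-free phase maps, which smooth optical
#' phases are.
#'
#' @param x A [complex_field()] or a real matrix of wrapped phases
#'   (radians).
#' @return Real matrix of unwrapped phases.
#' @export
unwrap_phase <- function(x) {
  psi <- if (inherits(x, "complex_field")) Arg(x$values) else x
  stopifnot(is.matrix(psi))
  if (any(!is.finite(psi))) stop("phase contains non-finite values")
  n <- dim(psi)
  if (min(n) < 2) return(psi)

  wrap <- function(d) (d + pi) %% (2 * pi) - pi
  dx <- matrix(0, n[1], n[2])
  dy <- matrix(0, n[1], n[2])
  dx[1:(n[1] - 1), ] <- wrap(psi[2:n[1], ] - psi[1:(n[1] - 1), ])
  dy[, 1:(n[2] - 1)] <- wrap(psi[, 2:n[2]] - psi[, 1:(n[2] - 1)])
  # divergence of the wrapped gradient field
  rho <- dx - rbind(0, dx[1:(n[1] - 1), , drop = FALSE]) +
         dy - cbind(0, dy[, 1:(n[2] - 1), drop = FALSE])

  # Neumann Poisson solve by even mirror extension + FFT
  ext <- function(m) {
    m2 <- rbind(m, m[n[1]:1, , drop = FALSE])
    cbind(m2, m2[, n[2]:1, drop = FALSE])
  }
  R <- fft2(ext(rho))
  wi <- 2 * cos(2 * pi * (0:(2 * n[1] - 1)) / (2 * n[1])) - 2
  wj <- 2 * cos(2 * pi * (0:(2 * n[2] - 1)) / (2 * n[2])) - 2
  den <- outer(wi, wj, "+")
  den[1, 1] <- 1
  Phi <- R / den
  Phi[1, 1] <- 0
  phi <- Re(ifft2(Phi))[1:n[1], 1:n[2], drop = FALSE]

  # congruence: keep the smooth surface but stay 2 pi-congruent to the input
  phi <- phi - (phi[1, 1] - psi[1, 1])
  psi + 2 * pi * round((phi - psi) / (2 * pi))
}
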