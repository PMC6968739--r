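# Image-quality metrics: SSIM (full and luminance-omitted), NRMSE modulo
# global phase and small shifts, and gradient-energy sharpness.

# Separable Gaussian-weighted local mean with symmetric (reflective) padding
gauss_blur_sym <- function(x, window, sigma) {
  h <- (window - 1) / 2
  k <- stats::dnorm(seq(-h, h), sd = sigma)
  k <- k / sum(k)
  n <- dim(x)
  pi_ <- c(h:1, 1:n[1], n[1]:(n[1] - h + 1))
  pj <- c(h:1, 1:n[2], n[2]:(n[2] - h + 1))
  xp <- x[pi_, pj, drop = FALSE]
  xp <- apply(xp, 2, function(col) stats::filter(col, k, sides = 2))
  xp <- t(apply(xp, 1, function(row) stats::filter(row, k, sides = 2)))
  xp[(h + 1):(h + n[1]), (h + 1):(h + n[2]), drop = FALSE]
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with a Gaussian window. With `omit_luminance = TRUE` the
#' luminance factor is dropped (exponent zero), so the result is invariant
#' to a constant intensity offset and compares only contrast and structure.
#'
#' @param a,b Real matrices of the same shape.
#' @param window Odd window size (px), default 11.
#' @param sigma Gaussian window sigma, default 1.5.
#' @param K Constants (K1, K2) with C_i = (K_i * data_range)^2.
#' @param data_range Dynamic range L; defaults to the range of `a` and `b`
#'   combined.
#' @param omit_luminance Drop the luminance term.
#' @return Scalar in [-1, 1].
#' @export
ssim <- function(a, b, window = 11, sigma = 1.5, K = c(0.01, 0.03),
                 data_range = NULL, omit_luminance = FALSE) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)),
            window >= 3, window %% 2 == 1)
  if (is.null(data_range)) data_range <- max(a, b) - min(a, b)
  if (data_range <= 0) data_range <- 1
  C1 <- (K[1] * data_range)^2
  C2 <- (K[2] * data_range)^2
  mu_a <- gauss_blur_sym(a, window, sigma)
  mu_b <- gauss_blur_sym(b, window, sigma)
  va <- gauss_blur_sym(a * a, window, sigma) - mu_a^2
  vb <- gauss_blur_sym(b * b, window, sigma) - mu_b^2
  cab <- gauss_blur_sym(a * b, window, sigma) - mu_a * mu_b
  cs <- (2 * cab + C2) / (va + vb + C2)
  if (omit_luminance) return(mean(cs))
  l <- (2 * mu_a * mu_b + C1) / (mu_a^2 + mu_b^2 + C1)
  mean(l * cs)
}

#' NRMSE modulo global phase and small integer shifts
#'
#' Normalised root-mean-square error between two complex fields, minimised
#' over a global phase factor (closed form) and integer circular shifts
#' within +/- `max_shift` pixels. Zero for fields equal up to a global
#' phase and a small translation.
#'
#' @param a,b [complex_field()]s or complex matrices of equal shape.
#' @param max_shift Shift search radius (px), default 2.
#' @return NRMSE (>= 0), normalised by the norm of `a`.
#' @export
nrmse_mod_phase <- function(a, b, max_shift = 2) {
  A <- if (inherits(a, "complex_field")) a$values else a
  B <- if (inherits(b, "complex_field")) b$values else b
  stopifnot(all(dim(A) == dim(B)))
  na2 <- sum(Mod(A)^2)
  nb2 <- sum(Mod(B)^2)
  best <- Inf
  for (dx in -max_shift:max_shift) for (dy in -max_shift:max_shift) {
    Bs <- circshift2(B, c(dx, dy))
    inner <- abs(sum(Conj(A) * Bs))
    err2 <- na2 + nb2 - 2 * inner
    if (err2 < best) best <- err2
  }
  sqrt(max(best, 0) / na2)
}

# 3x3 Sobel gradients (replicate boundary)
sobel_gradients <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  n <- dim(img)
  p <- img[c(1, 1:n[1], n[1]), c(1, 1:n[2], n[2])]
  gx <- EBImage::filter2(p, kx, boundary = "circular")[2:(n[1] + 1),
                                                       2:(n[2] + 1)]
  gy <- EBImage::filter2(p, t(kx), boundary = "circular")[2:(n[1] + 1),
                                                          2:(n[2] + 1)]
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Gradient-energy sharpness
#'
#' Sum of squared Sobel gradient magnitude; zero for constant images and
#' maximal when the image is in focus.
#'
#' @param img Real matrix.
#' @return Nonnegative scalar.
#' @export
gradient_energy <- function(img) {
  g <- sobel_gradients(img)
  sum(g$mag^2)
}
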