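#' Reconstruction options
#'
#' Options for the sequential Gauss-Newton FPM recovery.
#'
#' @param iterations Full passes over the stack (>= 1). 50 is usually ample
#'   for plain recovery; IPM refocusing typically needs ~150.
#' @param epry Enable embedded pupil function recovery (joint pupil
#'   estimation).
#' @param delta_obj,delta_pupil Gauss-Newton regularisers (small positive).
#' @param update_order `"na"` (centre-out by illumination NA, ties by frame
#'   index) or `"given"` (stack order).
#' @param upsample Integer ratio of reconstruction grid to raw grid;
#'   defaults to the stack's `downsample`. Must give a grid supporting the
#'   synthetic NA.
#' @param convergence_tol Stop when the relative change of the stacked
#'   residual between iterations falls below this.
#' @param max_pupil Cap on recovered pupil magnitude.
#' @return List of class `reconstruction_options`.
#' @export
reconstruction_options <- function(iterations = 50, epry = FALSE,
                                   delta_obj = 1e-3, delta_pupil = 1e-3,
                                   update_order = c("na", "given"),
                                   upsample = NULL,
                                   convergence_tol = 1e-4,
                                   max_pupil = 1.1) {
  stopifnot(iterations >= 1, delta_obj > 0, delta_pupil > 0,
            convergence_tol >= 0)
  structure(list(iterations = as.integer(iterations), epry = isTRUE(epry),
                 delta_obj = delta_obj, delta_pupil = delta_pupil,
                 update_order = match.arg(update_order),
                 upsample = if (is.null(upsample)) NULL else as.integer(upsample),
                 convergence_tol = convergence_tol, max_pupil = max_pupil),
            class = "reconstruction_options")
}

#' Initial high-resolution spectrum
#'
#' Standard initialisation: the centred spectrum of the band-limited
#' upsampled square root of the most on-axis intensity image (zero phase).
#'
#' @param stack A [lowres_stack()].
#' @param options [reconstruction_options()].
#' @return Complex matrix (centred layout) of size `upsample` times the raw
#'   grid.
#' @export
initialize_spectrum <- function(stack, options = reconstruction_options()) {
  stopifnot(inherits(stack, "lowres_stack"))
  if (length(stack$images) == 0) stop("empty stack")
  r <- if (is.null(options$upsample)) stack$downsample else options$upsample
  i0 <- which.min(stack$directions$alpha^2 + stack$directions$beta^2)
  amp <- sqrt(stack$images[[i0]])
  n_lo <- dim(amp)
  n_hi <- n_lo * r
  S_lo <- fftshift2(fft2(amp)) * r^2
  S <- matrix(0i, n_hi[1], n_hi[2])
  c_hi <- floor(n_hi / 2) + 1
  iidx <- (c_hi[1] - floor(n_lo[1] / 2)):(c_hi[1] + ceiling(n_lo[1] / 2) - 1)
  jidx <- (c_hi[2] - floor(n_lo[2] / 2)):(c_hi[2] + ceiling(n_lo[2] / 2) - 1)
  S[iidx, jidx] <- S_lo
  S
}

# One amplitude-replacement Gauss-Newton update for a single frame.
# S: centred high-res spectrum; P: pupil (centred, low-res grid);
# offset: integer (u,v) pixel offset of the passband centre in S.
# Returns list(S, P, resid2).
sequential_update_core <- function(S, P, image, offset, r, options,
                                   epry = options$epry) {
  n_lo <- dim(image)
  n_hi <- dim(S)
  c_hi <- floor(n_hi / 2) + 1
  iidx <- (c_hi[1] + offset[1] - floor(n_lo[1] / 2)):
          (c_hi[1] + offset[1] + ceiling(n_lo[1] / 2) - 1)
  jidx <- (c_hi[2] + offset[2] - floor(n_lo[2] / 2)):
          (c_hi[2] + offset[2] + ceiling(n_lo[2] / 2) - 1)
  if (iidx[1] < 1 || jidx[1] < 1 || iidx[length(iidx)] > n_hi[1] ||
      jidx[length(jidx)] > n_hi[2])
    stop("passband offset outside the reconstruction grid")

  O <- S[iidx, jidx, drop = FALSE]
  Pv <- P$values
  Psi <- O * Pv
  psi <- ifft2(ifftshift2(Psi)) / r^2
  amp_mod <- Mod(psi)
  amp_meas <- sqrt(image)
  resid2 <- sum((amp_meas - amp_mod)^2)

  ratio <- amp_meas / pmax(amp_mod, .Machine$double.eps)
  psi_new <- psi * ratio
  dPsi <- fftshift2(fft2(psi_new)) * r^2 - Psi

  aP <- Mod(Pv)
  S[iidx, jidx] <- O + Conj(Pv) * aP /
    (max(aP) * (aP^2 + options$delta_obj)) * dPsi
  if (epry) {
    aO <- Mod(O)
    Pnew <- Pv + Conj(O) * aO / (max(aO) * (aO^2 + options$delta_pupil)) * dPsi
    P <- enforce_pupil(P, Pnew)
  }
  list(S = S, P = P, resid2 = resid2)
}

#' Single sequential update (one frame)
#'
#' Applies one amplitude-replacement Gauss-Newton step for one measured
#' image: the modelled passband field has its amplitude replaced by the
#' square root of the measured intensity (phase kept), and the object
#' spectrum patch — and, with EPRY, the pupil — are updated with the
#' regularised Gauss-Newton weights. Exposed mainly for testing and
#' didactic use; [reconstruct()] drives it over the whole stack.
#'
#' @param spectrum Centred high-resolution complex spectrum.
#' @param pupil A [make_ctf()]-style pupil on the raw-image grid.
#' @param image Measured intensity image (nonnegative matrix).
#' @param direction List or one-row data frame with `alpha`, `beta`.
#' @param stack_meta List with `pixel_object` (um) and `wavelength` (um)
#'   (e.g. a [lowres_stack()] plus config wavelength).
#' @param options [reconstruction_options()].
#' @return List with updated `spectrum`, `pupil`, and the frame's squared
#'   amplitude residual `resid2`.
#' @export
sequential_update <- function(spectrum, pupil, image, direction, stack_meta,
                              options = reconstruction_options()) {
  n_hi <- dim(spectrum)
  n_lo <- dim(image)
  r <- n_hi[1] / n_lo[1]
  du <- 1 / (n_hi[1] * stack_meta$pixel_object)
  dv <- 1 / (n_hi[2] * stack_meta$pixel_object)
  offset <- c(-round(direction$alpha / stack_meta$wavelength / du),
              -round(direction$beta / stack_meta$wavelength / dv))
  upd <- sequential_update_core(spectrum, pupil, image, offset, r, options)
  list(spectrum = upd$S, pupil = upd$P, resid2 = upd$resid2)
}

#' Reconstruct a high-resolution complex field from an FPM stack
#'
#' Iterative sequential Gauss-Newton recovery: each pass visits every frame
#' (centre-out by illumination NA by default), replacing the modelled
#' passband amplitude with the measured one and updating the object
#' spectrum, with optional embedded pupil function recovery (EPRY). Energy
#' outside the synthetic NA disc is suppressed.
#'
#' @param stack A [lowres_stack()].
#' @param config An [optical_config()] (defaults to the stack's).
#' @param options [reconstruction_options()].
#' @param pupil_init Optional starting pupil (defaults to the ideal CTF);
#'   used by [ipm_refocus()] to inject a defocus term.
#' @return An object of class `fpm_recon` with elements `field`
#'   ([complex_field()]), `pupil`, `iterations_run`, `residuals`
#'   (per-iteration normalised data misfit), `options`, `config`,
#'   `cost_flops`.
#' @export
reconstruct <- function(stack, config = stack$config,
                        options = reconstruction_options(),
                        pupil_init = NULL) {
  stopifnot(inherits(stack, "lowres_stack"),
            inherits(config, "optical_config"))
  r <- if (is.null(options$upsample)) stack$downsample else options$upsample
  n_lo <- dim(stack$images[[1]])
  n_hi <- n_lo * r
  px_hi <- stack$pixel_object * stack$downsample / r
  lambda <- config$wavelength
  na_syn <- config$na_obj + max(stack$directions$na_illu)
  du <- 1 / (n_hi[1] * px_hi)
  if (na_syn / lambda > min(n_hi) / 2 * du)
    warning("reconstruction grid does not support the synthetic NA; ",
            "increase upsample")
  check_passband_overlap(stack, config)

  grid_lo <- frequency_grid(n_lo, stack$pixel_camera, "centered")
  pupil <- if (is.null(pupil_init))
    make_ctf(grid_lo, config$na_obj, lambda,
             max_transmittance = options$max_pupil)
  else pupil_init
  pupil0 <- pupil

  ord <- seq_len(length(stack$images))
  if (options$update_order == "na")
    ord <- order(stack$directions$na_illu, ord)

  S <- initialize_spectrum(stack, reconstruction_options(upsample = r))
  gr_hi <- frequency_grid(n_hi, px_hi, "centered")
  syn_mask <- (gr_hi$u^2 + gr_hi$v^2) <= (na_syn / lambda)^2
  S[!syn_mask] <- 0

  offsets <- cbind(-round(stack$directions$alpha / lambda / du),
                   -round(stack$directions$beta / lambda / gr_hi$dv))
  total_I <- sum(vapply(stack$images, sum, numeric(1)))

  residuals <- numeric(0)
  n_increase <- 0
  iterations_run <- 0
  for (it in seq_len(options$iterations)) {
    res2 <- 0
    for (i in ord) {
      upd <- sequential_update_core(S, pupil, stack$images[[i]],
                                    offsets[i, ], r, options)
      S <- upd$S; pupil <- upd$P
      res2 <- res2 + upd$resid2
    }
    res <- sqrt(res2 / total_I)
    residuals <- c(residuals, res)
    iterations_run <- it
    if (it >= 2) {
      prev <- residuals[it - 1]
      if (res > prev * 1.001 && res > 1e-12) n_increase <- n_increase + 1
      else n_increase <- 0
      if (n_increase >= 3)
        stop("reconstruction diverging: residual increased for 3 ",
             "consecutive iterations (", paste(signif(utils::tail(
               residuals, 4), 6), collapse = " -> "), ")")
      if (abs(prev - res) / max(prev, .Machine$double.eps) <
          options$convergence_tol) break
    }
  }
  S[!syn_mask] <- 0

  field <- complex_field(ifft2(ifftshift2(S)), px_hi, lambda, z = 0)
  cost <- iterations_run * length(stack$images) *
    2 * fft_flops(prod(n_lo)) + 2 * fft_flops(prod(n_hi))
  structure(list(field = field, pupil = pupil, pupil_init = pupil0,
                 iterations_run = iterations_run, residuals = residuals,
                 options = options, config = config, na_syn = na_syn,
                 cost_flops = cost),
            class = "fpm_recon")
}

# Warn when neighbouring passbands overlap by less than 40% of the pupil area
check_passband_overlap <- function(stack, config) {
  d <- stack$directions
  if (nrow(d) < 2) return(invisible())
  R <- config$na_obj
  pts <- cbind(d$alpha, d$beta)
  nn <- vapply(seq_len(nrow(pts)), function(i) {
    dd <- sqrt(rowSums((pts[-i, , drop = FALSE] -
                          matrix(pts[i, ], nrow(pts) - 1, 2, byrow = TRUE))^2))
    min(dd)
  }, numeric(1))
  dmax <- max(nn)
  if (dmax >= 2 * R) { warning("neighbouring passbands do not overlap"); return(invisible()) }
  # lens-shaped intersection area of two discs of radius R at distance dmax
  a <- 2 * R^2 * acos(dmax / (2 * R)) -
    dmax / 2 * sqrt(pmax(4 * R^2 - dmax^2, 0))
  frac <- a / (pi * R^2)
  if (frac < 0.4)
    warning(sprintf(
      "minimum areal passband overlap %.0f%% is below 40%%; recovery may stagnate",
      100 * frac))
  invisible(frac)
}

#' @export
print.fpm_recon <- function(x, ...) {
  d <- dim(x$field$values)
  cat(sprintf(
    "FPM reconstruction: %d x %d px (pixel %.4g um), NA_syn = %.3g\n",
    d[1], d[2], x$field$pixel, x$na_syn))
  cat(sprintf("  %d iteration(s), final residual %.4g%s\n",
              x$iterations_run, utils::tail(x$residuals, 1),
              if (x$options$epry) ", EPRY pupil recovery on" else ""))
  invisible(x)
}

#' @export
summary.fpm_recon <- function(object, ...) {
  z <- tryCatch(fit_zernike(object$pupil), error = function(e) NULL)
  out <- list(recon = object, zernike = z,
              residual = utils::tail(object$residuals, 1))
  class(out) <- "summary.fpm_recon"
  out
}

#' @export
print.summary.fpm_recon <- function(x, ...) {
  print(x$recon)
  if (!is.null(x$zernike)) {
    cat("  Pupil phase Zernike fit (rad, Noll-normalised):\n")
    print(round(x$zernike, 4))
  }
  invisible(x)
}

#' @export
residuals.fpm_recon <- function(object, ...) object$residuals

#' @export
coef.fpm_recon <- function(object, ...) fit_zernike(object$pupil)

#' @export
plot.fpm_recon <- function(x, what = c("amplitude", "phase", "residuals"),
                           ...) {
  what <- match.arg(what)
  if (what == "residuals") {
    graphics::plot(seq_along(x$residuals), x$residuals, type = "b",
                   xlab = "iteration", ylab = "normalised residual",
                   log = "y", ...)
  } else {
    img <- if (what == "amplitude") field_amplitude(x$field)
           else field_phase(x$field)
    graphics::image(img, asp = 1, col = grDevices::gray.colors(256),
                    axes = FALSE, main = paste("reconstructed", what), ...)
  }
  invisible(x)
}

# Evaluate a Noll-normalised Zernike polynomial Z(n, m) at (rho, theta)
zernike_poly <- function(n, m, rho, theta) {
  am <- abs(m)
  stopifnot(n >= am, (n - am) %% 2 == 0)
  rad <- 0
  for (k in 0:((n - am) / 2)) {
    rad <- rad + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + am) / 2 - k) *
         factorial((n - am) / 2 - k)) * rho^(n - 2 * k)
  }
  norm <- if (m == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
  ang <- if (m > 0) cos(am * theta) else if (m < 0) sin(am * theta) else 1
  norm * rad * ang
}

#' Fit Zernike coefficients to a pupil phase
#'
#' Least-squares projection of the pupil phase onto Noll-normalised Zernike
#' modes over the support disc. A piston term is always included in the fit
#' (and reported). Coefficients are in radians; defocus is
#' `Z(2,0) = sqrt(3) (2 rho^2 - 1)`.
#'
#' @param pupil A `pupil` (e.g. from [reconstruct()]).
#' @param modes Two-column matrix of (n, m) mode indices; default piston,
#'   x/y tilt and defocus.
#' @return Named numeric vector of coefficients (names `"Z<n>,<m>"`).
#' @export
fit_zernike <- function(pupil, modes = rbind(c(0, 0), c(1, 1), c(1, -1),
                                             c(2, 0))) {
  stopifnot(inherits(pupil, "pupil"))
  modes <- matrix(as.numeric(modes), ncol = 2)
  g <- pupil$grid
  rho <- sqrt(g$u^2 + g$v^2) / pupil$cutoff
  sup <- rho <= 1 & Mod(pupil$values) > 0
  if (sum(sup) < nrow(modes) + 1) stop("degenerate pupil support")
  theta <- atan2(g$v, g$u)
  ph <- Arg(pupil$values)[sup]
  X <- vapply(seq_len(nrow(modes)), function(i)
    zernike_poly(modes[i, 1], modes[i, 2], rho[sup], theta[sup]),
    numeric(sum(sup)))
  if (!any(modes[, 1] == 0)) X <- cbind(1, X)  # absorb piston
  cf <- stats::lsfit(X, ph, intercept = FALSE)$coefficients
  if (ncol(X) > nrow(modes)) cf <- cf[-1]
  stats::setNames(as.numeric(cf),
                  paste0("Z", modes[, 1], ",", modes[, 2]))
}
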