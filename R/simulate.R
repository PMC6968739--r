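#' Low-resolution FPM intensity stack
#'
#' Container for a raw FPM dataset: ordered intensity images with matching
#' illumination directions.
#'
#' @param images List of nonnegative real matrices (same shape).
#' @param directions Data frame with columns `alpha`, `beta` (direction
#'   cosines), one row per image.
#' @param config An [optical_config()].
#' @param pixel_object Sample-plane pitch (um) of the high-resolution object
#'   grid the stack refers to (camera sample-plane pixel / downsample).
#' @param downsample Integer camera downsampling ratio relative to the
#'   object grid.
#' @return An object of class `lowres_stack`.
#' @export
lowres_stack <- function(images, directions, config, pixel_object,
                         downsample = 1L) {
  stopifnot(is.list(images), length(images) >= 1,
            nrow(directions) == length(images),
            all(c("alpha", "beta") %in% names(directions)),
            inherits(config, "optical_config"))
  shp <- dim(images[[1]])
  for (im in images) {
    if (!all(dim(im) == shp)) stop("stack images differ in shape")
    if (any(im < 0)) stop("stack intensities must be nonnegative")
  }
  if (any(directions$alpha^2 + directions$beta^2 >= 1))
    stop("direction cosines must satisfy alpha^2 + beta^2 < 1")
  directions$na_illu <- sqrt(directions$alpha^2 + directions$beta^2)
  structure(list(images = images, directions = directions, config = config,
                 pixel_object = pixel_object,
                 pixel_camera = pixel_object * downsample,
                 downsample = as.integer(downsample)),
            class = "lowres_stack")
}

#' @export
print.lowres_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf(
    "FPM stack: %d frames of %d x %d px, camera pixel %.4g um at sample, NA_illu up to %.3g\n",
    length(x$images), d[1], d[2], x$pixel_camera, max(x$directions$na_illu)))
  invisible(x)
}

# Band-limited (Fourier-crop) downsampling of an intensity image; value
# (mean) preserving. Exact when the intensity band fits the reduced grid.
fourier_downsample <- function(img, ratio) {
  if (ratio == 1) return(img)
  n <- dim(img)
  if (any(n %% ratio != 0)) stop("image size not divisible by downsample ratio")
  m <- n %/% ratio
  S <- fftshift2(fft2(img))
  c0 <- floor(n / 2) + 1
  keep_i <- (c0[1] - floor(m[1] / 2)):(c0[1] + ceiling(m[1] / 2) - 1)
  keep_j <- (c0[2] - floor(m[2] / 2)):(c0[2] + ceiling(m[2] / 2) - 1)
  out <- Re(ifft2(ifftshift2(S[keep_i, keep_j, drop = FALSE])))
  out / ratio^2  # ifft2 divides by the reduced size; rescale to preserve values
}

#' Simulate a low-resolution FPM stack
#'
#' Forward model for angle-varied LED illumination: for each illumination
#' direction the object spectrum is shifted by (alpha/lambda, beta/lambda)
#' (rounded to the nearest high-resolution frequency pixel), the objective
#' CTF is applied, and the squared magnitude of the inverse transform is
#' recorded, then band-limited-downsampled to the camera grid. Optional
#' Poisson shot noise (photon budget per pixel) and Gaussian read noise.
#'
#' @param object High-resolution [complex_field()] (the exit-wave
#'   transmittance; compose layered samples first with
#'   [compose_layered_object()]).
#' @param config An [optical_config()].
#' @param directions Data frame with `alpha`, `beta` per frame (e.g. from
#'   [led_directions()]).
#' @param downsample Integer ratio between object and camera grids.
#' @param noise `NULL` (default, noise-free) or a list with elements
#'   `photons` (mean photon count at the brightfield level; Poisson shot
#'   noise) and/or `read_sd` (Gaussian read noise, intensity units).
#' @param seed RNG seed; required when `noise` is given.
#' @param aberration_phase Optional real matrix of pupil phase aberrations
#'   (radians) on the object-grid frequency grid in corner layout, e.g.
#'   from [zernike_defocus_phase()]; multiplied into the CTF.
#' @return A [lowres_stack()].
#' @export
simulate_low_res_stack <- function(object, config, directions,
                                   downsample = 1L, noise = NULL,
                                   seed = NULL, aberration_phase = NULL) {
  stopifnot(inherits(object, "complex_field"),
            inherits(config, "optical_config"), downsample >= 1)
  downsample <- as.integer(downsample)
  cam_px <- config$camera_pixel / config$magnification
  if (abs(object$pixel * downsample - cam_px) > 1e-9 * cam_px)
    warning(sprintf(
      "object pixel (%.5g um) x downsample != camera sample-plane pixel (%.5g um)",
      object$pixel, cam_px))
  n <- dim(object$values)
  grid <- frequency_grid(n, object$pixel, "corner")
  ctf <- Mod(make_ctf(grid, config$na_obj, config$wavelength)$values)
  if (!is.null(aberration_phase)) {
    stopifnot(all(dim(aberration_phase) == n))
    ctf <- ctf * exp(1i * aberration_phase)
  }
  Tspec <- fft2(object$values)
  cutoff_px <- config$na_obj / config$wavelength / grid$du
  lambda <- config$wavelength

  images <- vector("list", nrow(directions))
  for (i in seq_len(nrow(directions))) {
    cu <- round(directions$alpha[i] / lambda / grid$du)
    cv <- round(directions$beta[i] / lambda / grid$dv)
    if (abs(cu) + min(cutoff_px, n[1] / 2) > n[1] / 2 ||
        abs(cv) + min(cutoff_px, n[2] / 2) > n[2] / 2)
      stop("illumination shifts the passband beyond the grid extent (frame ",
           i, ")")
    E <- circshift2(Tspec, c(cu, cv)) * ctf
    img <- Mod(ifft2(E))^2
    img <- fourier_downsample(img, downsample)
    images[[i]] <- pmax(img, 0)
  }

  if (!is.null(noise)) {
    if (is.null(seed)) stop("a seed is required for noisy simulation")
    images <- with_seed(seed, {
      ref <- mean(images[[which.min(directions$alpha^2 + directions$beta^2)]])
      lapply(images, function(im) {
        if (!is.null(noise$photons)) {
          s <- noise$photons / ref
          im <- matrix(stats::rpois(length(im), im * s) / s, nrow(im))
        }
        if (!is.null(noise$read_sd) && noise$read_sd > 0)
          im <- im + matrix(stats::rnorm(length(im), 0, noise$read_sd),
                            nrow(im))
        pmax(im, 0)
      })
    })
  }

  lowres_stack(images, directions[, c("alpha", "beta")], config,
               pixel_object = object$pixel, downsample = downsample)
}
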