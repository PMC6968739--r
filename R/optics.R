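#' Optical system configuration
#'
#' Bundles the optical parameters of an FPM microscope. All lengths are in
#' micrometres; spatial frequencies throughout the package are in cycles/um,
#' so the coherent pupil cutoff is `na_obj / wavelength`.
#'
#' @param wavelength Illumination wavelength (um).
#' @param na_obj Objective numerical aperture.
#' @param magnification Objective magnification.
#' @param camera_pixel Physical camera pixel size (um). The sample-plane
#'   sampling of a raw image is `camera_pixel / magnification`.
#' @param n_medium Refractive index of the immersion medium (1 for air).
#' @return An object of class `optical_config`.
#' @examples
#' cfg <- optical_config(0.632, 0.3, 10, 4.25)
#' depth_of_field(cfg)
#' @export
optical_config <- function(wavelength, na_obj, magnification, camera_pixel,
                           n_medium = 1) {
  stopifnot(is.numeric(wavelength), length(wavelength) == 1, wavelength > 0,
            is.numeric(na_obj), length(na_obj) == 1, na_obj > 0,
            is.numeric(magnification), magnification > 0,
            is.numeric(camera_pixel), camera_pixel > 0,
            is.numeric(n_medium), n_medium >= 1)
  if (na_obj > n_medium)
    stop("na_obj must not exceed the immersion medium index")
  structure(list(wavelength = wavelength, na_obj = na_obj,
                 magnification = magnification, camera_pixel = camera_pixel,
                 n_medium = n_medium),
            class = "optical_config")
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(
    "Optical configuration: lambda = %.4g um, NA_obj = %.3g, M = %.3gx,\n  camera pixel = %.4g um (%.4g um at sample), n_medium = %.3g\n",
    x$wavelength, x$na_obj, x$magnification, x$camera_pixel,
    x$camera_pixel / x$magnification, x$n_medium))
  invisible(x)
}

#' LED array geometry
#'
#' Planar LED array a fixed distance below the sample, as used for
#' angle-varied FPM illumination.
#'
#' @param rows,cols Grid dimensions.
#' @param pitch LED spacing (mm).
#' @param distance Distance from array to sample plane (mm).
#' @param center_offset Lateral offset (mm, length 2) of the grid centre from
#'   the optical axis.
#' @param active Optional integer matrix with columns (row, col) selecting a
#'   subset of LEDs; `NULL` means all.
#' @return An object of class `led_array`.
#' @export
led_array <- function(rows, cols, pitch, distance, center_offset = c(0, 0),
                      active = NULL) {
  stopifnot(rows >= 1, cols >= 1, pitch > 0, distance > 0,
            length(center_offset) == 2)
  if (!is.null(active)) {
    active <- as.matrix(active)
    stopifnot(ncol(active) == 2)
    if (any(active[, 1] < 1 | active[, 1] > rows |
            active[, 2] < 1 | active[, 2] > cols))
      stop("active indices outside the LED grid")
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pitch = pitch, distance = distance,
                 center_offset = as.numeric(center_offset), active = active),
            class = "led_array")
}

#' Restrict an LED array to a filled circle
#'
#' Keeps the LEDs whose planar offset from the optical axis lies within
#' `diameter/2`, emulating illumination from a filled disc of LEDs.
#'
#' @param geom An [led_array()].
#' @param diameter Diameter of the disc (mm).
#' @return The geometry with `active` set accordingly.
#' @export
led_circle <- function(geom, diameter) {
  stopifnot(inherits(geom, "led_array"), diameter > 0)
  pos <- led_positions(geom, all = TRUE)
  keep <- sqrt(pos$x^2 + pos$y^2) <= diameter / 2
  if (!any(keep)) stop("no LEDs inside the requested circle")
  geom$active <- cbind(pos$row[keep], pos$col[keep])
  geom
}

# Planar LED positions (mm) relative to the optical axis
led_positions <- function(geom, all = FALSE) {
  if (is.null(geom$active) || all) {
    idx <- as.matrix(expand.grid(row = seq_len(geom$rows),
                                 col = seq_len(geom$cols)))
  } else {
    idx <- geom$active
  }
  x <- (idx[, 2] - (geom$cols + 1) / 2) * geom$pitch + geom$center_offset[1]
  y <- (idx[, 1] - (geom$rows + 1) / 2) * geom$pitch + geom$center_offset[2]
  list(row = idx[, 1], col = idx[, 2], x = x, y = y)
}

#' Illumination directions of an LED array
#'
#' Converts LED positions to illumination direction cosines. The sign
#' convention is fixed so that an LED displaced toward +x illuminates with
#' alpha < 0 and the captured passband shifts toward +u. Refraction through
#' the slide is ignored.
#'
#' @param geom An [led_array()].
#' @param order Ordering of the returned list: `"na"` (default,
#'   centre-out by increasing illumination NA, ties by grid index) or
#'   `"grid"` (row-major grid order).
#' @return A data frame with columns `row`, `col`, `alpha`, `beta`,
#'   `na_illu`.
#' @export
led_directions <- function(geom, order = c("na", "grid")) {
  stopifnot(inherits(geom, "led_array"))
  ord <- match.arg(order)
  pos <- led_positions(geom)
  if (length(pos$x) == 0) stop("LED active set is empty")
  r <- sqrt(pos$x^2 + pos$y^2 + geom$distance^2)
  d <- data.frame(row = pos$row, col = pos$col,
                  alpha = -pos$x / r, beta = -pos$y / r)
  d$na_illu <- sqrt(d$alpha^2 + d$beta^2)
  if (ord == "na") d <- d[order(d$na_illu, seq_len(nrow(d))), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Spatial-frequency grid
#'
#' 2D grid of spatial-frequency coordinates (cycles/um) matching an image of
#' a given shape and pixel pitch.
#'
#' @param shape Integer vector (rows, cols), both >= 2.
#' @param pixel Pixel pitch (um).
#' @param layout `"corner"` (zero frequency at element (1,1), FFT-native)
#'   or `"centered"` (zero frequency at floor(N/2)+1).
#' @return An object of class `frequency_grid` with matrices `u` (varying
#'   along rows / the x image axis) and `v` (along columns), spacings `du`,
#'   `dv`, and the layout tag.
#' @export
frequency_grid <- function(shape, pixel, layout = c("corner", "centered")) {
  layout <- match.arg(layout)
  stopifnot(length(shape) == 2, all(shape >= 2), pixel > 0)
  shape <- as.integer(shape)
  fu <- fft_freq(shape[1], pixel)
  fv <- fft_freq(shape[2], pixel)
  if (layout == "centered") { fu <- sort(fu); fv <- sort(fv) }
  structure(list(u = matrix(fu, shape[1], shape[2]),
                 v = matrix(fv, shape[1], shape[2], byrow = TRUE),
                 du = 1 / (shape[1] * pixel), dv = 1 / (shape[2] * pixel),
                 shape = shape, pixel = pixel, layout = layout),
            class = "frequency_grid")
}

#' Convert a frequency grid between layouts
#' @param grid A [frequency_grid()].
#' @param layout Target layout tag.
#' @return The grid in the requested layout.
#' @export
grid_to_layout <- function(grid, layout = c("corner", "centered")) {
  layout <- match.arg(layout)
  if (grid$layout == layout) return(grid)
  f <- if (layout == "centered") fftshift2 else ifftshift2
  grid$u <- f(grid$u); grid$v <- f(grid$v); grid$layout <- layout
  grid
}

#' Coherent transfer function (binary pupil)
#'
#' The CTF of an aberration-free objective: unit transmittance inside the
#' pupil cutoff `na / wavelength` (cycles/um), zero outside.
#'
#' @param grid A [frequency_grid()].
#' @param na Numerical aperture.
#' @param wavelength Wavelength (um).
#' @param max_transmittance Cap on pupil magnitude used when pupils are
#'   later updated (default 1.1).
#' @return An object of class `pupil`: complex `values` on the grid,
#'   `cutoff` (cycles/um), the grid, and the magnitude cap.
#' @export
make_ctf <- function(grid, na, wavelength, max_transmittance = 1.1) {
  stopifnot(inherits(grid, "frequency_grid"), na > 0, wavelength > 0)
  cutoff <- na / wavelength
  nyq <- min(max(abs(grid$u)), max(abs(grid$v)))
  if (cutoff > nyq)
    warning("pupil cutoff exceeds the grid Nyquist frequency; support truncated")
  vals <- (grid$u^2 + grid$v^2 <= cutoff^2) + 0i
  structure(list(values = vals, cutoff = cutoff, grid = grid,
                 max_transmittance = max_transmittance, na = na,
                 wavelength = wavelength),
            class = "pupil")
}

# Enforce pupil support and the magnitude cap after an update
enforce_pupil <- function(pupil, values) {
  sup <- Mod(make_ctf(pupil$grid, pupil$na, pupil$wavelength)$values) > 0
  values[!sup] <- 0
  m <- Mod(values)
  over <- m > pupil$max_transmittance
  if (any(over))
    values[over] <- values[over] * (pupil$max_transmittance / m[over])
  pupil$values <- values
  pupil
}

#' Zernike defocus phase map
#'
#' Defocus phase `z20 * sqrt(3) * (2 rho^2 - 1)` over the normalised pupil
#' radius `rho = wavelength * sqrt(u^2+v^2) / na` (Noll-normalised Z(2,0)),
#' zero outside the pupil.
#'
#' @inheritParams make_ctf
#' @param z20 Defocus coefficient (radians, Noll normalisation).
#' @return A real matrix of phases on the grid.
#' @export
zernike_defocus_phase <- function(grid, na, wavelength, z20) {
  stopifnot(inherits(grid, "frequency_grid"), na > 0, wavelength > 0)
  rho2 <- (wavelength / na)^2 * (grid$u^2 + grid$v^2)
  ph <- z20 * sqrt(3) * (2 * rho2 - 1)
  ph[rho2 > 1] <- 0
  ph
}

#' Depth of field of a microscope
#'
#' Classical incoherent-illumination depth of field
#' `lambda * n / NA^2 + n * e / (M * NA)` with camera pixel size `e` and
#' magnification `M`.
#'
#' @param config An [optical_config()].
#' @param na_effective Effective NA (defaults to the objective NA; pass the
#'   synthetic NA for a reconstructed FPM image).
#' @return Depth of field (um).
#' @examples
#' cfg <- optical_config(0.632, 0.3, 10, 4.25)
#' depth_of_field(cfg)                 # raw image, ~8.4 um
#' depth_of_field(cfg, 0.88)           # synthetic NA, ~1.3 um
#' @export
depth_of_field <- function(config, na_effective = config$na_obj) {
  stopifnot(inherits(config, "optical_config"))
  if (!is.numeric(na_effective) || na_effective <= 0)
    stop("na_effective must be positive")
  config$wavelength * config$n_medium / na_effective^2 +
    config$n_medium * config$camera_pixel /
      (config$magnification * na_effective)
}

#' First-Born thickness coefficient
#'
#' The first Born approximation for a weakly scattering sample of thickness
#' `t` is valid when `k * t * dn / 2 << 1`. This returns the coefficient
#' multiplying `t`: `k * |n_sample - n_medium| / 2` with `k = 2 pi / lambda`
#' (units 1/um), so validity requires `coefficient * t << 1`.
#'
#' @param wavelength Wavelength (um).
#' @param n_sample Sample refractive index.
#' @param n_medium Immersion medium refractive index.
#' @return Coefficient (1/um).
#' @examples
#' born_thickness_coefficient(0.63, 1.40, 1.0)  # dry sample, ~2 per um
#' born_thickness_coefficient(0.63, 1.40, 1.5)  # oil immersion, ~0.5 per um
#' @export
born_thickness_coefficient <- function(wavelength, n_sample, n_medium) {
  stopifnot(wavelength > 0)
  (2 * pi / wavelength) * abs(n_sample - n_medium) / 2
}

#' Thin-sample thickness limit for FPM
#'
#' Maximum sample thickness `h_max = pi / |k_z|_max` for the shifted-spectrum
#' (thin sample) approximation, where `|k_z|_max = k (1 - cos theta_max)` at
#' the largest illumination angle; equivalently
#' `lambda / (2 (1 - sqrt(1 - NA_illu^2)))`.
#'
#' @param wavelength Wavelength (um).
#' @param na_illu Illumination NA of the most oblique LED, in (0, 1).
#' @return Thickness limit (um).
#' @examples
#' ou_thickness_limit(0.632, 0.58)  # ~1.7 um (2.7 wavelengths)
#' @export
ou_thickness_limit <- function(wavelength, na_illu) {
  stopifnot(wavelength > 0)
  if (!is.numeric(na_illu) || na_illu <= 0 || na_illu >= 1)
    stop("na_illu must lie strictly between 0 and 1")
  wavelength / (2 * (1 - sqrt(1 - na_illu^2)))
}
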