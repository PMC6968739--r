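#' Complex optical field
#'
#' A 2D complex amplitude sampled on a sample-plane grid.
#'
#' @param values Complex (or real) matrix.
#' @param pixel Pixel pitch (um).
#' @param wavelength Wavelength (um).
#' @param z Axial position (um) relative to the nominal focal plane.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(values, pixel, wavelength, z = 0) {
  values <- as.matrix(values)
  if (!is.complex(values)) values <- values + 0i
  stopifnot(pixel > 0, wavelength > 0, length(z) == 1)
  if (any(!is.finite(Mod(values)))) stop("field values must be finite")
  structure(list(values = values, pixel = pixel, wavelength = wavelength,
                 z = z),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "Complex field: %d x %d px, pixel %.4g um (%.4g x %.4g um), lambda %.4g um, z = %+.3g um\n",
    d[1], d[2], x$pixel, d[1] * x$pixel, d[2] * x$pixel, x$wavelength, x$z))
  invisible(x)
}

#' Field amplitude
#' @param field A [complex_field()].
#' @return Real matrix `Mod(values)`.
#' @export
field_amplitude <- function(field) Mod(field$values)

#' Field phase (wrapped)
#' @param field A [complex_field()].
#' @return Real matrix `Arg(values)` in (-pi, pi].
#' @export
field_phase <- function(field) Arg(field$values)

#' Band-limit a field to a numerical aperture
#'
#' Low-passes the field with the circular frequency support of the given
#' NA — e.g. the synthetic aperture of an FPM reconstruction — which is
#' how a ground-truth phantom is reduced to what the instrument can
#' resolve.
#'
#' @param field A [complex_field()].
#' @param na Numerical aperture of the band limit.
#' @return The band-limited [complex_field()].
#' @export
bandlimit_field <- function(field, na) {
  g <- frequency_grid(dim(field$values), field$pixel, "corner")
  ctf <- Mod(make_ctf(g, na, field$wavelength)$values)
  field$values <- ifft2(fft2(field$values) * ctf)
  field
}
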