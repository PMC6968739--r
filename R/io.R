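# File I/O: multipage 32-bit TIFF rasters with JSON sidecars. Stored pages
# must lie in [0, 1], so every page is written affinely rescaled with its
# offset/scale recorded in the sidecar; round-trips are exact to the
# 32-bit quantisation of the page range (~2e-10).

page_encode <- function(m) {
  lo <- min(m); hi <- max(m)
  if (lo >= 0 && hi <= 1) return(list(page = m, offset = 0, scale = 1))
  s <- if (hi > lo) hi - lo else 1
  list(page = (m - lo) / s, offset = lo, scale = s)
}

page_decode <- function(p, offset, scale) p * scale + offset

sidecar_path <- function(path) paste0(path, ".json")

#' Write an FPM stack to a multipage TIFF plus JSON sidecar
#'
#' @param stack A [lowres_stack()].
#' @param path Output TIFF path; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @param seed Optional seed recorded for provenance.
#' @return Invisibly, the sidecar path.
#' @export
write_stack <- function(stack, path, seed = NULL) {
  stopifnot(inherits(stack, "lowres_stack"))
  enc <- lapply(stack$images, page_encode)
  tiff::writeTIFF(lapply(enc, `[[`, "page"), path, bits.per.sample = 32,
                  reduce = FALSE)
  meta <- list(
    type = "lowres_stack",
    n_frames = length(stack$images),
    directions = stack$directions[, c("alpha", "beta")],
    config = stack$config[c("wavelength", "na_obj", "magnification",
                            "camera_pixel", "n_medium")],
    pixel_object = stack$pixel_object,
    downsample = stack$downsample,
    page_offset = vapply(enc, `[[`, numeric(1), "offset"),
    page_scale = vapply(enc, `[[`, numeric(1), "scale"),
    seed = seed,
    checksum = unname(tools::md5sum(path)))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(sidecar_path(path))
}

#' Read an FPM stack written by [write_stack()]
#'
#' @param path TIFF path (sidecar expected at `paste0(path, ".json")`).
#' @param verify_checksum Check the recorded md5 of the TIFF.
#' @return A [lowres_stack()].
#' @export
read_stack <- function(path, verify_checksum = TRUE) {
  if (!file.exists(path)) stop("stack file not found: ", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("sidecar not found: ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (verify_checksum && !is.null(meta$checksum) &&
      !identical(unname(tools::md5sum(path)), meta$checksum))
    stop("stack checksum mismatch; file corrupted or modified")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != meta$n_frames)
    stop(sprintf("sidecar lists %d frames but TIFF has %d pages",
                 meta$n_frames, length(pages)))
  images <- lapply(seq_along(pages), function(i)
    page_decode(pages[[i]], meta$page_offset[i], meta$page_scale[i]))
  cfg <- optical_config(meta$config$wavelength, meta$config$na_obj,
                        meta$config$magnification, meta$config$camera_pixel,
                        meta$config$n_medium)
  lowres_stack(images, as.data.frame(meta$directions), cfg,
               pixel_object = meta$pixel_object,
               downsample = meta$downsample)
}

#' Write a complex field as a two-page float TIFF
#'
#' Page 1 holds the real part, page 2 the imaginary part; pixel pitch,
#' wavelength and z go to the JSON sidecar. Round-trips through
#' [read_complex_field()] to the 32-bit quantisation of each page's range.
#'
#' @param field A [complex_field()].
#' @param path Output TIFF path.
#' @return Invisibly, the sidecar path.
#' @export
write_complex_field <- function(field, path) {
  stopifnot(inherits(field, "complex_field"))
  enc <- lapply(list(Re(field$values), Im(field$values)), page_encode)
  tiff::writeTIFF(lapply(enc, `[[`, "page"), path, bits.per.sample = 32,
                  reduce = FALSE)
  meta <- list(type = "complex_field", pixel = field$pixel,
               wavelength = field$wavelength, z = field$z,
               page_offset = vapply(enc, `[[`, numeric(1), "offset"),
               page_scale = vapply(enc, `[[`, numeric(1), "scale"))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(sidecar_path(path))
}

#' Read a complex field written by [write_complex_field()]
#' @param path TIFF path.
#' @return A [complex_field()].
#' @export
read_complex_field <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 2) stop("complex-field TIFF must have two pages")
  re <- page_decode(pages[[1]], meta$page_offset[1], meta$page_scale[1])
  im <- page_decode(pages[[2]], meta$page_offset[2], meta$page_scale[2])
  complex_field(matrix(complex(real = re, imaginary = im), nrow(re)),
                meta$pixel, meta$wavelength, meta$z)
}

#' Write a focal series (alternating real/imaginary pages)
#' @param series A [focal_series()].
#' @param path Output TIFF path.
#' @return Invisibly, the sidecar path.
#' @export
write_focal_series <- function(series, path) {
  stopifnot(inherits(series, "focal_series"))
  pages <- list()
  for (pl in series$planes)
    pages <- c(pages, list(Re(pl$values), Im(pl$values)))
  enc <- lapply(pages, page_encode)
  tiff::writeTIFF(lapply(enc, `[[`, "page"), path, bits.per.sample = 32,
                  reduce = FALSE)
  meta <- list(type = "focal_series", z = series$z, kind = series$kind,
               pixel = series$planes[[1]]$pixel,
               wavelength = series$planes[[1]]$wavelength,
               source_z = series$source_z,
               page_offset = vapply(enc, `[[`, numeric(1), "offset"),
               page_scale = vapply(enc, `[[`, numeric(1), "scale"))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(sidecar_path(path))
}

#' Read a focal series written by [write_focal_series()]
#' @param path TIFF path.
#' @return A [focal_series()].
#' @export
read_focal_series <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- length(meta$z)
  if (length(pages) != 2 * nz)
    stop("focal-series TIFF page count does not match sidecar z list")
  planes <- lapply(seq_len(nz), function(k) {
    re <- page_decode(pages[[2 * k - 1]], meta$page_offset[2 * k - 1],
                      meta$page_scale[2 * k - 1])
    im <- page_decode(pages[[2 * k]], meta$page_offset[2 * k],
                      meta$page_scale[2 * k])
    complex_field(matrix(complex(real = re, imaginary = im), nrow(re)),
                  meta$pixel, meta$wavelength, meta$z[k])
  })
  structure(list(z = meta$z, planes = planes, kind = meta$kind,
                 source_z = meta$source_z,
                 cost_flops_per_plane = 2 * fft_flops(length(planes[[1]]$values))),
            class = "focal_series")
}
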