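#' Read optics and LED geometry from a YAML config file
#'
#' Recognised keys: `wavelength_um`, `na_obj`, `magnification`,
#' `camera_pixel_um`, `n_medium` (optional, default 1), and an optional
#' `led` block with `pitch_mm`, `distance_mm`, `rows`, `cols` and `active`
#' (either a list of `[row, col]` pairs or a string `"circle:<diameter_mm>"`
#' selecting a filled disc of LEDs). Unknown keys are an error, so typos do
#' not silently change the optics.
#'
#' @param path Path to the YAML file.
#' @return List with `config` ([optical_config()]) and `geom`
#'   ([led_array()] or `NULL`).
#' @export
read_optics_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known <- c("wavelength_um", "na_obj", "magnification", "camera_pixel_um",
             "n_medium", "led")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  need <- c("wavelength_um", "na_obj", "magnification", "camera_pixel_um")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop("missing config key(s): ", paste(miss, collapse = ", "))
  cfg <- optical_config(y$wavelength_um, y$na_obj, y$magnification,
                        y$camera_pixel_um,
                        if (is.null(y$n_medium)) 1 else y$n_medium)
  geom <- NULL
  if (!is.null(y$led)) {
    l <- y$led
    known_l <- c("pitch_mm", "distance_mm", "rows", "cols", "active")
    bad <- setdiff(names(l), known_l)
    if (length(bad)) stop("unknown led key(s): ", paste(bad, collapse = ", "))
    geom <- led_array(l$rows, l$cols, l$pitch_mm, l$distance_mm)
    if (!is.null(l$active)) {
      if (is.character(l$active) && grepl("^circle:", l$active)) {
        geom <- led_circle(geom,
                           as.numeric(sub("^circle:", "", l$active)))
      } else {
        geom$active <- do.call(rbind, lapply(l$active, as.integer))
      }
    }
  }
  list(config = cfg, geom = geom)
}
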