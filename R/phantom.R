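# Synthetic objects: a thin blood-film phantom (annular red blood cells with
# small dark parasite inclusions at distinct axial offsets), a two-layer
# calibration target, and thin-layer composition by propagate-multiply.

# Run expr with a local RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Thickness profile (um) of a dried, fixed film cell on normalised radius
# s in [0,1]: cells collapse to a flat pancake (near-constant interior
# optical path, so no microlensing) with a thicker rim torus peaking at
# t_max at the membrane ring. Dried smear cells are far thinner than the
# ~2.5 um of a live biconcave cell.
rbc_thickness <- function(s, t_max = 2.5) {
  plateau <- 0.44 * t_max * (1 - smoothstep(s, 0.85, 1))
  rim <- 0.56 * t_max * exp(-((s - 0.9) / 0.12)^2)
  t <- plateau + rim
  t[s > 1] <- 0
  t
}

#' Blood-film phantom
#'
#' Generates a synthetic thin blood film as a set of complex transmittance
#' layers plus an exact ground-truth record. Red blood cells are rendered as
#' annuli (dark membrane rim, weaker interior amplitude drop, phase
#' proportional to the optical path through a biconcave thickness profile
#' with sample index 1.40). A fraction of cells host one malaria-parasite
#' inclusion each: a dark chromatin spot with a fainter cytoplasmic ring,
#' placed on its own layer at an axial offset drawn uniformly from
#' `c(-parasite_z_range, parasite_z_range)`. In oil the membrane rim loses
#' contrast and the ring contrast is reduced, mimicking partial refractive
#' index matching.
#'
#' Coordinates in the truth record are micrometres, with `x` along matrix
#' rows and `y` along columns, measured from the field corner (pixel centre
#' of element (1,1) is at (pixel/2, pixel/2)).
#'
#' @param n_cells Number of cells to place (non-overlapping; an error is
#'   raised if placement fails after bounded retries).
#' @param field_px Field size in pixels (square, >= 64).
#' @param pixel Pixel pitch (um); default matches a 4.25 um camera pixel at
#'   10x magnification upsampled 3x.
#' @param seed RNG seed (required; the phantom is deterministic given it).
#' @param medium `"air"` (dried film) or `"oil"` (immersion).
#' @param infected_fraction Fraction of cells hosting one parasite.
#' @param parasite_z_range Half-range (um) of parasite axial offsets.
#' @param cell_radius_range Cell radius range (um); default 3-4 (6-8 um
#'   diameter).
#' @param parasite_radius Chromatin-spot radius (um; ~1.2 um diameter).
#' @param wavelength Wavelength (um) the transmittance is defined at.
#' @param contrast Optional list overriding amplitude contrast levels
#'   (`interior`, `rim`, `parasite`, `ring`) as fractional amplitude drops.
#' @return A list of class `blood_film_phantom`: `layers` (list of
#'   [complex_field()], sorted by z; cells at z = 0, one layer per
#'   parasite), and `truth` (list with data frames `cells`
#'   (id, x, y, radius, z) and `parasites` (id, cell, x, y, radius, z), and
#'   `medium`).
#' @export
make_blood_film_phantom <- function(n_cells = 20, field_px = 600,
                                    pixel = 4.25 / 10 / 3, seed,
                                    medium = c("air", "oil"),
                                    infected_fraction = 0.3,
                                    parasite_z_range = 1.5,
                                    cell_radius_range = c(3, 4),
                                    parasite_radius = 0.6,
                                    wavelength = 0.632,
                                    contrast = NULL) {
  medium <- match.arg(medium)
  if (missing(seed)) stop("a seed is required")
  stopifnot(field_px >= 64, pixel > 0, n_cells >= 0,
            infected_fraction >= 0, infected_fraction <= 1)
  cl <- list(interior = 0.12,
             rim = if (medium == "air") 0.45 else 0.06,
             parasite = 0.65,
             ring = if (medium == "air") 0.25 else 0.15)
  if (!is.null(contrast)) cl[names(contrast)] <- contrast
  n_medium <- if (medium == "air") 1.0 else 1.5
  k <- 2 * pi / wavelength
  extent <- field_px * pixel

  with_seed(seed, {
    # -- place non-overlapping cells ------------------------------------
    cells <- data.frame(id = integer(), x = numeric(), y = numeric(),
                        radius = numeric(), z = numeric())
    tries <- 0
    while (nrow(cells) < n_cells) {
      r <- stats::runif(1, cell_radius_range[1], cell_radius_range[2])
      x <- stats::runif(1, r + 1, extent - r - 1)
      y <- stats::runif(1, r + 1, extent - r - 1)
      ok <- nrow(cells) == 0 ||
        all(sqrt((cells$x - x)^2 + (cells$y - y)^2) > cells$radius + r + 0.5)
      if (ok) {
        cells <- rbind(cells, data.frame(id = nrow(cells) + 1L, x = x, y = y,
                                         radius = r, z = 0))
      }
      tries <- tries + 1
      if (tries > 500 * max(1, n_cells))
        stop("could not place ", n_cells, " non-overlapping cells; ",
             "reduce the count or enlarge the field")
    }

    # -- parasites: one per infected cell -------------------------------
    n_inf <- round(infected_fraction * n_cells)
    host <- if (n_inf > 0) sort(sample(seq_len(n_cells), n_inf)) else integer()
    parasites <- data.frame(id = integer(), cell = integer(), x = numeric(),
                            y = numeric(), radius = numeric(), z = numeric())
    for (h in host) {
      d <- stats::runif(1, 0, 0.45 * cells$radius[h])
      a <- stats::runif(1, 0, 2 * pi)
      parasites <- rbind(parasites, data.frame(
        id = nrow(parasites) + 1L, cell = h,
        x = cells$x[h] + d * cos(a), y = cells$y[h] + d * sin(a),
        radius = parasite_radius,
        z = stats::runif(1, -parasite_z_range, parasite_z_range)))
    }

    # -- render layers ---------------------------------------------------
    xs <- (seq_len(field_px) - 0.5) * pixel
    cell_layer <- matrix(1 + 0i, field_px, field_px)
    if (n_cells > 0) {
      amp <- matrix(1, field_px, field_px)
      ph <- matrix(0, field_px, field_px)
      for (i in seq_len(n_cells)) {
        rr <- cells$radius[i]
        ix <- which(abs(xs - cells$x[i]) <= rr)
        iy <- which(abs(xs - cells$y[i]) <= rr)
        s <- sqrt(outer((xs[ix] - cells$x[i])^2, (xs[iy] - cells$y[i])^2, "+")) / rr
        inside <- s <= 1
        interior <- cl$interior * (1 - smoothstep(s, 0.75, 1))
        rim <- cl$rim * exp(-((s - 0.9) / 0.07)^2)
        a <- 1 - (interior + rim) * inside
        amp[ix, iy] <- amp[ix, iy] * a
        ph[ix, iy] <- ph[ix, iy] +
          k * (1.40 - n_medium) * rbc_thickness(s) * inside
      }
      cell_layer <- amp * exp(1i * ph)
    }
    layers <- list(complex_field(cell_layer, pixel, wavelength, z = 0))

    if (nrow(parasites) > 0) {
      for (p in seq_len(nrow(parasites))) {
        rp <- parasites$radius[p]
        w <- 2.2 * rp
        ix <- which(abs(xs - parasites$x[p]) <= w)
        iy <- which(abs(xs - parasites$y[p]) <= w)
        d <- sqrt(outer((xs[ix] - parasites$x[p])^2,
                        (xs[iy] - parasites$y[p])^2, "+"))
        spot <- cl$parasite * (1 - smoothstep(d / rp, 0.7, 1.15))
        ring <- cl$ring * exp(-((d / rp - 1.5) / 0.35)^2)
        lay <- matrix(1 + 0i, field_px, field_px)
        # stained chromatin is modelled as purely absorbing: Giemsa dye
        # absorption dominates and a phase-shifting dot would defocus
        # antisymmetrically, which amplitude-based plane selection cannot
        # resolve (documented limitation)
        lay[ix, iy] <- (1 - (spot + ring)) + 0i
        layers <- c(layers, list(
          complex_field(lay, pixel, wavelength, z = parasites$z[p])))
      }
      ord <- order(vapply(layers, function(l) l$z, numeric(1)))
      layers <- layers[ord]
    }

    structure(list(layers = layers,
                   truth = list(cells = cells, parasites = parasites,
                                medium = medium),
                   pixel = pixel, wavelength = wavelength,
                   field_px = field_px),
              class = "blood_film_phantom")
  })
}

# C1 smooth ramp: 0 below lo, 1 above hi
smoothstep <- function(x, lo, hi) {
  t <- pmin(pmax((x - lo) / (hi - lo), 0), 1)
  t * t * (3 - 2 * t)
}

#' Two-layer calibration target
#'
#' Two binary-amplitude chrome-on-glass style layers separated axially: the
#' first carries an opaque disc (default 65 um diameter) and a vertical
#' line pair, the second a horizontal line pair and a digit-like "7" glyph.
#'
#' @param field_px Field size (px, square).
#' @param pixel Pixel pitch (um).
#' @param separation Axial separation (um, >= 0). Layer 1 sits at z = 0,
#'   layer 2 at z = separation; with separation 0 the layers multiply into
#'   one plane.
#' @param disc_diameter Disc diameter (um).
#' @param wavelength Wavelength (um).
#' @return List of class `two_layer_target`: `layers` (one or two
#'   [complex_field()]s) and `truth` (glyph centres in um).
#' @export
make_two_layer_target <- function(field_px = 256, pixel = 0.425,
                                  separation = 10, disc_diameter = 65,
                                  wavelength = 0.632) {
  stopifnot(separation >= 0, field_px >= 64)
  extent <- field_px * pixel
  if (disc_diameter > 0.6 * extent)
    stop("glyphs exceed the field; enlarge field_px or shrink the disc")
  xs <- (seq_len(field_px) - 0.5) * pixel

  disc_c <- c(0.32, 0.35) * extent
  vline_c <- c(0.72, 0.22) * extent
  hline_c <- c(0.25, 0.78) * extent
  seven_c <- c(0.72, 0.72) * extent

  l1 <- matrix(1, field_px, field_px)
  d <- sqrt(outer((xs - disc_c[1])^2, (xs - disc_c[2])^2, "+"))
  l1[d <= disc_diameter / 2] <- 0
  # vertical line pair: two bars 2 um wide, 14 um tall, 4 um apart
  for (off in c(-3, 3)) {
    ix <- abs(xs - vline_c[1]) <= 7
    iy <- abs(xs - (vline_c[2] + off)) <= 1
    l1[ix, iy] <- 0
  }

  l2 <- matrix(1, field_px, field_px)
  for (off in c(-3, 3)) {
    ix <- abs(xs - (hline_c[1] + off)) <= 1
    iy <- abs(xs - hline_c[2]) <= 7
    l2[ix, iy] <- 0
  }
  # numeral "7": horizontal top bar + diagonal descender
  ix <- abs(xs - (seven_c[1] - 6)) <= 1
  iy <- abs(xs - seven_c[2]) <= 5
  l2[ix, iy] <- 0
  for (tstep in seq(0, 1, length.out = 60)) {
    cx <- seven_c[1] - 5 + 11 * tstep
    cy <- seven_c[2] + 4 - 6 * tstep
    ix <- abs(xs - cx) <= 1
    iy <- abs(xs - cy) <= 1
    l2[ix, iy] <- 0
  }

  layers <- list(complex_field(l1, pixel, wavelength, z = 0))
  truth <- list(disc = disc_c, vlines = vline_c, hlines = hline_c,
                seven = seven_c, disc_diameter = disc_diameter,
                separation = separation)
  if (separation == 0) {
    layers[[1]]$values <- layers[[1]]$values * l2
  } else {
    layers <- c(layers, list(complex_field(l2, pixel, wavelength,
                                           z = separation)))
  }
  structure(list(layers = layers, truth = truth, pixel = pixel,
                 wavelength = wavelength),
            class = "two_layer_target")
}

#' Compose layered thin objects into one exit field
#'
#' Sequentially propagates the field between layers and multiplies by each
#' layer's transmittance (the standard multi-slice composition), returning
#' the equivalent exit field at the final layer's plane.
#'
#' @param layers List of [complex_field()]s sorted by increasing `z`.
#' @param wavelength Wavelength (um); defaults to the first layer's.
#' @return A [complex_field()] at the last layer's z.
#' @export
compose_layered_object <- function(layers, wavelength = NULL) {
  stopifnot(length(layers) >= 1)
  zs <- vapply(layers, function(l) l$z, numeric(1))
  if (is.unsorted(zs)) stop("layers must be sorted by z")
  dims <- vapply(layers, function(l) dim(l$values), integer(2))
  if (any(dims != dims[, 1])) stop("layer grids differ")
  if (is.null(wavelength)) wavelength <- layers[[1]]$wavelength
  field <- layers[[1]]
  field$wavelength <- wavelength
  if (length(layers) > 1) {
    for (i in seq(2, length(layers))) {
      field <- propagate(field, zs[i] - field$z)
      field$values <- field$values * layers[[i]]$values
    }
  }
  field
}
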