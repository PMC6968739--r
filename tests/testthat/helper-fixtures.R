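# Shared fixtures, built in code. Heavier objects are cached per session.

.fx <- new.env(parent = emptyenv())

fx_config <- function() optical_config(0.632, 0.3, 10, 4.25)

# Smooth band-limited complex object on an N^2 grid
fx_smooth_object <- function(N = 128, px = 0.425 / 2, na_band = 0.25,
                             seed = 2) {
  key <- sprintf("obj_%d_%g_%g_%d", N, px, na_band, seed)
  if (!is.null(.fx[[key]])) return(.fx[[key]])
  set.seed(seed)
  g <- frequency_grid(c(N, N), px)
  ctf <- Mod(make_ctf(g, na_band, 0.632)$values)
  sm <- Re(stats::fft(stats::fft(matrix(stats::rnorm(N^2), N)) * ctf,
                      inverse = TRUE)) / N^2
  sm <- sm / max(abs(sm))
  .fx[[key]] <- complex_field((1 + 0.5 * sm) * exp(1i * 0.4 * sm), px, 0.632)
  .fx[[key]]
}

# 69 LED directions below NA 0.5 (9x9 grid, 8 mm pitch, 62 mm away)
fx_dirs <- function(na_max = 0.5) {
  d <- led_directions(led_array(9, 9, 8, 62))
  d[d$na_illu < na_max, ]
}

# Small noise-free simulated stack + the object it came from
fx_small_stack <- function() {
  if (!is.null(.fx$small_stack)) return(.fx$small_stack)
  obj <- fx_smooth_object()
  stack <- simulate_low_res_stack(obj, fx_config(), fx_dirs(), downsample = 2)
  .fx$small_stack <- list(object = obj, stack = stack)
  .fx$small_stack
}

# Canonical blood-film phantom with its bandlimited exit wave and series
fx_phantom_series <- function(seed = 1, medium = "air", n_cells = 20,
                              field_px = 600) {
  key <- sprintf("ph_%d_%s_%d_%d", seed, medium, n_cells, field_px)
  if (!is.null(.fx[[key]])) return(.fx[[key]])
  ph <- make_blood_film_phantom(n_cells = n_cells, field_px = field_px,
                                seed = seed, medium = medium)
  exit <- bandlimit_field(compose_layered_object(ph$layers), 0.9)
  ser <- focal_series(exit, seq(-1.375, 1.375, by = 0.25))
  .fx[[key]] <- list(phantom = ph, exit = exit, series = ser)
  .fx[[key]]
}

# Match detected candidates against phantom truth; returns per-parasite
# detection flag and plane error in steps
match_parasites <- function(result, phantom, step = 0.25, tol_um = 1.5) {
  px <- phantom$pixel
  tr <- phantom$truth$parasites
  det <- logical(nrow(tr))
  err <- rep(NA_real_, nrow(tr))
  for (r in seq_len(nrow(tr))) {
    if (nrow(result$candidates) == 0) break
    d <- sqrt((result$candidates$i * px - tr$x[r])^2 +
                (result$candidates$j * px - tr$y[r])^2)
    if (min(d) < tol_um) {
      det[r] <- TRUE
      err[r] <- abs(result$candidates$z[which.min(d)] - tr$z[r]) / step
    }
  }
  list(detected = det, err_steps = err)
}

# local helpers mirroring the package-internal shifts (kept independent)
fftshift2_for_test <- function(x) {
  d <- dim(x)
  i <- c(seq.int(floor(d[1] / 2) + 1L, d[1]), seq.int(1L, floor(d[1] / 2)))
  j <- c(seq.int(floor(d[2] / 2) + 1L, d[2]), seq.int(1L, floor(d[2] / 2)))
  x[i, j, drop = FALSE]
}
ifftshift2_for_test <- function(x) {
  d <- dim(x)
  i <- c(seq.int(ceiling(d[1] / 2) + 1L, d[1]), seq.int(1L, ceiling(d[1] / 2)))
  j <- c(seq.int(ceiling(d[2] / 2) + 1L, d[2]), seq.int(1L, ceiling(d[2] / 2)))
  x[i, j, drop = FALSE]
}
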