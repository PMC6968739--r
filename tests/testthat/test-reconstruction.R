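test_that("spectrum initialisation reproduces the upsampled on-axis amplitude", {
  cfg <- fx_config()
  # uniform on-axis image of value 4 -> flat amplitude 2
  u <- lowres_stack(list(matrix(4, 32, 32)),
                    data.frame(alpha = 0, beta = 0), cfg,
                    pixel_object = 0.2125, downsample = 2L)
  S <- initialize_spectrum(u)
  amp <- Mod(stats::fft(ifftshift2_for_test(S), inverse = TRUE)) / length(S)
  expect_equal(amp, matrix(2, 64, 64), tolerance = 1e-10)

  # idempotent
  expect_identical(S, initialize_spectrum(u))

  # smooth image: initial amplitude ~ upsampled sqrt(I) within 1% RMS
  sm <- fx_small_stack()
  S2 <- initialize_spectrum(sm$stack)
  amp2 <- Mod(stats::fft(ifftshift2_for_test(S2), inverse = TRUE)) /
    length(S2)
  truth <- Mod(sm$object$values)  # object amplitude is the band-limited ref
  i0 <- which.min(sm$stack$directions$na_illu)
  # compare against the bandlimited upsampling oracle: Fourier-embed sqrt(I)
  a_lo <- sqrt(sm$stack$images[[i0]])
  n_lo <- dim(a_lo); r <- 2
  Slo <- fftshift2_for_test(stats::fft(a_lo)) * r^2
  Shi <- matrix(0i, n_lo[1] * r, n_lo[2] * r)
  c_hi <- floor(dim(Shi) / 2) + 1
  ii <- (c_hi[1] - floor(n_lo[1] / 2)):(c_hi[1] + ceiling(n_lo[1] / 2) - 1)
  Shi[ii, ii] <- Slo
  oracle <- Mod(stats::fft(ifftshift2_for_test(Shi), inverse = TRUE)) /
    length(Shi)
  expect_lt(sqrt(mean((amp2 - oracle)^2)) / mean(oracle), 1e-8)
  expect_lt(sqrt(mean((amp2 - truth)^2)) / mean(truth), 0.01)

  expect_error(initialize_spectrum(
    structure(list(images = list(), directions = data.frame()),
              class = "lowres_stack")))
})

test_that("a consistent measurement is a fixed point of the update", {
  sm <- fx_small_stack()
  stack <- sm$stack
  cfg <- fx_config()
  r <- 2
  S <- fftshift2_for_test(stats::fft(sm$object$values))
  grid_lo <- frequency_grid(dim(stack$images[[1]]), stack$pixel_camera,
                            "centered")
  pupil <- make_ctf(grid_lo, cfg$na_obj, cfg$wavelength)
  meta <- list(pixel_object = stack$pixel_object, wavelength = cfg$wavelength)
  for (i in c(1, 20, 69)) {
    upd <- sequential_update(S, pupil, stack$images[[i]],
                             stack$directions[i, ], meta)
    expect_equal(upd$spectrum, S, tolerance = 1e-8)
    expect_equal(upd$pupil$values, pupil$values, tolerance = 1e-12)
    expect_lt(upd$resid2 / sum(stack$images[[i]]), 1e-20)
  }
})

test_that("reconstruction recovers a noise-free object to numerical precision", {
  sm <- fx_small_stack()
  rec <- reconstruct(sm$stack, fx_config(),
                     reconstruction_options(iterations = 30))
  expect_s3_class(rec, "fpm_recon")
  expect_lt(nrmse_mod_phase(rec$field, sm$object), 1e-3)

  # residuals monotone after burn-in on noise-free data
  res <- residuals(rec)
  expect_true(all(diff(res[-1]) <= 1e-12))

  # doubling iterations never increases the final misfit
  rec2 <- reconstruct(sm$stack, fx_config(),
                      reconstruction_options(iterations = 60,
                                             convergence_tol = 0))
  expect_lte(utils::tail(rec2$residuals, 1), utils::tail(res, 1) + 1e-12)

  # energy outside the synthetic NA disc is zero
  S <- fftshift2_for_test(stats::fft(rec$field$values))
  g <- frequency_grid(dim(S), rec$field$pixel, "centered")
  na_syn <- 0.3 + max(sm$stack$directions$na_illu)
  outside <- (g$u^2 + g$v^2) > (na_syn / 0.632)^2
  expect_equal(sum(Mod(S[outside])), 0)

  # EPRY off: returned pupil identical to the initial CTF
  expect_identical(rec$pupil$values, rec$pupil_init$values)
})

test_that("a uniform object stays uniform after reconstruction", {
  N <- 128; px <- 0.425 / 2
  u <- complex_field(matrix(1 + 0i, N, N), px, 0.632)
  st <- simulate_low_res_stack(u, fx_config(), fx_dirs(), downsample = 2)
  rec <- reconstruct(st, fx_config(), reconstruction_options(iterations = 5))
  amp <- Mod(rec$field$values)
  expect_lt(stats::sd(amp) / mean(amp), 0.01)
})

test_that("Zernike fitting projects pupil phase onto the requested modes", {
  g <- frequency_grid(c(64, 64), 0.425, "centered")
  pp <- make_ctf(g, 0.3, 0.632)

  # constructed defocus of 0.26 rad recovered exactly
  pp1 <- pp
  pp1$values <- pp$values * exp(1i * zernike_defocus_phase(g, 0.3, 0.632,
                                                           0.26))
  cf <- fit_zernike(pp1)
  expect_equal(unname(cf["Z2,0"]), 0.26, tolerance = 1e-10)
  expect_lt(max(abs(cf[c("Z1,1", "Z1,-1")])), 1e-10)

  # pure tilt leaves defocus at zero (orthogonality)
  pp2 <- pp
  tilt <- 2 * pi * 0.15 * g$u / max(abs(g$u))
  pp2$values <- pp$values * exp(1i * tilt)
  cf2 <- fit_zernike(pp2)
  expect_lt(abs(cf2["Z2,0"]), 1e-6)
  expect_gt(abs(cf2["Z1,1"]) + abs(cf2["Z1,-1"]), 0.01)

  # multi-mode fit beats any single-mode fit on a random smooth phase
  set.seed(9)
  rho <- sqrt(g$u^2 + g$v^2) / pp$cutoff
  theta <- atan2(g$v, g$u)
  smooth_ph <- 0.3 * rho^2 + 0.2 * rho * cos(theta) - 0.1 * rho * sin(theta)
  pp3 <- pp
  pp3$values <- pp$values * exp(1i * smooth_ph)
  sup <- rho <= 1 & Mod(pp$values) > 0
  modes_all <- rbind(c(1, 1), c(1, -1), c(2, 0))
  resid_of <- function(modes) {
    cf <- fit_zernike(pp3, modes = rbind(c(0, 0), modes))
    fit <- matrix(0, 64, 64)
    for (k in seq_len(nrow(modes) + 1)) {
      nm <- rbind(c(0, 0), modes)[k, ]
      fit <- fit + cf[k] * fpmtools:::zernike_poly(nm[1], nm[2], rho, theta)
    }
    sqrt(mean((smooth_ph[sup] - fit[sup])^2))
  }
  r_all <- resid_of(modes_all)
  for (k in 1:3) expect_lt(r_all, resid_of(modes_all[k, , drop = FALSE]))

  expect_error(fit_zernike(structure(list(
    values = matrix(0i, 4, 4), cutoff = 1,
    grid = frequency_grid(c(4, 4), 1)), class = "pupil")), "support")
})

test_that("EPRY recovers an injected defocus aberration", {
  N <- 128; px <- 0.425 / 2
  obj <- fx_smooth_object(N, px)
  g <- frequency_grid(c(N, N), px, "corner")
  ab <- zernike_defocus_phase(g, 0.3, 0.632, -0.5)
  st <- simulate_low_res_stack(obj, fx_config(), fx_dirs(), downsample = 2,
                               aberration_phase = ab)
  rec <- reconstruct(st, fx_config(),
                     reconstruction_options(iterations = 40, epry = TRUE))
  z20 <- coef(rec)["Z2,0"]
  expect_lt(z20, 0)                       # sign
  expect_lt(abs(z20 - (-0.5)), 0.15)      # magnitude within 30%
})
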