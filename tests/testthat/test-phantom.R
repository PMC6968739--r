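test_that("blood-film phantom is deterministic and matches its truth record", {
  p1 <- make_blood_film_phantom(n_cells = 8, field_px = 300, seed = 11)
  p2 <- make_blood_film_phantom(n_cells = 8, field_px = 300, seed = 11)
  expect_identical(lapply(p1$layers, `[[`, "values"),
                   lapply(p2$layers, `[[`, "values"))
  expect_identical(p1$truth, p2$truth)

  # 20 cells, 30% infected: exactly 6 parasites, each inside its host disc
  ph <- make_blood_film_phantom(n_cells = 20, field_px = 600, seed = 1)
  expect_equal(nrow(ph$truth$cells), 20)
  expect_equal(nrow(ph$truth$parasites), 6)
  for (r in seq_len(6)) {
    h <- ph$truth$parasites$cell[r]
    d <- sqrt((ph$truth$parasites$x[r] - ph$truth$cells$x[h])^2 +
                (ph$truth$parasites$y[r] - ph$truth$cells$y[h])^2)
    expect_lt(d, ph$truth$cells$radius[h])
    expect_lte(abs(ph$truth$parasites$z[r]), 1.5)
  }

  # rendered membrane layer is dark where the truth says cells are
  memb <- ph$layers[[which(vapply(ph$layers, `[[`, numeric(1), "z") == 0)]]
  px <- ph$pixel
  for (h in c(1, 10, 20)) {
    i <- round(ph$truth$cells$x[h] / px)
    j <- round(ph$truth$cells$y[h] / px)
    expect_lt(Mod(memb$values[i, j]), 1)
  }

  # empty phantom: uniform background, empty truth
  p0 <- make_blood_film_phantom(n_cells = 0, field_px = 128, seed = 3)
  expect_true(all(p0$layers[[1]]$values == 1 + 0i))
  expect_equal(nrow(p0$truth$cells), 0)
  expect_equal(nrow(p0$truth$parasites), 0)

  # impossible packing fails explicitly
  expect_error(make_blood_film_phantom(n_cells = 60, field_px = 128,
                                       seed = 5), "non-overlapping")
})

test_that("two-layer target renders its glyphs where the truth says", {
  tt <- make_two_layer_target(separation = 10)
  expect_length(tt$layers, 2)
  expect_equal(tt$layers[[2]]$z, 10)

  # opaque disc: transmitted energy fraction = 1 - disc area / field area
  l1 <- Mod(tt$layers[[1]]$values)^2
  n_dark_disc <- sum(l1 == 0)
  frac <- mean(l1)
  area_frac <- n_dark_disc / length(l1)
  expect_equal(frac, 1 - area_frac, tolerance = 1e-12)
  disc_px <- pi * (tt$truth$disc_diameter / 2 / tt$pixel)^2
  expect_gt(n_dark_disc, 0.9 * disc_px)  # disc dominates layer-1 darkness

  # disc centroid within 1 px of the truth position
  idx <- which(l1 == 0, arr.ind = TRUE)
  d <- sqrt((idx[, 1] - tt$truth$disc[1] / tt$pixel)^2 +
              (idx[, 2] - tt$truth$disc[2] / tt$pixel)^2) * tt$pixel
  near <- idx[d < tt$truth$disc_diameter / 2 + 2, , drop = FALSE]
  expect_equal(mean(near[, 1]) * tt$pixel, tt$truth$disc[1],
               tolerance = tt$pixel * 2)

  # separation 0 collapses to the product of transmittances
  t0 <- make_two_layer_target(separation = 0)
  expect_length(t0$layers, 1)
  expect_error(make_two_layer_target(disc_diameter = 500), "exceed")
})

test_that("layer composition equals manual propagate-and-multiply", {
  obj <- fx_smooth_object(64, 0.5)
  one <- complex_field(matrix(1 + 0i, 64, 64), 0.5, 0.632, z = 0)

  # single layer unchanged
  expect_identical(compose_layered_object(list(obj))$values, obj$values)

  # two all-ones layers: plane wave unchanged up to global phase
  one2 <- complex_field(matrix(1 + 0i, 64, 64), 0.5, 0.632, z = 3)
  comp <- compose_layered_object(list(one, one2))
  expect_equal(Mod(comp$values), matrix(1, 64, 64), tolerance = 1e-10)
  expect_equal(comp$z, 3)

  # two-step oracle
  l1 <- obj
  l2 <- obj; l2$z <- 2.5
  comp2 <- compose_layered_object(list(l1, l2))
  manual <- propagate(l1, 2.5)
  manual$values <- manual$values * l2$values
  expect_equal(comp2$values, manual$values, tolerance = 1e-12)

  bad <- complex_field(matrix(1 + 0i, 32, 32), 0.5, 0.632, z = 5)
  expect_error(compose_layered_object(list(obj, bad)), "grids")
})

test_that("forward model reduces to |t|^2 for on-axis all-pass imaging", {
  N <- 64; px <- 0.5
  obj <- fx_smooth_object(N, px)
  # cutoff beyond the grid corner: every frequency passes
  cfg <- optical_config(0.5, 0.95, 10, px * 10)
  st <- suppressWarnings(simulate_low_res_stack(
    obj, cfg, data.frame(alpha = 0, beta = 0), downsample = 1))
  expect_equal(st$images[[1]], Mod(obj$values)^2, tolerance = 1e-12)
  # Parseval: summed intensity equals summed squared magnitude
  expect_equal(sum(st$images[[1]]), sum(Mod(obj$values)^2),
               tolerance = 1e-10)

  # uniform object, on-axis: constant brightfield
  u <- complex_field(matrix(1 + 0i, N, N), px, 0.632)
  cfgr <- optical_config(0.632, 0.3, 10, px * 10)
  stu <- simulate_low_res_stack(u, cfgr, data.frame(alpha = 0, beta = 0), 1)
  expect_equal(max(stu$images[[1]]) - min(stu$images[[1]]), 0,
               tolerance = 1e-10)
})

test_that("forward model obeys the shift theorem on grid frequencies", {
  N <- 128; px <- 0.425 / 2; lam <- 0.632
  obj <- fx_smooth_object(N, px)
  cfg <- optical_config(0.632, 0.3, 10, px * 10)
  du <- 1 / (N * px)
  a <- 9 * du * lam
  st1 <- simulate_low_res_stack(obj, cfg, data.frame(alpha = a, beta = 0), 1)
  xs <- (seq_len(N) - 1) * px
  mod <- obj
  mod$values <- obj$values * exp(2i * pi * (a / lam) * matrix(xs, N, N))
  st2 <- simulate_low_res_stack(mod, cfg, data.frame(alpha = 0, beta = 0), 1)
  expect_equal(st1$images[[1]], st2$images[[1]], tolerance = 1e-10)
})

test_that("darkfield frames carry only scattered light", {
  N <- 128; px <- 0.425 / 2
  set.seed(4)
  weak <- fx_smooth_object(N, px)
  weak$values <- 1 + 0.05 * (weak$values - mean(weak$values))
  cfg <- optical_config(0.632, 0.3, 10, px * 10)
  bf <- simulate_low_res_stack(weak, cfg, data.frame(alpha = 0, beta = 0), 1)
  df <- simulate_low_res_stack(weak, cfg,
                               data.frame(alpha = 0.45, beta = 0), 1)
  expect_lt(sum(df$images[[1]]), 0.1 * sum(bf$images[[1]]))
})

test_that("noise is reproducible under a fixed seed and off by default", {
  sm <- fx_small_stack()
  dirs <- data.frame(alpha = 0, beta = 0)
  s1 <- simulate_low_res_stack(sm$object, fx_config(), dirs, 2,
                               noise = list(photons = 500), seed = 42)
  s2 <- simulate_low_res_stack(sm$object, fx_config(), dirs, 2,
                               noise = list(photons = 500), seed = 42)
  s3 <- simulate_low_res_stack(sm$object, fx_config(), dirs, 2,
                               noise = list(photons = 500), seed = 43)
  clean <- simulate_low_res_stack(sm$object, fx_config(), dirs, 2)
  expect_identical(s1$images, s2$images)
  expect_false(identical(s1$images, s3$images))
  expect_false(identical(s1$images, clean$images))
  expect_error(simulate_low_res_stack(sm$object, fx_config(), dirs, 2,
                                      noise = list(photons = 500)), "seed")

  # out-of-band shift is an explicit error
  coarse <- complex_field(matrix(1 + 0i, 32, 32), 0.5, 0.632)
  cfg_c <- optical_config(0.632, 0.3, 10, 5)
  expect_error(simulate_low_res_stack(coarse, cfg_c,
                                      data.frame(alpha = 0.9, beta = 0), 1),
               "beyond the grid")
})
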