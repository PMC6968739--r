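test_that("phase unwrapping recovers smooth surfaces modulo 2 pi", {
  # constant phase
  expect_equal(unwrap_phase(matrix(0.7, 32, 32)), matrix(0.7, 32, 32))

  # smooth ramp exceeding 2 pi: monotone, no jumps, rewraps exactly
  xs <- seq(0, 6 * pi, length.out = 100)
  truth <- outer(xs, 0.3 * xs, "+")
  wrapped <- Arg(exp(1i * truth))
  uw <- unwrap_phase(wrapped)
  expect_true(all(abs(diff(uw[, 1])) < pi))
  off <- round(mean(uw - truth) / (2 * pi)) * 2 * pi
  expect_lt(max(abs(uw - truth - off)), 1e-6)
  expect_lt(max(abs(Arg(exp(1i * (uw - wrapped))))), 1e-9)

  # complex-field input uses the field's phase
  f <- complex_field(exp(1i * truth[1:32, 1:32]), 0.5, 0.632)
  expect_lt(max(abs(Arg(exp(1i * (unwrap_phase(f) - wrapped[1:32, 1:32]))))),
            1e-9)
  expect_error(unwrap_phase(matrix(c(NaN, 1, 2, 3), 2)), "finite")
})

test_that("air-variant mask segments phantom cells with high overlap", {
  ph <- make_blood_film_phantom(n_cells = 8, field_px = 360, seed = 21)
  exit <- bandlimit_field(compose_layered_object(ph$layers), 0.9)
  params <- segmentation_params(ph$pixel)
  amp <- field_amplitude(exit)
  uw <- unwrap_phase(exit)
  mask <- rbc_mask_air(amp, uw, params)

  lab <- EBImage::bwlabel(mask * 1)
  expect_equal(max(lab), 8)

  # each component overlaps its truth disc with IoU > 0.7
  px <- ph$pixel
  n <- dim(mask)
  xs <- (seq_len(n[1]) - 0.5) * px
  for (r in seq_len(8)) {
    disc <- outer((xs - ph$truth$cells$x[r])^2,
                  (xs - ph$truth$cells$y[r])^2, "+") <=
      ph$truth$cells$radius[r]^2
    ious <- vapply(seq_len(max(lab)), function(k) {
      m <- lab == k
      sum(m & disc) / sum(m | disc)
    }, numeric(1))
    expect_gt(max(ious), 0.7)
  }

  # blank input: empty mask
  expect_equal(sum(rbc_mask_air(matrix(1, 64, 64), matrix(0, 64, 64),
                                segmentation_params(0.1417))), 0)
  expect_error(rbc_mask_air(matrix(1, 0, 0), matrix(0, 0, 0), params))
})

test_that("clump splitting cuts a 2-px bridge between fused cells", {
  px <- 0.1417
  n <- 220
  xs <- (seq_len(n) - 0.5) * px
  r <- 3.2
  c1 <- c(10, 13); c2 <- c(10 + 2 * r + 0.45, 13)
  disc1 <- outer((xs - c1[1])^2, (xs - c1[2])^2, "+") <= r^2
  disc2 <- outer((xs - c2[1])^2, (xs - c2[2])^2, "+") <= r^2
  bridge <- abs(matrix(xs, n, n) - (c1[1] + r + 0.22)) <= 0.35 &
    abs(matrix(xs, n, n, byrow = TRUE) - 13) <= px
  shape <- disc1 | disc2 | bridge
  amp <- 1 - 0.4 * shape
  phase <- 2 * shape
  mask <- rbc_mask_air(amp, phase, segmentation_params(px))
  expect_equal(max(EBImage::bwlabel(mask * 1)), 2)
})

test_that("oil-variant mask recovers phantom cells", {
  ph <- make_blood_film_phantom(n_cells = 15, field_px = 520, seed = 31,
                                medium = "oil")
  exit <- bandlimit_field(compose_layered_object(ph$layers), 0.9)
  params <- segmentation_params(ph$pixel)
  mask <- rbc_mask_oil(field_amplitude(exit), field_phase(exit), params)
  n_cells <- max(EBImage::bwlabel(mask * 1))
  expect_gte(n_cells, 14)
  expect_lte(n_cells, 16)
  expect_equal(sum(rbc_mask_oil(matrix(1, 64, 64), matrix(0, 64, 64),
                                segmentation_params(0.1417))), 0)
})

test_that("both mask variants recover most cells of a high-contrast phantom", {
  ph <- make_blood_film_phantom(n_cells = 10, field_px = 420, seed = 41)
  exit <- bandlimit_field(compose_layered_object(ph$layers), 0.9)
  params <- segmentation_params(ph$pixel)
  amp <- field_amplitude(exit)
  uw <- unwrap_phase(exit)
  for (mask in list(rbc_mask_air(amp, uw, params),
                    rbc_mask_oil(amp, field_phase(exit), params))) {
    lab <- EBImage::bwlabel(mask * 1)
    px <- ph$pixel
    ij <- which(lab > 0, arr.ind = TRUE)
    found <- 0
    for (r in seq_len(10)) {
      d <- sqrt((ij[, 1] * px - ph$truth$cells$x[r])^2 +
                  (ij[, 2] * px - ph$truth$cells$y[r])^2)
      if (any(d < 0.5 * ph$truth$cells$radius[r])) found <- found + 1
    }
    expect_gte(found, 9)
  }
})

test_that("mask cleaning is idempotent and enforces the cell-area floor", {
  ph <- make_blood_film_phantom(n_cells = 6, field_px = 300, seed = 51)
  exit <- bandlimit_field(compose_layered_object(ph$layers), 0.9)
  params <- segmentation_params(ph$pixel)
  mask <- rbc_mask_air(field_amplitude(exit), unwrap_phase(exit), params)

  lab <- EBImage::bwlabel(mask * 1)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0]) * params$pixel^2
    expect_true(all(areas >= params$min_cell_area))
  }
  # re-applying the cleaning steps leaves the mask essentially unchanged
  mask2 <- fpmtools:::clean_mask(mask, params)
  expect_gt(sum(mask2 & mask) / sum(mask2 | mask), 0.95)
})

test_that("candidate detection finds parasites and rejects speckle", {
  px <- 0.1417
  n <- 160
  xs <- (seq_len(n) - 0.5) * px
  ctr <- n * px / 2
  footprint <- outer((xs - ctr)^2, (xs - ctr)^2, "+") <= 3.4^2

  mk_series <- function(amp) {
    f <- complex_field(amp + 0i, px, 0.632)
    structure(list(z = c(-0.25, 0, 0.25),
                   planes = list(f, f, f), kind = "angular_spectrum",
                   source_z = 0, cost_flops_per_plane = 0),
              class = "focal_series")
  }

  # uninfected interior: no candidates
  amp0 <- matrix(0.9, n, n); amp0[!footprint] <- 1
  p <- segmentation_params(px)
  expect_equal(nrow(detect_candidate_parasites(mk_series(amp0), footprint, p)),
               0)

  # one 1.2-um dark inclusion: exactly one candidate
  d <- sqrt(outer((xs - ctr - 0.8)^2, (xs - ctr)^2, "+"))
  amp1 <- amp0; amp1[d <= 0.6] <- 0.3
  cand <- detect_candidate_parasites(mk_series(amp1), footprint, p)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$i * px, ctr + 0.8, tolerance = 0.3)

  # a 0.5-um speckle falls below the size filter
  amp2 <- amp0; amp2[d <= 0.25] <- 0.3
  expect_equal(nrow(detect_candidate_parasites(mk_series(amp2), footprint, p)),
               0)
})

test_that("plane selection honours its tie and single-plane contracts", {
  px <- 0.1417
  n <- 120
  xs <- (seq_len(n) - 0.5) * px
  ctr <- n * px / 2
  d <- sqrt(outer((xs - ctr)^2, (xs - ctr)^2, "+"))
  amp <- matrix(0.9, n, n); amp[d <= 0.6] <- 0.3
  f <- complex_field(amp + 0i, px, 0.632)
  p <- segmentation_params(px)
  cand <- data.frame(i = ctr / px, j = ctr / px)

  single <- structure(list(z = 0, planes = list(f), kind = "angular_spectrum",
                           source_z = 0, cost_flops_per_plane = 0),
                      class = "focal_series")
  expect_equal(select_plane_air(cand, single, p, 1), 1)
  expect_equal(select_plane_oil(cand, single, p, 1), 1)

  # identical planes: tie resolves to the membrane plane
  five <- structure(list(z = seq(-0.5, 0.5, 0.25),
                         planes = rep(list(f), 5), kind = "angular_spectrum",
                         source_z = 0, cost_flops_per_plane = 0),
                    class = "focal_series")
  expect_equal(select_plane_air(cand, five, p, 4), 4)
  expect_equal(select_plane_oil(cand, five, p, 2), 2)
})

test_that("the consistency check resets only out-of-film outliers", {
  f <- complex_field(matrix(1 + 0i, 8, 8), 0.5, 0.632)
  ser <- structure(list(z = seq(-2, 2, 0.5), planes = rep(list(f), 9),
                        kind = "angular_spectrum", source_z = 0,
                        cost_flops_per_plane = 0),
                   class = "focal_series")

  # all equal: unchanged
  cc <- consistency_check(rep(5L, 4), ser, 3)
  expect_equal(cc$plane_idx, rep(5L, 4))
  expect_false(any(cc$flagged))

  # one outlier at the series edge among median-centred assignments
  idx <- c(4L, 5L, 5L, 5L, 6L, 9L)
  cc2 <- consistency_check(idx, ser, 3)
  expect_equal(cc2$flagged, c(rep(FALSE, 5), TRUE))
  expect_equal(cc2$plane_idx[6], 5L)

  # disagreement within tolerance: unchanged
  cc3 <- consistency_check(c(4L, 6L), ser, 3)
  expect_false(any(cc3$flagged))

  # explicit centre overrides the median
  cc4 <- consistency_check(c(1L, 5L), ser, 3, center = ser$z[1])
  expect_equal(cc4$flagged, c(FALSE, TRUE))
})

test_that("EDoF composition draws pixels verbatim from selected planes", {
  px <- 0.25
  n <- 96
  set.seed(8)
  mk <- function(v) complex_field(matrix(v, n, n) +
                                    0.01 * matrix(stats::runif(n^2), n), px,
                                  0.632)
  planes <- list(mk(0.5), mk(0.7), mk(0.9))
  ser <- structure(list(z = c(-0.5, 0, 0.5), planes = planes,
                        kind = "angular_spectrum", source_z = 0,
                        cost_flops_per_plane = 0),
                   class = "focal_series")
  labels <- matrix(0L, n, n)
  labels[30:60, 30:60] <- 1L
  params <- segmentation_params(px)

  ed <- compose_edof(ser, labels, c(`1` = 3L), params, base_plane = 1L)
  expect_equal(ed$base_plane, 1L)
  amp1 <- field_amplitude(planes[[1]])
  amp3 <- field_amplitude(planes[[3]])
  # outside cells: base plane verbatim
  expect_identical(ed$composite[labels == 0], amp1[labels == 0])
  expect_true(all(ed$plane_map[labels == 0] == 1))
  # cell core: selected plane verbatim
  core <- ed$plane_map == 3
  expect_true(any(core))
  expect_identical(ed$composite[core], amp3[core])
  # plane_map only uses planes present in the series
  expect_true(all(ed$plane_map %in% 1:3))

  # identical planes: composite equals any plane
  ser2 <- structure(list(z = c(0, 1), planes = list(planes[[2]], planes[[2]]),
                         kind = "angular_spectrum", source_z = 0,
                         cost_flops_per_plane = 0),
                    class = "focal_series")
  ed2 <- compose_edof(ser2, labels, c(`1` = 2L), params, base_plane = 1L)
  expect_equal(ed2$composite, field_amplitude(planes[[2]]))

  # no cells: composite = base plane
  ed3 <- compose_edof(ser, matrix(0L, n, n), integer(0), params,
                      base_plane = 2L)
  expect_identical(ed3$composite, field_amplitude(planes[[2]]))
})
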