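# Extended depth-of-field pipeline: per-plane RBC mask construction, clump
# splitting, candidate-parasite detection, per-cell focal-plane selection
# (air and oil variants), consistency check, and composite rendering.

#' Segmentation parameters for the EDoF pipeline
#'
#' Defaults follow the blood-film analysis conventions: very small objects
#' (< 50 px) are discarded, connected components smaller than a cell
#' (< 12 um^2, about half a typical RBC footprint) are excluded, candidate
#' parasites must be at least ~1 um in equivalent diameter, and the air
#' variant matches the refocused object perimeter to that of a typical
#' ring-stage parasite (4 um).
#'
#' @param pixel Pixel pitch of the focal-series grid (um).
#' @param min_object_px Size filter 1 (px).
#' @param min_cell_area Minimum cell area (um^2).
#' @param min_parasite_diameter Lower bound on parasite diameter (um).
#' @param max_parasite_diameter Upper bound on candidate equivalent
#'   diameter (um); larger dark structures are membrane/rim artefacts.
#' @param target_parasite_perimeter Perimeter matched by the air-variant
#'   plane selection (um).
#' @param adaptive_block Block size (px) of the adaptive amplitude
#'   threshold; default about twice an expected cell diameter.
#' @param sample_thickness Blood-film thickness (um) used by the
#'   consistency check.
#' @param membrane_band Width (um) of the membrane band kept at the base
#'   plane when intracellular regions are replaced.
#' @param interior_margin Erosion depth (um) of the cell footprint when
#'   searching for intracellular parasites; excludes the dark biconcave
#'   rim.
#' @return List of class `segmentation_params`.
#' @export
segmentation_params <- function(pixel,
                                min_object_px = 50,
                                min_cell_area = 12,
                                min_parasite_diameter = 1,
                                max_parasite_diameter = 2.5,
                                target_parasite_perimeter = 4,
                                adaptive_block = round(14 / pixel),
                                sample_thickness = 3,
                                membrane_band = 0.8,
                                interior_margin = 1.0) {
  stopifnot(pixel > 0, min_object_px > 0, min_cell_area > 0,
            min_parasite_diameter > 0, target_parasite_perimeter > 0)
  structure(list(pixel = pixel, min_object_px = min_object_px,
                 min_cell_area = min_cell_area,
                 min_parasite_diameter = min_parasite_diameter,
                 max_parasite_diameter = max_parasite_diameter,
                 target_parasite_perimeter = target_parasite_perimeter,
                 adaptive_block = adaptive_block,
                 sample_thickness = sample_thickness,
                 membrane_band = membrane_band,
                 interior_margin = interior_margin),
            class = "segmentation_params")
}

# Otsu threshold of a numeric vector (256-bin between-class variance)
otsu_vec <- function(x, bins = 256) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(pmax(findInterval(
    x, seq(r[1], r[2], length.out = bins + 1), all.inside = TRUE), 1), bins),
    bins)
  w <- h / sum(h)
  omega <- cumsum(w)
  centers <- seq(r[1], r[2], length.out = bins + 1)[-1] - diff(r) / (2 * bins)
  mu <- cumsum(w * centers)
  mu_t <- mu[bins]
  bc <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  bc[!is.finite(bc)] <- 0
  centers[which.max(bc)]
}

norm01 <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(x * 0)
  (x - r[1]) / diff(r)
}

# logical-matrix helpers on top of EBImage
rm_small <- function(mask, min_px) {
  lab <- EBImage::bwlabel(mask * 1)
  if (max(lab) == 0) return(mask & FALSE)
  keep <- which(tabulate(lab[lab > 0]) >= min_px)
  matrix(lab %in% keep, nrow(mask))
}

reflect_pad <- function(m, w) {
  n <- dim(m)
  m[c(w:1, 1:n[1], n[1]:(n[1] - w + 1)), c(w:1, 1:n[2], n[2]:(n[2] - w + 1))]
}

crop_pad <- function(m, w, n) m[(w + 1):(w + n[1]), (w + 1):(w + n[2])]

fill_holes <- function(mask) {
  EBImage::fillHull(EBImage::bwlabel(mask * 1)) > 0
}

# Raw (uncleaned) air-variant mask: OR of a gradient-based phase edge mask
# and an adaptive amplitude threshold mask
raw_mask_air <- function(amplitude, unwrapped_phase, params) {
  edge <- sobel_gradients(unwrapped_phase)$mag
  edge_bw <- edge > otsu_vec(edge)
  a <- norm01(amplitude)
  w <- max(5, round(params$adaptive_block / 2))
  w <- min(w, floor((min(dim(a)) - 1) / 2))
  dark <- EBImage::thresh(1 - a, w = w, h = w, offset = 0.02) > 0
  edge_bw | dark
}

# Raw oil-variant mask: (binarised amplitude OR binarised phase) AND
# (Sobel-edge amplitude OR Sobel-edge phase)
raw_mask_oil <- function(amplitude, phase, params) {
  a <- norm01(amplitude)
  p <- abs(phase - stats::median(phase))
  bwA <- (1 - a > otsu_vec(1 - a)) | (p > otsu_vec(p))
  ea <- sobel_gradients(a)$mag
  ep <- sobel_gradients(p)$mag
  bwB <- (ea > otsu_vec(ea)) | (ep > otsu_vec(ep))
  bwA & bwB
}

# Shared cleaning: size filter 1, reflect-pad + fill (mask 1), closing
# (mask 2), clump splitting by removing the band between the closed mask
# and its eroded interior (which severs bridge necks), then growing the
# resulting per-cell cores back through the filled mask and cutting along
# the grown-label boundaries; finally the cell-area filter.
clean_mask <- function(raw, params) {
  n <- dim(raw)
  px <- params$pixel
  m <- rm_small(raw, params$min_object_px)
  pad <- max(8, round(4 / px))
  m1 <- crop_pad(fill_holes(reflect_pad(m, pad)), pad, n)
  close_b <- EBImage::makeBrush(max(3, 2 * floor(round(1 / px) / 2) + 1),
                                "disc")
  m2 <- crop_pad(EBImage::closing(reflect_pad(m, pad) * 1, close_b) > 0,
                 pad, n)
  band_b <- EBImage::makeBrush(2 * floor(1.0 / px / 2) + 3, "disc")
  band <- m2 & !(EBImage::erode(m2 * 1, band_b) > 0)
  cores <- m1 & !band & (EBImage::erode(m1 * 1, band_b) > 0)
  cores <- rm_small(cores, 0.5 * params$min_cell_area / px^2)
  if (!any(cores)) return(cores)
  seeds <- EBImage::bwlabel(cores * 1)
  grown <- EBImage::propagate(m1 * 0, seeds, mask = m1)
  grown <- matrix(as.integer(grown), n[1], n[2])
  # cut boundaries between adjacent grown labels so components stay split
  # even under 8-connectivity (mark both pixels of every differing pair,
  # including diagonal pairs)
  cut <- matrix(FALSE, n[1], n[2])
  for (s in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    ia <- seq.int(max(1L, 1L - s[1]), n[1] - max(0L, s[1]))
    ja <- seq.int(max(1L, 1L - s[2]), n[2] - max(0L, s[2]))
    ib <- ia + s[1]
    jb <- ja + s[2]
    a <- grown[ia, ja, drop = FALSE]
    b <- grown[ib, jb, drop = FALSE]
    d <- a > 0 & b > 0 & a != b
    ca <- cut[ia, ja, drop = FALSE]; ca[d] <- TRUE; cut[ia, ja] <- ca
    cb <- cut[ib, jb, drop = FALSE]; cb[d] <- TRUE; cut[ib, jb] <- cb
  }
  final <- grown > 0 & !cut
  rm_small(final, params$min_cell_area / px^2)
}

#' RBC segmentation mask, air-dried film variant
#'
#' Combines a gradient-based edge mask of the unwrapped phase with an
#' adaptive amplitude threshold mask, removes small objects, fills cells
#' after reflective padding, splits clumps using the complement of a
#' closing-derived second mask, and drops components smaller than a cell.
#'
#' @param amplitude Amplitude image (matrix).
#' @param unwrapped_phase Unwrapped phase image (matrix, radians).
#' @param params [segmentation_params()].
#' @return Logical matrix.
#' @export
rbc_mask_air <- function(amplitude, unwrapped_phase, params) {
  stopifnot(all(dim(amplitude) == dim(unwrapped_phase)),
            length(amplitude) > 0)
  clean_mask(raw_mask_air(amplitude, unwrapped_phase, params), params)
}

#' RBC segmentation mask, oil-immersion variant
#'
#' Oil immersion removes the dark membrane rim, so the mask is built from
#' (binarised amplitude OR binarised phase) AND (Sobel edges of amplitude
#' OR of phase), followed by the same filling, padding, clump-splitting and
#' filtering steps as the air variant.
#'
#' @inheritParams rbc_mask_air
#' @param phase Phase image (wrapped or unwrapped).
#' @return Logical matrix.
#' @export
rbc_mask_oil <- function(amplitude, phase, params) {
  stopifnot(all(dim(amplitude) == dim(phase)), length(amplitude) > 0)
  clean_mask(raw_mask_oil(amplitude, phase, params), params)
}

# Label cells in a final mask; returns data frame + label image
label_cells <- function(mask, params) {
  lab <- EBImage::bwlabel(mask * 1)
  k <- max(lab)
  if (k == 0)
    return(list(labels = lab,
                cells = data.frame(label = integer(), x = numeric(),
                                   y = numeric(), area_um2 = numeric())))
  px <- params$pixel
  ij <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  cells <- data.frame(
    label = seq_len(k),
    x = (tapply(ij[, 1], l, mean) - 0.5) * px,
    y = (tapply(ij[, 2], l, mean) - 0.5) * px,
    area_um2 = as.numeric(tabulate(l, k)) * px^2)
  list(labels = lab, cells = cells)
}

#' Detect candidate parasites within one cell
#'
#' Global (Otsu) thresholding of the amplitude inside the eroded cell
#' footprint on every plane of the focal series; dark objects that are at
#' least `min_parasite_diameter` in equivalent diameter and clearly darker
#' than the cell interior are kept, and detections across planes are merged
#' by centroid proximity.
#'
#' @param series A [focal_series()].
#' @param footprint Logical matrix: the cell's pixel footprint.
#' @param params [segmentation_params()].
#' @return Data frame with one row per candidate: centroid (`i`, `j`, px),
#'   `area_um2` (largest across planes), `planes` (list column of plane
#'   indices where detected).
#' @export
detect_candidate_parasites <- function(series, footprint, params) {
  stopifnot(inherits(series, "focal_series"), any(footprint))
  px <- params$pixel
  interior <- EBImage::erode(
    footprint * 1,
    EBImage::makeBrush(2 * floor(params$interior_margin / px / 2) + 3,
                       "disc")) > 0
  if (!any(interior)) interior <- footprint
  min_area_px <- pi * (params$min_parasite_diameter / 2)^2 * 0.8 / px^2
  max_area_px <- pi * (params$max_parasite_diameter / 2)^2 / px^2
  found <- list()
  for (p in seq_along(series$planes)) {
    amp <- field_amplitude(series$planes[[p]])
    vals <- amp[interior]
    th <- otsu_vec(vals)
    med <- stats::median(vals)
    dark <- interior & (amp < th)
    lab <- EBImage::bwlabel(dark * 1)
    if (max(lab) == 0) next
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k, arr.ind = TRUE)
      if (nrow(idx) < min_area_px) next
      if (nrow(idx) > max_area_px) next
      if (mean(amp[lab == k]) > 0.8 * med) next
      found[[length(found) + 1]] <- data.frame(
        i = mean(idx[, 1]), j = mean(idx[, 2]),
        area_um2 = nrow(idx) * px^2, plane = p)
    }
  }
  if (length(found) == 0)
    return(data.frame(i = numeric(), j = numeric(), area_um2 = numeric(),
                      n_planes = integer(), first_plane = integer()))
  f <- do.call(rbind, found)
  # merge detections across planes by centroid proximity (1.5 um; defocus
  # drifts the apparent centroid)
  tol <- 1.5 / px
  groups <- rep(NA_integer_, nrow(f))
  g <- 0
  for (r in order(-f$area_um2)) {
    if (!is.na(groups[r])) next
    g <- g + 1
    d <- sqrt((f$i - f$i[r])^2 + (f$j - f$j[r])^2)
    groups[is.na(groups) & d <= tol] <- g
  }
  out <- do.call(rbind, lapply(seq_len(g), function(gr) {
    fr <- f[groups == gr, , drop = FALSE]
    data.frame(i = stats::median(fr$i), j = stats::median(fr$j),
               area_um2 = max(fr$area_um2), n_planes = nrow(fr),
               first_plane = min(fr$plane))
  }))
  # a real absorber persists across a large part of the series; defocus
  # caustics appear only in a few extreme planes
  min_planes <- min(max(2, ceiling(0.4 * length(series$planes))),
                    length(series$planes))
  out[out$n_planes >= min_planes, , drop = FALSE]
}

# Refine a candidate centroid by darkness weighting on the minimum
# projection of the series (the absorber is dark in every plane near its
# focus; defocus drift averages out in the projection).
refine_centroid <- function(series, ci, cj, params) {
  px <- params$pixel
  rad <- 0.9
  w <- ceiling(rad / px)
  n <- dim(series$planes[[1]]$values)
  ii <- max(1, round(ci) - w):min(n[1], round(ci) + w)
  jj <- max(1, round(cj) - w):min(n[2], round(cj) + w)
  mp <- Reduce(pmin, lapply(series$planes, function(pl)
    field_amplitude(pl)[ii, jj, drop = FALSE]))
  d <- sqrt(outer((ii - ci)^2, (jj - cj)^2, "+")) * px
  wt <- pmax(stats::quantile(mp, 0.9) - mp, 0)
  wt[d > rad] <- 0
  if (sum(wt) <= 0) return(c(ci, cj))
  c(sum(row(mp) * wt) / sum(wt) + ii[1] - 1,
    sum(col(mp) * wt) / sum(wt) + jj[1] - 1)
}

# Apparent perimeter of the candidate object on every plane of the series.
# Contour-pixel counts on coherent amplitude patches are dominated by
# defocus ringing, so the perimeter is measured as the area-equivalent
# circle perimeter 2 sqrt(pi A) of the candidate's dark footprint: soft
# (sub-pixel) coverage below a threshold that is held fixed across the
# whole series, restricted to the expected parasite neighbourhood, with
# the perimeter-vs-z curve lightly smoothed. Defocus blur shallows the
# object, so the apparent perimeter peaks at focus.
candidate_perimeter_curve <- function(series, ci, cj, params) {
  px <- params$pixel
  rad <- 0.5 * params$min_parasite_diameter
  w <- ceiling(rad / px)
  n <- dim(series$planes[[1]]$values)
  ii <- max(1, round(ci) - w):min(n[1], round(ci) + w)
  jj <- max(1, round(cj) - w):min(n[2], round(cj) + w)
  d <- sqrt(outer((ii - ci)^2, (jj - cj)^2, "+")) * px
  sel <- d <= rad
  pats <- lapply(series$planes, function(pl)
    field_amplitude(pl)[ii, jj, drop = FALSE][sel])
  lo <- min(vapply(pats, min, numeric(1)))
  hi <- stats::median(vapply(pats, function(p) stats::quantile(p, 0.9),
                             numeric(1)))
  th <- lo + 0.7 * (hi - lo)
  if (th <= lo) return(rep(0, length(pats)))
  area <- vapply(pats, function(pa)
    sum(pmin(pmax((th - pa) / (th - lo), 0), 1)), numeric(1))
  if (length(area) >= 3) {
    # the outermost planes support the smoothing only; selection is
    # restricted to interior planes, which the series is built to cover
    area <- stats::filter(area, c(0.25, 0.5, 0.25))
    area[is.na(area)] <- 0
  }
  2 * sqrt(pi * area) * px
}

#' Select the focal plane of a candidate parasite (air variant)
#'
#' Picks the plane whose apparent object perimeter is closest to the
#' perimeter of a typical ring-stage parasite (4 um); ties go to the plane
#' nearest the membrane plane. See [candidate_perimeter_curve()] internals
#' for how the perimeter is measured on coherent amplitudes.
#'
#' @param candidate One row of [detect_candidate_parasites()] output.
#' @param series A [focal_series()].
#' @param params [segmentation_params()].
#' @param membrane_plane Index of the plane where membranes are sharpest.
#' @return Plane index.
#' @export
select_plane_air <- function(candidate, series, params, membrane_plane = 1) {
  per <- candidate_perimeter_curve(series, candidate$i, candidate$j, params)
  score <- abs(per - params$target_parasite_perimeter)
  best <- which(score <= min(score) + 1e-12)
  best[which.min(abs(best - membrane_plane))]
}

#' Select the focal plane of a candidate parasite (oil variant)
#'
#' Picks the plane maximising the Michelson contrast of the candidate
#' against its intracellular surround; ties go to the plane nearest the
#' membrane plane.
#'
#' @inheritParams select_plane_air
#' @return Plane index.
#' @export
select_plane_oil <- function(candidate, series, params, membrane_plane = 1) {
  px <- params$pixel
  contrast <- vapply(series$planes, function(pl) {
    amp <- field_amplitude(pl)
    n <- dim(amp)
    ii <- max(1, round(candidate$i - 2.5 / px)):min(n[1], round(candidate$i + 2.5 / px))
    jj <- max(1, round(candidate$j - 2.5 / px)):min(n[2], round(candidate$j + 2.5 / px))
    patch <- amp[ii, jj, drop = FALSE]
    d <- sqrt(outer((ii - candidate$i)^2, (jj - candidate$j)^2, "+")) * px
    inner <- patch[d <= 0.8]
    surround <- patch[d > 1.2 & d <= 2.4]
    if (length(inner) == 0 || length(surround) == 0) return(0)
    lo <- stats::quantile(inner, 0.05)
    hi <- stats::median(surround)
    (hi - lo) / (hi + lo)
  }, numeric(1))
  best <- which(contrast >= max(contrast) - 1e-12)
  best[which.min(abs(best - membrane_plane))]
}

#' Consistency check on assigned focal planes
#'
#' Candidates assigned a plane farther than half the sample thickness from
#' the robust centre of the film are reset to the centre plane and
#' flagged; debris and staining artefacts otherwise pull single cells far
#' outside the film. The centre defaults to the median of all assignments;
#' the pipeline anchors it at the membrane plane, since parasites lie
#' within the film around the cell membranes and a median over few
#' assignments is easily skewed.
#'
#' @param plane_idx Integer vector of assigned plane indices.
#' @param series A [focal_series()] (provides the z of each plane).
#' @param sample_thickness Film thickness (um).
#' @param center Optional film centre (um, z coordinate); default the
#'   median of the assigned z values.
#' @return List with `plane_idx` (corrected) and `flagged` (logical).
#' @export
consistency_check <- function(plane_idx, series, sample_thickness = 3,
                              center = NULL) {
  if (length(plane_idx) == 0)
    return(list(plane_idx = plane_idx, flagged = logical(0)))
  z <- series$z[plane_idx]
  if (is.null(center)) center <- stats::median(z)
  ctr_idx <- which.min(abs(series$z - center))
  out <- abs(z - center) > sample_thickness / 2
  plane_idx[out] <- ctr_idx
  list(plane_idx = plane_idx, flagged = out)
}

#' Compose an extended depth-of-field image
#'
#' Base image is the plane where membranes are sharpest (by
#' [sharpness_rank()]); the intracellular region of each cell with a chosen
#' plane is replaced by that plane, with a 1-px feathered boundary. The
#' per-pixel plane index is recorded.
#'
#' @param series A [focal_series()].
#' @param labels Integer label matrix of the cell mask.
#' @param cell_planes Named integer vector: chosen plane index per cell
#'   label (cells without an entry stay at the base plane).
#' @param params [segmentation_params()].
#' @param base_plane Plane index of the membrane-focus base image;
#'   defaults to the coherent-film focus rank (gradient-energy minimum).
#' @return List of class `edof_image`: `composite` (amplitude matrix),
#'   `plane_map` (integer matrix), `base_plane`.
#' @export
compose_edof <- function(series, labels, cell_planes, params,
                         base_plane = NULL) {
  base_idx <- if (is.null(base_plane)) membrane_plane_rank(series)
              else base_plane
  composite <- field_amplitude(series$planes[[base_idx]])
  plane_map <- matrix(base_idx, nrow(composite), ncol(composite))
  band_px <- 2 * floor(params$membrane_band / params$pixel / 2) + 3
  for (lab in names(cell_planes)) {
    p <- cell_planes[[lab]]
    if (p == base_idx) next
    fp <- labels == as.integer(lab)
    interior <- EBImage::erode(fp * 1, EBImage::makeBrush(band_px, "disc")) > 0
    if (!any(interior)) next
    core <- EBImage::erode(interior * 1, EBImage::makeBrush(3, "box")) > 0
    feather <- interior & !core
    sel <- field_amplitude(series$planes[[p]])
    composite[core] <- sel[core]
    composite[feather] <- 0.5 * (composite[feather] + sel[feather])
    plane_map[core] <- p
  }
  structure(list(composite = composite, plane_map = plane_map,
                 base_plane = base_idx),
            class = "edof_image")
}

#' Full EDoF rendering pipeline
#'
#' Runs the complete pipeline on a focal series: per-plane raw RBC masks
#' are unioned across planes and cleaned, cells are labelled, candidate
#' parasites are detected and assigned focal planes (air: perimeter match;
#' oil: contrast maximisation), assignments pass the consistency check, and
#' the composite is rendered.
#'
#' @param series A [focal_series()].
#' @param params [segmentation_params()]; defaults from the series pixel
#'   pitch.
#' @param variant `"air"` or `"oil"`.
#' @param mask_planes `"union"` (default: raw masks from every plane are
#'   unioned before cleaning) or `"base"` (mask from the sharpest plane
#'   only).
#' @return List of class `edof_result`: `edof` ([compose_edof()] output),
#'   `mask`, `labels`, `cells` (data frame with assigned planes), and
#'   `candidates` (data frame: cell, centroid, plane index, z, flagged).
#' @export
run_edof_pipeline <- function(series, params = NULL,
                              variant = c("air", "oil"),
                              mask_planes = c("union", "base")) {
  stopifnot(inherits(series, "focal_series"))
  variant <- match.arg(variant)
  mask_planes <- match.arg(mask_planes)
  px <- series$planes[[1]]$pixel
  if (is.null(params)) params <- segmentation_params(px)

  membrane_plane <- membrane_plane_rank(series)
  plane_set <- if (mask_planes == "union") seq_along(series$planes)
               else membrane_plane
  raw <- NULL
  for (p in plane_set) {
    amp <- field_amplitude(series$planes[[p]])
    if (variant == "air") {
      ph <- unwrap_phase(series$planes[[p]])
      r <- raw_mask_air(amp, ph, params)
    } else {
      r <- raw_mask_oil(amp, field_phase(series$planes[[p]]), params)
    }
    raw <- if (is.null(raw)) r else raw | r
  }
  mask <- clean_mask(raw, params)
  lc <- label_cells(mask, params)

  cand_all <- list()
  cell_planes <- integer(0)
  for (ci in seq_len(nrow(lc$cells))) {
    lab <- lc$cells$label[ci]
    fp <- lc$labels == lab
    cand <- detect_candidate_parasites(series, fp, params)
    if (nrow(cand) == 0) next
    for (r in seq_len(nrow(cand))) {
      rc <- refine_centroid(series, cand$i[r], cand$j[r], params)
      cand$i[r] <- rc[1]; cand$j[r] <- rc[2]
    }
    cand$cell <- lab
    cand$plane <- vapply(seq_len(nrow(cand)), function(r) {
      if (variant == "air")
        select_plane_air(cand[r, ], series, params, membrane_plane)
      else select_plane_oil(cand[r, ], series, params, membrane_plane)
    }, integer(1))
    cand_all[[length(cand_all) + 1]] <- cand
  }
  if (length(cand_all) > 0) {
    cand <- do.call(rbind, cand_all)
    cc <- consistency_check(cand$plane, series, params$sample_thickness,
                            center = series$z[membrane_plane])
    cand$plane <- cc$plane_idx
    cand$flagged <- cc$flagged
    cand$z <- series$z[cand$plane]
    cell_planes <- vapply(split(cand$plane, cand$cell), function(p)
      as.integer(round(stats::median(p))), integer(1))
  } else {
    cand <- data.frame(i = numeric(), j = numeric(), area_um2 = numeric(),
                       n_planes = integer(), first_plane = integer(),
                       cell = integer(), plane = integer(),
                       flagged = logical(), z = numeric())
  }

  edof <- compose_edof(series, lc$labels, cell_planes, params,
                       base_plane = membrane_plane)
  cells <- lc$cells
  cells$plane <- rep(edof$base_plane, nrow(cells))
  if (length(cell_planes) > 0) {
    m <- match(names(cell_planes), as.character(cells$label))
    cells$plane[m] <- cell_planes
  }
  structure(list(edof = edof, mask = mask, labels = lc$labels,
                 cells = cells, candidates = cand, params = params,
                 variant = variant),
            class = "edof_result")
}
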