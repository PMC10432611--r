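#' Thorax extraction from raw chest CT
#'
#' The preprocessing pipeline converts a raw Hounsfield-unit chest CT
#' volume into the fixed-shape, \[0, 255\]-scaled thorax tensor the
#' networks consume: per-slice Gaussian smoothing and -600 HU
#' binarisation (lung parenchyma is hypodense), 2D component filtering by
#' area and eccentricity, 3D component selection by physical volume
#' (0.68-7.5 L) and distance to the scan centre, morphological lung
#' separation with per-slice convex hulls, a joint convex hull that pulls
#' the cardiac/mediastinal region into the thorax mask, HU clipping to
#' \[-1200, 600\] with linear rescaling to \[0, 255\] and a fill value of
#' 170 outside the mask, and resampling to the target grid.
#'
#' @name ct-preprocess
NULL

binary_mask <- function(voxels, label = "candidate") {
  structure(list(voxels = voxels, label = label), class = "binary_mask")
}

stop_empty_lung <- function(msg, diagnostics = NULL) {
  stop(structure(class = c("longisurv_empty_lung", "error", "condition"),
                 list(message = msg, call = sys.call(-1),
                      diagnostics = diagnostics)))
}

#' Smooth axial slices and binarise at an HU threshold
#'
#' @param volume a `ct_volume`.
#' @param sigma Gaussian sd in voxels, applied per axial slice; 0 = none.
#' @param threshold HU cutoff; voxels *below* the threshold become
#'   foreground (hypodense lung).
#' @return a `binary_mask`.
#' @export
smooth_and_binarize <- function(volume, sigma = 1, threshold = -600) {
  v <- volume$voxels
  if (length(dim(v)) != 3 || any(dim(v)[1:2] < 2))
    stop_invalid("need a 3D volume with non-degenerate slices")
  if (sigma < 0) stop_invalid("sigma must be >= 0")
  sm <- cpp_gauss_smooth2d(v, sigma)
  binary_mask(array(sm < threshold, dim = dim(v)), "candidate")
}

component_eccentricity <- function(xy) {
  if (nrow(xy) < 2) return(0)
  cv <- stats::cov(xy)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(0)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

#' Filter 2D connected components by area and eccentricity
#'
#' Removes, per axial slice, components smaller than `min_area` voxels or
#' with fitted-ellipse eccentricity above `max_eccentricity` (elongated
#' streaks are imaging noise, not parenchyma).
#'
#' @param mask a `binary_mask`.
#' @param min_area minimum component area in voxels.
#' @param max_eccentricity eccentricity cutoff in \[0, 1).
#' @return filtered `binary_mask`.
#' @export
filter_components_2d <- function(mask, min_area = 30,
                                 max_eccentricity = 0.99) {
  v <- mask$voxels
  out <- array(FALSE, dim = dim(v))
  for (z in seq_len(dim(v)[3])) {
    sl <- v[, , z]
    if (!any(sl)) next
    lab <- cpp_label2d(sl)
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k, arr.ind = TRUE)
      if (nrow(idx) < min_area) next
      if (component_eccentricity(idx) > max_eccentricity) next
      out[, , z][lab == k] <- TRUE
    }
  }
  binary_mask(out, mask$label)
}

#' Select lung-candidate 3D components by volume and centrality
#'
#' 3D connected components of the binarised stack are kept when their
#' physical volume lies in `volume_range` (litres) and their centroid is
#' within `max_center_distance` of the in-plane half-diagonal from the
#' scan centre.
#'
#' @param mask a `binary_mask`.
#' @param spacing per-axis voxel size in mm.
#' @param volume_range litres, default `c(0.68, 7.5)`.
#' @param max_center_distance fraction of the in-plane half-diagonal.
#' @return joint candidate-lung `binary_mask`; errors with per-component
#'   diagnostics when nothing survives.
#' @export
select_lung_candidates <- function(mask, spacing,
                                   volume_range = c(0.68, 7.5),
                                   max_center_distance = 0.62) {
  v <- mask$voxels
  d <- dim(v)
  lab <- cpp_label3d(v)
  ncomp <- max(lab)
  if (ncomp == 0) stop_empty_lung("no foreground components")
  voxel_l <- prod(spacing) / 1e6
  centre <- (d[1:2] - 1) / 2 * spacing[1:2]
  half_diag <- sqrt(sum((d[1:2] * spacing[1:2])^2)) / 2
  keep <- logical(ncomp)
  diag_rows <- vector("list", ncomp)
  for (k in seq_len(ncomp)) {
    idx <- which(lab == k, arr.ind = TRUE)
    vol_l <- nrow(idx) * voxel_l
    cen <- colMeans(idx[, 1:2, drop = FALSE] - 1) * spacing[1:2]
    dist_frac <- sqrt(sum((cen - centre)^2)) / half_diag
    keep[k] <- vol_l >= volume_range[1] && vol_l <= volume_range[2] &&
      dist_frac <= max_center_distance
    diag_rows[[k]] <- data.frame(component = k, volume_l = vol_l,
                                 center_distance_frac = dist_frac,
                                 kept = keep[k])
  }
  if (!any(keep))
    stop_empty_lung("no component passes the volume/centrality filter",
                    diagnostics = do.call(rbind, diag_rows))
  out <- array(lab %in% which(keep), dim = d)
  binary_mask(out, "joint")
}

fill_hull_slice <- function(sl) {
  idx <- which(sl, arr.ind = TRUE)
  if (nrow(idx) < 3) return(sl)
  h <- grDevices::chull(idx)
  if (length(h) < 3) return(sl)
  bnd <- idx[h, , drop = FALSE]
  cand <- which(!sl, arr.ind = TRUE)
  rng <- apply(bnd, 2, range)
  inside_bb <- cand[, 1] >= rng[1, 1] & cand[, 1] <= rng[2, 1] &
               cand[, 2] >= rng[1, 2] & cand[, 2] <= rng[2, 2]
  cand <- cand[inside_bb, , drop = FALSE]
  if (nrow(cand)) {
    # exact convex test: a point is in the hull iff it lies on the inner
    # side of every edge (tolerance keeps voxels exactly on an edge)
    x <- bnd[, 1]; y <- bnd[, 2]
    nv <- length(x)
    nxt <- c(2:nv, 1)
    if (sum(x * y[nxt] - x[nxt] * y) < 0) {   # ensure counter-clockwise
      bnd <- bnd[nv:1, , drop = FALSE]
      x <- bnd[, 1]; y <- bnd[, 2]
    }
    inside <- rep(TRUE, nrow(cand))
    for (i in seq_len(nv)) {
      j <- if (i == nv) 1 else i + 1
      cr <- (x[j] - x[i]) * (cand[, 2] - y[i]) -
            (y[j] - y[i]) * (cand[, 1] - x[i])
      inside <- inside & (cr >= -1e-9)
    }
    sl[cand[inside, , drop = FALSE]] <- TRUE
  }
  sl
}

hull_per_slice <- function(v) {
  for (z in seq_len(dim(v)[3])) v[, , z] <- fill_hull_slice(v[, , z])
  v
}

#' Separate a joint lung mask into left and right lungs
#'
#' Erosion disconnects lungs bridged at the anterior junction; the two
#' largest components are kept, convex-hulled per axial slice, and
#' dilated back. Left/right assignment is by centroid along the first
#' (left-right) axis.
#'
#' @param joint joint `binary_mask`.
#' @param erosion_radius,dilation_radius ball radii in voxels.
#' @return list `left`, `right` (`binary_mask`), `degenerate` (TRUE when
#'   erosion could not split the mask, in which case both entries are the
#'   whole mask).
#' @export
split_lungs <- function(joint, erosion_radius = 3, dilation_radius = 3) {
  v <- joint$voxels
  if (!any(v)) stop_empty_lung("empty joint mask")
  er <- cpp_morph3d(v, erosion_radius, dilate = FALSE)
  lab <- cpp_label3d(er)
  if (max(lab) < 2) {
    warning("single-lung mask: erosion found fewer than two components")
    return(list(left = binary_mask(v, "left_lung"),
                right = binary_mask(v, "right_lung"), degenerate = TRUE))
  }
  sizes <- tabulate(lab[lab > 0])
  top2 <- order(sizes, decreasing = TRUE)[1:2]
  parts <- lapply(top2, function(k) {
    m <- array(lab == k, dim = dim(v))
    m <- hull_per_slice(m)
    array(cpp_morph3d(m, dilation_radius, dilate = TRUE), dim = dim(v))
  })
  # dilating back cannot restore opening losses (thin polar caps); assign
  # every remaining joint-mask voxel to the nearer component so no lung
  # voxel is discarded by the split
  left_over <- which(v & !(parts[[1]] | parts[[2]]), arr.ind = TRUE)
  if (nrow(left_over)) {
    cen <- lapply(top2, function(k)
      colMeans(which(array(lab == k, dim = dim(v)), arr.ind = TRUE)))
    d1 <- rowSums((left_over - rep(cen[[1]], each = nrow(left_over)))^2)
    d2 <- rowSums((left_over - rep(cen[[2]], each = nrow(left_over)))^2)
    parts[[1]][left_over[d1 <= d2, , drop = FALSE]] <- TRUE
    parts[[2]][left_over[d1 > d2, , drop = FALSE]] <- TRUE
  }
  cx <- vapply(parts, function(m) mean(which(m, arr.ind = TRUE)[, 1]),
               numeric(1))
  ord <- order(cx)
  list(left = binary_mask(parts[[ord[1]]], "left_lung"),
       right = binary_mask(parts[[ord[2]]], "right_lung"),
       degenerate = FALSE)
}

#' Build the thorax mask from the two lung masks
#'
#' Takes the per-axial-slice convex hull of the union of the lung masks;
#' on slices where the lungs are separated this fills the mediastinal gap
#' and therefore includes the cardiac region.
#'
#' @param left,right `binary_mask` objects on the same grid.
#' @return thorax `binary_mask` (always a superset of the union).
#' @export
build_thorax_mask <- function(left, right) {
  if (!identical(dim(left$voxels), dim(right$voxels)))
    stop_invalid("mask grids differ")
  u <- left$voxels | right$voxels
  if (!any(u)) stop_empty_lung("both lung masks are empty")
  binary_mask(hull_per_slice(u), "thorax")
}

#' Clip, rescale and mask-fill a CT volume
#'
#' Inside the thorax mask HU values are clamped to
#' `[clip_low, clip_high]` and mapped linearly to \[0, 255\]; outside the
#' mask every voxel is set to `fill`.
#'
#' @param volume a `ct_volume`.
#' @param thorax thorax `binary_mask` (same grid).
#' @param clip_low,clip_high HU clipping interval, default -1200 / 600.
#' @param fill output-scale fill value, default 170 (the average
#'   soft-tissue value on the rescaled scale).
#' @return a `thorax_volume`: list with `voxels` in \[0, 255\], `mask`,
#'   `fill`.
#' @export
normalize_hu <- function(volume, thorax, clip_low = -1200, clip_high = 600,
                         fill = 170) {
  if (clip_low >= clip_high) stop_invalid("clip_low must be < clip_high")
  v <- volume$voxels
  if (!identical(dim(v), dim(thorax$voxels)))
    stop_invalid("mask/volume shape mismatch")
  out <- (pmin(pmax(v, clip_low), clip_high) - clip_low) /
    (clip_high - clip_low) * 255
  out[!thorax$voxels] <- fill
  structure(list(voxels = out, mask = thorax$voxels, fill = fill),
            class = "thorax_volume")
}

#' Resample a 3D grid to a target shape
#'
#' Corner voxel centres are aligned. Trilinear interpolation (order 1)
#' for intensities, nearest neighbour (order 0) for masks.
#'
#' @param volume 3D numeric array (or `ct_volume`/`thorax_volume`).
#' @param target_shape 3 positive integers.
#' @param order 0 or 1.
#' @return 3D array of shape `target_shape`.
#' @export
resample <- function(volume, target_shape, order = 1) {
  if (any(target_shape <= 0)) stop_invalid("target shape must be positive")
  v <- if (is.list(volume)) volume$voxels else volume
  storage.mode(v) <- "double"
  cpp_resample3d(v, as.integer(target_shape), as.integer(order))
}

#' Default preprocessing configuration
#'
#' All pipeline cutoffs in one place. The component-filter values
#' (min area 30, eccentricity 0.99, centre-distance 62% of the in-plane
#' half-diagonal) are configurable stand-ins for unpublished upstream
#' choices; the physical constants (threshold -600 HU, volume window
#' 0.68-7.5 L, clip -1200/600 HU, fill 170) are the documented pipeline.
#'
#' @param ... overrides of any default field.
#' @export
preprocess_config <- function(...) {
  cfg <- list(sigma_mm = 1, sigma = NULL, threshold = -600, min_area = 30,
              max_eccentricity = 0.99, volume_range = c(0.68, 7.5),
              max_center_distance = 0.62, erosion_radius = 3,
              dilation_radius = 3, clip_low = -1200, clip_high = 600,
              fill = 170, target_shape = c(256, 256, 128),
              register_to_last = FALSE)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full thorax-extraction pipeline on one scan
#'
#' @param volume a `ct_volume` in raw HU.
#' @param config a [preprocess_config()].
#' @return a `thorax_volume` at `config$target_shape`, carrying the
#'   resampled mask and `acquisition_day`.
#' @export
preprocess_scan <- function(volume, config = preprocess_config()) {
  # the smoothing scale is physical (mm) by default: 1 voxel on the ~1 mm
  # grids the upstream pipeline was designed for, a fraction of a voxel on
  # coarse desk-scale grids (a fixed 1-voxel sigma over-smooths those and
  # erodes the segmented lung boundary); set config$sigma to force voxels
  sigma <- config$sigma %||%
    (config$sigma_mm / mean(volume$spacing[1:2]))
  m <- smooth_and_binarize(volume, sigma, config$threshold)
  m <- filter_components_2d(m, config$min_area, config$max_eccentricity)
  joint <- select_lung_candidates(m, volume$spacing, config$volume_range,
                                  config$max_center_distance)
  lr <- split_lungs(joint, config$erosion_radius, config$dilation_radius)
  thorax <- build_thorax_mask(lr$left, lr$right)
  tv <- normalize_hu(volume, thorax, config$clip_low, config$clip_high,
                     config$fill)
  vox <- resample(tv$voxels, config$target_shape, order = 1)
  msk <- resample(tv$mask + 0, config$target_shape, order = 0) > 0.5
  vox[!msk] <- config$fill
  structure(list(voxels = vox, mask = msk, fill = config$fill,
                 acquisition_day = volume$acquisition_day),
            class = "thorax_volume")
}

#' Preprocess a longitudinal scan series
#'
#' Runs [preprocess_scan()] on every scan (optionally first registering
#' the earlier raw scans to the latest one), computes the inter-scan gaps,
#' and stacks the results oldest-first.
#'
#' @param scans list of `ct_volume` with strictly increasing
#'   `acquisition_day`.
#' @param config a [preprocess_config()].
#' @return a `longitudinal_series`: list with `volumes` (list of
#'   `thorax_volume`), `gaps` (from [encode_gaps()]), `days`.
#' @export
preprocess_series <- function(scans, config = preprocess_config()) {
  if (length(scans) < 1) stop_invalid("need at least one scan")
  days <- vapply(scans, function(s) s$acquisition_day, numeric(1))
  if (any(diff(days) <= 0))
    stop_invalid("acquisition days must be strictly increasing")
  n <- length(scans)
  if (isTRUE(config$register_to_last) && n > 1) {
    fixed <- scans[[n]]
    for (k in seq_len(n - 1)) {
      reg <- tryCatch(register_affine(scans[[k]], fixed),
                      error = function(e) NULL)
      if (!is.null(reg)) {
        reg$registered$acquisition_day <- scans[[k]]$acquisition_day
        scans[[k]] <- reg$registered
      }
    }
  }
  volumes <- vector("list", n)
  for (k in seq_len(n)) {
    volumes[[k]] <- tryCatch(preprocess_scan(scans[[k]], config),
      error = function(e) {
        stop_invalid("scan ", k, " (day ", days[k],
                     ") failed preprocessing: ", conditionMessage(e))
      })
  }
  structure(list(volumes = volumes, gaps = encode_gaps(days), days = days),
            class = "longitudinal_series")
}
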