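#' Synthetic longitudinal thorax phantoms with Cox-linked outcomes
#'
#' Generates thorax-like CT volumes (air background, soft-tissue body
#' ellipsoid, two hypodense lung ellipsoids, a cardiac ellipsoid in the
#' mediastinum) with planted progressive pathology, annual acquisition
#' schedules with realistic interval jitter, and right-censored survival
#' outcomes drawn from the proportional-hazards model the Cox head
#' assumes. Every other module is testable end-to-end against this
#' generator's analytically known ground truth.
#'
#' @name synthetic-phantoms
NULL

#' Construct a CT volume object
#'
#' @param voxels 3D array of Hounsfield-unit values, indexed (x, y, z)
#'   with z the axial slice axis.
#' @param spacing positive per-axis voxel size in mm.
#' @param acquisition_day integer days since the subject's baseline scan.
#' @return list of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), acquisition_day = 0L) {
  if (length(dim(voxels)) != 3 || any(dim(voxels) < 1))
    stop_invalid("voxels must be a 3D array")
  if (any(!is.finite(voxels))) stop_invalid("voxel values must be finite")
  if (any(spacing <= 0)) stop_invalid("spacing must be strictly positive")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 acquisition_day = as.integer(acquisition_day),
                 slice_axis = "z"),
            class = "ct_volume")
}

#' Specification of a thorax phantom
#'
#' Geometry is expressed as fractions of the grid, so the same anatomy
#' renders at any resolution; the physical field of view is fixed at
#' 384 x 384 x 320 mm (so voxel spacing scales inversely with the grid),
#' which keeps each lung at roughly 1.6 L for any grid shape.
#'
#' @param shape grid shape, default `c(64, 64, 32)`; tests use
#'   `c(32, 32, 16)`.
#' @param hu list of region means in HU (defaults: air -1000, body 40,
#'   lung -850, cardiac 30).
#' @param noise_sd additive Gaussian noise, default 25 HU (typical
#'   low-dose CT noise).
#' @param fov physical field of view in mm.
#' @return list of class `phantom_spec`, including the fractional
#'   ellipsoid geometry (centres/semi-axes for body, lungs, heart).
#' @export
thorax_phantom_spec <- function(shape = c(64, 64, 32),
                                hu = list(air = -1000, body = 40,
                                          lung = -850, cardiac = 30),
                                noise_sd = 25,
                                fov = c(384, 384, 320)) {
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  stopifnot(all(shape >= 8))
  geom <- list(
    body = list(c = c(0.50, 0.50, 0.50), s = c(0.41, 0.32, 0.48)),
    lung_left = list(c = c(0.30, 0.50, 0.50), s = c(0.125, 0.19, 0.34)),
    lung_right = list(c = c(0.70, 0.50, 0.50), s = c(0.125, 0.19, 0.34)),
    cardiac = list(c = c(0.50, 0.53, 0.44), s = c(0.078, 0.094, 0.19)))
  structure(list(shape = as.integer(shape), hu = hu, noise_sd = noise_sd,
                 spacing = fov / shape, geom = geom),
            class = "phantom_spec")
}

ellipsoid_mask <- function(shape, centre_frac, semi_frac) {
  cx <- centre_frac * (shape - 1)
  sx <- semi_frac * shape
  x <- ((seq_len(shape[1]) - 1 - cx[1]) / sx[1])^2
  y <- ((seq_len(shape[2]) - 1 - cx[2]) / sx[2])^2
  z <- ((seq_len(shape[3]) - 1 - cx[3]) / sx[3])^2
  outer(outer(x, y, `+`), z, `+`) <= 1
}

#' Ground-truth region masks of a phantom spec
#'
#' @param spec a `phantom_spec`.
#' @return list of logical arrays: `body`, `lung_left`, `lung_right`,
#'   `lungs`, `cardiac`.
#' @export
phantom_truth_masks <- function(spec) {
  g <- spec$geom
  m <- lapply(g, function(e) ellipsoid_mask(spec$shape, e$c, e$s))
  m$lungs <- m$lung_left | m$lung_right
  m
}

#' Render one thorax phantom volume
#'
#' Regions are painted in order background, body, lungs, cardiac; lesions
#' proportional to `burden` are added for non-zero `lesion`: `"cardiac"`
#' plants hyperdense foci (+500 HU, a calcification proxy) inside the
#' cardiac ellipsoid, `"respiratory"` raises the lung parenchyma
#' attenuation diffusely by up to 200 HU (a fibrosis/COPD proxy, capped so
#' the lungs stay below the -600 HU segmentation threshold).
#'
#' @param spec a `phantom_spec`.
#' @param seed integer seed; the same seed renders an identical volume.
#' @param burden lesion burden in \[0, 1\].
#' @param lesion `"none"`, `"cardiac"` or `"respiratory"`.
#' @param acquisition_day stored on the returned volume.
#' @param hu_offset global HU offset (site/scanner calibration shift).
#' @param noise_scale multiplier on the spec's noise sd.
#' @return a `ct_volume`.
#' @export
make_thorax_phantom <- function(spec, seed = 1, burden = 0,
                                lesion = c("none", "cardiac", "respiratory"),
                                acquisition_day = 0L, hu_offset = 0,
                                noise_scale = 1) {
  lesion <- match.arg(lesion)
  if (burden < 0 || burden > 1) stop_invalid("burden must lie in [0, 1]")
  m <- phantom_truth_masks(spec)
  if (sum(m$cardiac & m$lungs) > 0.01 * sum(m$cardiac))
    stop_invalid("phantom spec error: cardiac and lung ellipsoids overlap")
  v <- array(spec$hu$air, dim = spec$shape)
  v[m$body] <- spec$hu$body
  v[m$lungs] <- spec$hu$lung
  v[m$cardiac] <- spec$hu$cardiac
  set.seed(seed)
  if (lesion == "respiratory" && burden > 0) {
    v[m$lungs] <- v[m$lungs] + 200 * burden
  } else if (lesion == "cardiac" && burden > 0) {
    # deterministic (per-seed) candidate foci; burden controls how many
    idx <- which(m$cardiac)
    n_foci <- ceiling(12 * burden)
    centres <- sample(idx, min(n_foci, length(idx)))
    coord <- arrayInd(centres, spec$shape)
    for (k in seq_len(nrow(coord))) {
      rng <- lapply(1:3, function(a)
        pmax(1, coord[k, a] - 1):pmin(spec$shape[a], coord[k, a] + 1))
      v[rng[[1]], rng[[2]], rng[[3]]] <- spec$hu$cardiac + 500
    }
  }
  if (spec$noise_sd * noise_scale > 0)
    v <- v + array(rnorm(length(v), 0, spec$noise_sd * noise_scale),
                   dim = spec$shape)
  ct_volume(v + hu_offset, spacing = spec$spacing,
            acquisition_day = acquisition_day)
}

#' Render a longitudinal phantom series with progressive pathology
#'
#' Burden grows linearly with elapsed time,
#' \eqn{b_k = b_0 + \mathrm{rate} \cdot \mathrm{years}_k}, clipped to
#' \[0, 1\] with a warning; each timepoint is rendered with its burden.
#'
#' @param spec a `phantom_spec`.
#' @param days acquisition days (strictly increasing, first = baseline).
#' @param b0 baseline burden.
#' @param rate burden growth per year (>= 0).
#' @param kind lesion kind, as in [make_thorax_phantom()].
#' @param seed subject seed; timepoint k uses `seed + k` for its noise
#'   but shares the lesion layout seed so pathology grows in place.
#' @param hu_offset,noise_scale site-level acquisition shift.
#' @return list with `scans` (list of `ct_volume`) and `burden` (the true
#'   per-timepoint burden trajectory).
#' @export
plant_progression <- function(spec, days, b0, rate,
                              kind = c("none", "cardiac", "respiratory"),
                              seed = 1, hu_offset = 0, noise_scale = 1) {
  kind <- match.arg(kind)
  if (rate < 0) stop_invalid("progression rate must be >= 0")
  if (any(diff(days) <= 0)) stop_invalid("days must be strictly increasing")
  years <- (days - days[1]) / 365
  burden <- b0 + rate * years
  if (any(burden > 1)) {
    warning("burden clipped at anatomical capacity (1.0)")
    burden <- pmin(burden, 1)
  }
  scans <- vector("list", length(days))
  for (k in seq_along(days)) {
    # lesion layout comes from the shared subject seed; per-timepoint
    # noise decorrelates via a post-hoc reseed inside make_thorax_phantom
    scans[[k]] <- make_thorax_phantom(spec, seed = seed, burden = burden[k],
                                      lesion = kind,
                                      acquisition_day = days[k],
                                      hu_offset = hu_offset,
                                      noise_scale = 0)
    if (spec$noise_sd * noise_scale > 0) {
      set.seed(seed + 7919 * k)
      scans[[k]]$voxels <- scans[[k]]$voxels +
        array(rnorm(prod(spec$shape), 0, spec$noise_sd * noise_scale),
              dim = spec$shape)
    }
  }
  list(scans = scans, burden = burden)
}

#' Draw one right-censored survival record from the Cox model
#'
#' Event times are exponential with rate
#' \eqn{\lambda_0 e^{\beta x}} (a proportional-hazards model with a
#' constant baseline hazard); administrative censoring is applied at
#' `censor_day`. This inverts exactly the model the Cox head assumes, so
#' partial-likelihood estimation on the true covariate must recover
#' \eqn{\beta}.
#'
#' @param x covariate (lesion burden at the last scan by default).
#' @param beta log-hazard coefficient.
#' @param lambda0 baseline hazard per day (> 0).
#' @param censor_day administrative censoring horizon in days from the
#'   last scan.
#' @param cause cause label to assign when the event occurs.
#' @return one-row `survival_records`.
#' @export
simulate_survival <- function(x, beta, lambda0, censor_day = 4015,
                              cause = "cardiac") {
  if (lambda0 <= 0) stop_invalid("lambda0 must be > 0")
  t_event <- rexp(length(x), rate = lambda0 * exp(beta * x))
  event <- as.integer(t_event <= censor_day)
  survival_records(time = pmin(t_event, censor_day), event = event,
                   cause = ifelse(event == 1, cause, "none"))
}

#' Generate a matched longitudinal phantom cohort
#'
#' Emulates the structure of a screening-trial cohort: three roughly
#' annual scans per subject with interval jitter (default jitter sd of 30
#' days gives a gap inter-quartile range near 40 days), a non-survivor to
#' survivor case-control ratio (default 1:2), two non-survivor phenotypes
#' (cardiac foci vs diffuse respiratory change), matching covariates, an
#' internal/external site partition in which external scans carry a
#' systematic HU offset and noise change, and right-censored survival
#' measured from the last scan.
#'
#' Risk can be encoded in the burden at the last scan (default: a single
#' scan suffices in principle) or in the burden *slope* across timepoints
#' with the last-scan burden distribution identical in both classes, in
#' which case only a model that uses the follow-up history can separate
#' the classes.
#'
#' @param n cohort size (>= 12).
#' @param ratio `c(1, 2)` for the 1:2 non-survivor:survivor design, or
#'   `NULL` for the natural (unmatched) outcome distribution.
#' @param risk_covariate `"last"` or `"slope"`.
#' @param beta log-hazard coefficient per population standard deviation
#'   of the risk covariate (the scale hazard ratios are reported on).
#'   Default 2: a strongly separable world, so end-to-end tests measure
#'   pipeline correctness, not task difficulty.
#' @param lambda0 baseline hazard per day at the population-mean
#'   covariate (default 2.3e-4).
#' @param censor_day administrative censoring, default 4015 days (~11 y).
#' @param external_frac fraction of subjects at "external" sites.
#' @param jitter_sd sd (days) of the annual-interval jitter.
#' @param shape phantom grid shape.
#' @param seed cohort seed; all randomness flows from it.
#' @return list of class `synthetic_cohort`: `subjects` (data.frame with
#'   subject_id, event, time_days, cause, site, split, covariates, true
#'   burdens/rate), `schedule` (per-subject acquisition days), `spec`
#'   (the `phantom_spec`), and generation parameters. Volumes are
#'   rendered lazily with [render_subject()].
#' @export
generate_cohort <- function(n, ratio = c(1, 2),
                            risk_covariate = c("last", "slope"),
                            beta = 2, lambda0 = 2.3e-4, censor_day = 4015,
                            external_frac = 0.15, jitter_sd = 30,
                            shape = c(64, 64, 32), seed = 1) {
  risk_covariate <- match.arg(risk_covariate)
  if (n < 12) stop_invalid("need n >= 12 subjects")
  if (!is.null(ratio) && (length(ratio) != 2 || any(ratio <= 0)))
    stop_invalid("ratio must be NULL or two positive numbers")
  set.seed(seed)
  spec <- thorax_phantom_spec(shape = shape)
  # population moments of the raw covariate, fixed by the subject model:
  # "last"  burden = U(0,0.35) + 2yr * U(0,0.3)   -> mean 0.475, sd 0.2005
  # "slope" normalised rate = U(0,1)              -> mean 0.5,   sd 0.2887
  cov_mu <- if (risk_covariate == "last") 0.475 else 0.5
  cov_sd <- if (risk_covariate == "last") 0.2005 else 0.2887

  draw_subject <- function() {
    if (risk_covariate == "last") {
      b0 <- runif(1, 0, 0.35)
      rate <- runif(1, 0, 0.3)
    } else {
      # equalise last-scan burden across classes; risk rides on the slope
      b_last <- runif(1, 0.35, 0.65)
      rate <- runif(1, 0, 0.15)
      b0 <- max(b_last - rate * 2, 0)
    }
    list(b0 = b0, rate = rate)
  }

  # oversample candidates, then fill the design quotas
  n_cases <- if (is.null(ratio)) NA else round(n * ratio[1] / sum(ratio))
  cand_max <- if (is.null(ratio)) n else 20 * n
  rows <- list(); sched <- list(); kept <- 0
  quota_case <- if (is.null(ratio)) Inf else n_cases
  quota_ctrl <- if (is.null(ratio)) Inf else n - n_cases
  for (cand in seq_len(cand_max)) {
    if (kept >= n) break
    s <- draw_subject()
    days <- round(c(0, 365, 730) + c(0, rnorm(2, 0, jitter_sd)))
    days <- cummax(days + seq_along(days) - 1)  # keep strictly increasing
    years <- (days - days[1]) / 365
    b_traj <- pmin(s$b0 + s$rate * years, 1)
    xraw <- if (risk_covariate == "last") b_traj[length(b_traj)]
            else s$rate / 0.15
    xcov <- (xraw - cov_mu) / cov_sd     # hazard acts per SD of burden
    kind <- sample(c("cardiac", "respiratory"), 1)
    rec <- simulate_survival(xcov, beta, lambda0, censor_day, cause = kind)
    if (!is.null(ratio)) {
      if (rec$event == 1 && quota_case <= 0) next
      if (rec$event == 0 && quota_ctrl <= 0) next
    }
    if (rec$event == 1) quota_case <- quota_case - 1 else
      quota_ctrl <- quota_ctrl - 1
    kept <- kept + 1
    rows[[kept]] <- data.frame(
      subject_id = sprintf("S%04d", kept),
      event = rec$event, time_days = rec$time,
      cause = if (rec$event == 1) kind else "none",
      b0 = s$b0, rate = s$rate, burden_last = b_traj[length(b_traj)],
      risk_z = xcov, lesion_kind = kind,
      age = round(pmin(pmax(rnorm(1, 62, 5), 55), 74)),
      sex = sample(c("M", "F"), 1, prob = c(0.59, 0.41)),
      pack_years = round(pmax(rnorm(1, 56, 20), 30)),
      stringsAsFactors = FALSE)
    sched[[kept]] <- days
  }
  if (kept < n)
    stop_invalid("infeasible design: could not fill the ", ratio[1], ":",
                 ratio[2], " ratio for n = ", n)
  subjects <- do.call(rbind, rows)

  # site partition and splits: external sites get an acquisition shift
  n_ext <- round(n * external_frac)
  ext <- sample.int(n, n_ext)
  subjects$site <- ifelse(seq_len(n) %in% ext, "ext1", "int1")
  subjects$split <- NA_character_
  subjects$split[ext] <- "external_test"
  internal <- setdiff(seq_len(n), ext)
  n_test <- round(length(internal) * 0.2)
  test_idx <- sample(internal, n_test)
  subjects$split[test_idx] <- "internal_test"
  cvpool <- sample(setdiff(internal, test_idx))
  subjects$split[cvpool] <- paste0("cv", rep_len(1:5, length(cvpool)))
  subjects$subject_seed <- seed * 1000L + seq_len(n)

  structure(list(subjects = subjects, schedule = sched, spec = spec,
                 params = list(beta = beta, lambda0 = lambda0,
                               censor_day = censor_day,
                               risk_covariate = risk_covariate,
                               jitter_sd = jitter_sd, seed = seed,
                               ext_hu_offset = 30, ext_noise_scale = 1.3)),
            class = "synthetic_cohort")
}

#' Render the scan series of one cohort subject
#'
#' @param cohort a `synthetic_cohort`.
#' @param i subject row index (or subject_id string).
#' @return list with `scans` (list of `ct_volume`) and `burden`.
#' @export
render_subject <- function(cohort, i) {
  if (is.character(i)) i <- match(i, cohort$subjects$subject_id)
  s <- cohort$subjects[i, ]
  ext <- s$site != "int1"
  plant_progression(cohort$spec, cohort$schedule[[i]], s$b0, s$rate,
                    kind = s$lesion_kind, seed = s$subject_seed,
                    hu_offset = if (ext) cohort$params$ext_hu_offset else 0,
                    noise_scale = if (ext) cohort$params$ext_noise_scale else 1)
}

#' Survival records of a cohort (or a subset of it)
#'
#' @param cohort a `synthetic_cohort`.
#' @param idx optional row indices.
#' @export
cohort_records <- function(cohort, idx = NULL) {
  s <- cohort$subjects
  if (!is.null(idx)) s <- s[idx, ]
  survival_records(s$time_days, s$event, s$cause)
}
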