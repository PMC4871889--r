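# Deterministic synthetic phantoms: a labeled "head" with paired lateral
# structures, cohorts of diffeomorphically deformed copies with known
# truths, and aging template sequences with progressive shrinkage and
# gray/white contrast inversion.  All randomness is driven by explicit
# integer seeds so every generated object is bit-reproducible.

PHANTOM_BLOB_PAIRS <- list(
  blob_a = list(left = 21L, right = 22L, pos = c(0.35, 0.25), r = 0.10),
  blob_b = list(left = 23L, right = 24L, pos = c(0.35, -0.25), r = 0.09),
  blob_c = list(left = 25L, right = 26L, pos = c(0.15, 0.40), r = 0.07),
  blob_d = list(left = 27L, right = 28L, pos = c(0.15, -0.40), r = 0.08))

#' Label scheme of the synthetic phantom
#'
#' Mini parcellation scheme bundled with [make_phantom()]: a CSF rim, a
#' left/right split gray-matter ribbon and white-matter core, four pairs of
#' deep "nuclei" blobs and one unpaired midline structure.
#'
#' @return A [label_scheme()].
#' @export
phantom_label_scheme <- function() {
  df <- data.frame(
    id = c(10L, 11L, 12L, 13L, 14L,
           21L, 22L, 23L, 24L, 25L, 26L, 27L, 28L, 30L),
    name = c("csf_rim", "gm_ribbon_left", "gm_ribbon_right",
             "wm_core_left", "wm_core_right",
             "blob_a_left", "blob_a_right", "blob_b_left", "blob_b_right",
             "blob_c_left", "blob_c_right", "blob_d_left", "blob_d_right",
             "midline_bar"),
    hemisphere = c("none", "left", "right", "left", "right",
                   "left", "right", "left", "right", "left", "right",
                   "left", "right", "none"),
    partner_id = c(NA, 12L, 11L, 14L, 13L,
                   22L, 21L, 24L, 23L, 26L, 25L, 28L, 27L, NA),
    lobe = c("csf", "cortex", "cortex", "white_matter", "white_matter",
             "deep_gray", "deep_gray", "deep_gray", "deep_gray",
             "deep_gray", "deep_gray", "deep_gray", "deep_gray",
             "midline"),
    stringsAsFactors = FALSE)
  label_scheme(df)
}

#' Build a labeled synthetic head phantom
#'
#' Generates a concentric "head" (background, CSF rim, gray-matter ribbon,
#' white-matter core) with four pairs of lateral blobs, one unpaired
#' midline bar, and five named landmarks at structure extrema.  The
#' left-right axis is the first array axis.  A laterality factor scales the
#' left member of a pair so that its volume is `factor` times the right
#' one, giving a known ground-truth asymmetry coefficient
#' `S = 2|f - 1|/(f + 1)`.
#'
#' @param size Grid size per axis (scalar or vector, minimum 48).
#' @param laterality Named numeric vector of target left/right volume
#'   ratios per blob pair (names among `blob_a` ... `blob_d`); default all 1
#'   (mirror-symmetric phantom).
#' @param seed Unused by the deterministic geometry; kept so the signature
#'   matches the other generators.
#' @param spacing Voxel size in mm (default 1).
#' @param ndim 2 (default) or 3.
#' @param scale Global structure scale factor (used by the aging-sequence
#'   generator to emulate growth).
#' @param intensities Named tissue intensities (csf, gm, wm, blob, midline).
#' @param smooth_sigma Partial-volume smoothing of the intensity image in
#'   voxels (labels are never smoothed).
#' @return List with elements `image` ([image_volume()]), `labels`
#'   ([label_map()]), `landmarks` ([landmark_set()]) and `scheme`.
#' @export
make_phantom <- function(size = 96, laterality = NULL, seed = NULL,
                         spacing = 1, ndim = 2, scale = 1,
                         intensities = c(csf = 0.10, gm = 0.50, wm = 0.90,
                                         blob = 0.35, midline = 0.70),
                         smooth_sigma = 1) {
  size <- rep_len(as.integer(size), ndim)
  if (any(size < 48))
    stop("make_phantom: grid size must be at least 48 per axis")
  spacing <- rep_len(spacing, ndim)
  grid <- grid_geometry(size, spacing)
  ctr <- physical_center(grid)
  half <- (size - 1) * spacing / 2
  ax <- 0.9 * half * scale                    # head ellipse semi-axes

  pts <- grid_world_coords(grid)
  rel <- sweep(pts, 2, ctr, `-`)
  rho <- sqrt(rowSums(sweep(rel, 2, ax, `/`)^2))

  lab <- integer(nrow(pts))
  left_side <- rel[, 1] < 0
  lab[rho <= 1] <- 10L                                   # CSF rim
  lab[rho <= 0.88] <- ifelse(left_side[rho <= 0.88], 11L, 12L)  # GM ribbon
  lab[rho <= 0.70] <- ifelse(left_side[rho <= 0.70], 13L, 14L)  # WM core

  lat <- stats::setNames(rep(1, length(PHANTOM_BLOB_PAIRS)),
                         names(PHANTOM_BLOB_PAIRS))
  if (!is.null(laterality)) {
    unknown <- setdiff(names(laterality), names(lat))
    if (length(unknown))
      stop("make_phantom: unknown blob pair(s) ", paste(unknown, collapse = ", "))
    lat[names(laterality)] <- laterality
  }

  hmin <- min(half) * scale
  blob_center <- function(frac, side_sign) {
    ctr_off <- numeric(ndim)
    ctr_off[1] <- side_sign * frac[1] * hmin
    ctr_off[2] <- frac[2] * hmin
    ctr + ctr_off
  }
  for (nm in names(PHANTOM_BLOB_PAIRS)) {
    bp <- PHANTOM_BLOB_PAIRS[[nm]]
    r_right <- bp$r * hmin
    r_left <- r_right * lat[nm]^(1 / ndim)
    for (side in c("left", "right")) {
      sgn <- if (side == "left") -1 else 1
      r <- if (side == "left") r_left else r_right
      cb <- blob_center(bp$pos, sgn)
      d2 <- rowSums(sweep(pts, 2, cb, `-`)^2)
      lab[d2 <= r^2] <- bp[[side]]
    }
  }

  bar_half <- c(0.05, 0.30, 0.05)[seq_len(ndim)] * hmin
  in_bar <- rep(TRUE, nrow(pts))
  for (k in seq_len(ndim)) in_bar <- in_bar & abs(rel[, k]) <= bar_half[k]
  lab[in_bar] <- 30L

  tiss <- c("0" = 0, "10" = intensities[["csf"]],
            "11" = intensities[["gm"]], "12" = intensities[["gm"]],
            "13" = intensities[["wm"]], "14" = intensities[["wm"]],
            "21" = intensities[["blob"]], "22" = intensities[["blob"]],
            "23" = intensities[["blob"]], "24" = intensities[["blob"]],
            "25" = intensities[["blob"]], "26" = intensities[["blob"]],
            "27" = intensities[["blob"]], "28" = intensities[["blob"]],
            "30" = intensities[["midline"]])
  img_arr <- array(tiss[as.character(lab)], dim = size)
  if (smooth_sigma > 0) img_arr <- smooth_array(img_arr, smooth_sigma)

  lm <- rbind(
    blob_a_left = blob_center(PHANTOM_BLOB_PAIRS$blob_a$pos, -1),
    blob_a_right = blob_center(PHANTOM_BLOB_PAIRS$blob_a$pos, 1),
    anterior_pole = ctr + c(0, 0.79 * ax[2], numeric(ndim - 2)),
    posterior_pole = ctr - c(0, 0.79 * ax[2], numeric(ndim - 2)),
    midline_tip = ctr - c(0, bar_half[2], numeric(ndim - 2)))

  list(image = image_volume(img_arr, spacing),
       labels = label_map(array(as.integer(lab), dim = size), spacing),
       landmarks = landmark_set(lm),
       scheme = phantom_label_scheme())
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)
}

# random smooth stationary velocity field with max displacement `amplitude`
# voxels after smoothing with `sigma` voxels
random_velocity_field <- function(grid, amplitude, sigma, seed) {
  grid <- as_grid_geometry(grid)
  d <- length(grid$dim)
  set.seed(seed)
  vec <- array(stats::rnorm(prod(grid$dim) * d), dim = c(grid$dim, d))
  f <- displacement_field(vec, grid$spacing, grid$origin)
  f <- smooth_field_components(f, sigma)
  mv <- max_displacement_voxels(f)
  if (mv > 0) f$vectors <- f$vectors * (amplitude / mv)
  f
}

#' Cohort specification for the synthetic generator
#'
#' @param n_subjects Number of subjects.
#' @param size Grid size per axis.
#' @param deformation_amplitude Maximum true displacement in voxels
#'   (default 3, a realistic inter-subject shape variation at this grid
#'   scale).
#' @param smoothness_sigma Gaussian sigma (voxels) of the random velocity
#'   fields (default 4).
#' @param noise_sd Additive Gaussian noise SD as a fraction of the
#'   intensity range (default 0.02).
#' @param bias_amplitude Amplitude of the smooth multiplicative bias field
#'   (default 0.05, emulating the residual inhomogeneity left after
#'   upstream bias-field correction — registration inputs in this pipeline
#'   are assumed bias-corrected).
#' @param laterality Passed to [make_phantom()].
#' @param spacing Voxel size (mm).
#' @param ndim 2 or 3.
#' @param seed Integer master seed; fixes all randomness.
#' @return A `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_subjects = 8, size = 96,
                                  deformation_amplitude = 3,
                                  smoothness_sigma = 4,
                                  noise_sd = 0.02, bias_amplitude = 0.05,
                                  laterality = NULL, spacing = 1,
                                  ndim = 2, seed = 1) {
  stopifnot(n_subjects >= 1, deformation_amplitude >= 0, noise_sd >= 0,
            bias_amplitude >= 0)
  structure(list(n_subjects = as.integer(n_subjects), size = size,
                 deformation_amplitude = deformation_amplitude,
                 smoothness_sigma = smoothness_sigma, noise_sd = noise_sd,
                 bias_amplitude = bias_amplitude, laterality = laterality,
                 spacing = spacing, ndim = as.integer(ndim),
                 seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Each subject is the base phantom warped by a random smooth diffeomorphism
#' (a Gaussian-smoothed random stationary velocity field exponentiated by
#' scaling-and-squaring, so the true warp is fold-free by construction),
#' multiplied by a smooth bias field and corrupted with Gaussian noise.
#' True label maps, true transforms (subject to phantom, pull-back), true
#' landmark positions and the generating velocity are retained for
#' parameter-recovery testing.
#'
#' @param spec A [synthetic_cohort_spec()].
#' @return List with `base` (the phantom, see [make_phantom()]) and
#'   `subjects`, a list of per-subject lists with elements `image`,
#'   `labels`, `transform`, `landmarks` and `velocity`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  base <- make_phantom(spec$size, laterality = spec$laterality,
                       spacing = spec$spacing, ndim = spec$ndim)
  grid <- as_grid_geometry(base$image)
  rng <- range(base$image$data)
  subjects <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    amp <- spec$deformation_amplitude
    repeat {
      v <- random_velocity_field(grid, amp, spec$smoothness_sigma,
                                 derive_seed(spec$seed, i))
      s <- exp_velocity(v)
      if (amp == 0 || min(jacobian_determinant(s)$data) > 0) break
      amp <- amp * 0.8
      warning("make_cohort: subject ", i,
              " amplitude reduced to keep the warp diffeomorphic")
    }
    tr <- composite_transform(identity_affine(spec$ndim), s,
                              target_space = paste0("subject_", i),
                              source_space = "phantom")
    img <- resample_intensity(base$image, tr, grid)
    set.seed(derive_seed(spec$seed, 10000 + i))
    if (spec$bias_amplitude > 0) {
      b <- smooth_array(array(stats::rnorm(prod(grid$dim)), dim = grid$dim),
                        max(grid$dim) / 6)
      b <- b / max(abs(b)) * spec$bias_amplitude
      img$data <- img$data * (1 + b)
    }
    if (spec$noise_sd > 0)
      img$data <- img$data + stats::rnorm(length(img$data),
                                          sd = spec$noise_sd * diff(rng))
    labs <- resample_labels(base$labels, tr, grid)
    s_inv <- exp_velocity(negate_field(v))
    lm_true <- base$landmarks
    lm_true[] <- base$landmarks + field_at_points(s_inv, base$landmarks)
    subjects[[i]] <- list(image = img, labels = labs, transform = tr,
                          landmarks = lm_true, velocity = v)
  }
  list(base = base, subjects = subjects)
}

#' Localized smooth bump deformation with known truth
#'
#' Deforms the base phantom by a single Gaussian-bump displacement of known
#' amplitude, direction and centre — the canonical fully recoverable test
#' deformation for registration parameter-recovery studies (a coherent
#' bump, unlike a random field, is observable everywhere it acts, so the
#' recovered field can be compared to the truth without an aperture
#' ambiguity).
#'
#' @param phantom Output of [make_phantom()].
#' @param amplitude Peak displacement in voxels (default 3).
#' @param sigma Bump width in voxels (default 8).
#' @param seed Integer seed driving the bump centre and direction.
#' @param noise_sd Additive noise SD as a fraction of intensity range.
#' @return List with `image`, `labels`, `transform` (subject to phantom,
#'   pull-back), `landmarks` (true subject-space positions) and `velocity`.
#' @export
make_bump_deformation <- function(phantom, amplitude = 3, sigma = 8,
                                  seed = 1, noise_sd = 0.02) {
  g <- as_grid_geometry(phantom$image)
  d <- length(g$dim)
  set.seed(seed)
  ctr <- physical_center(g) +
    stats::runif(d, -1, 1) * 0.1 * (g$dim - 1) * g$spacing
  dir <- stats::runif(d, -1, 1)
  dir <- dir / sqrt(sum(dir^2))
  pts <- grid_world_coords(g)
  r2 <- rowSums(sweep(pts, 2, ctr, `-`)^2)
  mag <- amplitude * min(g$spacing) * exp(-r2 / (2 * (sigma * min(g$spacing))^2))
  vec <- vapply(seq_len(d), function(k) mag * dir[k], numeric(length(mag)))
  v <- displacement_field(array(vec, dim = c(g$dim, d)), g$spacing, g$origin)
  s <- exp_velocity(v)
  tr <- composite_transform(identity_affine(d), s,
                            target_space = "subject", source_space = "phantom")
  img <- resample_intensity(phantom$image, tr, g)
  if (noise_sd > 0) {
    set.seed(derive_seed(seed, 5000))
    img$data <- img$data + stats::rnorm(length(img$data),
                                        sd = noise_sd * diff(range(phantom$image$data)))
  }
  s_inv <- exp_velocity(negate_field(v))
  lm_true <- phantom$landmarks
  lm_true[] <- phantom$landmarks + field_at_points(s_inv, phantom$landmarks)
  list(image = img, labels = resample_labels(phantom$labels, tr, g),
       transform = tr, landmarks = lm_true, velocity = v)
}

#' Aging-sequence specification
#'
#' Describes an ordered ladder of age templates running from an adult-like
#' oldest stage to a neonatal-like youngest stage: structure size shrinks
#' monotonically and the white/gray contrast crosses from adult (WM bright)
#' to inverted (WM dark), emulating the effect of myelination on
#' T1-weighted contrast.
#'
#' @param n_stages Number of templates (oldest first; default 6).
#' @param size Grid size per axis (default 128).
#' @param scales Monotone per-stage global structure scale factors
#'   (default linear from 1.0 to 0.8).
#' @param wm_intensities Monotone per-stage WM intensity (default linear
#'   from 0.9 to 0.3, crossing the fixed GM level 0.5 exactly once).
#' @param gm_intensity Fixed GM intensity (default 0.5).
#' @param ages Strictly decreasing age tags (default `n_stages - 1` down
#'   to 0, arbitrary units).
#' @param seed Integer seed (reserved; the sequence itself is
#'   deterministic).
#' @return An `aging_sequence_spec`.
#' @export
aging_sequence_spec <- function(n_stages = 6, size = 128,
                                scales = seq(1, 0.8, length.out = n_stages),
                                wm_intensities = seq(0.9, 0.3,
                                                     length.out = n_stages),
                                gm_intensity = 0.5,
                                ages = seq(n_stages - 1, 0),
                                seed = 1) {
  stopifnot(n_stages >= 1, length(scales) == n_stages,
            length(wm_intensities) == n_stages, length(ages) == n_stages)
  if (n_stages > 1) {
    stopifnot(all(diff(scales) <= 0), all(diff(ages) < 0))
    stopifnot(all(diff(wm_intensities) <= 0) || all(diff(wm_intensities) >= 0))
  }
  structure(list(n_stages = as.integer(n_stages), size = size,
                 scales = scales, wm_intensities = wm_intensities,
                 gm_intensity = gm_intensity, ages = ages,
                 seed = as.integer(seed)),
            class = "aging_sequence_spec")
}

#' Ordered sequence of age templates
#'
#' @param templates List of [image_volume()]s, oldest (labeled end) first.
#' @param ages Strictly decreasing numeric age tags.
#' @param metric_schedule Per-step metric for inter-stage registration
#'   (default `"nmi"` everywhere).
#' @return A `temporal_sequence`.
#' @export
temporal_sequence <- function(templates, ages,
                              metric_schedule = rep("nmi",
                                                    max(length(templates) - 1, 0))) {
  stopifnot(length(templates) >= 2, length(ages) == length(templates),
            all(diff(ages) < 0))
  structure(list(templates = templates, ages = ages,
                 metric_schedule = metric_schedule),
            class = "temporal_sequence")
}

#' Generate a synthetic aging template sequence
#'
#' Builds the ladder described by an [aging_sequence_spec()] together with
#' the true stage-to-stage transforms (pull-back: each maps the younger
#' stage's coordinates to the older stage's coordinates — a pure expansion
#' about the grid centre, since growth is modeled as global scaling).
#'
#' @param spec An [aging_sequence_spec()].
#' @return List with `sequence` (a [temporal_sequence()]; single template
#'   if `n_stages` is 1), `true_transforms` (list of length
#'   `n_stages - 1`), and `phantoms` (per-stage [make_phantom()] output).
#' @export
make_aging_sequence <- function(spec) {
  stopifnot(inherits(spec, "aging_sequence_spec"))
  phantoms <- vector("list", spec$n_stages)
  for (s in seq_len(spec$n_stages)) {
    ints <- c(csf = 0.10, gm = spec$gm_intensity,
              wm = spec$wm_intensities[s], blob = 0.35, midline = 0.70)
    phantoms[[s]] <- make_phantom(spec$size, scale = spec$scales[s],
                                  intensities = ints)
  }
  templates <- lapply(phantoms, `[[`, "image")
  if (spec$n_stages == 1)
    return(list(sequence = list(templates = templates, ages = spec$ages),
                true_transforms = list(), phantoms = phantoms))
  seq_obj <- temporal_sequence(templates, spec$ages)
  ctr <- physical_center(templates[[1]])
  truths <- vector("list", spec$n_stages - 1)
  for (s in seq_len(spec$n_stages - 1)) {
    # younger stage s+1 -> older stage s: expansion by scales[s]/scales[s+1]
    f <- spec$scales[s] / spec$scales[s + 1]
    d <- length(grid_dim(templates[[1]]))
    truths[[s]] <- composite_transform(
      affine_transform(diag(f, d), ctr - f * ctr),
      target_space = paste0("stage_", s + 1),
      source_space = paste0("stage_", s))
  }
  list(sequence = seq_obj, true_transforms = truths, phantoms = phantoms)
}
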