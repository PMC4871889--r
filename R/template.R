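# Groupwise template construction: iterative joint optimization of the
# template's appearance and shape together with per-subject diffeomorphic
# mappings (symmetric groupwise normalization).  Each iteration (a)
# registers every subject to the current template, (b) updates the template
# appearance as the voxelwise mean of the warped subjects, and (c) applies
# a fraction of the inverse of the mean forward displacement field so the
# template shape drifts toward the group mean; four iterations by default.

template_sharpness <- function(img) {
  d <- length(grid_dim(img))
  g2 <- 0
  for (k in seq_len(d))
    g2 <- g2 + array_gradient(img$data, k, img$spacing[k])^2
  mean(sqrt(g2))
}

mean_image <- function(imgs) {
  acc <- imgs[[1]]$data
  for (im in imgs[-1]) acc <- acc + im$data
  image_volume(acc / length(imgs), imgs[[1]]$spacing, imgs[[1]]$origin)
}

#' Groupwise template construction
#'
#' Builds a population template from affinely pre-aligned subjects by
#' iterative appearance averaging and shape centering (see the file header
#' for the scheme).  Registrations within the build use identity affine
#' initialization; align subjects to the initial template beforehand (e.g.
#' with [affine_register()]) if they are not already in a common space.
#'
#' @param subjects List of >= 2 [image_volume()]s on one common grid.
#' @param init Initial template; default the voxelwise mean of `subjects`.
#' @param iterations Number of outer iterations (default 4).
#' @param config [registration_config()] for the per-subject registrations.
#' @param shape_step Fraction of the inverted mean displacement field
#'   applied to the template shape per iteration (default 0.25).
#' @return A `template_build_result`: list with `template`, `per_subject`
#'   (final `registration_result` per subject), `diagnostics` (per-iteration
#'   data.frame: mean displacement norm in mm, template sharpness as mean
#'   gradient magnitude, mean metric, subjects used) and `warped` (final
#'   warped subjects).
#' @export
build_template <- function(subjects, init = NULL, iterations = 4,
                           config = registration_config(),
                           shape_step = 0.25) {
  if (length(subjects) < 1)
    stop("build_template: need at least 1 subject")
  grid <- as_grid_geometry(subjects[[1]])
  for (s in subjects[-1])
    if (!same_grid(s, grid))
      stop("build_template: subjects must share one grid (affine ",
           "pre-alignment is a separate step)")
  template <- if (is.null(init)) mean_image(subjects) else init
  d <- length(grid$dim)
  diag_rows <- vector("list", iterations)
  per_subject <- warped <- vector("list", length(subjects))

  for (it in seq_len(iterations)) {
    used <- logical(length(subjects))
    fields <- vector("list", length(subjects))
    metrics <- rep(NA_real_, length(subjects))
    for (i in seq_along(subjects)) {
      res <- tryCatch(diffeo_register(template, subjects[[i]], config),
                      error = function(e) e)
      if (inherits(res, "error")) {
        warning("build_template: subject ", i, " excluded at iteration ",
                it, ": ", conditionMessage(res))
        next
      }
      used[i] <- TRUE
      per_subject[[i]] <- res
      fields[[i]] <- res$forward$local
      warped[[i]] <- resample_intensity(subjects[[i]], res$forward, grid)
      metrics[i] <- utils::tail(res$metric_trace$metric, 1)
    }
    if (!any(used))
      stop("build_template: every subject registration failed at iteration ", it)

    appearance <- mean_image(warped[used])
    mean_field <- zero_field(grid)
    subj_disp <- 0
    for (f in fields[used]) {
      mean_field$vectors <- mean_field$vectors + f$vectors
      subj_disp <- subj_disp + mean(sqrt(rowSums(matrix(f$vectors,
                                                        ncol = d)^2)))
    }
    mean_field$vectors <- mean_field$vectors / sum(used)
    subj_disp <- subj_disp / sum(used)
    disp_norm <- sqrt(Reduce(`+`, lapply(seq_len(d), function(k)
      field_component(mean_field, k)^2)))

    shape_note <- ""
    template_new <- appearance
    if (max(abs(mean_field$vectors)) > 1e-8) {
      winv <- tryCatch(invert_displacement(mean_field,
                                           tol = 0.05 * min(grid$spacing),
                                           max_iter = 40),
                       error = function(e) e)
      if (inherits(winv, "error")) {
        shape_note <- "shape update skipped (mean field not invertible)"
      } else {
        winv$vectors <- winv$vectors * shape_step
        template_new <- resample_intensity(appearance,
                                           composite_transform(
                                             identity_affine(d), winv),
                                           grid)
      }
    }
    template <- template_new
    diag_rows[[it]] <- data.frame(iteration = it,
                                  mean_disp_mm = subj_disp,
                                  mean_field_mm = mean(disp_norm),
                                  sharpness = template_sharpness(template),
                                  mean_metric = mean(metrics[used]),
                                  n_used = sum(used),
                                  note = shape_note)
  }
  structure(list(template = template,
                 per_subject = per_subject,
                 diagnostics = do.call(rbind, diag_rows),
                 warped = warped),
            class = "template_build_result")
}

#' Symmetric template construction by flipped-subject augmentation
#'
#' Mirrors every subject along the left-right axis and runs
#' [build_template()] on the doubled set, so the resulting template is
#' (up to registration error) identical to its own mirror image.  When
#' label maps and a scheme are supplied, the matching augmented label set
#' (originals followed by flipped maps with partner IDs swapped, see
#' [flip_labels_lr()]) is returned ready for [transport_modalities()] and
#' fusion.
#'
#' @param subjects List of [image_volume()]s on one common grid.
#' @param labels Optional list of per-subject [label_map()]s.
#' @param scheme [label_scheme()]; required when `labels` is given.
#' @inheritParams build_template
#' @return A `template_build_result` as in [build_template()] (with `2n`
#'   per-subject transforms for `n` subjects, originals first), plus
#'   `augmented_labels` when labels were supplied.
#' @export
build_symmetric_template <- function(subjects, labels = NULL, scheme = NULL,
                                     iterations = 4,
                                     config = registration_config(),
                                     shape_step = 0.25) {
  augmented <- c(subjects, lapply(subjects, flip_lr))
  res <- build_template(augmented, init = NULL, iterations = iterations,
                        config = config, shape_step = shape_step)
  if (!is.null(labels)) {
    if (is.null(scheme))
      stop("build_symmetric_template: a scheme is required to flip labels")
    res$augmented_labels <- c(labels,
                              lapply(labels, flip_labels_lr, scheme = scheme))
  }
  res$n_original <- length(subjects)
  res
}

#' Transport per-subject maps into template space
#'
#' Applies each subject's final template-to-subject transform to pull the
#' subject's co-registered maps onto the template grid: intensity images
#' via cubic B-spline, label maps via nearest neighbour, and tissue
#' probability stacks (lists of per-class [image_volume()]s) via linear
#' interpolation followed by per-voxel renormalization to sum 1.
#'
#' @param maps List with one element per subject (same length and order as
#'   `result$per_subject`): an [image_volume()], a [label_map()], or a list
#'   of per-class probability [image_volume()]s.
#' @param result A `template_build_result`.
#' @return List of transported maps on the template grid.
#' @export
transport_modalities <- function(maps, result) {
  stopifnot(inherits(result, "template_build_result"))
  if (length(maps) != length(result$per_subject))
    stop("transport_modalities: ", length(maps), " maps for ",
         length(result$per_subject), " subjects")
  grid <- as_grid_geometry(result$template)
  lapply(seq_along(maps), function(i) {
    tr <- result$per_subject[[i]]$forward
    m <- maps[[i]]
    if (inherits(m, "label_map"))
      return(resample_labels(m, tr, grid))
    if (inherits(m, "image_volume"))
      return(resample_intensity(m, tr, grid))
    if (is.list(m)) {
      probs <- lapply(m, resample_intensity, transform = tr,
                      target_grid = grid, method = "linear")
      tot <- Reduce(`+`, lapply(probs, `[[`, "data"))
      for (k in seq_along(probs)) {
        pk <- probs[[k]]$data
        pk[tot > 0] <- pk[tot > 0] / tot[tot > 0]
        pk[pk < 0] <- 0
        probs[[k]]$data <- pk
      }
      return(probs)
    }
    stop("transport_modalities: unsupported map class at position ", i)
  })
}
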