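# File input/output: NIfTI-1 volumes, label schemes (TSV/JSON), landmark
# CSVs, and tabular reports.  Grids are assumed axis-aligned; the NIfTI
# sform stores spacing on the diagonal and the origin in the offset column.

#' Read / write image volumes and label maps as NIfTI-1
#'
#' `write_image()` stores the array with spacing and origin in the sform;
#' `read_image()` restores them (a non-axis-aligned sform is rejected).
#' The label-map variants do the same with integer data.
#'
#' @param x An [image_volume()] or [label_map()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_image()` an [image_volume()]; `read_label_map()` a
#'   [label_map()]; the writers return `path` invisibly.
#' @export
write_image <- function(x, path) {
  stopifnot(is_image_like(x))
  d <- length(grid_dim(x))
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing
  m <- diag(4)
  diag(m)[seq_len(d)] <- x$spacing
  m[seq_len(d), 4] <- x$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

nifti_geometry <- function(img, nd) {
  x <- RNifti::xform(img)
  if (attr(x, "code") == 0)
    return(list(spacing = RNifti::pixdim(img)[seq_len(nd)],
                origin = rep(0, nd)))
  rot <- x[seq_len(nd), seq_len(nd), drop = FALSE]
  if (max(abs(rot - diag(diag(rot), nd))) > 1e-4 * max(abs(diag(rot))))
    stop("NIfTI orientation is not axis-aligned (off-diagonal xform terms); ",
         "this reader only supports axis-aligned grids")
  if (any(diag(rot) <= 0))
    stop("NIfTI xform has non-positive diagonal; unsupported axis flip")
  list(spacing = diag(rot), origin = x[seq_len(nd), 4])
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  geo <- nifti_geometry(img, length(dim(arr)))
  image_volume(array(as.numeric(arr), dim = dim(arr)),
               geo$spacing, geo$origin)
}

#' @rdname write_image
#' @export
read_label_map <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (max(abs(arr - round(arr))) > 1e-6)
    stop("read_label_map: file does not contain integer labels")
  geo <- nifti_geometry(img, length(dim(arr)))
  label_map(array(as.integer(round(arr)), dim = dim(arr)),
            geo$spacing, geo$origin)
}

#' @rdname write_image
#' @export
write_label_map <- function(x, path) write_image(x, path)

#' Read / write a label scheme
#'
#' TSV with columns `id`, `name`, `hemisphere`, `partner_id`, `lobe`
#' (empty partner/lobe for unpaired/ungrouped labels), or the equivalent
#' JSON array of records.  The scheme invariants (partner involution,
#' opposite hemispheres) are enforced on read.
#'
#' @param scheme A [label_scheme()].
#' @param path File path; format chosen by extension (`.tsv` or `.json`).
#' @return `read_label_scheme()` a [label_scheme()]; the writer returns
#'   `path` invisibly.
#' @export
write_label_scheme <- function(scheme, path) {
  df <- as.data.frame(scheme)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname write_label_scheme
#' @export
read_label_scheme <- function(path) {
  df <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path)
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  }
  label_scheme(df)
}

#' Read / write landmark sets as CSV
#'
#' Columns `name,x,y` (2D) or `name,x,y,z` (3D), coordinates in mm.
#'
#' @param lm A [landmark_set()].
#' @param path CSV file path.
#' @return `read_landmarks()` a [landmark_set()]; the writer returns
#'   `path` invisibly.
#' @export
write_landmarks <- function(lm, path) {
  d <- ncol(lm)
  df <- data.frame(name = rownames(lm), unclass(lm))
  names(df)[-1] <- c("x", "y", "z")[seq_len(d)]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"name" %in% names(df))
    stop("read_landmarks: CSV must have a 'name' column")
  coords <- as.matrix(df[, setdiff(names(df), "name"), drop = FALSE])
  rownames(coords) <- df$name
  landmark_set(coords)
}

#' Write / read a volume report CSV
#'
#' Single-map reports have columns `label,name,volume_cm3`; cohort reports
#' `label,name,mean_cm3,sd_cm3` (the shape of a normative volume table).
#'
#' @param volumes data.frame from [region_volumes()].
#' @param path CSV path.
#' @param scheme Optional [label_scheme()] used to attach region names.
#' @return `read_volume_report()` the data.frame back; writer returns
#'   `path` invisibly.
#' @export
write_volume_report <- function(volumes, path, scheme = NULL) {
  df <- volumes
  nm <- if (!is.null(scheme)) {
    scheme$name[match(df$label, scheme$id)]
  } else NA_character_
  df <- cbind(label = df$label, name = nm, df[setdiff(names(df), "label")])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_volume_report
#' @export
read_volume_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df[setdiff(names(df), "name")]
}

# ---------------------------------------------------------------------------
# Pipeline configuration

default_pipeline_config <- function() {
  list(
    seed = 42L,
    out_dir = "chronoatlas_out",
    simulate = list(n_subjects = 8L, size = 96L, deformation_amplitude = 3,
                    smoothness_sigma = 4, noise_sd = 0.02,
                    bias_amplitude = 0.05, laterality = NULL, ndim = 2L,
                    sequence_stages = 4L, sequence_size = 96L),
    registration = list(levels = 4L,
                        max_iters_per_level = c(100L, 100L, 100L, 20L),
                        metric = "ncc", histogram_bins = 32L,
                        update_smoothing_sigma = 1, field_smoothing_sigma = 2,
                        step_size = 0.25, convergence_tol = 1e-5),
    template = list(iterations = 4L, shape_step = 0.25, symmetric = TRUE),
    fusion = list(tie_rule = "smallest_id"),
    segmentation = list(max_iter = 50L, tol = 1e-5)
  )
}

merge_config <- function(base, user, path = "") {
  for (k in names(user)) {
    if (!k %in% names(base))
      stop("unknown configuration key '", paste0(path, k), "'")
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], as.list(user[[k]]),
                                paste0(path, k, "."))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Load a pipeline configuration
#'
#' Reads a YAML or JSON configuration file and merges it over the package
#' defaults; unknown keys are rejected so typos fail loudly.
#'
#' @param path Config file, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (is.null(path)) return(cfg)
  user <- if (grepl("\\.json$", path)) jsonlite::fromJSON(path,
                                                          simplifyVector = TRUE)
          else yaml::read_yaml(path)
  merge_config(cfg, user)
}

registration_config_from <- function(rc, metric = NULL) {
  registration_config(levels = rc$levels,
                      max_iters_per_level = rc$max_iters_per_level,
                      metric = if (is.null(metric)) rc$metric else metric,
                      histogram_bins = rc$histogram_bins,
                      update_smoothing_sigma = rc$update_smoothing_sigma,
                      field_smoothing_sigma = rc$field_smoothing_sigma,
                      step_size = rc$step_size,
                      convergence_tol = rc$convergence_tol)
}

file_or_null_hash <- function(paths) {
  ex <- paths[file.exists(paths)]
  if (!length(ex)) return(character(0))
  as.vector(tools::md5sum(ex))
}

# ---------------------------------------------------------------------------
# End-to-end pipeline

#' Run the full atlas-construction pipeline on synthetic data
#'
#' Executes the complete framework on a seeded synthetic cohort: simulate
#' cohort and aging sequence, build the temporal chain from the "adult"
#' labeled end to the cohort, propagate atlas labels to every subject,
#' build the (optionally symmetric) groupwise template, fuse the
#' propagated labels by majority vote, and produce volume, asymmetry and
#' validation reports plus a reproducibility manifest.  All artifacts are
#' written under `config$out_dir`.
#'
#' @param config Nested configuration list from [read_pipeline_config()].
#' @param verbose Print stage progress (default TRUE).
#' @return Invisibly, a list of in-memory artifacts: `template`, `fused`,
#'   `asymmetry`, `volumes`, `chain_info`, `dice`, `manifest`.
#' @export
run_end_to_end <- function(config = read_pipeline_config(), verbose = TRUE) {
  t_start <- Sys.time()
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[chronoatlas] ", ...)
  stage_times <- list()
  timed <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stage_times[[name]] <<- as.numeric(Sys.time() - t0, units = "secs")
    r
  }

  say("simulating cohort (n = ", config$simulate$n_subjects, ")")
  sim <- config$simulate
  coh <- timed("simulate_cohort", make_cohort(synthetic_cohort_spec(
    n_subjects = sim$n_subjects, size = sim$size,
    deformation_amplitude = sim$deformation_amplitude,
    smoothness_sigma = sim$smoothness_sigma, noise_sd = sim$noise_sd,
    bias_amplitude = sim$bias_amplitude, laterality = sim$laterality,
    ndim = sim$ndim, seed = config$seed)))
  scheme <- coh$base$scheme

  say("simulating aging sequence (", sim$sequence_stages, " stages)")
  aging <- timed("simulate_sequence", make_aging_sequence(aging_sequence_spec(
    n_stages = sim$sequence_stages, size = sim$sequence_size,
    seed = derive_seed(config$seed, 1))))

  rc <- config$registration
  say("building temporal chain to subject 1")
  # the oldest (adult-contrast) stage carries the reference parcellation;
  # the chain runs from each subject through the ladder to that end
  atlas_img <- aging$phantoms[[1]]$image
  atlas_lab <- aging$phantoms[[1]]$labels
  chain <- timed("temporal_chain", build_temporal_chain(
    atlas_img, aging$sequence, coh$subjects[[1]]$image,
    registration_config_from(rc)))
  chain_info <- attr(chain, "link_info")
  utils::write.csv(chain_info, file.path(out, "chain_report.csv"),
                   row.names = FALSE)
  prop1 <- timed("propagate", propagate_atlas_labels(
    atlas_lab, chain, as_grid_geometry(coh$subjects[[1]]$image)))
  write_label_map(prop1, file.path(out, "subject1_propagated_labels.nii.gz"))

  say("building ", if (isTRUE(config$template$symmetric)) "symmetric "
      else "", "template (", config$template$iterations, " iterations)")
  subs <- lapply(coh$subjects, `[[`, "image")
  labs <- lapply(coh$subjects, `[[`, "labels")
  build_cfg <- registration_config_from(rc, metric = "ncc")
  if (isTRUE(config$template$symmetric)) {
    tb <- timed("template", build_symmetric_template(
      subs, labs, scheme, iterations = config$template$iterations,
      config = build_cfg, shape_step = config$template$shape_step))
    transported <- timed("transport", transport_modalities(
      tb$augmented_labels, tb))
  } else {
    tb <- timed("template", build_template(
      subs, iterations = config$template$iterations,
      config = build_cfg, shape_step = config$template$shape_step))
    transported <- timed("transport", transport_modalities(labs, tb))
  }
  write_image(tb$template, file.path(out, "template.nii.gz"))
  utils::write.csv(tb$diagnostics, file.path(out, "template_diagnostics.csv"),
                   row.names = FALSE)

  say("fusing labels and measuring volumes / asymmetry")
  fused <- timed("fusion", majority_vote(transported))
  write_label_map(fused, file.path(out, "fused_labels.nii.gz"))
  vols <- region_volumes(fused)
  write_volume_report(vols, file.path(out, "volumes.csv"), scheme)
  cohort_vols <- region_volumes(labs)
  write_volume_report(cohort_vols, file.path(out, "cohort_volumes.csv"), scheme)
  asym <- asymmetry_report(fused, scheme)
  utils::write.csv(as.data.frame(asym), file.path(out, "asymmetry.csv"),
                   row.names = FALSE)

  say("validating against simulation truth")
  # fused template labels vs the phantom truth (the template approximates
  # the base phantom since the cohort's warps have ~zero mean)
  dice <- timed("validation", mean_dice(fused, coh$base$labels))
  val <- list(
    chain_mean_ncc = mean(chain_info$ncc_after[-1]),
    fused_dice_mean = dice$mean,
    fused_dice_per_label = as.list(dice$per_label),
    max_S = attr(asym, "max_S"))
  jsonlite::write_json(val, file.path(out, "validation.json"),
                       auto_unbox = TRUE, digits = NA)

  cfg_file <- file.path(out, "config.json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  manifest <- list(
    tool = paste0("chronoatlas ",
                  as.character(utils::packageVersion("chronoatlas"))),
    seed = config$seed,
    config_md5 = file_or_null_hash(cfg_file),
    outputs_md5 = as.list(tools::md5sum(list.files(out, full.names = TRUE,
                                                   pattern = "\\.(csv|json)$"))),
    stage_seconds = stage_times,
    total_seconds = as.numeric(Sys.time() - t_start, units = "secs"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done in ", round(manifest$total_seconds), " s; outputs in ", out)
  invisible(list(template = tb, fused = fused, asymmetry = asym,
                 volumes = vols, chain_info = chain_info, dice = dice,
                 manifest = manifest))
}
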