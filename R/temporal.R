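# Temporal atlas propagation: chain a labeled reference ("adult") end of a
# template ladder to a target cohort space through consecutive pairwise
# registrations, then transport the labels through the composed chain in a
# single nearest-neighbour pass.

config_with_metric <- function(config, metric) {
  config$metric <- metric
  config
}

register_link <- function(fixed, moving, metric, config,
                          target_space, source_space) {
  aff <- affine_register(fixed, moving, metric,
                         config_with_metric(config, metric))
  res <- diffeo_register(fixed, moving, config_with_metric(config, metric),
                         init = aff)
  link <- res$forward
  link$target_space <- target_space
  link$source_space <- source_space
  warped <- resample_intensity(moving, link, as_grid_geometry(fixed))
  list(link = link,
       info = data.frame(target = target_space, source = source_space,
                         metric = metric,
                         converged = res$converged,
                         affine_improved = isTRUE(attr(aff, "converged")),
                         ncc_after = ncc_metric(fixed, warped)))
}

#' Build the temporal propagation chain
#'
#' Registers the target to the youngest template, each template to the next
#' older one, and the oldest template to the labeled reference atlas, and
#' concatenates the resulting pull-back transforms so the chain maps target
#' coordinates all the way to atlas coordinates.  Inter-template and
#' template-to-atlas links use NMI (robust to the gradual contrast change
#' along the ladder); the target-side link is intra-modality and uses NCC.
#'
#' @param atlas_image Reference image in atlas space, or `NULL` to build a
#'   chain over the template ladder only.
#' @param seq A [temporal_sequence()] (oldest template first).
#' @param target Target image, or `NULL` to omit the target-side link.
#' @param config Base [registration_config()]; the per-link metric
#'   overrides its `metric` field.
#' @return A `transform_chain` with attribute `link_info`: a data.frame of
#'   per-link metric, convergence flag and post-warp NCC.  A non-converged
#'   link is kept but flagged.
#' @export
build_temporal_chain <- function(atlas_image = NULL, seq, target = NULL,
                                 config = registration_config()) {
  stopifnot(inherits(seq, "temporal_sequence"))
  n <- length(seq$templates)
  links <- list()
  infos <- list()
  if (!is.null(target)) {
    r <- register_link(target, seq$templates[[n]], "ncc", config,
                       "target", paste0("stage_", n))
    links <- c(links, list(r$link)); infos <- c(infos, list(r$info))
  }
  for (s in n:2) {
    metric <- seq$metric_schedule[s - 1]
    r <- register_link(seq$templates[[s]], seq$templates[[s - 1]], metric,
                       config, paste0("stage_", s), paste0("stage_", s - 1))
    links <- c(links, list(r$link)); infos <- c(infos, list(r$info))
  }
  if (!is.null(atlas_image)) {
    r <- register_link(seq$templates[[1]], atlas_image, "nmi", config,
                       "stage_1", "atlas")
    links <- c(links, list(r$link)); infos <- c(infos, list(r$info))
  }
  info <- do.call(rbind, infos)
  if (any(!info$converged))
    warning("build_temporal_chain: non-converged link(s): ",
            paste(info$target[!info$converged], "->",
                  info$source[!info$converged], collapse = "; "))
  chain <- concat_chain(links)
  attr(chain, "link_info") <- info
  chain
}

#' Propagate atlas labels through a transform chain
#'
#' Transports a parcellation from atlas space to the target grid through
#' the composed chain in one nearest-neighbour resampling pass: each target
#' voxel's coordinate is mapped through every link and the atlas labels are
#' sampled exactly once, avoiding the cumulative nearest-neighbour erosion
#' of stage-by-stage resampling.
#'
#' @param atlas_labels [label_map()] on the atlas grid.
#' @param chain `transform_chain` from [build_temporal_chain()] (its last
#'   link must end in atlas space).
#' @param target_grid Output [grid_geometry()].
#' @return [label_map()] on the target grid; no new label IDs can appear.
#' @export
propagate_atlas_labels <- function(atlas_labels, chain, target_grid) {
  stopifnot(inherits(atlas_labels, "label_map"),
            inherits(chain, "transform_chain"))
  last <- chain$links[[length(chain$links)]]
  if (!is.na(last$source_space) && last$source_space != "atlas")
    stop("propagate_atlas_labels: chain ends in space '",
         last$source_space, "', not 'atlas'")
  resample_labels(atlas_labels, chain, target_grid)
}

#' Per-step NCC of a temporal chain
#'
#' For every consecutive template pair, warps the older template into the
#' younger one's space through the corresponding chain link and reports the
#' normalized cross-correlation with the younger template — the accuracy
#' measure used for consecutive time points of a spatio-temporal atlas.
#'
#' @param seq The [temporal_sequence()] the chain was built from.
#' @param chain `transform_chain` from [build_temporal_chain()].
#' @return List with `per_step` (data.frame step, target, source, ncc),
#'   `mean`, `sd`.
#' @export
evaluate_chain_cc <- function(seq, chain) {
  n <- length(seq$templates)
  spaces <- vapply(chain$links, function(l) l$target_space, "")
  out <- data.frame(step = integer(0), target = character(0),
                    source = character(0), ncc = numeric(0))
  for (s in n:2) {
    k <- match(paste0("stage_", s), spaces)
    if (is.na(k)) stop("evaluate_chain_cc: chain lacks the link for stage ", s)
    link <- chain$links[[k]]
    warped <- resample_intensity(seq$templates[[s - 1]], link,
                                 as_grid_geometry(seq$templates[[s]]))
    out <- rbind(out, data.frame(step = n - s + 1L,
                                 target = paste0("stage_", s),
                                 source = paste0("stage_", s - 1),
                                 ncc = ncc_metric(seq$templates[[s]], warped)))
  }
  list(per_step = out, mean = mean(out$ncc), sd = stats::sd(out$ncc))
}
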