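# Groupwise template construction and modality transport.
# Cohorts are 64^2 with light registration settings; the full-scale
# symmetric build is exercised in the acceptance suite.

small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_cohort(synthetic_cohort_spec(3, 64, 2.5, 4, seed = 30))
    cache
  }
})

test_that("a single-subject build returns that subject", {
  coh <- small_cohort()
  res <- suppressWarnings(build_template(list(coh$subjects[[1]]$image),
                                         iterations = 1,
                                         config = light_config()))
  expect_lt(mean(abs(res$template$data - coh$subjects[[1]]$image$data)), 0.01)
})

test_that("two mirrored deformations average to the midpoint structure", {
  ph <- tiny_phantom()
  g <- as_grid_geometry(ph$image)
  # subjects displaced +/- d along axis 2 via opposite constant fields,
  # smoothly windowed to zero at the borders so the warp stays a bump
  pts <- grid_pts(ph$image)
  ctr <- chronoatlas:::physical_center(ph$image)
  win <- exp(-rowSums(sweep(pts, 2, ctr, `-`)^2) / (2 * 18^2))
  d <- 2.5
  mk <- function(sign) {
    v <- displacement_field(array(c(0 * win, sign * d * win),
                                  dim = c(g$dim, 2)), g$spacing, g$origin)
    resample_intensity(ph$image,
                       composite_transform(identity_affine(2),
                                           chronoatlas:::exp_velocity(v)), g)
  }
  subs <- list(mk(1), mk(-1))
  res <- suppressWarnings(build_template(subs, iterations = 2,
                                         config = light_config()))
  # structure centroid of the template vs the base phantom (midpoint)
  centroid <- function(img) {
    w <- pmax(as.vector(img$data), 0)
    colSums(grid_pts(img) * w) / sum(w)
  }
  expect_lt(max(abs(centroid(res$template) - centroid(ph$image))), 0.5)
})

test_that("builds from an external initial template centre the cohort", {
  coh <- small_cohort()
  subs <- lapply(coh$subjects, `[[`, "image")
  res <- suppressWarnings(build_template(subs, init = coh$base$image,
                                         iterations = 3,
                                         config = light_config()))
  dg <- res$diagnostics
  # per-subject displacement decreases or plateaus
  expect_lte(dg$mean_disp_mm[nrow(dg)], dg$mean_disp_mm[1] + 1e-6)
  # sharpness does not decrease from the first iteration to the last
  expect_gte(dg$sharpness[nrow(dg)], dg$sharpness[1] - 1e-9)
  # shape centering: mean residual field well under half a voxel
  expect_lte(dg$mean_field_mm[nrow(dg)] / min(coh$base$image$spacing), 0.5)
})

test_that("template construction is deterministic", {
  coh <- small_cohort()
  subs <- lapply(coh$subjects, `[[`, "image")[1:2]
  r1 <- suppressWarnings(build_template(subs, iterations = 1,
                                        config = light_config()))
  r2 <- suppressWarnings(build_template(subs, iterations = 1,
                                        config = light_config()))
  expect_identical(r1$template$data, r2$template$data)
})

test_that("symmetric builds mirror the template and double the transforms", {
  ph <- make_phantom(64)                      # mirror-symmetric input
  subs <- list(ph$image, ph$image)
  res <- suppressWarnings(build_symmetric_template(subs, iterations = 1,
                                                   config = light_config()))
  expect_length(res$per_subject, 4)           # 2n transforms for n subjects
  expect_gte(ncc_metric(res$template, flip_lr(res$template)), 0.999)

  # asymmetric cohort: symmetric build at least as mirror-consistent
  coh <- make_cohort(synthetic_cohort_spec(2, 64, 2, 4,
                                           laterality = c(blob_a = 1.8),
                                           seed = 31))
  subs2 <- lapply(coh$subjects, `[[`, "image")
  syms <- suppressWarnings(build_symmetric_template(subs2, iterations = 1,
                                                    config = light_config()))
  asym <- suppressWarnings(build_template(subs2, iterations = 1,
                                          config = light_config()))
  expect_gte(ncc_metric(syms$template, flip_lr(syms$template)),
             ncc_metric(asym$template, flip_lr(asym$template)))
})

test_that("modality transport warps images, labels and probabilities
           appropriately", {
  coh <- small_cohort()
  subs <- lapply(coh$subjects, `[[`, "image")
  labs <- lapply(coh$subjects, `[[`, "labels")
  res <- suppressWarnings(build_template(subs, iterations = 1,
                                         config = light_config()))
  # transporting each subject's own image reproduces its warped image
  imgs <- transport_modalities(subs, res)
  for (i in seq_along(subs))
    expect_gt(ncc_metric(imgs[[i]], res$warped[[i]]), 0.999)
  # labels stay integer with no new IDs
  tl <- transport_modalities(labs, res)
  for (i in seq_along(labs))
    expect_true(all(unique(as.vector(tl[[i]]$data)) %in%
                      c(0L, unique(as.vector(labs[[i]]$data)))))
  # probability stacks renormalize to 1 where occupied
  probs <- lapply(seq_along(subs), function(i) {
    on <- matrix(as.numeric(coh$subjects[[i]]$labels$data > 0), 64, 64)
    list(fg = image_volume(0.7 * on, subs[[i]]$spacing),
         bg = image_volume(0.3 * on, subs[[i]]$spacing))
  })
  tp <- transport_modalities(probs, res)
  tot <- tp[[1]]$fg$data + tp[[1]]$bg$data
  occ <- tot > 0
  expect_lt(max(abs(tot[occ] - 1)), 1e-6)
  # fused transported truth recovers the phantom parcellation
  fused <- majority_vote(tl)
  expect_gte(mean_dice(fused, coh$base$labels)$mean, 0.85)
  expect_error(transport_modalities(labs[1:2], res), "3 subjects")
})
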