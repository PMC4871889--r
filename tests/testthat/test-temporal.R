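# Temporal chain construction and label propagation.
# Uses a reduced 3-stage ladder at 64^2 so the whole file runs in well
# under a minute; the full-scale 6-stage analysis lives in the acceptance
# suite.

small_aging <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_aging_sequence(aging_sequence_spec(
        n_stages = 3, size = 64, scales = c(1, 0.95, 0.9),
        wm_intensities = c(0.9, 0.6, 0.3), seed = 3))
    cache
  }
})

test_that("a ladder of identical templates composes to near-identity", {
  ph <- tiny_phantom()
  seqv <- temporal_sequence(list(ph$image, ph$image, ph$image), c(2, 1, 0))
  chain <- suppressWarnings(build_temporal_chain(NULL, seqv, NULL,
                                                 light_config()))
  pts <- grid_pts(ph$image)
  interior <- interior_of(ph$image)
  mapped <- apply_transform_points(chain, pts[interior, ])
  expect_lte(max(sqrt(rowSums((mapped - pts[interior, ])^2))), 0.2)
  # identity-chain label transport leaves labels unchanged
  idchain <- concat_chain(list(
    composite_transform(identity_affine(2), target_space = "target",
                        source_space = "atlas")))
  moved <- propagate_atlas_labels(ph$labels, idchain,
                                  as_grid_geometry(ph$labels))
  expect_identical(moved$data, ph$labels$data)
})

test_that("a synthetic aging chain reaches the composed ground truth", {
  aging <- small_aging()
  chain <- suppressWarnings(build_temporal_chain(NULL, aging$sequence, NULL,
                                                 light_config("nmi")))
  tmn <- length(aging$sequence$templates)
  g <- as_grid_geometry(aging$sequence$templates[[tmn]])
  pts <- grid_pts(aging$sequence$templates[[tmn]])
  mask <- as.vector(aging$phantoms[[tmn]]$labels$data) > 0 &
    chronoatlas:::interior_mask(g$dim)
  est <- apply_transform_points(chain, pts[mask, ])
  tru <- pts[mask, ]
  for (s in rev(seq_len(tmn - 1)))
    tru <- apply_transform_points(aging$true_transforms[[s]], tru)
  err <- sqrt(rowSums((est - tru)^2))
  expect_lte(stats::median(err), 1)

  # label propagation: atlas = oldest stage's labels; chain must end there
  chain2 <- chain
  chain2$links[[length(chain2$links)]]$source_space <- "atlas"
  labs <- propagate_atlas_labels(aging$phantoms[[1]]$labels, chain2, g)
  expect_true(all(unique(as.vector(labs$data)) %in%
                    c(0L, unique(as.vector(aging$phantoms[[1]]$labels$data)))))
  d <- mean_dice(labs, aging$phantoms[[tmn]]$labels)
  expect_gte(d$mean, 0.80)
  # wrong terminal space is rejected
  expect_error(propagate_atlas_labels(aging$phantoms[[1]]$labels, chain, g),
               "atlas")
})

test_that("single-pass transport equals sequential coordinate mapping", {
  aging <- small_aging()
  chain <- suppressWarnings(build_temporal_chain(NULL, aging$sequence, NULL,
                                                 light_config("nmi")))
  g <- as_grid_geometry(aging$sequence$templates[[3]])
  pts <- grid_pts(aging$sequence$templates[[3]])
  # one-pass: map every voxel through the chain, sample once
  one_pass <- resample_labels(aging$phantoms[[1]]$labels, chain, g)
  seq_pts <- pts
  for (l in chain$links) seq_pts <- apply_transform_points(l, seq_pts)
  idx <- chronoatlas:::world_to_index(seq_pts,
                                      as_grid_geometry(aging$phantoms[[1]]$labels))
  sampled <- chronoatlas:::interp_at(aging$phantoms[[1]]$labels$data, idx,
                                     "nearest", fill = 0)
  expect_equal(as.vector(one_pass$data), sampled)
})

test_that("per-step NCC evaluation reports registered quality", {
  ph <- tiny_phantom()
  seqv <- temporal_sequence(list(ph$image, ph$image), c(1, 0))
  chain <- suppressWarnings(build_temporal_chain(NULL, seqv, NULL,
                                                 light_config()))
  cc <- evaluate_chain_cc(seqv, chain)
  expect_equal(cc$per_step$ncc, 1, tolerance = 1e-3)

  # identity (unregistered) links never beat the registered ones; NCC can
  # only reward alignment when the pair correlates positively at
  # registration, so this ladder keeps the gray/white ordering fixed
  aging <- make_aging_sequence(aging_sequence_spec(
    n_stages = 3, size = 64, scales = c(1, 0.95, 0.9),
    wm_intensities = c(0.9, 0.75, 0.6), seed = 3))
  chain2 <- suppressWarnings(build_temporal_chain(NULL, aging$sequence, NULL,
                                                  light_config("nmi")))
  cc2 <- evaluate_chain_cc(aging$sequence, chain2)
  idlinks <- lapply(seq_len(2), function(s)
    composite_transform(identity_affine(2),
                        target_space = paste0("stage_", 4 - s),
                        source_space = paste0("stage_", 3 - s)))
  cc_id <- evaluate_chain_cc(aging$sequence, concat_chain(idlinks))
  expect_true(all(cc2$per_step$ncc >= cc_id$per_step$ncc))
})

test_that("propagated-label overlap degrades as stage deformation grows", {
  # growth modeled as scaling: a steeper schedule must not fuse better
  mk <- function(final_scale) {
    aging <- make_aging_sequence(aging_sequence_spec(
      n_stages = 3, size = 64, scales = c(1, (1 + final_scale) / 2,
                                          final_scale),
      wm_intensities = c(0.9, 0.6, 0.3), seed = 3))
    chain <- suppressWarnings(build_temporal_chain(NULL, aging$sequence,
                                                   NULL, light_config("nmi")))
    chain$links[[length(chain$links)]]$source_space <- "atlas"
    g <- as_grid_geometry(aging$sequence$templates[[3]])
    labs <- propagate_atlas_labels(aging$phantoms[[1]]$labels, chain, g)
    mean_dice(labs, aging$phantoms[[3]]$labels)$mean
  }
  mild <- mk(0.95)
  severe <- mk(0.75)
  expect_gte(mild, severe - 0.02)   # allow voxelization jitter, not reversal
})
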