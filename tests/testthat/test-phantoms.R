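# Synthetic generator: determinism, ground-truth contracts.

test_that("phantom geometry, laterality and determinism behave as specified", {
  expect_error(make_phantom(32), "at least 48")
  ph <- make_phantom(64)
  # laterality 1 -> mirror symmetric, S = 0 for every pair
  expect_true(all(asymmetry_report(ph$labels, ph$scheme)$S == 0))
  # laterality 2 on one pair -> true S = 2/3 for that pair; the enlarged
  # blob is carved out of the white-matter core, which therefore inherits
  # a small complementary asymmetry, while the other pairs stay exact
  ph2 <- make_phantom(96, laterality = c(blob_b = 2))
  rep2 <- asymmetry_report(ph2$labels, ph2$scheme)
  expect_equal(rep2$S[rep2$region == "blob_b"], 2 / 3, tolerance = 0.02)
  other_blobs <- setdiff(grep("blob", rep2$region, value = TRUE), "blob_b")
  expect_true(all(rep2$S[rep2$region %in% c(other_blobs, "gm_ribbon")] == 0))
  expect_error(make_phantom(64, laterality = c(nope = 2)), "unknown")
  # bit-identical under repetition
  expect_identical(make_phantom(64)$image$data, ph$image$data)
  expect_identical(make_phantom(64)$labels$data, ph$labels$data)
  # five named landmarks
  expect_equal(nrow(ph$landmarks), 5)
  expect_false(anyDuplicated(rownames(ph$landmarks)) > 0)
})

test_that("cohort generation retains valid truths", {
  spec <- synthetic_cohort_spec(3, 64, deformation_amplitude = 0,
                                noise_sd = 0, bias_amplitude = 0, seed = 5)
  coh <- make_cohort(spec)
  for (s in coh$subjects)
    expect_lt(max(abs(s$image$data - coh$base$image$data)), 1e-9)
  spec2 <- synthetic_cohort_spec(3, 64, deformation_amplitude = 3, seed = 5)
  coh2 <- make_cohort(spec2)
  for (s in coh2$subjects) {
    jd <- jacobian_determinant(s$transform$local)$data
    expect_gt(min(jd[chronoatlas:::interior_mask(c(64, 64))]), 0)
    expect_true(all(unique(as.vector(s$labels$data)) %in%
                      c(0L, unique(as.vector(coh2$base$labels$data)))))
  }
  # determinism of the full cohort
  coh2b <- make_cohort(spec2)
  expect_identical(coh2$subjects[[2]]$image$data, coh2b$subjects[[2]]$image$data)
  # true landmarks satisfy T(landmark_subject) = landmark_phantom
  s1 <- coh2$subjects[[1]]
  mapped <- apply_transform_points(s1$transform, unclass(s1$landmarks))
  expect_lt(max(abs(mapped - unclass(coh2$base$landmarks))), 0.1)
})

test_that("mean true displacement shrinks roughly as 1/sqrt(n)", {
  field_mean_norm <- function(n, seed) {
    spec <- synthetic_cohort_spec(n, 64, 3, 4, noise_sd = 0,
                                  bias_amplitude = 0, seed = seed)
    coh <- make_cohort(spec)
    acc <- 0
    for (s in coh$subjects) acc <- acc + s$transform$local$vectors
    mean(sqrt(rowSums(matrix(acc / n, ncol = 2)^2)))
  }
  small <- mean(vapply(1:3, function(sd) field_mean_norm(2, 20 + sd), 0))
  large <- mean(vapply(1:3, function(sd) field_mean_norm(8, 40 + sd), 0))
  expect_lt(large, small)                 # more subjects -> smaller mean field
})

test_that("aging sequences shrink, invert contrast once, and stay similar
           between neighbours", {
  spec <- aging_sequence_spec(n_stages = 5, size = 64)
  aging <- make_aging_sequence(spec)
  tm <- aging$sequence$templates
  expect_length(tm, 5)
  expect_length(aging$true_transforms, 4)
  # WM/GM intensity ordering flips exactly once along the schedule
  ord <- sign(spec$wm_intensities - spec$gm_intensity)
  expect_equal(sum(diff(ord) != 0), 1)
  # NMI between adjacent stages >= NMI between the ends
  adj <- nmi_metric(tm[[1]], tm[[2]])
  ends <- nmi_metric(tm[[1]], tm[[5]])
  expect_gte(adj, ends)
  # single-stage degenerate case
  one <- make_aging_sequence(aging_sequence_spec(n_stages = 1, size = 64))
  expect_length(one$true_transforms, 0)
  expect_length(one$sequence$templates, 1)
  # monotone scales enforced
  expect_error(aging_sequence_spec(n_stages = 3, scales = c(1, 1.1, 0.9)))
})

test_that("bump deformations carry exact inverse-consistent truths", {
  ph <- tiny_phantom()
  b <- make_bump_deformation(ph, seed = 3)
  jd <- jacobian_determinant(b$transform$local)$data
  expect_gt(min(jd[interior_of(ph$image)]), 0)
  mapped <- apply_transform_points(b$transform, unclass(b$landmarks))
  expect_lt(max(abs(mapped - unclass(ph$landmarks))), 0.1)
  b2 <- make_bump_deformation(ph, seed = 3)
  expect_identical(b$image$data, b2$image$data)
})
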