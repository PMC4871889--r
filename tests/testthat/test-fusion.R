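# Majority voting, left-right operations, volumetry, asymmetry.

test_that("label schemes enforce the partner involution", {
  df <- data.frame(id = c(1L, 2L, 3L),
                   name = c("a_left", "a_right", "mid"),
                   hemisphere = c("left", "right", "none"),
                   partner_id = c(2L, 1L, NA))
  expect_s3_class(label_scheme(df), "label_scheme")
  bad <- df; bad$partner_id <- c(2L, 3L, 2L)
  expect_error(label_scheme(bad), "involution")
  same_side <- df; same_side$hemisphere <- c("left", "left", "none")
  expect_error(label_scheme(same_side), "opposite")
  expect_error(label_scheme(data.frame(id = 1, name = "x",
                                       hemisphere = "left", partner_id = 9)),
               "not in the scheme")
})

test_that("majority vote agrees exactly with the counting oracle", {
  m1 <- label_map(matrix(c(5L, 5L, 7L, 0L), 2, 2))
  expect_identical(majority_vote(list(m1)), m1)
  expect_identical(majority_vote(list(m1, m1, m1))$data, m1$data)
  # explicit {5, 5, 7} vote
  m2 <- label_map(matrix(c(5L, 7L, 7L, 1L), 2, 2))
  m3 <- label_map(matrix(c(7L, 5L, 5L, 1L), 2, 2))
  fused <- majority_vote(list(m1, m2, m3))
  expect_equal(fused$data[1, 1], 5L)
  # random stacks, including ties, exact agreement with brute force
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(2:7, 1)
    maps <- lapply(seq_len(n), function(i)
      label_map(matrix(sample(0:4, 32 * 32, replace = TRUE), 32, 32)))
    expect_identical(majority_vote(maps)$data, counting_oracle(maps)$data)
  }
  expect_error(majority_vote(list()), "at least one")
  off <- label_map(matrix(0L, 32, 16))
  expect_error(majority_vote(list(label_map(matrix(0L, 32, 32)), off)),
               "grid")
})

test_that("left-right flip with partner swap is an involution that
           exchanges voxel counts", {
  ph <- tiny_phantom()
  scheme <- ph$scheme
  flipped <- flip_labels_lr(ph$labels, scheme)
  expect_identical(flip_labels_lr(flipped, scheme)$data, ph$labels$data)
  pairs <- chronoatlas:::scheme_pairs(scheme)
  for (i in seq_len(nrow(pairs))) {
    expect_equal(sum(flipped$data == pairs$right_id[i]),
                 sum(ph$labels$data == pairs$left_id[i]))
    expect_equal(sum(flipped$data == pairs$left_id[i]),
                 sum(ph$labels$data == pairs$right_id[i]))
  }
  # hemispheric label without partner -> named rejection
  orphan <- label_scheme(data.frame(id = 30L, name = "midline_bar",
                                    hemisphere = "none",
                                    partner_id = NA_integer_))
  only21 <- label_map(matrix(c(21L, 0L, 0L, 0L), 2, 2))
  sch2 <- label_scheme(data.frame(id = c(21L), name = "blob",
                                  hemisphere = "none",
                                  partner_id = NA_integer_))
  expect_identical(sort(unique(as.vector(
    flip_labels_lr(only21, sch2)$data))), c(0L, 21L))
  expect_error(flip_labels_lr(only21, orphan), "21")
})

test_that("asymmetry coefficient follows its closed form", {
  expect_equal(asymmetry_coefficient(3, 3), 0)
  expect_equal(asymmetry_coefficient(5, 0), 2)
  # reported amygdala means: V_L 0.76, V_R 0.65 -> 0.15603 (5 d.p.)
  expect_equal(round(asymmetry_coefficient(0.76, 0.65), 5), 0.15603)
  # scale invariance
  for (k in c(0.1, 2, 1000))
    expect_equal(asymmetry_coefficient(k * 0.76, k * 0.65),
                 asymmetry_coefficient(0.76, 0.65))
  expect_true(is.na(asymmetry_coefficient(0, 0)))
  expect_error(asymmetry_coefficient(-1, 2), "non-negative")
})

test_that("region volumes are exact and conserve the grid volume", {
  arr <- array(0L, dim = c(20, 20, 20))
  arr[1:10, 1:10, 1:10] <- 3L
  lm <- label_map(arr, spacing = 1)
  v <- region_volumes(lm)
  expect_equal(v$volume_cm3[v$label == 3], 1)   # 1000 mm^3 = 1 cm^3
  vb <- region_volumes(lm, include_background = TRUE)
  expect_equal(sum(vb$volume_cm3), prod(dim(arr)) * 1 / 1000)
  # brute-force per-label count oracle on a random map
  set.seed(8)
  rm <- label_map(matrix(sample(0:5, 900, replace = TRUE), 30, 30),
                  spacing = c(2, 0.5))
  v2 <- region_volumes(rm, include_background = TRUE)
  for (i in seq_len(nrow(v2)))
    expect_equal(v2$volume_cm3[i],
                 sum(rm$data == v2$label[i]) * 2 * 0.5 / 1000)
  # cohort mode: mean/sd across subjects
  cohort <- region_volumes(list(lm, lm))
  expect_equal(cohort$sd_cm3[cohort$label == 3], 0)
  expect_equal(cohort$mean_cm3[cohort$label == 3], 1)
})

test_that("lobar ICV proportions match hand counts", {
  scheme <- label_scheme(data.frame(
    id = c(1L, 2L, 3L), name = c("a", "b", "c"),
    hemisphere = "none", partner_id = NA_integer_,
    lobe = c("front", "front", "back")))
  arr <- matrix(0L, 10, 10)
  arr[1:5, ] <- 1L; arr[6:8, ] <- 2L; arr[9, ] <- 3L
  labs <- label_map(arr)
  mask <- label_map(matrix(1L, 10, 10))
  p <- icv_proportions(labs, mask, scheme)
  expect_equal(p$percent_icv[p$lobe == "front"], 80)
  expect_equal(p$percent_icv[p$lobe == "back"], 10)
  expect_lte(sum(p$percent_icv), 100)
  # one lobe covering the whole mask
  all1 <- label_map(matrix(1L, 10, 10))
  expect_equal(icv_proportions(all1, mask, scheme)$percent_icv, 100)
  expect_error(icv_proportions(labs, label_map(matrix(0L, 10, 10)), scheme),
               "empty mask")
})

test_that("asymmetry reports match per-pair manual computation", {
  ph <- make_phantom(64)                       # laterality 1 -> symmetric
  rep0 <- asymmetry_report(ph$labels, ph$scheme)
  expect_true(all(rep0$S == 0))
  ph2 <- make_phantom(96, laterality = c(blob_a = 2))
  rep2 <- asymmetry_report(ph2$labels, ph2$scheme)
  sa <- rep2$S[rep2$region == "blob_a"]
  expect_equal(sa, 2 / 3, tolerance = 0.02)    # 2:1 volume ratio up to voxelization
  # manual recomputation on a random map
  set.seed(9)
  rnd <- label_map(matrix(sample(c(0L, 21L, 22L, 23L, 24L), 400,
                                 replace = TRUE), 20, 20))
  repr <- asymmetry_report(rnd, ph$scheme)
  vl <- sum(rnd$data == 21L); vr <- sum(rnd$data == 22L)
  expect_equal(repr$S[repr$region == "blob_a"],
               2 * abs(vl - vr) / (vl + vr))
})
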