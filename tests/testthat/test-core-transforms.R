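# Containers, point mapping, chain composition, inversion, Jacobians.

test_that("container constructors enforce their invariants", {
  expect_error(image_volume(array(1, dim = c(4, 4, 4, 4))), "rank")
  expect_error(image_volume(matrix(c(1, NA, 3, 4), 2, 2)), "finite")
  expect_error(image_volume(matrix(1, 4, 4), spacing = c(1, -1)), "spacing")
  expect_error(label_map(matrix(c(0.5, 1, 2, 3), 2, 2)), "integer")
  expect_error(label_map(matrix(c(-1L, 1L, 2L, 3L), 2, 2)), "non-negative")
  expect_error(affine_transform(matrix(0, 2, 2)), "singular")
  expect_error(displacement_field(array(Inf, dim = c(4, 4, 2))), "finite")
})

test_that("apply_transform_points follows the affine-plus-displacement rule", {
  # identity and pure translation
  expect_equal(as.vector(apply_transform_points(identity_affine(2), c(3, 4))),
               c(3, 4))
  tr <- affine_transform(diag(2), c(2, 0))
  expect_equal(as.vector(apply_transform_points(tr, c(3, 4))), c(5, 4))
  # affine scale 2 with constant field (+1, +1): 2*(1,1) + (1,1) = (3,3)
  f <- zero_field(grid_geometry(c(8, 8)))
  f$vectors[] <- 1
  comp <- composite_transform(affine_transform(diag(2, 2)), f)
  expect_equal(as.vector(apply_transform_points(comp, c(1, 1))), c(3, 3))
})

test_that("points outside the field domain get the global part and a flag", {
  f <- zero_field(grid_geometry(c(8, 8)))
  f$vectors[] <- 1
  comp <- composite_transform(identity_affine(2), f)
  out <- apply_transform_points(comp, rbind(c(3, 3), c(20, 3)))
  expect_equal(attr(out, "outside"), c(FALSE, TRUE))
  expect_equal(out[2, ], c(20, 3))   # global-only fallback
})

test_that("chains require compatible adjacent spaces and evaluate in order", {
  t1 <- composite_transform(affine_transform(diag(2), c(1, 0)),
                            target_space = "t", source_space = "a")
  t2 <- composite_transform(affine_transform(diag(2), c(0, 2)),
                            target_space = "a", source_space = "s")
  ch <- concat_chain(list(t1, t2))
  expect_equal(as.vector(apply_transform_points(ch, c(0, 0))), c(1, 2))
  ids <- replicate(3, composite_transform(identity_affine(2)),
                   simplify = FALSE)
  expect_equal(as.vector(apply_transform_points(concat_chain(ids), c(5, -2))),
               c(5, -2))
  bad <- composite_transform(identity_affine(2),
                             target_space = "x", source_space = "y")
  expect_error(concat_chain(list(t1, bad)), "'a'.*'x'")
})

test_that("chain evaluation equals brute-force sequential link evaluation", {
  g <- grid_geometry(c(24, 24))
  set.seed(7)
  links <- lapply(1:4, function(k)
    composite_transform(identity_affine(2),
                        random_smooth_field(g, 1.5, 3, 100 + k)))
  ch <- concat_chain(links)
  pts <- matrix(runif(200, 4, 19), ncol = 2)
  via_chain <- apply_transform_points(ch, pts)
  seq_pts <- pts
  for (l in links) seq_pts <- apply_transform_points(l, seq_pts)
  expect_lt(max(abs(via_chain - seq_pts)), 1e-6)
})

test_that("invert_displacement satisfies the composition contract", {
  g <- grid_geometry(c(32, 32))
  z <- zero_field(g)
  expect_equal(invert_displacement(z)$vectors, z$vectors)
  # constant translation inverts to its negation away from the boundary
  tfield <- zero_field(g)
  tfield$vectors[, , 1] <- 1.5
  inv <- invert_displacement(tfield, tol = 1e-6)
  expect_lt(max(abs(inv$vectors[8:24, 8:24, 1] + 1.5)), 1e-6)
  # random smooth field: residual of f o f^-1 below tolerance
  f <- random_smooth_field(grid_geometry(c(48, 48)), 2, 4, 5)
  finv <- invert_displacement(f, tol = 0.05)
  pts <- grid_pts(f)
  interior <- chronoatlas:::interior_mask(c(48, 48))
  resid <- chronoatlas:::field_at_points(f, pts + matrix(finv$vectors,
                                                         ncol = 2),
                                         clamp = TRUE) +
    matrix(finv$vectors, ncol = 2)
  expect_lte(max(sqrt(rowSums(resid[interior, ]^2))), 0.05)
})

test_that("jacobian determinants match analytic and oracle values", {
  g <- grid_geometry(c(24, 24))
  expect_equal(jacobian_determinant(zero_field(g))$data,
               array(1, dim = c(24, 24)))
  # uniform linear scaling by s: id + f with f = (s-1) x has det s^d
  s <- 1.3
  pts <- grid_pts(zero_field(g))
  f <- displacement_field(array((s - 1) * pts, dim = c(24, 24, 2)))
  jd <- jacobian_determinant(f)$data
  expect_lt(max(abs(jd - s^2)), 1e-9)
  # independent finite-difference oracle on a random smooth field
  f <- random_smooth_field(grid_geometry(c(20, 20)), 1.5, 3, 9)
  jd <- jacobian_determinant(f)$data
  oracle <- array(NA_real_, dim = c(20, 20))
  fx <- f$vectors[, , 1]; fy <- f$vectors[, , 2]
  for (i in 2:19) for (j in 2:19) {
    j11 <- 1 + (fx[i + 1, j] - fx[i - 1, j]) / 2
    j12 <- (fx[i, j + 1] - fx[i, j - 1]) / 2
    j21 <- (fy[i + 1, j] - fy[i - 1, j]) / 2
    j22 <- 1 + (fy[i, j + 1] - fy[i, j - 1]) / 2
    oracle[i, j] <- j11 * j22 - j12 * j21
  }
  expect_lt(max(abs(jd[2:19, 2:19] - oracle[2:19, 2:19])), 1e-8)
})

test_that("velocity exponentials are diffeomorphic and invertible", {
  v <- random_smooth_field(grid_geometry(c(48, 48)), 3, 4, 21)
  s <- chronoatlas:::exp_velocity(v)
  expect_gt(min(jacobian_determinant(s)$data[interior_of(
    image_volume(s$vectors[, , 1]))]), 0)
  s_inv <- chronoatlas:::exp_velocity(chronoatlas:::negate_field(v))
  pts <- grid_pts(s)
  # away from the border band, where composition must extrapolate the field
  deep <- rowSums(pts >= 4 & pts <= 43) == 2
  fwd <- pts + matrix(s$vectors, ncol = 2)
  back <- fwd + chronoatlas:::field_at_points(s_inv, fwd, clamp = TRUE)
  expect_lt(max(sqrt(rowSums((back - pts)[deep, ]^2))), 0.1)
})
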