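# Interpolation and resampling machinery.
#
# All samplers take continuous 0-based voxel index coordinates.  The image
# domain is the convex hull of voxel centres, [0, dim-1] per axis; samples
# outside it return the fill value.  Intensity resampling uses cubic
# B-spline interpolation (with the standard recursive prefilter, so grid
# values are reproduced exactly and polynomials up to cubic are represented
# exactly); label resampling uses nearest neighbour with the documented
# tie rule (an exact .5 fractional index rounds toward the lower index).

#' @keywords internal
bspline_weights <- function(t) {
  # cubic B-spline basis at offsets -1..2 for fractional position t in [0,1)
  t2 <- t * t; t3 <- t2 * t
  list(w0 = (1 - 3 * t + 3 * t2 - t3) / 6,
       w1 = (4 - 6 * t2 + 3 * t3) / 6,
       w2 = (1 + 3 * t + 3 * t2 - 3 * t3) / 6,
       w3 = t3 / 6)
}

# mirror (reflect-without-repeat) an integer index into [0, n-1]
mirror_index <- function(i, n) {
  if (n == 1) return(rep(0L, length(i)))
  p <- 2L * (n - 1L)
  i <- abs(i) %% p
  ifelse(i >= n, p - i, i)
}

# recursive causal/anticausal prefilter for cubic B-spline coefficients,
# applied along the first dimension of a matrix (columns are lines)
prefilter_lines <- function(x) {
  z <- sqrt(3) - 2
  n <- nrow(x)
  if (n < 2) return(x)
  x <- x * 6
  horizon <- min(n, ceiling(log(1e-12) / log(abs(z))))
  zi <- z^(seq_len(horizon) - 1)
  cp <- x
  cp[1, ] <- as.vector(zi %*% x[seq_len(horizon), , drop = FALSE])
  for (i in 2:n) cp[i, ] <- x[i, ] + z * cp[i - 1, ]
  cm <- cp
  cm[n, ] <- (z / (z * z - 1)) * (cp[n, ] + z * cp[n - 1, ])
  for (i in (n - 1):1) cm[i, ] <- z * (cm[i + 1, ] - cp[i, ])
  cm
}

apply_along_axis <- function(arr, axis, fn) {
  d <- dim(arr)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  m <- fn(m)
  a <- array(m, dim = d[perm])
  aperm(a, order(perm))
}

bspline_coefficients <- function(arr) {
  for (k in seq_along(dim(arr)))
    arr <- apply_along_axis(arr, k, prefilter_lines)
  arr
}

#' Sample an array at arbitrary continuous index coordinates
#'
#' Low-level sampler used by every resampling operation.
#'
#' @param arr Numeric array (rank 2 or 3).
#' @param idx n x rank matrix of continuous 0-based voxel indices.
#' @param method One of `"linear"`, `"nearest"`, `"bspline"`.
#' @param fill Value returned outside the domain (default 0).
#' @param coef Optional precomputed [bspline_coefficients()] of `arr`,
#'   reused across calls for speed.
#' @return Numeric vector of length `nrow(idx)`.
#' @keywords internal
#' @export
interp_at <- function(arr, idx, method = c("linear", "nearest", "bspline"),
                      fill = 0, coef = NULL) {
  method <- match.arg(method)
  dm <- dim(arr)
  d <- length(dm)
  idx <- rbind(idx)
  n <- nrow(idx)
  inside <- rep(TRUE, n)
  for (k in seq_len(d))
    inside <- inside & idx[, k] >= 0 & idx[, k] <= dm[k] - 1
  out <- rep(fill, n)
  if (!any(inside)) return(out)

  if (method == "nearest") {
    lin <- rep(1, n)
    mult <- 1
    for (k in seq_len(d)) {
      ik <- ceiling(idx[, k] - 0.5)        # half rounds toward lower index
      ik <- pmin(pmax(ik, 0), dm[k] - 1)
      lin <- lin + ik * mult
      mult <- mult * dm[k]
    }
    out[inside] <- arr[lin[inside]]
    return(out)
  }

  if (method == "linear") {
    i0 <- w <- matrix(0, n, d)
    for (k in seq_len(d)) {
      ik <- pmin(pmax(floor(idx[, k]), 0), max(dm[k] - 2, 0))
      i0[, k] <- ik
      w[, k] <- idx[, k] - ik
    }
    val <- numeric(n)
    for (corner in 0:(2^d - 1)) {
      lin <- rep(1, n)
      wt <- rep(1, n)
      mult <- 1
      for (k in seq_len(d)) {
        on <- bitwAnd(corner, bitwShiftL(1L, k - 1L)) > 0
        lin <- lin + (i0[, k] + as.numeric(on)) * mult
        mult <- mult * dm[k]
        wt <- wt * (if (on) w[, k] else 1 - w[, k])
      }
      val <- val + wt * arr[lin]
    }
    out[inside] <- val[inside]
    return(out)
  }

  # cubic B-spline
  if (is.null(coef)) coef <- bspline_coefficients(arr)
  i0 <- floor(idx)
  tfrac <- idx - i0
  wts <- vector("list", d)
  for (k in seq_len(d)) wts[[k]] <- bspline_weights(tfrac[, k])
  val <- numeric(n)
  offs <- -1:2
  # accumulate over the 4^d tap stencil with mirrored indices
  tap_lin <- vector("list", d)
  tap_wt <- vector("list", d)
  for (k in seq_len(d)) {
    tl <- tw <- vector("list", 4)
    for (j in 1:4) {
      tl[[j]] <- mirror_index(i0[, k] + offs[j], dm[k])
      tw[[j]] <- wts[[k]][[j]]
    }
    tap_lin[[k]] <- tl
    tap_wt[[k]] <- tw
  }
  mults <- cumprod(c(1, dm[-d]))
  rec <- function(k, lin, wt) {
    if (k > d) {
      val <<- val + wt * coef[lin]
      return(invisible())
    }
    for (j in 1:4)
      rec(k + 1, lin + tap_lin[[k]][[j]] * mults[k], wt * tap_wt[[k]][[j]])
  }
  rec(1, rep(1, n), rep(1, n))
  out[inside] <- val[inside]
  out
}

# --- Gaussian smoothing -----------------------------------------------------

gaussian_kernel_1d <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  if (sigma <= 0) return(1)
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# banded smoothing matrix with renormalised (reflect-free) truncation at edges
smoothing_matrix <- function(n, sigma) {
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1) / 2
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1, i - r):min(n, i + r)
    K[i, j] <- k[j - i + r + 1]
    K[i, j] <- K[i, j] / sum(K[i, j])
  }
  K
}

#' Separable Gaussian smoothing of an array
#' @param arr Numeric array, rank 2 or 3.
#' @param sigma Standard deviation in voxels, scalar or per-axis.
#' @return Smoothed array of the same dimensions.
#' @keywords internal
smooth_array <- function(arr, sigma) {
  d <- dim(arr)
  sigma <- rep_len(sigma, length(d))
  for (k in seq_along(d)) {
    if (sigma[k] <= 0) next
    K <- smoothing_matrix(d[k], sigma[k])
    arr <- apply_along_axis(arr, k, function(m) K %*% m)
  }
  arr
}

# downsample an image/array by factor 2 with Gaussian anti-aliasing
downsample_image <- function(img, sigma = 0.85) {
  d <- grid_dim(img)
  sm <- smooth_array(img$data, sigma)
  keep <- lapply(d, function(n) seq(1, n, by = 2))
  sub <- if (length(d) == 2) sm[keep[[1]], keep[[2]], drop = FALSE]
         else sm[keep[[1]], keep[[2]], keep[[3]], drop = FALSE]
  image_volume(sub, spacing = img$spacing * 2, origin = img$origin)
}

# --- Resampling -------------------------------------------------------------

#' Resample an intensity image through a spatial transform
#'
#' Pulls source intensities onto a target grid: each target voxel's world
#' coordinate is mapped through `transform` into source space and the source
#' image is sampled there by cubic B-spline interpolation.  Voxels mapping
#' outside the source domain are filled with 0.
#'
#' @param src Source [image_volume()].
#' @param transform An `affine_transform`, `composite_transform` or
#'   `transform_chain` mapping target coordinates to source coordinates
#'   (pull-back convention); `NULL` means identity.
#' @param target_grid A [grid_geometry()] or any object a grid can be
#'   derived from (defaults to the source grid).
#' @param method Interpolator, default `"bspline"`; `"linear"` is used
#'   internally for probability maps.
#' @return An [image_volume()] on the target grid.
#' @export
resample_intensity <- function(src, transform = NULL,
                               target_grid = as_grid_geometry(src),
                               method = c("bspline", "linear", "nearest")) {
  stopifnot(inherits(src, "image_volume"))
  method <- match.arg(method)
  grid <- as_grid_geometry(target_grid)
  if (any(grid$dim < 2))
    stop("resample_intensity: degenerate target grid")
  pts <- grid_world_coords(grid)
  mapped <- if (is.null(transform)) pts else apply_transform_points(transform, pts)
  idx <- world_to_index(mapped, as_grid_geometry(src))
  vals <- interp_at(src$data, idx, method = method, fill = 0)
  image_volume(array(vals, dim = grid$dim), grid$spacing, grid$origin)
}

#' Resample a label map through a spatial transform
#'
#' Nearest-neighbour transport of integer labels so that no new label IDs
#' can be introduced.  Exact half-voxel ties round toward the lower index.
#'
#' @param src Source [label_map()].
#' @inheritParams resample_intensity
#' @return A [label_map()] on the target grid; its label set is a subset of
#'   the source labels plus background 0.
#' @export
resample_labels <- function(src, transform = NULL,
                            target_grid = as_grid_geometry(src)) {
  stopifnot(inherits(src, "label_map"))
  grid <- as_grid_geometry(target_grid)
  if (any(grid$dim < 2))
    stop("resample_labels: degenerate target grid")
  pts <- grid_world_coords(grid)
  mapped <- if (is.null(transform)) pts else apply_transform_points(transform, pts)
  idx <- world_to_index(mapped, as_grid_geometry(src))
  vals <- interp_at(src$data, idx, method = "nearest", fill = 0)
  label_map(array(as.integer(vals), dim = grid$dim), grid$spacing, grid$origin)
}
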