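# Spatial transforms.
#
# Every transform follows the pull-back convention: it maps coordinates of a
# "target" space into a "source" space, so that source values can be sampled
# onto the target grid.  A composite transform T is evaluated literally as
# T(x) = A x + t + D(x): the displacement field D lives on the target grid
# and is added after the affine part, with linear interpolation of D between
# its grid nodes.

#' Affine transform
#'
#' Linear map plus translation in physical coordinates: `x -> M x + t`.
#'
#' @param matrix rank x rank matrix; must be invertible.
#' @param translation Translation vector (mm).
#' @return An `affine_transform`.
#' @export
affine_transform <- function(matrix, translation = rep(0, nrow(matrix))) {
  matrix <- as.matrix(matrix)
  d <- nrow(matrix)
  stopifnot(ncol(matrix) == d, length(translation) == d)
  if (abs(det(matrix)) < 1e-10)
    stop("affine_transform: matrix is singular (|det| < 1e-10)")
  structure(list(matrix = matrix, translation = as.numeric(translation)),
            class = "affine_transform")
}

#' @rdname affine_transform
#' @param rank Spatial rank (2 or 3).
#' @export
identity_affine <- function(rank) affine_transform(diag(rank))

#' Invert an affine transform
#' @param a An `affine_transform`.
#' @return The inverse `affine_transform`.
#' @export
invert_affine <- function(a) {
  Mi <- solve(a$matrix)
  affine_transform(Mi, -as.vector(Mi %*% a$translation))
}

#' Dense displacement field
#'
#' Vector field on a reference grid; `vectors` has one more dimension than
#' the grid, the last axis indexing the displacement components (mm).
#'
#' @param vectors Array of dim `c(grid, rank)`.
#' @param spacing,origin Grid geometry, as in [image_volume()].
#' @return A `displacement_field`.
#' @export
displacement_field <- function(vectors,
                               spacing = rep(1, length(dim(vectors)) - 1),
                               origin = rep(0, length(dim(vectors)) - 1)) {
  vectors <- as.array(vectors)
  nd <- length(dim(vectors)) - 1L
  if (!(nd %in% c(2L, 3L)) || dim(vectors)[nd + 1L] != nd)
    stop("displacement_field: vectors must have dim c(grid, rank), rank 2 or 3")
  if (!all(is.finite(vectors)))
    stop("displacement_field: all components must be finite")
  structure(list(vectors = vectors,
                 spacing = rep_len(as.numeric(spacing), nd),
                 origin = rep_len(as.numeric(origin), nd)),
            class = "displacement_field")
}

negate_field <- function(f) {
  f$vectors <- -f$vectors
  f
}

zero_field <- function(grid) {
  grid <- as_grid_geometry(grid)
  d <- length(grid$dim)
  displacement_field(array(0, dim = c(grid$dim, d)), grid$spacing, grid$origin)
}

field_component <- function(f, k) {
  d <- dim(f$vectors)
  nd <- length(d) - 1L
  if (nd == 2) f$vectors[, , k] else f$vectors[, , , k]
}

`field_component<-` <- function(f, k, value) {
  nd <- length(dim(f$vectors)) - 1L
  if (nd == 2) f$vectors[, , k] <- value else f$vectors[, , , k] <- value
  f
}

# sample displacement vectors (mm) at world points; outside the field domain
# the displacement is 0 (clamp = FALSE) or taken at the clamped index
# (clamp = TRUE, used when composing a field with itself)
field_at_points <- function(f, pts, clamp = FALSE) {
  grid <- as_grid_geometry(f)
  idx <- world_to_index(pts, grid)
  d <- length(grid$dim)
  if (clamp)
    for (k in seq_len(d))
      idx[, k] <- pmin(pmax(idx[, k], 0), grid$dim[k] - 1)
  out <- matrix(0, nrow(idx), d)
  for (k in seq_len(d))
    out[, k] <- interp_at(field_component(f, k), idx, method = "linear", fill = 0)
  out
}

max_displacement_voxels <- function(f) {
  d <- length(f$spacing)
  m <- 0
  for (k in seq_len(d))
    m <- max(m, max(abs(field_component(f, k))) / f$spacing[k])
  m
}

# displacement of (id + a) o (id + b) at the grid nodes of b:
# x -> x + b(x) + a(x + b(x))
compose_fields <- function(a, b, clamp = TRUE) {
  grid <- as_grid_geometry(b)
  pts <- grid_world_coords(grid)
  db <- matrix(as.vector(b$vectors), ncol = length(grid$dim))
  da <- field_at_points(a, pts + db, clamp = clamp)
  displacement_field(array(db + da, dim = dim(b$vectors)),
                     grid$spacing, grid$origin)
}

# exponential of a stationary velocity field by scaling and squaring;
# guarantees a diffeomorphic (positive-Jacobian) displacement for smooth v
exp_velocity <- function(v, steps = NULL) {
  mv <- max_displacement_voxels(v)
  if (mv == 0) return(v)
  n <- if (is.null(steps)) max(0L, ceiling(log2(mv / 0.25))) else steps
  n <- min(n, 14L)
  u <- v
  u$vectors <- u$vectors / 2^n
  for (i in seq_len(n)) u <- compose_fields(u, u)
  u
}

#' Composite transform (affine plus displacement field)
#'
#' @param global An `affine_transform`.
#' @param local A `displacement_field` on the target grid, or `NULL`.
#' @param target_space,source_space Optional space names used to validate
#'   chain concatenation.
#' @return A `composite_transform`.
#' @export
composite_transform <- function(global, local = NULL,
                                target_space = NA_character_,
                                source_space = NA_character_) {
  stopifnot(inherits(global, "affine_transform"))
  if (!is.null(local)) stopifnot(inherits(local, "displacement_field"))
  structure(list(global = global, local = local,
                 target_space = target_space, source_space = source_space),
            class = "composite_transform")
}

as_composite <- function(t) {
  if (inherits(t, "composite_transform")) return(t)
  if (inherits(t, "affine_transform")) return(composite_transform(t))
  stop("cannot convert class ", paste(class(t), collapse = "/"),
       " to composite_transform")
}

#' Ordered chain of composite transforms
#'
#' Concatenates registrations spanning several intermediate spaces into one
#' mapping.  Evaluation applies the links in order (first link first), so a
#' chain annotated target->A, A->B, B->source maps target coordinates all
#' the way to source coordinates.
#'
#' @param links List of `composite_transform` (or `affine_transform`)
#'   objects, each optionally annotated with target/source space names.
#' @return A `transform_chain`.
#' @export
concat_chain <- function(links) {
  links <- lapply(links, as_composite)
  if (length(links) == 0) stop("concat_chain: empty chain")
  for (k in seq_len(length(links) - 1)) {
    src <- links[[k]]$source_space
    tgt <- links[[k + 1]]$target_space
    if (!is.na(src) && !is.na(tgt) && src != tgt)
      stop("concat_chain: link ", k, " maps into space '", src,
           "' but link ", k + 1, " expects space '", tgt, "'")
  }
  structure(list(links = links), class = "transform_chain")
}

#' Map physical points through a transform
#'
#' Evaluates an affine, composite or chained transform at a set of points.
#' For a composite transform the result is `M x + t + D(x)`; points outside
#' the displacement field's domain receive the global part only and are
#' flagged in the `"outside"` attribute of the result.
#'
#' @param transform `affine_transform`, `composite_transform` or
#'   `transform_chain`.
#' @param pts n x rank matrix of points (mm); a single point may be given
#'   as a vector.
#' @return n x rank matrix of mapped points, with attribute `"outside"`:
#'   logical vector marking points that fell outside a local field domain.
#' @export
apply_transform_points <- function(transform, pts) {
  pts <- rbind(pts)
  stopifnot(all(is.finite(pts)))
  outside <- rep(FALSE, nrow(pts))
  if (inherits(transform, "transform_chain")) {
    for (link in transform$links) {
      pts <- apply_transform_points(link, pts)
      outside <- outside | attr(pts, "outside")
    }
    attr(pts, "outside") <- outside
    return(pts)
  }
  if (inherits(transform, "affine_transform")) {
    out <- pts %*% t(transform$matrix) +
      rep(transform$translation, each = nrow(pts))
    attr(out, "outside") <- outside
    return(out)
  }
  transform <- as_composite(transform)
  a <- transform$global
  out <- pts %*% t(a$matrix) + rep(a$translation, each = nrow(pts))
  if (!is.null(transform$local)) {
    grid <- as_grid_geometry(transform$local)
    idx <- world_to_index(pts, grid)
    for (k in seq_along(grid$dim))
      outside <- outside | idx[, k] < 0 | idx[, k] > grid$dim[k] - 1
    out <- out + field_at_points(transform$local, pts, clamp = FALSE)
  }
  attr(out, "outside") <- outside
  out
}

#' Invert a displacement field by fixed-point iteration
#'
#' Finds g with (id + f) o (id + g) = id to within `tol`, iterating
#' g <- -f(x + g(x)).  Requires f to be diffeomorphic (positive Jacobian).
#'
#' @param f A `displacement_field`.
#' @param tol Maximum residual displacement norm (mm) on interior voxels.
#' @param max_iter Iteration cap.
#' @return The inverse `displacement_field`.
#' @export
invert_displacement <- function(f, tol = 0.01, max_iter = 50) {
  grid <- as_grid_geometry(f)
  pts <- grid_world_coords(grid)
  d <- length(grid$dim)
  g <- matrix(0, nrow(pts), d)
  interior <- interior_mask(grid$dim)
  achieved <- Inf
  for (it in seq_len(max_iter)) {
    fg <- field_at_points(f, pts + g, clamp = TRUE)
    resid <- g + fg
    achieved <- max(sqrt(rowSums(resid[interior, , drop = FALSE]^2)))
    if (achieved <= tol) break
    g <- -fg
  }
  if (achieved > tol)
    stop("invert_displacement: residual ", signif(achieved, 4),
         " mm after ", max_iter, " iterations (tol ", tol, ")")
  displacement_field(array(g, dim = dim(f$vectors)), grid$spacing, grid$origin)
}

interior_mask <- function(dm) {
  d <- length(dm)
  idx <- lapply(dm, function(n) seq_len(n))
  g <- expand.grid(idx, KEEP.OUT.ATTRS = FALSE)
  keep <- rep(TRUE, nrow(g))
  for (k in seq_len(d)) keep <- keep & g[, k] > 1 & g[, k] < dm[k]
  keep
}

# d/dx_axis of arr with central differences (one-sided at edges), physical units
array_gradient <- function(arr, axis, h) {
  apply_along_axis(arr, axis, function(m) {
    n <- nrow(m)
    g <- m
    if (n >= 3) g[2:(n - 1), ] <- (m[3:n, , drop = FALSE] -
                                   m[1:(n - 2), , drop = FALSE]) / (2 * h)
    g[1, ] <- (m[2, ] - m[1, ]) / h
    g[n, ] <- (m[n, ] - m[n - 1, ]) / h
    g
  })
}

#' Jacobian determinant of a deformation
#'
#' Determinant of the Jacobian of `id + f` at every voxel, computed with
#' central finite differences (one-sided at the boundary).  Values > 0
#' everywhere certify that the sampled deformation does not fold.
#'
#' @param f A `displacement_field`.
#' @return An [image_volume()] of determinants on the field's grid.
#' @export
jacobian_determinant <- function(f) {
  grid <- as_grid_geometry(f)
  d <- length(grid$dim)
  J <- vector("list", d * d)
  for (i in seq_len(d)) {
    ci <- field_component(f, i)
    for (j in seq_len(d)) {
      g <- array_gradient(ci, j, grid$spacing[j])
      if (i == j) g <- g + 1
      J[[(i - 1) * d + j]] <- g
    }
  }
  det_arr <- if (d == 2) {
    J[[1]] * J[[4]] - J[[2]] * J[[3]]
  } else {
    J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
      J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
      J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
  }
  image_volume(det_arr, grid$spacing, grid$origin)
}
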