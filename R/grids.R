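# Image containers: scalar volumes and integer label maps on regular,
# axis-aligned grids.  Coordinates are physical millimetres; the world
# position of voxel index i (0-based) along axis k is origin[k] + i*spacing[k].

#' Scalar image volume on a regular grid
#'
#' Container for a dense rank-2 or rank-3 array of finite real intensities
#' together with its physical geometry.  All spatial algorithms in the
#' package are rank-generic and accept 2D as well as 3D volumes.
#'
#' @param data Numeric array of rank 2 or 3; all values must be finite.
#' @param spacing Numeric vector, physical size of one voxel per axis (mm);
#'   all components must be positive.  Recycled to the rank of `data` if
#'   length 1.
#' @param origin Physical coordinate (mm) of voxel `(0, ..., 0)`; defaults
#'   to the zero vector.
#' @return An object of class `image_volume` with fields `data`, `spacing`
#'   and `origin`.
#' @examples
#' img <- image_volume(matrix(rnorm(64), 8, 8), spacing = c(2, 2))
#' grid_dim(img)
#' @export
image_volume <- function(data, spacing = rep(1, length(dim(data))),
                         origin = rep(0, length(dim(data)))) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (!(nd %in% c(2L, 3L)))
    stop("image_volume: data must have rank 2 or 3, got rank ", nd)
  if (!all(is.finite(data)))
    stop("image_volume: all intensities must be finite")
  spacing <- rep_len(as.numeric(spacing), nd)
  origin <- rep_len(as.numeric(origin), nd)
  if (any(spacing <= 0))
    stop("image_volume: spacing components must be > 0")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Integer label map on a regular grid
#'
#' Like [image_volume()] but holding non-negative integer anatomical label
#' IDs; ID 0 is reserved for background.
#'
#' @param data Integer-valued array of rank 2 or 3, values >= 0.
#' @inheritParams image_volume
#' @return An object of class `label_map`.
#' @export
label_map <- function(data, spacing = rep(1, length(dim(data))),
                      origin = rep(0, length(dim(data)))) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (!(nd %in% c(2L, 3L)))
    stop("label_map: data must have rank 2 or 3, got rank ", nd)
  if (!all(is.finite(data)) || any(data < 0) || any(data != round(data)))
    stop("label_map: values must be non-negative integers")
  storage.mode(data) <- "integer"
  spacing <- rep_len(as.numeric(spacing), nd)
  origin <- rep_len(as.numeric(origin), nd)
  if (any(spacing <= 0))
    stop("label_map: spacing components must be > 0")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "label_map")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = "x"),
      " spacing [", paste(signif(x$spacing, 4), collapse = ", "),
      "] mm, range [", signif(min(x$data), 4), ", ",
      signif(max(x$data), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  ids <- sort(unique(as.vector(x$data)))
  cat("<label_map> ", paste(dim(x$data), collapse = "x"),
      " spacing [", paste(signif(x$spacing, 4), collapse = ", "),
      "] mm, ", length(setdiff(ids, 0L)), " foreground labels\n", sep = "")
  invisible(x)
}

is_image_like <- function(x) inherits(x, c("image_volume", "label_map"))

#' Grid dimensions of an image, label map or displacement field
#' @param x An `image_volume`, `label_map` or `displacement_field`.
#' @return Integer vector of voxel counts per spatial axis.
#' @export
grid_dim <- function(x) {
  if (inherits(x, "displacement_field")) {
    d <- dim(x$vectors)
    return(d[-length(d)])
  }
  dim(x$data)
}

#' Grid geometry descriptor
#'
#' A lightweight (dim, spacing, origin) triple used to specify the output
#' grid of a resampling operation.
#'
#' @param dim Integer vector of voxel counts per axis (rank 2 or 3).
#' @param spacing,origin As in [image_volume()].
#' @return A `grid_geometry` object.
#' @export
grid_geometry <- function(dim, spacing = rep(1, length(dim)),
                          origin = rep(0, length(dim))) {
  dim <- as.integer(dim)
  if (!(length(dim) %in% c(2L, 3L)) || any(dim < 1))
    stop("grid_geometry: need 2 or 3 positive dimensions")
  structure(list(dim = dim,
                 spacing = rep_len(as.numeric(spacing), length(dim)),
                 origin = rep_len(as.numeric(origin), length(dim))),
            class = "grid_geometry")
}

#' @rdname grid_geometry
#' @param x Object to convert (an image, label map or displacement field).
#' @export
as_grid_geometry <- function(x) {
  if (inherits(x, "grid_geometry")) return(x)
  if (is_image_like(x) || inherits(x, "displacement_field"))
    return(grid_geometry(grid_dim(x), x$spacing, x$origin))
  stop("cannot derive a grid geometry from class ",
       paste(class(x), collapse = "/"))
}

same_grid <- function(a, b, tol = 1e-8) {
  ga <- as_grid_geometry(a); gb <- as_grid_geometry(b)
  identical(ga$dim, gb$dim) &&
    max(abs(ga$spacing - gb$spacing)) <= tol &&
    max(abs(ga$origin - gb$origin)) <= tol
}

# world coordinates (n x d matrix, mm) of every voxel of a grid, in R's
# column-major array order
grid_world_coords <- function(grid) {
  grid <- as_grid_geometry(grid)
  d <- length(grid$dim)
  idx <- lapply(seq_len(d), function(k) seq_len(grid$dim[k]) - 1)
  g <- as.matrix(expand.grid(idx, KEEP.OUT.ATTRS = FALSE))
  sweep(g, 2, grid$spacing, `*`) + rep(grid$origin, each = nrow(g))
}

# physical point (mm) -> continuous 0-based voxel index of a grid
world_to_index <- function(pts, grid) {
  grid <- as_grid_geometry(grid)
  pts <- rbind(pts)
  sweep(sweep(pts, 2, grid$origin, `-`), 2, grid$spacing, `/`)
}

index_to_world <- function(idx, grid) {
  grid <- as_grid_geometry(grid)
  idx <- rbind(idx)
  sweep(sweep(idx, 2, grid$spacing, `*`), 2, grid$origin, `+`)
}

#' Mirror an image or label map along the left-right axis
#'
#' Flips the array along the first spatial axis (the left-right axis by the
#' package's orientation convention), keeping the grid geometry fixed so the
#' mirror plane is the grid centre.  For label maps see [flip_labels_lr()],
#' which additionally swaps paired left/right label IDs.
#'
#' @param x An `image_volume` or `label_map`.
#' @return Object of the same class, mirrored.
#' @export
flip_lr <- function(x) {
  stopifnot(is_image_like(x))
  d <- dim(x$data)
  flipped <- if (length(d) == 2L) x$data[d[1]:1, , drop = FALSE]
             else x$data[d[1]:1, , , drop = FALSE]
  x$data <- flipped
  x
}
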