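# Quantitative validation: landmark transfer errors, intraclass
# correlation, and overlap measures.

#' Named landmark set
#'
#' @param points Numeric matrix (landmarks x coordinates, mm) with unique
#'   row names, or a named list of coordinate vectors.
#' @return A `landmark_set` (matrix with class attribute).
#' @export
landmark_set <- function(points) {
  if (is.list(points) && !is.matrix(points))
    points <- do.call(rbind, points)
  points <- as.matrix(points)
  if (is.null(rownames(points)) || anyDuplicated(rownames(points)))
    stop("landmark_set: landmarks need unique names")
  if (!all(is.finite(points)))
    stop("landmark_set: coordinates must be finite")
  class(points) <- c("landmark_set", class(matrix()))
  points
}

#' Euclidean landmark transfer error
#'
#' Per-landmark Euclidean distance (mm) between two sets sharing the same
#' landmark names, with mean and SD summaries.
#'
#' @param truth,test [landmark_set()]s with identical names.
#' @return List with `per_landmark` (named distances, mm), `mean`, `sd`.
#' @export
landmark_error <- function(truth, test) {
  nt <- rownames(truth); ns <- rownames(test)
  if (!setequal(nt, ns))
    stop("landmark_error: landmark names differ: only in truth [",
         paste(setdiff(nt, ns), collapse = ", "), "], only in test [",
         paste(setdiff(ns, nt), collapse = ", "), "]")
  test <- test[nt, , drop = FALSE]
  d <- sqrt(rowSums((unclass(truth) - unclass(test))^2))
  list(per_landmark = d, mean = mean(d), sd = stats::sd(d))
}

#' Map landmarks through a transform
#'
#' @param lm A [landmark_set()] in the transform's target space.
#' @param transform Any transform accepted by [apply_transform_points()].
#' @return The mapped [landmark_set()]; landmarks falling outside a local
#'   displacement-field domain are flagged in the `"outside"` attribute.
#' @export
transfer_landmarks <- function(lm, transform) {
  mapped <- apply_transform_points(transform, unclass(lm))
  out <- landmark_set(structure(as.matrix(mapped), dimnames = dimnames(lm)))
  attr(out, "outside") <- stats::setNames(attr(mapped, "outside"),
                                          rownames(lm))
  out
}

#' Intraclass correlation coefficient, two-way mixed, consistency
#'
#' ICC(3,1): single-measures consistency from the two-way mean squares,
#' `(MS_targets - MS_error) / (MS_targets + (k - 1) MS_error)`, the common
#' reading of "two-way mixed effects model" for repeated landmark
#' placement by a fixed set of raters.
#'
#' @param ratings n x k matrix: n targets measured by k raters.
#' @return ICC clamped to `[-1, 1]`, or `NA` when total variance is zero.
#' @export
icc_two_way_mixed <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("icc_two_way_mixed: need >= 2 targets and raters")
  if (!all(is.finite(ratings))) stop("icc_two_way_mixed: non-finite ratings")
  if (stats::var(as.vector(ratings)) == 0) return(NA_real_)
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  icc <- (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
  max(-1, min(1, icc))
}

#' Dice overlap coefficient for one label
#'
#' `2 |A ∩ B| / (|A| + |B|)` for the voxels carrying `label` in each map.
#'
#' @param a,b [label_map()]s on the same grid.
#' @param label Label ID to compare.
#' @return Dice in `[0, 1]`, or `NA` when the label is absent from both.
#' @export
dice_coefficient <- function(a, b, label) {
  if (!same_grid(a, b)) stop("dice_coefficient: maps must share a grid")
  am <- as.vector(a$data) == label
  bm <- as.vector(b$data) == label
  na <- sum(am); nb <- sum(bm)
  if (na + nb == 0) return(NA_real_)
  2 * sum(am & bm) / (na + nb)
}

#' Mean Dice over all foreground labels
#' @inheritParams dice_coefficient
#' @param labels Label IDs to average over; default all foreground labels
#'   present in either map.
#' @return List with `per_label` and `mean`.
#' @export
mean_dice <- function(a, b, labels = NULL) {
  if (is.null(labels))
    labels <- setdiff(sort(unique(c(a$data, b$data))), 0L)
  d <- vapply(labels, function(l) dice_coefficient(a, b, l), 0)
  list(per_label = stats::setNames(d, labels), mean = mean(d, na.rm = TRUE))
}
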