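# Image similarity metrics.

#' Normalized cross-correlation between two images
#'
#' Pearson correlation of the voxel intensities of two images on the same
#' grid.  Lies in `[-1, 1]` and is invariant to affine rescaling of either
#' input, which makes it the metric of choice for intra-modality
#' registration steps.
#'
#' @param a,b [image_volume()]s on the same grid.
#' @return Scalar NCC; 0 (with a warning) if either input has zero variance.
#' @export
ncc_metric <- function(a, b) {
  if (!same_grid(a, b)) stop("ncc_metric: images must share a grid")
  x <- as.vector(a$data); y <- as.vector(b$data)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    warning("ncc_metric: zero-variance input; returning 0")
    return(0)
  }
  mean((x - mean(x)) * (y - mean(y))) / (sx * sy) * length(x) / (length(x) - 1)
}

bin_indices <- function(x, bins) {
  r <- range(x)
  if (r[1] == r[2]) return(rep(1L, length(x)))
  i <- floor((x - r[1]) / (r[2] - r[1]) * bins)
  as.integer(pmin(i, bins - 1L)) + 1L
}

entropy_from_counts <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Studholme normalized mutual information
#'
#' `NMI = (H(A) + H(B)) / H(A, B)` computed from a joint histogram with
#' equal-width bins over each image's own intensity range.  Takes values in
#' `[1, 2]`: 1 for independent images, 2 for a bijective intensity
#' relationship.  Invariant under any bijective remapping of histogram bins
#' of either input, which is what makes it robust to the gray/white
#' contrast inversion between neonatal and adult T1-weighted images.
#'
#' @param a,b [image_volume()]s on the same grid.
#' @param bins Number of histogram bins per image (default 32).
#' @param parzen_sigma Gaussian smoothing (in bins) of the joint histogram
#'   before the entropies are taken.  0 (the default) gives the plain
#'   histogram estimate used for reporting; the registration optimizers
#'   use 1 bin of Parzen smoothing so the metric varies smoothly with
#'   small transform changes.
#' @return Scalar NMI in `[1, 2]`; 1 (with a warning) for a constant input.
#' @export
nmi_metric <- function(a, b, bins = 32, parzen_sigma = 0) {
  if (!same_grid(a, b)) stop("nmi_metric: images must share a grid")
  x <- as.vector(a$data); y <- as.vector(b$data)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("nmi_metric: constant input; returning independence limit 1")
    return(1)
  }
  ia <- bin_indices(x, bins); ib <- bin_indices(y, bins)
  joint <- tabulate((ia - 1L) * bins + ib, nbins = bins * bins)
  jm <- matrix(joint, bins, bins)
  if (parzen_sigma > 0) jm <- smooth_array(jm, parzen_sigma)
  ha <- entropy_from_counts(colSums(jm))
  hb <- entropy_from_counts(rowSums(jm))
  hab <- entropy_from_counts(as.vector(jm))
  if (hab == 0) return(1)
  (ha + hb) / hab
}

image_metric <- function(a, b, metric, bins = 32, parzen_sigma = 0) {
  switch(metric,
         ncc = ncc_metric(a, b),
         nmi = nmi_metric(a, b, bins, parzen_sigma),
         stop("unknown metric '", metric, "'"))
}

# Histogram-based intensity transfer: remap src intensities so that each
# source bin takes the mean reference intensity observed in it (Parzen-
# smoothed across bins).  Turns a multi-modal (contrast-inverted) pair into
# an approximately mono-modal one for difference-based force computation.
remap_intensities <- function(src, ref, bins = 32, parzen_sigma = 1) {
  x <- as.vector(src); y <- as.vector(ref)
  r <- range(x)
  if (r[1] == r[2]) return(src)
  ix <- bin_indices(x, bins)
  num <- tapply(y, ix, sum)
  cnt <- tapply(y, ix, length)
  means <- rep(NA_real_, bins)
  means[as.integer(names(num))] <- num / cnt
  w <- rep(0, bins); w[as.integer(names(cnt))] <- cnt
  if (parzen_sigma > 0) {
    K <- smoothing_matrix(bins, parzen_sigma)
    m0 <- ifelse(is.na(means), 0, means)
    sm <- as.vector(K %*% (m0 * w))
    sw <- as.vector(K %*% w)
    means <- ifelse(sw > 0, sm / sw, NA_real_)
  }
  ok <- which(!is.na(means))
  if (length(ok) < 2) return(src)
  centers <- r[1] + (seq_len(bins) - 0.5) / bins * (r[2] - r[1])
  mapped <- stats::approx(centers[ok], means[ok], xout = x, rule = 2)$y
  array(mapped, dim = dim(src))
}
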