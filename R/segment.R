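# Expectation-maximization tissue classification with spatial priors.
#
# Gaussian intensity model per class modulated by voxelwise spatial prior
# probabilities; no Markov-random-field term and no bias-field estimation
# inside EM (bias correction is an upstream concern in this pipeline).

#' EM tissue segmentation with spatial priors
#'
#' Classifies each in-mask voxel into one of the prior classes (typically
#' CSF, GM, WM) by expectation-maximization: the E-step combines Gaussian
#' class likelihoods with the spatial priors and normalizes per voxel, the
#' M-step re-estimates class means and variances from the posteriors.
#' Class means are initialized from prior-weighted intensity averages
#' (falling back to intensity quantiles when the priors are uninformative).
#' The log-likelihood is non-decreasing across iterations; iteration stops
#' when its relative change drops below `tol`.
#'
#' @param image [image_volume()] to classify.
#' @param priors Named list of per-class prior probability
#'   [image_volume()]s on the image grid (renormalized internally to sum
#'   to 1 in-mask).
#' @param mask Optional [label_map()] (non-zero = in mask); default whole
#'   grid.
#' @param max_iter Iteration cap (default 50).
#' @param tol Relative log-likelihood change for convergence (default 1e-5).
#' @return List with `posteriors` (named list of [image_volume()]s summing
#'   to 1 in-mask), `hard` ([label_map()], class index 1..K, ties toward
#'   the smallest class index), `means`, `variances`, `log_likelihood`
#'   (per-iteration trace), `converged`, and `flags` (e.g. variance
#'   flooring events).
#' @export
em_tissue_segment <- function(image, priors, mask = NULL,
                              max_iter = 50, tol = 1e-5) {
  stopifnot(inherits(image, "image_volume"), length(priors) >= 2)
  grid <- as_grid_geometry(image)
  for (p in priors)
    if (!same_grid(p, grid))
      stop("em_tissue_segment: priors must be on the image grid")
  K <- length(priors)
  cls <- names(priors)
  if (is.null(cls)) cls <- paste0("class", seq_len(K))
  x <- as.vector(image$data)
  m <- if (is.null(mask)) rep(TRUE, length(x)) else as.vector(mask$data) != 0L
  if (!any(m)) stop("em_tissue_segment: empty mask")
  xm <- x[m]
  rng <- diff(range(xm))
  var_floor <- (1e-6 * max(rng, 1e-12))^2
  flags <- character(0)

  P <- vapply(priors, function(p) as.vector(p$data)[m], numeric(sum(m)))
  P[P < 0] <- 0
  tot <- rowSums(P)
  ok <- tot > 0
  P[ok, ] <- P[ok, ] / tot[ok]
  P[!ok, ] <- 1 / K

  mu <- as.vector(crossprod(P, xm) / pmax(colSums(P), 1e-12))
  # uninformative (e.g. flat) priors leave all class means at the global
  # mean; break the symmetry with intensity quantiles
  if (diff(range(mu)) < 1e-3 * max(rng, 1e-12))
    mu <- as.vector(stats::quantile(xm, (seq_len(K) - 0.5) / K, names = FALSE))
  sg2 <- vapply(seq_len(K), function(k)
    sum(P[, k] * (xm - mu[k])^2) / max(sum(P[, k]), 1e-12), 0)
  sg2 <- pmax(sg2, var_floor)

  loglik <- numeric(0)
  converged <- FALSE
  post <- P
  for (it in seq_len(max_iter)) {
    lik <- vapply(seq_len(K), function(k)
      stats::dnorm(xm, mu[k], sqrt(sg2[k])), numeric(length(xm)))
    num <- lik * P
    tot <- rowSums(num)
    ll <- sum(log(pmax(tot, 1e-300)))
    loglik <- c(loglik, ll)
    zero <- tot <= 0
    post <- num
    post[!zero, ] <- post[!zero, ] / tot[!zero]
    post[zero, ] <- P[zero, ]
    if (it > 1 && abs(ll - loglik[it - 1]) <=
        tol * max(abs(ll), 1e-12)) { converged <- TRUE; break }
    nk <- pmax(colSums(post), 1e-12)
    mu <- as.vector(crossprod(post, xm) / nk)
    sg2_new <- vapply(seq_len(K), function(k)
      sum(post[, k] * (xm - mu[k])^2) / nk[k], 0)
    if (any(sg2_new < var_floor)) {
      flags <- c(flags, paste0("iteration ", it, ": variance floored for ",
                               paste(cls[sg2_new < var_floor], collapse = ", ")))
      sg2_new <- pmax(sg2_new, var_floor)
    }
    sg2 <- sg2_new
  }

  posteriors <- lapply(seq_len(K), function(k) {
    arr <- array(0, dim = grid$dim)
    arr[m] <- post[, k]
    image_volume(arr, grid$spacing, grid$origin)
  })
  names(posteriors) <- cls
  hard_arr <- array(0L, dim = grid$dim)
  hard_arr[m] <- max.col(post, ties.method = "first")
  list(posteriors = posteriors,
       hard = label_map(hard_arr, grid$spacing, grid$origin),
       means = stats::setNames(mu, cls),
       variances = stats::setNames(sg2, cls),
       log_likelihood = loglik,
       converged = converged,
       flags = flags)
}

#' Cohort-average tissue probability maps
#'
#' Voxelwise mean of per-subject posterior maps in a common (template)
#' space, renormalized per voxel to sum to 1 where any class has support.
#'
#' @param per_subject List of per-subject posterior lists (each a named
#'   list of per-class [image_volume()]s on the template grid).
#' @return Named list of per-class average probability [image_volume()]s.
#' @export
average_tissue_maps <- function(per_subject) {
  stopifnot(length(per_subject) >= 1)
  ref <- per_subject[[1]]
  grid <- as_grid_geometry(ref[[1]])
  K <- length(ref)
  for (s in per_subject)
    for (p in s)
      if (!same_grid(p, grid))
        stop("average_tissue_maps: all maps must be on one grid")
  avg <- lapply(seq_len(K), function(k) {
    acc <- Reduce(`+`, lapply(per_subject, function(s) s[[k]]$data))
    acc / length(per_subject)
  })
  tot <- Reduce(`+`, avg)
  out <- lapply(avg, function(a) {
    a[tot > 0] <- a[tot > 0] / tot[tot > 0]
    image_volume(a, grid$spacing, grid$origin)
  })
  names(out) <- names(ref)
  out
}
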