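#' Fit a 1D Gaussian mixture by EM
#'
#' Standard expectation-maximization for a k-component univariate Gaussian
#' mixture of pixel intensities, initialized from K-means (component means,
#' within-cluster variances, and cluster fractions). E-step: posteriors by
#' Bayes' rule; M-step: weighted fraction / mean / variance updates.
#' Iteration stops when the summed squared parameter change falls below
#' `tol`. The log-likelihood is non-decreasing across iterations (tracked
#' in `loglik_trace`). Collapsing components (vanishing weight or floored
#' variance) trigger a re-seeded restart, at most 3 times.
#'
#' @param intensities numeric vector (n >= 10 k).
#' @param k number of components (default 2).
#' @param seed RNG seed for the K-means initialization.
#' @param tol convergence threshold on the squared parameter change
#'   (default 1e-6).
#' @param max_iters maximum EM iterations (default 200).
#' @return list of class `gmm_fit`: `weights`, `means`, `variances`,
#'   `posteriors` (n x k, rows sum to 1), `loglik_trace`, `iterations`,
#'   `converged`.
#' @export
gmm_fit <- function(intensities, k = 2L, seed = 1L, tol = 1e-6,
                    max_iters = 200L) {
  x <- as.numeric(intensities)
  if (any(!is.finite(x))) stop("gmm_fit: intensities must be finite")
  n <- length(x)
  if (n < 10L * k) stop("gmm_fit: need at least 10 k observations")
  var_floor <- max(1e-10 * stats::var(x), 1e-12)
  if (stats::var(x) <= 0)
    stop("gmm_fit: degenerate data (all observations identical)")
  for (attempt in 0:3) {
    init <- with_seed(seed + attempt, {
      km <- suppressWarnings(stats::kmeans(x, centers = k, nstart = 1L))
      list(means = as.numeric(km$centers),
           variances = pmax(vapply(seq_len(k), function(i) {
             xi <- x[km$cluster == i]
             if (length(xi) > 1L) stats::var(xi) else var_floor
           }, numeric(1)), var_floor),
           weights = as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / n)
    })
    fit <- gmm_em(x, init, tol, max_iters, var_floor)
    if (!fit$collapsed) {
      fit$collapsed <- NULL
      fit$k <- k
      class(fit) <- "gmm_fit"
      return(fit)
    }
  }
  stop("gmm_fit: component collapse persisted across restarts (degenerate data)")
}

gmm_em <- function(x, theta, tol, max_iters, var_floor) {
  n <- length(x)
  k <- length(theta$means)
  loglik_trace <- numeric(0)
  post <- NULL
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    dens <- vapply(seq_len(k), function(i)
      theta$weights[i] * stats::dnorm(x, theta$means[i],
                                      sqrt(theta$variances[i])),
      numeric(n))
    fx <- rowSums(dens)
    fx <- pmax(fx, 1e-300)
    loglik_trace <- c(loglik_trace, sum(log(fx)))
    post <- dens / fx
    nk <- colSums(post)
    new <- list(weights = nk / n,
                means = colSums(post * x) / nk,
                variances = numeric(k))
    new$variances <- vapply(seq_len(k), function(i)
      sum(post[, i] * (x - new$means[i])^2) / nk[i], numeric(1))
    new$variances <- pmax(new$variances, var_floor)
    if (any(new$weights < 1e-6))
      return(list(collapsed = TRUE))
    delta <- sum((new$weights - theta$weights)^2) +
      sum((new$means - theta$means)^2) +
      sum((new$variances - theta$variances)^2)
    theta <- new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(weights = theta$weights, means = theta$means,
       variances = theta$variances, posteriors = post,
       loglik_trace = loglik_trace, iterations = length(loglik_trace),
       converged = converged, collapsed = FALSE)
}

#' Fit fuzzy C-means on 1D intensities
#'
#' Minimizes `J = sum_j sum_i u_ij^m |x_j - v_i|^2` by alternating the
#' membership update `u_ij = 1 / sum_k (|x_j - v_i| / |x_j - v_k|)^(2/(m-1))`
#' (with the degenerate rule: a pixel exactly at a center gets membership 1
#' there) and the center update `v_i = sum_j u_ij^m x_j / sum_j u_ij^m`.
#' Centers are initialized from `c` distinct data points drawn with the
#' given seed. Stops when the largest center shift drops below `tol`; the
#' objective trace `J` is non-increasing.
#'
#' @param intensities numeric vector (n >= 10 c).
#' @param c number of clusters (default 2).
#' @param m fuzzifier, > 1 (default 2).
#' @param seed RNG seed for center initialization.
#' @param tol center-shift convergence threshold (default 1e-5).
#' @param max_iters maximum iterations (default 200).
#' @return list of class `fcm_fit`: `centers`, `memberships` (n x c, rows
#'   sum to 1), `objective_trace`, `iterations`, `converged`.
#' @export
fcm_fit <- function(intensities, c = 2L, m = 2, seed = 1L, tol = 1e-5,
                    max_iters = 200L) {
  x <- as.numeric(intensities)
  if (any(!is.finite(x))) stop("fcm_fit: intensities must be finite")
  n <- length(x)
  if (n < 10L * c) stop("fcm_fit: need at least 10 c observations")
  if (m <= 1) stop("fcm_fit: fuzzifier m must be > 1")
  ux <- unique(x)
  if (length(ux) < c)
    stop("fcm_fit: fewer distinct intensities than clusters (degenerate)")
  v <- with_seed(seed, sort(sample(ux, c)))
  expo <- 2 / (m - 1)
  J_trace <- numeric(0)
  u <- NULL
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    d2 <- outer(x, v, function(a, b) (a - b)^2)
    u <- fcm_memberships(d2, expo)
    J_trace <- c(J_trace, sum(u^m * d2))
    um <- u^m
    v_new <- colSums(um * x) / colSums(um)
    if (anyDuplicated(round(v_new, 12))) {
      # coincident centers: perturb deterministically and continue
      v_new <- v_new + seq_along(v_new) * 1e-8 * max(1, diff(range(x)))
    }
    shift <- max(abs(v_new - v))
    v <- v_new
    if (shift < tol) { converged <- TRUE; break }
  }
  d2 <- outer(x, v, function(a, b) (a - b)^2)
  u <- fcm_memberships(d2, expo)
  structure(list(centers = v, memberships = u, objective_trace = J_trace,
                 iterations = length(J_trace), converged = converged,
                 c = c, m = m),
            class = "fcm_fit")
}

fcm_memberships <- function(d2, expo) {
  n <- nrow(d2); k <- ncol(d2)
  # u_ij = 1 / sum_l (d_ij / d_lj)^(1/(m-1)) on squared distances
  inv <- d2^(-expo / 2)
  u <- inv / rowSums(inv)
  zero <- d2 <= 0
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    u[hit, ] <- 0
    u[hit, ][zero[hit, , drop = FALSE]] <- 1
    u[hit, ] <- u[hit, , drop = FALSE] / rowSums(u[hit, , drop = FALSE])
  }
  u
}

#' Turn per-pixel cluster labels into a foreground mask
#'
#' The cluster with the higher mean image intensity becomes the foreground
#' (bone is bright on PD-weighted slices); on an exact tie the lower
#' cluster index wins. The mask is clipped to the ROI disk.
#'
#' @param labels integer vector of cluster assignments, one per ROI pixel
#'   (in column-major order of `which(roi_mask == 1)`).
#' @param roi a [circle_roi()].
#' @param image the [image2d()] the labels were computed from.
#' @return a [binary_mask()].
#' @export
labels_to_mask <- function(labels, roi, image) {
  I <- as_pixels(image)
  rmask <- roi$roi_mask$pixels
  idx <- which(rmask == 1)
  if (length(labels) != length(idx))
    stop("labels_to_mask: one label per ROI pixel required")
  means <- vapply(sort(unique(labels)), function(l)
    mean(I[idx[labels == l]]), numeric(1))
  names(means) <- sort(unique(labels))
  best <- names(means)[which.max(means + 0)]  # which.max: first (lowest index) on ties
  out <- matrix(0L, nrow(I), ncol(I))
  out[idx[labels == as.integer(best)]] <- 1L
  binary_mask(out)
}

#' Segment the ROI by intensity clustering
#'
#' Clusters the preprocessed ROI intensities into 2 classes with either the
#' Gaussian mixture ([gmm_fit()]) or fuzzy C-means ([fcm_fit()]) and keeps
#' the brighter class as foreground.
#'
#' @param image [image2d()] (preprocessed).
#' @param roi a [circle_roi()].
#' @param seed RNG seed for the initialization.
#' @param k,m clusters / fuzzifier.
#' @return a [segmentation_result()].
#' @export
gmm_segment <- function(image, roi, seed = 1L, k = 2L) {
  I <- as_pixels(image)
  idx <- which(roi$roi_mask$pixels == 1)
  fit <- gmm_fit(I[idx], k = k, seed = seed)
  labels <- max.col(fit$posteriors, ties.method = "first")
  mask <- labels_to_mask(labels, roi, image)
  bnd <- if (sum(mask$pixels) > 0) extract_boundary(mask) else NULL
  segmentation_result(mask, bnd, "gmm", fit$iterations)
}

#' @rdname gmm_segment
#' @export
fcm_segment <- function(image, roi, seed = 1L, k = 2L, m = 2) {
  I <- as_pixels(image)
  idx <- which(roi$roi_mask$pixels == 1)
  fit <- fcm_fit(I[idx], c = k, m = m, seed = seed)
  labels <- max.col(fit$memberships, ties.method = "first")
  mask <- labels_to_mask(labels, roi, image)
  bnd <- if (sum(mask$pixels) > 0) extract_boundary(mask) else NULL
  segmentation_result(mask, bnd, "fcm", fit$iterations)
}
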