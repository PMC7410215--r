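#' Bias coefficient of the k-nearest-neighbour alpha-divergence estimator
#'
#' Computes \eqn{B_{k,\alpha} = \Gamma(k)^2 / (\Gamma(k-\alpha+1)\Gamma(k+\alpha-1))},
#' the multiplicative coefficient that makes the k-NN divergence estimator
#' asymptotically unbiased.
#'
#' @param k neighbour order, a positive integer.
#' @param order divergence order \eqn{\alpha \in (0, 1]}; the Hellinger case is
#'   \code{order = 0.5}.
#' @return A positive scalar.
#' @examples
#' knn_coefficient(3, 1)        # 1
#' knn_coefficient(1, 0.5)      # 2/pi
#' @export
knn_coefficient <- function(k, order) {
  if (!is_count(k) || k < 1) stop("'k' must be a positive integer", call. = FALSE)
  if (!is.numeric(order) || length(order) != 1L || order <= 0 || order > 1) {
    stop("'order' must be a scalar in (0, 1]", call. = FALSE)
  }
  if (k - order + 1 <= 0 || k + order - 1 <= 0) {
    stop("gamma-function arguments must be positive", call. = FALSE)
  }
  exp(2 * lgamma(k) - lgamma(k - order + 1) - lgamma(k + order - 1))
}

#' k-th nearest neighbour distances
#'
#' For each query point, the Euclidean distance to its k-th nearest neighbour
#' among the reference points. With \code{exclude_self = TRUE} the query and
#' reference sets must be the same matrix and each point's own zero distance is
#' excluded.
#'
#' @param reference numeric matrix, reference samples in rows.
#' @param queries numeric matrix with the same number of columns; defaults to
#'   \code{reference}.
#' @param k neighbour order.
#' @param exclude_self logical; exclude each query point itself from its
#'   neighbour set (requires \code{queries} to be the reference set).
#' @return Numeric vector of nonnegative distances, one per query row.
#' @export
kth_nearest_distances <- function(reference, queries = reference, k,
                                  exclude_self = FALSE) {
  reference <- as_sample_matrix(reference, "reference")
  queries <- as_sample_matrix(queries, "queries")
  if (ncol(reference) != ncol(queries)) {
    stop("'reference' and 'queries' must have the same dimensionality", call. = FALSE)
  }
  if (!is_count(k) || k < 1) stop("'k' must be a positive integer", call. = FALSE)
  avail <- nrow(reference) - as.integer(exclude_self)
  if (k > avail) {
    stop(sprintf("k = %d exceeds the %d available neighbours", k, avail), call. = FALSE)
  }
  if (exclude_self && !identical(dim(reference), dim(queries))) {
    stop("'exclude_self' requires queries and reference to be the same set", call. = FALSE)
  }
  cpp_knn_kth_dist(t(reference), t(queries), as.integer(k), isTRUE(exclude_self))
}

#' k-NN estimate of the alpha-divergence between two sample sets
#'
#' Estimates \eqn{D_\alpha(p \| q) = \int p^\alpha q^{1-\alpha}} from samples
#' \code{X} of \eqn{p} and \code{Y} of \eqn{q} using ratios of k-th
#' nearest-neighbour distances,
#' \deqn{\hat D_\alpha = \frac{1}{N}\sum_i
#'   \left(\frac{(N-1)\rho_k(i)}{N_y\,\nu_k(i)}\right)^{1-\alpha} B_{k,\alpha},}
#' where \eqn{\rho_k(i)} is the distance from \eqn{X_i} to its k-th neighbour
#' within \code{X} (self excluded) and \eqn{\nu_k(i)} the distance to its k-th
#' neighbour in \code{Y}. The estimator is invariant to reordering of either
#' sample but not symmetric in \code{(X, Y)}. Zero \eqn{\nu} distances (exact
#' duplicates across the sets, as happens with integer-valued summaries) are
#' replaced by the smallest positive \eqn{\nu} so the estimate stays finite.
#'
#' @param X numeric matrix of samples from the first distribution (rows).
#' @param Y numeric matrix of samples from the second distribution.
#' @param k neighbour order; must satisfy \code{k < nrow(X)} and
#'   \code{k <= nrow(Y)}.
#' @param order divergence order in (0, 1].
#' @return An object of class \code{knn_divergence}: a list with elements
#'   \code{value} (the raw, unclipped estimate), \code{k}, \code{order},
#'   \code{n_samples} and \code{clipped} (always \code{FALSE} here; see
#'   \code{\link{hellinger_estimate}}).
#' @export
knn_alpha_divergence <- function(X, Y, k = 5, order = 0.5) {
  X <- as_sample_matrix(X, "X")
  Y <- as_sample_matrix(Y, "Y")
  if (ncol(X) != ncol(Y)) stop("'X' and 'Y' must have the same dimensionality", call. = FALSE)
  if (!is_count(k) || k < 1) stop("'k' must be a positive integer", call. = FALSE)
  if (k >= nrow(X)) stop("'k' must be smaller than the number of samples in 'X'", call. = FALSE)
  if (k > nrow(Y)) stop("'k' must not exceed the number of samples in 'Y'", call. = FALSE)
  B <- knn_coefficient(k, order)
  value <- cpp_knn_alpha_divergence(t(X), t(Y), as.integer(k), order, B)
  if (is.na(value)) {
    stop("degenerate sample sets: all nearest-neighbour distances are zero", call. = FALSE)
  }
  structure(
    list(value = value, k = as.integer(k), order = order,
         n_samples = nrow(X), clipped = FALSE),
    class = "knn_divergence"
  )
}

#' k-NN Hellinger distance estimate between two sample sets
#'
#' Returns \eqn{1 - \hat D_{1/2}(X \| Y)}, the sample-based Hellinger distance
#' used throughout the adaptive weighting algorithm, with the raw
#' \eqn{\hat D_{1/2}} clipped to \eqn{[0, 1]} beforehand (at finite sample size
#' the raw estimate can exceed 1).
#'
#' @inheritParams knn_alpha_divergence
#' @return A \code{knn_divergence} object whose \code{value} lies in
#'   \eqn{[0, 1]}; \code{clipped} records whether clipping occurred.
#' @examples
#' x <- matrix(rnorm(500), ncol = 1)
#' y <- matrix(rnorm(500, mean = 2), ncol = 1)
#' hellinger_estimate(x, y, k = 5)$value   # near 1 - exp(-0.5)
#' @export
hellinger_estimate <- function(X, Y, k = 5) {
  est <- knn_alpha_divergence(X, Y, k = k, order = 0.5)
  clipped <- est$value > 1 || est$value < 0
  d <- min(max(est$value, 0), 1)
  est$value <- 1 - d
  est$clipped <- clipped
  est
}

#' Closed-form Hellinger distance between two univariate normals
#'
#' Test oracle for the k-NN estimator: for \eqn{N(\mu_1, \sigma_1^2)} and
#' \eqn{N(\mu_2, \sigma_2^2)} returns
#' \eqn{1 - \sqrt{2\sigma_1\sigma_2 / (\sigma_1^2+\sigma_2^2)}
#'   \exp(-(\mu_1-\mu_2)^2 / (4(\sigma_1^2+\sigma_2^2)))},
#' i.e. \eqn{1 - \int\sqrt{pq}}, matching the quantity the estimator targets.
#'
#' @param mean1,sd1 mean and standard deviation of the first normal.
#' @param mean2,sd2 mean and standard deviation of the second normal.
#' @return A scalar in \eqn{[0, 1]}.
#' @export
gaussian_hellinger_closed_form <- function(mean1, sd1, mean2, sd2) {
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive", call. = FALSE)
  s2 <- sd1^2 + sd2^2
  bc <- sqrt(2 * sd1 * sd2 / s2) * exp(-(mean1 - mean2)^2 / (4 * s2))
  1 - bc
}

#' @export
print.knn_divergence <- function(x, ...) {
  kind <- if (x$order == 0.5) "Hellinger (1 - D_1/2)" else sprintf("alpha = %g divergence", x$order)
  cat(sprintf("k-NN %s estimate: %.4f  (k = %d, n = %d%s)\n",
              kind, x$value, x$k, x$n_samples,
              if (isTRUE(x$clipped)) ", clipped" else ""))
  invisible(x)
}
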