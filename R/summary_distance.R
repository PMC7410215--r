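#' Weighted Euclidean ABC distance
#'
#' \eqn{d_w(s_1, s_2) = \sqrt{\sum_i w_i (s_{1i} - s_{2i})^2}}, the distance
#' used to rank simulated summary vectors against the observed summary. The
#' ranking induced by \eqn{d_w} is invariant to positive rescaling of
#' \code{w}, which is why weight vectors are normalized to the simplex.
#'
#' @param s1,s2 numeric summary vectors of equal length.
#' @param w nonnegative weight vector of the same length.
#' @return A nonnegative scalar.
#' @export
weighted_distance <- function(s1, s2, w) {
  if (length(s1) != length(s2) || length(s1) != length(w)) {
    stop("summary vectors and weights must have equal length", call. = FALSE)
  }
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  sqrt(sum(w * (s1 - s2)^2))
}

#' Median absolute deviation (raw)
#'
#' The median of absolute deviations from the median, without any consistency
#' scaling: a robust measure of the spread of a simulated summary statistic.
#'
#' @param values non-empty numeric vector.
#' @return A nonnegative scalar; zero for a constant vector.
#' @examples
#' median_abs_dev(c(1, 2, 3, 4, 100))  # 1
#' @export
median_abs_dev <- function(values) {
  if (length(values) == 0L) stop("'values' must be non-empty", call. = FALSE)
  stats::mad(values, constant = 1)
}

#' Normalize a weight vector to the simplex
#'
#' @param w nonnegative numeric vector with positive sum.
#' @return \code{w / sum(w)}.
#' @export
normalize_weights <- function(w) {
  if (any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  s <- sum(w)
  if (s <= 0) stop("weights must have positive sum", call. = FALSE)
  w / s
}

#' MAD-scaled baseline weights
#'
#' The scale-based baseline weighting scheme: each summary statistic receives
#' weight \eqn{1/\sigma_i}, where \eqn{\sigma_i} is the median absolute
#' deviation of statistic \eqn{i} across the generation's simulated summaries.
#' Statistics whose simulated values are (robustly) constant carry no ranking
#' information and receive weight zero. The result is normalized to the
#' simplex.
#'
#' @param sims numeric matrix of simulated summaries, one simulation per row.
#' @return A normalized weight vector of length \code{ncol(sims)}.
#' @export
mad_weights <- function(sims) {
  sims <- as_sample_matrix(sims, "sims")
  if (nrow(sims) < 2L) stop("'sims' must have at least two rows", call. = FALSE)
  sigma <- unname(apply(sims, 2L, median_abs_dev))
  w <- ifelse(sigma > 0, 1 / sigma, 0)
  if (all(w == 0)) {
    stop("all summary statistics are degenerate (zero spread)", call. = FALSE)
  }
  normalize_weights(w)
}

#' Uniform baseline weights
#'
#' Equal weight on every summary statistic, normalized to the simplex.
#'
#' @param kappa number of summary statistics.
#' @return A weight vector \code{rep(1/kappa, kappa)}.
#' @export
uniform_weights <- function(kappa) {
  if (!is_count(kappa) || kappa < 1) stop("'kappa' must be a positive integer", call. = FALSE)
  rep(1 / kappa, kappa)
}
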