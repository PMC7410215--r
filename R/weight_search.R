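#' Candidate pool for one generation's weight search
#'
#' Bundles the frozen inputs of one weight optimization: the M simulated
#' parameter/summary pairs of the generation, the observed summary vector, and
#' a fixed reference sample from the prior. Freezing these makes the objective
#' deterministic: no re-simulation happens inside objective evaluations.
#'
#' @param thetas numeric matrix of candidate parameters on the inference
#'   scale, one candidate per row (M x p).
#' @param summaries numeric matrix of the corresponding simulated summaries
#'   (M x kappa), rows aligned with \code{thetas}.
#' @param observed observed summary vector of length kappa.
#' @param prior_reference numeric matrix of N prior draws on the inference
#'   scale; the first argument of the Hellinger estimator.
#' @return An object of class \code{candidate_pool}.
#' @export
candidate_pool <- function(thetas, summaries, observed, prior_reference) {
  thetas <- as_sample_matrix(thetas, "thetas")
  summaries <- as_sample_matrix(summaries, "summaries")
  prior_reference <- as_sample_matrix(prior_reference, "prior_reference")
  if (nrow(thetas) != nrow(summaries)) {
    stop("'thetas' and 'summaries' must have the same number of rows", call. = FALSE)
  }
  if (length(observed) != ncol(summaries)) {
    stop("'observed' length must match ncol(summaries)", call. = FALSE)
  }
  if (ncol(prior_reference) != ncol(thetas)) {
    stop("'prior_reference' and 'thetas' must have the same dimensionality", call. = FALSE)
  }
  if (nrow(thetas) < nrow(prior_reference)) {
    stop("need at least as many candidates as prior reference draws", call. = FALSE)
  }
  structure(
    list(thetas = thetas, summaries = summaries,
         observed = as.numeric(observed), prior_reference = prior_reference),
    class = "candidate_pool"
  )
}

#' Search configuration for the weight optimizer
#'
#' @param n_restarts total number of optimizer starts; the first two are the
#'   uniform and MAD-scaled weight vectors, the rest seeded flat-Dirichlet
#'   draws.
#' @param tolerance relative convergence tolerance on the objective.
#' @param max_evals cap on objective evaluations per start.
#' @param seed integer seed for the random restarts.
#' @return An object of class \code{search_config}.
#' @export
search_config <- function(n_restarts = 5, tolerance = 1e-6, max_evals = 2000,
                          seed = 1L) {
  stopifnot(is_count(n_restarts), n_restarts >= 1, tolerance > 0,
            is_count(max_evals), max_evals >= 1, is_count(seed))
  structure(
    list(n_restarts = as.integer(n_restarts), tolerance = tolerance,
         max_evals = as.integer(max_evals), seed = as.integer(seed)),
    class = "search_config"
  )
}

#' Indices of the N candidates closest to the observed summary
#'
#' Ranks the pool's simulated summaries by weighted Euclidean distance to the
#' observed summary and returns the indices of the \code{N} closest. Ties are
#' broken deterministically by simulation index (lower index kept).
#'
#' @param pool a \code{\link{candidate_pool}}.
#' @param w weight vector of length kappa.
#' @param N number of candidates to keep.
#' @return Integer vector of \code{N} indices, ordered by increasing
#'   (distance, index).
#' @export
select_closest <- function(pool, w, N) {
  stopifnot(inherits(pool, "candidate_pool"))
  M <- nrow(pool$summaries)
  if (!is_count(N) || N < 1 || N > M) {
    stop(sprintf("'N' must be an integer in [1, %d]", M), call. = FALSE)
  }
  if (length(w) != ncol(pool$summaries)) stop("weight length mismatch", call. = FALSE)
  cpp_select_closest(pool$summaries, pool$observed, as.numeric(w), as.integer(N))$idx
}

#' Weight-search objective L(w)
#'
#' \eqn{L(w) = 1 - \hat D_{1/2}(\xi \| \theta^{(w)})}: the estimated Hellinger
#' distance between the frozen prior reference sample and the \code{N}
#' candidate parameters closest to the observed data under the weighted
#' distance \eqn{d_w}. Maximizing \eqn{L} over the weight simplex picks the
#' weighting that extracts the most information from the data. \eqn{L} is
#' invariant to positive rescaling of \code{w}.
#'
#' @inheritParams select_closest
#' @param k neighbour order of the Hellinger estimator.
#' @return A scalar in \eqn{[0, 1]}.
#' @export
weight_objective <- function(w, pool, N, k = 5) {
  stopifnot(inherits(pool, "candidate_pool"))
  rho <- cpp_knn_self_dist(t(pool$prior_reference), as.integer(k))
  obj_from_rho(w, pool, N, k, rho)
}

obj_from_rho <- function(w, pool, N, k, rho, thetas_t = t(pool$thetas),
                         prior_t = t(pool$prior_reference),
                         B = knn_coefficient(k, 0.5), cache = NULL,
                         fpool = NULL) {
  val <- cpp_weight_objective(pool$summaries, pool$observed, as.numeric(w),
                              thetas_t, prior_t, rho,
                              as.integer(N), as.integer(k), B, cache, fpool)
  if (is.na(val)) {
    stop("degenerate selection: all nearest-neighbour distances are zero", call. = FALSE)
  }
  val
}

#' Maximize the weight-search objective over the weight simplex
#'
#' Multi-start constrained maximization of \code{\link{weight_objective}}.
#' The simplex constraint is enforced by a softmax reparameterization of
#' \eqn{\kappa - 1} free log-ratio variables, optimized with Nelder-Mead from
#' each start. Starts are the uniform weights, the MAD-scaled weights of the
#' pool, and seeded flat-Dirichlet draws, so the returned optimum is never
#' worse than either baseline. The objective surface is typically flat in
#' several coordinates, so restarts matter more than tight local convergence.
#'
#' @inheritParams weight_objective
#' @param cfg a \code{\link{search_config}}.
#' @return An object of class \code{weight_search_result}: list with
#'   \code{w_star} (normalized optimal weights), \code{L_star},
#'   \code{selected_indices} (the N kept candidates under \code{w_star}),
#'   \code{n_evals} and \code{start_values} (objective at each start, for
#'   diagnostics).
#' @export
optimize_weights <- function(pool, N, k = 5, cfg = search_config()) {
  stopifnot(inherits(pool, "candidate_pool"), inherits(cfg, "search_config"))
  kappa <- ncol(pool$summaries)
  if (kappa == 1L) {
    # ranking does not depend on a single weight
    w <- 1
    L <- weight_objective(w, pool, N, k)
    return(structure(
      list(w_star = w, L_star = L, selected_indices = select_closest(pool, w, N),
           n_evals = 1L, start_values = L),
      class = "weight_search_result"
    ))
  }

  rho <- cpp_knn_self_dist(t(pool$prior_reference), as.integer(k))
  thetas_t <- t(pool$thetas)
  prior_t <- t(pool$prior_reference)
  B <- knn_coefficient(k, 0.5)
  cache <- cpp_new_objective_cache()
  # single-precision residuals inside the search; every returned value is
  # re-evaluated on the double-precision path below
  fpool <- cpp_make_residual_pool(pool$summaries, pool$observed)
  evals <- 0L
  fn <- function(z) {
    evals <<- evals + 1L
    w <- softmax(c(z, 0))
    obj_from_rho(w, pool, N, k, rho, thetas_t, prior_t, B, cache, fpool)
  }

  starts <- list(uniform_weights(kappa))
  mw <- tryCatch(mad_weights(pool$summaries), error = function(e) NULL)
  if (!is.null(mw)) starts <- c(starts, list(mw))
  n_random <- max(cfg$n_restarts - length(starts), 0L)
  if (n_random > 0) {
    dirichlet <- with_local_seed(cfg$seed, function() {
      lapply(seq_len(n_random), function(i) normalize_weights(rgamma(kappa, 1)))
    })
    starts <- c(starts, dirichlet)
  }
  starts <- starts[seq_len(min(length(starts), cfg$n_restarts))]

  candidates <- list()
  start_idx <- integer(length(starts))
  for (i in seq_along(starts)) {
    w0 <- pmax(starts[[i]], 1e-8)
    z0 <- log(w0[-kappa]) - log(w0[kappa])
    candidates[[length(candidates) + 1L]] <- softmax(c(z0, 0))
    start_idx[i] <- length(candidates)
    fit <- tryCatch(
      if (kappa == 2L) {
        # one free log-ratio: bounded Brent instead of Nelder-Mead
        optim(z0, fn, method = "Brent", lower = z0 - 30, upper = z0 + 30,
              control = list(fnscale = -1, reltol = cfg$tolerance,
                             maxit = cfg$max_evals))
      } else {
        optim(z0, fn, method = "Nelder-Mead",
              control = list(fnscale = -1, reltol = cfg$tolerance,
                             maxit = cfg$max_evals))
      },
      error = function(e) NULL
    )
    if (!is.null(fit) && is.finite(fit$value)) {
      candidates[[length(candidates) + 1L]] <- softmax(c(fit$par, 0))
    }
  }
  if (length(candidates) == 0L) {
    stop("objective evaluation failed at every start", call. = FALSE)
  }
  # re-evaluate every start and every local optimum in double precision;
  # the reported optimum is exact and never worse than any start
  cand_L <- vapply(candidates, function(w)
    obj_from_rho(w, pool, N, k, rho, thetas_t, prior_t, B), numeric(1))
  evals <- evals + length(candidates)
  best <- which.max(cand_L)
  best_w <- candidates[[best]]
  start_values <- cand_L[start_idx]
  structure(
    list(w_star = as.numeric(best_w), L_star = cand_L[best],
         selected_indices = select_closest(pool, best_w, N),
         n_evals = evals, start_values = start_values),
    class = "weight_search_result"
  )
}

#' @export
print.weight_search_result <- function(x, ...) {
  cat(sprintf("weight search: L* = %.4f after %d objective evaluations\n",
              x$L_star, x$n_evals))
  cat("w* =", paste(sprintf("%.3f", x$w_star), collapse = " "), "\n")
  invisible(x)
}
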