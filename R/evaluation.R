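#' Exact posterior for the uniform toy model
#'
#' With r i.i.d. Uniform[0, theta] observations and a prior uniform on
#' log10(theta) over [lower, upper], the likelihood is
#' \eqn{\theta^{-r} 1[\theta \ge \max_i y_i]} and the posterior density on the
#' log10 inference scale u is proportional to \eqn{10^{-ru}} on
#' [log10 max(y), log10 upper]: a truncated exponential with a closed-form
#' inverse CDF.
#'
#' @param observed the observed dataset (order statistics); only its maximum
#'   matters.
#' @param prior_bounds natural-scale prior bounds, default c(1, 100).
#' @return An object of class \code{exact_posterior}: list with
#'   \code{density} (unnormalized, on the inference scale), \code{sampler}
#'   (function of n returning an n x 1 matrix of log10-theta draws),
#'   \code{cdf}, and \code{support}.
#' @export
exact_posterior_uniform_toy <- function(observed, prior_bounds = c(1, 100)) {
  stopifnot(length(observed) >= 1, all(is.finite(observed)))
  r <- length(observed)
  lo <- log10(max(max(observed), prior_bounds[1]))
  hi <- log10(prior_bounds[2])
  if (lo >= hi) stop("degenerate support: max(observed) >= upper prior bound", call. = FALSE)
  rate <- r * log(10)  # density on u: exp(-rate * (u - lo)) on [lo, hi]
  z <- 1 - exp(-rate * (hi - lo))
  cdf <- function(u) {
    pmin(pmax((1 - exp(-rate * (u - lo))) / z, 0), 1)
  }
  sampler <- function(n) {
    u <- runif(n)
    matrix(lo - log(1 - u * z) / rate, ncol = 1)
  }
  structure(
    list(density = function(u) ifelse(u >= lo & u <= hi, 10^(-r * u), 0),
         sampler = sampler, cdf = cdf, support = c(lo, hi)),
    class = "exact_posterior"
  )
}

#' Exact grid posterior for the bimodal sine model
#'
#' The likelihood is explicit Gaussian, so the posterior is evaluated on a
#' regular grid over the prior box [0, 2*pi]^2 and normalized; the sampler
#' draws grid cells by weight and jitters uniformly within the cell. For the
#' observation \eqn{(\sqrt2/2, -\sqrt2/2)} the density has four well-separated
#' local maxima.
#'
#' @param observed numeric 2-vector.
#' @param resolution grid points per axis (at least 32, for mode separation).
#' @param noise_sd observation noise standard deviation of the model.
#' @return An \code{exact_posterior} with additional elements \code{grid}
#'   (axis values) and \code{density_matrix} (normalized cell probabilities).
#' @export
exact_posterior_bimodal <- function(observed, resolution = 128, noise_sd = 0.1) {
  stopifnot(length(observed) == 2L)
  if (resolution < 32) stop("'resolution' must be at least 32", call. = FALSE)
  h <- 2 * pi / resolution
  ax <- h * (seq_len(resolution) - 0.5)  # cell centres
  ll1 <- -(sin(ax) - observed[1])^2 / (2 * noise_sd^2)
  ll2 <- -(sin(ax) - observed[2])^2 / (2 * noise_sd^2)
  logd <- outer(ll1, ll2, "+")
  dmat <- exp(logd - max(logd))
  dmat <- dmat / sum(dmat)
  sampler <- function(n) {
    cells <- sample.int(length(dmat), n, replace = TRUE, prob = as.vector(dmat))
    i <- (cells - 1L) %% resolution + 1L
    j <- (cells - 1L) %/% resolution + 1L
    cbind(ax[i] + runif(n, -h / 2, h / 2), ax[j] + runif(n, -h / 2, h / 2))
  }
  density <- function(theta) {
    if (is.vector(theta)) theta <- matrix(theta, nrow = 1)
    exp(-(sin(theta[, 1]) - observed[1])^2 / (2 * noise_sd^2) -
          (sin(theta[, 2]) - observed[2])^2 / (2 * noise_sd^2))
  }
  structure(
    list(density = density, sampler = sampler, support = c(0, 2 * pi),
         grid = ax, density_matrix = dmat),
    class = "exact_posterior"
  )
}

#' Maximum a posteriori estimate from a weighted particle sample
#'
#' The mode of a weighted Gaussian kernel density estimate over the particles
#' (Silverman's rule bandwidth per component, using the effective sample
#' size), located by evaluating the KDE at every particle and polishing the
#' best particle with a local Nelder-Mead ascent. Deterministic; exact ties
#' between particles are broken toward the lexicographically smaller point.
#'
#' @param particles numeric matrix of particles (rows, inference scale).
#' @param weights importance weights (any positive scale).
#' @return Numeric parameter vector.
#' @export
map_estimate <- function(particles, weights = NULL) {
  particles <- as_sample_matrix(particles, "particles")
  n <- nrow(particles)
  p <- ncol(particles)
  if (n < 2L) stop("need at least two particles", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (all(weights == 0)) stop("all weights are zero", call. = FALSE)
  w <- weights / sum(weights)
  neff <- 1 / sum(w^2)
  mom <- weighted_moments(particles, w)
  bw <- 1.06 * sqrt(pmax(mom$var, 0)) * neff^(-1 / (4 + p))
  if (all(bw == 0)) return(particles[1, ])  # all particles identical
  bw[bw == 0] <- min(bw[bw > 0]) * 1e-3
  kde <- function(x) {
    lg <- -0.5 * colSums((t(particles) - x)^2 / bw^2)
    sum(w * exp(lg))
  }
  # KDE at every particle, chunked to keep the pairwise distance blocks small
  y <- sweep(particles, 2L, bw, "/")
  ynorm <- rowSums(y^2)
  dens_at <- numeric(n)
  chunk <- 512L
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d2 <- outer(ynorm[s:e], ynorm, "+") - 2 * tcrossprod(y[s:e, , drop = FALSE], y)
    dens_at[s:e] <- exp(-0.5 * pmax(d2, 0)) %*% w
  }
  best <- which(dens_at == max(dens_at))
  if (length(best) > 1L) {
    ord <- do.call(order, as.data.frame(particles[best, , drop = FALSE]))
    best <- best[ord[1]]
  }
  x0 <- particles[best, ]
  if (p == 1L) {
    # local polish only: a wider bracket could jump to a different mode and
    # break the deterministic tie rule
    fit <- stats::optimize(function(x) kde(x), maximum = TRUE,
                           lower = x0 - bw, upper = x0 + bw,
                           tol = 1e-10)
    if (fit$objective >= dens_at[best]) fit$maximum else x0
  } else {
    fit <- optim(x0, kde, method = "Nelder-Mead",
                 control = list(fnscale = -1, reltol = 1e-10, maxit = 500))
    if (fit$value >= dens_at[best]) fit$par else x0
  }
}

#' Posterior quality metrics for a completed run
#'
#' Computes the evaluation metrics for the final particle population:
#' \describe{
#'   \item{hellinger_prior_post}{k-NN Hellinger distance
#'     \eqn{\sqrt{1 - \hat D_{1/2}}} between fresh prior draws (a dedicated
#'     substream, not the reference sample used inside the weight search) and
#'     the final particles; larger means more information gained.
#'     \eqn{1 - D_{1/2}} itself is the squared Hellinger distance, so the
#'     reported metric is on the Hellinger-distance scale.}
#'   \item{hellinger_post_exact}{the same distance between draws from the
#'     exact posterior and the final particles (estimator direction: exact
#'     draws first); smaller means a better approximation. \code{NA} when no
#'     exact posterior is available.}
#'   \item{mse}{weighted mean squared Euclidean distance of the particles to
#'     the problem's reference point (the true parameter, or the mode centre
#'     for the bimodal problem), on the inference scale.}
#'   \item{bias / bias_mean}{Euclidean distance of the KDE-mode MAP estimate
#'     (and of the posterior mean) from the true parameter on the inference
#'     scale.}
#' }
#'
#' @param run an \code{abc_run}.
#' @param problem the \code{abc_problem} it was run on.
#' @param exact optional \code{exact_posterior}.
#' @param k neighbour order for the Hellinger estimates.
#' @param metric_seed seed of the fresh prior / exact-posterior draw
#'   substream; defaults to a stream derived from the run's seed.
#' @return A one-row data frame (metrics row).
#' @export
compute_metrics <- function(run, problem, exact = NULL, k = 5,
                            metric_seed = NULL) {
  stopifnot(inherits(run, "abc_run"), inherits(problem, "abc_problem"))
  if (is.null(metric_seed)) metric_seed <- derive_seed(run$config$seed, "metrics")
  final <- run$populations[[length(run$populations)]]
  N <- nrow(final$theta)
  draws <- with_local_seed(metric_seed, function() {
    list(prior = prior_sample(problem, N),
         exact = if (!is.null(exact)) exact$sampler(N) else NULL)
  })
  # 1 - D_{1/2} is the squared Hellinger distance (D_{1/2} is the
  # Bhattacharyya coefficient); the reported metric is the Hellinger
  # distance itself, H = sqrt(1 - D_hat_{1/2}). The weight search maximizes
  # 1 - D_hat, which has the same argmax.
  h_pp <- sqrt(hellinger_estimate(draws$prior, final$theta, k = k)$value)
  h_pe <- if (!is.null(exact)) {
    sqrt(hellinger_estimate(draws$exact, final$theta, k = k)$value)
  } else NA_real_
  ref <- problem$reference_point
  mse <- sum(final$v * colSums((t(final$theta) - ref)^2))
  map <- map_estimate(final$theta, final$v)
  pm <- weighted_moments(final$theta, final$v)$mean
  truth <- problem$theta_true_inference
  data.frame(
    problem = problem$name, method = run$config$method,
    N = run$config$N, alpha = run$config$alpha, T = run$config$T,
    hellinger_prior_post = h_pp, hellinger_post_exact = h_pe,
    mse = mse,
    bias = sqrt(sum((map - truth)^2)),
    bias_mean = sqrt(sum((pm - truth)^2)),
    n_simulations = run$n_simulations,
    runtime_s = run$runtime_s,
    stringsAsFactors = FALSE
  )
}

#' Repeated-run benchmark harness
#'
#' Runs each weighting method \code{n_repeats} times on a problem (seeds
#' derived deterministically from \code{seed}) and collects the per-run
#' metrics plus per-method aggregate means.
#'
#' @param problem an \code{abc_problem}.
#' @param methods character vector of weighting methods to compare.
#' @param n_repeats runs per method.
#' @param N,alpha,T,k,kernel_scale run settings shared across methods.
#' @param seed master seed.
#' @param exact optional \code{exact_posterior} for the
#'   posterior-versus-exact metric.
#' @param search a \code{\link{search_config}}.
#' @param fresh_data if \code{TRUE}, regenerate the observed dataset for each
#'   repeat (a new problem seed per repeat), as in repeated-run comparisons on
#'   different datasets.
#' @return A data frame with one row per (method, repeat) and one aggregate
#'   row per method (\code{repeat == NA}).
#' @export
benchmark_repeat <- function(problem, methods = c("adaptive", "uniform", "scaled"),
                             n_repeats = 1, N = 500, alpha = 0.5, T = 5, k = 5,
                             kernel_scale = 2, seed = 1L, exact = NULL,
                             search = search_config(), fresh_data = FALSE) {
  stopifnot(n_repeats >= 1)
  rows <- list()
  for (method in methods) {
    for (rep_i in seq_len(n_repeats)) {
      run_seed <- derive_seed(seed, paste0(method, "-rep", rep_i))
      prob_i <- problem
      exact_i <- exact
      if (fresh_data) {
        prob_i <- make_problem(problem$name, obs_seed = derive_seed(seed, paste0("data", rep_i)))
        if (!is.null(exact) && problem$name == "uniform_toy") {
          exact_i <- exact_posterior_uniform_toy(prob_i$observed)
        }
      }
      cfg <- smc_config(N = N, alpha = alpha, T = T, method = method, k = k,
                        kernel_scale = kernel_scale, seed = run_seed,
                        search = search)
      run <- run_abc(prob_i, cfg)
      row <- compute_metrics(run, prob_i, exact = exact_i, k = k)
      row$repeat_id <- rep_i
      rows[[length(rows) + 1L]] <- row
    }
  }
  tab <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(unique(tab$method), function(m) {
    sub <- tab[tab$method == m, ]
    out <- sub[1, ]
    num <- vapply(sub, is.numeric, logical(1))
    out[num] <- lapply(sub[num], mean, na.rm = TRUE)
    out$repeat_id <- NA_integer_
    out
  }))
  rbind(tab, agg)
}
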