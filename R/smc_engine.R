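#' SMC run configuration
#'
#' @param N number of particles kept per generation.
#' @param alpha acceptance proportion in (0, 1]; each generation simulates
#'   \code{M = ceiling(N / alpha)} accepted candidates and keeps the closest
#'   \code{N}.
#' @param T number of generations.
#' @param method weighting scheme: \code{"adaptive"} (per-generation weight
#'   optimization), \code{"uniform"} (equal weights) or \code{"scaled"}
#'   (MAD-scaled weights recomputed each generation).
#' @param k neighbour order of the Hellinger estimator.
#' @param kernel_scale multiplier on the previous population's weighted
#'   component variances for the Gaussian perturbation kernel.
#' @param seed master seed; all per-generation randomness derives from it.
#' @param max_proposals cap on simulated proposals per generation; default
#'   \code{200 * M}.
#' @param search a \code{\link{search_config}} for the weight optimizer.
#' @return An object of class \code{smc_config}.
#' @export
smc_config <- function(N, alpha, T = 10, method = c("adaptive", "uniform", "scaled"),
                       k = 5, kernel_scale = 2, seed = 1L, max_proposals = NULL,
                       search = search_config()) {
  method <- match.arg(method)
  stopifnot(is_count(N), N >= 2, is.numeric(alpha), length(alpha) == 1L,
            alpha > 0, alpha <= 1, is_count(T), T >= 1, is_count(k), k >= 1,
            kernel_scale >= 0, is_count(seed))
  M <- as.integer(ceiling(N / alpha))
  if (is.null(max_proposals)) max_proposals <- 200 * M
  structure(
    list(N = as.integer(N), alpha = alpha, T = as.integer(T), M = M,
         method = method, k = as.integer(k), kernel_scale = kernel_scale,
         seed = as.integer(seed), max_proposals = max_proposals,
         search = search),
    class = "smc_config"
  )
}

#' Tolerance as an order-statistic quantile of candidate distances
#'
#' Returns the \code{ceiling(alpha * M)}-th smallest distance, the
#' per-generation tolerance \eqn{\epsilon_t}.
#'
#' @param distances non-empty numeric vector.
#' @param alpha quantile level in (0, 1].
#' @return A scalar.
#' @export
tolerance_quantile <- function(distances, alpha) {
  if (length(distances) == 0L) stop("'distances' must be non-empty", call. = FALSE)
  stopifnot(alpha > 0, alpha <= 1)
  sort(distances)[ceiling(alpha * length(distances))]
}

# weighted mean / variance of a particle population (v normalized)
weighted_moments <- function(theta, v) {
  mu <- colSums(theta * v)
  centered <- sweep(theta, 2L, mu)
  list(mean = mu, var = colSums(centered^2 * v))
}

#' Gaussian perturbation kernel standard deviations
#'
#' Component standard deviations of the perturbation kernel \eqn{K_t}:
#' \code{sqrt(kernel_scale * weighted sample variance)} of the previous
#' population. Degenerate components fall back to a small fixed jitter.
#'
#' @param prev an \code{abc_population}.
#' @param kernel_scale variance multiplier (2 is the standard ABC-SMC choice).
#' @return Numeric vector of standard deviations, one per parameter.
#' @export
kernel_sds <- function(prev, kernel_scale) {
  v <- weighted_moments(prev$theta, prev$v)$var
  s <- sqrt(kernel_scale * v)
  if (any(s <= 0)) {
    warning("degenerate previous-population variance; using fixed jitter")
    s[s <= 0] <- 1e-6
  }
  s
}

#' Perturb a parameter vector with the SMC kernel
#'
#' @param theta parameter vector on the inference scale.
#' @param prev previous \code{abc_population}.
#' @param kernel_scale variance multiplier.
#' @return The perturbed parameter vector.
#' @export
perturb <- function(theta, prev, kernel_scale = 2) {
  s <- if (kernel_scale > 0) kernel_sds(prev, kernel_scale) else rep(0, length(theta))
  theta + rnorm(length(theta), 0, s)
}

#' Importance weights for an SMC generation
#'
#' \eqn{v_i = \pi(\theta_i) / \sum_j v_{t-1,j} K_t(\theta_{t-1,j}, \theta_i)},
#' the standard ABC-SMC correction for sampling from the perturbed previous
#' population instead of the prior. Generation 1 bypasses this (all weights
#' equal).
#'
#' @param theta matrix of accepted parameters (rows, inference scale).
#' @param prior_density_values prior density at each row of \code{theta}.
#' @param prev previous \code{abc_population} (normalized weights).
#' @param sds kernel component standard deviations.
#' @return Unnormalized positive weights.
#' @export
importance_weights <- function(theta, prior_density_values, prev, sds) {
  denom <- cpp_kernel_mixture_density(t(theta), t(prev$theta), prev$v, sds)
  if (any(denom <= 0)) stop("zero kernel mixture density: kernel misconfiguration", call. = FALSE)
  prior_density_values / denom
}

# draw perturbed proposals from the previous population until all lie inside
# the prior support ("if pi(theta) = 0, resample and repeat")
propose_from_previous <- function(problem, prev, sds, n) {
  box <- prior_box(problem)
  cpp_propose(prev$theta, prev$v, sds, box[, 1], box[, 2], as.integer(n))
}

# choose the generation's weight vector and kept particles for a candidate set
weighting_step <- function(method, thetas, summaries, observed, prior_reference,
                           N, k, search_cfg) {
  kappa <- ncol(summaries)
  pool <- candidate_pool(thetas, summaries, observed, prior_reference)
  if (method == "adaptive") {
    res <- optimize_weights(pool, N, k, search_cfg)
    w <- res$w_star
    idx <- res$selected_indices
    L <- res$L_star
  } else {
    w <- if (method == "uniform") uniform_weights(kappa) else mad_weights(summaries)
    idx <- select_closest(pool, w, N)
    L <- weight_objective(w, pool, N, k)
  }
  dist_all <- cpp_weighted_dist(summaries, observed, w)
  list(w = w, idx = idx, L = L, dist_all = dist_all)
}

#' Run one generation of (adaptive) ABC-SMC
#'
#' Generation 1 draws \code{M} candidates from the prior; later generations
#' propose perturbed particles from the previous population and keep
#' simulating until \code{M} candidates satisfy every stored
#' previous-generation acceptance threshold (the nested acceptance rule
#' \eqn{d_{w_j^*}(s, s(y)) < \epsilon_j} for all \eqn{j < t}). The
#' generation's weights are then fixed (uniform / MAD-scaled) or optimized
#' (adaptive), the closest \code{N} candidates are kept, the tolerance
#' \eqn{\epsilon_t} is the alpha-quantile of the generation's raw proposal
#' distances under those weights (this keeps the proposal acceptance rate
#' near alpha from one generation to the next; quantiling only the accepted
#' candidates would compound the threshold and collapse the acceptance
#' rate geometrically), and importance weights are computed and normalized.
#'
#' @param problem an \code{abc_problem}.
#' @param prev previous \code{abc_population}, or \code{NULL} for
#'   generation 1.
#' @param cfg an \code{smc_config}.
#' @param gen_index generation number t.
#' @param history list of previous populations (for the nested thresholds).
#' @return An object of class \code{abc_population}: list with \code{theta}
#'   (N x p matrix), \code{v} (normalized importance weights),
#'   \code{distance}, \code{w_star}, \code{epsilon}, \code{L_star},
#'   \code{n_simulations}, \code{n_proposals}.
#' @export
run_generation <- function(problem, prev, cfg, gen_index, history = list()) {
  M <- cfg$M
  N <- cfg$N
  observed <- problem$observed
  search_cfg <- cfg$search
  search_cfg$seed <- derive_seed(cfg$seed, paste0("search", gen_index))

  if (gen_index == 1L) {
    thetas <- prior_sample(problem, M)
    summaries <- problem$simulate_batch(thetas)
    n_prop <- M
    prop_pool <- summaries  # generation 1: candidates are the raw proposals
    n_pool_total <- M
  } else {
    stopifnot(!is.null(prev))
    sds <- kernel_sds(prev, cfg$kernel_scale)
    hist_W <- vapply(history, `[[`, numeric(problem$kappa), "w_star")
    hist_W <- matrix(hist_W, nrow = problem$kappa)
    hist_eps <- vapply(history, `[[`, numeric(1), "epsilon")
    thetas <- matrix(NA_real_, 0, problem$dim_theta)
    summaries <- NULL
    n_prop <- 0L
    # representative sample of raw proposal summaries for the epsilon
    # quantile; proposals within a generation are exchangeable, so keeping
    # the first pool_cap of them is unbiased
    pool_cap <- 200000L
    prop_pool <- NULL
    rate <- 0.5  # adapted from observed acceptance as batches complete
    while (nrow(thetas) < M) {
      remaining <- M - nrow(thetas)
      # cap single batches so low acceptance rates cannot request huge
      # simulation blocks in one allocation
      batch <- min(max(ceiling(remaining / rate * 1.1), 64L), 1000000L,
                   cfg$max_proposals - n_prop)
      if (batch <= 0) {
        # proposal budget exhausted: the nested acceptance region has become
        # too tight to fill the full candidate pool. With at least N accepted
        # candidates the generation can still complete (the weight search and
        # closest-N selection just see a smaller pool); below N there is no
        # valid population and the run stops, naming the binding threshold.
        if (nrow(thetas) >= N) {
          warning(sprintf(
            "generation %d: max_proposals (%d) exhausted with %d of %d candidates; continuing with the smaller pool",
            gen_index, cfg$max_proposals, nrow(thetas), M), call. = FALSE)
          break
        }
        j_bind <- if (is.null(prop_pool)) length(history) else {
          which.min(vapply(seq_along(history), function(j) {
            mean(cpp_weighted_dist(prop_pool, observed, history[[j]]$w_star) <
                   history[[j]]$epsilon)
          }, numeric(1)))
        }
        stop(sprintf(
          "generation %d: max_proposals (%d) exhausted before %d acceptances; binding threshold epsilon_%d = %.4g",
          gen_index, cfg$max_proposals, N, j_bind,
          history[[j_bind]]$epsilon), call. = FALSE)
      }
      prop <- propose_from_previous(problem, prev, sds, batch)
      sims <- problem$simulate_batch(prop)
      n_prop <- n_prop + batch
      if (is.null(prop_pool)) {
        prop_pool <- sims[seq_len(min(batch, pool_cap)), , drop = FALSE]
      } else if (nrow(prop_pool) < pool_cap) {
        take <- min(batch, pool_cap - nrow(prop_pool))
        prop_pool <- rbind(prop_pool, sims[seq_len(take), , drop = FALSE])
      }
      keep <- cpp_nested_accept(sims, observed, hist_W, hist_eps)
      thetas <- rbind(thetas, prop[keep, , drop = FALSE])
      summaries <- rbind(summaries, sims[keep, , drop = FALSE])
      rate <- max(nrow(thetas) / n_prop, 0.01)
    }
    if (nrow(thetas) > M) {
      thetas <- thetas[seq_len(M), , drop = FALSE]
      summaries <- summaries[seq_len(M), , drop = FALSE]
    }
    n_pool_total <- n_prop
  }

  prior_reference <- prior_sample(problem, N)  # fresh draws each generation
  ws <- weighting_step(cfg$method, thetas, summaries, observed,
                       prior_reference, N, cfg$k, search_cfg)
  kept <- ws$idx
  theta_kept <- thetas[kept, , drop = FALSE]
  # epsilon_t: alpha-quantile of the generation's raw proposal distances
  # under the accepted weights (at t = 1 the proposals are the candidates)
  d_pool <- cpp_weighted_dist(prop_pool, observed, ws$w)
  epsilon <- tolerance_quantile(d_pool, cfg$alpha)

  if (gen_index == 1L) {
    v <- rep(1 / N, N)
  } else {
    pd <- prior_density(problem, theta_kept)
    v <- importance_weights(theta_kept, pd, prev, sds)
    v <- v / sum(v)
  }

  structure(
    list(generation = gen_index, theta = theta_kept, v = v,
         distance = ws$dist_all[kept], summaries = summaries[kept, , drop = FALSE],
         w_star = ws$w, epsilon = epsilon,
         L_star = ws$L, method = cfg$method,
         n_simulations = n_prop, n_proposals = n_prop),
    class = "abc_population"
  )
}

#' Run rejection ABC / ABC-SMC / adaptive ABC-SMC
#'
#' Runs \code{cfg$T} generations of the sequential algorithm for the given
#' benchmark problem. With \code{T = 1} this is rejection ABC (keep the
#' closest proportion alpha of prior simulations); with
#' \code{method = "uniform"} or \code{"scaled"} it is standard ABC-SMC with
#' fixed or MAD-scaled distance weights; with \code{method = "adaptive"} the
#' distance weights are re-optimized every generation by maximizing the
#' estimated prior-to-posterior Hellinger distance. Identical seeds give
#' bit-identical results.
#'
#' @param problem an \code{abc_problem}, e.g. from \code{\link{make_problem}}.
#' @param cfg an \code{\link{smc_config}}.
#' @return An object of class \code{abc_run}: list with \code{populations}
#'   (one \code{abc_population} per generation), \code{w_schedule}
#'   (T x kappa matrix of accepted weight vectors), \code{eps_schedule},
#'   \code{n_simulations}, \code{config}, \code{problem_name},
#'   \code{runtime_s}.
#' @export
run_abc <- function(problem, cfg) {
  stopifnot(inherits(problem, "abc_problem"), inherits(cfg, "smc_config"))
  t0 <- proc.time()[["elapsed"]]
  gen_seeds <- vapply(seq_len(cfg$T), function(t) derive_seed(cfg$seed, paste0("gen", t)),
                      integer(1))
  populations <- vector("list", cfg$T)
  prev <- NULL
  for (t in seq_len(cfg$T)) {
    set.seed(gen_seeds[t])
    populations[[t]] <- run_generation(problem, prev, cfg, t,
                                       history = populations[seq_len(t - 1L)])
    prev <- populations[[t]]
  }
  w_schedule <- do.call(rbind, lapply(populations, `[[`, "w_star"))
  structure(
    list(populations = populations,
         w_schedule = w_schedule,
         eps_schedule = vapply(populations, `[[`, numeric(1), "epsilon"),
         L_schedule = vapply(populations, `[[`, numeric(1), "L_star"),
         n_simulations = sum(vapply(populations, `[[`, numeric(1), "n_simulations")),
         config = cfg, problem_name = problem$name,
         runtime_s = proc.time()[["elapsed"]] - t0),
    class = "abc_run"
  )
}

#' Final particle sample of a run
#'
#' @param run an \code{abc_run}.
#' @return The final generation's particle matrix (N x p, inference scale).
#' @export
final_particles <- function(run) {
  run$populations[[length(run$populations)]]$theta
}

#' @export
print.abc_run <- function(x, ...) {
  cat(sprintf("ABC-SMC run on '%s' (%s weights): N = %d, alpha = %g, T = %d\n",
              x$problem_name, x$config$method, x$config$N, x$config$alpha,
              x$config$T))
  cat(sprintf("total simulations: %d; runtime %.1f s\n",
              x$n_simulations, x$runtime_s))
  cat("epsilon schedule:", paste(signif(x$eps_schedule, 4), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.abc_population <- function(x, ...) {
  cat(sprintf("generation %d: %d particles, epsilon = %.4g, L = %.4f (%s weights)\n",
              x$generation, nrow(x$theta), x$epsilon, x$L_star, x$method))
  invisible(x)
}
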