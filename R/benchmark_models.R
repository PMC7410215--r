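#' Mass-action reaction network
#'
#' Describes a chemical reaction network for the Gillespie direct-method
#' simulator. Propensities follow stochastic mass-action kinetics with
#' combinatorial counts: a reaction of order one in species S has propensity
#' \eqn{c\,S}, a homodimerization \eqn{S + S \to \cdot} has propensity
#' \eqn{c\,S(S-1)/2}.
#'
#' @param species character vector of species names.
#' @param stoich integer matrix (reactions x species) of state-change vectors.
#' @param orders integer matrix (reactions x species) of reactant orders.
#' @param initial nonnegative integer initial state, one entry per species.
#' @return An object of class \code{reaction_network}.
#' @export
reaction_network <- function(species, stoich, orders, initial) {
  stoich <- as.matrix(stoich)
  orders <- as.matrix(orders)
  storage.mode(stoich) <- "integer"
  storage.mode(orders) <- "integer"
  stopifnot(ncol(stoich) == length(species), identical(dim(stoich), dim(orders)),
            length(initial) == length(species), all(initial >= 0),
            all(initial == as.integer(initial)), all(orders >= 0))
  structure(
    list(species = species, stoich = stoich, orders = orders,
         initial = as.numeric(initial)),
    class = "reaction_network"
  )
}

#' Exact stochastic simulation (Gillespie direct method)
#'
#' Samples one exact trajectory of a mass-action reaction network and records
#' the state at the requested observation times. Between observation times
#' every reaction firing is simulated individually; states are always
#' nonnegative integers.
#'
#' @param network a \code{\link{reaction_network}}.
#' @param rates nonnegative rate constants, one per reaction.
#' @param times strictly increasing observation times (time starts at 0).
#' @param max_steps guard on the number of reaction firings.
#' @return Numeric matrix with one row per observation time and one column per
#'   species.
#' @export
gillespie_direct <- function(network, rates, times, max_steps = 1e9) {
  stopifnot(inherits(network, "reaction_network"),
            length(rates) == nrow(network$stoich), all(rates >= 0),
            length(times) >= 1, all(diff(times) > 0), times[1] >= 0)
  out <- cpp_gillespie(network$initial, network$stoich, network$orders,
                       as.numeric(rates), as.numeric(times), max_steps)
  colnames(out) <- network$species
  out
}

#' Uniform toy model simulator
#'
#' Draws \code{r} i.i.d. Uniform[0, theta] observations and returns them
#' sorted ascending: the summary statistics are the order statistics of the
#' sample, the last of which (the sample maximum) is sufficient for theta.
#'
#' @param theta positive scale parameter (natural scale).
#' @param r number of observations.
#' @return Sorted numeric vector of length \code{r}.
#' @export
simulate_uniform_toy <- function(theta, r = 10) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0) {
    stop("'theta' must be a positive scalar", call. = FALSE)
  }
  if (!is_count(r) || r < 1) stop("'r' must be a positive integer", call. = FALSE)
  sort(runif(r, 0, theta))
}

#' Bimodal sine model simulator
#'
#' Observation model \eqn{s \sim N((\sin\theta_1, \sin\theta_2), 0.1^2 I_2)}
#' on \eqn{\theta \in [0, 2\pi]^2}. With observed summary
#' \eqn{(\sqrt2/2, -\sqrt2/2)} the posterior has four well-separated modes.
#'
#' @param theta numeric 2-vector.
#' @param noise_sd observation noise standard deviation.
#' @return Numeric 2-vector.
#' @export
simulate_bimodal <- function(theta, noise_sd = 0.1) {
  stopifnot(length(theta) == 2L)
  sin(theta) + rnorm(2L, 0, noise_sd)
}

dimerization_network <- function() {
  # R1: S1 -> 0;  R2: S2 -> S3;  R3: S1 + S1 -> S2;  R4: S2 -> S1 + S1
  reaction_network(
    species = c("S1", "S2", "S3"),
    stoich = rbind(c(-1L, 0L, 0L), c(0L, -1L, 1L), c(-2L, 1L, 0L), c(2L, -1L, 0L)),
    orders = rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(2L, 0L, 0L), c(0L, 1L, 0L)),
    initial = c(1e5, 0, 0)
  )
}

diffusion_network <- function(m = 8, n_left = 10) {
  # nearest-neighbour jumps on m voxels with zero-flux boundaries; every jump
  # reaction has the same rate constant theta = D / h^2
  n_jump <- 2L * (m - 1L)
  stoich <- matrix(0L, n_jump, m)
  orders <- matrix(0L, n_jump, m)
  jr <- 1L
  for (v in seq_len(m - 1L)) {
    stoich[jr, v] <- -1L; stoich[jr, v + 1L] <- 1L; orders[jr, v] <- 1L  # right
    jr <- jr + 1L
    stoich[jr, v + 1L] <- -1L; stoich[jr, v] <- 1L; orders[jr, v + 1L] <- 1L  # left
    jr <- jr + 1L
  }
  initial <- c(rep(n_left, m / 2), rep(0, m / 2))
  reaction_network(paste0("V", seq_len(m)), stoich, orders, initial)
}

make_problem_spec <- function(name, prior, simulate, simulate_batch, theta_true,
                              observed, reference_point = NULL, obs_seed = NULL) {
  p <- nrow(prior)
  inf_true <- ifelse(prior$scale == "log10", log10(theta_true), theta_true)
  structure(
    list(name = name, dim_theta = p, kappa = length(observed),
         prior = prior, simulate = simulate, simulate_batch = simulate_batch,
         theta_true = theta_true, theta_true_inference = inf_true,
         observed = observed,
         reference_point = if (is.null(reference_point)) inf_true else reference_point,
         obs_seed = obs_seed),
    class = "abc_problem"
  )
}

#' @export
print.abc_problem <- function(x, ...) {
  cat(sprintf("ABC benchmark problem '%s': %d parameter(s), %d summary statistics\n",
              x$name, x$dim_theta, x$kappa))
  cat(sprintf("true theta: %s\n", paste(signif(x$theta_true, 4), collapse = ", ")))
  invisible(x)
}

# prior helpers: the inference scale is linear for uniform components and
# log10 for log-uniform components, so the prior is a uniform box there
prior_box <- function(problem) {
  lo <- ifelse(problem$prior$scale == "log10", log10(problem$prior$lower),
               problem$prior$lower)
  hi <- ifelse(problem$prior$scale == "log10", log10(problem$prior$upper),
               problem$prior$upper)
  cbind(lower = lo, upper = hi)
}

#' Sample from a problem's prior on the inference scale
#'
#' @param problem an \code{abc_problem}.
#' @param n number of draws.
#' @return Numeric matrix (n x dim_theta) on the inference scale (log10 for
#'   log-uniform components).
#' @export
prior_sample <- function(problem, n) {
  box <- prior_box(problem)
  m <- matrix(runif(n * problem$dim_theta), n, problem$dim_theta)
  sweep(sweep(m, 2L, box[, 2] - box[, 1], "*"), 2L, box[, 1], "+")
}

#' Prior density on the inference scale
#'
#' Constant inside the prior box, zero outside.
#'
#' @param problem an \code{abc_problem}.
#' @param theta matrix of parameter points (rows) on the inference scale, or a
#'   single parameter vector.
#' @return Numeric vector of densities.
#' @export
prior_density <- function(problem, theta) {
  if (is.vector(theta)) theta <- matrix(theta, nrow = 1)
  box <- prior_box(problem)
  dens <- 1 / prod(box[, 2] - box[, 1])
  inside <- rep(TRUE, nrow(theta))
  for (j in seq_len(ncol(theta))) {
    inside <- inside & theta[, j] >= box[j, 1] & theta[, j] <= box[j, 2]
  }
  ifelse(inside, dens, 0)
}

#' Built-in benchmark problems
#'
#' Constructs one of the four benchmark inference problems with its prior,
#' simulator, summary map, true parameter and observed summary vector. The
#' observed data are generated from the simulator at the true parameter under
#' a fixed problem seed (so a given \code{obs_seed} always regenerates the
#' identical observed summary); the bimodal problem instead uses the fixed
#' analytic observation \eqn{(\sqrt2/2, -\sqrt2/2)}.
#'
#' \describe{
#'   \item{uniform_toy}{r = 10 draws from Uniform[0, theta], summaries the
#'     order statistics; theta_true = 10, prior log10-uniform on [1, 100].}
#'   \item{bimodal}{two-parameter sine model with Gaussian observation noise
#'     (sd 0.1), uniform prior on [0, 2*pi]^2; four posterior modes.}
#'   \item{dimerization}{four-rate dimerization reaction system started from
#'     S1 = 1e5 molecules, observed at 8 geometrically spaced times in
#'     [0.1, 100] (24 summary statistics); log10-uniform priors;
#'     theta_true = (1, 0.04, 0.002, 0.5).}
#'   \item{diffusion}{particles jumping between 8 voxels at rate
#'     theta = D/h^2 with zero-flux boundaries, 10 particles initially in each
#'     left-hand voxel, observed at 8 equally spaced times in [2.5, 20]
#'     (64 summary statistics); theta_true = 0.1, prior log10-uniform on
#'     [1e-4, 1].}
#' }
#'
#' @param name one of \code{"uniform_toy"}, \code{"bimodal"},
#'   \code{"dimerization"}, \code{"diffusion"}.
#' @param obs_seed integer seed used to generate the observed dataset at the
#'   true parameter.
#' @return An object of class \code{abc_problem}. Its \code{simulate} element
#'   maps a parameter vector on the inference scale to a summary vector;
#'   \code{simulate_batch} maps a matrix of parameter rows to a summary
#'   matrix.
#' @export
make_problem <- function(name, obs_seed = 20200806L) {
  valid <- c("uniform_toy", "bimodal", "dimerization", "diffusion")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid)) {
    stop(sprintf("unknown problem '%s'; valid names: %s",
                 paste(name, collapse = ","), paste(valid, collapse = ", ")),
         call. = FALSE)
  }
  switch(
    name,
    uniform_toy = {
      r <- 10L
      prior <- data.frame(lower = 1, upper = 100, scale = "log10")
      sim <- function(theta) simulate_uniform_toy(10^theta[1], r)
      simb <- function(thetas) {
        cpp_uniform_toy_batch(10^thetas[, 1], r)
      }
      observed <- with_local_seed(obs_seed, function() simulate_uniform_toy(10, r))
      make_problem_spec("uniform_toy", prior, sim, simb, theta_true = 10,
                        observed = observed, obs_seed = obs_seed)
    },
    bimodal = {
      prior <- data.frame(lower = c(0, 0), upper = c(2 * pi, 2 * pi),
                          scale = c("linear", "linear"))
      sim <- function(theta) simulate_bimodal(theta)
      simb <- function(thetas) {
        sin(thetas) + matrix(rnorm(length(thetas), 0, 0.1), nrow(thetas), 2)
      }
      # analytic observation; the four modes are at sin(theta1) = sqrt(2)/2,
      # sin(theta2) = -sqrt(2)/2, centred on (pi/2, 3*pi/2)
      make_problem_spec("bimodal", prior, sim, simb,
                        theta_true = c(pi / 4, 5 * pi / 4),
                        observed = c(sqrt(2) / 2, -sqrt(2) / 2),
                        reference_point = c(pi / 2, 3 * pi / 2),
                        obs_seed = obs_seed)
    },
    dimerization = {
      net <- dimerization_network()
      times <- 0.1 * 1000^((0:7) / 7)  # 8 geometrically spaced times in [0.1, 100]
      prior <- data.frame(lower = c(1e-2, 1e-3, 1e-5, 1e-3),
                          upper = c(1e2, 1e1, 1e-1, 1e1),
                          scale = rep("log10", 4))
      sim <- function(theta) {
        as.vector(gillespie_direct(net, 10^theta, times))
      }
      simb <- function(thetas) {
        cpp_gillespie_batch(net$initial, net$stoich, net$orders, 10^thetas,
                            times, 1e10)
      }
      theta_true <- c(1, 0.04, 0.002, 0.5)
      observed <- with_local_seed(obs_seed, function() sim(log10(theta_true)))
      make_problem_spec("dimerization", prior, sim, simb, theta_true, observed,
                        obs_seed = obs_seed)
    },
    diffusion = {
      net <- diffusion_network()
      times <- seq(2.5, 20, by = 2.5)  # 8 equally spaced observation times
      n_jump <- nrow(net$stoich)
      prior <- data.frame(lower = 1e-4, upper = 1, scale = "log10")
      sim <- function(theta) {
        as.vector(gillespie_direct(net, rep(10^theta[1], n_jump), times))
      }
      simb <- function(thetas) {
        rates <- matrix(10^thetas[, 1], nrow(thetas), n_jump)
        cpp_gillespie_batch(net$initial, net$stoich, net$orders, rates,
                            times, 1e10)
      }
      observed <- with_local_seed(obs_seed, function() sim(log10(0.1)))
      make_problem_spec("diffusion", prior, sim, simb, theta_true = 0.1,
                        observed = observed, obs_seed = obs_seed)
    }
  )
}

#' @rdname make_problem
#' @export
make_dimerization_problem <- function(obs_seed = 20200806L) {
  make_problem("dimerization", obs_seed)
}

#' @rdname make_problem
#' @export
make_diffusion_problem <- function(obs_seed = 20200806L) {
  make_problem("diffusion", obs_seed)
}
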