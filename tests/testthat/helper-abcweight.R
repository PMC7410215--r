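# shared helpers for the test suite

# small sample matrices
col1 <- function(x) matrix(x, ncol = 1)

# a candidate pool for the uniform toy model at modest size
toy_pool <- function(M = 400, N = 100, seed = 1) {
  prob <- make_problem("uniform_toy")
  with_seed(seed, {
    th <- prior_sample(prob, M)
    sims <- prob$simulate_batch(th)
    candidate_pool(th, sims, prob$observed, prior_sample(prob, N))
  })
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# independent oracle for the voxel diffusion model: each particle performs its
# own continuous-time random walk on the voxel chain (rate theta to each
# available neighbour), so occupancy moments can be cross-checked against the
# reaction-network simulator without sharing any code with it
walk_diffusion_once <- function(theta, m = 8, n_left = 10, t_end = 20,
                                record = t_end) {
  pos <- rep(seq_len(m / 2), each = n_left)
  out <- matrix(0, length(record), m)
  for (p in seq_along(pos)) {
    t <- 0
    x <- pos[p]
    repeat {
      nbr <- c(if (x > 1) x - 1L, if (x < m) x + 1L)
      rate <- theta * length(nbr)
      t_next <- t + rexp(1, rate)
      for (ri in seq_along(record)) {
        if (t <= record[ri] && record[ri] < t_next) {
          out[ri, x] <- out[ri, x] + 1
        }
      }
      if (t_next > max(record)) break
      t <- t_next
      x <- if (length(nbr) == 2L) nbr[1 + (runif(1) < 0.5)] else nbr
    }
  }
  out
}

# run one seeded ABC configuration and return its metrics row
run_with_metrics <- function(problem, method, N, alpha, T, seed, exact = NULL) {
  cfg <- smc_config(N = N, alpha = alpha, T = T, method = method, seed = seed)
  run <- run_abc(problem, cfg)
  compute_metrics(run, problem, exact = exact)
}
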