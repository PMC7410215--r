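fake_population <- function(theta, v = NULL) {
  if (is.null(v)) v <- rep(1 / nrow(theta), nrow(theta))
  structure(list(generation = 1L, theta = theta, v = v / sum(v)),
            class = "abc_population")
}

test_that("tolerance is the ceiling(alpha*M)-th order statistic", {
  expect_equal(tolerance_quantile(10:1, 0.5), 5)
  expect_equal(tolerance_quantile(1:10, 1), 10)
  expect_equal(tolerance_quantile(3.5, 0.2), 3.5)
  expect_equal(tolerance_quantile(c(4, 2, 9), 0.34), 4)  # ceiling(1.02) = 2nd
  expect_error(tolerance_quantile(numeric(0), 0.5), "non-empty")
})

test_that("kernel standard deviations follow the weighted-variance rule", {
  # unweighted particles with component variances (1, 4), kernel_scale 2
  th <- cbind(c(-1, 1, -1, 1), c(-2, 2, -2, 2))
  pop <- fake_population(th)
  expect_equal(kernel_sds(pop, 2), c(sqrt(2), sqrt(8)))
  # degenerate component falls back to jitter, with a warning
  pop2 <- fake_population(cbind(c(-1, 1, -1, 1), 5))
  expect_warning(s <- kernel_sds(pop2, 2), "degenerate")
  expect_equal(s[1], sqrt(2))
  expect_gt(s[2], 0)
})

test_that("perturbation kernel has the stated variance and no-noise limit", {
  th <- cbind(c(-1, 1, -1, 1), c(-2, 2, -2, 2))
  pop <- fake_population(th)
  expect_equal(perturb(c(0.3, -0.7), pop, kernel_scale = 0), c(0.3, -0.7))
  with_seed(41, {
    draws <- t(replicate(20000, perturb(c(0, 0), pop, kernel_scale = 2)))
    expect_lt(abs(var(draws[, 1]) / 2 - 1), 0.05)
    expect_lt(abs(var(draws[, 2]) / 8 - 1), 0.05)
  })
})

test_that("importance weights implement the SMC correction", {
  prev <- fake_population(col1(0), v = 1)
  sds <- 0.7
  theta <- col1(c(0.5, -1.2))
  pd <- c(0.25, 0.25)  # uniform prior density
  v <- importance_weights(theta, pd, prev, sds)
  expect_equal(v, pd / dnorm(theta[, 1], 0, sds))
  # scaling the unnormalized prior density leaves normalized weights unchanged
  v2 <- importance_weights(theta, 2 * pd, prev, sds)
  expect_equal(v2 / sum(v2), v / sum(v))
})

test_that("generation one is rejection sampling with equal particle weights", {
  prob <- make_problem("uniform_toy")
  cfg <- smc_config(N = 100, alpha = 0.5, T = 1, method = "uniform", seed = 42)
  run <- run_abc(prob, cfg)
  pop <- run$populations[[1]]
  expect_equal(pop$v, rep(1 / 100, 100))
  # kept particles are the closest N: all kept distances are <= epsilon_1,
  # which is the alpha-quantile of the M candidate distances
  expect_true(all(pop$distance <= pop$epsilon))
  expect_equal(max(pop$distance), pop$epsilon)
  # the posterior has learned something the prior does not know
  expect_lt(sd(pop$theta), sd(prior_sample(prob, 2000)))
})

test_that("every population is normalized and satisfies the nested rule", {
  prob <- make_problem("uniform_toy")
  for (method in c("adaptive", "uniform", "scaled")) {
    cfg <- smc_config(N = 80, alpha = 0.5, T = 3, method = method, seed = 43)
    run <- run_abc(prob, cfg)
    expect_length(run$populations, 3L)
    for (t in seq_along(run$populations)) {
      pop <- run$populations[[t]]
      expect_equal(sum(pop$v), 1)
      expect_true(all(pop$v >= 0))
      # nested acceptance: kept particles pass all earlier thresholds strictly
      for (j in seq_len(t - 1)) {
        prev <- run$populations[[j]]
        d <- apply(pop$summaries, 1, weighted_distance, s2 = prob$observed,
                   w = prev$w_star)
        expect_true(all(d < prev$epsilon))
      }
    }
    expect_equal(nrow(run$w_schedule), 3L)
    expect_equal(rowSums(run$w_schedule), rep(1, 3))
  }
})

test_that("identical seeds give bit-identical runs", {
  prob <- make_problem("uniform_toy")
  cfg <- smc_config(N = 60, alpha = 0.5, T = 3, method = "adaptive", seed = 44)
  r1 <- run_abc(prob, cfg)
  r2 <- run_abc(prob, cfg)
  expect_identical(r1$populations, r2$populations)
  expect_identical(r1$eps_schedule, r2$eps_schedule)
  r3 <- run_abc(prob, smc_config(N = 60, alpha = 0.5, T = 3,
                                 method = "adaptive", seed = 45))
  expect_false(identical(r1$populations, r3$populations))
})

test_that("posterior moves away from the prior over generations", {
  prob <- make_problem("uniform_toy")
  hs <- sapply(1:10, function(s) {
    cfg <- smc_config(N = 150, alpha = 0.5, T = 4, method = "adaptive",
                      seed = 500 + s)
    run <- run_abc(prob, cfg)
    ref <- with_seed(900 + s, prior_sample(prob, 150))
    vapply(run$populations, function(pop)
      hellinger_estimate(ref, pop$theta, k = 5)$value, numeric(1))
  })
  med <- apply(hs, 1, median)
  expect_true(all(diff(med) >= 0))
})

test_that("an exhausted proposal budget degrades gracefully or fails loudly", {
  prob <- make_problem("uniform_toy")
  # budget runs out after enough acceptances: the generation completes on the
  # smaller candidate pool, with a warning
  cfg <- smc_config(N = 20, alpha = 0.05, T = 2, method = "uniform", seed = 46,
                    max_proposals = 420)
  expect_warning(run <- run_abc(prob, cfg), "max_proposals")
  expect_equal(nrow(final_particles(run)), 20)
  # budget too small for even N acceptances: error naming the threshold
  cfg2 <- smc_config(N = 10, alpha = 0.01, T = 2, method = "uniform", seed = 47,
                     max_proposals = 70)
  expect_error(suppressWarnings(run_abc(prob, cfg2)), "binding threshold")
})
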