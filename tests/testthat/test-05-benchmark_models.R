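test_that("uniform toy simulator returns sorted draws on the right support", {
  with_seed(51, {
    s <- simulate_uniform_toy(7, 12)
    expect_length(s, 12)
    expect_true(all(s >= 0 & s <= 7))
    expect_equal(s, sort(s))
    expect_error(simulate_uniform_toy(-1), "positive")
  })
})

test_that("sample maximum matches its Beta order-statistic expectation", {
  # E[max of r Uniform(0, theta)] = theta * r / (r + 1) = 9.0909 at theta = 10
  with_seed(52, {
    m <- replicate(5000, max(simulate_uniform_toy(10, 10)))
    expect_lt(abs(mean(m) - 10 * 10 / 11), 0.05)
  })
  # the batch path draws from the same law
  prob <- make_problem("uniform_toy")
  with_seed(53, {
    batch <- prob$simulate_batch(matrix(1, 5000, 1))  # theta = 10 on log10 scale
    expect_lt(abs(mean(batch[, 10]) - 10 * 10 / 11), 0.05)
    expect_true(all(batch >= 0 & batch <= 10))
  })
})

test_that("bimodal simulator is centred on (sin t1, sin t2)", {
  th <- c(1.1, 4.0)
  expect_equal(simulate_bimodal(th, noise_sd = 0), sin(th))
  with_seed(54, {
    draws <- t(replicate(1e4, simulate_bimodal(th)))
    expect_lt(max(abs(colMeans(draws) - sin(th))), 0.005)
  })
})

test_that("frozen networks stay at their initial state", {
  net <- reaction_network("S", matrix(-1L, 1, 1), matrix(1L, 1, 1), 50)
  out <- gillespie_direct(net, 0, c(1, 2, 5))
  expect_equal(unname(out[, 1]), rep(50, 3))
})

test_that("pure death process matches its analytic mean within Monte Carlo error", {
  # S(0) = 100 decaying at rate 1: E[S(1)] = 100 exp(-1), Var = 100 e^-1 (1 - e^-1)
  net <- reaction_network("S", matrix(-1L, 1, 1), matrix(1L, 1, 1), 100)
  with_seed(55, {
    fin <- replicate(2000, gillespie_direct(net, 1, 1)[1, 1])
  })
  mu <- 100 * exp(-1)
  sig <- sqrt(100 * exp(-1) * (1 - exp(-1)))
  z <- (mean(fin) - mu) / (sig / sqrt(2000))
  expect_lt(abs(z), 3)
  expect_lt(abs(mean(fin) - mu), 1.5)
  expect_true(all(fin == floor(fin) & fin >= 0))
})

test_that("immigration-death moments match the analytic transient solution", {
  # 0 -> S at rate b, S -> 0 at rate d, S(0) = 0:
  # mean(t) = (b/d)(1 - e^{-dt}); the transient law is Poisson, so var = mean
  net <- reaction_network("S",
                          stoich = rbind(1L, -1L),
                          orders = rbind(0L, 1L),
                          initial = 0)
  b <- 30; d <- 1.5; tt <- 0.8
  with_seed(56, {
    fin <- replicate(2000, gillespie_direct(net, c(b, d), tt)[1, 1])
  })
  mu <- b / d * (1 - exp(-d * tt))
  z_mean <- (mean(fin) - mu) / sqrt(mu / 2000)
  expect_lt(abs(z_mean), 3)
  expect_lt(abs(var(fin) / mu - 1), 0.15)
})

test_that("dimerization firings respect stoichiometry and propensity", {
  dn <- abcweight:::dimerization_network()
  expect_equal(dn$stoich[3, ], c(-2L, 1L, 0L))  # S1 + S1 -> S2
  # with only R3 and R4 active, S1 + 2 S2 is conserved exactly
  net <- reaction_network(dn$species, dn$stoich, dn$orders, c(10, 0, 0))
  with_seed(57, {
    out <- gillespie_direct(net, c(0, 0, 0.5, 0.3), c(0.5, 1, 4))
  })
  expect_true(all(out[, "S1"] + 2 * out[, "S2"] == 10))
  expect_true(all(out[, "S3"] == 0))
  expect_true(all(out == floor(out) & out >= 0))
  # dimerization propensity k3 * S1 (S1 - 1) / 2: from S1 = 4, k3 = 1 the
  # waiting time is Exp(6), so P(no firing by t = 0.1) = exp(-0.6)
  net4 <- reaction_network(dn$species, dn$stoich, dn$orders, c(4, 0, 0))
  with_seed(58, {
    still <- replicate(2000, gillespie_direct(net4, c(0, 0, 1, 0), 0.1)[1, 1] == 4)
  })
  p <- exp(-0.6)
  z <- (mean(still) - p) / sqrt(p * (1 - p) / 2000)
  expect_lt(abs(z), 3)
})

test_that("dimerization problem reproduces the stated dynamics and geometry", {
  prob <- make_problem("dimerization")
  expect_equal(prob$kappa, 24)
  expect_equal(prob$dim_theta, 4)
  expect_equal(prob$theta_true, c(1, 0.04, 0.002, 0.5))
  # 8 geometrically spaced observation times spanning [0.1, 100]
  traj <- matrix(prob$observed, 8, 3)
  s1 <- traj[, 1]; s2 <- traj[, 2]; s3 <- traj[, 3]
  # fast S1 decay (essentially over before the first geometric observation
  # time), S2 already at its peak there and decaying afterwards, slower S3
  # accumulation saturating late
  expect_equal(which.max(s1), 1L)
  expect_true(all(diff(s1) <= 0))
  expect_lte(which.max(s2), 2L)
  expect_true(all(diff(s2[2:8]) <= 0))
  expect_gte(which.max(s3), 5L)
  expect_gte(s3[8], 0.95 * max(s3))
  expect_gt(s3[8], s2[8])
})

test_that("diffusion problem conserves particles and mixes to uniformity", {
  prob <- make_problem("diffusion")
  expect_equal(prob$kappa, 64)
  expect_equal(prob$theta_true, 0.1)
  occ <- matrix(prob$observed, 8, 8)  # times x voxels
  expect_equal(unname(rowSums(occ)), rep(40, 8))
  # theta = 0 freezes the initial occupancy
  net <- abcweight:::diffusion_network()
  frozen <- gillespie_direct(net, rep(0, 14), c(5, 20))
  expect_equal(unname(frozen[1, ]), c(rep(10, 4), rep(0, 4)))
  # once the chain has relaxed (theta = 1, upper end of the prior) the
  # stationary occupancy of 5 per voxel is reached by t = 20
  with_seed(59, {
    fin <- replicate(600, {
      r <- prob$simulate_batch(matrix(0, 1, 1))  # log10(1)
      matrix(r, 8, 8)[8, ]
    })
  })
  # interior voxels: the boundary voxels carry the largest residual of the
  # slowest relaxation mode
  expect_lt(max(abs(rowMeans(fin)[3:6] - 5)), 0.3)
  # at theta = 0.1 relaxation is incomplete at t = 20: left half still leads
  occ20 <- matrix(prob$observed, 8, 8)[8, ]
  expect_gt(sum(occ20[1:4]), sum(occ20[5:8]))
})

test_that("network and per-particle walk simulators agree on occupancy moments", {
  net <- abcweight:::diffusion_network()
  theta <- 0.1
  nrep <- 400
  with_seed(60, {
    a <- replicate(nrep, gillespie_direct(net, rep(theta, 14), c(5, 20)))
    b <- replicate(nrep, walk_diffusion_once(theta, record = c(5, 20)))
  })
  for (ti in 1:2) {
    ma <- rowMeans(a[ti, , ]); mb <- rowMeans(b[ti, , ])
    se <- sqrt((apply(a[ti, , ], 1, var) + apply(b[ti, , ], 1, var)) / nrep)
    expect_true(all(abs(ma - mb) < 3 * se + 1e-9))
  }
})

test_that("problem registry validates names and regenerates observed data", {
  expect_error(make_problem("nope"), "uniform_toy")
  expect_equal(make_problem("uniform_toy")$kappa, 10)
  expect_equal(make_problem("bimodal")$observed, c(sqrt(2) / 2, -sqrt(2) / 2))
  p1 <- make_problem("uniform_toy", obs_seed = 123)
  p2 <- make_problem("uniform_toy", obs_seed = 123)
  p3 <- make_problem("uniform_toy", obs_seed = 124)
  expect_identical(p1$observed, p2$observed)
  expect_false(identical(p1$observed, p3$observed))
  expect_identical(make_dimerization_problem()$name, "dimerization")
  expect_identical(make_diffusion_problem()$name, "diffusion")
})
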