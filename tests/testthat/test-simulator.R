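test_that("the exact sampler is reproducible and respects threshold limits", {
  p <- random_gif_params(3, seed = 3)
  a <- sample_exact(p, 40, seed = 11)
  b <- sample_exact(p, 40, seed = 11)
  expect_identical(a$omega, b$omega)
  expect_false(identical(a$omega, sample_exact(p, 40, seed = 12)$omega))
  # unreachable threshold: silent raster; threshold far below: saturated
  hi <- p; hi$theta <- 1e3
  expect_equal(sum(sample_exact(hi, 30, seed = 1)$omega), 0)
  lo <- p; lo$theta <- -1e3
  r_lo <- sample_exact(lo, 30, seed = 1)
  sampled <- r_lo$omega[, -1]          # drop the seed history column
  expect_equal(mean(sampled), 1)
})

test_that("the incremental sampler state matches direct recomputation", {
  p <- random_gif_params(3, seed = 7)
  r <- sample_exact(p, 25, seed = 5)
  Xh <- attr(r, "X")
  sf <- attr(r, "sampled_from")
  for (step in c(1, 7, 18, 25)) {
    n <- sf + step - 1
    Xd <- vapply(1:3, function(k) firing_argument(p, r, k, n), numeric(1))
    expect_equal(Xh[, step], Xd, tolerance = 1e-8)
  }
})

test_that("long-run firing rates stay inside the per-neuron probability window", {
  p <- decay_test_params()
  b <- derive_bounds(p)
  r <- sample_exact(p, 400, seed = 9)
  rates <- rowMeans(r$omega[, -1])
  expect_true(all(rates > 0), info = "network must actually fire")
  expect_true(all(rates > b$pi_minus - 1e-12))
  expect_true(all(rates < b$pi_plus + 1e-12))
})

test_that("one-step empirical frequencies match the exact law", {
  p <- random_gif_params(2, seed = 19)
  r <- rand_raster(2, 30, t0 = -29, p = 0.35, seed = 6)
  et <- empirical_transition(p, r, 1, n_draws = 20000, seed = 4)
  expect_equal(sum(et$freq), 1)
  expect_true(all(abs(et$freq - et$prob) <= 3 * et$se + 1e-9))
  # binomial standard errors scale as 1/sqrt(n)
  et2 <- empirical_transition(p, r, 1, n_draws = 80000, seed = 4)
  expect_equal(et2$se / et$se, rep(0.5, 4), tolerance = 1e-9)
})

test_that("noise-free zero-coupling SDE reproduces the LIF relaxation", {
  pz <- gif_params(N = 1, G = matrix(0, 1, 1), theta = 100, E_L = -1,
                   i_ext = 2, C = 1, g_L = 0.5,
                   sigma_B = 1e-12, sigma_R = 1e-12)
  # past ends with a spike: the voltage restarts from (almost exactly) 0
  past <- gif_raster(matrix(c(0L, 1L), 1, 2), t0 = -1)
  sim <- simulate_sde(pz, T = 6, sde_dt = 1e-3, seed = 2,
                      initial_past = past)
  v_inf <- -1 + 2 / 0.5
  t_grid <- 1:6
  v_ref <- v_inf * (1 - exp(-t_grid / 2))
  expect_equal(unname(sim$V[1, -1]), v_ref, tolerance = 2e-3)
  expect_equal(sum(sim$raster$omega), 1)  # only the seeded spike
})

test_that("clamped SDE moments agree with the conditional Gaussian law", {
  p <- random_gif_params(2, seed = 11)
  past <- rand_raster(2, 20, t0 = -19, p = 0.4, seed = 2)
  # silence the last three steps so that both neurons carry memory
  past$omega[, 18:20] <- 0L
  t <- 1
  law <- conditional_law(p, past, t)
  n_paths <- 4000
  mc <- sde_clamped_sample(p, past, t, sde_dt = 1e-3,
                           n_paths = n_paths, seed = 3)
  se_mean <- sqrt(law$var / n_paths)
  se_var <- law$var * sqrt(2 / (n_paths - 1))
  expect_true(all(abs(mc$mean - law$mean) <= 4 * se_mean))
  expect_true(all(abs(mc$var - law$var) <= 4 * se_var))
  # conditional independence across neurons
  se_cov <- sqrt(law$var[1] * law$var[2] / n_paths)
  expect_lt(abs(mc$cov[1, 2]), 4 * se_cov)
  # threshold frequencies estimate the exact firing probabilities
  pf <- firing_prob(vapply(1:2, function(k)
    firing_argument(p, past, k, t + 1), numeric(1)))
  se_p <- sqrt(pf * (1 - pf) / n_paths)
  expect_true(all(abs(mc$p_fire_hat - pf) <= 4 * se_p + 2e-3))
})

test_that("refining the Euler step moves firing frequencies toward the exact law", {
  p <- decay_test_params()
  past <- rand_raster(2, 12, t0 = -11, p = 0.3, seed = 5)
  past$omega[, 11:12] <- 0L
  pf <- firing_prob(vapply(1:2, function(k)
    firing_argument(p, past, k, 1), numeric(1)))
  err <- vapply(c(1e-2, 1e-3), function(dt) {
    mc <- sde_clamped_sample(p, past, 0, sde_dt = dt,
                             n_paths = 20000, seed = 8)
    max(abs(mc$p_fire_hat - pf))
  }, numeric(1))
  expect_lte(err[2], err[1] + 2e-3)  # discretization bias shrinks
})

test_that("free-running SDE and exact sampler see compatible spike statistics", {
  # weak coupling keeps the network monostable, so long-run rates of
  # the two integrators are directly comparable
  p <- gif_params(N = 2, C = 1, g_L = 0.8, theta = 5.5,
                  G = matrix(c(0, 0.02, 0.02, 0), 2, 2, byrow = TRUE),
                  tau_syn = 2, i_ext = 3, sigma_B = 1.5, sigma_R = 1)
  sim <- simulate_sde(p, T = 300, sde_dt = 5e-3, seed = 6, rule = "endpoint")
  ex <- sample_exact(p, 300, seed = 6)
  rate_sde <- mean(sim$raster$omega[, -1])
  rate_ex <- mean(ex$omega[, -1])
  expect_gt(rate_sde, 0)
  expect_gt(rate_ex, 0)
  expect_lt(abs(rate_sde - rate_ex), 0.05)
  # the crossing rule registers at least the endpoint spikes' order
  sim2 <- simulate_sde(p, T = 20, sde_dt = 5e-3, seed = 6, rule = "crossing")
  expect_equal(dim(sim2$raster$omega), c(2L, 21L))
})
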