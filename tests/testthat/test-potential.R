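test_that("effective leak: identity at equal times, closed form at zero coupling", {
  p <- random_gif_params(2, seed = 5)
  r <- rand_raster(2, 20, t0 = -10, seed = 5)
  for (t in c(-3.7, 0, 4.25))
    expect_identical(effective_leak(p, r, 1, t, t), 1)
  expect_error(effective_leak(p, r, 1, 2, 1), "t1 <= t2")
  pz <- gif_params(N = 2, G = matrix(0, 2, 2), C = c(1, 2), g_L = c(0.5, 0.4))
  for (k in 1:2) {
    tau_L <- pz$C[k] / pz$g_L[k]
    expect_equal(effective_leak(pz, r, k, -1.3, 3.9),
                 exp(-(3.9 + 1.3) / tau_L), tolerance = 1e-10)
  }
})

test_that("effective leak satisfies the semigroup identity and its sandwich", {
  for (s in 1:10) {
    p <- random_gif_params(2, seed = 40 + s)
    r <- rand_raster(2, 30, t0 = -20, p = 0.4, seed = s)
    b <- derive_bounds(p)
    ts <- sort(stats::runif(3, -15, 8))
    k <- 1 + s %% 2
    g_full <- effective_leak(p, r, k, ts[1], ts[3])
    g_split <- effective_leak(p, r, k, ts[1], ts[2]) *
      effective_leak(p, r, k, ts[2], ts[3])
    expect_equal(g_full, g_split, tolerance = 1e-10)
    dt <- ts[3] - ts[1]
    expect_gte(g_full, exp(-dt / b$tau_M[k]) - 1e-10)
    expect_lte(g_full, exp(-dt / b$tau_L[k]) + 1e-10)
  }
})

test_that("leak-weighted integrals match a fine-grid brute-force oracle", {
  p <- random_gif_params(2, seed = 8)
  # single presynaptic spike feeding neuron 1
  r <- gif_raster(matrix(c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L), 2, 4), t0 = 0)
  s <- 0; t <- 3.6
  vs_ref <- sum(vapply(1:2, function(j) {
    p$W[1, j] * brute_leak_integral(
      p, r, 1, s, t, function(u) alpha_sum(p, r, 1, j, u), dt = 5e-4)
  }, numeric(1))) / p$C[1]
  expect_equal(v_syn(p, r, 1, s, t), vs_ref, tolerance = 1e-6)
  ve_ref <- p$E_L / (p$C[1] / p$g_L[1]) *
    brute_leak_integral(p, r, 1, s, t, function(u) rep(1, length(u)),
                        dt = 5e-4) +
    brute_leak_integral(p, r, 1, s, t,
                        function(u) i_ext_value(p, 1, u), dt = 5e-4) / p$C[1]
  expect_equal(v_ext(p, r, 1, s, t), ve_ref, tolerance = 1e-6)
})

test_that("zero-coupling external potential matches the LIF closed form", {
  pz <- gif_params(N = 1, G = matrix(0, 1, 1), E_L = -1.5, i_ext = 2,
                   C = 1, g_L = 0.5)
  r0 <- raster_fixture("omega0", 1, 5, t0 = 0)
  tau_L <- 2
  for (span in c(0.8, 3, 12)) {
    ref <- (pz$E_L + 2 / 0.5) * (1 - exp(-span / tau_L))
    expect_equal(v_ext(pz, r0, 1, 4 - span, 4), ref, tolerance = 1e-9)
  }
  # infinite-past limit: equilibrium value E_L + i/g_L
  expect_equal(v_ext(pz, r0, 1, -Inf, 4), pz$E_L + 4, tolerance = 1e-8)
  expect_equal(v_syn(pz, r0, 1, -Inf, 4), 0)
})

test_that("noise variance: reset value at zero lag, stationary limit, sandwich", {
  pz <- gif_params(N = 1, G = matrix(0, 1, 1), sigma_B = 1.5, sigma_R = 0.8)
  r <- gif_raster(matrix(c(0L, 1L, 0L, 0L), 1, 4), t0 = 0)
  expect_equal(noise_variance(pz, r, 1, 1), 0.8^2)  # just reset
  r0 <- raster_fixture("omega0", 1, 4, t0 = 0)
  tau_L <- pz$C[1] / pz$g_L[1]
  expect_equal(noise_variance(pz, r0, 1, 2.5),
               (1.5 / 1)^2 * tau_L / 2, tolerance = 1e-8)
  for (s in 1:10) {
    p <- random_gif_params(3, seed = 60 + s)
    rr <- rand_raster(3, 25, t0 = -15, seed = s)
    b <- derive_bounds(p)
    t <- stats::runif(1, -10, 9)
    for (k in 1:3) {
      v <- noise_variance(p, rr, k, t)
      expect_gte(v, b$sigma_minus[k]^2 - 1e-9)
      expect_lte(v, b$sigma_plus[k]^2 + 1e-9)
    }
  }
})

test_that("potential decomposition obeys the deterministic and leak sandwiches", {
  for (s in 1:15) {
    p <- random_gif_params(2, seed = 80 + s, profile_degree = s %% 2)
    r <- rand_raster(2, 30, t0 = -20, p = 0.35, seed = s)
    b <- derive_bounds(p)
    t <- stats::runif(1, -10, 9)
    for (k in 1:2) {
      pd <- potential_decomposition(p, r, k, t)
      expect_gt(pd$V_det, b$V_minus[k])
      expect_lt(pd$V_det, b$V_plus[k])
      if (is.finite(pd$tau)) {
        dt <- t - pd$tau
        expect_gte(pd$Gamma, exp(-dt / b$tau_M[k]) - 1e-10)
        expect_lte(pd$Gamma, exp(-dt / b$tau_L[k]) + 1e-10)
      }
      expect_lt(pd$truncation_error_bound, 1e-8)
    }
  }
})

test_that("quadrature refinement changes nothing beyond tolerance", {
  p <- random_gif_params(3, seed = 13)
  r <- rand_raster(3, 30, t0 = -20, p = 0.4, seed = 13)
  for (t in c(-2.3, 6.75)) for (k in 1:3) {
    a <- potential_decomposition(p, r, k, t, order = 8)
    bb <- potential_decomposition(p, r, k, t, order = 16)
    expect_equal(a$V_det, bb$V_det, tolerance = 1e-9)
    expect_equal(a$sigma2, bb$sigma2, tolerance = 1e-9)
    expect_equal(a$Gamma, bb$Gamma, tolerance = 1e-9)
  }
})

test_that("conditional law: just-reset neurons are centred reset Gaussians", {
  p <- random_gif_params(2, seed = 21)
  r <- gif_raster(matrix(c(0L, 0L, 1L, 1L), 2, 2), t0 = 0)
  law <- conditional_law(p, r, 1)
  expect_equal(law$mean, c(0, 0))
  expect_equal(law$var, rep(p$sigma_R^2, 2))
  expect_equal(law$tau, c(1, 1))
})
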