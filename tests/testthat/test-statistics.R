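test_that("the Gaussian tail firing probability matches the erfc oracle", {
  expect_equal(firing_prob(0), 0.5)
  expect_equal(firing_prob(1.959964), 0.025, tolerance = 1e-6)
  x <- seq(-4, 4, by = 0.37)
  expect_equal(firing_prob(x), pracma::erfc(x / sqrt(2)) / 2,
               tolerance = 1e-12)
  expect_equal(firing_prob(x) + firing_prob(-x), rep(1, length(x)))
  expect_true(all(diff(firing_prob(x)) < 0))
})

test_that("the normalized threshold distance behaves at reset and at zero coupling", {
  p <- random_gif_params(2, seed = 31)
  # neuron reset at n - 1: X = theta / sigma_R
  r <- gif_raster(matrix(c(1L, 1L), 2, 1), t0 = 5)
  for (k in 1:2)
    expect_equal(firing_argument(p, r, k, 6), p$theta / p$sigma_R)
  # zero-coupling stationary limit: LIF closed form
  pz <- gif_params(N = 1, G = matrix(0, 1, 1), E_L = -1, i_ext = 2,
                   theta = 6, C = 1, g_L = 0.5, sigma_B = 1.5, sigma_R = 1)
  r0 <- raster_fixture("omega0", 1, 3, t0 = 0)
  X <- firing_argument(pz, r0, 1, 3)
  v_inf <- -1 + 2 / 0.5
  s_inf <- sqrt(1.5^2 * 2 / 2)
  expect_equal(X, (6 - v_inf) / s_inf, tolerance = 1e-8)
  # uniform window on random inputs
  for (s in 1:10) {
    q <- random_gif_params(3, seed = 130 + s)
    rr <- rand_raster(3, 25, t0 = -15, seed = s)
    b <- derive_bounds(q)
    for (k in 1:3) {
      Xk <- firing_argument(q, rr, k, 5)
      expect_gt(Xk, b$X_lower[k])
      expect_lt(Xk, b$X_upper[k])
    }
  }
})

test_that("transition probabilities normalize, factorize and respect the bounds", {
  p <- random_gif_params(3, seed = 17)
  b <- derive_bounds(p)
  pats <- gifnet:::.all_patterns(3)
  for (s in 1:6) {
    r <- rand_raster(3, 30, t0 = -25, p = 0.35, seed = 200 + s)
    tps <- lapply(seq_len(nrow(pats)), function(i)
      transition_probability(p, r, 4, pats[i, ]))
    total <- sum(vapply(tps, `[[`, numeric(1), "p_pattern"))
    expect_equal(total, 1, tolerance = 1e-12)
    for (tp in tps) {
      # exact per-neuron Bernoulli factorization
      terms <- ifelse(tp$pattern == 1, tp$p_fire, 1 - tp$p_fire)
      expect_equal(tp$p_pattern, prod(terms), tolerance = 1e-14)
      expect_identical(tp$p_pattern, exp(tp$phi))
      # per-neuron spiking-state probabilities inside (Pi-, Pi+),
      # checked on the log scale where the bounds stay representable
      expect_true(all(tp$phi_k > b$log_Pi_minus))
      expect_true(all(tp$phi_k < 0))
      expect_true(all(log1p(-exp(tp$phi_k)) > b$log_1m_Pi_plus))
    }
  }
})

test_that("the summed potential telescopes into block probabilities", {
  p <- random_gif_params(2, seed = 23)
  r <- sample_exact(p, 12, seed = 7)
  n0 <- attr(r, "sampled_from")
  # single step is the log transition probability
  expect_equal(gibbs_potential(p, r, n0 + 2, n0 + 2),
               transition_probability(p, r, n0 + 2)$phi)
  # a 3-step block equals the product of its transition probabilities
  phi <- gibbs_potential(p, r, n0 + 3, n0 + 5)
  prods <- prod(vapply((n0 + 3):(n0 + 5), function(l)
    transition_probability(p, r, l)$p_pattern, numeric(1)))
  expect_equal(exp(phi), prods, tolerance = 1e-12)
})

test_that("exhaustive block enumeration shows partition function one", {
  p <- random_gif_params(2, seed = 29)
  past <- rand_raster(2, 20, t0 = -19, p = 0.4, seed = 3)
  pats <- gifnet:::.all_patterns(2)
  L <- 2  # 16 two-step continuations
  codes <- gifnet:::.all_patterns(2 * L)
  total <- sum(vapply(seq_len(nrow(codes)), function(i) {
    blk <- matrix(codes[i, ], 2, L)
    r <- past
    for (l in seq_len(L)) r <- gifnet:::.raster_append(r, blk[, l])
    exp(gibbs_potential(p, r, 1, L))
  }, numeric(1)))
  expect_equal(total, 1, tolerance = 1e-12)
})

test_that("truncated potentials are normalized and converge with depth", {
  p <- random_gif_params(2, seed = 37)
  blk <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  tp <- truncated_potential(p, blk, "zeros")
  expect_gt(tp$Z, 0)
  expect_equal(tp$Z, 1, tolerance = 1e-12)
  expect_equal(tp$p, exp(tp$phi), tolerance = 1e-12)
  # deep reference: long explicit zero past (beyond the enumeration
  # guard, so computed directly on a raster); phi^(D) approaches it as
  # D grows (continuity of the potential)
  deep <- matrix(0L, 2, 31); deep[, 31] <- c(1L, 0L)
  rdeep <- gif_raster(deep, t0 = -30, past_padding = "zeros")
  ref <- transition_probability(p, rdeep, 0)$phi
  errs <- vapply(c(1, 3, 6, 10), function(D) {
    b <- matrix(0L, 2, D + 1); b[, D + 1] <- c(1L, 0L)
    abs(truncated_potential(p, b, "zeros")$phi - ref)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[4], 1e-3)
  expect_error(truncated_potential(p, matrix(0L, 2, 15)), "guard")
})

test_that("Moebius inversion reproduces the potential and kills time-0 cross terms", {
  p1 <- random_gif_params(1, seed = 41)
  ex1 <- monomial_expansion(p1, D = 1, "zeros")
  for (i in 1:4) {
    b <- matrix(gifnet:::.all_patterns(2)[i, ], 1, 2)
    expect_equal(expansion_value(ex1, b),
                 truncated_potential(p1, b, "zeros")$phi,
                 tolerance = 1e-10)
  }
  p2 <- random_gif_params(2, seed = 43)
  for (D in 0:1) {
    ex <- monomial_expansion(p2, D = D, "zeros")
    # constant term is the potential of the all-zero block
    expect_equal(ex$lambda[1],
                 truncated_potential(p2, matrix(0L, 2, D + 1),
                                     "zeros")$phi,
                 tolerance = 1e-12)
    multi0 <- vapply(ex$monomial, function(m) sum(m[, "n"] == 0) >= 2,
                     logical(1))
    expect_lt(max(abs(ex$lambda[multi0])), 1e-10)
    # reconstruction on every block
    codes <- gifnet:::.all_patterns(2 * (D + 1))
    err <- max(vapply(seq_len(nrow(codes)), function(i) {
      b <- matrix(codes[i, ], 2, D + 1)
      abs(expansion_value(ex, b) - truncated_potential(p2, b, "zeros")$phi)
    }, numeric(1)))
    expect_lt(err, 1e-10)
  }
  # D = 0 with any boundary: only the constant and the N singleton
  # time-0 terms survive - an independent-Bernoulli model
  ex0 <- monomial_expansion(p2, D = 0, "ones")
  sizes <- vapply(ex0$monomial, nrow, integer(1))
  expect_lt(max(abs(ex0$lambda[sizes >= 2])), 1e-10)
  expect_error(monomial_expansion(p2, D = 11), "guard")
})

test_that("silent-window bounds are ordered, geometric, and certified positive", {
  p <- decay_test_params()
  b1 <- no_fire_probability_bounds(p, 1)
  expect_true(b1[["lower"]] < b1[["upper"]])
  for (len in 2:6) {
    bl <- no_fire_probability_bounds(p, len)
    expect_equal(bl[["lower"]], b1[["lower"]]^len, tolerance = 1e-12)
    expect_equal(bl[["upper"]], b1[["upper"]]^len, tolerance = 1e-12)
  }
  # strict Pi+ < 1 certified on the log scale (the plain value can
  # round to 1 in double precision for loose envelopes)
  expect_true(all(is.finite(derive_bounds(p)$log_1m_Pi_plus)))
})

test_that("uniqueness criteria: positive probability floor, finite variation sum", {
  p <- decay_test_params()
  uc <- uniqueness_criteria(p, t = 0, m_max = 8, n_pairs = 5, seed = 2)
  expect_true(is.finite(uc$log_m_p_lower))    # m(p) > 0, on the log scale
  expect_gte(uc$partial_sum, 0)
  expect_gt(uc$tail_bound, 0)
  expect_true(is.finite(uc$v_p_estimate))
  expect_gte(uc$v_p_estimate, uc$partial_sum)
})
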