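# shared fixtures: all inputs are generated in code under fixed seeds

rand_raster <- function(N, T, t0 = 1L, p = 0.3, seed = 1)
  raster_fixture("random", N, T, t0 = t0, p = p, seed = seed)

# small strongly-driven network with well separated decay times
# (tau_syn = 4 > tau_L = 1.25): the memory-decay rate of every
# history-dependent quantity is dominated by the synaptic tail
decay_test_params <- function() {
  gif_params(N = 2, C = 1, g_L = 0.8, theta = 6,
             G = matrix(c(0, 0.1, 0.12, 0), 2, 2, byrow = TRUE),
             tau_syn = 4, i_ext = 3, sigma_B = 1.5, sigma_R = 1)
}

# brute-force midpoint-rule oracle for the leak-weighted integrals of
# one neuron: integral over [s, t] of Gamma(t1, t) * h(t1) dt1 on a
# fine uniform grid.  Midpoint panels keep the integer-time jumps of
# the integrand on panel edges, so the rule stays second order.
brute_leak_integral <- function(params, raster, k, s, t, h, dt = 1e-4) {
  n <- round((t - s) / dt)
  dt <- (t - s) / n
  mid <- s + (seq_len(n) - 0.5) * dt
  g <- conductance(params, raster, k, mid)
  Aedge <- c(0, cumsum(g * dt))
  Amid <- Aedge[seq_len(n)] + g * dt / 2
  Gam <- exp(-(Aedge[n + 1] - Amid) / params$C[k])
  sum(Gam * h(mid) * dt)
}
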