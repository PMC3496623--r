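# Incremental sampler state.
#
# For each neuron the one-step sampling law needs four history
# integrals taken from the last reset: the effective-leak-weighted
# kernel sums (one per presynaptic neuron), the plain and
# current-weighted leak integrals, the squared-leak integral, and the
# leak factor since the reset.  All integrands before the current time
# are frozen by causality, so advancing one unit time step only
# multiplies the old integrals by the unit-interval leak factor and
# adds one unit-interval quadrature.

.state_init <- function(params, raster, tol, order) {
  n_end <- .raster_t_end(raster)
  lapply(seq_len(params$N), function(k) {
    tau <- last_reset(raster, k, n_end)
    m <- .pd_horizon(params, k, tol)
    reset_in <- is.finite(tau) && tau >= n_end - m
    s_eff <- if (reset_in) tau else n_end - m
    core <- .pd_core(params, raster, k, s_eff, n_end, tol, order)
    list(Jsyn = core$Jsyn, JextL = core$JextL, Jexti = core$Jexti,
         J2 = core$J2, Gr = if (reset_in) core$Gamma_r else 0)
  })
}

# advance neuron k's integrals across [n, n + 1]; raster holds all
# spikes up to time n
.state_advance_k <- function(params, raster, state_k, k, n, tol, order) {
  tab <- .conductance_table(params, raster, k, n, n + 1, tol, order)
  Ck <- params$C[k]
  gam <- exp(-tab$A_total / Ck)
  Gnode <- exp(-(tab$A_total - tab$A) / Ck)
  wG <- tab$wts * Gnode
  list(Jsyn = state_k$Jsyn * gam + as.vector(wG %*% tab$alphaM),
       JextL = state_k$JextL * gam + sum(wG),
       Jexti = state_k$Jexti * gam + sum(wG * tab$iext),
       J2 = state_k$J2 * gam^2 + sum(tab$wts * Gnode^2),
       Gr = state_k$Gr * gam)
}

.state_X <- function(params, state_k, k) {
  p <- params
  tau_L <- p$C[k] / p$g_L[k]
  V_syn <- sum(p$W[k, ] * state_k$Jsyn) / p$C[k]
  V_ext <- p$E_L / tau_L * state_k$JextL + state_k$Jexti / p$C[k]
  sigma2 <- state_k$Gr^2 * p$sigma_R^2 + (p$sigma_B / p$C[k])^2 * state_k$J2
  (p$theta - V_syn - V_ext) / sqrt(sigma2)
}

.state_reset <- function(params) {
  list(Jsyn = numeric(params$N), JextL = 0, Jexti = 0, J2 = 0, Gr = 1)
}

.default_past <- function(params)
  raster_fixture("omega0", params$N, 1L, t0 = 0L)

#' Exact sequential sampling of a raster
#'
#' Draws a raster directly from the conditional spike law: at each
#' integer step the per-neuron firing probabilities are computed exactly
#' from the accumulated raster (normalized threshold distance passed
#' through the Gaussian tail), and the new spiking pattern is drawn as
#' independent Bernoullis.  This is the reference sampler for the
#' spike-train distribution; no membrane-potential trajectory is
#' integrated.
#'
#' @param params a valid [gif_params()] object.
#' @param T number of time steps to sample.
#' @param seed integer seed (same seed, same raster, bit for bit).
#' @param initial_past a [gif_raster()] supplying the history; default
#'   is the all-zero past (no spike ever, zeros padding).
#' @param tol,order numerical controls of the history integrals.
#' @return A [gif_raster()] whose window is the initial past followed
#'   by the \code{T} sampled columns; attributes \code{p_fire} and
#'   \code{X} hold the per-step firing probabilities and normalized
#'   threshold distances used, and \code{sampled_from} the first
#'   sampled time.
#' @export
sample_exact <- function(params, T, seed = 1, initial_past = NULL,
                         tol = 1e-8, order = 8) {
  .assert_valid(params)
  if (is.null(initial_past)) initial_past <- .default_past(params)
  N <- params$N
  raster <- initial_past
  state <- .state_init(params, raster, tol, order)
  n_prev <- .raster_t_end(raster)
  p_hist <- matrix(NA_real_, N, T)
  X_hist <- matrix(NA_real_, N, T)
  .with_seed(seed, {
    for (step in seq_len(T)) {
      n <- n_prev + step
      X <- vapply(seq_len(N), function(k) .state_X(params, state[[k]], k),
                  numeric(1))
      p <- firing_prob(X)
      pattern <- as.integer(stats::runif(N) < p)
      for (k in seq_len(N))
        state[[k]] <- .state_advance_k(params, raster, state[[k]], k,
                                       n - 1, tol, order)
      raster <- .raster_append(raster, pattern)
      for (k in which(pattern == 1L)) state[[k]] <- .state_reset(params)
      p_hist[, step] <- p
      X_hist[, step] <- X
    }
  })
  attr(raster, "p_fire") <- p_hist
  attr(raster, "X") <- X_hist
  attr(raster, "sampled_from") <- n_prev + 1L
  raster
}

#' Euler-Maruyama simulation of the membrane equation
#'
#' Integrates the stochastic membrane equation (capacitance times the
#' voltage derivative plus conductance times voltage equals the total
#' current, with additive white noise of amplitude \code{sigma_B})
#' with threshold and random reset, recomputing the conductances from
#' the evolving raster.  A spike is registered at integer time
#' \code{n} either when the voltage reaches threshold anywhere in
#' \code{(n - 1, n]} (\code{rule = "crossing"}, the continuous-time
#' registration convention) or when the voltage at time \code{n - 1}
#' is at or above threshold (\code{rule = "endpoint"}, the rule under
#' which the one-step conditional spike probabilities are derived).
#' After registration the neuron's voltage is frozen for the remainder
#' of the unit interval (the spike shape plays no role) and redrawn
#' from the Gaussian reset law at the spike time.
#'
#' The diffusion coefficient is constant (additive noise), so
#' Euler-Maruyama is strong order 1 here; halving \code{sde_dt} should
#' move one-step firing frequencies toward the exact conditional
#' probabilities.
#'
#' @param params a valid [gif_params()] object.
#' @param T number of unit time steps.
#' @param sde_dt Euler step; must divide the unit interval exactly
#'   (default 1e-3) and lie in (0, 0.1].
#' @param seed integer seed.
#' @param initial_past history raster, as in [sample_exact()]; the
#'   initial voltage is drawn from the conditional Gaussian law given
#'   that past.
#' @param rule spike registration rule, see above.
#' @param tol kernel truncation tolerance.
#' @return list with \code{raster} (past plus simulated columns),
#'   \code{V} (voltages at integer times, neurons x times, columns
#'   named by time; \code{NA} during the step in which a neuron spikes)
#'   and \code{rule}.
#' @export
simulate_sde <- function(params, T, sde_dt = 1e-3, seed = 1,
                         initial_past = NULL,
                         rule = c("crossing", "endpoint"),
                         tol = 1e-8) {
  .assert_valid(params)
  rule <- match.arg(rule)
  if (sde_dt <= 0 || sde_dt > 0.1)
    stop("sde_dt must lie in (0, 0.1]")
  nsub <- round(1 / sde_dt)
  if (abs(nsub * sde_dt - 1) > 1e-9)
    stop("sde_dt must divide the unit time interval exactly")
  if (is.null(initial_past)) initial_past <- .default_past(params)
  N <- params$N
  raster <- initial_past
  n_prev <- .raster_t_end(raster)
  law <- conditional_law(params, raster, n_prev, tol = tol)
  Vrec <- matrix(NA_real_, N, T + 1L,
                 dimnames = list(NULL, n_prev + 0:T))
  .with_seed(seed, {
    V <- stats::rnorm(N, law$mean, law$sd)
    Vrec[, 1L] <- V
    sig_step <- params$sigma_B / params$C * sqrt(sde_dt)
    for (step in seq_len(T)) {
      n <- n_prev + step
      tgrid <- (n - 1) + sde_dt * (0:(nsub - 1L))
      gmat <- matrix(0, N, nsub)
      imat <- matrix(0, N, nsub)
      for (k in seq_len(N)) {
        gk <- rep(params$g_L[k], nsub)
        ik <- params$g_L[k] * params$E_L + i_ext_value(params, k, tgrid)
        for (j in which(params$G[k, ] > 0)) {
          a <- alpha_sum(params, raster, k, j, tgrid, tol)
          gk <- gk + params$G[k, j] * a
          ik <- ik + params$W[k, j] * a
        }
        gmat[k, ] <- gk
        imat[k, ] <- ik
      }
      fired <- if (rule == "endpoint") V >= params$theta else rep(FALSE, N)
      for (i in seq_len(nsub)) {
        act <- !fired
        if (any(act)) {
          V[act] <- V[act] +
            sde_dt * (-gmat[act, i] * V[act] + imat[act, i]) /
              params$C[act] +
            sig_step[act] * stats::rnorm(sum(act))
          if (rule == "crossing")
            fired <- fired | (V >= params$theta)
        }
      }
      pattern <- as.integer(fired)
      V[fired] <- stats::rnorm(sum(fired), 0, params$sigma_R)
      raster <- .raster_append(raster, pattern)
      Vrec[, step + 1L] <- V
    }
  })
  list(raster = raster, V = Vrec, rule = rule)
}

#' Clamped-raster SDE sample of the membrane potential
#'
#' Monte-Carlo oracle for the conditional Gaussian law: with the raster
#' held fixed (spikes clamped, no thresholding), each neuron's voltage
#' is integrated by Euler-Maruyama from its last reset (starting at the
#' Gaussian reset value; from a zero start beyond the truncation
#' horizon when the neuron never fired) up to time \code{t}, for
#' \code{n_paths} independent noise paths.  The sample mean, variance
#' and cross-covariances of the resulting voltages estimate the
#' conditional law computed analytically by [conditional_law()];
#' threshold indicator frequencies at \code{t = n - 1} estimate the
#' one-step firing probabilities.
#'
#' @param params a valid [gif_params()] object.
#' @param raster the clamped [gif_raster()].
#' @param t target time.
#' @param sde_dt Euler step (must divide the unit interval).
#' @param n_paths number of independent paths.
#' @param seed integer seed.
#' @param tol kernel truncation tolerance (also sets the backward
#'   horizon for never-reset neurons).
#' @return list with \code{V} (\code{n_paths x N} voltages at
#'   \code{t}), \code{fired} (logical matrix \code{V >= theta}),
#'   \code{mean}, \code{var}, \code{cov} (sample moments) and
#'   \code{p_fire_hat} (threshold frequencies).
#' @export
sde_clamped_sample <- function(params, raster, t, sde_dt = 1e-3,
                               n_paths = 1000, seed = 1, tol = 1e-6) {
  .assert_valid(params)
  nsub_unit <- round(1 / sde_dt)
  if (abs(nsub_unit * sde_dt - 1) > 1e-9)
    stop("sde_dt must divide the unit time interval exactly")
  N <- params$N
  V <- matrix(0, n_paths, N)
  .with_seed(seed, {
    for (k in seq_len(N)) {
      tau <- last_reset(raster, k, t)
      m <- .pd_horizon(params, k, tol)
      reset_in <- is.finite(tau) && tau >= t - m
      s0 <- if (reset_in) tau else t - m
      nstep <- round((t - s0) / sde_dt)
      v <- if (reset_in) stats::rnorm(n_paths, 0, params$sigma_R)
           else numeric(n_paths)
      if (nstep > 0) {
        tgrid <- s0 + sde_dt * (0:(nstep - 1L))
        gk <- rep(params$g_L[k], nstep)
        ik <- params$g_L[k] * params$E_L + i_ext_value(params, k, tgrid)
        for (j in which(params$G[k, ] > 0)) {
          a <- alpha_sum(params, raster, k, j, tgrid, tol)
          gk <- gk + params$G[k, j] * a
          ik <- ik + params$W[k, j] * a
        }
        drift_a <- 1 - sde_dt * gk / params$C[k]
        drift_b <- sde_dt * ik / params$C[k]
        sig <- params$sigma_B / params$C[k] * sqrt(sde_dt)
        for (i in seq_len(nstep))
          v <- v * drift_a[i] + drift_b[i] + sig * stats::rnorm(n_paths)
      }
      V[, k] <- v
    }
  })
  fired <- V >= params$theta
  list(V = V, fired = fired,
       mean = colMeans(V), var = apply(V, 2L, stats::var),
       cov = stats::cov(V), p_fire_hat = colMeans(fired))
}

#' Empirical one-step transition frequencies
#'
#' Repeatedly samples the next spiking pattern from the exact
#' conditional law for a fixed history and tabulates pattern
#' frequencies with binomial standard errors, next to the exact
#' pattern probabilities.  A validation harness: frequencies must agree
#' with the exact law within sampling error, and the standard errors
#' shrink as \code{1/sqrt(n_draws)}.
#'
#' @param params a valid [gif_params()] object (small \code{N}).
#' @param raster the fixed history raster.
#' @param n integer time of the sampled pattern (history is the raster
#'   before \code{n}).
#' @param n_draws number of independent one-step draws.
#' @param seed integer seed.
#' @param tol,order numerical controls.
#' @return data frame with one row per pattern: \code{pattern} (string,
#'   neuron order), \code{prob} (exact), \code{freq} (empirical),
#'   \code{se} (binomial standard error of \code{freq}).
#' @export
empirical_transition <- function(params, raster, n, n_draws = 10000,
                                 seed = 1, tol = 1e-8, order = 8) {
  N <- params$N
  if (N > 6) stop("empirical_transition is meant for small networks (N <= 6)")
  X <- vapply(seq_len(N),
              function(k) firing_argument(params, raster, k, n, tol, order),
              numeric(1))
  p <- firing_prob(X)
  pats <- .all_patterns(N)
  prob <- apply(pats, 1L, function(w) prod(ifelse(w == 1, p, 1 - p)))
  draws <- .with_seed(seed,
    matrix(stats::runif(n_draws * N), n_draws, N) <
      matrix(p, n_draws, N, byrow = TRUE))
  code <- as.vector(draws %*% 2^(0:(N - 1)))
  counts <- tabulate(code + 1L, nbins = 2^N)
  freq <- counts / n_draws
  data.frame(
    pattern = apply(pats, 1L, paste, collapse = ""),
    prob = prob, freq = freq,
    se = sqrt(pmax(prob * (1 - prob), 1e-12) / n_draws))
}
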