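#' Analytic envelope of the m-variation of a model quantity
#'
#' Evaluates the proved exponential-decay envelope of the maximal change
#' of a history-dependent quantity over pasts that agree on the last
#' \code{m + 1} time steps.  Supported quantities and their envelopes
#' (with \code{tail(m) = P_d(m/tau) exp(-m/tau)} the kernel tail bound):
#' \itemize{
#'   \item \code{alpha_sum}: \code{2 * tail_kj(m)};
#'   \item \code{conductance}: \code{2 * sum_j G[k, j] * tail_kj(m)};
#'   \item \code{v_syn}: \code{sum_j A_syn_kj * tail_kj(m) + B_syn_k *
#'     exp(-m / tau_L)} with \code{A_syn_kj = (2|W_kj| + a+ G_kj / g_L *
#'     sum_j' |W_kj'|) / g_L} and \code{B_syn_k = a+ / g_L *
#'     sum_j |W_kj|};
#'   \item \code{v_ext}: \code{sum_j A_ext_kj * tail_kj(m) + B_ext_k *
#'     exp(-m / tau_L)} with \code{B_ext_k = |E_L| + i+ / g_L} and
#'     \code{A_ext_kj = 2 G_kj / g_L * B_ext_k};
#'   \item \code{sigma2}: \code{sum_j A_sig_kj * tail_kj(m) + C_sig_k *
#'     exp(-2 m / tau_L)} with \code{A_sig_kj = G_kj / g_L * (sigma_B
#'     tau_L / C)^2} and \code{C_sig_k = (sigma_B tau_L / C)^2 / 2 +
#'     2 sigma_R^2};
#'   \item \code{transition}: \code{(2 pi)^{-1/2}} times the summed
#'     envelope of the normalized threshold distances over all neurons,
#'     combining the \code{v_syn + v_ext} envelope scaled by
#'     \code{1/sigma_minus} and the \code{sigma2} envelope scaled by
#'     \code{max(|theta - V-|, |theta - V+|) / (2 sigma_minus^3)}.
#' }
#' The kernel-sum constant \code{a+} used in the envelopes is the
#' every-real-time bound \code{alpha_sup} of [derive_bounds()].  The
#' envelopes are asymptotic upper bounds: comparisons with empirical
#' variations are made from a reported lag \code{m0} onward.
#'
#' @param params a [gif_params()] object.
#' @param quantity one of \code{"alpha_sum"}, \code{"conductance"},
#'   \code{"v_syn"}, \code{"v_ext"}, \code{"sigma2"},
#'   \code{"transition"}.
#' @param m lag(s), vectorized.
#' @param k postsynaptic neuron index (ignored for \code{"transition"},
#'   which sums over neurons).
#' @param j presynaptic neuron index, for \code{"alpha_sum"} only
#'   (default: strongest synapse onto \code{k}).
#' @return envelope value(s).
#' @export
analytic_envelope <- function(params, quantity, m, k = 1, j = NULL) {
  p <- params
  b <- derive_bounds(p)
  d <- p$profile_degree
  tails <- function(kk) vapply(seq_len(p$N), function(jj)
    tail_bound(d, p$tau_syn[kk, jj], m), numeric(length(m)))
  tails_mat <- function(kk) matrix(tails(kk), nrow = length(m))
  one_k <- function(kk, what) {
    tau_L <- b$tau_L[kk]
    g_L <- p$g_L[kk]
    tl <- tails_mat(kk)
    switch(what,
      alpha_sum = {
        jj <- if (is.null(j)) which.max(p$G[kk, ]) else j
        2 * tail_bound(d, p$tau_syn[kk, jj], m)
      },
      conductance = 2 * as.vector(tl %*% p$G[kk, ]),
      v_syn = {
        A <- (2 * abs(p$W[kk, ]) +
                b$alpha_sup * p$G[kk, ] / g_L * sum(abs(p$W[kk, ]))) / g_L
        B <- b$alpha_sup / g_L * sum(abs(p$W[kk, ]))
        as.vector(tl %*% A) + B * exp(-m / tau_L)
      },
      v_ext = {
        B <- abs(p$E_L) + p$i_plus / g_L
        A <- 2 * p$G[kk, ] / g_L * B
        as.vector(tl %*% A) + B * exp(-m / tau_L)
      },
      sigma2 = {
        s2 <- (p$sigma_B * tau_L / p$C[kk])^2
        A <- p$G[kk, ] / g_L * s2
        Cc <- s2 / 2 + 2 * p$sigma_R^2
        as.vector(tl %*% A) + Cc * exp(-2 * m / tau_L)
      },
      stop("unknown quantity: ", what))
  }
  if (quantity == "transition") {
    tot <- 0
    for (kk in seq_len(p$N)) {
      vdet_env <- one_k(kk, "v_syn") + one_k(kk, "v_ext")
      sig_env <- one_k(kk, "sigma2")
      M <- max(abs(p$theta - b$V_minus[kk]), abs(p$theta - b$V_plus[kk]))
      varX <- vdet_env / b$sigma_minus[kk] +
        M * sig_env / (2 * b$sigma_minus[kk]^3)
      tot <- tot + varX
    }
    tot / sqrt(2 * pi)
  } else {
    one_k(k, quantity)
  }
}

#' Empirical m-variation of a model quantity
#'
#' Measures, for each requested lag \code{m}, how much a
#' history-dependent quantity can change between two rasters that carry
#' identical spiking patterns over the last \code{m + 1} time steps but
#' differ before.  The supremum over all such pasts is probed from
#' below with an adversarial pair - the all-zeros versus all-ones past
#' (the extreme conductance states), sharing a random recent window -
#' plus \code{n_pairs} random-past pairs.  The reported value is the
#' maximal absolute difference over the probes, a lower bound on the
#' true variation by construction, so comparisons against
#' [analytic_envelope()] are valid one-sided tests.
#'
#' @param params a [gif_params()] object.
#' @param quantity one of \code{"alpha_sum"}, \code{"conductance"},
#'   \code{"gamma"}, \code{"v_syn"}, \code{"v_ext"}, \code{"sigma2"},
#'   \code{"transition"}.
#' @param t real probe time (quantities are evaluated at \code{t}; the
#'   transition probability at pattern time \code{floor(t)}).
#' @param m_list integer lags to probe.
#' @param n_pairs number of random-past pairs per lag.
#' @param seed integer seed.
#' @param k,j neuron indices where the quantity requires them.
#' @param p_common firing probability of the shared recent window.
#' @param gamma_lag lag used for the \code{"gamma"} quantity, which is
#'   the effective leak over \code{[t - gamma_lag, t]}.
#' @param M_past length of the explicit differing past window (the
#'   padding conventions extend the difference to the infinite past for
#'   the adversarial pair).
#' @param tol,order numerical controls.
#' @return A data frame of class \code{"gif_variation"} with columns
#'   \code{m}, \code{var_m} and (where defined) \code{envelope};
#'   attributes \code{slope} (fitted decay rate of \code{log var_m}),
#'   \code{m0} (smallest lag from which \code{var_m <= envelope} for
#'   all larger probed lags) and \code{quantity}.
#' @export
empirical_variation <- function(params, quantity, t, m_list,
                                n_pairs = 10, seed = 1,
                                k = 1, j = NULL, p_common = 0.5,
                                gamma_lag = 5, M_past = 10,
                                tol = 1e-8, order = 8) {
  qs <- c("alpha_sum", "conductance", "gamma", "v_syn", "v_ext",
          "sigma2", "transition")
  if (!quantity %in% qs)
    stop("unknown quantity '", quantity, "'; use one of: ",
         paste(qs, collapse = ", "))
  p <- params
  N <- p$N
  n0 <- floor(t)
  if (is.null(j)) j <- which.max(p$G[k, ])
  eval_q <- function(r) {
    switch(quantity,
      alpha_sum = alpha_sum(p, r, k, j, t, tol),
      conductance = conductance(p, r, k, t, tol),
      gamma = effective_leak(p, r, k, t - gamma_lag, t, tol, order),
      v_syn = ,
      v_ext = ,
      sigma2 = {
        pd <- potential_decomposition(p, r, k, t, tol, order)
        switch(quantity, v_syn = pd$V_syn, v_ext = pd$V_ext,
               sigma2 = pd$sigma2)
      },
      transition = transition_probability(
        p, r, n0, r$omega[, n0 - r$t0 + 1L], tol, order)$p_pattern)
  }
  # one common recent window per pair, nested across lags: for depth m
  # both rasters end with the same last m+1 columns of the pair's
  # common window (so the pattern at the probe time never changes with
  # m) and differ in the M_past columns before, plus the padding.
  mmax <- max(m_list)
  probe <- .with_seed(seed, {
    common_adv <- matrix(stats::rbinom(N * (mmax + 1L), 1L, p_common),
                         N, mmax + 1L)
    pairs <- list(list(common = common_adv,
                       pre1 = matrix(0L, N, M_past), pad1 = "zeros",
                       pre2 = matrix(1L, N, M_past), pad2 = "ones"))
    for (i in seq_len(n_pairs)) {
      pairs[[i + 1L]] <- list(
        common = matrix(stats::rbinom(N * (mmax + 1L), 1L, p_common),
                        N, mmax + 1L),
        pre1 = matrix(stats::rbinom(N * M_past, 1L, 0.5), N, M_past),
        pad1 = "zeros",
        pre2 = matrix(stats::rbinom(N * M_past, 1L, 0.5), N, M_past),
        pad2 = "zeros")
    }
    pairs
  })
  one_m <- function(m) {
    cols <- (mmax + 1L - m):(mmax + 1L)
    max(vapply(probe, function(pr) {
      r1 <- gif_raster(cbind(pr$pre1, pr$common[, cols, drop = FALSE]),
                       t0 = n0 - m - M_past, past_padding = pr$pad1)
      r2 <- gif_raster(cbind(pr$pre2, pr$common[, cols, drop = FALSE]),
                       t0 = n0 - m - M_past, past_padding = pr$pad2)
      abs(eval_q(r1) - eval_q(r2))
    }, numeric(1)))
  }
  var_m <- vapply(m_list, one_m, numeric(1))
  out <- data.frame(m = m_list, var_m = var_m)
  if (quantity %in% c("alpha_sum", "conductance", "v_syn", "v_ext",
                      "sigma2", "transition"))
    out$envelope <- analytic_envelope(p, quantity, m_list, k, j)
  pos <- var_m > 1e-13
  slope <- if (sum(pos) >= 3)
    unname(stats::coef(stats::lm(log(var_m[pos]) ~ m_list[pos]))[2])
  else NA_real_
  m0 <- NA_integer_
  if (!is.null(out$envelope)) {
    ok_from <- rev(cumprod(rev(out$var_m <= out$envelope))) == 1
    if (any(ok_from)) m0 <- m_list[which(ok_from)[1]]
  }
  structure(out, slope = slope, m0 = m0, quantity = quantity,
            class = c("gif_variation", "data.frame"))
}

#' @export
print.gif_variation <- function(x, ...) {
  cat(sprintf("m-variation of '%s' (fitted log-slope %.4g, m0 = %s):\n",
              attr(x, "quantity"), attr(x, "slope"),
              format(attr(x, "m0"))))
  print.data.frame(x, ...)
  invisible(x)
}
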