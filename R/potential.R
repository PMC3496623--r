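# Composite Gauss-Legendre machinery on unit-aligned pieces.
#
# All integrands of the model (conductance, effective leak, synaptic
# drive) are smooth inside each unit time interval: kinks only occur at
# integer spike times and at external-current breakpoints.  Quadrature
# pieces therefore never straddle an integer or a current breakpoint,
# which restores spectral accuracy of Gauss-Legendre on each piece.

.gifnet_env <- new.env(parent = emptyenv())

# reference Gauss-Legendre rule on [0, 1] plus the partial-integration
# matrix S with S[i, j] = integral over [0, x_i] of the j-th Lagrange
# basis polynomial on the nodes: node values of a smooth function map to
# its cumulative integral at the nodes via S %*% values.
.gl_ref <- function(order) {
  key <- sprintf("gl%d", order)
  if (!is.null(.gifnet_env[[key]])) return(.gifnet_env[[key]])
  gl <- pracma::gaussLegendre(order, 0, 1)
  x <- gl$x; w <- gl$w
  bw <- vapply(seq_along(x),
               function(j) 1 / prod(x[j] - x[-j]), numeric(1))
  lag_eval <- function(y) {
    # rows: evaluation points y, cols: basis index
    out <- matrix(0, length(y), length(x))
    for (m in seq_along(y)) {
      dif <- y[m] - x
      hit <- which(abs(dif) < 1e-14)
      if (length(hit)) { out[m, hit[1]] <- 1; next }
      r <- bw / dif
      out[m, ] <- r / sum(r)
    }
    out
  }
  S <- matrix(0, order, order)
  fine <- pracma::gaussLegendre(max(2 * order, 16), 0, 1)
  for (i in seq_along(x)) {
    y <- fine$x * x[i]
    S[i, ] <- (x[i] * fine$w) %*% lag_eval(y)
  }
  .gifnet_env[[key]] <- list(x = x, w = w, S = S)
  .gifnet_env[[key]]
}

# piece boundaries of [lo, hi]: integers and external-current
# breakpoints interior to the range
.piece_points <- function(params, lo, hi) {
  pts <- c(lo, hi)
  ints <- seq.int(ceiling(lo), floor(hi))
  pts <- c(pts, ints)
  sb <- .iext_subbreaks(params)
  if (length(sb)) {
    base <- seq.int(floor(lo), floor(hi))
    pts <- c(pts, as.vector(outer(base, sb, "+")))
  }
  pts <- sort(unique(pts))
  pts <- pts[pts >= lo - 1e-12 & pts <= hi + 1e-12]
  pts[c(TRUE, diff(pts) > 1e-12)]
}

# Cumulative-conductance table for neuron k on [lo, hi]: quadrature
# nodes, scaled weights, conductance and kernel values at the nodes, and
# the running integral A(x) = int_lo^x g of the conductance.
.conductance_table <- function(params, raster, k, lo, hi,
                               tol = 1e-10, order = 8) {
  ref <- .gl_ref(order)
  pts <- .piece_points(params, lo, hi)
  np <- length(pts) - 1L
  lens <- diff(pts)
  nodes <- as.vector(vapply(seq_len(np),
    function(p) pts[p] + lens[p] * ref$x, numeric(order)))
  wts <- as.vector(vapply(seq_len(np),
    function(p) lens[p] * ref$w, numeric(order)))
  N <- params$N
  alphaM <- matrix(0, length(nodes), N)
  active <- which(params$G[k, ] > 0)
  for (j in active)
    alphaM[, j] <- alpha_sum(params, raster, k, j, nodes, tol)
  g <- params$g_L[k] + as.vector(alphaM %*% params$G[k, ])
  gm <- matrix(g, nrow = order)
  piece_int <- lens * colSums(ref$w * gm)
  prefix <- c(0, cumsum(piece_int))
  A <- as.vector(vapply(seq_len(np),
    function(p) prefix[p] + lens[p] * (ref$S %*% gm[, p]),
    numeric(order)))
  list(nodes = nodes, wts = wts, g = g, A = A,
       A_total = prefix[np + 1L], alphaM = alphaM,
       iext = i_ext_value(params, k, nodes))
}

#' Effective leak factor between two times
#'
#' The decay factor \code{Gamma_k(t1, t2, omega) = exp(-(1/C_k) *
#' integral of g_k(u, omega) over [t1, t2])} that weights how much of
#' the membrane potential at \code{t1} survives at \code{t2}.  It equals
#' 1 at coincident endpoints and, for any raster, lies between the
#' all-one-raster and all-zero-raster values
#' \code{exp(-(t2-t1)/tau_M)} and \code{exp(-(t2-t1)/tau_L)}.
#'
#' @param params a [gif_params()] object.
#' @param raster a [gif_raster()] object.
#' @param k neuron index.
#' @param t1,t2 real times with \code{t1 <= t2}.
#' @param tol kernel truncation tolerance.
#' @param order Gauss-Legendre order per quadrature piece.
#' @return value in (0, 1].
#' @export
effective_leak <- function(params, raster, k, t1, t2,
                           tol = 1e-10, order = 8) {
  if (t1 > t2) stop("effective_leak requires t1 <= t2")
  if (t1 == t2) return(1)
  tab <- .conductance_table(params, raster, k, t1, t2, tol, order)
  exp(-tab$A_total / params$C[k])
}

# conservative backward-integration horizon: beyond this depth every
# remaining contribution (synaptic, external, noise-variance, reset
# factor) is below tol thanks to the exponential leak envelope.
.pd_horizon <- function(params, k, tol = 1e-10) {
  p <- params
  tau_L <- p$C[k] / p$g_L[k]
  d <- p$profile_degree
  a_crude <- 1 + max(tail_bound(d, max(p$tau_syn), 0), 1)
  K <- abs(p$E_L) + p$i_plus / p$g_L[k] +
    a_crude / p$g_L[k] * sum(abs(p$W[k, ])) +
    p$sigma_R^2 + (p$sigma_B / p$C[k])^2 * tau_L + 1
  max(5L, as.integer(ceiling(tau_L * log(K / tol))) + 5L)
}

# shared integral kernel: all history integrals of neuron k from s to t
.pd_core <- function(params, raster, k, s, t, tol, order) {
  Ck <- params$C[k]
  if (t - s < 1e-14) {
    return(list(Gamma_r = 1, Jsyn = numeric(params$N),
                JextL = 0, Jexti = 0, J2 = 0))
  }
  tab <- .conductance_table(params, raster, k, s, t, tol, order)
  Gnode <- exp(-(tab$A_total - tab$A) / Ck)
  wG <- tab$wts * Gnode
  list(Gamma_r = exp(-tab$A_total / Ck),
       Jsyn = as.vector(wG %*% tab$alphaM),
       JextL = sum(wG),
       Jexti = sum(wG * tab$iext),
       J2 = sum(tab$wts * Gnode^2))
}

#' Conditional decomposition of the membrane potential at a time
#'
#' Evaluates, for neuron \code{k} at real time \code{t} under a fixed
#' raster, every ingredient of the conditional Gaussian law of the
#' membrane potential: the last reset time, the effective leak since
#' that reset, the synaptic and external contributions to the
#' deterministic potential, and the conditional noise variance
#' (reset-value variance decayed by the squared leak plus the integrated
#' Wiener-noise variance).
#'
#' When the neuron never fired (last reset \code{-Inf}) the integrals
#' extend over the infinite past; they are truncated at a horizon where
#' the exponential leak envelope puts the remaining mass below
#' \code{tol}, and the accumulated bound on what was dropped is
#' reported as \code{truncation_error_bound}.
#'
#' @inheritParams effective_leak
#' @param t real query time.
#' @return A list of class \code{"gif_potential"} with fields \code{k},
#'   \code{t}, \code{tau} (last reset or \code{-Inf}), \code{Gamma},
#'   \code{V_syn}, \code{V_ext}, \code{V_det}, \code{sigma2},
#'   \code{truncation_error_bound}.
#' @export
potential_decomposition <- function(params, raster, k, t,
                                    tol = 1e-10, order = 8) {
  p <- params
  tau <- last_reset(raster, k, t)
  m <- .pd_horizon(p, k, tol)
  tau_L <- p$C[k] / p$g_L[k]
  reset_in <- is.finite(tau) && tau >= t - m
  s_eff <- if (reset_in) tau else t - m
  core <- .pd_core(p, raster, k, s_eff, t, tol, order)
  V_syn <- sum(p$W[k, ] * core$Jsyn) / p$C[k]
  V_ext <- p$E_L / tau_L * core$JextL + core$Jexti / p$C[k]
  sigma2 <- (if (reset_in) core$Gamma_r^2 * p$sigma_R^2 else 0) +
    (p$sigma_B / p$C[k])^2 * core$J2
  trunc <- if (reset_in) 0 else {
    env <- exp(-m / tau_L)
    a_crude <- 1 + max(tail_bound(p$profile_degree, max(p$tau_syn), 0), 1)
    env * (a_crude / p$g_L[k] * sum(abs(p$W[k, ]))) +
      env * (abs(p$E_L) + p$i_plus / p$g_L[k]) +
      env^2 * (p$sigma_R^2 + (p$sigma_B / p$C[k])^2 * tau_L / 2)
  }
  structure(
    list(k = k, t = t, tau = tau,
         Gamma = if (reset_in) core$Gamma_r else 0,
         V_syn = V_syn, V_ext = V_ext, V_det = V_syn + V_ext,
         sigma2 = sigma2, truncation_error_bound = trunc),
    class = "gif_potential")
}

#' @export
print.gif_potential <- function(x, ...) {
  cat(sprintf(
    "membrane potential of neuron %d at t = %g (last reset %s):\n",
    x$k, x$t, if (is.finite(x$tau)) format(x$tau) else "-Inf"))
  cat(sprintf("  Gamma = %.6g, V_syn = %.6g, V_ext = %.6g, V_det = %.6g\n",
              x$Gamma, x$V_syn, x$V_ext, x$V_det))
  cat(sprintf("  sigma2 = %.6g (truncation bound %.3g)\n",
              x$sigma2, x$truncation_error_bound))
  invisible(x)
}

#' Synaptic contribution to the membrane potential
#'
#' \code{V_syn(s, t) = (1/C_k) * sum_j W[k, j] * integral over [s, t] of
#' Gamma_k(t1, t, omega) * alpha_sum(k, j, t1)}.  \code{s = -Inf}
#' integrates over the full past, truncated where the leak envelope
#' makes the remainder negligible.
#'
#' @inheritParams effective_leak
#' @param s lower integration time (may be \code{-Inf}).
#' @param t upper integration time.
#' @return a voltage.
#' @export
v_syn <- function(params, raster, k, s, t, tol = 1e-10, order = 8) {
  if (!is.finite(s)) s <- t - .pd_horizon(params, k, tol)
  if (s > t) stop("v_syn requires s <= t")
  core <- .pd_core(params, raster, k, s, t, tol, order)
  sum(params$W[k, ] * core$Jsyn) / params$C[k]
}

#' External (leak + stimulus) contribution to the membrane potential
#'
#' \code{V_ext(s, t) = (E_L/tau_L) * integral of Gamma + (1/C_k) *
#' integral of i_ext * Gamma} over \code{[s, t]}; bounded in absolute
#' value by \code{|E_L| + i_plus / g_L[k]} uniformly in \code{s, t} and
#' the raster.
#'
#' @inheritParams v_syn
#' @return a voltage.
#' @export
v_ext <- function(params, raster, k, s, t, tol = 1e-10, order = 8) {
  if (!is.finite(s)) s <- t - .pd_horizon(params, k, tol)
  if (s > t) stop("v_ext requires s <= t")
  core <- .pd_core(params, raster, k, s, t, tol, order)
  tau_L <- params$C[k] / params$g_L[k]
  params$E_L / tau_L * core$JextL + core$Jexti / params$C[k]
}

#' Conditional noise variance of the membrane potential
#'
#' Variance of the stochastic part of the potential at \code{t} given
#' the raster: the reset-value variance decayed by the squared effective
#' leak since the last reset, plus the accumulated Wiener-noise
#' variance \code{(sigma_B/C_k)^2 * integral of Gamma^2}.  Just after a
#' reset the value is \code{sigma_R^2}; it always lies inside the
#' \code{[sigma_minus^2, sigma_plus^2]} window of [derive_bounds()].
#'
#' @inheritParams effective_leak
#' @param t real query time.
#' @return a squared voltage.
#' @export
noise_variance <- function(params, raster, k, t, tol = 1e-10, order = 8) {
  potential_decomposition(params, raster, k, t, tol, order)$sigma2
}

#' Conditional Gaussian law of the network potential
#'
#' Given the raster up to \code{floor(t)}, the membrane potentials at
#' \code{t} are conditionally independent Gaussians; this returns their
#' means (the deterministic potential) and variances per neuron.
#'
#' @inheritParams effective_leak
#' @param t real query time.
#' @return a data frame with columns \code{k}, \code{mean}, \code{var},
#'   \code{sd}, \code{tau} (last reset).
#' @export
conditional_law <- function(params, raster, t, tol = 1e-10, order = 8) {
  rows <- lapply(seq_len(params$N), function(k) {
    pd <- potential_decomposition(params, raster, k, t, tol, order)
    data.frame(k = k, mean = pd$V_det, var = pd$sigma2,
               sd = sqrt(pd$sigma2), tau = pd$tau)
  })
  do.call(rbind, rows)
}
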