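#' Alpha-kernel value
#'
#' Causal synaptic response kernel \code{alpha(t) = (t/tau)^d
#' exp(-t/tau)} for \code{t >= 0} and 0 for \code{t < 0}.  Degree
#' \code{d = 0} is the exponential profile (value 1 at \code{t = 0},
#' taking the right-limit convention for the Heaviside factor); degree
#' \code{d = 1} is the classical alpha function, zero at the spike time
#' and maximal at \code{t = tau}.
#'
#' @param d integer kernel degree (>= 0).
#' @param tau decay time (> 0).
#' @param t time lag(s) since the presynaptic spike; vectorized.
#' @return dimensionless kernel value(s).
#' @export
alpha_value <- function(d, tau, t) {
  out <- numeric(length(t))
  pos <- t >= 0
  x <- t[pos] / tau
  out[pos] <- x^d * exp(-x)
  out
}

#' Tail bound on the spike-history kernel sum
#'
#' Closed-form upper bound on the total kernel mass contributed by
#' spikes older than lag \code{m}: the integral of \code{(u/tau)^d
#' exp(-u/tau)} from \code{m} to infinity, i.e. \code{tau * Gamma(d+1) *
#' Q(d+1, m/tau)} with \code{Q} the upper regularized incomplete gamma
#' function.  For \code{d = 0} this is \code{tau * exp(-m/tau)}; for
#' \code{d = 1} it is \code{(m + tau) * exp(-m/tau)}.  The bound is the
#' basis of the automatic history-truncation horizon.
#'
#' @param d integer kernel degree.
#' @param tau decay time.
#' @param m lag (>= 0); vectorized.
#' @return nonnegative bound value(s), decreasing in \code{m} beyond the
#'   kernel peak.
#' @export
tail_bound <- function(d, tau, m) {
  m <- pmax(m, 0)
  tau * gamma(d + 1) *
    stats::pgamma(m / tau, shape = d + 1, lower.tail = FALSE)
}

#' History truncation horizon
#'
#' Smallest integer lag \code{m >= 1} at which [tail_bound()] falls
#' below \code{tol}: spikes more than \code{m} steps in the past can be
#' dropped from the kernel sum with an error below \code{tol}.
#'
#' @param d integer kernel degree.
#' @param tau decay time.
#' @param tol absolute tolerance (default \code{1e-10}).
#' @return integer horizon.
#' @export
truncation_horizon <- function(d, tau, tol = 1e-10) {
  # analytic seed for the exponential factor, then exact scan
  m <- max(1, ceiling(tau * log(max(tau, 1) / tol)))
  while (m > 1 && tail_bound(d, tau, m - 1) < tol) m <- m - 1
  while (tail_bound(d, tau, m) >= tol) m <- m + 1
  as.integer(m)
}

#' Spike-history kernel sum
#'
#' Sum of \code{alpha_kj(t - s)} over all spike times \code{s} of
#' presynaptic neuron \code{j} strictly before \code{t}, under the
#' raster's padding convention.  With zeros padding the sum is exact;
#' with ones padding the infinite padded past is truncated at the lag
#' where [tail_bound()] drops below \code{tol}.
#'
#' @param params a [gif_params()] object.
#' @param raster a [gif_raster()] object.
#' @param k,j postsynaptic / presynaptic neuron indices (the pair
#'   selects the decay time \code{tau_syn[k, j]}).
#' @param t real time(s); vectorized.
#' @param tol truncation tolerance for the padded past.
#' @return dimensionless value(s) of the summed synaptic response.
#' @export
alpha_sum <- function(params, raster, k, j, t, tol = 1e-10) {
  d <- params$profile_degree
  tau <- params$tau_syn[k, j]
  m_h <- truncation_horizon(d, tau, tol)
  s <- spike_times(raster, j, floor(min(t)) - m_h, ceiling(max(t)))
  if (!length(s)) return(numeric(length(t)))
  lag <- outer(t, s, "-")
  contrib <- matrix(alpha_value(d, tau, as.vector(lag)), nrow = length(t))
  contrib[lag <= 0] <- 0  # only spikes strictly before t
  rowSums(contrib)
}

#' Total membrane conductance at a time
#'
#' Leak plus spike-driven synaptic conductance,
#' \code{g_k(t, omega) = g_L[k] + sum_j G[k, j] * alpha_sum(k, j, t)}.
#' Over all rasters the value is sandwiched between \code{g_L[k]}
#' (all-zero raster) and the maximal conductance \code{g_M[k]} of
#' [derive_bounds()] (all-one raster).
#'
#' @inheritParams alpha_sum
#' @return conductance value(s), vectorized over \code{t}.
#' @export
conductance <- function(params, raster, k, t, tol = 1e-10) {
  g <- rep(params$g_L[k], length(t))
  for (j in which(params$G[k, ] > 0))
    g <- g + params$G[k, j] * alpha_sum(params, raster, k, j, t, tol)
  g
}
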