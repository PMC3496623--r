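#' Gaussian tail firing probability
#'
#' Probability that a standard Gaussian exceeds \code{x}: the one-step
#' firing probability of a neuron whose normalized distance to threshold
#' is \code{x}.  Strictly decreasing, with values in (0, 1) for finite
#' \code{x} and the symmetry \code{firing_prob(x) + firing_prob(-x) = 1}.
#'
#' @param x numeric, vectorized.
#' @return probability value(s).
#' @export
firing_prob <- function(x) stats::pnorm(x, lower.tail = FALSE)

#' Normalized distance to threshold
#'
#' \code{X_k(n - 1, omega) = (theta - V_det) / sigma}, evaluated at
#' time \code{n - 1} with the deterministic potential and conditional
#' standard deviation taken from the last reset of neuron \code{k}.
#' The one-step firing probability of the neuron at time \code{n} is
#' \code{firing_prob(X_k)}.  Always finite: the conditional standard
#' deviation is bounded below by \code{sigma_minus > 0}.
#'
#' @param params a [gif_params()] object.
#' @param raster a [gif_raster()] object covering history up to
#'   \code{n - 1} (with its padding convention).
#' @param k neuron index.
#' @param n integer time of the prospective spike.
#' @param tol,order numerical controls, see [potential_decomposition()].
#' @return a real number.
#' @export
firing_argument <- function(params, raster, k, n, tol = 1e-10, order = 8) {
  pd <- potential_decomposition(params, raster, k, n - 1, tol, order)
  (params$theta - pd$V_det) / sqrt(pd$sigma2)
}

#' One-step transition probability of a spiking pattern
#'
#' Probability of observing pattern \code{omega(n)} given the raster
#' before \code{n}: the product over neurons of the Bernoulli terms
#' \code{omega_k(n) * pi_k + (1 - omega_k(n)) * (1 - pi_k)} with
#' \code{pi_k = firing_prob(X_k(n - 1))} (neurons are conditionally
#' independent given the past).  The log of the pattern probability is
#' the one-step Gibbs potential.
#'
#' @inheritParams firing_argument
#' @param pattern length-\code{N} 0/1 vector; defaults to the raster's
#'   own column at time \code{n}.
#' @return A list of class \code{"gif_transition"}: \code{n},
#'   \code{pattern}, \code{X} (per-neuron normalized distances),
#'   \code{p_fire} (per-neuron firing probabilities),
#'   \code{p_pattern}, \code{phi} (log of \code{p_pattern}) and the
#'   per-neuron \code{phi_k}.
#' @export
transition_probability <- function(params, raster, n, pattern = NULL,
                                   tol = 1e-10, order = 8) {
  N <- params$N
  if (is.null(pattern)) {
    if (n < raster$t0 || n > .raster_t_end(raster))
      stop("no pattern supplied and time n outside the raster window")
    pattern <- raster$omega[, n - raster$t0 + 1L]
  }
  pattern <- as.integer(pattern)
  stopifnot(length(pattern) == N, all(pattern %in% 0:1))
  X <- vapply(seq_len(N),
              function(k) firing_argument(params, raster, k, n, tol, order),
              numeric(1))
  p <- firing_prob(X)
  phi_k <- ifelse(pattern == 1L, log(p), log1p(-p))
  structure(
    list(n = n, pattern = pattern, X = X, p_fire = p,
         p_pattern = exp(sum(phi_k)), phi = sum(phi_k), phi_k = phi_k),
    class = "gif_transition")
}

#' @export
print.gif_transition <- function(x, ...) {
  cat(sprintf("transition at n = %d: pattern [%s]\n",
              x$n, paste(x$pattern, collapse = " ")))
  cat(sprintf("  p_fire:    %s\n", paste(signif(x$p_fire, 4), collapse = " ")))
  cat(sprintf("  p_pattern = %.6g, phi = %.6g\n", x$p_pattern, x$phi))
  invisible(x)
}

#' Gibbs potential of a spike block
#'
#' Sum of the one-step log transition probabilities over the block of
#' times \code{m..n} of the raster: \code{exp} of the result is the
#' conditional probability of the block given the raster before
#' \code{m}.  Summing \code{exp} over all possible blocks of that
#' length (for a fixed past) gives 1 - the infinite-memory potential is
#' exactly normalized.
#'
#' @inheritParams firing_argument
#' @param m,n integer block limits, \code{m <= n}, both inside the
#'   raster window.
#' @return the (negative) potential value \code{sum_l log p(l, omega)}.
#' @export
gibbs_potential <- function(params, raster, m, n, tol = 1e-10, order = 8) {
  stopifnot(m <= n)
  sum(vapply(m:n, function(l)
    transition_probability(params, raster, l, NULL, tol, order)$phi,
    numeric(1)))
}

.enumeration_guard <- function(bits) {
  if (bits > 22)
    stop(sprintf(
      "enumeration over %d binary variables exceeds the 22-bit guard", bits))
}

#' Finite-memory truncation of the Gibbs potential
#'
#' Evaluates the one-step potential of the pattern at relative time 0 of
#' a block spanning relative times \code{-D..0}, with the infinite past
#' before \code{-D} replaced by a stated boundary condition (zeros or
#' ones padding).  Also returns the normalization
#' \code{Z = sum over patterns at time 0 of exp(phi)} obtained by
#' explicit enumeration; since the truncation replaces the past but
#' keeps the conditional-probability form, \code{exp(phi) / Z} is a
#' valid conditional probability (and \code{Z} is 1 up to floating
#' error).
#'
#' @param params a [gif_params()] object.
#' @param block \code{N x (D + 1)} 0/1 matrix, columns at relative times
#'   \code{-D..0}.
#' @param boundary \code{"zeros"} or \code{"ones"}: the assumed past
#'   before time \code{-D}.
#' @param tol,order numerical controls.
#' @return list with \code{phi}, \code{Z} and the conditional
#'   probability \code{p = exp(phi) / Z}.
#' @export
truncated_potential <- function(params, block, boundary = c("zeros", "ones"),
                                tol = 1e-10, order = 8) {
  boundary <- match.arg(boundary)
  block <- as.matrix(block)
  N <- params$N
  stopifnot(nrow(block) == N)
  D <- ncol(block) - 1L
  .enumeration_guard(N * (D + 1L))
  r <- gif_raster(block, t0 = -D, past_padding = boundary)
  X <- vapply(seq_len(N),
              function(k) firing_argument(params, r, k, 0L, tol, order),
              numeric(1))
  p <- firing_prob(X)
  phi_of <- function(pat) sum(ifelse(pat == 1L, log(p), log1p(-p)))
  phi <- phi_of(block[, D + 1L])
  pats <- .all_patterns(N)
  Z <- sum(exp(apply(pats, 1L, phi_of)))
  list(phi = phi, Z = Z, p = exp(phi) / Z)
}

# all 2^N spiking patterns as a (2^N) x N 0/1 matrix, pattern index in
# row order = little-endian binary code (neuron 1 is bit 0)
.all_patterns <- function(N) {
  idx <- 0:(2^N - 1)
  m <- matrix(0L, length(idx), N)
  for (k in seq_len(N)) m[, k] <- bitwAnd(idx %/% 2^(k - 1), 1L)
  m
}

#' Monomial expansion of the truncated potential
#'
#' Writes the depth-\code{D} truncated potential as a pseudo-Boolean
#' polynomial over the spike indicators of the block: \code{phi(block) =
#' sum over subsets S of lambda_S * prod_{(k,n) in S} omega_k(n)}, with
#' coefficients obtained by exact Moebius inversion over all
#' \code{2^(N(D+1))} blocks.  Because the potential is a sum over
#' neurons of terms each affine in that neuron's time-0 indicator, every
#' coefficient of a monomial containing two or more time-0 factors
#' vanishes; at \code{D = 0} the expansion reduces to a constant plus
#' independent per-neuron terms (an independent-Bernoulli model, with no
#' pairwise coupling).
#'
#' @param params a [gif_params()] object.
#' @param D memory depth (block spans relative times \code{-D..0});
#'   \code{N * (D + 1)} must stay within the 22-bit enumeration guard.
#' @param boundary assumed past before \code{-D}, \code{"zeros"} or
#'   \code{"ones"} (the coefficients are defined relative to it).
#' @param tol,order numerical controls.
#' @return A list of class \code{"gif_expansion"}: \code{lambda}
#'   (coefficient per subset, indexed by bit mask + 1), \code{monomial}
#'   (list of \code{(k, n)} pair matrices per mask), \code{phi} (the
#'   enumerated potential values), \code{D}, \code{boundary}, and the
#'   bit layout (\code{bit_k}, \code{bit_n}).
#' @export
monomial_expansion <- function(params, D, boundary = c("zeros", "ones"),
                               tol = 1e-10, order = 8) {
  boundary <- match.arg(boundary)
  N <- params$N
  B <- N * (D + 1L)
  .enumeration_guard(B)
  # bit b (0-based) encodes neuron k = b %% N + 1 at time n = b %/% N - D
  bit_k <- (0:(B - 1)) %% N + 1L
  bit_n <- (0:(B - 1)) %/% N - D
  n_hist_bits <- N * D
  n_hist <- 2^n_hist_bits
  pats <- .all_patterns(N)
  phi <- numeric(2^B)
  for (h in 0:(n_hist - 1)) {
    hist <- matrix(0L, N, max(D, 1L))
    if (D > 0) {
      bits <- bitwAnd(h %/% 2^(0:(n_hist_bits - 1)), 1L)
      hist <- matrix(bits, N, D)  # columns: times -D .. -1
    }
    block0 <- if (D > 0) hist else matrix(0L, N, 0)
    r <- gif_raster(cbind(block0, 0L), t0 = -D, past_padding = boundary)
    X <- vapply(seq_len(N),
                function(k) firing_argument(params, r, k, 0L, tol, order),
                numeric(1))
    p <- firing_prob(X)
    lp1 <- log(p); lp0 <- log1p(-p)
    phi_pat <- pats %*% lp1 + (1 - pats) %*% lp0
    phi[h + 2^n_hist_bits * (0:(2^N - 1)) + 1L] <- phi_pat
  }
  lambda <- phi
  for (b in 0:(B - 1)) {           # in-place Moebius transform
    step <- 2^b
    idx <- which(bitwAnd((0:(2^B - 1)) %/% step, 1L) == 1L)
    lambda[idx] <- lambda[idx] - lambda[idx - step]
  }
  monomial <- lapply(0:(2^B - 1), function(mask) {
    b <- which(bitwAnd(mask %/% 2^(0:(B - 1)), 1L) == 1L)
    cbind(k = bit_k[b], n = bit_n[b])
  })
  structure(list(lambda = lambda, monomial = monomial, phi = phi,
                 D = D, boundary = boundary,
                 bit_k = bit_k, bit_n = bit_n),
            class = "gif_expansion")
}

#' Evaluate a monomial expansion on a block
#'
#' Reconstructs \code{phi(block)} from the coefficients of
#' [monomial_expansion()] by summing \code{lambda_S} over all subsets
#' \code{S} of the block's active (spiking) indicators.
#'
#' @param expansion a \code{"gif_expansion"} object.
#' @param block \code{N x (D + 1)} 0/1 matrix.
#' @return the reconstructed potential value.
#' @export
expansion_value <- function(expansion, block) {
  B <- length(expansion$bit_k)
  active <- which(as.vector(block) == 1L) - 1L  # bit indices
  masks <- 0L
  for (b in active) masks <- c(masks, masks + 2^b)
  sum(expansion$lambda[masks + 1L])
}

#' Bounds on the probability of a silent window
#'
#' Uniform geometric bounds on the probability that no neuron-\code{k}
#' spike constraint is violated... more precisely: the probability that
#' a given neuron stays silent over \code{len} consecutive time steps
#' lies strictly between \code{Pi_prod_minus^len} and
#' \code{Pi_prod_plus^len}, the products over neurons of the per-neuron
#' one-step spiking-state bounds of [derive_bounds()].  Both bounds
#' decay geometrically: silence becomes exponentially rare with window
#' length, but never has probability zero.
#'
#' @param params a [gif_params()] object.
#' @param len window length (>= 1).
#' @return named vector \code{c(lower, upper)}.
#' @export
no_fire_probability_bounds <- function(params, len) {
  stopifnot(len >= 1)
  b <- derive_bounds(params)
  c(lower = b$Pi_prod_minus^len, upper = b$Pi_prod_plus^len)
}

#' Uniqueness-criterion quantities for the spike-train law
#'
#' The conditional spike law admits a unique consistent Gibbs measure
#' when (i) one-step pattern probabilities are uniformly bounded below
#' by a positive constant and (ii) the summed variation of the
#' transition probability over all lags is finite.  This returns a
#' certified lower bound for (i) - the product of the per-neuron
#' \code{Pi_minus} bounds - and a numerical estimate of (ii): the
#' empirical partial sum of measured variations up to \code{m_max},
#' plus the analytic geometric tail of the variation envelope summed to
#' convergence.  The tail uses proved envelope constants, but the
#' partial sum is an empirical lower-bound probe, so the total is an
#' estimate rather than a proof.
#'
#' @param params a [gif_params()] object.
#' @param t integer time at which variations are probed.
#' @param m_max largest lag measured empirically.
#' @param n_pairs random raster pairs per lag (on top of the
#'   adversarial all-zeros/all-ones pair).
#' @param seed integer seed.
#' @param tol,order numerical controls.
#' @return list with \code{m_p_lower} (and its always-finite log-scale
#'   companion \code{log_m_p_lower}, which certifies strict positivity
#'   even when the plain product underflows), \code{v_p_estimate},
#'   \code{partial_sum}, \code{tail_bound}, and the per-lag empirical
#'   variations \code{var_m}.
#' @export
uniqueness_criteria <- function(params, t = 0, m_max = 10, n_pairs = 10,
                                seed = 1, tol = 1e-8, order = 8) {
  b <- derive_bounds(params)
  rep_ <- empirical_variation(params, "transition", t, 0:m_max,
                              n_pairs, seed, tol = tol, order = order)
  partial <- sum(rep_$var_m)
  tail_sum <- 0
  m <- m_max + 1
  repeat {
    term <- analytic_envelope(params, "transition", m)
    tail_sum <- tail_sum + term
    if (term < 1e-12 * max(tail_sum, 1e-300)) break
    m <- m + 1
    if (m > m_max + 10000) break
  }
  list(m_p_lower = b$Pi_prod_minus,
       log_m_p_lower = b$log_Pi_prod_minus,
       v_p_estimate = partial + tail_sum,
       partial_sum = partial, tail_bound = tail_sum,
       var_m = rep_$var_m)
}
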