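#' Construct a gIF network parameter set
#'
#' Bundles every constant of a stochastic conductance-based
#' integrate-and-fire network: membrane capacitances and leak
#' conductances, the shared firing threshold, reversal potentials, the
#' synaptic amplitude matrix together with the population label (E/I) of
#' each presynaptic neuron, the synaptic decay-time matrix and kernel
#' degree, the two noise amplitudes (Wiener noise on the current and the
#' random reset value), and the external current.
#'
#' Time is measured in units of the spike duration (one raster time
#' step).  Voltages are measured relative to the rest potential, which
#' is also the mean of the random reset value; the threshold is
#' therefore a positive number in typical use.  Conductance, capacitance
#' and current units only need to be mutually consistent.
#'
#' The synaptic weight matrix \code{W} is derived, not supplied:
#' \code{W[k, j] = E_plus * G[k, j]} when presynaptic neuron \code{j} is
#' excitatory and \code{E_minus * G[k, j]} when it is inhibitory.
#' \code{G[k, j] = 0} encodes the absence of a synapse from \code{j} to
#' \code{k}.
#'
#' @param N number of neurons.
#' @param C membrane capacitance, scalar or length-\code{N} (positive).
#' @param theta firing threshold, shared by all neurons.
#' @param E_L leak reversal potential.
#' @param E_plus,E_minus excitatory / inhibitory reversal potentials.
#' @param g_L leak conductance, scalar or length-\code{N} (positive).
#' @param G \code{N x N} nonnegative matrix of maximal synaptic
#'   conductance amplitudes (row = postsynaptic, column = presynaptic).
#' @param pop length-\code{N} character vector of population labels,
#'   \code{"E"} or \code{"I"}, for each (presynaptic) neuron.
#' @param tau_syn synaptic decay times, scalar or \code{N x N} positive
#'   matrix.
#' @param profile_degree integer degree \code{d >= 0} of the alpha
#'   kernel family \code{(t/tau)^d exp(-t/tau)} (0 = exponential,
#'   1 = classical alpha function).
#' @param sigma_B amplitude (> 0) of the white noise on the membrane
#'   current.
#' @param sigma_R standard deviation (> 0) of the Gaussian reset value.
#' @param i_ext external current: a scalar or length-\code{N} numeric
#'   (constant in time), or a list \code{list(breaks =, values =)}
#'   describing a piecewise-constant current repeating over each unit
#'   time interval: \code{breaks} is an increasing vector in
#'   \code{[0, 1)} starting at 0 and \code{values} an \code{N x
#'   length(breaks)} matrix, column \code{l} applying on
#'   \code{[n + breaks[l], n + breaks[l + 1])} for every integer
#'   \code{n}.
#' @param tau_sep minimal separation (>= 1) between successive spikes of
#'   one neuron; with spikes aligned on the integer grid the default 1
#'   allows firing at consecutive time steps.
#'
#' @return An object of class \code{"gif_params"}: a list with the
#'   supplied fields (scalars broadcast to full length), the derived
#'   weight matrix \code{W} and the external-current bound
#'   \code{i_plus}.
#' @seealso [validate_params()], [derive_bounds()], [read_gif_params()]
#' @export
gif_params <- function(N,
                       C = 1,
                       theta = 8,
                       E_L = 0,
                       E_plus = 65,
                       E_minus = -5,
                       g_L = 0.5,
                       G = matrix(0, N, N),
                       pop = rep("E", N),
                       tau_syn = 2,
                       profile_degree = 0,
                       sigma_B = 1.5,
                       sigma_R = 1,
                       i_ext = 0,
                       tau_sep = 1) {
  N <- as.integer(N)
  if (length(N) != 1L || is.na(N) || N < 1L)
    stop("N must be a positive integer")
  C <- .broadcast(C, N, "C")
  g_L <- .broadcast(g_L, N, "g_L")
  G <- as.matrix(G)
  if (!all(dim(G) == c(N, N))) stop("G must be an N x N matrix")
  if (is.matrix(tau_syn)) {
    if (!all(dim(tau_syn) == c(N, N))) stop("tau_syn must be N x N")
  } else {
    tau_syn <- matrix(as.numeric(tau_syn), N, N)
  }
  pop <- as.character(pop)
  if (length(pop) == 1L) pop <- rep(pop, N)
  i_ext <- .normalize_iext(i_ext, N)

  p <- structure(
    list(N = N, C = C, theta = as.numeric(theta), E_L = as.numeric(E_L),
         E_plus = as.numeric(E_plus), E_minus = as.numeric(E_minus),
         g_L = g_L, G = G, pop = pop, tau_syn = tau_syn,
         profile_degree = as.integer(profile_degree),
         sigma_B = as.numeric(sigma_B), sigma_R = as.numeric(sigma_R),
         i_ext = i_ext, tau_sep = as.numeric(tau_sep)),
    class = "gif_params")
  p$W <- .weight_matrix(p)
  p$i_plus <- .iext_bound(i_ext)
  p
}

.broadcast <- function(x, N, name) {
  x <- as.numeric(x)
  if (length(x) == 1L) x <- rep(x, N)
  if (length(x) != N) stop(sprintf("%s must have length 1 or N", name))
  x
}

# canonical internal form of i_ext: list(breaks, values) with values N x L
.normalize_iext <- function(i_ext, N) {
  if (is.list(i_ext)) {
    breaks <- as.numeric(i_ext$breaks)
    values <- as.matrix(i_ext$values)
    if (length(breaks) < 1L || breaks[1] != 0 || any(diff(breaks) <= 0) ||
        any(breaks >= 1))
      stop("i_ext$breaks must be increasing, start at 0 and lie in [0, 1)")
    if (nrow(values) != N || ncol(values) != length(breaks))
      stop("i_ext$values must be N x length(breaks)")
    list(breaks = breaks, values = values)
  } else {
    v <- .broadcast(i_ext, N, "i_ext")
    list(breaks = 0, values = matrix(v, N, 1))
  }
}

.iext_bound <- function(i_ext) max(abs(i_ext$values))

.weight_matrix <- function(p) {
  rev_pot <- ifelse(p$pop == "E", p$E_plus, p$E_minus)
  sweep(p$G, 2L, rev_pot, "*")
}

#' External current at given times
#'
#' Evaluates the (piecewise-constant) external current of neuron
#' \code{k} at a vector of times.
#'
#' @param params a [gif_params()] object.
#' @param k neuron index.
#' @param t numeric vector of times.
#' @return numeric vector of current values.
#' @export
i_ext_value <- function(params, k, t) {
  br <- params$i_ext$breaks
  v <- params$i_ext$values[k, ]
  if (length(br) == 1L) return(rep(v, length(t)))
  frac <- t - floor(t)
  idx <- findInterval(frac, br)
  v[idx]
}

# fractional breakpoints of i_ext inside each unit interval (excluding 0)
.iext_subbreaks <- function(params) {
  br <- params$i_ext$breaks
  br[br > 0]
}

#' Validate a gIF parameter set
#'
#' Checks the positivity and structural constraints of the model:
#' strictly positive capacitances, leak conductances, synaptic decay
#' times and noise amplitudes, a nonnegative synaptic amplitude matrix,
#' population labels in \{E, I\}, a finite threshold, and a spike
#' separation of at least one time step.
#'
#' @param params a [gif_params()] object.
#' @return A character vector of violations, each naming the offending
#'   field; empty when the parameter set is admissible.
#' @export
validate_params <- function(params) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  p <- params
  if (!inherits(p, "gif_params")) return("params: not a gif_params object")
  if (any(!is.finite(p$C)) || any(p$C <= 0))
    add("C: capacitances must be strictly positive and finite")
  if (any(!is.finite(p$g_L)) || any(p$g_L <= 0))
    add("g_L: leak conductances must be strictly positive and finite")
  if (!is.finite(p$theta)) add("theta: threshold must be finite")
  if (!all(is.finite(c(p$E_L, p$E_plus, p$E_minus))))
    add("E_L/E_plus/E_minus: reversal potentials must be finite")
  if (any(!is.finite(p$G)) || any(p$G < 0))
    add("G: synaptic amplitudes must be nonnegative and finite")
  if (any(!is.finite(p$tau_syn)) || any(p$tau_syn <= 0))
    add("tau_syn: synaptic decay times must be strictly positive")
  if (!all(p$pop %in% c("E", "I")))
    add("pop: population labels must be 'E' or 'I'")
  if (p$profile_degree < 0)
    add("profile_degree: kernel degree must be >= 0")
  if (!is.finite(p$sigma_B) || p$sigma_B <= 0)
    add("sigma_B: current noise amplitude must be strictly positive")
  if (!is.finite(p$sigma_R) || p$sigma_R <= 0)
    add("sigma_R: reset standard deviation must be strictly positive")
  if (any(!is.finite(p$i_ext$values)))
    add("i_ext: external current must be finite (bounded)")
  if (!is.finite(p$tau_sep) || p$tau_sep < 1)
    add("tau_sep: spike separation must be >= 1")
  v
}

.assert_valid <- function(params) {
  v <- validate_params(params)
  if (length(v))
    stop("invalid parameter set:\n  ", paste(v, collapse = "\n  "))
  invisible(params)
}

#' Closed-form bounds derived from a parameter set
#'
#' Computes the uniform bounds that control every history-dependent
#' quantity of the network, whatever the raster:
#' \itemize{
#'   \item \code{alpha_plus}: series bound on the spike-history kernel
#'     sum, \code{max_{kj} sum_{n >= 1} sup(alpha_kj)} over unit
#'     intervals (for the exponential kernel with common decay time
#'     \code{tau} this is \code{exp(-1/tau) / (1 - exp(-1/tau))});
#'   \item \code{alpha_sup}: the same series including the \code{n = 0}
#'     term, i.e. a bound on the kernel sum valid at every real time,
#'     including times inside the first unit interval after a spike;
#'   \item \code{g_M}: maximal conductance \code{g_L + alpha_sup *
#'     rowSums(G)} and the relaxation-time window \code{tau_M <= tau_L};
#'   \item \code{V_minus < V_plus}: envelope of the deterministic part
#'     of the membrane potential;
#'   \item \code{sigma_minus <= sigma_plus}: envelope of the conditional
#'     standard deviation;
#'   \item \code{pi_minus < pi_plus} and \code{Pi_minus < Pi_plus}:
#'     per-neuron bounds on the one-step firing probability and on any
#'     one-step spiking-state probability, all strictly inside (0, 1),
#'     together with their products over neurons
#'     (\code{Pi_prod_minus}, \code{Pi_prod_plus}).
#' }
#'
#' \code{alpha_plus} follows the printed series construction (sum from
#' \code{n = 1}), which equals the kernel sum over the all-ones raster
#' sampled at integer times.  At non-integer times the most recent spike
#' can contribute an extra term of up to \code{sup alpha}, so the
#' conductance and potential envelopes are built from \code{alpha_sup}
#' to make them valid at every real time.
#'
#' @param params a valid [gif_params()] object.
#' @return A list of class \code{"gif_bounds"}.
#' @export
derive_bounds <- function(params) {
  .assert_valid(params)
  p <- params
  d <- p$profile_degree
  a1 <- matrix(0, p$N, p$N)  # sum from n = 1
  a0 <- matrix(0, p$N, p$N)  # sum from n = 0
  for (k in seq_len(p$N)) for (j in seq_len(p$N)) {
    s <- .alpha_envelope_series(d, p$tau_syn[k, j])
    a1[k, j] <- s["from1"]
    a0[k, j] <- s["from0"]
  }
  alpha_plus <- max(a1)
  alpha_sup <- max(a0)
  g_M <- p$g_L + alpha_sup * rowSums(p$G)
  tau_L <- p$C / p$g_L
  tau_M <- p$C / g_M
  Wp <- pmax(p$W, 0)
  Wn <- pmin(p$W, 0)
  ext_b <- abs(p$E_L) + p$i_plus / p$g_L
  V_minus <- alpha_sup / p$g_L * rowSums(Wn) - ext_b
  V_plus <- alpha_sup / p$g_L * rowSums(Wp) + ext_b
  sigma_minus <- pmin(p$sigma_B / p$C * sqrt(tau_M / 2), p$sigma_R)
  sigma_plus <- pmax(p$sigma_B / p$C * sqrt(tau_L / 2), p$sigma_R)
  # extremes of X = (theta - Vdet)/sigma over the V and sigma windows
  num_lo <- p$theta - V_plus
  num_hi <- p$theta - V_minus
  X_hi <- pmax(num_hi / sigma_minus, num_hi / sigma_plus)
  X_lo <- pmin(num_lo / sigma_minus, num_lo / sigma_plus)
  pi_minus <- firing_prob(X_hi)
  pi_plus <- firing_prob(X_lo)
  # mathematically 0 < Pi_minus < Pi_plus < 1 always; for very loose
  # envelopes the plain values can round to 0 or 1 in double precision,
  # so log-scale companions carry the strict positivity of Pi_minus and
  # of 1 - Pi_plus at any parameter scale.
  log_pi_minus <- stats::pnorm(X_hi, lower.tail = FALSE, log.p = TRUE)
  log_1m_pi_plus <- stats::pnorm(X_lo, log.p = TRUE)
  Pi_minus <- pmin(pi_minus, 1 - pi_plus)
  Pi_plus <- pmax(pi_plus, 1 - pi_minus)
  log_Pi_minus <- pmin(log_pi_minus, log_1m_pi_plus)
  log_1m_Pi_plus <- pmin(log_1m_pi_plus, log_pi_minus)
  structure(
    list(alpha_plus = alpha_plus, alpha_sup = alpha_sup,
         g_M = g_M, tau_L = tau_L, tau_M = tau_M,
         V_minus = V_minus, V_plus = V_plus,
         sigma_minus = sigma_minus, sigma_plus = sigma_plus,
         X_lower = X_lo, X_upper = X_hi,
         pi_minus = pi_minus, pi_plus = pi_plus,
         Pi_minus = Pi_minus, Pi_plus = Pi_plus,
         log_Pi_minus = log_Pi_minus, log_1m_Pi_plus = log_1m_Pi_plus,
         Pi_prod_minus = prod(Pi_minus), Pi_prod_plus = prod(Pi_plus),
         log_Pi_prod_minus = sum(log_Pi_minus)),
    class = "gif_bounds")
}

# per-unit-interval suprema of the alpha kernel, summed.  Returns the
# series from n = 1 and from n = 0; terms are max over the interval
# endpoints and the kernel peak t = d * tau when it falls inside.
.alpha_envelope_series <- function(d, tau) {
  sup_on <- function(n) {
    cand <- c(n, n + 1)
    peak <- d * tau
    if (peak > n && peak < n + 1) cand <- c(cand, peak)
    max(alpha_value(d, tau, cand))
  }
  total <- sup_on(0)
  from1 <- 0
  n <- 1
  repeat {
    term <- sup_on(n)
    from1 <- from1 + term
    if (n > d * tau && tail_bound(d, tau, n) < 1e-15) break
    n <- n + 1
    if (n > 1e6) break
  }
  c(from1 = from1, from0 = total + from1)
}

#' @export
print.gif_params <- function(x, ...) {
  cat(sprintf("gIF network parameters: N = %d neurons (%d E, %d I)\n",
              x$N, sum(x$pop == "E"), sum(x$pop == "I")))
  cat(sprintf("  theta = %g, E_L = %g, E+ = %g, E- = %g\n",
              x$theta, x$E_L, x$E_plus, x$E_minus))
  cat(sprintf("  C in [%g, %g], g_L in [%g, %g], tau_L in [%g, %g]\n",
              min(x$C), max(x$C), min(x$g_L), max(x$g_L),
              min(x$C / x$g_L), max(x$C / x$g_L)))
  cat(sprintf("  synapses: %d nonzero of %d, kernel degree d = %d, tau in [%g, %g]\n",
              sum(x$G > 0), x$N^2, x$profile_degree,
              min(x$tau_syn), max(x$tau_syn)))
  cat(sprintf("  sigma_B = %g, sigma_R = %g, |i_ext| <= %g, tau_sep = %g\n",
              x$sigma_B, x$sigma_R, x$i_plus, x$tau_sep))
  invisible(x)
}

#' @export
print.gif_bounds <- function(x, ...) {
  cat("Derived uniform bounds:\n")
  cat(sprintf("  alpha_plus = %.6g (alpha_sup = %.6g)\n",
              x$alpha_plus, x$alpha_sup))
  cat(sprintf("  g_M:    %s\n", paste(signif(x$g_M, 4), collapse = " ")))
  cat(sprintf("  V-:     %s\n", paste(signif(x$V_minus, 4), collapse = " ")))
  cat(sprintf("  V+:     %s\n", paste(signif(x$V_plus, 4), collapse = " ")))
  cat(sprintf("  sigma-: %s\n", paste(signif(x$sigma_minus, 4), collapse = " ")))
  cat(sprintf("  sigma+: %s\n", paste(signif(x$sigma_plus, 4), collapse = " ")))
  cat(sprintf("  Pi-:    %s\n", paste(signif(x$Pi_minus, 4), collapse = " ")))
  cat(sprintf("  Pi+:    %s\n", paste(signif(x$Pi_plus, 4), collapse = " ")))
  invisible(x)
}

#' Read a parameter file (YAML or JSON)
#'
#' The file mirrors the [gif_params()] argument names; scalars broadcast
#' (a single \code{C} applies to all neurons) and \code{G},
#' \code{tau_syn} may be given as lists of rows.
#'
#' @param path file path; format chosen by extension (\code{.json} vs
#'   \code{.yaml}/\code{.yml}).
#' @return a validated [gif_params()] object.
#' @export
read_gif_params <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  # a bare YAML key `N` parses as boolean FALSE under YAML 1.1 rules
  names(x)[names(x) == "FALSE"] <- "N"
  if (is.null(x$N)) stop("parameter file must supply N")
  for (f in c("G", "tau_syn")) {
    if (!is.null(x[[f]]) && is.list(x[[f]]))
      x[[f]] <- do.call(rbind, lapply(x[[f]], function(row)
        as.numeric(unlist(row))))
  }
  for (f in c("C", "g_L", "theta"))
    if (is.list(x[[f]])) x[[f]] <- as.numeric(unlist(x[[f]]))
  if (is.list(x$i_ext) && is.null(x$i_ext$breaks))
    x$i_ext <- as.numeric(unlist(x$i_ext))
  allowed <- names(formals(gif_params))
  unknown <- setdiff(names(x), allowed)
  if (length(unknown))
    warning("ignoring unknown parameter fields: ",
            paste(unknown, collapse = ", "))
  p <- do.call(gif_params, x[intersect(names(x), allowed)])
  .assert_valid(p)
  p
}

#' Random parameter set in a bounded physiological box
#'
#' Draws a valid parameter set with all constants in fixed, bounded
#' ranges around the package's example scales: unit capacitance order,
#' leak times of a few time steps, synaptic decay times of a few time
#' steps, conductance amplitudes giving postsynaptic potentials of a few
#' voltage units, and noise levels placing typical one-step firing
#' probabilities well inside (0, 1).  Used throughout the test and
#' validation suites as the randomized sampler of admissible models.
#'
#' @param N number of neurons.
#' @param seed integer seed.
#' @param profile_degree alpha-kernel degree.
#' @param p_connect probability of a synapse between an ordered pair.
#' @param frac_inhib fraction of inhibitory neurons (at least one
#'   excitatory neuron is kept when \code{N > 1}).
#' @return a validated [gif_params()] object.
#' @export
random_gif_params <- function(N, seed = 1, profile_degree = 0,
                              p_connect = 0.7, frac_inhib = 0.25) {
  .with_seed(seed, {
    n_i <- min(N - (N > 1), round(frac_inhib * N))
    pop <- rep("E", N)
    if (n_i > 0) pop[sample.int(N, n_i)] <- "I"
    G <- matrix(stats::runif(N * N, 0.02, 0.15), N, N) *
      matrix(stats::rbinom(N * N, 1, p_connect), N, N)
    gif_params(
      N = N,
      C = stats::runif(N, 0.8, 1.2),
      theta = stats::runif(1, 5, 8),
      E_L = stats::runif(1, -2, 0),
      E_plus = 65, E_minus = -5,
      g_L = stats::runif(N, 0.4, 0.8),
      G = G, pop = pop,
      tau_syn = matrix(stats::runif(N * N, 1.5, 3), N, N),
      profile_degree = profile_degree,
      sigma_B = stats::runif(1, 1, 2.5),
      sigma_R = stats::runif(1, 0.6, 1.4),
      i_ext = stats::runif(N, 2, 4))
  })
}

# evaluate expr under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
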