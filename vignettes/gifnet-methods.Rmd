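---
title: "Spike-train statistics of conductance-based integrate-and-fire networks"
author: "gifnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-train statistics of conductance-based integrate-and-fire networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gifnet)
```

## The model

`gifnet` implements a stochastic network of \(N\) point neurons whose
membrane potentials follow a conductance-based integrate-and-fire law.
Below threshold, neuron \(k\) obeys

\[ C_k \frac{dV_k}{dt} + g_k(t,\omega)\, V_k = i_k(t,\omega) +
\sigma_B \xi_k(t), \]

where the conductance \(g_k\) and the current \(i_k\) depend on the
discrete spike history \(\omega\) of the whole network: every
presynaptic spike of neuron \(j\) at integer time \(s\) adds a causal
kernel \(G_{kj}\,\alpha_{kj}(t-s)\) to the conductance, with
\(\alpha(t) = (t/\tau)^d e^{-t/\tau}\) (degree \(d = 0\): exponential;
\(d = 1\): the classical alpha function).  The current combines the
leak drive \(g_{L,k} E_L\), the synaptic drive \(W_{kj}\alpha_{kj}\)
with weights \(W_{kj} = E_\pm G_{kj}\) signed by the presynaptic
population, a bounded external stimulus, and additive white noise.
Spikes are discrete events: a spike registered at integer time \(n\)
resets the potential at \(n\) to a Gaussian value of mean 0 (the rest
potential) and standard deviation \(\sigma_R > 0\).

Two structural facts drive everything in the package:

1. **Conditional Gaussianity.** Given the spike history up to
   \(\lfloor t\rfloor\), the potentials at \(t\) are independent
   Gaussians.  Writing \(\tau_k\) for the last reset time and
   \(\Gamma_k(t_1,t_2,\omega) = \exp(-\frac1{C_k}\int_{t_1}^{t_2}
   g_k)\) for the effective leak, the conditional mean is the
   deterministic potential \(V^{det}_k = V^{syn}_k + V^{ext}_k\)
   (leak-weighted integrals of the synaptic and external drives from
   \(\tau_k\)), and the conditional variance is
   \(\Gamma_k^2 \sigma_R^2 + (\sigma_B/C_k)^2 \int \Gamma_k^2\).
2. **An explicit conditional spike law.** The probability that neuron
   \(k\) fires at time \(n\) is the Gaussian tail probability
   \(\pi(X_k)\) of the normalized threshold distance
   \(X_k = (\theta - V^{det}_k)/\sigma_k\) at \(n-1\); neurons fire
   conditionally independently.  The log of the pattern probability is
   the one-step potential \(\phi(n,\omega)\); summed over a block it
   gives exact block probabilities with partition function 1.

Because the conductance integrates the entire spike past, the process
has unbounded memory (it is not Markovian at any finite order).  The
package quantifies that memory: the *m-variation* of a quantity is its
maximal change over pasts agreeing on the last \(m+1\) steps, and every
model quantity has a proved exponential envelope for it, with rate
\(1/\max(\tau_{kj}, \tau_{L,k})\).  Uniform bounds on conductance,
potential, variance and firing probabilities make the one-step law
non-degenerate, which (with summable variation) is the criterion for a
unique consistent spike-train law; `uniqueness_criteria()` evaluates
both quantities numerically.

## Parameters, units, defaults

Time is measured in units of the spike duration, i.e. one raster step
(about a millisecond physiologically).  Voltages are measured relative
to the rest potential, which is also the mean reset value, so the
threshold \(\theta\) is positive (the example file uses 8, i.e. a
threshold ~8 mV above rest).  Conductances, capacitances and currents
only need mutually consistent units; the example file uses \(C = 1\),
\(g_L = 0.5\) (leak time \(\tau_L = 2\) steps), synaptic decay
\(\tau = 2\) steps, reversal potentials \(E_+ = 65\), \(E_- = -5\),
\(E_L = 0\) in the rest-referenced convention, and noise amplitudes
\(\sigma_B = 1.5\), \(\sigma_R = 1\).  These were chosen once so that
typical one-step firing probabilities sit well inside \((0,1)\)
(rates of order 0.1–0.5 per step): the statistics of interest are all
conditional probabilities, and a silent or saturated network exercises
none of them.

`random_gif_params()` draws admissible parameter sets from a fixed
bounded box around those scales (capacitance 0.8–1.2, leak conductance
0.4–0.8, thresholds 5–8, synaptic decay times 1.5–3, amplitudes up to
0.15 with 70% connectivity, external currents 2–4).  The box is the
package's randomized model sampler for property checks; boundedness
and positivity are the only constraints the theory needs, so the box
is a convenience, not a restriction, and validation does not enforce
it.

The external current is piecewise constant on a declared sub-grid of
each unit interval (default: constant per neuron).  Only its bound
\(i_+\) enters the analytic envelopes; piecewise constancy keeps every
quadrature integrand smooth within pieces.

## Numerical design

**Quadrature.** All integrals run over pieces that never straddle an
integer time or a current breakpoint — the only places where
integrands kink — with composite Gauss–Legendre of order 8 per piece
(order is a parameter; doubling it is the built-in convergence check).
The nested leak-weighted integrals use a cumulative-conductance table:
conductance values at the nodes are mapped to the running integral
\(A(x)=\int g\) through a precomputed Lagrange partial-integration
matrix, so \(\Gamma(t_1,t) = \exp(-(A(t)-A(t_1))/C)\) is available at
every node from a single pass.

**Infinite pasts.** Finite raster windows carry a `past_padding`
convention (all-silent or all-saturated) standing in for the infinite
past.  Backward integrals truncate at a horizon where the exponential
leak envelope bounds the dropped mass below a tolerance (default
1e-10); the accumulated bound is reported as
`truncation_error_bound`.  Kernel sums over the padded past truncate
where the closed-form kernel tail \(\tau\,\Gamma(d{+}1)\,Q(d{+}1,
m/\tau)\) (upper incomplete gamma; \(\tau e^{-m/\tau}\) at \(d=0\),
\((m+\tau)e^{-m/\tau}\) at \(d=1\)) drops below tolerance — the same
expression for every degree, so no separate numerical integration is
needed.

**The kernel-sum constant.** The classical series bound on the summed
kernel, `alpha_plus` \(= \max_{kj}\sum_{n\ge 1}\sup_{[n,n+1)}
\alpha\), equals the all-ones-raster kernel sum *at integer times*.
At non-integer times the most recent spike can contribute up to
\(\sup\alpha\) more, so the package also derives `alpha_sup` (the same
series from \(n = 0\)) and builds the maximal conductance \(g_M\) and
all downstream envelopes (\(V^\pm\), \(\sigma^\pm\), \(\Pi^\pm\),
variation constants) from it.  That makes every sandwich valid at
every real time, at the price of slightly wider envelopes; both
constants are reported.

**Probability bounds in floating point.** The uniform firing-probability
bounds \(\Pi^\pm\) are strict in exact arithmetic but can be
astronomically close to 0 or 1 (they assume every neuron firing always,
or never).  `derive_bounds()` therefore carries log-scale companions
(`log_Pi_minus`, `log_1m_Pi_plus`) computed in the accurate Gaussian
tail, which certify strict positivity at any parameter scale; the
plain values may round to the boundary in double precision.

**Degenerate inputs.** A neuron reset at the query time has a
zero-length window: the decomposition short-circuits to
\(\Gamma = 1\), \(V^{det} = 0\), \(\sigma^2 = \sigma_R^2\), keeping
\(X_k\) finite (\(\sigma\) is bounded below, so no conditional
probability ever reaches 0 or 1 and no special-casing is needed).

## Conventions that were genuinely open

**Reset timing.** A spike recorded at integer \(n\) is treated as a
reset *at* \(n\) (the last reset time is the spike integer itself).
With unit spike separation and spikes aligned on the integer grid this
coincides with the "next integer after the crossing" rule, and it
keeps the one-step law well defined when a neuron fired at the
previous step.  Since the reset value is random, the choice does not
affect the statistics.

**Spike registration in the SDE integrator.** The exact conditional
law is derived from the event \(V_k(n-1)\ge\theta\); the
continuous-time convention registers a spike when the potential
touches threshold anywhere in \((n-1,n]\).  `simulate_sde()` supports
both (`rule = "endpoint"` and `rule = "crossing"`) rather than hiding
the difference; the cross-validation tests use the endpoint rule,
which is the one the discrete pipeline realizes, and the free-running
comparison quantifies that both produce compatible rates in a
monostable regime.  Euler–Maruyama is used because the noise is
additive (constant diffusion), where it is strong order 1; the spike
shape inside a step is never modelled — a registered neuron is frozen
until its reset, since only threshold events enter the statistics.

**Truncated potentials and their coefficients.** The finite-memory
potential \(\phi^{(D)}\) replaces the infinite past with a named
boundary condition (default: the silent past).  Its monomial
coefficients are obtained by exact Möbius inversion over all
\(2^{N(D+1)}\) blocks — the coefficients are boundary-dependent, so
the expansion names its boundary.  Exhaustive operations are guarded
at \(N(D+1)\le 22\) bits and rejected, not approximated, beyond that.
Because the one-step potential is affine in each time-0 indicator,
every coefficient with two or more time-0 factors vanishes; at
\(D = 0\) the law collapses to independent Bernoullis — an
instantaneous pairwise (Ising-type) coupling term can only appear
after temporal binning, never at the native time resolution.

**Variation probes are lower bounds.** The m-variation is a supremum
over uncountably many pasts.  `empirical_variation()` probes it from
below with an adversarial pair — the all-silent versus all-saturated
past (the extreme conductance states), sharing a nested common recent
window — plus random pairs.  Comparisons against the analytic
envelopes are therefore valid one-sided tests, reported from a lag
`m0` onward because the envelopes are asymptotic.  The envelope
constants follow the printed closed forms with `alpha_sup` in place of
the integer-time constant.  The summed-variation estimate in
`uniqueness_criteria()` is labelled an estimate: empirical partial sum
plus the analytic geometric tail.

## What the tests do and do not show

The validation suite checks, at desk scale: exact normalization of the
one-step law (\(N = 3\), 100 random histories, 1e-12); partition
function 1 of the summed potential over exhaustively enumerated
three-step blocks (\(N = 2\), 1e-10); the identity \(\Gamma(t,t)=1\);
vanishing kernel sums on the silent raster; all conductance, leak,
potential, variance and probability sandwiches on 1000 randomized
(parameters, raster, time) triples; zero-coupling agreement with
leaky-integrate-and-fire closed forms to 1e-6 relative; agreement of
Euler–Maruyama moments and firing frequencies with the conditional
Gaussian law within three standard errors (\(dt = 10^{-3}\), \(10^4\)
paths); silent-window frequencies inside the geometric bounds over
\(10^4\) exactly sampled five-step continuations; variation decay at
the dominant time constant within 15%, below the envelopes; and the
vanishing of instantaneous multi-spike coefficients (1e-10).  The
heavier Monte-Carlo sizes were chosen to finish in a few minutes on a
single core while leaving the statistical checks well resolved.

Rasters here are generated by the model itself (or i.i.d. fixtures);
nothing in the suite involves recorded neural data, spike sorting, or
model misspecification.  Passing tests show the implementation
realizes this model's law and bounds — not that the model fits any
particular biological preparation.

## Known limitations

* Kernel degrees are supported for any \(d \ge 0\), but the analytic
  discussion and defaults target \(d \in \{0, 1\}\), the forms used in
  practice.
* Refractory periods longer than one step (which forbid spike
  sequences and turn the state space into a constrained grammar) are
  not implemented; `tau_sep` is validated but the sampler assumes
  consecutive firing is allowed.
* The exact sampler and the statistics pipeline are \(O(N^2)\) per
  step through the kernel sums; the package targets the small networks
  (a handful of neurons) where the exhaustive and enumeration-based
  validations are feasible, not large-scale simulation.
* Synaptic amplitudes are constant: no plasticity, and no fitting of
  parameters or of expansion coefficients from recorded rasters.
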