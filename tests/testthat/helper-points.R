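# Shared reference parameter points.
#
# plus_point():   the marked point of the heterogeneity regime diagram
#                 (eta = 1.59, V_syn = -56.5); Delta chooses the side.
# square_point(): the marked point of the noise regime diagram.
# deep_stationary(): strongly damped equilibrium (max Re lambda ~ -0.07),
#                 used for finite-size and scheme-comparison runs.

plus_point <- function(Delta = 0.04, ...) {
  mt_params(eta = 1.59, V_syn = -56.5, P_syn = 0.1, sigma = 0.1,
            Delta = Delta, ...)
}

square_point <- function(sigma = 0.1, ...) {
  mt_params(eta = 1.6, V_syn = -57.3, P_syn = 0.1, Delta = 0.04,
            sigma = sigma, ...)
}

deep_stationary <- function(...) {
  mt_params(eta = 0.3, V_syn = -56.5, P_syn = 0.1, Delta = 0.04,
            sigma = 0.1, ...)
}

# robust micro-trace threshold: finite-size stochastic resonance keeps
# stationary-side excursion ratios below ~0.5 at N >= 1000, limit cycles
# exceed ~2
MICRO_THRESHOLD <- 1.0

# scaled-down population with the total coupling g_peak*P_syn*N held at
# its reference (N = 3000) value, so the macroscopic limit is unchanged
scaled_N <- function(p, N) {
  p$g_peak <- p$g_peak * p$N / N
  p$N <- as.integer(N)
  p
}

# exact moments of a distribution with exactly two circular cumulants
two_cumulant_modes <- function(Z, kappa, J) {
  vapply(seq_len(J), function(j) moments_from_cumulants(Z, kappa, j, exact = TRUE),
         complex(1))
}
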