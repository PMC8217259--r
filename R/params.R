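#' Model parameters for the inhibitory theta-neuron network
#'
#' Bundles every physical constant of the modified theta (MT) network:
#' single-neuron membrane constants, GABAergic synapse constants, and the
#' drive distribution (Cauchy--Lorentz heterogeneity plus white noise).
#'
#' Units are fixed package-wide: time in ms, voltage in mV, conductance
#' density in mS/cm^2, capacitance in uF/cm^2, current in uA/cm^2. Firing
#' rates therefore come out in kHz (multiply by 1000 for Hz).
#'
#' @param C membrane capacitance (uF/cm^2).
#' @param g_L leak conductance (mS/cm^2).
#' @param V_T firing threshold (mV); must exceed `V_R`.
#' @param V_R resting potential (mV).
#' @param V_syn synaptic reversal potential (mV). Controls whether the
#'   GABAergic synapse depolarizes or hyperpolarizes the target.
#' @param tau_d synaptic decay time constant (ms).
#' @param g_peak peak conductance density of a single synaptic event
#'   (mS/cm^2); see [peak_conductance_density()].
#' @param P_syn connection probability between neuron pairs, in \[0, 1\].
#' @param N population size (also enters the mean-field drive of the
#'   conductance equation).
#' @param eta center of the Cauchy--Lorentz input-current distribution
#'   (uA/cm^2).
#' @param Delta half-width of the input-current distribution (uA/cm^2);
#'   the heterogeneity scale.
#' @param sigma noise magnitude (uA/cm^2 ms^{1/2}).
#'
#' @return An object of class `mt_params` (a named list).
#' @examples
#' p <- mt_params()              # reference operating point
#' mt_params(Delta = 0.05)      # more heterogeneous population
#' @export
mt_params <- function(C = 1, g_L = 0.1, V_T = -55, V_R = -62,
                      V_syn = -56.5, tau_d = 5, g_peak = 0.0214,
                      P_syn = 0.1, N = 3000,
                      eta = 1.59, Delta = 0.04, sigma = 0.1) {
  p <- list(C = C, g_L = g_L, V_T = V_T, V_R = V_R, V_syn = V_syn,
            tau_d = tau_d, g_peak = g_peak, P_syn = P_syn, N = as.integer(N),
            eta = eta, Delta = Delta, sigma = sigma)
  class(p) <- "mt_params"
  validate_params(p)
  p
}

#' @export
print.mt_params <- function(x, ...) {
  cat("MT network parameters\n")
  cat(sprintf("  neuron : C=%g uF/cm^2, g_L=%g mS/cm^2, V_T=%g mV, V_R=%g mV\n",
              x$C, x$g_L, x$V_T, x$V_R))
  cat(sprintf("  synapse: V_syn=%g mV, tau_d=%g ms, g_peak=%g mS/cm^2, P_syn=%g, N=%d\n",
              x$V_syn, x$tau_d, x$g_peak, x$P_syn, x$N))
  cat(sprintf("  drive  : eta=%g, Delta=%g uA/cm^2, sigma=%g uA/cm^2 ms^0.5\n",
              x$eta, x$Delta, x$sigma))
  invisible(x)
}

#' Validate an `mt_params` object
#'
#' Checks the physical invariants (positive capacitance and time constant,
#' `V_T > V_R`, `Delta > 0`, `sigma >= 0`, `P_syn` a probability, `N >= 1`)
#' and stops with an informative message naming the offending field.
#'
#' @param p an [mt_params()] object (or plain named list with those fields).
#' @return `p`, invisibly, if valid.
#' @export
validate_params <- function(p) {
  stopifnot(is.list(p))
  num1 <- function(field) {
    v <- p[[field]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("parameter '%s' must be a single finite number", field))
    v
  }
  for (f in c("C", "g_L", "V_T", "V_R", "V_syn", "tau_d", "g_peak",
              "P_syn", "N", "eta", "Delta", "sigma")) num1(f)
  if (p$C <= 0) stop("C must be > 0")
  if (p$g_L < 0) stop("g_L must be >= 0")
  if (p$V_T <= p$V_R) stop("V_T must be > V_R (got V_T <= V_R)")
  if (p$tau_d <= 0) stop("tau_d must be > 0")
  if (p$g_peak < 0) stop("g_peak must be >= 0")
  if (p$P_syn < 0 || p$P_syn > 1) stop("P_syn must lie in [0, 1]")
  if (p$N < 1) stop("N must be >= 1")
  if (p$Delta <= 0) stop("Delta must be > 0")
  if (p$sigma < 0) stop("sigma must be >= 0")
  invisible(p)
}

#' Derived coefficients of the phase equations
#'
#' The three real constants that appear throughout the phase dynamics and
#' its mean-field reduction:
#' \deqn{c_1 = 2/(V_T - V_R), \quad
#'       c_2 = (2 V_{syn} - V_T - V_R)/(V_T - V_R), \quad
#'       c_3 = c_1^2 / (4 C^2).}
#' `c2` is an affine, strictly increasing function of `V_syn` with
#' `c2(V_R) = -1` and `c2(V_T) = +1`: it encodes where the synaptic
#' reversal potential sits relative to the subthreshold voltage range.
#'
#' @param p an [mt_params()] object.
#' @return A list with numeric scalars `c1`, `c2`, `c3`.
#' @export
derived_coefficients <- function(p) {
  validate_params(p)
  dv <- p$V_T - p$V_R
  list(c1 = 2 / dv,
       c2 = (2 * p$V_syn - p$V_T - p$V_R) / dv,
       c3 = (2 / dv)^2 / (4 * p$C^2))
}

#' Complex drive fields of the macroscopic equations
#'
#' Evaluates the complex coefficients of the first-harmonic decomposition
#' of the phase drift, continued to the pole of the Cauchy--Lorentz drive
#' distribution, `I = eta + i Delta`:
#' \deqn{f   = \frac{1}{2C}[-g_L + c_1(\eta + i\Delta) + c_2 g_{syn} + i g_{syn}]}
#' \deqn{h   = \frac{1}{C}[c_1(\eta + i\Delta) + c_2 g_{syn}]}
#' \deqn{f^* = f - i g_{syn} / C.}
#' Note that `f_star` is *not* the complex conjugate of `f` when
#' `Delta > 0`: only the `i g_syn` term flips sign. The conjugate-looking
#' notation is exact on real currents and the analytic continuation keeps
#' `+ i Delta` in both fields.
#'
#' @param p an [mt_params()] object.
#' @param g_syn instantaneous synaptic conductance (mS/cm^2), `>= 0`.
#' @return A list with complex scalars `f`, `h`, `f_star`.
#' @export
drive_fields <- function(p, g_syn) {
  stopifnot(is.numeric(g_syn), length(g_syn) == 1L, g_syn >= 0)
  co <- derived_coefficients(p)
  Ieff <- complex(real = p$eta, imaginary = p$Delta)
  f <- (-p$g_L + co$c1 * Ieff + co$c2 * g_syn + 1i * g_syn) / (2 * p$C)
  h <- (co$c1 * Ieff + co$c2 * g_syn) / p$C
  list(f = f, h = h, f_star = f - 1i * g_syn / p$C)
}

#' Phase/voltage transform of the modified theta neuron
#'
#' The MT phase is related to the quadratic integrate-and-fire membrane
#' potential by
#' \deqn{V = \frac{V_T + V_R}{2} + \frac{V_T - V_R}{2}\tan(\theta/2),}
#' which maps `theta = 0` to the midpoint of the subthreshold range and
#' diverges at `|theta| = pi` (the firing point, where V jumps from
#' +Inf to -Inf). `voltage_to_theta` is the inverse map.
#'
#' @param theta phase(s) in `(-pi, pi)`.
#' @param V membrane potential(s) (mV).
#' @param p an [mt_params()] object.
#' @return `theta_to_voltage`: potential(s) in mV; `voltage_to_theta`:
#'   phase(s) in `(-pi, pi)`.
#' @export
theta_to_voltage <- function(theta, p) {
  validate_params(p)
  if (any(abs(theta) >= pi))
    stop("|theta| >= pi: membrane potential diverges at the firing point")
  (p$V_T + p$V_R) / 2 + (p$V_T - p$V_R) / 2 * tan(theta / 2)
}

#' @rdname theta_to_voltage
#' @export
voltage_to_theta <- function(V, p) {
  validate_params(p)
  2 * atan((2 * V - p$V_T - p$V_R) / (p$V_T - p$V_R))
}

#' Peak synaptic conductance density from absolute conductance
#'
#' Converts an absolute peak conductance (nS, as measured for a unitary
#' GABAergic synapse) into a conductance density (mS/cm^2) by dividing by
#' the membrane surface area. With 6.2 nS and 2.9e-4 cm^2 this gives the
#' default `g_peak = 0.0214 mS/cm^2`.
#'
#' @param g_abs_nS absolute peak conductance in nS, `> 0`.
#' @param area_cm2 membrane surface area in cm^2, `> 0`.
#' @return conductance density in mS/cm^2.
#' @examples
#' peak_conductance_density(6.2, 2.9e-4)  # ~0.0214
#' @export
peak_conductance_density <- function(g_abs_nS, area_cm2) {
  if (!is.numeric(g_abs_nS) || any(g_abs_nS <= 0))
    stop("g_abs_nS must be > 0")
  if (!is.numeric(area_cm2) || any(area_cm2 <= 0))
    stop("area_cm2 must be > 0")
  g_abs_nS * 1e-6 / area_cm2   # nS -> mS, then per cm^2
}

#' Saddle-node drive current of an uncoupled neuron
#'
#' The input current at which an isolated, noise-free neuron sits exactly
#' at the saddle-node (onset of firing): `g_L (V_T - V_R) / 4`. Below it
#' the neuron is quiescent; above it, periodically firing.
#'
#' @param p an [mt_params()] object.
#' @return threshold current (uA/cm^2).
#' @export
saddle_node_current <- function(p) {
  validate_params(p)
  p$g_L * (p$V_T - p$V_R) / 4
}
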