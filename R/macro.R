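#' Right-hand side of the two-cumulant macroscopic model
#'
#' Time derivatives of the first two circular cumulants and the shared
#' conductance:
#' \deqn{\dot Z = i f (Z^2 + \kappa) + i h Z + i f^* -
#'       c_3 \sigma^2 [(Z+1)^3 + 3\kappa(Z+1)]}
#' \deqn{\dot\kappa = 4 i f Z \kappa + 2 i h \kappa -
#'       c_3 \sigma^2 [(Z+1)^4 + 12\kappa(Z+1)^2 + 9\kappa^2]}
#' \deqn{\dot g = -g/\tau_d + \bar g_{peak} P_{syn} N A(Z, \kappa).}
#' With `sigma = 0` and `kappa = 0` the `Z` equation reduces exactly to
#' the Ott--Antonsen dimension reduction, and the Ott--Antonsen manifold
#' `kappa = 0` is invariant.
#'
#' @param Z complex first circular cumulant (Kuramoto order parameter).
#' @param kappa complex second circular cumulant.
#' @param g_syn conductance (mS/cm^2).
#' @param p an [mt_params()] object.
#' @param clip_rate clip a negative rate to zero in the conductance
#'   drive (the `kappa` correction can transiently push `A` below 0).
#' @return list with `dZ`, `dkappa` (complex), `dg_syn`, and the rate `A`
#'   (kHz) used in the drive.
#' @export
macro_rhs <- function(Z, kappa, g_syn, p, clip_rate = TRUE) {
  fl <- drive_fields(p, max(g_syn, 0))
  co <- derived_coefficients(p)
  s2 <- co$c3 * p$sigma^2
  dZ <- 1i * fl$f * (Z^2 + kappa) + 1i * fl$h * Z + 1i * fl$f_star -
    s2 * ((Z + 1)^3 + 3 * kappa * (Z + 1))
  dk <- 4i * fl$f * Z * kappa + 2i * fl$h * kappa -
    s2 * ((Z + 1)^4 + 12 * kappa * (Z + 1)^2 + 9 * kappa^2)
  A <- firing_rate(Z, kappa, p, clip = clip_rate)
  list(dZ = dZ, dkappa = dk,
       dg_syn = -g_syn / p$tau_d + p$g_peak * p$P_syn * p$N * A,
       A = A)
}

#' Population firing rate from the circular cumulants
#'
#' \deqn{A = \frac{g_L}{C\pi}\left[\frac{1 - |Z|^2}{2|1+Z|^2} +
#'   \mathrm{Re}\frac{\kappa}{(1+Z)^3}\right]} in kHz. The state
#' `Z = -1` (all mass at the firing point) is singular. The second term
#' is a truncation correction and can drive the expression slightly
#' negative; with `clip = TRUE` (default) the value is floored at 0 and
#' flagged via the `"clipped"` attribute.
#'
#' @inheritParams macro_rhs
#' @param clip floor the rate at zero.
#' @return firing rate (kHz), possibly with attribute `clipped = TRUE`.
#' @export
firing_rate <- function(Z, kappa, p, clip = TRUE) {
  if (abs(1 + Z) < 1e-12)
    stop("Z = -1 is a firing-rate singularity")
  A <- (p$g_L / (p$C * pi)) *
    ((1 - Mod(Z)^2) / (2 * Mod(1 + Z)^2) + Re(kappa / (1 + Z)^3))
  if (clip && A < 0) {
    A <- structure(0, clipped = TRUE)
  }
  A
}

state_to_vec <- function(Z, kappa, g_syn) c(Re(Z), Im(Z), Re(kappa), Im(kappa), g_syn)
vec_to_state <- function(y) list(Z = complex(real = y[1], imaginary = y[2]),
                                 kappa = complex(real = y[3], imaginary = y[4]),
                                 g_syn = y[5])

## deSolve-style rhs on the 5-real-dimensional state
macro_rhs_vec <- function(t, y, p) {
  st <- vec_to_state(y)
  d <- macro_rhs(st$Z, st$kappa, st$g_syn, p)
  list(c(Re(d$dZ), Im(d$dZ), Re(d$dkappa), Im(d$dkappa), d$dg_syn),
       A = as.numeric(d$A))
}

#' Integrate the two-cumulant macroscopic model
#'
#' Adaptive integration of the 5-real-dimensional system
#' (Re Z, Im Z, Re kappa, Im kappa, g_syn) with `deSolve::ode`.
#'
#' @param p an [mt_params()] object.
#' @param T duration (ms).
#' @param state0 initial state, either a 5-vector or a list with
#'   `Z`, `kappa`, `g_syn`. Default: fully incoherent rest state.
#' @param dt_out output sampling interval (ms).
#' @param rtol,atol adaptive error tolerances.
#' @param method `deSolve` method (default `"lsoda"`, stiff-capable).
#' @return data.frame of class `mt_macro_traj` with columns `t`, `ReZ`,
#'   `ImZ`, `ReKappa`, `ImKappa`, `g_syn`, `A`.
#' @examples
#' tr <- integrate_macro(mt_params(), T = 200)
#' tail(tr$A, 1)  # kHz
#' @export
integrate_macro <- function(p, T, state0 = c(0, 0, 0, 0, 0), dt_out = 0.5,
                            rtol = 1e-9, atol = 1e-12, method = "lsoda") {
  validate_params(p)
  if (is.list(state0)) state0 <- state_to_vec(state0$Z, state0$kappa, state0$g_syn)
  times <- seq(0, T, by = dt_out)
  sol <- deSolve::ode(y = state0, times = times, func = macro_rhs_vec,
                      parms = p, method = method, rtol = rtol, atol = atol)
  out <- data.frame(t = sol[, 1], ReZ = sol[, 2], ImZ = sol[, 3],
                    ReKappa = sol[, 4], ImKappa = sol[, 5], g_syn = sol[, 6],
                    A = sol[, "A"])
  class(out) <- c("mt_macro_traj", "data.frame")
  out
}

#' Independent one-cumulant (Ott--Antonsen) integrator
#'
#' Reference integrator for the noise-free Ott--Antonsen reduction,
#' coded directly from the OA manifold equations (not via
#' [macro_rhs()]): \eqn{\dot Z = i f Z^2 + i h Z + i f^*} plus the
#' conductance equation with the `kappa = 0` rate. Only valid for
#' `sigma = 0` (errors otherwise): with noise the OA manifold is not
#' invariant.
#'
#' @inheritParams integrate_macro
#' @param state0 3-vector (ReZ, ImZ, g_syn).
#' @return data.frame with columns `t`, `ReZ`, `ImZ`, `g_syn`, `A`.
#' @export
integrate_oa <- function(p, T, state0 = c(0, 0, 0), dt_out = 0.5,
                         rtol = 1e-9, atol = 1e-12, method = "lsoda") {
  validate_params(p)
  if (p$sigma != 0)
    stop("the one-cumulant Ott-Antonsen reduction requires sigma = 0")
  co <- derived_coefficients(p)
  Ieff <- complex(real = p$eta, imaginary = p$Delta)
  rhs <- function(t, y, parms) {
    Z <- complex(real = y[1], imaginary = y[2]); g <- y[3]
    f <- (-p$g_L + co$c1 * Ieff + co$c2 * g + 1i * g) / (2 * p$C)
    fs <- f - 1i * g / p$C
    h <- (co$c1 * Ieff + co$c2 * g) / p$C
    dZ <- 1i * f * Z^2 + 1i * h * Z + 1i * fs
    A <- (p$g_L / (p$C * pi)) * (1 - Mod(Z)^2) / (2 * Mod(1 + Z)^2)
    list(c(Re(dZ), Im(dZ), -g / p$tau_d + p$g_peak * p$P_syn * p$N * A), A = A)
  }
  sol <- deSolve::ode(y = state0, times = seq(0, T, by = dt_out), func = rhs,
                      parms = NULL, method = method, rtol = rtol, atol = atol)
  data.frame(t = sol[, 1], ReZ = sol[, 2], ImZ = sol[, 3], g_syn = sol[, 4],
             A = sol[, "A"])
}

#' Kuramoto--Daido mode-hierarchy right-hand side
#'
#' The Fourier-mode truncation of the Fokker--Planck equation evaluated
#' at the Cauchy pole: for `j = 1..J`,
#' \deqn{\dot Z_j = i j f Z_{j+1} + i j h Z_j + i j f^* Z_{j-1}
#'  - \tfrac12 c_3\sigma^2[6j^2 Z_j + (4j^2+2j) Z_{j+1} + (4j^2-2j) Z_{j-1}
#'  + (j^2+j) Z_{j+2} + (j^2-j) Z_{j-2}]}
#' with \eqn{Z_0 = 1}, \eqn{Z_{-1} = 0}, and modes above `J` closed to
#' zero (default) -- the reference ("oracle") dynamics against which the
#' two-cumulant truncation is checked.
#'
#' @param Zvec complex vector of Kuramoto--Daido order parameters
#'   `Z_1..Z_J` (`J >= 4`).
#' @param g_syn conductance (mS/cm^2).
#' @param p an [mt_params()] object.
#' @return list with complex `dZ` (length `J`), `dg_syn`, and the rate
#'   `A` computed from `(Z_1, Z_2)` through the cumulant rate formula.
#' @export
mode_hierarchy_rhs <- function(Zvec, g_syn, p) {
  J <- length(Zvec)
  if (J < 4) stop("hierarchy needs J >= 4 modes")
  fl <- drive_fields(p, max(g_syn, 0))
  co <- derived_coefficients(p)
  s2h <- 0.5 * co$c3 * p$sigma^2
  Zp <- c(Zvec, 0 + 0i, 0 + 0i)      # zero closure above J
  Zm <- function(idx) {               # Z_{idx} with Z_0 = 1, Z_{-1} = 0
    ifelse(idx == 0, 1 + 0i, ifelse(idx < 0, 0 + 0i, Zp[pmax(idx, 1)]))
  }
  j <- seq_len(J)
  dZ <- 1i * j * fl$f * Zm(j + 1) + 1i * j * fl$h * Zm(j) +
    1i * j * fl$f_star * Zm(j - 1) -
    s2h * (6 * j^2 * Zm(j) + (4 * j^2 + 2 * j) * Zm(j + 1) +
             (4 * j^2 - 2 * j) * Zm(j - 1) + (j^2 + j) * Zm(j + 2) +
             (j^2 - j) * Zm(j - 2))
  kap <- Zvec[2] - Zvec[1]^2
  A <- firing_rate(Zvec[1], kap, p)
  list(dZ = dZ, dg_syn = -g_syn / p$tau_d + p$g_peak * p$P_syn * p$N * A,
       A = A)
}

#' Integrate the J-mode hierarchy
#'
#' Note: with noise, hard zero closure above mode `J` introduces spurious
#' weakly-physical truncation modes that can destabilize long
#' integrations; for equilibrium work prefer [hierarchy_equilibrium()],
#' which is algebraically exact at fixed conductance.
#'
#' @inheritParams integrate_macro
#' @param J number of retained modes (default 64).
#' @param state0 optional initial complex `Z_1..Z_J` plus `g_syn`; default
#'   fully incoherent (all zero).
#' @return data.frame with `t`, `ReZ1`, `ImZ1`, `ReZ2`, `ImZ2`, `g_syn`,
#'   `A`, plus the full final mode vector as attribute `"Z_final"`.
#' @export
integrate_hierarchy <- function(p, T, J = 64, state0 = NULL, dt_out = 0.5,
                                rtol = 1e-10, atol = 1e-12, method = "lsoda") {
  validate_params(p)
  if (is.null(state0)) state0 <- c(rep(0, 2 * J), 0)
  rhs <- function(t, y, parms) {
    Z <- complex(real = y[seq(1, 2 * J, 2)], imaginary = y[seq(2, 2 * J, 2)])
    d <- mode_hierarchy_rhs(Z, y[2 * J + 1], p)
    list(c(rbind(Re(d$dZ), Im(d$dZ)), d$dg_syn), A = as.numeric(d$A))
  }
  sol <- deSolve::ode(y = state0, times = seq(0, T, by = dt_out), func = rhs,
                      parms = NULL, method = method, rtol = rtol, atol = atol)
  nlast <- nrow(sol)
  Zf <- complex(real = sol[nlast, 1 + seq(1, 2 * J, 2)],
                imaginary = sol[nlast, 1 + seq(2, 2 * J, 2)])
  out <- data.frame(t = sol[, 1], ReZ1 = sol[, 2], ImZ1 = sol[, 3],
                    ReZ2 = sol[, 4], ImZ2 = sol[, 5],
                    g_syn = sol[, 2 * J + 2], A = sol[, "A"])
  attr(out, "Z_final") <- Zf
  out
}

#' Equilibrium of the J-mode hierarchy
#'
#' At fixed conductance the hierarchy is linear in the mode vector, so
#' the equilibrium reduces to a one-dimensional root problem in `g_syn`:
#' solve `M(g) Z = -b(g)` and require self-consistency of the rate drive.
#' Stability comes from the full real Jacobian of the closed system.
#'
#' @param p an [mt_params()] object.
#' @param J number of modes.
#' @param g_max upper bracket for the conductance root search.
#' @return list with `Z` (complex modes), `g_syn`, `A` (kHz),
#'   `max_real_part` of the Jacobian spectrum, and `residual`.
#' @export
hierarchy_equilibrium <- function(p, J = 64, g_max = 10) {
  validate_params(p)
  sys_at <- function(g) {
    fl <- drive_fields(p, g)
    co <- derived_coefficients(p)
    s2h <- 0.5 * co$c3 * p$sigma^2
    M <- matrix(0 + 0i, J, J)
    b <- complex(J)
    put <- function(row, idx, val) {
      if (idx == 0) b[row] <<- b[row] + val
      else if (idx >= 1 && idx <= J) M[row, idx] <<- M[row, idx] + val
    }
    for (j in seq_len(J)) {
      put(j, j + 1, 1i * j * fl$f); put(j, j, 1i * j * fl$h)
      put(j, j - 1, 1i * j * fl$f_star)
      put(j, j, -s2h * 6 * j^2)
      put(j, j + 1, -s2h * (4 * j^2 + 2 * j))
      put(j, j - 1, -s2h * (4 * j^2 - 2 * j))
      put(j, j + 2, -s2h * (j^2 + j))
      put(j, j - 2, -s2h * (j^2 - j))
    }
    list(M = M, b = b)
  }
  rate_of <- function(Z) as.numeric(firing_rate(Z[1], Z[2] - Z[1]^2, p))
  gap <- function(g) {
    sys <- sys_at(g)
    Z <- solve(sys$M, -sys$b)
    p$tau_d * p$g_peak * p$P_syn * p$N * rate_of(Z) - g
  }
  g <- stats::uniroot(gap, c(0, g_max), tol = 1e-13)$root
  Z <- solve(sys_at(g)$M, -sys_at(g)$b)
  ## full (2J+1)-real Jacobian for stability
  rhs <- function(y) {
    Zc <- complex(real = y[seq(1, 2 * J, 2)], imaginary = y[seq(2, 2 * J, 2)])
    d <- mode_hierarchy_rhs(Zc, y[2 * J + 1], p)
    c(rbind(Re(d$dZ), Im(d$dZ)), d$dg_syn)
  }
  y <- c(rbind(Re(Z), Im(Z)), g)
  n <- 2 * J + 1
  Jm <- matrix(0, n, n)
  for (jj in seq_len(n)) {
    d <- rep(0, n); d[jj] <- 1e-7 * max(1, abs(y[jj]))
    Jm[, jj] <- (rhs(y + d) - rhs(y - d)) / (2 * d[jj])
  }
  list(Z = Z, g_syn = g, A = rate_of(Z),
       max_real_part = max(Re(eigen(Jm, only.values = TRUE)$values)),
       residual = max(abs(rhs(y))))
}

#' Circular cumulants from Kuramoto--Daido moments, and back
#'
#' `cumulants_from_moments` maps the first two moments to cumulants:
#' `chi1 = Z1`, `chi2 = Z2 - Z1^2`. `moments_from_cumulants` reconstructs
#' the j-th moment of a distribution whose circular cumulants beyond the
#' second vanish. The default is the truncation used for the density and
#' rate reconstruction, `Z_j = Z^j + j(j-1)/2 kappa Z^{j-2}` (linear in
#' `kappa`); `exact = TRUE` keeps all powers of `kappa`
#' (`sum_m j!/(m! (j-2m)! 2^m) kappa^m Z^{j-2m}`), the exact moments of
#' the two-cumulant exponential family, used by the hierarchy
#' consistency oracle.
#'
#' @param Z1,Z2 complex first/second moments.
#' @param Z,kappa complex first/second circular cumulants.
#' @param j moment order, `>= 0`.
#' @param exact keep all powers of `kappa` (see Details).
#' @return `cumulants_from_moments`: list `chi1`, `chi2`;
#'   `moments_from_cumulants`: complex `Z_j`.
#' @export
cumulants_from_moments <- function(Z1, Z2) {
  list(chi1 = Z1, chi2 = Z2 - Z1^2)
}

#' @rdname cumulants_from_moments
#' @export
moments_from_cumulants <- function(Z, kappa, j, exact = FALSE) {
  if (any(j < 0)) stop("moment order j must be >= 0")
  one <- function(jj) {
    if (jj == 0) return(1 + 0i)
    if (!exact) {
      zjm2 <- if (jj >= 2) Z^(jj - 2) else 0 + 0i
      return(Z^jj + jj * (jj - 1) / 2 * kappa * zjm2)
    }
    m <- 0:(jj %/% 2)
    sum(factorial(jj) / (factorial(m) * factorial(jj - 2 * m) * 2^m) *
          kappa^m * Z^(jj - 2 * m))
  }
  vapply(j, one, complex(1))
}

#' Reconstruct the marginal phase density from two cumulants
#'
#' Sums the Fourier series of the phase density under the two-cumulant
#' moment closure, marginalized over the drive distribution:
#' \deqn{\rho(\theta) = \frac{1}{2\pi}\left[
#'   \frac{1-|Z|^2}{|e^{i\theta}-Z|^2} +
#'   2\,\mathrm{Re}\frac{\kappa e^{i\theta}}{(e^{i\theta}-Z)^3}\right].}
#' The first term is the wrapped-Cauchy (Ott--Antonsen) density; the
#' second is the leading noise correction. Integrates to 1 for any
#' `(Z, kappa)` with `|Z| < 1`, and is pointwise nonnegative whenever
#' `|kappa| <= (1-|Z|)^3`.
#'
#' @param theta grid of phases (rad).
#' @param Z complex first cumulant, `|Z| < 1`.
#' @param kappa complex second cumulant.
#' @return density values on `theta` (1/rad).
#' @export
reconstruct_density <- function(theta, Z, kappa = 0 + 0i) {
  if (Mod(Z) >= 1) stop("|Z| >= 1: density reconstruction requires |Z| < 1")
  e <- exp(1i * theta)
  (1 / (2 * pi)) * ((1 - Mod(Z)^2) / Mod(e - Z)^2 +
                      2 * Re(kappa * e / (e - Z)^3))
}
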