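test_that("firing rate formula: uniform, coherent, and corrected states", {
  p <- mt_params()
  # incoherent state: A = g_L / (2 pi C)
  expect_equal(firing_rate(0 + 0i, 0 + 0i, p), p$g_L / (2 * pi * p$C))
  # full coherence at theta = 0: no flux at the firing point
  expect_equal(firing_rate(1 + 0i, 0 + 0i, p), 0)
  # frozen direct evaluation with the kappa correction
  expect_equal(firing_rate(0.5 + 0i, 0.01 + 0i, p),
               (0.1 / pi) * (0.75 / (2 * 2.25) + 0.01 / 3.375),
               tolerance = 1e-14)
  expect_error(firing_rate(-1 + 0i, 0.01 + 0i, p), "singularity")
  # negative corrected rate is clipped and flagged
  A <- firing_rate(0.5 + 0i, -0.6 + 0i, p)
  expect_identical(as.numeric(A), 0)
  expect_true(isTRUE(attr(A, "clipped")))
})

test_that("Ott-Antonsen manifold is invariant without noise", {
  p <- mt_params(sigma = 0)
  d <- macro_rhs(0.3 - 0.2i, 0 + 0i, 0.4, p)
  expect_identical(d$dkappa, 0 + 0i)
  # and the Z equation reduces to the OA form
  fl <- drive_fields(p, 0.4)
  Z <- 0.3 - 0.2i
  expect_equal(d$dZ, 1i * fl$f * Z^2 + 1i * fl$h * Z + 1i * fl$f_star)
})

test_that("two-cumulant derivatives equal the mode hierarchy through exact moments", {
  # hierarchy initialized at the exact moments of a two-cumulant state;
  # chain rule d(chi2) = dZ2 - 2 Z1 dZ1
  set.seed(11)
  for (i in 1:12) {
    rZ <- sqrt(runif(1, 0, 0.36)); phZ <- runif(1, 0, 2 * pi)
    Z <- rZ * exp(1i * phZ)
    kap <- runif(1, 0, 0.03) * exp(1i * runif(1, 0, 2 * pi))
    g <- runif(1, 0, 1)
    p <- mt_params(eta = runif(1, 0.3, 1.6), Delta = runif(1, 0.02, 0.06),
                   sigma = 0.05, V_syn = runif(1, -58, -55))
    Zvec <- two_cumulant_modes(Z, kap, 64)
    dh <- mode_hierarchy_rhs(Zvec, g, p)
    dm <- macro_rhs(Z, kap, g, p)
    expect_equal(dm$dZ, dh$dZ[1], tolerance = 1e-6)
    expect_equal(dm$dkappa, dh$dZ[2] - 2 * Zvec[1] * dh$dZ[1], tolerance = 1e-6)
    expect_equal(dm$dg_syn, dh$dg_syn, tolerance = 1e-10)
  }
})

test_that("mode hierarchy: incoherent forcing and OA self-consistency", {
  p <- mt_params(sigma = 0.2)
  co <- derived_coefficients(p)
  fl <- drive_fields(p, 0.3)
  d0 <- mode_hierarchy_rhs(complex(64), 0.3, p)
  # all modes zero: only the Z_0 = 1 terms force mode 1
  expect_equal(d0$dZ[1], 1i * fl$f_star - co$c3 * p$sigma^2)

  # sigma = 0: d/dt Z_j = j Z_{j-1} dZ_1 on the OA manifold Z_j = a^j
  p0 <- mt_params(sigma = 0, eta = 0.9, Delta = 0.04)
  a <- 0.4 - 0.3i
  Zv <- a^(1:32)
  d <- mode_hierarchy_rhs(Zv, 0.2, p0)
  for (j in 2:31)
    expect_equal(d$dZ[j], j * a^(j - 1) * d$dZ[1], tolerance = 1e-12)

  expect_error(mode_hierarchy_rhs(complex(3), 0, p), "J >= 4")
})

test_that("cumulant/moment algebra closes", {
  expect_equal(cumulants_from_moments(0.5 + 0i, 0.3 + 0i)$chi2, 0.05 + 0i)
  Z <- 0.4 + 0.1i; kap <- 0.02 - 0.01i
  Z1 <- moments_from_cumulants(Z, kap, 1)
  Z2 <- moments_from_cumulants(Z, kap, 2)
  cm <- cumulants_from_moments(Z1, Z2)
  expect_equal(cm$chi1, Z)
  expect_equal(cm$chi2, kap)
  # kappa = 0 collapses to pure powers
  expect_equal(moments_from_cumulants(Z, 0 + 0i, 5), Z^5)
  # truncated and exact moments agree to first order in kappa (j = 2, 3)
  expect_equal(moments_from_cumulants(Z, kap, 2, exact = TRUE),
               moments_from_cumulants(Z, kap, 2))
  expect_equal(moments_from_cumulants(Z, kap, 3, exact = TRUE),
               moments_from_cumulants(Z, kap, 3))
  # at j = 4 the exact version keeps the 3 kappa^2 term
  expect_equal(moments_from_cumulants(Z, kap, 4, exact = TRUE) -
                 moments_from_cumulants(Z, kap, 4), 3 * kap^2)
  expect_error(moments_from_cumulants(Z, kap, -1), ">= 0")
})

test_that("reconstructed density: normalization, positivity, special values", {
  th <- seq(-pi, pi, length.out = 4097)[-1]
  expect_equal(reconstruct_density(th, 0 + 0i), rep(1 / (2 * pi), 4096))
  expect_equal(reconstruct_density(0, 0.5 + 0i), 3 / (2 * pi))
  set.seed(5)
  for (i in 1:10) {
    Z <- sqrt(runif(1, 0, 0.81)) * exp(1i * runif(1, 0, 2 * pi))
    kap <- runif(1, 0, 0.05) * exp(1i * runif(1, 0, 2 * pi))
    rho <- reconstruct_density(th, Z, kap)
    expect_equal(sum(rho) * 2 * pi / 4096, 1, tolerance = 1e-8)
    if (Mod(kap) <= (1 - Mod(Z))^3) expect_true(all(rho >= 0))
  }
  expect_error(reconstruct_density(th, 1.2 + 0i), "\\|Z\\|")
})

test_that("rate formula equals the probability flux at the firing point", {
  p <- mt_params()
  set.seed(9)
  for (i in 1:10) {
    Z <- sqrt(runif(1, 0, 0.64)) * exp(1i * runif(1, 0, 2 * pi))
    kap <- runif(1, 0, 0.03) * exp(1i * runif(1, 0, 2 * pi))
    g <- runif(1, 0, 1)
    flux <- phase_drift_corrected(pi, 57.3, g, p) * reconstruct_density(pi, Z, kap)
    expect_equal(as.numeric(firing_rate(Z, kap, p)), flux, tolerance = 1e-6)
  }
})

test_that("macro integration: invariant manifold and equilibrium consistency", {
  # sigma = 0, kappa(0) = 0 stays on the OA manifold
  p0 <- mt_params(eta = 1.59, Delta = 0.04, sigma = 0)
  tr <- integrate_macro(p0, T = 300, rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(tr$ReKappa), abs(tr$ImKappa)), 1e-9)

  # stationary regime: trajectory converges to the Newton equilibrium
  p1 <- deep_stationary()
  tr1 <- integrate_macro(p1, T = 2000)
  eq <- find_equilibrium(p1)
  expect_true(eq$converged)
  expect_equal(as.numeric(tr1[nrow(tr1), 2:6]), eq$state_star, tolerance = 1e-6)

  # oscillatory regime: limit-cycle period in the gamma range (5-33 ms)
  p2 <- plus_point(Delta = 0.04)
  tr2 <- integrate_macro(p2, T = 1500, dt_out = 0.1)
  tail_tr <- tr2[tr2$t > 1300, ]
  x <- tail_tr$A
  pk <- which(x[2:(length(x) - 1)] > x[1:(length(x) - 2)] &
                x[2:(length(x) - 1)] >= x[3:length(x)]) + 1
  pk <- pk[x[pk] > mean(x)]          # major peaks only
  period <- mean(diff(tail_tr$t[pk]))
  expect_gt(period, 5); expect_lt(period, 33)
})

test_that("noise-free hierarchy integration reproduces the OA trajectory", {
  # J must out-run the geometric mode tail |Z_1|^J (~0.85 here), so the
  # zero closure's feedback stays below the asserted tolerance
  p <- mt_params(eta = 0.8, Delta = 0.05, sigma = 0)
  hr <- integrate_hierarchy(p, T = 100, J = 128, dt_out = 1,
                            rtol = 1e-10, atol = 1e-12)
  oa <- integrate_oa(p, T = 100, dt_out = 1, rtol = 1e-10, atol = 1e-12)
  dZ <- complex(real = hr$ReZ1 - oa$ReZ, imaginary = hr$ImZ1 - oa$ImZ)
  expect_lt(max(Mod(dZ)), 1e-7)
  # the final mode vector lies on the OA manifold Z_j = Z_1^j
  Zf <- attr(hr, "Z_final")
  expect_lt(max(Mod(Zf[1:10] - Zf[1]^(1:10))), 1e-8)
})

test_that("hierarchy equilibrium rate is converged in J", {
  p <- mt_params(eta = 1.2, Delta = 0.05, sigma = 0.1)
  h64 <- hierarchy_equilibrium(p, J = 64)
  h96 <- hierarchy_equilibrium(p, J = 96)
  expect_lt(abs(h64$A - h96$A), 1e-8)
  expect_lt(h64$residual, 1e-10)
  # mode amplitudes decay geometrically; tail is resolved
  expect_lt(Mod(h64$Z[64]), 1e-4)
  expect_gt(Mod(h64$Z[1]), 0.5)
})
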