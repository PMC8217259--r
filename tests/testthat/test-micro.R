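test_that("input currents: quantile grid and iid draws behave as specified", {
  p <- mt_params(eta = 0, Delta = 1)
  # N = 2 closed-form quantiles: tan(+/- pi/4)
  expect_equal(sample_input_currents(p, 2), c(-1, 1))
  # odd N: middle entry is the Cauchy median, exactly eta
  p2 <- mt_params(eta = 0.37, Delta = 0.04)
  I <- sample_input_currents(p2, 11)
  expect_identical(I[6], 0.37)
  expect_equal(I + rev(I), rep(2 * 0.37, 11))  # symmetric about eta
  # iid mode is seed-reproducible
  a <- sample_input_currents(p2, 50, "iid", seed = 99)
  b <- sample_input_currents(p2, 50, "iid", seed = 99)
  expect_identical(a, b)
})

test_that("drift and diffusion match the phase equation at special points", {
  p <- mt_params(sigma = 0.2)
  # diffusion vanishes at the firing point for arbitrary parameters
  set.seed(3)
  for (i in 1:8) {
    pr <- mt_params(sigma = runif(1, 0, 0.5), C = runif(1, 0.5, 2),
                    V_T = -55, V_R = runif(1, -70, -58))
    expect_identical(phase_diffusion(pi, pr), 0)
    # Stratonovich correction also vanishes there
    expect_equal(phase_drift_corrected(pi, 1, 1, pr),
                 phase_drift(pi, 1, 1, pr))
  }
  # at theta = pi all (1+cos) terms and sin vanish: u = g_L/C regardless of I, g
  expect_equal(phase_drift(pi, 123, 4.5, p), p$g_L / p$C)
  # zero drift at theta = 0 exactly at the saddle-node current
  expect_equal(saddle_node_current(p), 0.175)
  expect_equal(phase_drift(0, 0.175, 0, p), 0)
})

test_that("single neuron: quiescent below the saddle-node, periodic above", {
  # subthreshold: no spikes from the stable basin
  p <- mt_params(eta = 0.1, Delta = 1e-6, sigma = 0, N = 1, g_peak = 0)
  r <- simulate_network(p, mt_sim_config(T_total = 1000, T_discard = 0, seed = 1),
                        theta0 = 0)
  expect_identical(nrow(r$raster), 0L)

  # suprathreshold: strictly periodic, period against quadrature oracle
  p2 <- mt_params(eta = 0.5, Delta = 1e-6, sigma = 0, N = 1, g_peak = 0)
  r2 <- simulate_network(p2, mt_sim_config(T_total = 400, T_discard = 0, seed = 1),
                         theta0 = 0)
  isi <- diff(r2$raster$time)
  expect_gt(length(isi), 4)
  expect_lt(diff(range(isi)), 0.021)    # constant to spike-time resolution
  T_oracle <- stats::integrate(function(th) 1 / phase_drift(th, 0.5, 0, p2),
                               -pi, pi, rel.tol = 1e-10)$value
  expect_equal(mean(isi), T_oracle, tolerance = 0.01)
})

test_that("conductance decays exactly when g_peak = 0; empty raster when quiescent", {
  p <- mt_params(eta = -1, sigma = 0, N = 50, g_peak = 0)
  st <- list(theta = rep(-2, 50), g_syn = 0.7, t = 0,
             I = sample_input_currents(p, 50))
  for (k in 1:200) st <- step_network(st, p, dt = 0.05)
  expect_equal(st$g_syn, 0.7 * exp(-200 * 0.05 / p$tau_d), tolerance = 1e-12)

  # strongly negative drive: raster empty after transient (eta far enough
  # below the saddle-node that even the heavy Cauchy quantile tail at this
  # N stays subthreshold)
  p3 <- mt_params(eta = -3, Delta = 0.04, sigma = 0, N = 100)
  r3 <- simulate_network(p3, mt_sim_config(T_total = 400, T_discard = 100, seed = 2))
  expect_identical(nrow(r3$raster), 0L)
  expect_true(all(r3$A == 0))
})

test_that("permutation symmetry: identical neurons stay identical", {
  N <- 40
  p <- mt_params(eta = 0.5, sigma = 0, N = N)
  r <- simulate_network(p, mt_sim_config(T_total = 100, T_discard = 50, seed = 4),
                        theta0 = rep(0.2, N), I = rep(0.5, N))
  expect_equal(diff(range(r$theta_final)), 0)
})

test_that("delta-kick coupling: full connectivity reproduces the mean field exactly", {
  N <- 150
  p <- mt_params(eta = 1.0, Delta = 0.04, sigma = 0.1, N = N, P_syn = 1)
  cfg <- mt_sim_config(T_total = 250, T_discard = 50, seed = 7)
  mf <- simulate_network(p, cfg)
  dk <- simulate_delta_kick(p, cfg)
  # identical forcing step-for-step; the population mean only carries
  # summation roundoff relative to the shared scalar
  expect_equal(dk$g_syn, mf$g_syn, tolerance = 1e-12)
  expect_identical(dk$raster, mf$raster)

  # no connections: per-neuron conductances stay at zero
  p0 <- mt_params(eta = 1.0, Delta = 0.04, sigma = 0.1, N = 100, P_syn = 0)
  dk0 <- simulate_delta_kick(p0, mt_sim_config(T_total = 200, T_discard = 50, seed = 7))
  expect_true(all(dk0$g_syn == 0))
  expect_true(all(dk0$g_syn_final == 0))
})

test_that("sparse random coupling is captured by the mean-field conductance", {
  # stationary regime: time-mean of the population-mean per-neuron
  # conductance within 5% of the shared mean-field trace
  p <- deep_stationary(N = 1000)
  cfg <- mt_sim_config(T_total = 1000, T_discard = 300, seed = 21)
  mf <- simulate_network(p, cfg)
  dk <- simulate_delta_kick(p, cfg)
  expect_equal(mean(dk$g_syn), mean(mf$g_syn), tolerance = 0.05)
})

test_that("Heun and corrected-Euler schemes agree in distribution", {
  p <- deep_stationary(N = 800)
  h <- simulate_network(p, mt_sim_config(T_total = 1000, T_discard = 300,
                                         seed = 31, scheme = "heun"))
  e <- simulate_network(p, mt_sim_config(T_total = 1000, T_discard = 300,
                                         seed = 31, scheme = "euler"))
  expect_equal(mean(e$g_syn), mean(h$g_syn), tolerance = 0.02)
  expect_equal(stats::sd(e$g_syn), stats::sd(h$g_syn), tolerance = 0.02)
})

test_that("binned rate estimator conserves counts", {
  raster <- data.frame(time = seq(0.0005, 1, length.out = 3000),
                       neuron = rep(1:3000, length.out = 3000))
  r <- firing_rate_estimate(raster, 1, 3000, t_range = c(0, 1))
  expect_equal(r$rate, 1)                          # 3000 spikes / (3000 * 1 ms)
  z <- firing_rate_estimate(raster[0, ], 0.5, 100, t_range = c(0, 10))
  expect_true(all(z$rate == 0))
  # halving the bin width leaves the time-averaged rate unchanged
  r1 <- firing_rate_estimate(raster, 0.25, 3000, t_range = c(0, 1))
  r2 <- firing_rate_estimate(raster, 0.125, 3000, t_range = c(0, 1))
  expect_equal(mean(r1$rate), mean(r2$rate), tolerance = 1e-12)
})

test_that("phase snapshots are recorded on the requested stride", {
  p <- mt_params(eta = 0.8, N = 50)
  r <- simulate_network(p, mt_sim_config(T_total = 50, T_discard = 10, seed = 2,
                                         record_phases = TRUE,
                                         phase_stride = 1000))
  expect_identical(dim(r$phase_snapshots), c(5L, 50L))
  expect_equal(r$snapshot_times, (1:5) * 10)
  expect_true(all(abs(r$phase_snapshots) <= pi))
})

test_that("config invariants are enforced", {
  expect_error(mt_sim_config(dt = 0.2), "dt")
  expect_error(mt_sim_config(T_total = 100, T_discard = 100), "T_discard")
})
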