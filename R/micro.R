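#' Simulation configuration for the finite-size network
#'
#' @param dt integration step (ms); capped at 0.05 ms (the multiplicative
#'   noise and spike detection need a fine step).
#' @param T_total total simulated duration (ms).
#' @param T_discard initial transient discarded from returned traces and
#'   raster (ms); must be `< T_total`.
#' @param scheme `"heun"` (stochastic Heun, Stratonovich-consistent;
#'   default) or `"euler"` (Euler--Maruyama plus the explicit
#'   Stratonovich drift correction, so both schemes target the same
#'   Fokker--Planck equation).
#' @param het_mode `"quantile"` (deterministic Cauchy quantile grid;
#'   default, removes sampling variance from the heavy tails) or `"iid"`
#'   (seeded Cauchy draws) for the frozen input currents.
#' @param seed integer seed; expanded into independent per-component
#'   streams (currents, initial phases, noise, adjacency) via
#'   [child_seed()].
#' @param record_phases keep phase snapshots every `phase_stride` steps.
#' @param phase_stride snapshot stride in steps (ignored unless
#'   `record_phases`).
#' @return An object of class `mt_sim_config`.
#' @export
mt_sim_config <- function(dt = 0.01, T_total = 2500, T_discard = 1000,
                          scheme = c("heun", "euler"),
                          het_mode = c("quantile", "iid"),
                          seed = 1L, record_phases = FALSE,
                          phase_stride = 100L) {
  scheme <- match.arg(scheme)
  het_mode <- match.arg(het_mode)
  if (dt <= 0 || dt > 0.05) stop("dt must satisfy 0 < dt <= 0.05 ms")
  if (T_discard >= T_total) stop("T_discard must be < T_total")
  structure(list(dt = dt, T_total = T_total, T_discard = T_discard,
                 scheme = scheme, het_mode = het_mode, seed = as.integer(seed),
                 record_phases = isTRUE(record_phases),
                 phase_stride = as.integer(phase_stride)),
            class = "mt_sim_config")
}

#' Frozen input currents of the heterogeneous population
#'
#' Draws the quenched per-neuron drive from the Cauchy--Lorentz
#' distribution with center `eta` and half-width `Delta`. In
#' `"quantile"` mode the currents are the deterministic quantile grid
#' \deqn{I_i = \eta + \Delta \tan\left(\pi \frac{2i - N - 1}{2N}\right),
#' \quad i = 1..N,} symmetric about `eta` (the median current is exactly
#' `eta` for odd `N`). In `"iid"` mode they are seeded Cauchy draws.
#'
#' @param p an [mt_params()] object (uses `eta`, `Delta`).
#' @param N number of neurons.
#' @param mode `"quantile"` or `"iid"`.
#' @param seed seed for `"iid"` mode (ignored for `"quantile"`).
#' @return numeric vector of `N` currents (uA/cm^2).
#' @export
sample_input_currents <- function(p, N = p$N, mode = c("quantile", "iid"),
                                  seed = NULL) {
  mode <- match.arg(mode)
  validate_params(p)
  if (N < 1) stop("N must be >= 1")
  if (mode == "quantile") {
    i <- seq_len(N)
    p$eta + p$Delta * tan(pi * (2 * i - N - 1) / (2 * N))
  } else {
    if (!is.null(seed)) set.seed(seed)
    p$eta + p$Delta * stats::rcauchy(N)
  }
}

#' Drift and diffusion of the phase equation
#'
#' `phase_drift` is the deterministic part of the phase velocity
#' (rad/ms); `phase_diffusion` the multiplicative noise amplitude. The
#' diffusion vanishes at `theta = pi`: noise can never push a neuron
#' across threshold exactly at the firing point.
#' `phase_drift_corrected` adds the Stratonovich correction
#' `(w/2) dw/dtheta`, which is the effective probability-flux drift in
#' the Fokker--Planck picture.
#'
#' @param theta phase(s) (rad).
#' @param I input current(s) (uA/cm^2), recycled against `theta`.
#' @param g_syn synaptic conductance (mS/cm^2).
#' @param p an [mt_params()] object.
#' @return numeric vector, same length as `theta`.
#' @export
phase_drift <- function(theta, I, g_syn, p) {
  co <- derived_coefficients(p)
  (-p$g_L * cos(theta) + co$c1 * I * (1 + cos(theta)) +
     g_syn * (co$c2 * (1 + cos(theta)) - sin(theta))) / p$C
}

#' @rdname phase_drift
#' @export
phase_diffusion <- function(theta, p) {
  co <- derived_coefficients(p)
  co$c1 * p$sigma * (1 + cos(theta)) / p$C
}

#' @rdname phase_drift
#' @export
phase_drift_corrected <- function(theta, I, g_syn, p) {
  co <- derived_coefficients(p)
  a <- co$c1 * p$sigma / p$C
  phase_drift(theta, I, g_syn, p) - 0.5 * a^2 * (1 + cos(theta)) * sin(theta)
}

## shared sanity checks + C++ call for both simulator variants
run_network <- function(p, config, coupling, adjacency = list(),
                        theta0 = NULL, I = NULL, g0 = NULL) {
  validate_params(p)
  stopifnot(inherits(config, "mt_sim_config"))
  N <- p$N
  if (is.null(I)) {
    if (config$het_mode == "quantile") {
      I <- sample_input_currents(p, N, "quantile")
    } else {
      I <- sample_input_currents(p, N, "iid",
                                 seed = child_seed(config$seed, "currents"))
    }
  }
  if (is.null(theta0)) {
    set.seed(child_seed(config$seed, "phases"))
    theta0 <- stats::runif(N, -pi, pi)
  }
  if (is.null(g0)) g0 <- if (coupling == 0L) 0 else numeric(N)
  nsteps <- round(config$T_total / config$dt)
  set.seed(child_seed(config$seed, "noise"))
  .mt_run_cpp(theta0, I, g0,
              p$C, p$g_L, p$V_T, p$V_R, p$V_syn, p$tau_d, p$g_peak,
              p$P_syn, p$sigma, config$dt, nsteps, 0,
              scheme = if (config$scheme == "heun") 0L else 1L,
              coupling = coupling, adjacency = adjacency,
              record_phases = config$record_phases,
              phase_stride = config$phase_stride)
}

finish_sim <- function(raw, p, config, coupling) {
  dt <- config$dt
  t_grid <- seq_len(round(config$T_total / dt)) * dt
  keep <- t_grid > config$T_discard
  raster <- data.frame(time = raw$spike_times, neuron = raw$spike_neuron)
  raster <- raster[raster$time > config$T_discard, , drop = FALSE]
  rownames(raster) <- NULL
  res <- list(times = t_grid[keep],
              g_syn = raw$g_trace[keep],
              A = raw$A_trace[keep],
              raster = raster,
              theta_final = raw$theta,
              g_syn_final = raw$g_syn,
              params = p, config = config,
              coupling = if (coupling == 0L) "mean_field" else "delta_kick")
  if (!is.null(raw$phase_snapshots)) {
    res$phase_snapshots <- raw$phase_snapshots
    res$snapshot_times <- raw$snapshot_times
  }
  class(res) <- "mt_sim"
  res
}

#' Simulate the finite-size network (mean-field shared conductance)
#'
#' Integrates the N-neuron stochastic phase network with a single shared
#' synaptic conductance driven by the population rate
#' `A(t) = spikes per step / (N dt)`. The returned traces and raster have
#' the initial transient (`T_discard`) removed.
#'
#' @param p an [mt_params()] object.
#' @param config an [mt_sim_config()] object.
#' @param theta0,I optional initial phases / frozen currents (length-`N`
#'   vectors) overriding the seeded defaults.
#' @return An object of class `mt_sim`: list with `times` (ms), `g_syn`
#'   (mS/cm^2), `A` (kHz), `raster` (data.frame `time`, `neuron`), final
#'   state, and the configuration echo.
#' @examples
#' p <- mt_params(N = 200)
#' r <- simulate_network(p, mt_sim_config(T_total = 300, T_discard = 100))
#' range(r$g_syn)
#' @export
simulate_network <- function(p, config = mt_sim_config(), theta0 = NULL,
                             I = NULL) {
  raw <- run_network(p, config, coupling = 0L, theta0 = theta0, I = I)
  finish_sim(raw, p, config, 0L)
}

#' Simulate the network with per-neuron delta-kick conductances
#'
#' The event-based variant used to validate the mean-field replacement:
#' each neuron keeps its own conductance, incremented by `g_peak` whenever
#' a connected presynaptic neuron fires. Connectivity is a directed
#' Bernoulli(`P_syn`) random graph drawn from `adjacency_seed` (with
#' `P_syn = 1` the population-mean conductance coincides step-for-step
#' with [simulate_network()] under the same seed).
#'
#' @inheritParams simulate_network
#' @param adjacency_seed seed of the Bernoulli adjacency draw; defaults
#'   to a child stream of `config$seed`.
#' @return An `mt_sim` object; `g_syn` holds the population-mean
#'   conductance trace.
#' @export
simulate_delta_kick <- function(p, config = mt_sim_config(),
                                adjacency_seed = NULL, theta0 = NULL,
                                I = NULL) {
  N <- p$N
  if (is.null(adjacency_seed))
    adjacency_seed <- child_seed(config$seed, "adjacency")
  if (p$P_syn == 1) {
    adjacency <- rep(list(seq_len(N)), N)
  } else if (p$P_syn == 0) {
    adjacency <- rep(list(integer(0)), N)
  } else {
    set.seed(adjacency_seed)
    adjacency <- lapply(seq_len(N), function(k)
      which(stats::runif(N) < p$P_syn))
  }
  raw <- run_network(p, config, coupling = 1L, adjacency = adjacency,
                     theta0 = theta0, I = I)
  finish_sim(raw, p, config, 1L)
}

#' Advance a network state by one integration step
#'
#' Single-step version of the stepper, for inspecting the discrete
#' dynamics. Consumes the current R random stream (call `set.seed()`
#' beforehand for reproducibility).
#'
#' @param state list with `theta` (N phases), `g_syn` (scalar), `t` (ms),
#'   `I` (N currents).
#' @param p an [mt_params()] object.
#' @param dt step (ms).
#' @param scheme `"heun"` or `"euler"`.
#' @return updated state list, plus `spikes` (indices fired this step).
#' @export
step_network <- function(state, p, dt = 0.01, scheme = c("heun", "euler")) {
  scheme <- match.arg(scheme)
  validate_params(p)
  raw <- .mt_run_cpp(state$theta, state$I, state$g_syn,
                     p$C, p$g_L, p$V_T, p$V_R, p$V_syn, p$tau_d, p$g_peak,
                     p$P_syn, p$sigma, dt, 1L, state$t,
                     scheme = if (scheme == "heun") 0L else 1L,
                     coupling = 0L, adjacency = list(),
                     record_phases = FALSE, phase_stride = 1L)
  list(theta = raw$theta, g_syn = raw$g_syn, t = state$t + dt, I = state$I,
       spikes = raw$spike_neuron)
}

#' Binned population firing-rate estimate from a spike raster
#'
#' @param raster data.frame with columns `time` (ms) and `neuron`.
#' @param bin_width bin width (ms).
#' @param N population size.
#' @param t_range optional c(start, end) (ms); defaults to the raster
#'   span. An empty raster gives an all-zero series over `t_range`.
#' @return data.frame with bin centers `time` (ms) and `rate` (kHz).
#' @export
firing_rate_estimate <- function(raster, bin_width, N, t_range = NULL) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  if (is.null(t_range)) {
    if (nrow(raster) == 0) stop("empty raster needs an explicit t_range")
    t_range <- range(raster$time)
  }
  nbins <- max(1L, as.integer(ceiling((t_range[2] - t_range[1]) / bin_width -
                                        1e-9)))
  breaks <- t_range[1] + (0:nbins) * bin_width
  counts <- if (nrow(raster) == 0) {
    integer(nbins)
  } else {
    tabulate(findInterval(raster$time, breaks, rightmost.closed = TRUE),
             nbins = nbins)
  }
  data.frame(time = breaks[-length(breaks)] + bin_width / 2,
             rate = counts / (N * bin_width))
}

#' @export
print.mt_sim <- function(x, ...) {
  cat(sprintf("MT network simulation (%s): N=%d, %g ms (discard %g), %d spikes kept\n",
              x$coupling, x$params$N, x$config$T_total, x$config$T_discard,
              nrow(x$raster)))
  cat(sprintf("  g_syn mean %.4g, sd %.4g mS/cm^2; mean rate %.4g kHz\n",
              mean(x$g_syn), stats::sd(x$g_syn), mean(x$A)))
  invisible(x)
}

#' Write simulation outputs as delimited text
#'
#' `write_raster` writes the two-column raster (time_ms, neuron_id);
#' `write_traces` the (t, g_syn, A) table. Both are plain TSV.
#'
#' @param sim an `mt_sim` object.
#' @param path output file path.
#' @export
write_raster <- function(sim, path) {
  utils::write.table(sim$raster, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
write_traces <- function(sim, path) {
  utils::write.table(data.frame(t = sim$times, g_syn = sim$g_syn, A = sim$A),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
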