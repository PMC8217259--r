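#' One-sided power spectral density of a conductance trace
#'
#' Plain rectangular-window periodogram of the mean-removed trace. The
#' normalization satisfies the discrete Parseval identity exactly:
#' `sum(psd) * df` equals the (population) variance of the detrended
#' trace. Frequencies are reported in Hz (the trace is sampled in ms).
#'
#' @param x numeric trace, at least 256 samples.
#' @param dt sampling interval in ms.
#' @return An object of class `mt_spectrum`: list with `freqs` (Hz),
#'   `psd` (x^2/Hz), `df`, and `variance` of the detrended trace.
#' @export
psd <- function(x, dt) {
  n <- length(x)
  if (n < 256) stop("trace too short: need >= 256 samples")
  if (dt <= 0) stop("dt must be > 0")
  fs <- 1000 / dt                 # Hz
  x <- x - mean(x)
  X <- stats::fft(x)
  nh <- n %/% 2
  pw <- Mod(X)^2 / (fs * n)       # two-sided density
  one <- pw[1:(nh + 1)]
  if (n %% 2 == 0) {
    if (nh >= 2) one[2:nh] <- 2 * one[2:nh]          # Nyquist bin unpaired
  } else {
    one[2:(nh + 1)] <- 2 * one[2:(nh + 1)]
  }
  out <- list(freqs = (0:nh) * fs / n, psd = one, df = fs / n,
              variance = mean(x^2))
  class(out) <- "mt_spectrum"
  out
}

#' @export
print.mt_spectrum <- function(x, ...) {
  gp <- gamma_power(x)
  cat(sprintf("spectrum: %d bins, df = %.3g Hz, P_gamma = %.4g, P'_gamma = %.4g\n",
              length(x$freqs), x$df, gp$P_gamma, gp$P_gamma_prime))
  invisible(x)
}

#' Gamma-band power and its logarithmic transform
#'
#' Integrates the PSD over the gamma band (default 30--200 Hz) by the
#' trapezoid rule, then applies the compressive transform
#' \deqn{P'_\gamma = \ln(10^4 P_\gamma + 1),} which maps zero band power
#' to zero and tames the orders-of-magnitude contrast between stationary
#' and oscillatory regimes. The integration is done first and the
#' transform applied to the integral (not bin-wise).
#'
#' @param spectrum an [psd()] result.
#' @param band length-2 band edges in Hz, within `(0, Nyquist)`.
#' @return list with `P_gamma` and `P_gamma_prime`.
#' @export
gamma_power <- function(spectrum, band = c(30, 200)) {
  stopifnot(inherits(spectrum, "mt_spectrum"))
  fmax <- max(spectrum$freqs)
  if (band[1] <= 0 || band[2] > fmax || band[1] >= band[2])
    stop("band must lie within (0, Nyquist]")
  sel <- spectrum$freqs >= band[1] & spectrum$freqs <= band[2]
  f <- spectrum$freqs[sel]; v <- spectrum$psd[sel]
  P <- if (length(f) < 2) 0 else sum(diff(f) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
  list(P_gamma = P, P_gamma_prime = log(1e4 * P + 1))
}

#' Peak (center) frequency within the gamma band
#'
#' Argmax of the PSD inside the band with three-point parabolic
#' refinement. A flat band (no positive power) returns the lower band
#' edge with attribute `flat = TRUE`.
#'
#' @inheritParams gamma_power
#' @return center frequency in Hz.
#' @export
center_frequency <- function(spectrum, band = c(30, 200)) {
  stopifnot(inherits(spectrum, "mt_spectrum"))
  sel <- which(spectrum$freqs >= band[1] & spectrum$freqs <= band[2])
  if (length(sel) == 0) stop("band outside spectrum")
  v <- spectrum$psd[sel]
  if (max(v) <= 0 || diff(range(v)) == 0)
    return(structure(band[1], flat = TRUE))
  k <- sel[which.max(v)]
  f0 <- spectrum$freqs[k]
  if (k > 1 && k < length(spectrum$psd)) {
    ym <- spectrum$psd[k - 1]; y0 <- spectrum$psd[k]; yp <- spectrum$psd[k + 1]
    den <- ym - 2 * y0 + yp
    if (den < 0) f0 <- f0 + 0.5 * (ym - yp) / den * spectrum$df
  }
  f0
}

#' Gamma-power heatmap over a parameter plane
#'
#' Runs the finite-network simulator at every node of a parameter grid,
#' computes the transformed gamma-band power of the post-transient
#' conductance trace, and classifies the same nodes with the macroscopic
#' model for overlaying the regime boundary. Each cell gets its own
#' child seed, so the scan is reproducible and insensitive to cell
#' order; per-cell failures are recorded as `NA` and the scan continues.
#'
#' @param p an [mt_params()] object (off-grid parameters).
#' @param x_name,x_values,y_name,y_values grid specification.
#' @param config an [mt_sim_config()]; its `seed` is the scan's master
#'   seed.
#' @param classify also run the macroscopic classifier per cell.
#' @return An object of class `mt_heatmap`: list with matrix
#'   `P_gamma_prime` (rows = y, cols = x), optional character matrix
#'   `macro_class`, the grids, and the config echo.
#' @export
heatmap_scan <- function(p, x_name, x_values, y_name, y_values,
                         config = mt_sim_config(T_total = 1500, T_discard = 500),
                         classify = TRUE) {
  if (length(x_values) < 2 || length(y_values) < 2)
    stop("grids must have >= 2 points")
  H <- matrix(NA_real_, length(y_values), length(x_values))
  cls <- if (classify) matrix(NA_character_, length(y_values), length(x_values))
  for (iy in seq_along(y_values)) {
    for (ix in seq_along(x_values)) {
      p2 <- p
      p2[[x_name]] <- x_values[ix]
      p2[[y_name]] <- y_values[iy]
      cell <- (iy - 1L) * length(x_values) + ix
      cfg <- config
      cfg$seed <- child_seed(config$seed, paste0("cell", cell))
      val <- try({
        sim <- simulate_network(p2, cfg)
        gamma_power(psd(sim$g_syn, cfg$dt))$P_gamma_prime
      }, silent = TRUE)
      if (!inherits(val, "try-error")) H[iy, ix] <- val
      if (classify) {
        lab <- try(classify_state(p2), silent = TRUE)
        if (!inherits(lab, "try-error")) cls[iy, ix] <- as.character(lab)
      }
    }
  }
  structure(list(P_gamma_prime = H, macro_class = cls,
                 x_name = x_name, x_values = x_values,
                 y_name = y_name, y_values = y_values, config = config),
            class = "mt_heatmap")
}

#' @export
print.mt_heatmap <- function(x, ...) {
  cat(sprintf("gamma-power heatmap: %s x %s, %d x %d cells, P' range [%.3g, %.3g]\n",
              x$x_name, x$y_name, length(x$x_values), length(x$y_values),
              min(x$P_gamma_prime, na.rm = TRUE),
              max(x$P_gamma_prime, na.rm = TRUE)))
  invisible(x)
}

#' Write a heatmap as a delimited matrix with coordinate headers
#'
#' @param hm an `mt_heatmap` object.
#' @param path output TSV path.
#' @export
write_heatmap <- function(hm, path) {
  M <- hm$P_gamma_prime
  rownames(M) <- hm$y_values
  colnames(M) <- hm$x_values
  utils::write.table(M, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
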