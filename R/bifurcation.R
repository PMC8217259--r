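#' Find an equilibrium of the macroscopic model
#'
#' Damped Newton iteration on the 5-real-dimensional state
#' (Re Z, Im Z, Re kappa, Im kappa, g_syn), with the Jacobian from
#' central finite differences (relative step 1e-6) and backtracking line
#' search on the residual norm. The default initial guess is the
#' endpoint of a forward integration from the incoherent rest state --
#' the physically reached branch; if Newton stalls there, a coarse
#' multi-start grid of guesses is tried.
#'
#' @param p an [mt_params()] object.
#' @param guess optional 5-vector initial guess.
#' @param tol residual tolerance for convergence.
#' @param max_iter Newton iteration cap.
#' @return An object of class `mt_equilibrium`: `state_star` (5-vector),
#'   `Z`, `kappa`, `g_syn`, `A`, `eigenvalues` (5 complex), `max_real_part`,
#'   `classification` (`"stationary"` / `"oscillatory"`), `converged`,
#'   `residual`.
#' @export
find_equilibrium <- function(p, guess = NULL, tol = 1e-10, max_iter = 80) {
  validate_params(p)
  F <- function(y) {
    d <- macro_rhs_vec(0, y, p)[[1]]
    if (!all(is.finite(d))) rep(1e6, 5) else d
  }
  newton <- function(y) {
    J <- NULL
    for (it in seq_len(max_iter)) {
      J <- jacobian_fd(F, y)
      step <- tryCatch(solve(J, -F(y)), error = function(e) NULL)
      if (is.null(step)) return(list(y = y, J = J, ok = FALSE))
      lam <- 1
      f0 <- max(abs(F(y)))
      while (lam > 1e-6 && max(abs(F(y + lam * step))) > f0) lam <- lam / 2
      y <- y + lam * step
      if (max(abs(step)) < 1e-13 || max(abs(F(y))) < tol * 1e-2) break
    }
    list(y = y, J = jacobian_fd(F, y), ok = max(abs(F(y))) < tol)
  }
  if (is.null(guess)) {
    tr <- integrate_macro(p, T = 3000, dt_out = 10, rtol = 1e-8, atol = 1e-10)
    guess <- as.numeric(tr[nrow(tr), 2:6])
  }
  res <- newton(guess)
  if (!res$ok) {
    ## multi-start fallback over a coarse grid of plausible states
    for (zr in c(-0.5, 0, 0.5)) for (g0 in c(0, 0.3, 1)) {
      res2 <- newton(c(zr, 0, 0, 0, g0))
      if (res2$ok) { res <- res2; break }
    }
  }
  y <- res$y
  ev <- eigen(res$J, only.values = TRUE)$values
  mr <- max(Re(ev))
  st <- vec_to_state(y)
  out <- list(state_star = y, Z = st$Z, kappa = st$kappa, g_syn = st$g_syn,
              A = as.numeric(firing_rate(st$Z, st$kappa, p)),
              eigenvalues = ev, max_real_part = mr,
              classification = if (mr > 0) "oscillatory" else "stationary",
              converged = res$ok, residual = max(abs(F(y))))
  class(out) <- "mt_equilibrium"
  out
}

jacobian_fd <- function(F, y, rel = 1e-6) {
  n <- length(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    d <- rep(0, n); d[j] <- rel * max(1, abs(y[j]))
    J[, j] <- (F(y + d) - F(y - d)) / (2 * d[j])
  }
  J
}

#' @export
print.mt_equilibrium <- function(x, ...) {
  cat(sprintf("MT equilibrium (%s): |Z|=%.4f, g_syn=%.4f, A=%.4f kHz\n",
              x$classification, Mod(x$Z), x$g_syn, x$A))
  cat(sprintf("  max Re(lambda) = %+.5f, converged = %s\n",
              x$max_real_part, x$converged))
  invisible(x)
}

#' Classify a parameter point as stationary or oscillatory
#'
#' Primary route: eigenvalues of the Jacobian at the equilibrium reached
#' by forward integration from rest -- `"oscillatory"` iff the leading
#' real part exceeds `tol`. If equilibrium finding fails, falls back to
#' long integration and the amplitude criterion of [classify_trace()].
#'
#' @param p an [mt_params()] object.
#' @param tol eigenvalue tolerance: leading real parts within `±tol` of
#'   zero are at the resolution limit of the classification, and the
#'   sign decides.
#' @param amplitude_threshold fallback threshold passed to
#'   [classify_trace()].
#' @return `"stationary"` or `"oscillatory"` with attribute
#'   `"max_real_part"` (NA when the fallback was used).
#' @export
classify_state <- function(p, tol = 1e-6, amplitude_threshold = 0.01) {
  eq <- try(find_equilibrium(p), silent = TRUE)
  if (!inherits(eq, "try-error") && eq$converged) {
    lab <- if (eq$max_real_part > tol) "oscillatory" else "stationary"
    return(structure(lab, max_real_part = eq$max_real_part))
  }
  tr <- integrate_macro(p, T = 2500, dt_out = 0.25, rtol = 1e-8, atol = 1e-10)
  tail_i <- tr$t > max(tr$t) - 500
  structure(classify_trace(tr$A[tail_i], threshold = amplitude_threshold),
            max_real_part = NA_real_)
}

#' Amplitude criterion on a (post-transient) trace
#'
#' Declares `"oscillatory"` when the peak-to-trough excursion of the
#' trace exceeds `threshold` times its mean. For noisy finite-network
#' traces use a robust quantile excursion and a coarser threshold (see
#' `robust`): the finite-size fluctuation floor is of order `N^{-1/2}`,
#' so a deterministic-model threshold of 1% would misread it.
#'
#' @param x numeric trace (typically `A` or `g_syn` after transient
#'   removal).
#' @param threshold excursion/mean ratio above which the trace counts as
#'   oscillatory.
#' @param robust use the 5%--95% quantile excursion instead of the full
#'   range (recommended for stochastic traces).
#' @return `"stationary"` or `"oscillatory"` with attribute
#'   `"excursion_ratio"`.
#' @export
classify_trace <- function(x, threshold = 0.01, robust = FALSE) {
  m <- mean(x)
  exc <- if (robust) diff(stats::quantile(x, c(0.05, 0.95), names = FALSE))
         else diff(range(x))
  ratio <- if (m > 0) exc / m else 0
  structure(if (ratio > threshold) "oscillatory" else "stationary",
            excursion_ratio = ratio)
}

## leading eigenvalue real part along a 1-parameter family, with
## warm-started equilibrium continuation
max_re_scan <- function(p, scan_name, values) {
  out <- numeric(length(values))
  im <- numeric(length(values))
  guess <- NULL
  for (i in seq_along(values)) {
    p[[scan_name]] <- values[i]
    eq <- try(find_equilibrium(p, guess = guess), silent = TRUE)
    if (inherits(eq, "try-error") || !eq$converged) {
      eq <- try(find_equilibrium(p, guess = NULL), silent = TRUE)
    }
    if (inherits(eq, "try-error") || !eq$converged) {
      out[i] <- NA; im[i] <- NA
    } else {
      out[i] <- eq$max_real_part
      lead <- eq$eigenvalues[which.max(Re(eq$eigenvalues))]
      im[i] <- abs(Im(lead))
      guess <- eq$state_star
    }
  }
  list(max_re = out, im = im)
}

#' Locate Hopf points along one parameter
#'
#' Scans the leading eigenvalue real part of the equilibrium on a grid
#' over `[lo, hi]` of parameter `scan_name`, brackets every sign change,
#' and refines each by bisection to `|interval| <= tol`. Handles
#' re-entrant regions (multiple crossings) by returning all roots.
#'
#' @param p an [mt_params()] object (fixed parameters).
#' @param scan_name one of `"eta"`, `"V_syn"`, `"P_syn"`, `"Delta"`,
#'   `"sigma"`.
#' @param lo,hi scan range (`lo < hi`).
#' @param n_grid number of grid points for bracketing.
#' @param tol bisection interval tolerance.
#' @return numeric vector of Hopf parameter values (possibly empty), with
#'   attribute `"im_at_root"` (imaginary parts of the crossing pair).
#' @export
hopf_locus_1d <- function(p, scan_name, lo, hi, n_grid = 41, tol = 1e-4) {
  if (lo >= hi) stop("need lo < hi")
  grid <- seq(lo, hi, length.out = n_grid)
  sc <- max_re_scan(p, scan_name, grid)
  v <- sc$max_re
  roots <- numeric(0); ims <- numeric(0)
  guess <- NULL        # warm-start continuation through the refinements
  one_eq <- function(x) {
    p[[scan_name]] <- x
    eq <- try(find_equilibrium(p, guess = guess), silent = TRUE)
    if (inherits(eq, "try-error") || !eq$converged)
      eq <- try(find_equilibrium(p), silent = TRUE)
    if (inherits(eq, "try-error") || !eq$converged) return(NULL)
    guess <<- eq$state_star
    eq
  }
  for (i in seq_len(n_grid - 1)) {
    if (is.na(v[i]) || is.na(v[i + 1])) next
    if (sign(v[i]) != sign(v[i + 1]) && v[i] != 0) {
      a <- grid[i]; b <- grid[i + 1]; va <- v[i]
      guess <- NULL
      while (b - a > tol) {
        m <- (a + b) / 2
        eqm <- one_eq(m)
        if (is.null(eqm)) break
        if (sign(eqm$max_real_part) == sign(va)) {
          a <- m; va <- eqm$max_real_part
        } else b <- m
      }
      root <- (a + b) / 2
      eqr <- one_eq(root)
      imr <- if (is.null(eqr)) NA_real_ else {
        abs(Im(eqr$eigenvalues[which.max(Re(eqr$eigenvalues))]))
      }
      roots <- c(roots, root); ims <- c(ims, imr)
    }
  }
  structure(roots, im_at_root = ims)
}

#' Trace a Hopf curve in a two-parameter plane
#'
#' For each value of the `y` parameter, finds all Hopf crossings in the
#' `x` parameter with [hopf_locus_1d()] and chains the collected points
#' into branches by nearest-neighbor continuation. Closed-loop regime
#' boundaries appear naturally as slices with two roots.
#'
#' @param p an [mt_params()] object (fixed parameters).
#' @param x_name,y_name scanned parameter names.
#' @param x_range length-2 range for the `x` scans.
#' @param y_grid vector of `y` values (one 1-d scan per value).
#' @param n_grid_x grid resolution of each `x` scan.
#' @param tol bisection tolerance.
#' @return An object of class `mt_hopf_curve`: data.frame with columns
#'   `y`, `x`, `branch`, plus the plane names as attributes.
#' @export
trace_hopf_curve_2d <- function(p, x_name, x_range, y_name, y_grid,
                                n_grid_x = 41, tol = 1e-4) {
  if (length(x_range) != 2 || diff(x_range) <= 0) {
    pts <- data.frame(y = numeric(0), x = numeric(0), branch = integer(0))
  } else {
    rows <- lapply(y_grid, function(yv) {
      p[[y_name]] <- yv
      r <- hopf_locus_1d(p, x_name, x_range[1], x_range[2],
                         n_grid = n_grid_x, tol = tol)
      if (length(r) == 0) return(NULL)
      data.frame(y = yv, x = as.numeric(r))
    })
    pts <- do.call(rbind, rows)
    if (is.null(pts)) pts <- data.frame(y = numeric(0), x = numeric(0))
    pts$branch <- chain_branches(pts, diff(x_range))
  }
  structure(pts, x_name = x_name, y_name = y_name,
            class = c("mt_hopf_curve", "data.frame"))
}

## nearest-neighbor chaining of per-slice roots into curve branches
chain_branches <- function(pts, scan_width) {
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  branch <- rep(NA_integer_, n)
  ys <- sort(unique(pts$y))
  dthresh <- 0.35 * scan_width + 1e-12   # max x-jump between adjacent slices
  next_branch <- 1L
  prev_idx <- integer(0)
  for (yv in ys) {
    idx <- which(pts$y == yv)
    idx <- idx[order(pts$x[idx])]
    for (i in idx) {
      if (length(prev_idx) > 0) {
        d <- abs(pts$x[prev_idx] - pts$x[i])
        j <- prev_idx[which.min(d)]
        if (min(d) < dthresh) {
          branch[i] <- branch[j]
          next
        }
      }
      branch[i] <- next_branch
      next_branch <- next_branch + 1L
    }
    prev_idx <- idx
  }
  branch
}

#' Oscillatory-region area in a parameter plane
#'
#' Classifies every node of a rectangular grid with [classify_state()]
#' and returns the oscillatory fraction times the plane area -- a simple
#' monotonicity-friendly measure of how large the unstable region is.
#'
#' @param p an [mt_params()] object.
#' @param x_name,x_grid,y_name,y_grid grid specification.
#' @return list with `area`, `fraction`, and the logical matrix
#'   `oscillatory` (rows = y, cols = x).
#' @export
oscillatory_area <- function(p, x_name, x_grid, y_name, y_grid) {
  M <- matrix(FALSE, length(y_grid), length(x_grid))
  for (ix in seq_along(x_grid)) {
    p[[x_name]] <- x_grid[ix]
    guess <- NULL        # continue along y from the first slice
    for (iy in seq_along(y_grid)) {
      p[[y_name]] <- y_grid[iy]
      eq <- try(find_equilibrium(p, guess = guess), silent = TRUE)
      ## a converged equilibrium with clipped zero rate under
      ## supra-threshold drive is a truncation artifact, not physical
      ok <- !inherits(eq, "try-error") && eq$converged &&
        (eq$A > 0 || p$eta < saddle_node_current(p))
      if (ok) {
        M[iy, ix] <- eq$max_real_part > 1e-6
        guess <- eq$state_star
      } else {
        M[iy, ix] <- classify_state(p) == "oscillatory"
        guess <- NULL
      }
    }
  }
  frac <- mean(M)
  list(area = frac * diff(range(x_grid)) * diff(range(y_grid)),
       fraction = frac, oscillatory = M)
}
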