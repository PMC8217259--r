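---
title: "Two-cumulant mean-field analysis of interneuron gamma oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-cumulant mean-field analysis of interneuron gamma oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtgamma)
```

## The model

`mtgamma` studies interneuron gamma (ING) rhythms: collective 30–200 Hz
oscillations generated by a population of GABAergic neurons coupled
through a shared inhibitory conductance. Each neuron is a *modified
theta* (MT) neuron — the phase form of a conductance-based quadratic
integrate-and-fire model, obtained through
$V = (V_T+V_R)/2 + (V_T-V_R)/2\,\tan(\theta/2)$ — with phase dynamics

$$C\,\dot\theta_i = -g_L\cos\theta_i
  + c_1(1+\cos\theta_i)\,(I_i + \sigma\xi_i(t))
  + g_{syn}\left[c_2(1+\cos\theta_i) - \sin\theta_i\right],$$

where $c_1 = 2/(V_T-V_R)$ and $c_2 = (2V_{syn}-V_T-V_R)/(V_T-V_R)$. A
neuron fires when its phase crosses $\pi$. The quenched input currents
$I_i$ follow a Cauchy–Lorentz distribution with center $\eta$ and
half-width $\Delta$ (the heterogeneity scale), $\xi_i$ is unit white
noise read in the Stratonovich convention, and the shared conductance
relaxes with time constant $\tau_d$ while being driven by the population
rate $A(t)$:

$$\dot g_{syn} = -g_{syn}/\tau_d + \bar g_{peak}\,P_{syn}\,N\,A(t).$$

The synaptic reversal potential $V_{syn}$ decides whether the GABAergic
conductance depolarizes or hyperpolarizes: $c_2$ is an affine, strictly
increasing function of $V_{syn}$ with $c_2(V_R) = -1$ and
$c_2(V_T) = +1$.

Units are fixed throughout: ms, mV, mS/cm², µF/cm², µA/cm²; rates are
therefore in kHz. The leak conductance is taken as
$g_L = 0.1\ \mathrm{mS/cm^2}$; with $C = 1\ \mathrm{µF/cm^2}$ this gives
the membrane rate constant $g_L/C = 0.1\ \mathrm{ms^{-1}}$ required for
gamma-range firing (a µS/cm² reading would put all rates near 0.02 Hz).
The default $\bar g_{peak} = 0.0214\ \mathrm{mS/cm^2}$ is the unitary
GABA conductance 6.2 nS spread over a membrane area of
$2.9\times10^{-4}\ \mathrm{cm^2}$ (`peak_conductance_density()`).

## The two-cumulant reduction

In the thermodynamic limit the network state is a phase density obeying
a Fokker–Planck equation. Expanding in Fourier modes and evaluating at
the Cauchy pole $I = \eta + i\Delta$ yields an infinite hierarchy for the
Kuramoto–Daido order parameters $Z_j = \langle e^{ij\theta}\rangle$
(`mode_hierarchy_rhs()`). Truncating the *circular cumulants* of
$e^{i\theta}$ after the second gives the macroscopic model integrated by
`integrate_macro()`:

$$\dot Z = if(Z^2+\kappa) + ihZ + if^* - c_3\sigma^2\left[(Z+1)^3 + 3\kappa(Z+1)\right],$$
$$\dot\kappa = 4ifZ\kappa + 2ih\kappa - c_3\sigma^2\left[(Z+1)^4 + 12\kappa(Z+1)^2 + 9\kappa^2\right],$$

with $c_3 = c_1^2/(4C^2)$ and the drive fields
$f = \frac{1}{2C}[-g_L + c_1(\eta+i\Delta) + c_2 g_{syn} + i g_{syn}]$,
$h = \frac{1}{C}[c_1(\eta+i\Delta) + c_2 g_{syn}]$,
$f^* = f - i g_{syn}/C$. The population rate closing the conductance
equation is

$$A = \frac{g_L}{C\pi}\left[\frac{1-|Z|^2}{2|1+Z|^2}
     + \mathrm{Re}\,\frac{\kappa}{(1+Z)^3}\right].$$

Three structural facts anchor the implementation, and each is enforced
by a test:

* **$f^*$ is not $\overline f$.** On real currents $f^*$ is the complex
  conjugate of $f$; after the residue evaluation both fields carry
  $+i\Delta$ and only the $ig_{syn}$ term flips sign. Treating $f^*$ as
  `Conj(f)` for $\Delta > 0$ destroys the regime structure entirely (no
  Hopf curve survives on the reference slice).
* **The OA manifold $\kappa = 0$ is invariant at $\sigma = 0$**, where
  the $Z$ equation is exactly the Ott–Antonsen reduction. An
  independently coded one-cumulant integrator (`integrate_oa()`) matches
  the two-cumulant trajectory to better than $10^{-8}$ over 500 ms.
* **The cumulant equations are an exact image of the mode hierarchy.**
  Initializing the hierarchy at the exact moments of a two-cumulant
  state — $Z_j = \sum_m \binom{j}{2m}(2m-1)!!\,\kappa^m Z^{j-2m}$, kept
  as `moments_from_cumulants(..., exact = TRUE)` — and mapping
  derivatives through $\dot\chi_2 = \dot Z_2 - 2Z_1\dot Z_1$ reproduces
  $\dot Z$ and $\dot\kappa$ including the $9\kappa^2$ term. The linear
  truncation $Z_j = Z^j + \tfrac{j(j-1)}{2}\kappa Z^{j-2}$ (the default)
  is what the density and rate reconstruction use; it drops an
  $O(\kappa^2)$ term that is irrelevant there but would spoil the
  derivative identity.

The reconstructed phase density (`reconstruct_density()`) is the wrapped
Cauchy (OA) kernel plus the leading noise correction; it integrates to 1
for any $|Z| < 1$ and is pointwise nonnegative whenever
$|\kappa| \le (1-|Z|)^3$. The rate formula is identically the
probability flux $(u + \tfrac{w}{2}\partial_\theta w)\rho$ at
$\theta = \pi$, which the tests verify numerically against
`phase_drift_corrected()`.

## The finite-size simulator

`simulate_network()` integrates the N-neuron stochastic system with a
C++ stepper. The multiplicative noise $w(\theta) \propto 1+\cos\theta$
is read in the Stratonovich convention, so the default scheme is
stochastic Heun; the literal Euler–Maruyama mode adds the drift
correction $(w/2)\,\partial_\theta w$ explicitly so that both schemes
target the same Fokker–Planck equation (they agree in mean and standard
deviation of $g_{syn}$ to better than 2% at $dt = 0.01$ ms). Spikes are
upward crossings of $\theta = \pi$ within a step, wrapped by $-2\pi$;
the diffusion vanishes at $\theta = \pi$, so noise can neither create
nor destroy a spike exactly at threshold. The same-step binned rate
$A(t) = (\text{spikes})/(N\,dt)$ forces the conductance, which decays by
the exact exponential factor per step.

Heterogeneity defaults to the deterministic Cauchy quantile grid
$I_i = \eta + \Delta\tan\!\big(\pi\,(2i-N-1)/(2N)\big)$: reproducible
and free of the sampling variance of heavy-tailed iid draws (which
remain available as `het_mode = "iid"`). Because the Cauchy tails are
heavy, a handful of neurons remain suprathreshold even at strongly
negative $\eta$; "quiescent" here always means *almost all* neurons
silent. Initial phases are iid uniform on $(-\pi,\pi]$, $g_{syn}(0)=0$,
and the first 1000 ms (configurable) are discarded.

`simulate_delta_kick()` is the event-based variant used to validate the
mean-field replacement: each neuron keeps a private conductance kicked
by $\bar g_{peak}$ per connected presynaptic spike on a Bernoulli
($P_{syn}$) digraph. With $P_{syn} = 1$ it reproduces the shared-trace
simulation spike for spike; at $P_{syn} = 0.1$, $N = 1000$ the time-mean
conductances agree within 5%.

**Scaling N.** The conductance drive carries an explicit factor $N$, so
changing $N$ at fixed $\bar g_{peak}$ changes the total coupling
$G = \bar g_{peak} P_{syn} N$ — a different macroscopic model, not a
finite-size approximation of the same one. Every scaled-down or
N-swept computation in the package therefore holds $G$ at its reference
value $0.0214 \times 0.1 \times 3000 = 6.42$ by rescaling
$\bar g_{peak} \propto 1/N$. Under that convention the post-transient
fluctuation of $g_{syn}$ in a stationary regime scales as $N^{-1/2}$
(measured log–log slope $\approx -0.5$ over $N = 500$–$4000$); without
it the slope is positive, because growing $N$ literally strengthens the
feedback loop.

## Stability analysis and regime classification

`find_equilibrium()` runs damped Newton iteration on the 5-real-vector
$(\mathrm{Re}Z, \mathrm{Im}Z, \mathrm{Re}\kappa, \mathrm{Im}\kappa,
g_{syn})$ with a central-difference Jacobian (relative step $10^{-6}$),
starting from the end of a forward integration — the physically reached
branch — with a coarse multi-start fallback. A point is *oscillatory*
when the leading eigenvalue real part is positive: the equilibrium has
lost stability through a Hopf bifurcation and the rate $A(t)$ settles on
a limit cycle whose frequency at onset is $\mathrm{Im}\,\lambda/2\pi$,
in the gamma band throughout the studied region.

`hopf_locus_1d()` brackets sign changes of the leading real part on a
parameter grid and bisects each bracket, warm-starting Newton along the
way; `trace_hopf_curve_2d()` repeats this per slice and chains roots
into branches by nearest-neighbor continuation (tolerant of re-entrant,
closed-loop boundaries, which simply appear as two roots per slice).
Grid-scan-plus-bisection was chosen over pseudo-arclength continuation:
it is robust to closed loops and easy to test, at the cost of missing
boundary folds between grid slices.

Two numerical caveats, both visible in the code and tests:

* When the $\kappa$ correction drives the closed-form rate negative, the
  conductance drive clips it at zero (flagged via the `clipped`
  attribute). A *converged equilibrium with clipped zero rate under
  suprathreshold drive* is a truncation artifact, and the area scan
  rejects it and falls back to trajectory classification.
* Near full synchrony ($|Z|$ close to 1, $Z$ near $-1$) Newton may fail;
  `classify_state()` then falls back to long integration with the
  amplitude criterion: peak-to-trough of $A(t)$ over the last 500 ms
  above 1% of its mean (configurable) declares oscillation. For *noisy
  finite-network* traces the same idea uses the robust 5–95% quantile
  excursion and a threshold of 1.0: at $N = 1000$ measured stationary
  points sit at 0.3–0.4 (the $N^{-1/2}$ fluctuation floor, resonantly
  amplified near the boundary) while limit cycles exceed 2.

The mode hierarchy deserves its own caveat: with noise, hard zero
closure above mode $J$ produces spurious strongly unstable truncation
eigenvalues, so the hierarchy is *not* integrated to find equilibria.
Instead `hierarchy_equilibrium()` exploits that the hierarchy is linear
in the modes at fixed conductance: solve $M(g)Z = -b(g)$ and close the
loop with a one-dimensional root in $g$ — exact and fast. Mode
amplitudes decay like $|Z_1|^j$ with $|Z_1| \approx 0.88$ at the
operating points studied, so equilibrium rates are converged to
$\sim10^{-10}$ by $J = 64$ (the default; $J=64$ vs $96$ agree below
$10^{-8}$, $J = 32$ is about $5\times10^{-7}$ away).

At the reference operating point ($\eta = 1.2$, $\Delta = 0.05$,
$V_{syn} = -56.5$, $P_{syn} = 0.1$) the two-cumulant equilibrium rate
deviates from the hierarchy by $1.5\times10^{-8}$, $2.8\times10^{-7}$,
$5.0\times10^{-6}$ and $8.7\times10^{-5}$ (relative) at
$\sigma = 0.02, 0.05, 0.1, 0.2$ — monotone and $\propto\sigma^4$,
exactly the footprint of the neglected third cumulant. This is why the
studied noise range stops at $\sigma \approx 0.25$.

## Spectral pipeline

`psd()` is a plain rectangular-window periodogram of the mean-removed
post-transient $g_{syn}$ trace, normalized so that
$\sum \mathrm{psd} \cdot df$ equals the variance exactly (Parseval,
asserted at $10^{-10}$). Gamma-band power integrates the density over
30–200 Hz by the trapezoid rule *first*, and then applies the
compressive transform $P'_\gamma = \ln(10^4 P_\gamma + 1)$; the
alternative reading (transform per-bin, then integrate) was rejected
because the transform of an already-integrated band power is the only
order under which $P_\gamma = 0 \mapsto P'_\gamma = 0$ and single-tone
calibration stays exact. `center_frequency()` is the band argmax with
three-point parabolic refinement, and increases monotonically with
$V_{syn}$ along the oscillatory slice. `heatmap_scan()` runs one seeded
simulation per grid cell (child seeds per cell, so the scan is
order-independent and reproducible) and pairs the $P'_\gamma$ matrix
with the macroscopic classification of the same grid.

## What the tests do and do not show

The synthetic-data generator *is* the microscopic simulator: all inputs
are parameter sets, and every figure-level claim is checked by
regenerating the data. Test problem sizes are deliberately desk-scale —
$N$ = 800–1000 for 1.2–1.5 s in classification and heatmap checks,
$N \le 4000$ in the scaling study, coarse 5×5 to 13×8 parameter grids —
chosen so the whole suite replays the qualitative regime structure in
minutes; the same functions run the full $N = 3000$, dense-grid versions
by changing the configuration. Passing tests demonstrate internal
consistency of the two description levels and of the printed constants;
they do not, of course, validate the MT model itself against
physiological recordings, nor explore outside the studied parameter
window ($\Delta \approx 0.015$–0.08, $\sigma \le 0.25$, $V_{syn}$
between roughly $-58$ and $-50$ mV).

One reproducibility caveat is worth stating openly. On the slice
$V_{syn} = -56.5$, $P_{syn} = 0.1$, $\sigma = 0.1$, this implementation
puts the Hopf drive at $\eta \approx 1.404$ for $\Delta = 0.04$ and
$\eta \approx 1.531$ for $\Delta = 0.05$. The marked reference drive
$\eta = 1.59$ therefore falls on the *oscillatory* side for both
heterogeneity values, while the source regime diagrams place it between
the two boundaries (stationary for $\Delta = 0.05$). The package's two
levels agree with each other at that point — the $N = 3000$ simulation
oscillates strongly at both $\Delta$ values, matching the eigenvalue
analysis — and the stabilizing *direction* of heterogeneity (boundary
moving right with $\Delta$, oscillatory area shrinking) is reproduced
throughout; only the absolute position of the $\Delta = 0.05$ boundary
disagrees. All cross-checks (independent OA integrator, exact mode
hierarchy, conjugate-variant exclusion, two independent simulation
routes) point to the printed equations and constants simply not placing
that boundary where the diagrams draw it.

## Worked example

```{r example, eval = FALSE}
library(mtgamma)

p <- mt_params()                 # reference operating point
find_equilibrium(p)              # oscillatory: max Re lambda = +0.0057

r <- simulate_network(mt_params(N = 1000, g_peak = 0.0642),
                      mt_sim_config(T_total = 1500, T_discard = 500, seed = 1))
gamma_power(psd(r$g_syn, 0.01))  # band power of the conductance rhythm
```

The command-line interface (`inst/cli/mtgamma.R`) exposes
`simulate-micro`, `simulate-macro`, `hopf-curve`, `heatmap` and
`validate` over flat YAML configurations; every run writes a
`manifest.yaml` from which its outputs are byte-reproducible.
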