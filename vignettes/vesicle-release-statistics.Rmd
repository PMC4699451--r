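---
title: "Vesicle transport and the statistics of sustained release"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vesicle transport and the statistics of sustained release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vesiflux)
```

## The model

During the sustained phase of exocytosis the pools of pre-docked and primed
vesicles are depleted and each release requires a fresh vesicle to travel
from the reserve pool to the membrane. Transport is slow (seconds) compared
with docking, priming and fusion (tens of milliseconds), so the sequence of
release times — a point process extracted from an amperometric recording —
carries information about the transport mechanism. `vesiflux` couples a
mechanistic simulator of that transport to the statistical machinery needed
to classify the resulting spike trains.

### Transport simulator

Vesicles are hard spheres of radius $r$ performing overdamped Langevin
motion in a cuboid $L_x \times L_y \times L_z$ that represents the
sub-membrane active zone. Per axis and time step the Euler–Maruyama update
is

$$\Delta x = \mu F \,\mathrm{d}t + \sqrt{2 D\,\mathrm{d}t}\;\xi,\qquad
\xi \sim \mathcal N(0,1),$$

with mobility $\mu = D/(k_B T)$ (Einstein relation). Five faces reflect
specularly (applied to the radius-inset planes so the *surface* of the
sphere touches the wall); the sixth face, $y = 0$, is the membrane: a
vesicle whose centre comes within one radius of it is recorded as a release
event and replaced at a uniformly drawn non-overlapping position, keeping
the vesicle count constant. Overlapping pairs after a step are pushed apart
symmetrically along their centre line to contact distance $2r$ (up to 10
sweeps); because the dynamics is overdamped there are no velocities to
exchange, so non-penetration is the whole content of a "collision". The
optional membrane-directed force is harmonic, $F_y = -\alpha (y - y_0)$
with $y_0 = 0$, acting over the whole box depth, and $F_x = F_z = 0$.

Default physical parameters are the active-zone conditions the package is
built around: $D = 3.22\times10^{-14}\,\mathrm{m^2\,s^{-1}}$, $T = 296$ K,
$r = 150$ nm, density 2.09 vesicles/μm³ in a $4.4 \times 1 \times 4.4$ μm
box, giving $n = \mathrm{round}(2.09 \cdot 19.36) = 40$ vesicles, and
$\alpha = 1.275\times10^{-13}$ N/m for the directed-transport variant.

Numerical choices:

* **Time step.** Default $\mathrm{d}t = 1$ ms, giving an rms step of
  $\sqrt{2D\,\mathrm{d}t} \approx 8$ nm $\ll r$; the constructor rejects
  any $\mathrm{d}t$ whose rms step exceeds $r/3$. Halving
  $\mathrm{d}t$ moves the mean interspike time by under 5 % (tested); the
  residual discretization bias is the usual boundary-shift effect of
  checking absorption only at step ends, about $0.58\sqrt{2D\,\mathrm{d}t}$
  of effective extra travel, i.e. ~1–2 % on the mean first-passage time.
* **Event timestamps** are the end of the step in which contact occurs; if
  several vesicles arrive in one step their events are spread evenly across
  that step so event times stay strictly increasing (well under 1 % of
  events at the default step).
* **Noise convention.** The per-axis step variance $2D\,\mathrm{d}t$ is the
  standard choice and the default. Because the coupling between friction,
  noise amplitude and $D$ is the single most convention-sensitive part of
  any overdamped integrator, a `noise_convention = "halved"` switch with
  per-axis variance $D\,\mathrm{d}t$ (the literal reading of a noise
  coupling $\sigma/\gamma = \sqrt D$) is provided; it halves the effective
  diffusivity and thus doubles all transport times.
* **Replacement.** "A randomly chosen position" is ambiguous; the default
  re-inserts uniformly over the inset cuboid, and a `far_wall` option
  re-inserts on the face opposite the membrane. The choice shifts the mean
  interspike time (far-wall cycles are roughly 3/2 of uniform ones, since
  $L^2/2D$ replaces $L^2/3D$) but not the qualitative statistics.
* **Determinism.** All randomness, including inside the compiled core, is
  drawn from R's RNG, so a `set.seed()`/`seed =` call makes entire
  simulations bit-reproducible.

### What the free-Brownian model must produce

With no potential, each vesicle independently performs a renewal cycle:
uniform restart, then first passage to the membrane through an interval of
effective length $L_\mathrm{eff} = L_y - 2r = 0.7$ μm (absorbing at one
radius, reflecting at the opposite inset face). The closed-form mean
first-passage time from a uniform start,

$$\langle T\rangle = \frac{L_\mathrm{eff}^2}{3D} \approx 5.07\ \mathrm{s},$$

is used as an oracle in the acceptance suite (the simulator reproduces it
to within its ~1–2 % discretization bias). Forty independent cycles pool to
an event rate of $n/\langle T\rangle \approx 7.9\ \mathrm{s^{-1}}$, i.e. a
mean interspike time of about **0.13 s**, and — by the superposition
(Palm–Khintchine) limit — to near-Poisson pooled interspike statistics
regardless of how regular each vesicle's cycle is. Two consequences are
worth stating plainly, because they bound what this class of model can do:

1. The pooled interspike mean is pinned to $\langle T\rangle/n$. Reported
   values of order 0.6–0.7 s for nominally these parameters correspond to
   an effective $\langle T\rangle/n$ five-fold larger and are not
   reachable from the stated $D$, box and density under any step-variance
   convention within a factor of two; the package reports what its stated
   parameters actually give.
2. A pooled train of ~40 independent renewal sources cannot have a gamma
   shape parameter far above 1: superposition drives the pooled interval
   distribution toward exponential even when each source is strongly
   regular (we measure $p \approx 1.0$–$1.2$ at drift rates up to
   5 s⁻¹). Clearly gamma-shaped pooled statistics ($p \approx 1.6$) require
   few effective sources — e.g. one to four transport "lanes" — or a
   mechanism that synchronizes vesicles. Relatedly, with Einstein mobility
   the default $\alpha$ gives a drift relaxation rate
   $\alpha D/(k_B T) \approx 10^{-6}\,\mathrm{s^{-1}}$ — dynamically inert
   over a 1 μm box — so the shipped harmonic variant behaves like the free
   one; a physically *effective* harmonic force at this geometry needs
   $\alpha$ of order $10^{-7}$ N/m (relaxation ~1 s⁻¹, Boltzmann layer
   $\sqrt{D/k_\mathrm{drift}} \approx 0.18$ μm).

The slight *over*dispersion the free model does produce (shape ~0.85–0.9,
count dispersion ~1.2) is real physics of the uniform-replacement rule:
restarts that happen to land near the membrane re-fire quickly, which
fattens the short-interval end of the pooled distribution.

### Rate estimation and time-rescaling

The release rate is estimated by the density-function method: each spike is
replaced by a unit-mass Gaussian kernel,
$\lambda(t) = \sum_n \omega(t - t_n)$. The bandwidth is the kernel standard
deviation; the default 10 s suits trains of several hundred spikes over
several hundred seconds at ~1 Hz (the bandwidth must be small against the
rate's variation scale but large against the mean interspike). No boundary
correction is applied, so $\int_0^T\lambda \le N$ with only edge leakage
missing; rescaled means inherit a bias of order (bandwidth/duration), which
is why short test runs use proportionally smaller bandwidths. Statistics
derived after rescaling should be checked for bandwidth sensitivity rather
than assumed immune; the unit-mean invariant (below) is the first such
check.

The cumulative intensity $\Lambda(t) = \int_0^t \lambda$ (trapezoid rule on
the grid, exact partial-cell handling off-grid) rescales event times,
$\tau_i = \Lambda(t_i)$, $u_i = \Lambda(t_i) - \Lambda(t_{i-1})$. Rescaling
a train by its own estimated rate gives $\mathrm{mean}(u) = 1$ within 5 %
(asserted for simulator output, renewal trains and logistic-rate trains);
rescaling an inhomogeneous-Poisson train by its *true* rate gives
$u_i \sim \mathrm{Exp}(1)$ (Kolmogorov–Smirnov check). The inverse map
$\Lambda^{-1}$ (monotone linear interpolation on the same grid) round-trips
to $<10^{-6}$ on a 0.01 s grid and is what the synthetic generator uses.

Decaying rates are summarized by a logistic fit
$r(t) = r_0/(1+e^{-\beta_r (t-\mu_r)}) + r_f$ with the sign of $\beta_r$
free (decays have $\beta_r < 0$). The logistic is multimodal in its
parameters, so the optimizer (Levenberg–Marquardt) is started from a small
deterministic grid: amplitude/offset from the rate range, midpoint from the
first and last half-range crossings plus the grid midpoint, slope magnitude
from the quartile-crossing spread at three scales, sign from the end-to-end
slope; the lowest-SSE solution wins. A kernel estimate can wobble around
the half level, and a single midpoint start occasionally strands the fit in
a degenerate near-linear basin — the multi-start removes that failure mode.

### Histograms, candidate models, fitting

Interspike histograms use the prescribed bin width
$h = (\mu + 2.85\sigma)/\sqrt N$ for $N < 1000$ spikes and the scaled
Scott blend $h = (\mu+2.85\sigma)\left(\tfrac1{2\sqrt N} +
\tfrac1{2N^{1/3}}\right)$ for larger trains; count histograms use window
$\Delta T = 4\mu$ (and $\bar\tau = 4.0$ after rescaling). Bins are
right-closed from zero; the trailing partial count window is discarded so
all counts are identically distributed.

The model families are the exponential density and Poisson pmf (purely
random release) and the gamma density with the gamma-count pmf
$P(k) = G(pk, \beta T) - G(pk+p, \beta T)$, $\beta = 1/\theta$, plus a
log-normal alternative. $G$ is the regularized lower incomplete gamma;
the convention $G(0, x) = 1$ (which `pgamma(x, shape = 0)` already obeys)
makes the pmf telescope to total mass 1 and reduces it *exactly* to the
Poisson pmf at $p = 1$ — both identities are asserted to $10^{-12}$.
One caveat is documented rather than hidden: the gamma-count law describes
counts in a window opened at an event (an ordinary renewal process), while
measured windows are stationary; for $p \ne 1$ the two means differ by a
bounded start-of-window correction of order $(1 - \mathrm{CV}^2)/2$ counts.

Fits minimize the unweighted SSE between the model curve evaluated at bin
centres (pmf at integer counts) and the density-normalized histogram,
keeping empty bins (dropping them biases the tails). Maximum likelihood
would be the textbook estimator, but histogram least squares is what the
reported quantities are defined by, so MLE appears only as a cross-check in
tests. Starts are moment estimates ($p_0 = \mu^2/\sigma^2$,
$\theta_0 = \sigma^2/\mu$); the gamma families also try the nested
exponential-equivalent start ($p = 1$) and keep the lower-SSE solution, so
the gamma fit can never do worse than the Poisson one on the same data.
Fit quality is $R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$, clamped to $[0,1]$
with a warning flag. `combined_fit` shares one parameter set between the
interspike and count histograms (both density-normalized, so the two
residual blocks are commensurate); `model_report` runs the whole chain and
reports both the per-histogram and the combined fits, the combined one
being the headline number.

### Docking-to-fusion lags

Release = arrival + an independent lag $\Delta t_\mathrm{fus}$.
`sampler_from_histogram` turns an empirical lag histogram into a continuous
density by closed-form convolution of each bin with a Gaussian of standard
deviation 0.2 bin widths; smoothing mass that leaks below zero is folded
back across the origin so each bin keeps its probability mass. The default
`empirical_like` family is a shifted generalized-gamma on support
10–260 ms with its mode at 18 ms — a parametric stand-in (synthetic, not
measured) for published SNARE docking-to-fusion lag histograms whose
numerical values are not available; gamma, exponential, a deliberately
bimodal "arbitrary" shape, a constant and a zero family are included for
robustness checks. Sampling is inverse-transform on the tabulated cdf.

Adding lags re-sorts the release times. The interspike *mean* is protected
by an exact telescoping bound,
$|\Delta\bar{\delta t}| \le \max(\Delta t_\mathrm{fus})/(N-1)$, which holds
even with re-sorting and is asserted on simulated data. The interspike
*variance* grows by $2\,\mathrm{Var}(\Delta t_\mathrm{fus})$ exactly when
no events reorder; each reordering claws back a piece of order
(lag × interspike), so on trains with appreciable short-interval mass the
realized inflation sits below the $2\,\mathrm{Var}$ ceiling (both regimes
are tested). When the lag support is 1–2 orders of magnitude below the
interspike scale — the regime the fusion argument is about — the fitted
gamma shape moves by well under 0.15 across all lag families, and the train
stays clearly non-Poisson.

### Synthetic data generator

The generator exists so every pipeline stage has a ground truth. Its fixed
study conditions emulate a single sustained-release recording: gamma
interspikes with shape $p = 1.6$ mapped through the inverse cumulative
intensity of a logistic rate with $r_0 = 2$ Hz, $r_f = 0.2$ Hz,
$\beta_r = -0.05\ \mathrm{s^{-1}}$, $\mu_r = 400$ s (a ~7-minute plateau,
then an S-shaped decay; mean rate inside the realistic 0.6–2.5 Hz band) and
$n = 900$ spikes. The end-to-end check — generate, estimate the rate, fit
the logistic, rescale, combined-fit — recovers $p$ within ±0.2 and $\mu_r$
within ±10 % on every one of ten fixed seeds.

Synthetic amperometric traces are baseline + slow sinusoidal drift +
Gaussian noise of configurable RMS (default 0.3 pA, within the realistic
0.2–0.5 pA floor) with one template peak per spike (instantaneous or short
linear rise, single-exponential decay). The detector smooths with a moving
average, subtracts a rolling-median baseline, estimates the noise RMS
robustly (MAD of the *raw* baseline-subtracted trace — the 3×RMS criterion
refers to the baseline noise, not the quieter smoothed residual) and keeps
runs of ≥3 supra-threshold samples, returning the local-maximum times. It
recovers ≥99 % of 10×RMS peaks at sparse spacing and rejects 2×RMS peaks;
it is validated only against its own synthetic traces. The generator does
not emulate amplitude/charge marks, overlapping-peak interference,
electrode drift nonstationarity, or "foot" signals — so passing tests say
the *pipeline* is correct, not that the detector is field-ready for noisy
real recordings.

### Problem sizes and reproducibility

The shipped test suite runs the full-size studies it makes claims about:
16 000 events for the free-Brownian run, 4 500 for the harmonic one, 15
fusion-lag replicates, 6 000 single-vesicle cycles for the first-passage
oracle, and $10^5$-draw Monte-Carlo checks for distributional identities —
about one to two minutes of compute in total. `scripts/acceptance.R`
recomputes every headline number from scratch with one seed argument
driving all random streams.

### Known limitations

* The cuboid-with-replacement geometry is a caricature of the cell cortex:
  no cytoskeletal obstacles, no hydrodynamics, no size polydispersity, no
  calcium dynamics, and a flat membrane with every contact counted as
  fusion (no dead-end docking).
* As derived above, the pooled statistics of ~40 independent vesicles are
  structurally near-Poisson; reproducing strongly gamma-shaped pooled
  trains requires different effective parameters (fewer sources, stronger
  coupling) than the shipped defaults, and the package makes that explicit
  rather than adjusting constants to force agreement.
* The density-function rate estimator has no boundary correction, and
  rescaled statistics inherit mild bandwidth sensitivity.
* The gamma-count law is an ordinary-renewal count model applied to
  stationary windows; for $p$ near 1.6 the mean offset is ~0.2 counts on a
  4-interspike window.
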