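# vesiflux

Sustained exocytosis in neuroendocrine (chromaffin) cells releases
catecholamines one vesicle at a time; an amperometric electrode sees each
fusion as a current spike, so a recording becomes a point process of release
times. In the sustained phase release is rate-limited by vesicle *transport*
from the reserve pool to the membrane, which makes the interspike statistics
a window into how vesicles move. `vesiflux` implements both halves of that
argument in one package:

* a **stochastic transport simulator** — overdamped Langevin dynamics of
  hard-sphere vesicles in a cuboidal sub-membrane volume with reflecting
  walls, an absorbing membrane face (each contact = one release event,
  vesicle replaced to keep the count constant), and an optional attractive
  harmonic force toward the membrane;
* a **point-process statistics pipeline** — kernel ("density-function")
  estimation of the time-varying release rate λ(t), logistic-rate fits,
  the time-rescaling transformation τ = Λ(t) = ∫₀ᵗ λ(s) ds that maps any
  train to unit rate, interspike-time and frequency-count histograms with
  prescribed bin-width rules, and least-squares fits of the candidate
  models: exponential/Poisson (purely random release) versus
  gamma/gamma-count (regular, history-dependent release), plus log-normal.

The discriminating statistic is the gamma shape parameter *p* of the
interspike density f(δt) = δt^(p−1) e^(−δt/θ) / (θ^p Γ(p)) together with the
count dispersion index σ²/μ: a Poisson train has p = 1 and σ²/μ = 1, while
directed (membrane-biased) transport with few effective sources produces
p > 1 and underdispersed counts. Window counts under gamma interspikes
follow the gamma-count law P(k) = G(pk, βT) − G(pk+p, βT) with
G the regularized lower incomplete gamma and β = 1/θ.

A third module superimposes docking-to-fusion lag times (inverse-transform
sampling from a tabulated or histogram-derived density) on simulated
arrivals, and a synthetic-data module generates gamma-renewal trains under a
logistic decaying rate plus amperometric current traces with a 3×RMS
threshold spike detector, so the whole pipeline is testable end to end
without experimental recordings.

## Worked example

Generate a synthetic recording (900 spikes, gamma shape 1.6, a ~7-minute
rate plateau decaying logistically), recover the rate, rescale, and compare
the Poisson and gamma descriptions:

```r
library(vesiflux)

s <- generate_inhomogeneous_sequence(logistic_rate_params(2, 0.2, -0.05, 400),
                                     p = 1.6, n_spikes = 900, seed = 42)
s
#> spike_sequence: 900 events on (0, 417.553]  [logistic-gamma synthetic (p=1.6)]

rate <- estimate_rate(s, bandwidth = 10)
fit_logistic_rate(rate)
#> logistic rate: r0=2.242 /s, rf=0 /s, beta_r=-0.04453 /s, mu_r=406.4 s

resc <- rescale_sequence(s, rate)
resc
#> rescaled_sequence: 900 events, mean rescaled interspike 0.9864

model_report(as_spike_sequence(resc), window = 4)
#> model_report: 900 spikes, ISI mean 0.9864, dispersion 0.6021
#>   gamma fit: p=1.523, theta=0.666 (R^2 0.984)
#>   exponential fit: lambda=0.8031 (R^2 0.883)
```

The report says what it should: the estimated midpoint (406 s) and decay
sign match the generating rate; rescaling normalizes the mean interspike to
≈ 1; the gamma model recovers p ≈ 1.5–1.6 with a far better R² than the
exponential fit; and the counts are underdispersed (σ²/μ ≈ 0.60), i.e. the
train is clearly not Poisson. The shared-parameter fit of both histograms at
once (`combined_fit`, reported as `gamma_pair`) gives p = 1.54 against the
generating 1.6.

Running the transport simulator instead (40 vesicles, D = 3.22e-14 m²/s,
4.4 × 1 × 4.4 μm box, no potential):

```r
sim <- run_simulation(sim_config(stop_events = 2000), seed = 42)
model_report(sim)
#> model_report: 2000 spikes, ISI mean 0.1077, dispersion 1.203
#>   gamma fit: p=0.7898, theta=0.1308 (R^2 0.996)
#>   exponential fit: lambda=10.44 (R^2 0.981)
```

Free Brownian transport pools 40 independent first-passage cycles into a
near-exponential interspike distribution (p ≈ 0.8–0.9) — see the methods
vignette (`vignettes/vesicle-release-statistics.Rmd`) for why the pooled
rate is set by the mean first-passage time L²/(3D) divided by the vesicle
count, and for a frank discussion of which published simulation values this
model does and does not reproduce from its stated parameters.

The three headline studies are wrapped as one-call experiments:

```r
rep <- run_experiment("harmonic", seed = 1)   # attractive potential on
report_json(rep)                              # JSON-ready, byte-reproducible
```

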