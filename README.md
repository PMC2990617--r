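# hyperflux

Kinetic analysis of hyperpolarised ¹³C magnetic resonance spectroscopy
for detecting tumour treatment response — with a fully seeded synthetic
data generator, so the entire pipeline is testable without scanner data.

## Who this is for

Dissolution-DNP experiments inject a hyperpolarised ¹³C-labelled
substrate and watch its enzymatic conversion in real time, one spectrum
per second, while the polarisation decays with T₁ (~30 s). Two readouts
dominate early-response studies in oncology:

* the apparent rate constant **k_P** of ¹³C label exchange between
  [1-¹³C]pyruvate and lactate (LDH-catalysed), which *falls* after
  genotoxic treatment as the NAD(H) pool is depleted, and
* the fumarate→malate conversion (fumarase), visible only when cell
  membranes are compromised: the rate constant **k_F**, or the
  **malate/fumarate peak ratio** in a single spectrum ~20 s
  post-injection, *rises* with necrosis.

This package is for analysts of such dynamic MRS data and for
methodologists who need a controlled test bed: it implements the forward
model, the fits, the spectral quantification and the cohort statistics,
plus a generator that emulates the cell-suspension and xenograft
experiments end to end.

## The model

Longitudinal magnetisation of the substrate/product pair follows the
exchange-coupled Bloch equations

    d/dt [Ms, Mp]ᵀ = [ -(k_fwd + R1s)   k_rev          ] [Ms]
                     [  k_fwd          -(k_rev + R1p)  ] [Mp]

solved in closed form (`evolveClosedForm`). Acquisition
(`simulateAcquisition`) applies a pulse of flip angle θ every repetition
time: signal = sin θ · Mz per pool, then Mz ← cos θ · Mz. Rate constants
are estimated by joint two-channel nonlinear least squares
(`fitExchangeRate`, Levenberg–Marquardt, log-parameterised, multi-start),
with relaxation rates fixed (default R1 = 1/30 s⁻¹). Spectra are sums of
Lorentzians quantified by window integration with analytic tail and
overlap corrections (`quantifyPeaks`); the combined malate C1+C4 area
over fumarate gives the necrosis ratio. Group comparisons use an exact
(enumerated, tie-aware) Mann–Whitney test.

See `vignettes/hyperflux-methods.Rmd` for assumptions, parameter
defaults and their rationale, and known limitations.

## Worked example

Simulate an untreated-tumour acquisition and recover its rate constant:

```r
library(hyperflux)
params <- ExchangeParameters(kFwd = 0.075)        # k_P, s^-1
scheme <- tumourScheme()                          # 5 deg, 1 s, 128 transients
traj   <- simulateAcquisition(params, scheme)
fitExchangeRate(asPeakSeries(traj), scheme)
#> FitResult (unidirectional): k = 0.075 +/- NA s^-1
#>   m0 = 1, residual norm = 9.792e-21
```

The fit returns the generating 0.075 s⁻¹ exactly (the NA standard error
is honest: at a machine-precision fit the noise-scaled covariance is
degenerate). Now a full synthetic treatment study — four cell batches
per group, 10% biological CV, 2% observation noise:

```r
coh  <- generateCohort(cellSchedule(), nPerGroup = 4, seed = 1)
fits <- fitCohort(coh, cellScheme())
print(buildReport(coh, fits))
#> Group untreated:
#>   kP             0.077 +/- 0.006 (n=4)
#>   nadh           1000 +/- 9.7 (n=4)
#> ...
#> 96h vs untreated:
#>   kP             -72% change (0.28-fold), P = 0.0286 *
#>   kF             +3171% change (33-fold), P = 0.0286 *
#>   necroticFrac   +1246% change (13-fold), P = 0.0286 *
#>   nadh           -89% change (0.11-fold), P = 0.0286 *
```

Read: by 96 h post-doxorubicin the pyruvate–lactate exchange constant
has fallen 72% and NADH autofluorescence 89%, while fumarate→malate
flux has appeared with the necrotic fraction — the signature of a
responding tumour model. P = 0.0286 is the smallest two-sided p-value an
exact 4-vs-4 rank-sum test can produce.

A thin CLI wraps the same functions
(`inst/scripts/hyperflux simulate|cohort|fit|ratio|report`); every run
is reproducible from its config file and seed.

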