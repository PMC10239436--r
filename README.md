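# degronKinetics

Quantitative analysis of **degron-tunable CRISPR repressor systems** from
flow-cytometry data. The package is written for groups engineering
ligand-titratable gene repression — a dCas9/Cas13d repressor fused to a
degron (e.g. FKBP12^F36V^, degraded on dTAG-13 binding) — who need to turn
single-cell fluorescence measurements into the numbers that characterise
such a system:

* **Flow preprocessing** — FCS 3.0/3.1 and CSV event tables; reusable
  live (scatter-percentile) and singlet (robust FSC-H~FSC-A band) gates
  with explicit, re-applicable coordinates; median fluorescence intensity
  (MFI) with autofluorescence background subtraction; fold changes and
  0–1 time-course scaling.
* **Degron metrics** — leakiness (100 − A), efficiency (100 − B) and
  dynamic range (fold separation of stabilised/destabilised states) from
  tRFP/tBFP ratios relative to a no-degron control.
* **Repression kinetics** — the ODE model
  `dR/dt = βR − αR·R`, `dT/dt = αT·(f(R(t − Δt)) − T)` with
  `f(R) = 1/(1 + (R/K)^n)`; closed-form repressor fits parameterised by
  the half-time (`R(t) = 1 − 2^(−t/t½)` up, `R(t) = exp(−αR+·t)` down);
  target degradation rate from `T(t) = 1 + (T0 − 1)·exp(−αT·t)`; and the
  repressor-to-target delay Δt by a mean-absolute-error grid search over
  simulated trajectories.
* **Hill dose–response** — four-parameter fits of target fold change
  against regulator fold change X:
  `Tmin + (1 − Tmin)/(1 + (X½/X)^n)` for activated targets (ceiling
  fixed at 1) and `Tmax − (Tmax − 1)/(1 + (X½/X)^n)` for repressed
  targets (floor fixed at 1), including the colony-phenotype variant.
* **Modality testing** — analog (unimodal) vs digital (bimodal)
  repression classified by the Hall–York calibrated critical-bandwidth
  test: log10 transform, replicates merged, mode locations bounded to
  the 5th–95th percentile, smoothed bootstrap with a mandatory seed.
* **Synthetic data** — seeded generators for event populations (with
  doublets and autofluorescence), analog/digital regimes, model-generated
  kinetic time courses and Hill titration tables, so the entire pipeline
  is testable offline.
* **Pipeline** — `runPipeline()` executes a YAML-declared stage list with
  pre-flight validation and a deterministic JSON report; a thin CLI
  wrapper lives in `inst/scripts/pipeline.R`.

## Worked example

```r
library(degronKinetics)

## events -> gated population -> MFI
ev <- readEventTable(system.file("extdata", "example_events.csv",
                                 package = "degronKinetics"))
live    <- gateLiveCells(ev, 1, 99)     # kept 289 / 300 events (96.3%)
cells   <- applyGate(ev, live)
singlet <- gateSinglets(cells, 4)       # kept 278 / 289 events (96.2%)
cells   <- applyGate(cells, singlet)
computeMfi(cells, "mCherry-A")
#> [1] 3143.638

## repressor upregulation kinetics from a simulated 3-replicate course
m   <- KineticModel(tHalf = 7, alphaT = 0.036, K = 0.2, n = 2)
sim <- simulateTimecourse(m, "up", noiseCv = 0.05, seed = 1)
fitRepressorUp(sim$repressor)
#> RepressorFit (up): t1/2 = 7.043 +/- 0.207 h (alpha = 0.0984 1/h, n = 33 points)

## digital vs analog repression at matched intermediate levels
d <- simulateRegime("digital", rBar = 0.3, pOff = 0.5, nCells = 10000, seed = 1)
hallYorkTest(prepareDistribution(list(d$target)), nBoot = 500, seed = 2)
#> Hall-York modality test: h_crit = 0.9251, p = 0.001 (500 bootstraps, seed 2)
#>   decision at alpha = 0.01: multimodal
a <- simulateRegime("analog", rBar = 0.3, cv = 0.2, K = 0.3, n = 2,
                    nCells = 10000, seed = 1)
hallYorkTest(prepareDistribution(list(a$target)), nBoot = 500, seed = 2)
#> Hall-York modality test: h_crit = 0.02096, p = 0.8301 (500 bootstraps, seed 2)
#>   decision at alpha = 0.01: unimodal

## Hill dose-response of an activated target
tab <- simulateDoseResponse("activated", 0.55, 2, 0.05, seed = 3)
fitDoseResponse(tab)
#> HillFit (activated): [X]1/2 = 0.557 +/- 0.013, n = 1.89 +/- 0.077
#>   floor = 0.0421, ceiling = 1, R^2 = 0.9967 [ok]
```

The two modality verdicts illustrate the package's central biological
distinction: a bimodal (digital, KRAB-like) mixture is rejected as
unimodal at p < 0.01 while a graded (analog, HDAC4/Cas13d-like)
population of identical bulk MFI is not — a difference invisible to any
bulk measurement.

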