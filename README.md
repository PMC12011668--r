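# scintunmix

Per-crystal energy estimation for PET detectors that read **two
scintillators through one photosensor** — phoswich stacks and
metascintillators. When a 511 keV gamma-ray shares its energy between two
crystals with different light yields and decay times, the photosensor
records the *sum* of two bi-exponential pulses, and neither its amplitude
nor its integral maps to deposited energy any more. This package is for
detector physicists who want to study how well that mixture can be unmixed
back into per-crystal energies.

Each clean component follows

```
f(t) = E·LY/(τ_d − τ_r) · (exp(−t/τ_d) − exp(−t/τ_r)),   t ≥ 0,
```

so a mixed record is `y = A·x + N`: `A` holds one peak-normalized pulse
profile per crystal, `x` the per-crystal component amplitudes, `N` white
Gaussian noise. The package implements

* a **simulator** of digitized mixed events (1024 samples at 1 ns) with
  noise and leading-edge-trigger **time-walk**, plus ground-truth labels;
* the **pseudo-inverse estimator** `x̂ = (AᵀA)⁻¹Aᵀy` (the
  maximum-likelihood solution under white noise), with template building
  from averaged peak-normalized pulses;
* an **MLP estimator** (1024–256–256–2, ReLU) regressing the two
  per-crystal labels directly from the waveform;
* an **evaluation harness** scoring both by R² against ground truth over
  the twelve standard crystal pairings (BGO, LGSO, GAGG × EJ200, EJ228,
  EJ232, plus the three dense–dense pairs).

## Worked example

Simulate BGO–EJ200 mixtures with time-walk and 1 % noise, build empirical
templates from single-crystal calibration runs, and score both estimators
on the same validation events:

```r
library(scintunmix)

ds <- generate_dataset(c("BGO", "EJ200"), 2000, acquisition_config(seed = 42))
tm <- empirical_templates(c("BGO", "EJ200"), acquisition_config(seed = 43), 5000)
sp <- split_dataset(ds, 0.8, seed = 1)

est_pinv <- batch_estimate(tm, sp$validation, "integral")
evaluate_run(sp$validation, est_pinv, seed = 42)
#>        pair crystal method label_type r_squared n_events noise_sigma time_walk
#> 1 BGO-EJ200     BGO   pinv   integral 0.8872585      400   0.1345445      TRUE
#> 2 BGO-EJ200   EJ200   pinv   integral 0.9942298      400   0.1345445      TRUE

model <- train_ann(sp$train, sp$validation,
                   ann_config(epochs = 30, batch_size = 256, seed = 2), "integral")
evaluate_run(sp$validation, predict(model, sp$validation), seed = 42)
#>        pair crystal method label_type r_squared n_events noise_sigma time_walk
#> 1 BGO-EJ200     BGO    ann   integral 0.9997394      400   0.1345445      TRUE
#> 2 BGO-EJ200   EJ200    ann   integral 0.9998860      400   0.1345445      TRUE
```

(the `seed` column is elided above). Read: with trigger time-walk on, the
linear solve against a fixed template cannot absorb the amplitude-dependent
record misalignment — the dim, slow BGO component pays for the bright
plastic's misfit (R² ≈ 0.89) — while the network, which sees walked records
in training, recovers both labels at R² > 0.999. `benchmark_matrix()` runs this comparison over all twelve
pairings, both label types and several seeds; `time_walk_sweep()` shows
the pseudo-inverse degrading as the trigger threshold (hence the walk)
grows.

A thin command-line wrapper with `simulate`, `templates`, `estimate`,
`train-ann` and `benchmark` subcommands is installed at
`inst/cli/scintunmix.R`.

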