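# nmdarkinetics

Quantitative analysis of NMDA-receptor (NMDAR) gating and the cell-biology
assays that accompany whole-cell electrophysiology. The package is aimed at
ion-channel labs that estimate channel open probability from open-channel
blocker kinetics and quantify the downstream consequences of altered gating
— excitotoxic cell death and changes in receptor trafficking and dendritic
spine morphology.

## What it computes

The core estimator works from a four-state macroscopic gating scheme in
saturating agonist,

    D  <=[kd]/[kr]=>  C  <=[ko]/[kc]=>  O  --[kb·[B]]-->  B

(desensitized, closed, open, blocked), with the microscopic open
probability

    Po = ko / (ko + kc),      kc = 250 s^-1 (convention),
                              kb = 25 uM^-1 s^-1 (MK-801).

Given a recorded current trace with agonist and MK-801 application epochs,
`estimate_po()` measures the desensitization extent
`D = 1 - Imax/Ipeak` and onset time constant `tau_d`, fits the opening rate
`ko` by matching the simulated open-state decay to the observed blocking
onset, and reports `Po` with convergence diagnostics.

Around the core estimator:

* `simulate_scheme()` / `simulate_blocker_onset()` — stiff-capable ODE and
  matrix-exponential solutions of the gating scheme.
* `fit_exponential()`, `weighted_tau()`, `blocker_onset_tau()`,
  `memantine_kinetics()` — single/double-exponential trace decomposition
  with the amplitude-weighted time constant
  `tau_w = (tf·Af + ts·As)/(Af + As)`.
* `fit_hill()` / `fit_inhibition()` — Hill fits of agonist
  concentration–response (`I = Imax/(1 + (EC50/[A])^h)`) and antagonist
  inhibition (`I = 1/(1 + ([ant]/IC50)^h)`) curves, per-cell or pooled.
* `fit_two_gaussian()` / `classify_nuclei()` — EM fit of a two-component
  Gaussian mixture over nuclear areas and posterior classification of
  pyknotic (condensed) nuclei, as used in excitotoxicity assays.
* `surface_total_ratio()`, `colocalization_ratio()`, `classify_spine()` —
  background-corrected fluorescence ratio metrics and rule-based
  dendritic-spine classification (mushroom / stubby / thin / filopodia).
* `generate_trace()` and friends — synthetic-data generators that emulate
  the recording and imaging conditions (solution exchange ~17 ms, 5 kHz
  digitization, additive recording noise) with ground truth attached, so
  every stage is testable end to end.

## Worked example

```r
library(nmdarkinetics)

tr  <- generate_trace(po = 0.066, seed = 1)   # synthetic WT-like recording
fit <- estimate_po(tr)
fit
#> Open-probability estimate from blocking kinetics
#>   Po = 0.0655  (ko = 17.51 /s, kc = 250 /s)
#>   desensitization extent D = 0.411, tau_d = 0.5162 s
#>   residual norm 0.4184; converged: TRUE

blocker_onset_tau(tr)$tau_w      # weighted MK-801 onset time constant, s
#> [1] 1.036546
```

The trace was generated with a true `Po` of 0.066 (a typical wild-type
GluN1/GluN2A-like value), desensitization extent 0.4 and 2% recording
noise; the estimate recovers it within ~1%. The onset time constant
(~1.04 s at 1 µM MK-801) is the quantity that discriminates receptor
variants: higher-`Po` channels are blocked faster.

```r
s <- generate_dose_response(5.27, 1.20, response_type = "activation",
                            noise_sigma = 0.05, seed = 1)
fit_hill(s)
#> Hill activation fit: EC50 = 4.803 uM (se 0.436), h = 1.24 (se 0.115)
#>   Imax = 0.9877 (se 0.0258)

nu <- generate_nuclei(n = 2000, seed = 1)     # 30% pyknotic ground truth
gm <- fit_two_gaussian(nu, seed = 1)
classify_nuclei(gm, nu$areas)$pyknotic_fraction
#> [1] 0.3105
```

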