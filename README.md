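# crycycle

Kinetic modeling of the plant cryptochrome photocycle in R.

Arabidopsis cryptochromes (cry1, cry2) are blue-light photoreceptors whose
flavin (FAD) chromophore cycles through three redox states: oxidized
(FADox, the dark resting state), the neutral radical (FADH°, the putative
signaling or "lit" state), and fully reduced (FADH⁻). Blue light drives
FADox → FADH° at rate k₁ and blue/green light drives FADH° → FADH⁻ at rate
k₂, while both reduced states reoxidize in a light-independent,
oxygen-dependent manner (rates k₁b, k₂b). The population dynamics obey a
linear first-order system:

```
d[FADox]/dt  = −k1 [FADox] + k1b [FADH°] + k2b [FADH⁻]
d[FADH°]/dt  =  k1 [FADox] − (k2 + k1b) [FADH°]
d[FADH⁻]/dt  =  k2 [FADH°] − k2b [FADH⁻]
```

with [FADox] + [FADH°] + [FADH⁻] = 1. The light-driven rates are
proportional to the photon fluence rate, k = σI, where the photoconversion
cross section σ relates to the quantum yield φ and the extinction
coefficient ε by σ = 2.3 ε φ. `crycycle` provides:

* **kinetics** — the three-state ODE system, a fixed-step RK4 integrator,
  two-state closed forms, dark-reoxidation decay, half-lives, steady
  states;
* **spectra** — the two-wavelength Beer–Lambert bridge between absorbance
  (400–570 nm) and redox-state concentrations: `[FADox] = A(450) − A(560)`,
  `[FADH°] = 2 A(560)` under the half-extinction assumption
  ε_H(450) = ε_H(560) = ε_ox(450)/2, with FADH⁻ by conservation;
* **estimation** — Levenberg–Marquardt dark-reoxidation fits, the two-state
  (k₁) and three-state (k₂) inversion algorithms, through-origin
  dose-response fits k = σI, and quantum yields;
* **invivo** — the same machinery applied to biological readouts (hypocotyl
  length for cry1, cry2 protein level for cry2) mapped to FADH°
  concentration by an anchored affine inverse relation;
* **synthetic** — generators for spectral series, dose-response series, and
  in vivo readout series with known ground truth, for validation and
  Monte-Carlo recovery studies;
* **interface** — `run_pipeline()` plus a thin CLI (`inst/cli/crycycle`)
  and CSV/YAML/JSON round-tripping for reproducible runs.

## Worked example

Simulate a cry2-like experiment (20-s blue illuminations, dark recovery
over ~3 half-lives, 0.5% absorbance noise), then run the full analysis —
dark-reoxidation fit, per-fluence two-state inversion, dose-response fit,
quantum yield:

```r
library(crycycle)

cfg <- synthetic_config(noise_sd = 0.005, seed = 42)

## dark reoxidation: FADH° decay after the light is switched off
reox <- generate_reoxidation_series(cfg)
reox <- normalize_to_dark(reox, reox[[1]])
conc <- series_concentrations(reox[-1], tol = 0.05)
fit  <- fit_reoxidation(conc$time, conc$fadh_rad, species = "fadh_rad")
#> k1b = 0.00311 s^-1, half-life = 223 s, R2 = 0.997

## blue-light dose response: invert each spectrum to k1, fit k1 = sigma1 I1
blue <- generate_blue_dose_series(cfg)
blue <- normalize_to_dark(blue, blue[[1]])
bc   <- series_concentrations(blue[-1], tol = 0.05)
k1   <- sapply(seq_len(nrow(bc)), function(i)
  infer_k1(bc$fadh_rad[i], "fadh_rad", t_illum = 20, k1b = fit$k1b))
#> 0.00376 0.00799 0.01514 0.03202 0.06139   (s^-1, at I1 = 25...400)
cs   <- fit_cross_section(cfg$blue_fluences, k1)
quantum_yield(cs$sigma, cry_extinction("cry2"))
#> sigma1 = 1.547e-04 umol^-1 m^2 (R2 = 1.000), phi1 = 0.132
```

The generating parameters were σ₁ = 1.6e-4 µmol⁻¹ m² and k₁b = 0.003 s⁻¹
(φ₁ = 0.137); the recovered values differ only through the injected
measurement noise. The same steps run via the pipeline interface:

```r
run_pipeline(run_config("simulate", experiment = "blue_dose",
                        out = "blue", noise_sd = 0, k1b = 0.003))
run_pipeline(run_config("fit-blue", input = "blue.csv", out = "fit",
                        k1b = 0.003, receptor = "cry2"))
```

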