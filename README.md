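# ttdpa

Simulation and analysis of **transient triplet differential (TTD)
photoacoustic imaging** — a pump-probe scheme for background-free imaging of
phosphorescent contrast agents such as methylene-blue-conjugated
nanoparticles.

Intrinsic tissue chromophores (hemoglobin above all) generate strong
photoacoustic background at any single wavelength. A phosphorescent dye,
however, has a long-lived triplet state with its own absorption band. TTD
imaging acquires three measurements — a *pump* pulse at the dye's
ground-state peak (660 nm), a *probe* pulse at the triplet absorption peak
(840 nm) delayed by ~1 µs, and both pulses together — and forms

```
TTD = PA(pump+probe) − PA(pump) − PA(probe)
```

Non-phosphorescent chromophores contribute identically to the combined and
single-beam frames and cancel exactly; only the triplet-populated agent
survives the subtraction. The package provides:

* **Kinetics** — triplet pumping `Φ_ISC (1 − e^(−F/F_sat))`, monomer/dimer
  biexponential decay, Stern–Volmer oxygen quenching
  `1/τ_eff = 1/τ₀ + k_q·[O₂]`, and lifetime fitting (`fit_decay`).
* **Optics** — diffuse fluence `φ(z) = φ(0) e^(−μ_eff z)` with
  `μ_eff = √(3 μ_a (μ_a + μ_s'))`, and closed-form maximum imaging depth per
  beam (`max_ttd_depth`).
* **Synthetic data** — gridded phantoms with parametric chromophore spectra
  (dye, Hb/HbO₂, blue ink, gold nanoparticles, water), the linear PA forward
  model, pump/probe/pump+probe triples with seeded noise, the six-sample
  background series, a tumor accumulation time-lapse, and A-line waveform
  synthesis.
* **Recovery methods** — TTD extraction, nonnegative spectral unmixing at
  570/606/660 nm (in-package Lawson–Hanson NNLS), and the single-wavelength
  differential.
* **Metrics** — contrast-to-noise ratio, detection limit / sensitivity, ROI
  time-courses, parameter sweeps, and t-test sample comparisons.

## Worked example

Six tube phantoms — 2.0 mg/mL dye alone, dye in 5% blood, + 0.1% blue ink,
+ 5% gold nanoparticles, and two dye-free controls — measured with 5 noisy
repeats, then reduced by TTD extraction and by spectral unmixing:

```r
library(ttdpa)
cfg <- run_config(seed = 5, repeats = 5, output_dir = "results/backgrounds")
res <- run_experiment(cfg, "backgrounds")
res$ttd_ttests
#>          sample         mean      p_value stars
#>            MBNP 17.739567917           NA
#>      MBNP_blood 18.485136782 3.399624e-01
#>  MBNP_blood_ink 18.477786918 3.095988e-01
#>  MBNP_blood_GNP 17.923947148 6.687715e-01
#>           blood  0.002110523 4.025766e-07   ***
#>           water -0.002491270 4.040890e-07   ***
res$su_ttests
#>          sample         mean      p_value stars
#>            MBNP 22.493186102           NA
#>      MBNP_blood 23.418400423 3.502549e-01
#>  MBNP_blood_ink 52.094538580 3.394997e-05   ***
#>  MBNP_blood_GNP 22.509718088 9.754254e-01
#>           blood  0.007565939 4.292592e-07   ***
#>           water  0.005699482 4.291244e-07   ***
```

Reading: the TTD amplitude is statistically identical across all four
dye-containing samples regardless of background (p ≫ 0.01 against the
dye-only sample) and indistinguishable from zero for both controls —
background-free contrast. Spectral unmixing shows the characteristic
failure: the blue ink, spectrally collinear with the dye at the unmixing
wavelengths, inflates the estimated dye concentration from ~22.5 to ~52
(p < 0.001).

Penetration depth from the bundled representative tissue tables:

```r
skin <- read_tissue_csv(system.file("extdata", "tissue_skin_synthetic.csv",
                                    package = "ttdpa"))
max_ttd_depth(skin, pump_nm = 660, probe_nm = 840,
              min_pump = 1.6, min_probe = 2.7, surface_fluence = 20)
#> Max TTD imaging depth: 0.390 cm (limited by 660 nm)
#>   pump depth:  0.390 cm
#>   probe depth: 0.575 cm
```

The numbered scripts under `analysis/` run the full set of studies
(waveforms, kinetic sweeps, energy/depth, CNR and sensitivity, background
series, tumor time-lapse) and write their tables under `results/`.

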