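# tissuelight

Estimation of tissue optical properties from integrating-sphere
measurements, and the dosimetric quantities that follow from them.

Near-infrared laser procedures (photobiomodulation, photodynamic therapy,
transcranial stimulation) need the absorption coefficient μa and the
reduced scattering coefficient μs′ = μs(1−g) of the target tissue, in
cm⁻¹: together they set the optical penetration depth
δ = 1/√(3 μa (μa + μs′)) and the spread of the fluence rate at the tissue
surface. `tissuelight` is for experimentalists who measure diffuse
reflectance R_d and transmittance T_d of thin tissue slabs in a single
integrating sphere and want a tested chain from raw spectrometer traces to
transport coefficients and dose-relevant maps.

The package implements:

* **Two-flux (Kubelka–Munk) model** — forward slab solution
  R_d = sinh(SYD) / (X sinh(SYD) + Y cosh(SYD)),
  T_d = Y / (X sinh(SYD) + Y cosh(SYD)), with X = 1 + A/S, Y = √(X²−1),
  and the exact Kottler inversion X = (1 + R_d² − T_d²)/(2R_d),
  S = ln[(1 − R_d(X−Y))/T_d]/(YD), A = (X−1)S; conversion
  A = 2μa, S = ¾μs′ − ¼μa; penetration depth δ = 1/√(3 μa (μa+μs′)).
* **Spectrum reduction** — trapezoidal band integration at the 808 nm
  laser line and empty-sphere calibration (the empty-sphere transmission
  band is the 100% level), with replicate mean/rms summaries.
* **Synthetic-data generator** — integrating-sphere-like spectra with
  known ground truth: μs′ falling linearly from 37 to 9 cm⁻¹ (skull) and
  12 to 5.8 cm⁻¹ (skin) over 150–350 mW, constant μa, lognormal
  multiplicative noise.
* **Diffusion fluence solver** — steady-state
  μaφ − ∇·(D∇φ) = S with D = 1/(3(μa+μs′)) on a 2D surface grid, direct
  sparse solve, validated against the analytic Green's function
  φ(r) = S K₀(μ_eff r)/(2πD).
* **Photon Monte Carlo** (Rcpp) — single-slab hop–drop–spin transport with
  Henyey–Greenstein scattering, Fresnel boundaries, Russian roulette, and
  radially resolved diffuse reflectance, for anisotropy experiments.
* **ROC/AUC statistics** — empirical ROC with midrank Mann–Whitney AUC
  (exactly the trapezoidal area under the curve) and Youden operating
  points, reported per power pair.

## Worked example

Invert one measurement and run the full synthetic pipeline:

```r
library(tissuelight)

m <- diffuse_measurement(r_d = 0.4610, t_d = 0.4453, thickness_cm = 0.1,
                         power_mw = 250)
p <- estimate_optical_properties(m)
p
#> <optical_properties> mu_a = 0.5001 1/cm, mu_s' = 13.5 1/cm, D = 0.1 cm
penetration_depth(p)
#> 0.2182  # cm

cfg <- default_config("skull", outdir = "out", noise_cv = 0,
                      n_replicates = 1, seed = 1, mc_photons = 2e4,
                      roc_pairs = list(c(150, 350)))
res <- run_analysis(cfg)
res$summary[, c("power_mw", "mu_s_prime_mean", "mu_a_mean", "depth_mean")]
#>     power_mw mu_s_prime_mean mu_a_mean depth_mean
#> 150      150            37.0       0.5     0.1333
#> 200      200            30.0       0.5     0.1478
#> 225      225            26.5       0.5     0.1571
#> 250      250            23.0       0.5     0.1684
#> 300      300            16.0       0.5     0.2010
#> 350      350             9.0       0.5     0.2649
```

The recovered μs′ falls from 37 to 9 cm⁻¹ across the power series (the
generator's ground truth, inverted back exactly in the noise-free case),
μa stays at its constant fixture value, and the penetration depth roughly
doubles — deeper light delivery at higher power. The fluence stage turns
the same properties into surface maps whose 1/e width grows monotonically
with power (`res$fluence_widths`), and the Monte-Carlo stage shows total
diffuse reflectance dropping as the anisotropy factor rises at fixed μs:

```r
res$mc$totals
#>      g total_rd total_td total_absorbed    se_rd
#> 1 0.80   0.6106   0.2840        0.10534 0.003448
#> 2 0.85   0.5490   0.3472        0.10375 0.003519
#> 3 0.90   0.4417   0.4588        0.09949 0.003511
```

A command-line interface wraps every stage
(`inst/cli/tissuelight simulate-data|reduce|invert|fluence|mc|roc|run`);
see `?tissuelight_cli`.

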