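# tuberlight

Tissue optics and Monte Carlo light transport for non-destructive detection
of **blackheart** in potato tubers.

Blackheart is an internal physiological disorder: the central medulla
darkens during storage while the tuber shows no external symptoms, so
affected tubers pass visual grading. The darkened tissue absorbs markedly
more Vis-NIR light (especially over 550–850 nm) and scatters differently,
which makes optical sensing a viable screening technology — provided the
light actually reaches the core and returns with a measurable signature.
`tuberlight` implements the complete computational chain needed to study
that question and to build discriminant detectors on top of it:

1. **Synthetic tissue optics** — parametric absorption (μ<sub>a</sub>) and
   reduced scattering (μ′<sub>s</sub>) spectra for healthy, slightly
   blackhearted and blackhearted medulla tissue on a 400–1000 nm grid, with
   a carotenoid band at 490 nm, a water band at 980 nm and per-sample
   lognormal biological variability. Group means pass exactly through
   pinned anchor values at 490 and 805 nm.
2. **Adding-doubling radiative transfer** (`slab_rt`) — total reflectance
   R<sub>t</sub> and transmittance T<sub>t</sub> of a tissue slab under
   collimated normal incidence: Henyey–Greenstein redistribution on a
   Gauss–Radau quadrature (split at the critical angle for index-mismatched
   boundaries), thin-layer initialization, repeated doubling, Fresnel
   boundary layers.
3. **Inverse adding-doubling** (`invert_rt`, `extract_op_spectrum`) — the
   IAD search recovering (μ<sub>a</sub>, μ′<sub>s</sub>) from measured
   (R<sub>t</sub>, T<sub>t</sub>) pairs per wavelength.
4. **Voxel Monte Carlo photon transport** (`run_mc`, compiled in C++) —
   weighted photon packets on a voxel grid with exponential stepping,
   Henyey–Greenstein scattering, Fresnel reflection/refraction wherever the
   refractive index changes, Russian-roulette termination and per-photon
   counter-based RNG streams; slice (2 mm), half-tuber (30.5 mm) and
   whole-tuber (61 mm) layered geometries (`build_geometry`).
5. **Optical metrics** — the diffusion-approximation penetration depth
   σ = 1/√(3 μ<sub>a</sub>(μ<sub>a</sub> + μ′<sub>s</sub>)), depth-difference
   wavelength selection, fluence 1/e depth, simulated-vs-measured error.
6. **Discrimination** — PLS-DA and SVM-DA on optical features
   (T<sub>t</sub>, R<sub>t</sub>, μ<sub>a</sub>, μ′<sub>s</sub>) with
   stratified 70:30 calibration / cross-validation reporting.
7. **Pipeline** (`run_pipeline`) — the end-to-end run with CSV/NRRD/JSON
   artifacts and a checksummed manifest.

## Worked example

```r
library(tuberlight)

healthy      <- generate_group_spectrum("healthy")
blackhearted <- generate_group_spectrum("blackhearted")

# depth of 1/e light penetration at the two working wavelengths
penetration_depth(0.0110, 0.6581)   # healthy at 805 nm      -> 6.73 mm
penetration_depth(0.1500, 1.1649)   # blackhearted at 805 nm -> 1.30 mm

# wavelengths of extreme healthy-vs-blackhearted depth difference
select_wavelengths(penetration_profile(healthy),
                   penetration_profile(blackhearted))
#> $lambda_max_diff  810     (largest contrast, 5.44 mm)
#> $lambda_min_diff  990     (smallest contrast, 1.30 mm)

# photon transport through a whole tuber with a blackhearted core
geo <- build_geometry("whole", 805, op_test = blackhearted,
                      op_healthy = healthy, lateral_voxels = 40)
run_mc(geo, mc_config(n_photons = 1e5, seed = 7))
#> mc_result (whole, 1e+05 photons, seed 7)
#>   specular 0.0211 | R_d 0.5825 | T 0.093597 | A 0.3028 (sum 1.000000)

# discriminate healthy vs blackhearted from absorption at 490/805 nm
cohort <- generate_cohort(cohort_spec(n_per_group = 40, seed = 7))
evaluate_discrimination("svmda",
                        cohort_features(cohort, "mu_a", c(490, 805)),
                        seed = 7)
#> SVMDA on mu_a features
#>   calibration      : blackhearted 100.00% | healthy 100.00% | overall 100.00%
#>   cross-validation : blackhearted 100.00% | healthy 100.00% | overall 100.00%
```

The budget line reads: ~2% of the beam is lost to specular reflection at
the skin, ~58% returns as diffuse reflectance, ~30% is absorbed inside the
tuber, and the remainder leaves through the finite lateral faces (escapes
are classified by exit direction). The blackhearted core at 28.5–32.5 mm
depth sharply attenuates the energy reaching the distal half — the
volumetric signature that makes 805 nm a useful detection wavelength.

A command-line wrapper over the same functions is provided:

```sh
Rscript scripts/tuberlight.R run --seed 7 --out runs/demo
Rscript scripts/tuberlight.R mc-run --geometry whole --wavelength-nm 805 --photons 1e6
Rscript scripts/tuberlight.R classify --features mu_a --model svmda
```

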