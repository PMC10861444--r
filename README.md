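# opmsim

Vectorial diffraction simulation of oblique plane light-sheet microscopes
(OPM), for microscope builders and computational imaging researchers who
need to predict how a tilted three-microscope detection train — primary
objective, remote-focusing relay, and a tertiary microscope inclined along
the light-sheet normal — performs as a function of light-sheet inclination,
light-sheet **polarization**, photon budget, and the immersion change in
front of the tertiary objective.

## What it computes

Fluorophores are modelled as non-rotating dipoles photoselected by the
sheet polarization ê (excitation probability |p̂·ê|²). Each emission
direction is traced through the lens train as a 3×3 polarization matrix
chain

&nbsp;&nbsp;T(θ₁, φ, α) = R_z(φ_α) M₃ F_T R_z(−φ_α) R_x(−α) R_z(φ) M̄₂ M₁ R_z(−φ),

where the microscope factors Mᵢ combine the meridional lens bends of an
objective/tube-lens pair under the Abbe sine condition
(θ′ = arcsin((NA′/NA)·n·sin θ)), the objective transmission mask Γᵢ(θ)
applied in its s/p basis, and the aplanatic apodization
√(cos θ_out / cos θ_in); F_T is the Fresnel transmission of the tilted
immersion change. The focal field is evaluated by an FFT-based Debye
integral, the camera adds Poisson shot noise, Gaussian read noise and a
bias offset (SNR = N_p/√(N_p + σ²)), and resolution limits follow from
the first zero crossing of the optical transfer function after
subtracting its expected noise background
|η̂| = √(DC + N_vox(σ² − b)). The on-axis axial crossing gives the
optical sectioning thickness S, the largest contiguous axial extent the
axial resolution, and the ellipsoid (x, y, S) gives the in-focus PSF
area and volume. Light efficiency is the energy-true fraction of
ensemble emission transmitted to the camera.

## Worked example

A 1.35 NA silicone-immersion primary, 0.95 NA dry secondary and 1 NA
glass-tipped coated tertiary objective at a 30° sheet inclination,
488/507 nm, 10⁴ photons at the brightest voxel:

```r
library(opmsim)

cfg <- opm_config(alpha_deg = 30, sheet_polarization = "s", grid_n = 128)
psf <- ensemble_psf(cfg)          # 100-dipole photoselected ensemble PSF
resolution_limits(psf, n_realizations = 3)
#> <resolution_report> x 196.6  y 216.9  z 308.8  S 618.7 nm  (SNR 100, 3 realizations)
#>   ellipsoid area 0.0335 um^2, volume 0.01382 um^3

optical_efficiency(cfg)                      # s-polarized sheet
#> [1] 0.2591
optical_efficiency(cfg, polarization = "p")
#> [1] 0.2400
lightsheet_geometry(cfg)$length_um
#> [1] 6.485667
```

Read: at 30° the system resolves ~197 nm along the tilt axis and ~217 nm
across it, sections ~0.6 µm, collects 25.9% of the emitted light with an
s-polarized sheet versus 24.0% with a p-polarized one (an ~8% gain for
s), and the sheet stays usable over ~6.5 µm. `run_sweep()` tabulates the
same quantities over inclination × photon count × polarization grids and
writes CSV plus a seeded manifest; `efficiency_sweep()` and
`efficiency_crossing()` compare the polarizations across inclinations.
`opm_preset()` provides the standard configurations (coated glass-tipped,
coverslip + water, and the hypothetical lossless dry tertiary arm).

A command-line front end for shell use ships in `inst/cli/opmsim.R`
(subcommands `simulate`, `sweep`, `efficiency`, `fixtures`, `validate`).

The methods vignette (`vignettes/opm-simulation.Rmd`) documents the
model, its conventions, every tunable parameter and the numerical
choices.

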