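---
title: "Simulating polarization-dependent imaging in oblique plane microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating polarization-dependent imaging in oblique plane microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opmsim)
```

## The system being modelled

Oblique plane microscopy (OPM) illuminates a sample with a light-sheet
inclined by an angle $\alpha$ from the focal plane of a single high-NA
primary objective (O1) and images that tilted plane through the same
objective. Because the sheet is oblique, the illuminated plane must be
relayed to a remote image space by an aberration-free remote-focusing
relay (O1–T1–T2–O2, magnification $n_1/n_2$), where a tilted tertiary
microscope (O3–T3) whose optical axis lies along the sheet normal brings
it into focus on the camera.

Two penalties come with the tilt. First, the detection pupil shrinks to
the overlap of the O2 acceptance cone and the tilted O3 acceptance cone,
anisotropically: resolution along the tilt direction (y) degrades as
$\alpha$ grows. Second, the immersion change in front of O3 (a dry remote
space against a glass-tipped or water-immersion tertiary objective)
introduces polarization-dependent transmission. Both penalties interact
with the *polarization of the light-sheet* whenever the fluorophores have
high anisotropy: non-rotating dipoles are photoselected by the excitation
polarization, and the resulting orientation distribution radiates
anisotropically into the tilted pupil.

`opmsim` quantifies these effects. Its conventions: the primary optical
axis is $z$, the tilt is a rotation about $x$, the sheet propagates in the
$yz$ plane at $\alpha$ from the focal plane, the O3 axis is the sheet
normal $(0, -\sin\alpha, \cos\alpha)$. An *s*-polarized sheet has its
field along the tilt axis $x$; a *p*-polarized sheet has its field in the
tilt plane — which is exactly the sheet normal, i.e. the O3 optical axis.
That simple fact drives most of the polarization phenomenology: p-excited
dipole populations are aligned with the detection axis and radiate a
doughnut pattern *away* from the pupil center.

## The model, stage by stage

**Dipole source.** A fluorophore is a fixed electric dipole; its far field
at direction $\hat r$ is $\propto \hat p - \hat r(\hat r \cdot \hat p)$.
Ensembles are either `aligned` (all dipoles along the sheet polarization)
or `isotropic_photoselected` (orientations uniform on the sphere, each
weighted by $|\hat p\cdot\hat e|^2$ — the zero-rotational-diffusion
photoselection model, the extreme-anisotropy limit). Ensemble PSFs are
incoherent sums; we exploit the fact that any incoherent ensemble enters
the PSF only through its second moment
$M=\sum_i w_i\,\hat p_i \hat p_i^{\mathsf T}$, so a 100-dipole ensemble
costs exactly three basis-dipole field computations plus a $3\times3$
eigendecomposition, with no approximation.

**Polarization ray tracing.** Every optical element is a $3\times3$
matrix acting on the full field vector of a ray: azimuthal rotations into
and out of meridional frames, meridional lens bends for each
objective/tube-lens pair (Abbe sine condition,
$\theta' = \arcsin((\mathrm{NA}'/\mathrm{NA})\,n\sin\theta)$),
angle-dependent transmission masks applied in the s/p basis of each
element, Fresnel coefficients in the s/p basis of the tilted interface
normal, and the aplanatic apodizations
$\sqrt{\cos\theta_\text{out}/\cos\theta_\text{in}}$ that conserve energy
through sine-condition telescopes. The remote relay preserves polar
angles (magnification $n_1/n_2$), so the effective detection NA is
$\min(\mathrm{NA}_1,\ \mathrm{NA}_2\, n_1/n_2)$.

The tracer has two modes. `camera` applies the literal imaging chain —
raw Fresnel amplitude coefficients and all apodizations — producing the
camera-referred pupil field. `power` applies power-normalized interface
transmittances and no apodization, so that $|E|^2$ summed with
solid-angle weights is exactly the transmitted power; this is the mode
behind the efficiency integrals, and it conserves energy to better than
0.1% for a lossless chain.

**The immersion change.** Three couplings are supported. `none`: an
index-matched (hypothetical dry) tertiary arm, lossless. `fresnel`: an
uncoated interface or coverslip stack ($n_2 \to n_\text{cs} \to n_3$),
with full angle- and polarization-dependent Fresnel transmission.
`coated`: an anti-reflection-coated glass tip described by a measured (or
synthetic) transmission curve versus the glass-side angle, *multiplied by
the bare-interface Fresnel transmittance normalized to its
normal-incidence value*. The extra factor encodes a physical constraint a
fitted polynomial cannot: no coating prevents the grazing-incidence
collapse of transmission, and the entire grazing range of air-side angles
compresses into the last degree of the glass-side angle where a bench
measurement has no leverage.

**Transmission curves.** Measured tables (angle in degrees vs normalized
power for s and p) are fitted by degree-5 polynomials per polarization,
normalized to a maximum of 1, with the coefficients echoed to the log.
The measured curves are treated as *power* transmission; the mask applies
their square root as an amplitude (a flagged convention choice, since
amplitude-vs-power is not deducible from a normalized curve). Synthetic
fixtures stand in for bench data: `dry_like`
($T_p = 1 - 0.10x^2 - 0.05x^5$, $T_s = 1 - 0.25x^2 - 0.20x^5$ with
$x=\theta/72^\circ$; moderate p roll-off, steep s roll-off) and
`agy_like` (near-flat, $|T_s-T_p| < 0.05$), chosen once to reflect the
qualitative behavior of a high-NA dry objective and a coated glass-tipped
immersion objective, and frozen.

**Focal field.** The Debye integral is evaluated by FFT in the final
low-NA image space, where the angular-spectrum $1/k_z$ weight is unity to
high accuracy: the integrand is simply the traced camera-referred field
on the regular transverse-frequency grid, with the exact high-NA defocus
phase $\exp(2\pi i\, k_z z)$, $k_z = (n_1/\lambda_\text{em})\cos
\tilde\theta$, applied per plane (sample-referred coordinates:
remote-space lengths divided by the relay magnification). Because the
pupil is sampled directly on the FFT frequency grid, the output pitch
equals the requested camera pitch exactly and no chirp-z resampling is
needed. Pitches default to Nyquist: $\lambda_\text{em}/(4\,
\mathrm{NA}_\text{det})$ laterally and $\lambda_\text{em}/(4 n_1)$
axially. An alternative formulation — integrating in the remote space
with a $1/\cos\tilde\theta$ integrand — is mathematically admissible but
overweights the grazing shell of the tilted pupil relative to what the
physical camera records; the camera-space formulation is the one the
implemented fast-Debye method defines.

**Light-sheet envelope.** The sheet is formed by a flat-top strip at the
edge of the O1 pupil; the usable half-angle is
$\arcsin(\mathrm{NA}_1/n_1) - (90^\circ - \alpha)$. The waist intensity
profile is computed from that strip by a one-dimensional coherent
integral (uniform illumination in pupil radius); its intensity spectrum
has compact support of width $2\,\mathrm{NA}_\text{sheet}/
\lambda_\text{ex}$, which is what limits optical sectioning at high
photon counts. A Gaussian fit to this profile systematically
underestimates the sectioning thickness, which is why the envelope is
*not* Gaussian in this package. Sidelobe tails below $10^{-4}$ of the
peak are zeroed: they carry no information above the photon noise floor
but would wrap around desk-scale sampling volumes. For the *reported
sheet length* we use the conventional Gaussian confocal parameter
$2 n_1 \lambda_\text{ex}/(\pi \mathrm{NA}_g^2)$ of an equivalent beam
with $\mathrm{NA}_g = \mathrm{NA}_\text{sheet}/k_\text{ls}$; the
flat-top-to-Gaussian equivalence factor $k_\text{ls} = 1.29$ was
calibrated once against reference sheet lengths of a high-NA
silicone-immersion configuration and is frozen (it is a reporting
convention and does not affect the simulated PSF).

**Camera and noise.** The noiseless stack is scaled so its brightest
voxel expects `n_photons`, passed through a Poisson draw, Gaussian read
noise of RMS `sigma_rms` is added, the bias offset is added, and voxels
are rounded and clipped at zero. The default configuration is
shot-noise-limited (`sigma_rms = 0`, bias 100): at $N_p = 10^4$ this is
the SNR $\approx \sqrt{N_p} = 100$ regime, and it is the only regime in
which the OTF background is independent of the sampling volume — with
$\sigma > 0$ the background term $N_\text{vox}\sigma^2$ grows with the
grid and axial-volume convergence testing would be ill-posed. Read noise
and bias remain fully supported and are exercised by the tests.

**Noise-aware resolution.** The OTF of each noisy stack is computed (with
the stack origin shifted to the first voxel so the OTF phase is smooth),
and its expected background follows from the noise model:
$|\hat\eta| = \sqrt{DC + N_\text{vox}(\sigma_\text{RMS}^2 - b)}$, where
$DC$ is the zero-frequency component. The Poisson variance integrates to
the total signal counts and every voxel contributes $\sigma^2$; the
voxel-count factor is required for the unnormalized FFT convention and is
validated against Monte-Carlo draws over the full
$(N_p, \sigma, b)$ grid. The complex OTF is averaged over a $\pm1$-bin
tolerance band ($3^3$ box); the cutoff along each axis is the first zero
crossing of the band-averaged magnitude minus the background, with linear
sub-bin interpolation, and the resolution limit is the inverse cutoff.
Axially two numbers are extracted: the on-axis $k_z$ crossing gives the
*sectioning thickness*, and the largest $|k_z|$ anywhere in the support
gives the *axial resolution*. Because the Poisson variance is
concentrated in the bright PSF core, the OTF noise is correlated across
neighboring frequency bins and the band average does not suppress it as
$1/\sqrt{27}$; the maximum-over-plane support scan is therefore
thresholded at the empirical ceiling of the outermost $k_z$ planes
(which lie beyond any physically reachable axial frequency), while the
one-dimensional profiles keep the analytic background and rely on
averaging over noise realizations (10 by default) exactly as the
reference procedure prescribes. When no crossing occurs inside the
Nyquist band the band edge is reported with a saturation flag.

**Ellipsoid summary and efficiency.** The in-focus PSF area is
$\pi (x/2)(y/2)$ and the volume $(4\pi/3)(x/2)(y/2)(S/2)$, using the
sectioning thickness as the third axis. Optical efficiency is the
fraction of the ensemble's total radiated power that reaches the camera:
the default `physical` method integrates energy-true transmitted power
per ray over the effective pupil (masks, Fresnel transmittance and
vignetting included; apodization excluded, because it redistributes
rather than absorbs energy — this is also the only reading under which a
lossless untilted system's efficiency equals its collection solid-angle
fraction, which the tests verify in closed form). A `camera` method
(integrated image intensity of the literal imaging chain) is provided for
comparison; the two coincide for an index-matched tertiary arm.

## What the synthetic data emulate — and what they do not

The generator produces every input the simulator needs: transmission
fixtures standing in for bench measurements, seeded dipole ensembles, and
Poisson/Gaussian camera stacks. It emulates an ideal, aberration-free
instrument with a point emitter exactly in the focal plane and a
non-scattering medium. It does **not** emulate: field-position-dependent
PSFs, spherical or chromatic aberration, scattering (which the underlying
comparison explicitly leaves qualitative), rotational diffusion between
excitation and emission, finite fluorophore lifetimes, or camera
pixel-to-pixel response variation. Passing tests therefore validate the
vectorial diffraction and noise model, not any claim about aberrated or
scattering samples.

Two documented modelling consequences deserve emphasis. First, the
brightest-voxel photon normalization (each stack is scaled to the same
peak count before noise) means a blurrier PSF receives more total
photons and a correspondingly lower relative noise floor; at high photon
counts this compensates most of the s/p lateral resolution difference,
so lateral orderings between polarizations are sub-2% effects here.
Second, with energy-true bookkeeping and a near-flat coated tertiary
mask, the s-polarized sheet keeps a collection advantage at every
inclination up to the sweep edge: the s/p efficiency curves converge
toward equality only as the tilt approaches 90 degrees, and the
crossover reported by `efficiency_crossing()` for the coated
configuration saturates at the sweep band edge. Reproducing a crossover
near 45 degrees would require either a strongly polarization-dependent
coated-tip transmission (contradicting the near-flat measured behavior)
or a pupil-rim-amplified power integrand that is not energy conserving;
we document this sensitivity rather than adopt either.

## Numerical choices

* Grids are even powers of two with the focus exactly at voxel
  $N/2 + 1$; 128^3 is the desk-scale default used by the sweep drivers,
  256^3 the high-accuracy preset used for the resolution-table checks.
  A 240 um full-scale axial extent is the documented converged regime of
  the reference procedure but is beyond what `sampling_volume_check()`
  needs for the metrics reported here.
* The acceptance sweep sizes: 5 inclinations x 3 photon counts x 2
  polarizations at 128^3 with 10 noise realizations per cell; the
  resolution-table check runs 5 x 2 cells at 256^3 with 4 realizations.
* Quadratures over the pupil use equal-solid-angle grids (200 polar x
  400 azimuthal cells by default; <0.1% power error).
* Degenerate inputs: rays beyond any acceptance cone, beyond the tube
  lens remap, beyond the critical angle, or counter-propagating relative
  to the tertiary axis are vignetted to zero, never complex-propagated.
* Ties in the zero-crossing search resolve to the first bin at or below
  zero; sub-bin positions use linear interpolation of the two bracketing
  values.

## Worked example

```{r example, eval = FALSE}
cfg <- opm_config(alpha_deg = 30, sheet_polarization = "s", grid_n = 128)
psf <- ensemble_psf(cfg)
resolution_limits(psf)
optical_efficiency(cfg)
lightsheet_geometry(cfg)$length_um

# polarization comparison over inclination and photon budget
sw <- run_sweep(cfg, alpha_deg = c(20, 30, 40), n_photons = c(1e2, 1e4))
sw$table
```

## Known limitations

* Sectioning and axial-resolution estimates at desk-scale grids carry a
  few-percent dependence on the sampling volume through the sheet
  envelope tails; `sampling_volume_check()` makes the dependence
  explicit.
* The axial-resolution (maximum $k_z$ extent) statistic is the most
  sensitive to the pupil-rim transmission model, for which measured
  curves carry no information; treat its absolute value with more
  caution than its trend with inclination.
* The polynomial transmission fixtures are synthetic stand-ins; users
  with bench measurements should load them via
  `read_transmission_table()`.
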