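---
title: "Models and methods behind nanoholo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanoholo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`nanoholo` is a desk-scale, fully synthetic re-implementation of the
computational chain used in phase-contrast hard X-ray nanoholotomography of
paraffin-embedded brain tissue: phantom generation, multi-distance in-line
hologram simulation and phase retrieval, two-step automated soma
segmentation, and the quantitative metrics with which such data are
characterised. This vignette records the models, the parameters that
matter, the numerical choices, and the places where the design was
genuinely open. It states no empirical result that the package's tests and
acceptance script do not themselves compute.

## The tissue phantom (module `phantom`)

Reconstructed holotomograms of paraffin-embedded tissue show neuron somata
against the neuropil through a *region-level* refractive-index contrast;
plasma membranes are not resolved as edges. The phantom therefore models:

* a neuropil background at gray value 0.45 on a dimensionless
  electron-density-like scale in roughly [0, 1] (the absolute refractive
  index decrement is never calibrated, so the scale is arbitrary by
  design);
* a low-pass-filtered Gaussian texture (correlation length 3 voxels, sd
  0.02) standing in for unresolved neuropil structure;
* ellipsoidal somata with nested compartments at fixed default densities
  ordered as in the imaging literature for this contrast mechanism:
  nucleus 0.35 < neuropil 0.45 < cytoplasm 0.60 < nuclear envelope 0.75 <
  nucleolus 0.90. The envelope is the outer shell (default 2 voxels) of
  the nucleus ellipsoid (default 0.55 of the soma semi-axes); the
  nucleolus is a small central sphere (default 3.5 voxels).
* degradation by a Gaussian point-spread function (default sd 1 voxel) and
  additive Gaussian noise (default sd 0.05). Photon (Poisson) noise is
  *not* applied here; it belongs to the hologram forward model.

The benchmark phantom (`benchmark_phantom_spec()`) fixes the stated world
of the segmentation studies: ~200^3 voxels, 10 cells with semi-axes
uniform in 15-25 voxels, none touching the border, soma/neuropil contrast
0.15 = 3x the noise sd. These values were chosen once, before any
benchmark was run, and are not tuned.

What the generator does **not** emulate: dendrites and axons (tissue
damage from paraffin embedding makes them unsegmentable in the real data,
so they are declared out of scope), paraffin cracks, intensity
inhomogeneity of the illumination, and reconstruction artefacts such as
rings. A green segmentation test therefore establishes that the two-step
pipeline works under the stated contrast/noise/size regime — not that it
survives every artefact of beamline data.

Ground-truth labels encode cell `i`, compartment `c` as `(i-1)*10 + c`
(`compartment_mask()`), taken before degradation, so truth is exact.

## Hologram simulation and phase retrieval (module `holography`)

The cone-beam geometry follows the magnification relation `M = (D1+D2)/D1`
and the Fresnel scaling theorem: propagation is simulated as a parallel
beam over `D_eff = D1 D2/(D1+D2)` at the demagnified pixel
`detector_pixel/M`. The focus-detector distance defaults to 1208.0 mm,
recovered by self-consistency from the 200 nm prescan geometry
(`3 um x 80.533 mm / 200 nm`); the instrument papers state only "about
1.2 m". The wavelength is `hc/E` (0.0729 nm at 17 keV).

Propagation uses the single-FFT transfer-function propagator
`exp(-i pi lambda D f^2)` with periodic boundaries; total intensity is
conserved to Parseval precision. Desk-scale grids (128^2-512^2 instead of
4096^2) undersample the physical chirp at the full Table-style distances;
the propagator warns in that case. Retrieval round-trip tests remain
meaningful because forward and inverse share the sampled kernel exactly;
absolute PSF fidelity at 4096^2 scale is not claimed.

Phase retrieval is the least-squares multi-distance inversion of the
weak-object, pure-phase contrast transfer function:
`phase_hat = sum_d sin(chi_d) I_hat_d / (2 sum_d sin^2(chi_d) + eps)` with
`chi_d = pi lambda D_d f^2`. A pure-phase model is justified for soft
tissue in the hard X-ray regime, where the refractive index decrement
exceeds its absorptive part by orders of magnitude; the exact "adapted"
beamline algorithm is unpublished, so only this weak-object core is
implemented and tested. `eps` defaults to `1e-3` of the peak denominator —
the beamline value is unpublished, and this choice suppresses the
zero-frequency and CTF-zero divisions while biasing recovered amplitudes
by well under 1%. The retrieved zero-frequency (mean phase) is arbitrary
under regularization; comparisons subtract a reference region.

Noise is Poisson at the stated photons per pixel and projection; flat
fields receive the same statistics. Tomographic reconstruction is
ramp-filtered back projection with linear interpolation, and a forward
Radon operator is provided for round-trip tests.

## Detection stage (module `detection`)

Somata are detected by a multi-scale Hessian filter with the published
operating point `alpha = 0.5`, `beta = 0.1`, `gamma = 60`, radius range
15-25 voxels (step 2), threshold 0.01, objects under 20 000 voxels or
touching the margin rejected. Three conventions had to be fixed:

* **Scale mapping.** `sigma = r/2` for target radius `r` (common blob
  practice); exposed as `sigma_per_radius`.
* **Gamma scaling.** A structureness cutoff in gray units is only
  meaningful relative to the data's gray range; `gamma = 60` presumes
  8-bit-range data. The effective cutoff is
  `gamma x (0.1-99.9 percentile range)/255`, a fixed documented rule
  (`gamma_scale = "none"` applies gamma verbatim).
* **Orientation of the blobness term.** The textbook vesselness factor
  `exp(-R_B^2/2 beta^2)` with `beta = 0.1` suppresses *everything except
  thin tubes*: a smooth bright ellipsoid or shell can mathematically never
  reach the 0.01 threshold under it (its `R_B` is of order
  `sqrt(sigma/r)`). Since the detection target here is somata — 0-dimensional
  structures in the objectness taxonomy — the package defaults to the
  objectness-for-blobs orientation `1 - exp(-R_B^2/2 beta^2)`
  (`blobness = "enhance"`), under which the filter responds to strong
  intensity changes on and inside cell margins while the gamma term
  suppresses background noise. The classical tube-selective filter
  remains available as `blobness = "suppress"` and is covered by tests.

Eigenvalues are sorted by magnitude (`|l1| <= |l2| <= |l3|`), bright
polarity requires `l2, l3 < 0`, components are 26-connected, and border
contact is tested on all six faces. The sampled second-derivative kernels
are projected to zero sum so that constant volumes yield exactly zero
response and the filter is offset-invariant.

## Level-set refinement (modules `levelset`)

The refinement is a sparse-field level-set evolution: only a five-layer
band around the zero level set is stored in lists and updated, which both
bounds the cost per iteration by the contour length and prevents spurious
region nucleation away from the front. The published schedule is
slice-wise 2-D evolution (900 iterations, smoothness weight
`zeta = 0.01`), a 3-D step (60 iterations, `zeta = 1`) initialized from
the stacked 2-D result, and removal of objects under 300 voxels (applied
after the 3-D step, per the order in which the procedure is described).

The energy the contour descends is not published; a two-phase region
energy (Chan-Vese data term: squared deviation from the inside/outside
mean intensities) is adopted because the contrast mechanism in this data
is region-level. The data force on the zero layer is normalized by its
maximum magnitude and `zeta` multiplies a finite-difference mean
curvature, so `zeta` is genuinely the *relative* weight of curve
smoothness; the step size is `0.45/max|dphi|` (CFL-safe). Layer
reassignment follows the standard transfer-list procedure with scan-order
tie-breaking, making the whole pipeline bit-deterministic.

The semi-automated mode evolves expert seed masks on one slice, then
propagates the converged contour outward slice by slice until it vanishes,
followed by the same 3-D step. During propagation the region means are
*frozen* at the seed-slice values: with adaptive means a contour on a
cell-free slice sees two equal-mean phases, feels no net force, and never
dies; with the frozen cell model it shrinks away, which is the stopping
rule. The propagation order (outward from the seed slice) was an open
interpretation and is documented as such.

Region growing for subcellular structures is a 6-connected flood fill
against a running region mean with a gray-unit tolerance, with a relative
`1e-12` slack so that tolerance 0 admits exactly-equal neighbours despite
floating-point accumulation.

## Metrics (module `metrics`)

* **CNR** `= |I1-I2|/sqrt(s1^2+s2^2)`, from ROI moments or from a
  two-Gaussian mixture fit to the 256-bin intensity histogram (weighted
  EM, deterministic median-split initialization; component weight < 1% is
  a fit error). Optional uncertainty intervals use a bootstrap over
  slices — the interval method in the source literature is unstated, so
  the bootstrap is labelled as the package's own choice.
* **Resolution** is edge-based: edge-spread profile (optionally the
  voxel-wise median over n slices, the low-CNR variant), derivative,
  Fourier magnitude normalized at the lowest nonzero frequency, and the
  10% crossing. The reported value is the **half-period** `1/(2 f10)`;
  half- versus full-period is not stated in the source convention and
  this choice is flagged prominently. An edge sharper than the band
  reports the one-voxel Nyquist half-period with `at_band_edge = TRUE`.
* **Sensitivity** `S = TP/T` is the fraction of detected objects that are
  true cells (the printed formula "S = TP = T" is read as the ratio its
  defining sentence describes). The matching criterion — centroid inside
  a truth cell and overlap at least half the smaller object — replaces
  the expert's visual judgement and is configurable.
* **Curvature** assumes elliptical cells: `R = a^2/b` from an
  inertia-tensor fit (for a solid ellipse the semi-axes are twice the
  principal standard deviations; mid-slice reduction for 3-D masks).
* **Registration** is translation-only by normalized cross-correlation
  with quadratic sub-voxel peak refinement, flagging peaks below 0.3.
* **H&E colour transfer** inverts a histology RGB-to-gray mapping by
  binning histology pixels on integer gray values, averaging RGB per bin,
  interpolating interior gaps and clamping (with a warning) beyond the
  occupied range.

## Pipeline and reproducibility (module `io_cli`)

`run_pipeline()` mirrors the hierarchical acquisition: master phantom,
factor-4 binned prescan, automatic region-of-interest selection
(maximizing detection-response mass — a deterministic stand-in for the
expert's visual choice), full-resolution segmentation and evaluation. All
artifacts, a JSON metrics report and a provenance manifest (config
checksum, seed, versions, photon budget) land in the run directory;
re-running a config reproduces the report. Volumes travel as multi-page
uncompressed TIFF or MHD/RAW — both writers/readers are implemented in
base R because no TIFF package is available in the target environment —
and configuration is JSON with unknown keys rejected. Every random draw
descends from one explicit seed.

## Known limitations

* The detection stage's response inside large flat cell interiors comes
  from compartment boundaries; a hypothetical perfectly homogeneous cell
  larger than ~20 000 voxels of constant intensity would be detected only
  through its margin band.
* Cells below the 20 000-voxel detection filter (sphere radius ~17
  voxels) are dropped by construction; the published filter makes the
  same trade.
* The simulated optics are scalar, fully coherent and detector-blur-free;
  partial coherence and scintillator response are out of scope.
* Runtimes are tuned for ~200^3 volumes on one CPU; memory scales as a
  handful of double-precision copies of the volume.
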