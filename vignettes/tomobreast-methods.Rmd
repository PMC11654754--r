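---
title: "Models and methods behind tomobreast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tomobreast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tomobreast)
```

`tomobreast` is a desk-scale simulator and reconstruction toolkit for
wide-angle digital breast tomosynthesis (DBT) with a flying-focal-spot (FFS)
X-ray source. This vignette documents the models, the numerical choices, the
parameters that matter, and — just as importantly — what the synthetic
experiments do and do not establish.

## 1. Acquisition geometry and timing

A scan is a source sweeping a circular arc of angular range $\theta$
(default 50°) above a stationary flat-panel detector (a-Se, 85 µm pitch),
acquiring $n$ evenly timed pulsed projections (default 25). Two timing modes
are built in: *fast* (4.8 s, up to 40 ms pulses) and *moderate fast* (8.1 s,
68 ms pulses), both with 150 ms detector readout. Derived schedule
quantities are defined over the sweep: frames per second is
$(n-1)/T$ (so fps·$T = n-1$ exactly) and the tube traveling speed is
$\theta/T$ (10.42°/s in fast mode, reported to one decimal as 10.4). For the
moderate mode $\theta/T = 6.17$°/s; published spec sheets sometimes quote
6.0°/s, presumably excluding turnaround margins — we report the raw
quotient and do not special-case it.

Coordinates: $x$ is the tube-travel direction, $y$ chest wall to nipple,
$z$ height above the detector at $z=0$; millimeters everywhere, degrees at
the API. The source–detector distance (SID, default 650 mm) and the
rotation-center height (default 0, i.e. the arc is centered on the detector
plane) are not published for the modeled system class; the defaults are
typical mammographic values and both are configurable.

**Flying focal spot.** During each pulse the gantry moves; without
compensation the focal spot smears by the arc chord swept in one pulse
(≈ 4.7 mm in fast mode — `source_position()` with `tau = ±0.5`). With
`ffs_enabled`, electromagnetic deflection cancels the motion: the effective
source position is constant over the pulse. The deflected spot may shrink
slightly; this is modeled as a linear factor per degree of deflection with
default coefficient 0 (the effect is described qualitatively as marginal, so
the neutral default is no shrink).

## 2. Sampling analysis

For in-plane frequency $f$ and scan angle $\theta$ the native slice
thickness is $d(f) = 1/(2 f \tan(\theta/2))$ and the depth-frequency
coverage is $F_z = f\tan(\theta/2) = 1/(2d)$. These are exact algebraic
statements and are tested to machine precision. `kspace_mask()` renders the
wedge of central-slice lines the projections fill in $(f_x, f_z)$ space; it
is a QC/teaching artifact only and is not used by the reconstructor.

## 3. Spectra, CNR, dose, and the CNR²/AGD scan

Spectra are Kramers-form bremsstrahlung $N(E)\propto(kVp-E)/E$ on a
5–50 keV grid (0.5 keV bins), normalized to a nominal fluence scale
($10^6$ photons/mm²/mAs at 28 kVp, growing as kVp²). Tungsten L-lines are
omitted. Attenuation is per-bin Beer–Lambert with embedded µ tables
(Al, Rh, PMMA, adipose/glandular/50-50 breast, calcium, titanium, a-Se)
interpolated log-log from approximate standard-reference anchors; the Rh
table carries its K-edge at 23.22 keV as a genuine discontinuity, the Al
table has no edge in range. The tables are accurate at the 10–20 % level —
enough for *ranking* filters and voltages, not for absolute dosimetry, and
every claim the package makes from them is directional.

The 1-D CNR model is quantum-noise-only with an energy-integrating a-Se
detector: signal $\sum \Phi E\,\varepsilon(E)$, noise
$\sqrt{\sum \Phi (E\varepsilon)^2}$, contrast from an object replacing an
equal thickness of background; CNR scales exactly as $\sqrt{\mathrm{mAs}}$.
AGD uses a deliberately simple slab-absorption model (energy absorbed per
areal mass, attributed to the glandular fraction) — not Dance g·c·s
factors. `scan_fom()` finds, per (kVp, filter), the mAs matching a
reference CNR, the resulting AGD, the figure of merit CNR²/AGD, and the
exposure time per projection at the 5 kW generator limit, flagging
candidates that exceed the pulse budget. On a 60 mm breast the 0.7 mm Al
filter (no K-edge) reaches matched CNR with a markedly shorter exposure
time per projection than 0.05 mm Rh — the direction that motivates
edge-free filtration for fast wide-angle scanning. The absolute optimal kVp
from this scan inherits the table approximations and should not be read as
a clinical technique chart.

## 4. Phantoms

`build_slab_phantom()` makes a compressed-breast slab whose
glandular/adipose mixing field is isotropic $1/f^\beta$ noise thresholded
to the requested mean glandularity; $\beta = 3$ by default
(literature-typical anatomical texture; the exponent is configurable and no
claim depends on its exact value). All generators are pure functions of
(config, seed). Inserts: microcalcification clusters (calcium spheres,
partial-volume voxelized with 3³ sub-sampling and a density factor, default
2, standing in for hydroxyapatite), rectangular titanium clips
(3×1×1 mm), thin tilted wires (25 µm, voxelized with bilinear sub-voxel
weights so they act as a line stimulus), and full-field Al sheets. The
phantoms emulate quantum noise, power-law texture, and high-contrast
objects; they do **not** emulate skin, compression paddles, scatter, or
anthropomorphic anatomy — a green test here says the *algorithms* behave as
specified, not that clinical image quality is reproduced.

## 5. Forward projector

Cone-beam ray integrals through the voxel grid by incremental traversal
with trilinear interpolation (Joseph-style), step = half the smallest voxel
dimension. The integration box is the full support of the trilinear
interpolant (one voxel beyond the outer voxel centers), which makes the
projector agree with a dense-sampling oracle to the midpoint-rule error and
conserves the slab's areal mass. Detector pixels integrate their aperture
along the travel direction with `n_det_sub` sub-samples (default 5;
Dirichlet-comb error < 2 % of the aperture sinc up to 5 lp/mm). Focal-spot
extent and pulse time are sampled with `n_spot_samples` ×
`n_time_samples` (defaults 5 × 5; FFS collapses the time axis), and
transmissions are averaged in the intensity domain, which is the physically
correct order for blur. Effective-energy mode (single µ volume) is the
default; polychromatic mode projects per-material path lengths and applies
the spectrum afterwards. Poisson noise is applied as
$\mathrm{Pois}(g\cdot I)/g$ with a seed recorded in the stack; for
$\lambda > 10^7$ a normal approximation is used.

## 6. Reconstruction

Log-normalized projections are ramp-filtered row-wise along the travel
direction (frequency-domain $|f|$, windows `none`/`hann`/`hamming`,
default `hann`; zero-padding to twice the next power of two with
edge-replicate fill, so constants filter to exactly zero and border ringing
is suppressed). Backprojection is a plain unweighted mean over views into
the **perspective coordinate system**: voxel $(r,c)$ of every slice lies on
central-view detector ray $(r,c)$, so each (voxel, view) costs one bilinear
interpolation and a structure keeps its in-plane index across slices.
Off-detector samples are excluded with per-voxel weight renormalization
(zero-fill would shade the breast edge). `resample_cartesian()` maps slices
onto the fixed detector grid (identity at $z=0$; bilinear; out-of-FOV = 0).
`merge_slabs()` implements contrast-preserving slabbing as
$(1-\lambda)\,\text{mean} + \lambda\,\text{signed extremum}$ per pixel
(λ = 0.5 default) — our concrete realization of an unspecified product
feature, exposed in config.

**How static is "static"?** With the rotation center on the detector plane,
the perspective invariance is exact on the central axis and degrades
slightly off-axis (the outer views' source height $R\cos\alpha$ differs
from SID), at the level of ~0.15 px per mm of off-axis distance over the
full stack height in the default geometry. Tests therefore assert that the
*center* of a point's out-of-focus trace stays on its central-ray index
(the trace itself is a comb of discrete view spikes whose interior argmax
is not a stable statistic), and that a Cartesian volume instead places the
structure at its demagnified world position.

## 7. Artifact reduction

Following the projection-domain scheme: per view, background = grayscale
opening (disk, default radius 15 px); mask = residual > k·MAD (k = 4);
components below 5 px (too small to cause artifacts) or above 25 % of the
view (implants, risk of over-correction) are dropped; the survivors are
dilated (default 2 px). `remove_objects()` inpaints masked pixels with the
background estimate (rP); `masked_backproject()` reads each masked
(voxel, view) sample from ramp-filtered rP instead of oP. Two refinements
the literal scheme needs in practice, both documented in code:

* **Object consensus.** A voxel masked in ≥ 90 % of its contributing views
  is the high-contrast object itself in focus; it keeps the original data.
  Without this the clip would be erased along with its artifacts.
* The consensus is judged on the **pre-dilation core mask**, so enlarging
  the conservative margin strictly enlarges the corrected region and never
  re-exposes artifacts (monotone suppression), and the dark-shadow ring at
  the focus plane is still corrected.

Shadow regions behind large objects retain residual traces by design — the
projections simply carry no information there.

## 8. Post-processing

*Baseline equalization* removes breast-thickness trends: per slice, a
heavy Gaussian low-pass (default 20 mm) computed inside the breast mask by
normalized convolution is subtracted and the masked mean restored. All
Gaussian blurs in the package are zero-padded *and renormalized by the
blurred indicator*, so means are preserved to float precision — an easy
place to silently lose mass otherwise.

*Multifrequency flavoring* uses a difference-of-Gaussians octave stack
(σ = 1, 2, 4, … px; exact reconstruction by summation) with per-band gains;
dark-overshoot suppression scales negative excursions of the finest bands
near strong edges (|band| > 4 robust σ, dilated 2 px) by the clamp
fraction. Identity configuration is a machine-precision no-op.

*Physics-constrained denoising*: a pluggable estimator (default: Anscombe
transform, Gaussian low-pass, soft-threshold of the fine band at 2 VST σ,
first-order-unbiased inverse) yields a noise estimate that a plausibility
filter clamps to $\pm k\sqrt{I/g}$ — the quantum-noise prediction — before
subtraction. The hard bound is the contribution we implement; the trained
network it constrains in the product is out of scope and replaced by the
classical default. `clamp_k = 0` is the identity by construction.

*Synthetic mammogram*: background = triangular-weighted mean of the central
$2k{+}1$ denoised projections mapped through the volume's mid-height to
central-view coordinates; detail = per-pixel signed extremum across slices
of the volume's fine band; SM = background + weight·detail, all in the
attenuation domain. A property-level stand-in: calcification positions
register with the central projection to ≤ 1 px and detail weight increases
their contrast; appearance is not modeled.

## 9. Effective MTF

`emtf_from_wire()` extracts the line-spread function of a slightly tilted
wire per view (centroid line fit; perpendicular-distance binning at 0.1 px;
linear tail detrend; no apodization), takes |DFT|, normalizes at DC,
averages the curves over all views, and rescales the frequency axis to the
plane of the wire by dividing detector-plane frequency by $M(h)$.

Two numerical notes. First, the axis convention: dividing by $M$ is the
stated convention of the toolkit and is applied identically to every
setting compared, so all FFS/height/FFDM comparisons are internally
consistent; under the alternative convention (multiplying, i.e. plotting
against true object-plane frequency) all curves shift but every ordering
claim below is unchanged. Second, with a *rectangular* 40 ms pulse the
FFS-off motion blur is a ~0.48 mm box whose |sinc| has sidelobes: at h =
60 mm the view-averaged eMTF near 4 lp/mm floors at ≈ 0.066 (0.096 with
the default 5 pulse-time samples; the discrete tau comb has larger
sidelobes than the continuous box it approximates). A perceptual
"vanishes" threshold of 0.05 is therefore not reached in this stated
world — real pulses are not rectangular — and the corresponding acceptance
assertion is deliberately left failing rather than tuned. Everything
qualitative reproduces cleanly: resolution at 4 lp/mm is comfortably
visible at 20 mm without FFS and collapses by 60 mm; FFS-on dominates
FFS-off at every frequency with a gap that widens with height; and the
FFS-on DBT curve tracks a stationary-source single-shot (FFDM-like)
simulation within 0.05 everywhere.

## 10. Reproducibility and I/O

Arrays travel as multi-page 32-bit-float TIFF plus a JSON sidecar carrying
geometry, coordinate system, exposure, and seeds; the round trip is
bit-exact. (The TIFF subset is implemented in-package — uncompressed,
little-endian, one strip per page — because no TIFF-capable R package is
available in the deployment environment; standard readers open the files.)
`run_pipeline()` executes any prefix of
phantom → simulate → recon → postproc → SM from a single JSON config,
records per-stage seeds, timings and output digests in a manifest, and is
digest-reproducible. Configs are JSON rather than YAML for the same
dependency reason.

## 11. Known limitations

No scatter, grids, heel effect, detector lag, or anthropomorphic anatomy;
AGD is a slab model suitable for ranking only; spectral tables are
approximate; the SM and slabbing algorithms are documented stand-ins for
proprietary product algorithms; iterative reconstruction and DICOM output
are out of scope. Desk-scale test sizes (coarser pitch, smaller detectors)
are chosen so the full suite runs in minutes; every geometric and
statistical claim tested is scale-free.
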