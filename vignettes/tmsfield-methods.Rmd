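---
title: "Modelling and predicting TMS electric fields with tmsfield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and predicting TMS electric fields with tmsfield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Transcranial magnetic stimulation (TMS) drives cortical neurons with the
electric field induced by a pulsed coil held against the scalp. Where and how
strongly the brain is stimulated depends on the coil pose and on the
conductive structure of the head, so treatment planning wants the induced
E-field for the *current* coil pose, updated as the coil moves. Conventional
finite-element pipelines deliver one accurate field per pose in seconds to
minutes; a navigation loop needs it in fractions of a second. The approach
implemented here follows the now-standard recipe: compute accurate fields
offline with a physics solver, train a volumetric convolutional surrogate to
map (tissue conductivity, coil primary field) to the induced field, and
stream predictions to the navigation side over a wire protocol.

`tmsfield` implements that entire loop in a self-contained, desk-scale form:
synthetic multi-shell spherical heads stand in for segmented MRI, a
finite-volume solver stands in for the FEM ground truth, and an in-process
transport stands in for the network link. Every stage is the real algorithm
at reduced size, not a mock.

## Physical model

Under the quasi-static approximation the induced field splits into a primary
and a secondary part,

$$ \mathbf{E} = -\frac{\partial \mathbf{A}}{\partial t} - \nabla\varphi, $$

where $\partial\mathbf{A}/\partial t$ is the time derivative of the coil's
magnetic vector potential and the scalar potential $\varphi$ enforces charge
conservation $\nabla\cdot(\sigma \mathbf{E}) = 0$ in the head, with zero
normal current through the scalp:

$$ \nabla\cdot\left(\sigma\,(\nabla\varphi + \partial_t\mathbf{A})\right) = 0
   \quad\text{in } \Omega, \qquad
   \mathbf{n}\cdot\sigma\,(\nabla\varphi + \partial_t\mathbf{A}) = 0
   \quad\text{on } \partial\Omega. $$

$\sigma$ is a per-voxel symmetric 3×3 conductivity tensor (S/m), anisotropic
in white matter. The field unit is V/m; world coordinates are RAS
millimetres, voxel indices 0-based, and the affine maps index to world.

### Coil model

The figure-8 coil is two coplanar counter-wound circular loops (default:
radius 27 mm, centres ±27 mm, 64 chords per loop, dI/dt = 1 MA/s — a
plausible proxy for a 70 mm treatment coil; vendors do not publish winding
geometry). Each straight segment contributes the closed-form line integral

$$ \frac{\partial\mathbf{A}}{\partial t}(\mathbf{r}) =
   \frac{\mu_0\,\dot I}{4\pi}\sum_s \hat{\mathbf{u}}_s
   \ln\frac{d_1 + d_2 + L_s}{d_1 + d_2 - L_s}, $$

with $d_1, d_2$ the distances to the segment ends and $L_s$ its length.
Chord vertices are placed on a slightly enlarged circle so each polygon's
area (hence magnetic moment) equals the continuous loop's; this removes the
systematic $O(1/n^2)$ amplitude bias of naive chord placement, and a 64-chord
coil then agrees with a 640-chord reference to a relative L2 error below
1e-7. Points closer than 0.5 mm to a wire have the integrand clamped (with a
warning) — they only occur in air next to the casing.

### Synthetic heads

`makeSphereHead()` builds five concentric shells (scalp 0.465, skull 0.010,
CSF 1.654, gray matter 0.275, white matter 0.126 S/m — standard literature
values; the shell boundaries default to fixed fractions of the outer radius).
Each voxel takes the conductivity of the innermost shell containing its
centre; a centre exactly on a boundary belongs to the outer shell. The desk
default is a 55 mm head on a 48³ grid of 2.5 mm voxels; 1 mm paper-scale
grids work through the same API. `randomizeConductivityTensors()` rebuilds
white-matter voxels with a random unit principal direction and eigenvalues
$(\lambda_1, \lambda_2, \lambda_2)$ with $\lambda_1/\lambda_2$ = 3 (a typical
mean white-matter anisotropy), preserving the trace exactly — this
synthesizes what diffusion MRI provides for real heads. Coil placements are
sampled from an idealized EEG 10–10 table (73 sites constructed from the
standard ring/arc geometry on the unit sphere) × evenly spaced handle
directions (default 78 over 360°, direction 0 at the "toward nasion"
tangent), with a 2 mm scalp standoff for the casing.

### Finite-volume solver

`solvePotentialFdm()` discretizes the conservation law with a cell-centred
finite volume scheme: the normal flux through each interior face couples the
two adjacent cells through the harmonic mean of their diagonal tensor
entries (exact for layered media), off-diagonal tensor components enter as
central-difference cross terms averaged to faces, and the *source* flux
$\sigma\,\partial_t\mathbf{A}$ uses the same transmissibilities as the
potential flux — the consistency that makes a gradient source
$\partial_t\mathbf{A} = \nabla\psi$ reproduce $\varphi = -\psi$ to 0.1% on a
48³ ball. Faces to masked-out cells are omitted (natural Neumann). The
symmetric isotropic system is solved with Jacobi-preconditioned conjugate
gradients to a relative residual of 1e-8; anisotropic cross terms make the
assembled operator nonsymmetric, and the solver then switches to
Jacobi-preconditioned BiCGSTAB with the same contract. The potential is
gauged to zero mean over the mask. `totalEfield()` assembles
$\mathbf{E} = -\partial_t\mathbf{A} - \nabla\varphi$ with central differences
(one-sided at the mask boundary) and zeroes the field outside the head.

**Staircase boundaries and where to trust the field.** A voxelized sphere
has axis-aligned boundary faces, so the discrete zero-flux condition is
imposed on a staircase rather than the smooth scalp. The resulting error is
confined to a one-voxel boundary layer but is locally large: on symmetry
oracles (where the continuum answer is exact) the maximum tangentiality
violation over the *whole* head mask stays at tens of percent regardless of
resolution, while two voxels in it drops to ~2% and in the cortical
compartment below 1%. We examined graded (partial-volume and smoothstep)
boundaries and an embedded-boundary (cut-cell aperture) scheme; none brings
the full-mask maximum near the interior values, because any low-conductivity
transition voxel amplifies spurious normal currents as $1/\sigma$. The
package therefore defines its physics validation on the cortical
compartment — inside the gray-matter radius (or 0.8 of the outer radius for
single-shell symmetry phantoms) — which is also the region whose field the
surrogate and the navigation display actually use. On that compartment, at
48³: a coaxial loop over a uniform sphere leaves
$\max\lVert\nabla\varphi\rVert < 1\%$ of $\max\lVert\partial_t\mathbf{A}\rVert$,
and the total field on the five-shell head has a maximal radial component
below 5% of the field maximum for arbitrary coil poses, decreasing
monotonically under grid refinement (24³ → 48³ → 64³). Conductivity-scale
invariance and dI/dt linearity hold to machine precision.

### Training cases

`groundTruthCase()` computes dA/dt on the head grid, solves for $\varphi$,
forms $\mathbf{E}$, and crops everything to a reduced field of view centred
at the coil's scalp projection (desk default 24³ at 2.5 mm; the paper-scale
70×90×50 shape is available via `paperScaleConfig()`). The network input
concatenates 6 conductivity-tensor channels (xx, yy, zz, xy, xz, yz) and 3
dA/dt channels; the target is the 3-channel E-field. An FOV reaching past
the grid is clipped with zero fill and a warning.

## The surrogate

The surrogate is a residual 3D U-Net with deep supervision: a stem
convolution, one residual block per resolution level (identity shortcut
around a 3³ convolution), stride-2 convolutions down, nearest-neighbour
upsampling + convolution up, additive encoder skips, and 1³ output heads at
every decoder scale. The loss is the voxelwise vector mean-squared error at
full resolution plus auxiliary MSEs against average-pooled targets at the
two coarser scales, weighted 1 / 0.5 / 0.25 ("multi-scale" is not further
specified in the literature this follows; deep supervision at the decoder
scales is our documented reading). Inputs are z-scored per channel and the
target is scaled to unit RMS; both statistics are stored in the checkpoint
and inverted at prediction time.

Training uses Adam (β = 0.9/0.999) with linear warmup over 5% of the steps
followed by cosine decay to zero. The defaults — 3 levels, 4 base channels,
batch 4, peak learning rate 3e-3 — were sized on solver-generated data so a
100-epoch run on 52 cases of 24³ trains on one desktop CPU core in minutes;
at this scale the wider/slower variants we tried (8 base channels, lr 1e-3)
learned no better per wall-clock. Convolutions run in single precision
through im2col + GEMM kernels (Rcpp/Armadillo) with a hand-derived backward
pass verified against finite differences in the test suite; training is
bitwise reproducible for a fixed seed.

Accuracy is reported as the normalized root-mean-square error

$$ \mathrm{NE} = \sqrt{\frac{\sum_{\text{mask}} \lVert \mathbf{E}_{\mathrm{pred}}
- \mathbf{E}_{\mathrm{true}}\rVert^2}{\sum_{\text{mask}} \lVert
\mathbf{E}_{\mathrm{true}}\rVert^2}}, $$

so 0 is perfect and the zero predictor scores exactly 1. The vector residual
over the full FOV is our documented choice (whether the reference work
masked or used magnitudes is not printed); the field *magnitude* is what the
streaming loop ships, derived per voxel from the vector prediction. At the
desk scale (64 synthetic cases, 24³ FOV, 100 epochs, CPU) held-out NE
reaches ≈ 0.8 — far from the ≈ 0.2 reported for the full-scale pipeline
(hundreds of real-MRI cases, 2000 GPU epochs), which this package explicitly
does not attempt to reproduce. What the desk runs *do* establish is that the
implementation learns: NE drops well below both the untrained network and
the zero predictor, deterministically.

What the synthetic generator does not emulate: real cortical folding (the
solver's fields on spheres are smoother than on real gray matter), realistic
skull thickness variation, diffusion-tensor-derived fibre coherence (ours is
voxelwise random), and measurement noise. Passing tests on synthetic heads
therefore validate the machinery and its physics, not clinical accuracy on
real anatomy.

## Streaming loop

The wire format is an OpenIGTLink v2 subset: a 58-byte big-endian header
(version, 12-byte type name, 20-byte device name, 32+32-bit timestamp,
64-bit body size, CRC-64/ECMA checksum of the body) followed by the body.
TRANSFORM bodies are 12 float32 values (rotation column-major, then offset,
48 bytes); IMAGE bodies carry dimensions, spacings and a dtype tag ahead of
the voxels, which travel as float64 so the streamed magnitude image is
bit-identical to the in-process prediction. Only these two message types are
implemented — the pair the prediction loop uses; decoding verifies framing,
type and checksum, and a flipped body byte is detected. The float32
TRANSFORM quantizes the rotation slightly; decoding re-orthonormalizes via
SVD so downstream code always sees a valid rigid pose.

`runServerLoop()` serves poses: for each TRANSFORM it crops the conductivity
to the model's FOV at the pose's scalp projection, evaluates dA/dt
analytically on that FOV, predicts, and replies with the magnitude IMAGE,
recording the prediction time (`cnn_seconds`) and the encode/send time
(`vis_seconds`) separately per run — the split used by the timing tables. A
malformed frame draws an identity-TRANSFORM reply from device `"ERROR"` and
the loop continues; an exhausted transport aborts with partial statistics.
Transports are pluggable: `localTransport()` (ordered, reliable, in-process;
what the tests and demo use) and `tcpTransport()` with the same interface
for deployment against OpenIGTLink-speaking navigation software
(compatibility is intended but not certified here).

## Evaluation machinery

`timePipeline()` summarizes per-run times as mean ± sample SD over exactly
`runs` records (default 50, the published protocol). `twoSampleTTest()` is
the pooled-variance two-sided independent-samples test with
df = n1 + n2 − 2; pooling (rather than Welch) matches the published df = 38
for two groups of 20, and on the packaged data both variants agree to three
significant figures. A packaged fixture transcribes the published 10-subject
× 2-machine visualization-time comparison between a FEM tool and the
real-time pipeline, *verbatim* including its printed quirks (the real-time
tool's per-subject "mean" column repeats its second-machine cell; one cell
is printed with six decimals; the printed per-subject improvement factors do
not exactly equal the ratios of the printed means). `reproduceTable2()`
therefore reports improvement factors in both the as-printed and the
recomputed interpretation, pools the 20 cells per tool (7.58798 ± 0.59553 s
vs 0.08506 ± 0.02365 s), and recovers t(38) = 56.3, p < 0.0001.

## Numerical choices and degenerate inputs

* Interpolation: trilinear for fields, nearest for masks; out-of-bounds
  samples are zero records (fields vanish away from the head).
* Shell ties: a voxel centre exactly on a shell radius belongs to the outer
  shell; a centre exactly on the scalp radius is inside the mask.
* Solver: relative residual ≤ 1e-8, iteration cap 1000·N^(1/3); zero source
  returns φ ≡ 0 without iterating; non-convergence is an error carrying the
  final residual; grids must be axis-aligned (resample first otherwise).
* Zero pooled variance in the t-test: equal means → t = 0, p = 1; unequal →
  flagged infinite t.
* NE with zero-energy truth is an error, not NaN.
* All seeded code draws from an isolated RNG stream and restores the
  caller's.

## Problem sizes

The defaults are chosen so every documented run fits a single desktop CPU
core: head grids 48³ (solves in seconds), training sets of 64 cases at 24³
(the full generate-train-evaluate cycle in minutes), 50-run streaming
sessions (seconds). The same code paths accept paper-scale inputs (1 mm
grids, 70×90×50 FOV, 300 placements) — only time separates the two regimes.

## Known limitations

* Voxelized staircase boundaries: fields within ~2 voxels of a tissue
  interface carry locally large discretization error; trust the cortical
  compartment (see above).
* The solver is a voxel method; it will not numerically match a
  conforming-mesh FEM cell-by-cell, and no parity with external tools is
  claimed.
* The 10–10 table is the idealized spherical construction, appropriate for
  spherical phantoms only.
* TRK tractography and HDF5 containers are not read or written; streamlines
  use JSON polylines and datasets/checkpoints use RDS files.
* The TCP transport is provided for deployment but the shipped tests
  exercise the in-process transport only.
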