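---
title: "Segmenting the fascia lata and quantifying intermuscular fat: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting the fascia lata and quantifying intermuscular fat: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the model behind
each pipeline stage, the parameters that matter and why their defaults
are what they are, what the synthetic phantom does and does not emulate,
and the numerical decisions a maintainer would want written down.

## The segmentation model

The thigh cross-section, outside the femur, is a nested arrangement:
skin, subcutaneous adipose tissue (SAT), the fascia lata (FL) — a thin
fibrous sheet forming a closed 3D surface — perimuscular adipose tissue,
and the muscle ensemble with intramuscular fat inclusions. On
T1-weighted images the four relevant intensity populations are ordered
`bone/background < fibrous < muscle < adipose`, which is the single
assumption the clustering stage relies on. Everything downstream is
geometry: the muscle ensemble is the innermost large connected body, the
FL is the only *closed* plate-like fibrous surface outside it, and
intermuscular adipose tissue (IMAT) is the adipose volume the FL
encloses (femur excluded).

### Bias correction (`correct_bias`)

The multiplicative scanner field is modelled as `exp(P(x))`, `P` a 3D
polynomial of total order 3 in per-axis coordinates normalised to
[-1, 1]. The fit alternates a 1D k-means assignment of the log
intensities (k = 6; with a thigh mask the log-intensity mixture has six
visible populations — clipped background, cortical bone, fibrous,
muscle, skin, adipose — and a coarser k merges cortex with fibrous and
lets the polynomial absorb anatomy) with a least-squares fit of the
log-residuals, damped by 0.7, residuals trimmed at 3 MAD so thin or rare
tissues cannot bend the field. Convergence: maximum log-field update
below 1e-3, at most 20 iterations; non-convergence returns the last
iterate with a warning rather than failing, since a slightly
under-converged field is still usable by the clustering. The
reconstructed field is clamped to its in-mask range (the polynomial is
unconstrained outside the fit mask) and normalised to mean 1 over the
mask. The k-means step uses a fixed internal seed and multiple starts,
so the whole correction is deterministic.

### Fuzzy c-means (`fcm`, `harden`)

Standard FCM on scalar intensity with m = 2, tolerance 1e-4 of the
intensity range, at most 200 iterations, centres initialised at the
5/35/65/95th percentiles — deterministic, no random initialisation.
Identical intensities are pooled, making each iteration O(#unique
values). The objective `sum u^m d^2` is recorded per iteration and
asserted non-increasing in the tests. Hardening takes the argmax
membership; ties break toward the lower-intensity cluster, and tissue
names attach to clusters by ascending centre intensity, so any
permutation of cluster indices yields the same label map.

Thigh extraction removes an outer rind of 2 in-plane voxels where the
intensity exceeds the midpoint of the muscle and adipose centres (the
skin); structuring elements are 2D in-plane disks because 3 mm slices
against 0.5 mm in-plane voxels would smear any 3D element across
anatomy. Connected components, by contrast, are genuine 3D
(6-connectivity). The femur is the interior bone-cluster component
nearest the thigh centroid, hole-filled per slice to include the marrow;
its absence is an error, not an empty mask.

### The two level sets (`muscle_envelope`, `fl_surface`)

Both fronts use the same discrete geodesic-active-contour scheme: a
threshold-dynamics approximation in which the front contracts by one
in-plane voxel per iteration (balloon −1), voxels where the stopping
function `g` falls below `g_stop` are frozen once reached, and an
in-plane morphological opening every 5 iterations plays the curvature
term. Every update is a subset of the previous front, so the scheme is
unconditionally stable, monotonically contractive, and deterministic —
the properties a PDE upwind solver would only give conditionally.
Convergence: fewer than 0.01 % of grid voxels changing over 5
consecutive iterations, capped at 300.

The envelope's stopping function is `g = exp(-s |grad u_muscle|)` with
gradients in mm; `s` is calibrated so that `g` equals 0.1 at the 90th
percentile of the gradient magnitude *among edge candidates* (voxels
above 10 % of the maximum gradient). Restricting the calibration to
candidates matters: over all voxels the 90th percentile sits at the
noise floor and the front would freeze everywhere. `g_stop = 0.2`
freezes the front on the strong muscle-boundary band only. Because the
band's outer skirt lies about one voxel outside the true muscle surface,
the converged region is eroded by one in-plane voxel (`tighten = 1`);
without this the envelope systematically carries a one-voxel rim of
perimuscular fat, which inflates IMAT_ME. Isolated muscle-labelled
islands in the SAT (veins) disconnect from the main body and are
discarded with the largest-component step.

The fascia front uses `g = 1 - w` with the plate-likeness weights
dilated by one in-plane voxel (bridging single-voxel evidence gaps) and
`g_stop = 0.3`; the muscle envelope is locked, so `ME ⊆ IF ⊆ thigh` by
construction. After convergence the undilated evidence band itself is
removed from the region: the intra-fascia VOI is what the FL *encloses*,
so it ends at the sheet's inner surface. Fibrous fragments that do not
close around ME — the saphenous-fascia decoy — are passed by the front,
left as disconnected debris, and removed; with zero fascia evidence the
front collapses onto ME and the result is flagged degenerate rather
than failing, so batch runs complete and flag themselves for refinement.

### Plate filtering (`hessian_eigen`, `plate_weight`)

Hessians are computed on the Gaussian-smoothed volume at scales
{1.0, 1.5, 2.5} mm (the FL is nominally 1–2 mm thick), derivatives in
mm, scale-normalised by sigma squared; through-slice components are
down-weighted by the in-plane/through-slice spacing ratio because 3 mm
slices undersample the sheet along z and unweighted z-curvature is
dominated by slice jumps. Eigenvalues come from the closed-form
trigonometric solution for symmetric 3x3 matrices, vectorised over the
grid, sorted by absolute value. The sheetness combines
`R_sheet = |l2|/|l3|` (alpha = 0.5), `R_blob = |l1|/sqrt(|l2 l3|)`
(beta = 0.5) and the Frobenius norm `S`; polarity is gated to dark
sheets (`l3 > 0`), since the FL is hypointense inside bright SAT. The
structureness cutoff is adaptive, `c = S_max/4` over the support
(fibrous voxels outside ME): because that support is dominated by the
fascia itself, the conventional half-max would cap the true sheet's
weight near 0.7; a quarter-max leaves the sheet near 1 while still
suppressing low-`S` noise structures. Weights are taken as the maximum
over scales and zeroed outside the support, so adding a constant to the
image leaves them unchanged.

### Livewire refinement (`cost_map`, `shortest_path`, `propagate_seeds`)

The cost is `w_edge (1 - G) + w_fascia (1 - w)` with `G` the in-plane
gradient magnitude normalised per slice and defaults
`w_edge = 0.6, w_fascia = 0.4` — the fascia term is secondary because it
is zero off the fibrous cluster. Paths are 8-connected, each step
costing the mean of the endpoint costs times the Euclidean step length.
The A* heuristic (Euclidean distance times the slice-minimum cost) never
overestimates and is consistent, so the search is exactly optimal — the
tests assert equality with a textbook Dijkstra on random grids — and
ties break by lexicographic voxel order for determinism. Seeds propagate
to the next 10 slices, each snapping to the minimum-cost voxel in a
7x7 window (window 3); a snap landing outside the mask leaves the seed
unsnapped and flagged. Contour application fills the closed polygon with
even-odd parity, boundary voxels included (a side-`s` square fills
exactly `s^2` voxels), rejects self-intersecting contours, and touches
only the edited slice. The Laplacian zero-crossing term of the classic
intelligent-scissors cost is omitted; the gradient and fascia terms
already define the paths of interest here.

### Registration and FF quantification (`register_rigid`, `mt_threshold`, `ff_mt`)

The T1w-to-Dixon transform is 6-DOF rigid, found by maximising mutual
information over voxels of the fixed thigh mask, the moving image
interpolated linearly. The joint histogram (32 bins per axis, fixed
value ranges) uses bilinear Parzen binning — with hard binning the
discretisation noise exceeds the rotational signal near the optimum.
Translation is initialised at the mask-centroid offset; optimisation is
Nelder-Mead at two sampling levels (20 000 samples, then up to 120 000 —
the thin structures carry the rotation information, so the fine level
needs a dense sample). Masks are resampled nearest-neighbour, scalar
volumes trilinearly, out-of-field voxels taking a declared fill value.

Muscle tissue is separated from adipose tissue inside the IF VOI on the
FF volume by the minimum of the log(1 + count) histogram (bin width 10
intensity units = 1 % FF, moving average of 5 bins). Two details make
the minimum well-defined: the secondary mode must rise at least 1
log-unit above the inter-mode valley (noise bumps are not tissue
modes; failing this, the result is flagged unimodal with fallback
threshold 500), and when the inter-mode bins are empty the minimal
plateau's *middle* bin is taken — the first empty bin would bias the
threshold toward the muscle mode. Muscle tissue is `FF < threshold`
(strict), and `FF_MT` is the mean FF intensity over that mask divided by
10 (scanner scale 0–1000 = 0.0–100.0 %).

Quantification trims the first and last 3 slices (segmentation support
is weakest at the stack edges) and reports IMAT volumes as adipose voxel
count times voxel volume; IMAT_ME uses the identical code path with the
envelope as region, so the FL-vs-ME comparison is a pure region swap.

### Precision statistics (`rms_sd`, `rms_cv`)

Per-subject standard deviations use the sample (n−1) denominator — the
convention of the standard precision-error framework; the root mean
square over subjects gives RMS-SD in the variable's units and RMS-CV in
percent. Both are invariant to subject order; RMS-SD scales linearly
under unit change while RMS-CV does not.

## The phantom: what it emulates, what it does not

`phantom_spec()` encodes the acquisition this pipeline targets: 0.5 x
0.5 x 3.0 mm T1w voxels with a paired 0.8 x 0.8 x 3.0 mm FF volume
under a small rigid offset (defaults: 1.5 degrees in-plane, ~2.5 mm
translation), FF intensities 0–1000 for 0.0–100.0 %. The default grid
(152 x 152 x 17) holds a reduced-field thigh of 32 mm mean radius: all
tissue interfaces keep their real voxel-relative scale (the FL is 3
in-plane voxels thick) while volumes stay small enough for a full
pipeline run in tens of seconds; the unit-test fixture shrinks further
to 96 x 96 x 12 at 20 mm radius.

Geometry choices, made once:

* Cross-sections are star-convex perturbed circles (harmonics 2–4,
  amplitudes 1–4 %) — circles would make the envelope step degenerate.
* The FL centre drifts sinusoidally through the stack (amplitude
  1.5 mm), so the sheet is a genuine 3D surface that exercises the 3D
  plate filter and the slice propagation.
* The perimuscular ring's area is an exact fraction `f` of the
  intra-fascia area (`r_ME = sqrt(1-f) * r_IF` for similar outlines),
  so the truth IMAT difference is analytic.
* Intramuscular streaks are radial segments, evenly spaced with a random
  rotation and small jitter. Independently uniform angles make spokes
  overlap near the centre, so the streak volume saturates stochastically
  and no batch can show the strong linear FL-vs-ME relation that
  motivates the method; evenly spaced streaks match the
  between-compartment anatomy of fat infiltration. Streaks keep a
  clearance of 2 mm + half their width from the muscle surface.
* The saphenous decoy is a 60-degree fascia-like arc in mid-SAT — a
  schematic, not an anatomically calibrated vessel sheath.
* Noise is additive Gaussian (sd 15 against class gaps >= 150), not
  Rician: downstream stages respond to contrast, not to noise tails.
* The bias field is `exp(polynomial)`, about +/-10 % across the grid.

The phantom does **not** emulate: partial-volume averaging (voxels are
pure classes plus noise), chemical-shift or k-space artefacts, per-muscle
anatomy within the ensemble, or fascia thinning/interruption. Passing
the phantom suite therefore demonstrates the pipeline's geometric and
numerical correctness — boundary placement, ordering, invariants,
recovery of known quantities — not robustness to partial volume or
pathology; on clinical data the livewire refinement exists precisely for
the cases the automatic stages miss.

## Validation suites and problem sizes

The acceptance tests run ten full-size phantoms spanning perimuscular
fat fractions 0.055–0.19 with 3–6 streaks (fixed seeds) for the Dice and
IMAT-recovery checks, two of them with distinct rigid offsets (up to
4 mm / 3 degrees) for registration recovery; the FL-vs-ME relation uses
twenty reduced-field phantoms whose perimuscular fraction (0.046–0.35)
and streak load (count 3–8, width 0.86–2.0 mm) grow together, emulating
a young-to-sarcopenic range — both fat compartments scale with overall
adiposity, which is what makes the two IMAT measures strongly linearly
related in the first place. `scripts/acceptance.R` reruns the same
computations from scratch (one full pipeline, a 12-phantom batch, the
oracle checks) and writes every number it reports as JSON.

## Known limitations

* NIfTI-1 is the only on-disk format; no DICOM reading (no R reader
  available) and no DICOM writing.
* The morphological level set moves in whole-voxel steps in-plane; the
  boundary is accurate to about one voxel, which is also why the
  envelope needs its final one-voxel tightening.
* Registration assumes a mostly in-plane offset regime (multi-slice
  stacks provide coarse z-resolution; the z-translation is the least
  constrained parameter).
* The FF histogram threshold needs two separated modes; very lean
  subjects with little IMAT may trigger the unimodal fallback.
* `correct_bias` fits one global polynomial; fields with structure
  beyond order 3 are only partially removed.
EOF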