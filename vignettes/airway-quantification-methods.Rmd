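---
title: "Airway quantification in bronchiq: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Airway quantification in bronchiq: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: what each stage of
the pipeline assumes, which parameters matter and why their defaults are
what they are, what the synthetic phantoms do and do not establish, and
where the design was genuinely open.

## The measurement problem

The inputs are a chest CT volume (Hounsfield units) and a co-registered
binary segmentation of the airway lumen. The outputs are per-segment lumen
geometry and two patient-level biomarkers of traction bronchiectasis:
median intersegmental tapering, `100 (d_p - d) / d_p`, and median
segmental tortuosity, `L_a / L_e`, over airway generations 2–6, plus the
total number of airway segments identified. All geometry is computed in
world millimetres with voxel positions `origin + index * spacing`, after
reorientation to a fixed right–anterior–superior (RAS) axis convention; the
lobe classifier and the trachea-seed heuristic depend on that convention.
Masks must be voxel-aligned with the CT — the package deliberately never
resamples a mask, so measurement provenance stays trivial.

## Mask preparation

Closing uses a spherical element whose radius (default: one smallest-voxel
width) is converted per axis to voxels, rounded up. The default is the
smallest element that can bridge a one-voxel gap — segmentations typically
lose thin airway necks one voxel at a time, and a larger element would
start welding adjacent branches. Afterwards only the largest 26-connected
component survives. 26-connectivity is used throughout for the foreground
because thin distal airways are often only diagonally continuous at the
voxel scale; ties between equal components are broken towards the lowest
voxel index so the stage is deterministic.

## Skeletonization

The centreline is obtained by distance-ordered homotopic thinning: voxels
are peeled in increasing chamfer (3-4-5) distance order, a voxel being
removable only if it is *simple* — its removal provably preserves local
topology (one 26-connected object component in the 26-neighbourhood, one
6-connected background component in the 18-neighbourhood adjacent to the
voxel) — and not a curve endpoint. Two refinements matter in practice:

- **directional sub-iterations.** Within one iteration, six sub-cycles
  each admit only voxels whose background neighbour lies in one designated
  direction. This allows a redundant parallel voxel column to collapse
  laterally in a single sub-cycle while limiting erosion along a
  structure's axis to one layer per iteration.
- **geodesic anchors.** Even with endpoint preservation, a tube whose axis
  falls exactly midway between voxel columns can erode away completely:
  no curve endpoint ever forms, and every voxel stays simple until the
  structure vanishes (reference implementations of standard 3D thinning
  show the same behaviour on such inputs). The package therefore computes
  the geodesic distance from the trachea seed inside the mask and forbids
  removal of one voxel per local-maximum plateau — exactly one anchor per
  branch tip. This is the same physical idea as wavefront-propagation
  centreline methods: the farthest geodesic points are the branch ends.

The trachea seed is the centroid-nearest foreground voxel of the largest
component within the most superior 5% of foreground-bearing axial slices —
the trachea is reliably the most superior airway structure in a chest CT.

Three clean-up passes follow. *Cycle breaking*: the skeleton's voxel
adjacency is spanned by a shortest-path tree from the root; non-tree
adjacencies with fundamental cycles shorter than 5 mm are corner artifacts
of diagonal connectivity and are ignored, longer ones are genuine loops
(segmentation leaks) and are cut at their midpoint, avoiding junctions.
*Spur pruning*: terminal chains shorter than 2 mm — or shorter than 1.2×
the local lumen radius at their attachment, whichever is larger — are
thinning artifacts of bumpy masks and junction bulges (a junction between
tubes of radius r sprouts anchor spurs up to about r long, so a fixed
threshold cannot be right at all calibres). *Tip retraction*: an
endpoint-preserving skeleton runs to the apex of a rounded airway tip,
overshooting the medial endpoint by the local radius; each terminal chain
is retracted by the local distance-transform plateau minus the tip's own
boundary distance. Without retraction, terminal segments are too long
(biasing tortuosity denominators) and their diameter series dip into the
closing tip.

## Graph extraction and anatomy

Nodes are voxels where the spanning structure branches or ends; edges are
maximal single-child chains, oriented proximal→distal. Internal edges
shorter than 2 mm (default) are merged into their parent — the junction
slides distally, turning a near-trifurcation that thinning split into two
junctions back into one. Generation counting starts at the trachea
(generation 0) and increments at every division, so the main bronchi are
generation 1 and lobar bronchi typically generation 2; the analysis window
2–6 therefore starts at the lobar bronchi. Generations are counted
globally from the trachea by default; the per-lobe restart
(`lobar_generation()`) is computed and exported but not used in the
default summaries, because the global count is unambiguous for a window
definition while the lobar count depends on where each lobar seed happens
to sit.

The lobe classifier is direction-based. At the first division the most
rightward/leftward children (RAS x component) are the main bronchi. On
each side the most superior-directed child of the main bronchus seeds the
upper lobe; when one sibling remains it is the intermediate bronchus
(labelled with the trachea/main class) and at its next division the most
anterior-directed child seeds the middle lobe — the lingula playing the
left middle lobe — with the rest seeding the lower lobe; when several
siblings remain the same middle/lower rule applies to them directly.
Descendants inherit their seed's lobe; a two-column `node_id,lobe` CSV of
overrides relabels whole subtrees and always wins. The same rule is used
on both sides deliberately: it makes the labelling exactly
mirror-symmetric (left–right reflection swaps R and L labels segment for
segment), which is both anatomically defensible — the lingula behaves as
the left homologue of the right middle lobe — and testable as a hard
invariant. An asymmetric variant that nests the lingula inside the
left-upper subtree was considered and rejected because it cannot satisfy
the mirror invariant exactly on asymmetric trees.

## The caliper

The measurement interval is half the smallest voxel dimension
(0.4 mm for 0.8 × 0.8 × 1.0 mm voxels); the patch pixel pitch defaults to
the same value, keeping sub-voxel resolution consistent between the
centreline walk and the cross-sectional image.

**Centreline spline.** Each segment's voxel path is fitted per coordinate
with a cubic smoothing spline parameterised by cumulative chord length.
The smoothing strength is chosen deterministically: the stiffest spline
(smallest equivalent degrees of freedom from the ladder 2, 3, 4, 6, 8, 12,
16, 24, 32) whose maximum 3D deviation from the path stays within one
voxel, then one ladder step finer. The rationale: the discrete skeleton of
a straight oblique tube is a staircase with ~half-voxel excursions — an
interpolating spline would inflate its arc length by several percent,
destroying tortuosity — while genuine airway curvature lives at
supra-voxel scales. The one-step refinement halves the amplitude
attenuation of real curvature at negligible staircase cost (the residual
tolerance alone would allow a fitted sinusoid to be shaved by up to a
voxel of amplitude). Arc length is then computed by quadrature at a tenth
of the measurement interval; Euclidean length is the distance between the
spline endpoints.

**Perpendicular patches.** At each sample the CT is resampled by
trilinear interpolation on a square grid normal to the local tangent,
capped at 40 × 40 mm — large enough to frame any airway including the
trachea. The in-plane basis is deterministic (tangent × global z,
falling back to global x for vertical tangents), out-of-volume samples
are filled with −1000 HU and flagged.

**FWHM edge-cued ellipse.** From the patch centre — first re-centred on
the centroid of the connected low-HU (< −800) region containing it, since
the skeleton may sit slightly off-axis — intensity profiles are cast at
60 equally spaced angles, sampled every half pixel. On each ray the wall
is the HU maximum beyond a 0.5 mm dead zone (rejecting centre noise) and
must rise at least 100 HU above the lumen baseline (the minimum HU between
centre and peak). The wall is modelled as a Gaussian in radius, fitted in
closed form by an intensity-weighted log-parabola (Caruana/Guo) over a
window from 2 mm inside the peak to 0.75 mm outside it — asymmetric
because the outer flank sits on the parenchymal baseline, not the lumen
baseline that the half-maximum refers to. The lumen boundary is the inner
radius where the fitted Gaussian crosses halfway between peak and lumen
baseline, `mu - sigma_wall * sqrt(2 ln 2)`. Two numerical details:

- the *fitted* width includes the variance of the package's own
  resampling kernels (trilinear volume→patch and linear patch→profile
  interpolation), which is known exactly per ray direction; it is
  subtracted in quadrature before the half-maximum offset is computed.
  Scanner PSF and partial-volume blur are unknown in practice and are
  deliberately not corrected — the measured wall width absorbs them, as
  in any FWHM-based caliper.
- when the Gaussian fit degenerates, the boundary falls back to direct
  linear interpolation of the half-maximum crossing on the raw profile.

Boundary radii more than 3 scaled MADs from the median are discarded; a
direct least-squares (Fitzgibbon) ellipse is fitted to the survivors; at
least 60% of rays must survive for a valid fit; the diameter is the
geometric mean `2 sqrt(r_minor r_major)`. A sample is additionally invalid
when its (refined) centre is brighter than −800 HU: the edge-cue model
requires a resolvably dark air core, and below roughly two voxels of lumen
diameter partial volume lifts the centre intensity and the technique's
output is no longer meaningful — such airways are flagged rather than
mismeasured. A segment's mean diameter is the mean over valid samples; a
segment is invalid when fewer than half its samples are valid. One robust
consistency filter operates at segment level: samples whose diameter
stands more than `max(4 MAD, 25%)` off the segment's median are flagged —
at a junction the "cross-section" opens into the parent or child lumen and
the ellipse no longer measures this segment; the threshold's relative part
is wide enough to keep genuinely tapering cones.

## Phantoms: what they establish and what they cannot

A phantom is a declarative tree of tube branches — straight chord plus an
optional single-cycle sinusoidal displacement, linear radius taper along
the branch — rendered at 2× supersampling (partial-volume realism at the
voxel boundary) with the radial model: lumen −1000 HU, Gaussian wall of
width σ = 0.6 mm peaking at 0 HU, parenchymal background −850 HU,
optional seeded Gaussian noise. The wall Gaussian is centred at
`r + sigma sqrt(2 ln 2)` so that the *declared lumen radius is exactly the
inner half-maximum radius of the rendered wall* — the quantity an FWHM
caliper is defined to measure. (Centring the wall at the radius itself
would make the declared value unrecoverable by construction: the inner
half-maximum of such a wall lies `sigma sqrt(2 ln 2)` ≈ 0.7 mm inside the
declared boundary, which is a property of the rendering, not of any
measurement method.) Ground truth — mean diameter, arc and Euclidean
length, tortuosity, tapering versus parent — is computed analytically or
by fine quadrature, never by the pipeline under test.

The standard cohort generator draws, per case, a taper fraction from
U(0.20, 0.30) — bracketing the ~25% narrowing per division of healthy
airways — and a sinusoid amplitude-to-length ratio from U(0, 0.03), builds
the six-lobe tree (trachea radius 4.5 mm, radii shrinking by the taper
fraction at each division, branch lengths decaying geometrically, split
planes alternating so subtrees spread in 3D without collision) down to
generation 6 at 0.75 mm isotropic voxels, and records the drawn parameters
in the truth table. All branches of a case share one amplitude ratio, so
the whole case has a single analytic tortuosity — which is what makes
median-recovery checks sharp. Distal generations of a strongly tapering
case fall below the two-voxel resolvability floor; they are correctly
flagged invalid by the dark-core criterion and drop out of the medians,
which is the intended behaviour, not a loss.

What passing phantom tests shows: the geometry chain (thinning → graph →
spline → perpendicular resampling → FWHM ellipse → metrics) is correct and
unbiased to within the stated tolerances under the model's own contrast
assumptions. What they cannot show: robustness to real segmentation
pathology (leaks, missing subtrees), breathing artefacts, scanner PSF
variation, mucus plugging, or anatomical variants of the lobar bronchi —
the phantom's lobar geometry is stylised, and real trees with very short,
wide proximal bronchi can make a curve skeleton place a junction
proximally of its anatomical position. The direction-based lobe classifier
is a heuristic; the override mechanism is the guaranteed-correct path on
real data.

## Reproducibility and problem sizes

Everything in the main pipeline is deterministic: fixed tie-breaks
(lowest voxel index) in components, thinning order, BFS edge order, and a
deterministic spline-stiffness ladder. The only randomness anywhere is the
phantom noise and cohort parameter draws, both seeded. Re-running a saved
configuration reproduces `segments.csv` and `patient_summary.csv` byte for
byte.

The validation suite exercises: cylinders with radii 1.5–6 mm at 0.6–1.0 mm
voxels (diameter recovery within half a voxel or 5%); straight and
sinusoidal tubes with analytic tortuosity up to ≈1.26 (recovery within
0.02, straight within 0.001); six-lobe trees of 31 branches with uniform
25% narrowing (median tapering within ±3 points) and an equal-diameter
tree (within ±2 of zero); and a three-case cohort at generation depth 4,
run twice, for byte-level determinism. These sizes keep a full run in the
low minutes while covering every code path; the generator accepts deeper
trees (the cohort default is generation 6) for larger studies.

## Known limitations

- The FWHM caliper reads low by 2–5% of the diameter near the resolution
  limit; uncorrected scanner-and-rendering blur shifts the inner
  half-maximum inwards. The bias shrinks with voxel size and is smallest
  for large airways.
- Curve skeletons of short, wide branches (length below ~1.6× the sum of
  parent and child diameters) can split prematurely at junctions; the
  short-edge merge recovers mild cases.
- Lobar labels on atypical anatomy (tracheal bronchus, accessory lobes)
  need the override file.
- The tapering sign convention is `100 (d_p − d)/d_p` (positive = normal
  narrowing, reduced values = disease), recorded in every export; cohort
  tortuosity can optionally be z-standardised in the survival table
  export, since raw medians sit close to 1 with small dispersion.
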