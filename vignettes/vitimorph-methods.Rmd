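---
title: "Methods: seed outline morphometrics and stepwise discriminant classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed outline morphometrics and stepwise discriminant classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitimorph)
```

## The problem

Grape pips are among the commonest plant macro-remains on archaeological
sites, and whether they come from gathered wild vines (*Vitis vinifera*
subsp. *sylvestris*) or cultivated ones (subsp. *vinifera*) bears directly
on when viticulture began in a region. Wild pips are small and round with a
short stalk; cultivated pips are larger, elongated and pyriform. The
classical breadth:length (B:L) index separates fresh material reasonably
well, but almost all archaeological pips are *charred*, and carbonisation
systematically inflates B:L and shrinks the seed, so charred cultivated
pips masquerade as wild ones under the old index. The workable strategy is
therefore: build a reference collection of *experimentally charred* modern
seeds of known status, measure shape exhaustively, train a discriminant
classifier, and classify archaeological material as unknown lots against
that charred reference. This package implements the measurement and
classification machinery, plus a synthetic image generator that stands in
for the (unpublished) scan collections so that every stage is testable.

## Pipeline overview

One *observation* is one seed side: seeds are scanned twice (ventral and
dorsal), and the two sides enter the analysis as independent cases — an
8-seed archaeological lot contributes 16 rows. Per image:

1. binarize (Otsu by default) → 2. label 8-connected particles, fill
holes, drop border-touching particles and specks → 3. Moore-trace each
boundary to a Freeman chain code → 4. measure 26 shape descriptors →
5. compute 77 normalized elliptic Fourier descriptors (EFDs) at 20
harmonics → 6. assemble the 103-column feature table → 7. stepwise linear
discriminant analysis with leave-one-out cross-validation → 8. classify
unknown lots and print percent-with-count cross-tabulations.

## Segmentation conventions

* **Thresholding.** Otsu's histogram criterion on the 256-bin gray
  histogram, foreground = dark phase; a fixed manual threshold and an
  inversion flag are available. Scanner setups differ, so the method is a
  declared default, not an inference.
* **Connectivity.** Foreground is 8-connected, background 4-connected —
  the combination consistent with 8-direction Freeman chains.
* **Holes.** Interior holes are filled before measurement (charred seeds
  often scan with bright specks); all descriptors assume a filled
  silhouette.
* **Boundary tracing.** Moore neighbour tracing over boundary *pixel
  centres*, started at the topmost-then-leftmost foreground pixel with
  Jacob's stopping criterion, orientation forced counter-clockwise
  (positive signed area in y-up axes; image rows increase downwards, and
  every signed-area or angle computation negates y first). The
  deterministic start pixel is arbitrary — seed "apex" detection is not
  attempted — because the EFD normalization removes start-point dependence
  anyway.
* **Ordering.** Particles are returned in reading order (bounding-box
  top-left, row-major) for reproducible CSVs; dataset extraction matches
  particles to labelled seeds by nearest truth centroid, which is robust
  to reading-order swaps between unequal seeds.

## The 26 descriptors

Base quantities, all in pixel units: `Pixels` (foreground count), `Perim`
(chain length: 1 per axial step, √2 per diagonal), `Area` (shoelace area
of the boundary-centre polygon), convex hull perimeter `CHull` and area
`CArea`, `Feret` (largest distance between hull vertices), `Breadth`
(largest hull extent perpendicular to the Feret axis), `MinR`/`MaxR`
(smallest/largest distance from the mass centroid to the boundary),
`MBCRadius` (exact minimal enclosing circle of the hull, Welzl's
algorithm run in deterministic order). Derived ratios follow the standard
definitions (`Circ = 4πA/P²`, `Roundness = 4A/(πF²)`, `Solidity =
A/CArea`, `Sphericity = MinR/MaxR`, `Rectang = A/(F·B)`, …).

Numerical conventions worth knowing:

* **Chain-length perimeter bias.** Freeman chain length overestimates a
  smooth boundary by ≈ 5.5% (staircase effect), so a digitized disk's
  circularity is ≈ 0.89, not 1. No corner correction is applied; all
  perimeter-derived ratios inherit the convention, which cancels in
  between-class comparisons at a fixed resolution.
* **`PerEquivD`.** Some legacy feature lists print the
  perimeter-equivalent diameter as `Area/π`, which is dimensionally an
  area. The default here is `Perim/π`; `strict_per_equiv_d = TRUE`
  reproduces the legacy value for compatibility.
* **Feret ties.** Integer pixel coordinates routinely produce several
  point pairs at exactly the maximal distance; the implementation picks
  the lexicographically smallest endpoint pair so that `Breadth` is
  deterministic and oracle-checkable.
* **`MinR`** is the centroid-to-boundary minimum (the "inscribed circle
  centred at the middle of mass"), not the true maximal inscribed circle.
* **Units.** Classification runs in pixel units — LDA is affine-invariant,
  so only *mixed* resolutions are harmful, and the pipeline refuses them.
  `to_physical()` converts to millimetres (25.4/dpi per pixel) for
  presentation.

## Elliptic Fourier descriptors

The closed contour is expanded by separate Fourier series of x(t) and
y(t) as functions of the cumulative arc length t along the polygon, using
the exact piecewise-linear closed form (not an FFT). Harmonic n carries a
quadruple (aₙ, bₙ, cₙ, dₙ); the first harmonic is the best-fitting
ellipse. Normalization follows the standard first-harmonic scheme: a
start-phase shift aligns the parameter origin with the semi-major axis, a
rotation aligns that axis with x, and all coefficients are divided by the
semi-major magnitude E, fixing a₁ = 1, b₁ = c₁ = 0 and leaving 4N − 3 free
values (77 at N = 20; an alternative √(first-ellipse area) scale mode
exists but is off by default). Three choices deserve comment:

* **Parameterization.** With the arc-length parameter, a true ellipse is
  *not* exactly a single harmonic (its coordinates are not sinusoidal in
  arc length): a 2:1 ellipse yields d₁ ≈ 0.587, not b/a = 0.5, with a few
  percent of harmonic-3 leakage. `compute_efd()` therefore accepts an
  optional explicit parameter vector `t`; supplying the curve's own
  parameter recovers the textbook single-harmonic result exactly, while
  the pipeline always uses arc length, the convention for chain-coded
  contours.
* **Branch fixing.** The residual two-fold ambiguity (half-period start
  shift combined with a 180° rotation) flips the sign of even harmonics
  only; the branch with a₂ ≥ 0 is chosen. The synthetic generator keeps
  its template a₂ positive so generated and extracted coefficients share
  the branch.
* **Reflection.** Mirror images are *not* normalized away: ventral and
  dorsal sides are genuinely distinct observations, and collapsing
  chirality would discard that information.

Position (A₀, C₀) is excluded from the feature vector. The audit columns
`E_px`, `theta_rad`, `psi_rad` record the removed transform per
observation.

Measured error bounds under the defaults (frozen in the tests): raster
extraction at 400 dpi recovers the exact generating polygon's normalized
coefficients to max |error| ≤ 0.02; pose changes (rotation, start point)
move them < 0.02; 200 vs 400 dpi < 0.03; a 20-harmonic reconstruction
stays within 1 px of the traced contour.

## Stepwise discriminant analysis

Selection is greedy Wilks'-Λ stepwise. With g groups, n fitting rows and p
variables entered, the partial F-to-enter of a candidate x is

F = ((n − g − p)/(g − 1)) · (Λ_p / Λ_{p+x} − 1),

computed for all candidates at once via Schur complements of the within-
and total-SSCP matrices. The largest-F candidate enters if F ≥ `f_enter`
(default 3.84, the classical χ²₁/F ≈ 0.05 criterion); after each entry,
entered variables with F-to-remove < `f_remove` (default 2.71) are
dropped. Two tolerance guards — 1 − R² of the candidate against the
entered set, computed on both the total and the within-group SSCP — must
stay ≥ `tol_min` (default 0.001); they block collinear entries and bound
the conditioning of the pooled covariance. Ties break by the frozen
column order; selection halts at p = n − g − 1. Classification uses
linear classification functions sₖ(x) = μₖᵀΣ⁻¹x − ½μₖᵀΣ⁻¹μₖ + ln πₖ with
the unbiased pooled Σ; priors are equal by default (proportional and
custom priors available — reports are sensitive to this, so the choice is
logged). Score ties go to the first group in sorted label order.

**LOOCV scope.** The default leave-one-out estimate refits only the
classification functions per fold, with the variable selection held fixed
from the full fitting set — mirroring how the classical software combines
stepwise selection with cross-validation. This estimate is *optimistic*
whenever selection capitalises on chance: with 103 candidates and
`f_enter = 3.84`, the largest F among pure-noise candidates exceeds the
threshold with probability near 1 at any realistic n, so on null data the
procedure always selects something and fixed-selection LOOCV lands well
above 50%. `loocv(..., reselect = TRUE)` provides the honest nested
variant (selection redone in every fold), which is what the package's
chance-level and separation-monotonicity checks use; folds in which
nothing clears the threshold fall back to the prior-only classifier.

## The synthetic generator

Classes are defined in *normalized EFD space*, so the extractor has exact
ground truth: the first harmonic fixes length (`scale_mm`) and B:L
(`aspect`), harmonics 2–3 carry the pyriform stalk bulge
(`stalk_amplitude`), and i.i.d. Gaussian noise (`coeff_sd`) on the free
coefficients of harmonics 1–6 generates within-class variation. Charring
is modelled as the two quantified effects reported for carbonised pips —
an additive B:L increase (`charring_bl_shift`, default 0.08) and isotropic
shrinkage (`charring_shrink`, default 0.90) — plus small random
high-harmonic (7–12) boundary jitter. Defaults place the wild class at
4.8 mm / B:L 0.74 / weak stalk and the cultivated class at 6.2 mm / 0.56 /
strong stalk, in the range seed atlases report for the two subspecies;
`seed_classes(separation)` interpolates both toward their midpoint, with
`separation = 0` an exact null. Within-class spread (`coeff_sd = 0.02`) is
a placeholder chosen for test stability — no quantitative within-class
variance is available for real material — and is *not* claimed to match
real grape morphology. Scenes render at 400 dpi by default (0.0635 mm per
pixel) on a light background with dark silhouettes; each seed's shape
comes from an RNG substream keyed by its id, so lot order does not affect
shapes, and a fixed master seed reproduces images byte-for-byte. The
dorsal side is the mirrored outline with an independent noise draw.

What the generator does **not** emulate: texture and interior gray
structure, cracking or fragmentation of charred seeds,
temperature-specific deformation, touching seeds, uneven illumination.
Passing tests therefore demonstrate the correctness of the measurement
and classification machinery under controlled geometry — not field
performance on real scans.

## Problem sizes in the tests

The oracle-equivalence suite compares all base quantities against
exhaustive brute-force implementations (all-pairs Feret, Jarvis-march
hull, O(n³) bounding circle) on 50 random ≤ 60×60 masks at 10⁻⁹; the
step-1 stepwise F is checked against one-way ANOVA on every one of the
103 columns of a Gaussian fixture. End-to-end checks run a 30+30
charred-seed study with an 8-seed unknown lot (LOOCV 100% at the default
separation; unknowns all assigned wild), a 20-replicate zero-separation
null at chance level under nested LOOCV, and a 3-level × 10-replicate
separation sweep whose mean nested accuracy is monotone. Replicate
datasets render at 150 dpi with 8–10 seeds per class — sizes chosen so the
whole suite stays in a few minutes; the invariances they exercise are
resolution-independent (checked explicitly at 200 vs 400 dpi).

## Known limitations

* Charred-seed reality is richer than the B:L-plus-shrinkage model;
  classifiers trained on the synthetic classes say nothing about real
  charring temperatures.
* The chain-length perimeter convention biases `Circ`, `Convexity`,
  `Shape` and `PerEquivD` relative to corner-corrected definitions.
* Stepwise selection with F ≥ 3.84 over 103 candidates overfits small
  samples by construction (see the LOOCV discussion); for honest error
  rates on modest datasets use `reselect = TRUE`.
* `Breadth` is defined via hull projections perpendicular to the Feret
  axis; rotating-calipers minimum width would differ slightly.
* No touching-seed separation: scans must place seeds apart.
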