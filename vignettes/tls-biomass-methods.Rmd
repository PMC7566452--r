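---
title: "Stem geometry, cylinder models and biomass from TLS point clouds: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stem geometry, cylinder models and biomass from TLS point clouds: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlsbiomass)
```

This vignette is the package's own account of the science it implements:
the measurement definitions, the model assumptions behind each stage, what
the synthetic-data generator does and does not emulate, and the numerical
and design choices a maintainer would want written down. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The problem

Very large conifers dominate the above-ground biomass (AGB) of the stands
they grow in, yet they are the trees least represented in the destructive
harvests that calibrate allometric biomass equations. Terrestrial laser
scanning (TLS) offers an independent route: a dense point cloud of the
standing tree, a geometric reconstruction of its woody volume, and a
conversion to mass through wood density. The package implements that route
for single-tree clouds and the comparison machinery against a bank of
published allometric model forms.

All heights in the pipeline are measured **relative to the cloud's lowest
point**; no ground model is fitted. Slabs are half-open `[z_lo, z_hi)`.

## Stem metrics

**Height** is the z-range of the cloud (highest minus lowest point).

**DBH** comes from a least-squares circle fit to the 1.2–1.4 m slab,
collapsed to 2D. The fit minimises the geometric objective
$\sum_i (d_i - r)^2$, with a Taubin-style algebraic fit as the starting
point and Gauss–Newton refinement; given the centre, the optimal radius is
the mean point-to-centre distance, which makes the inner loop cheap and
stable. The reported RMSE is
$\sqrt{\operatorname{mean}(d_i - r)^2}$ — on a circular stem it measures
ranging noise, on a fluted stem it mostly measures non-circularity, and in
both cases it is the uncertainty later propagated into AGB.

**fDBH** (functional DBH) is the diameter of the circle whose area equals
the actual, possibly deeply non-circular, cross-section:
$\mathrm{fDBH} = 2\sqrt{A/\pi}$. The area comes from an alpha shape: the
Delaunay triangulation of the slab points, keeping triangles whose
circumradius is at most $1/\alpha$. The convention is fixed and documented
because alpha-shape conventions differ across libraries: $\alpha$ is in
m⁻¹ and **larger alpha is tighter**; the default is $\alpha = 4$
(circumradius ≤ 0.25 m), a balance between tracing flutes and not
disintegrating on sampling gaps.

Two practical points shape the implementation:

* A laser samples only the stem *surface*, so a slab is an annular band of
  points, not a filled disk, and the kept complex is a ring (possibly an
  open arc where occlusion removed a sector). The cross-section area is
  therefore taken from the band's **outer envelope**: boundary vertices of
  the kept complex are binned by azimuth about the section's algebraic
  circle-fit centre (a robust stand-in for the stem axis), the outermost
  vertex per bin is kept, and the shoelace area of that polygon is
  reported. Occlusion gaps and alpha-bridged valleys close with chords;
  solid point sets (a filled square, say) reduce to the ordinary outer
  boundary.
* Components of the kept complex below 15% of the largest one are
  discarded as noise; if the complex covers less than a quarter of the
  section points the alpha is reported as degenerate rather than silently
  patched.

The alpha-shape "RMSE of fit" has no standard definition; here it is the
RMS distance to the boundary polyline over the input points lying within
5 cm of the boundary. It plays the same role for fDBH that the circle
RMSE plays for DBH.

**DTB** (diameter at top of buttress) is a circle fit to the 4.0–4.5 m
slab, high enough to clear basal flare. The slab is measured from the
lowest point, consistent with the DBH slab.

The cohort statistic `dbh_fdbh_difference()` uses the convention
$100\,(\mathrm{DBH} - \mathrm{fDBH})/\mathrm{fDBH}$, so stems whose
concave flutes make the equivalent-area diameter exceed the circle-fit
diameter give **negative** values.

## The cylinder model (QSM)

`build_skeleton()` covers the cloud with segments: a k-nearest-neighbour
graph (k = 8, grid-hashed search in C++), geodesic distances from the
basal band (all points within a few spacings of the lowest point, joined
through a zero-weight virtual root so that shells are true
distance-up-the-structure bands), shells of width `patch_size`, and
connected clusters within each shell. Each segment's parent is the nearest
cluster in the previous shell. Orphan fragments outside the main connected
component (sparse branch tips) are dropped up to 20% of the cloud; beyond
that the cloud is reported disconnected.

`fit_cylinders()` places one cylinder per segment. The axis runs from the
parent centroid to the segment centroid; root and tip segments extend to
the extreme point projections, so lengths telescope exactly along each
chain (this is what makes the noise-free cylinder volume exact to well
under 0.1%). The radius is the least-squares solution
$r = \operatorname{mean}(d_i)$ over the points that project into the
cylinder's actual span — the segment's own members plus the parent's,
whose upper half lies inside it — with a cutoff at twice the median
distance so the stub of an attached branch cannot inflate a trunk radius.
Segments with fewer than 10 points take `min(own estimate, parent radius)`
rather than inheriting the parent radius outright: a thin branch child of
a fat trunk segment must never become trunk-sized. Branch-base cylinders
start at the parent trunk's surface rather than its axis, so the overlap
inside the trunk is not double-counted.

Volume is $\sum \pi r^2 L$ and surface area the lateral
$\sum 2\pi r L$ (no end caps — caps double-count at joints). The trunk is
the root-to-tip path that follows, shell by shell, the heaviest
direction-consistent continuation (cumulative point count, requiring the
step direction to stay within ~70° of a smoothed running direction); when
occlusion splits a shell into arcs the path may hop to the nearest
consistent arc. The decomposition `total = trunk + branch` holds exactly
by construction.

`qsm_ensemble()` refits the model over a grid of patch sizes (default
{0.3, 0.5, 0.8} m × 3 seeded ~2% point-drop jitters = 9 runs) and reports
the mean and sample SD of total volume; the SD is the TLS volume
uncertainty carried into plot summaries.

Known limitations, visible in the tests: circular cylinders systematically
under-measure deeply fluted trunks (a section of area
$\pi R^2(1 + \sum a_k^2/2)$ is read as $\pi R^2$), and on giant stems with
heavy crowns the trunk/branch attribution is much less reliable than the
total — the ensemble *total* stays within a few percent of ground truth
while the split can be off by tens of percent. Totals, not splits, feed
the biomass numbers.

## Allometric models and uncertainty

The bank of seven model forms (two generalised DBH-only log-log models;
two DBH+H volume models; DTB+fDBH and DTB+H power-product volume models; a
DBH-only log-log model with a back-transformation correction factor) ships
as YAML **data**, never as constants in code: form, predictor set, units,
coefficients, correction factor and wood density per model, validated at
load. The two generalised models carry their published coefficient values;
the five species-specific models are labelled synthetic stand-ins whose
coefficients were chosen once from geometric form-factor reasoning (stem
volume ≈ form factor × basal area × height at basic density 330 kg m⁻³),
because the original coefficient tables are not redistributable here. They
exercise the machinery with realistic magnitudes; they are not the
published calibrations.

Wood density defaults to 330 kg m⁻³, the basic density consistent with
redwood-class TLS volume-to-mass conversions (a 321 m³ stem at 330 kg m⁻³
is 106 t). Masses are metric tons throughout.

`predict_agb()` propagates geometric uncertainty by seeded Monte Carlo:
`mc_n` (default 1000) draws of each diameter from a truncated-positive
Normal centred on the measurement with the fit RMSE as SD (height carries
no fit RMSE and is held fixed); the AGB SD is the SD of the resulting mass
draws. The first-order delta method ($\sigma_{AGB} \approx AGB\,\beta_1
\sigma_D/D$ for log-log forms) is kept as an independent oracle in the
tests; the Monte-Carlo route is the implementation because the
two-diameter forms mix correlated-magnitude uncertainties that the delta
method handles less transparently. `tls_agb()` is the exact linear map
$\rho V$, mean and SD alike.

`fit_power_law()` fits $y = a\,x_1^{b_1} x_2^{b_2}\cdots$ by `nls()` in
arithmetic space, initialised from the log-log linearisation (exact on
noise-free data); `rmse_percent` is 100·RMSE/mean(response). The companion
`power_law_rmse()` evaluates fixed published coefficients on the same
records, which is how a recalibrated model is compared against its
original parameters, and how a height-only reduced form is shown to fit
worse than the two-predictor form.

## Plot-level statistics

`compare_regression()` regresses candidate (model) AGB on reference (TLS)
AGB per tree by OLS **in arithmetic tons, TLS as x** — the near-unit
slopes and small intercepts this produces are the natural scale for
method comparison; a log-space option exists for sensitivity. `CV% =
100·RMSE/mean(reference)`; this definition is internal-consistency tested
(CV ∝ RMSE) since no canonical definition exists. The
`include_largest = FALSE` variant drops the single largest-reference tree,
quantifying the leverage one giant stem exerts: with it included, r²
rises and the slope's standard error shrinks.

`plot_agbd()` is exact arithmetic, `sum(AGB)/area`, with per-tree SDs
combined in quadrature under an independent-tree assumption — the closest
defensible reading of a "standard error" for a plot sum of independently
reconstructed trees.

## The synthetic forest

The generator defines the study conditions for every cohort-level result
in the package. A stem is
$r(z,\theta) = r_0(z)\,(1+b(z))\,(1 + \sum_k a_k\cos(k\theta+\phi_k))$
with $r_0(z) = R_b (1 - z/H)^t$, a linearly-vanishing basal buttress
$b(z)$ below 2.8–4 m, and cosine flute harmonics — the minimal family
whose cross-section area is analytic
($A(z) = \pi R(z)^2 (1 + \tfrac12\sum a_k^2)$), so ground-truth volumes
come from 1-cm trapezoid quadrature of exact areas, never from the sampled
points. Branches are straight cylinders in whorls (crown base above 6 m so
the DTB slab stays clean); their volumes are closed-form. Surface points
are sampled at a target spacing, with three scanner-geometry touches: the
lower trunk (which carries both measurement slabs) is sampled finely
enough to resolve a 20-cm slab regardless of the overall budget; ring
point counts scale with the maximum angular speed of the fluted outline so
flanks stay resolved; and occlusion removes contiguous azimuth sectors
whose placement is re-drawn every 5 m of height (multi-position scanning
makes shadows stripes, not full-height cuts — and full-height cuts would
disconnect the cloud). Radial Gaussian noise (default 5 mm) emulates
ranging error. Everything is deterministic given the spec, whose seed is
part of it.

The study cohort (`study_specs()`) emulates a three-plot campaign: 26, 37
and 82 trees on 0.25-ha plots with plot-specific height ranges (old-growth
up to ~85 m; secondary growth 12–60 m), a power-law height-diameter
relation with lognormal scatter clamped to DBH 0.1–3.5 m, and one
separately processed ~88 m, DBH ~3.39 m giant — 146 trees in all. Flute
amplitudes follow a size-aware two-regime design calibrated once, before
the test suite existed, so that the *measured* cohort DBH-vs-fDBH
statistic has the sign and scale reported for heavily fluted redwood
cohorts (mean around −5 to −7%, a few points of spread, the large
majority of trees with fDBH > DBH): large stems get broad, deep lobes that
the alpha ball traces (ratio $\approx 1/\sqrt{1+s/2}-1$ with
$s=\sum a_k^2$), small stems get sharp bark-ridge harmonics whose valleys
the ball bridges (ratio $\approx -a_1/(1+a_1)$), each with small empirical
offsets for the outer-envelope bias. The generator does **not** emulate
leaf/needle returns, terrain relief, trunk lean, reiterated or epicormic
branching, multi-stem fairy rings, or range-dependent beam footprint —
so green tests demonstrate the pipeline's correctness on clean woody
geometry, not robustness to every field artefact.

## Problem sizes and numerical choices

The default test and reproduction runs use desk-scale sizes chosen as a
deliberate compromise: ~4000–6000 points per cohort tree (the giant gets
~100k and a 9-run ensemble), 2–3 QSM runs per cohort tree, and 300–1000
Monte-Carlo draws per tree × model. Sections larger than 6000 points are
thinned deterministically before triangulation. Other numerical choices:

* Delaunay triangulation is incremental Bowyer–Watson (C++); a
  deterministic ~1e-7-relative jitter breaks the exact cocircularity of
  ring-sampled sections.
* Circle-fit degeneracy (collinear points) is an error, as is an alpha so
  tight the complex disintegrates; a tree shorter than a slab yields NA
  for that metric with a warning while the rest are returned.
* All randomness flows from explicit integer seeds; sub-seeds derive from
  a fixed 32-bit linear map, so every stage is reproducible in isolation.
* Truncated-positive Monte-Carlo draws use redraw (not clipping), keeping
  the small-noise mean unbiased.

## What the green suite does and does not show

The suite verifies: exact closed-form volumes (cylinder, cone) and their
QSM recovery; shoelace-oracle agreement of analytic fluted sections;
grid-search and `optim` oracle equivalence of the circle fit; closed-form
OLS equivalence of the comparison regression at 1e-9; exact AGBD and
volume identities; power-law recovery within 2 SE at cohort size;
determinism of every seeded stage; and the directional cohort facts
(fDBH > DBH on fluted stems, recalibration beating original parameters,
height-only fits being worse). It does not validate the synthetic
stand-in allometric coefficients against field data, and it cannot speak
to segmentation quality of real plot clouds, which enter this package
pre-segmented.
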