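---
title: "Modelling ventricular activation under RV pacing and LBBB"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ventricular activation under RV pacing and LBBB}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacesim)
```

## The question

In cardiac resynchronization therapy (CRT) the right-ventricular (RV) lead
is placed either at the RV apex or on the mid septum, and the two positions
produce different ventricular activation sequences. Because the left
ventricular (LV) lead is often targeted at the latest-activated LV region,
the RV stimulation site can change where that target lies. `pacesim`
provides a desk-scale model of this problem: an idealized biventricular
surface geometry, an activation-time simulator for intrinsic left bundle
branch block (LBBB) and four RV pacing scenarios, the activation metrics
used by non-invasive electrocardiographic imaging (ECGi) analyses, and a
synthetic paired-cohort generator with the matching statistical pipeline.

## Geometry

The heart is represented as labelled triangulated surfaces in a canonical
frame: long axis along +z, base plane at z = 0, apex at z = L, and
circumferential angle zero at the mid-septum increasing toward the anterior
wall. The LV is a pair of nested truncated half-ellipsoids (epicardium and
endocardium); the RV free wall is a two-layer crescent bulge welded onto the
septal arc of the LV outer shell, so that the outer shell under the crescent
becomes the RV-facing septal surface. This reproduces the label structure of
a real biventricular anatomy with three surface layers — epicardium, LV
endocardium, and the RV cavity lining (RV free-wall endocardium plus the RV
face of the septum) — each edge-connected, with transmural links joining
endocardium to epicardium across the wall.

Default dimensions approximate an adult dilated LV: 90 mm long axis, 35 mm
epicardial radius, 10 mm LV wall, a 120° septal arc (the standard
angular extent of the AHA septal sectors), an RV crescent up to 16 mm proud
of the septum reaching 78% of the way to the apex. The default grid
(40 circumferential x 20 longitudinal nodes per layer, about 1950 vertices)
resolves the activation patterns while keeping every simulation below a
second; tests use 12-32 circumferential nodes for speed.

Two numerical details matter. First, quad diagonals alternate in a
checkerboard pattern: with an even circumferential count this makes the
lattice exactly mirror-symmetric about the mid-septal meridian, so
geodesic wavefronts from a mid-septal source meet the lateral wall on the
mid-lateral meridian instead of drifting with the diagonal direction.
Second, the endocardial crescent's footprint is shrunk strictly inside the
epicardial one so its rim welds onto the septal surface — this keeps the RV
cavity lining edge-connected, which the fast endocardial conduction layer
relies on.

Septal vertices carry chamber label `SEPTUM`. They count toward the LV for
the LV metrics (the septum is anatomically part of the LV mass) and act as
pacing substrate from their RV face; both choices are configurable where
they matter (`include_septum` arguments).

## Conduction model and simulator

Activation is modelled with a graph-eikonal surrogate: the arrival time at
a vertex is the minimum over pacing sources of onset plus geodesic traversal
time through the mesh edge graph, solved exactly with multi-source Dijkstra.
An edge costs its length divided by the harmonic mean of its endpoint
velocities; the harmonic mean is the correct composition rule for traversal
at piecewise velocity and makes a scar multiplier of zero block the edge
outright. Transmural links use the transmural velocity. This surrogate
yields activation times only — no transmembrane voltages, electrograms, or
repolarization — which is exactly what the downstream metrics consume.

Defaults: 0.6 mm/ms on every surface layer and transmurally (mid-range
human working myocardium), and a fast RV endocardial layer at 4x
(Purkinje-like rapid conduction) used by the intrinsic LBBB scenario.
The five scenarios are LBBB (breakthrough on the anterior RV endocardial
free wall, fast layer on) and four paced scenarios (apical anterior / mid /
posterior and mid-septal, fast layer off, since a paced wavefront spreads
through working myocardium). Whether the fast layer should remain active
distal to a paced site is physiologically uncertain; here it is a single
flag (`fast_layer`) that can be overridden per scenario.

Pacing sites are 5 mm-radius vertex sets around named anatomical landmarks
on the RV cavity lining. The apex landmarks sit where the endocardial
crescent is about 2 mm proud of the septal surface, which guarantees
capture at every supported mesh resolution; enlarge `radius_mm` on very
coarse meshes.

## Activation metrics

For one activation map (unreached, scar-blocked vertices excluded
everywhere):

* **VVtat** — range (max - min) of activation times over both ventricles (ms).
* **LVtat** — the same range over LV vertices, septum included.
* **VVsync** — absolute difference of the mean LV and mean RV activation
  times, the "ventricular electrical uncoupling". A signed variant is
  available; the absolute value is the default because only magnitudes are
  reported in the source summaries.
* **LVdisp** — population (divide-by-N) standard deviation of LV
  *epicardial* activation times.
* **Isochrones** — 30 equal-width bands over the observed time range; the
  maximum falls in the last band, a constant map occupies band 1.
* **Terminal AHA segments** — the 16-segment AHA model is assigned by
  long-axis thirds and the standard 60°/60°/90° circumferential sectors;
  the terminal segments are those containing at least one LV vertex of the
  final band (several when the band straddles a boundary). If the final
  band is RV-only the latest LV-occupied band is used, with a logged
  message.
* **Wave-front angle (WFA)** — orientation in [0°, 180°) of the
  total-least-squares line through the projected positions of one band in
  the LAO-cranial view (long axis in-plane, base up — the view that
  maximizes the projected base-apex distance). This automates what is done
  manually with an on-screen protractor; the default band is the one
  containing the median activation time, a reproducible stand-in for a
  user-selected "most prominent" isochrone. When two maps are compared the
  same band index is used in both.

Scenario comparison normalizes each map to its own span (shift to zero,
divide by VVtat), computes the Pearson correlation over all vertices reached
in both maps, the Euclidean shift between the latest-activated-region
centroids within the LV free wall (LV epicardium; the septum carries no
epicardium here), and the signed WFA difference in (-90°, 90°].

Invariance properties guaranteed by construction and enforced by tests:
all metrics are invariant to a global time shift; the four time metrics
scale linearly with time while WFA, terminal segments and the correlation
do not change; WFA is rotation-equivariant modulo 180°; scaling every
conduction velocity by c divides every activation time by c.

## Synthetic cohorts

Two independent generator paths emulate a paired CRT cohort (each patient
mapped in intrinsic LBBB and under RV pacing; 9 apical and 5 septal leads;
8 of 14 ischemic):

* The **metric-level path** draws each patient's (intrinsic, paced) value of
  each metric from a bivariate normal with the published per-subgroup
  means/SDs and within-patient correlation ρ. Only group summaries are
  published, so ρ is a free parameter; the default 0.7 encodes the strong
  within-patient pairing evident in the individual-change plots and gives
  paired tests realistic power at n = 14. This path feeds the statistics
  stage with exactly known parameters.
* The **map-level path** runs the simulator per synthetic patient with a
  shared lognormal conduction-velocity multiplier (sdlog 0.1,
  ~10% between-patient spread), a 12 mm slow-conduction patch (velocity
  x0.3) at a random LV epicardial site for ischemic patients, and additive
  Gaussian measurement noise (SD 3 ms, the scale of ECGi annotation
  uncertainty). This path exercises the whole chain end-to-end.

With SDs and noise set to zero both paths are exactly deterministic, which
the tests use as an anchor. What the generator does *not* emulate: torso
conduction and inverse-reconstruction artefacts, spatially correlated noise,
real scar architecture, or heterogeneity of LBBB activation patterns beyond
a global velocity scale. Passing cohort-level tests therefore demonstrate
that the pipeline recovers the statistical structure it was given, not that
it would recover the physiology of any particular patient population.

## Statistics

The reporting pipeline mirrors common clinical practice: a one-sample
Kolmogorov-Smirnov gate against a normal with the sample's own mean/SD
(note: with estimated parameters the null p-values are conservative; pass
the true parameters for the classical calibrated test), then a
pooled-variance independent-samples t test when both groups pass at
α = 0.05 and the Mann-Whitney U test otherwise (exact for small untied
samples, normal approximation with tie correction else). The
independent-samples default follows the source analysis even though the
design is paired; `paired = TRUE` switches to the statistically preferable
paired t / Wilcoxon signed-rank variants. Below n = 3 normality is
untestable and the t path is used. No multiplicity correction is applied by
default (`holm = TRUE` is available). Degenerate inputs (all values tied)
report a p-value of 1 rather than erroring, so zero-variance synthetic
cohorts flow through the report.

## Problem sizes and reproducibility

The test suite runs the simulator-vs-Dijkstra oracle on 50 random meshes of
up to 500 vertices, the metric-vs-formula oracle on 1000 random maps, 1000
replicate 14-patient cohorts for direction-of-effect recovery, a 10,000
patient cohort for parameter recovery, and 5000 null cohorts for type-I
calibration — sizes chosen so the whole suite completes in about a minute
while keeping Monte-Carlo error well inside the asserted bounds. All
randomness flows from explicit seeds; `scripts/acceptance.R` derives every
stochastic stage from its single `--seed` argument.

## Known limitations

* The geometry is an idealized surface model: no fiber architecture, no
  wall-thickness gradients, no valve plane, no volumetric septum. Absolute
  activation times and shift distances are geometry-specific; only
  directions of effect and orderings are meaningful.
* The eikonal surrogate ignores wavefront curvature effects, source-sink
  mismatch and repolarization; it cannot produce electrograms or QRS
  morphology.
* The latest-activation-region comparison depends on the 30-band
  quantization; with a symmetric geometry several scenarios can terminate
  in nearby regions, so small shift differences (a few mm) should not be
  over-interpreted.
* Cohort-level conclusions inherit the bivariate-normal assumption and the
  assumed ρ; they describe the statistical pipeline, not new clinical
  evidence.
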