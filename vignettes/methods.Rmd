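---
title: "Methods: range-based Least Concern screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: range-based Least Concern screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcscreen)
```

## The screening model

`lcscreen` implements a triage model for plant Red List assessment: species
whose geographic range is demonstrably large are unlikely to qualify for a
threatened or Near Threatened category under the range-based criteria, and
can be documented as Least Concern (LC) with default supporting data. The
model's single substantive assumption is that **range size, estimated from
native-range occurrence records, is a sufficient statistic for ruling
categories out** (never for ruling them in). Four statistics are computed
per species:

* **EOO** (extent of occurrence): area of the minimum convex polygon of the
  retained occurrence points, in km².
* **AOO** (area of occupancy): number of occupied grid cells times the cell
  area, on a 10 km × 10 km grid by default.
* **RecordCount**: unique retained (longitude, latitude) pairs.
* **TDWGCount**: number of native WGSRPD Level-3 regions with at least one
  retained point.

A species is suggested LC iff *every* statistic meets or exceeds its
threshold and no warning was raised during computation. The comparison is
inclusive (`>=`): the operative rule is "meets or exceeds", and we pin that
reading explicitly because guideline texts sometimes quote a strict
inequality; the difference affects only metrics landing exactly on a
threshold.

The model cannot detect threats that act across an entire large range —
over-harvesting, disease, range-wide habitat loss. A widespread, heavily
collected species will pass every range gauge and still be threatened; the
calibration data contain exactly this pattern (a wide-ranging orchid
predicted LC at every tested threshold whose published category is
Vulnerable). For that reason classification output is a suggestion: no SIS
bundle is written unless the operator sets `accept_lc`, standing in for the
interactive accept/reject step of an assessment workflow.

## Native-range restriction

Aggregated occurrence data do not distinguish native from introduced
records, and naive range metrics computed from them overestimate. The
pipeline therefore intersects cleaned occurrences with the species' native
range as documented by a checklist provider at WGSRPD Level 3 ("botanical
countries"). A record is retained iff it falls inside, or exactly on the
boundary of, a native-region polygon:

* **Boundary points count as inside.** Excluding them could only shrink the
  metrics and push a genuinely widespread species below a threshold — the
  error direction we must avoid is falsely *declaring* LC, but discarding
  boundary records would bias the opposite, precautionary direction for no
  gain in safety.
* Point-in-polygon runs on raw longitude/latitude treated as planar
  (winding-number algorithm with an explicit on-segment test). Level-3
  units are hundreds of kilometres across; geodesic refinement at their
  borders is far below the noise floor of aggregated georeferencing.
* The geometry store contract requires polygons crossing the antimeridian
  to be pre-split into two lobes with longitudes in [-180, 180]; the
  filtering code assumes this and does not attempt winding disambiguation.

`TDWGCount` counts regions *actually occupied* by retained points, not the
full native list from the checklist. The alternative (counting the
checklist's native regions directly) would make the statistic independent
of the occurrence data and inconsistent with the other three; occupied
regions is also what "regions in which the species occur" describes.

## Projection and area computation

Areas must be in km², so points are projected with a cylindrical equal-area
projection fitted **per species**: the central meridian is the points' mean
longitude and the standard parallel their mean latitude,

$$x = R\,(\lambda - \lambda_0)\cos\varphi_1, \qquad
  y = R\,\frac{\sin\varphi - \sin\varphi_1}{\cos\varphi_1},$$

with $R = 6371.0088$ km. Equal-area projections preserve area everywhere,
and centring the projection on the species minimises shape distortion where
the points actually are; the $\sin\varphi_1$ offset places the projection
origin at the species' centroid in both axes, which matters for the grid
anchor below. EOO is the shoelace area of the convex hull of the projected
points (hull vertices from the standard planar algorithm). Degenerate
inputs are warnings, never errors: fewer than three distinct points, or
collinear points, give EOO 0 with an explanatory warning. Collinearity is
detected as hull area below $10^{-12}$ of the squared point-set extent,
absorbing floating-point slivers left by projection round-trips.

## The AOO grid anchor

AOO is computed at a 10 km cell scale — deliberately coarser than the 2 km
IUCN reference scale, because aggregated records carry unquantified
georeference error; the resulting figure is a screening statistic, not a
strict-sense AOO estimate (a single occupied cell contributes 100 km²).
Two details are pinned:

* **No origin optimisation.** The grid is fixed by the projection context;
  we do not search grid offsets for the minimal cell count. Determinism
  across reruns matters more for a screening tool than the marginally
  smaller AOO an offset search yields.
* **A cell is centred on the projection origin** (cell index
  $\lfloor x/c + 1/2 \rfloor$). Because the projection origin is the
  species' centroid, anchoring a cell *corner* there would place every
  species' centroid exactly on a grid corner, and any tight cluster would
  straddle up to four cells — a 1 km cluster would report 400 km² instead
  of 100 km². Centring a cell on the origin restores the intended
  behaviour: point sets much smaller than a cell occupy one cell.

Jitter within a cell, and permutation of point order, provably leave AOO
unchanged; both are enforced by property tests, as are the subdivision
bound (halving the cell side at most quadruples the occupied count) and
equivalence with brute-force cell enumeration.

## Thresholds and calibration

Default thresholds are EOO 30,000 km², AOO 3,000 km², 75 records, 5
regions; occurrence fetches are bounded to [1,000, 10,000] records with a
default of 3,000, and batches to 100 species (matching the practical limits
of the downstream assessment database). The EOO and AOO values trace to the
guideline levels above which range-based criteria cannot plausibly trigger;
the record and region thresholds are precautionary choices balanced against
false positives.

`sweep_threshold()` re-derives this calibration for any validation set:
species with published categories are reduced to a binary truth (LC
positive; threatened **and NT** negative, since the tool's job is isolating
LC from everything of elevated concern; DD and NE excluded), and each
parameter is swept independently over a threshold grid, scoring a
confusion matrix at each value. Sweeps are per-parameter with the other
three ignored — matching how calibration curves are read — and predictions
are monotone in the threshold by construction, which the tests assert
alongside equivalence with a naive per-record loop.

## Synthetic data

All tests run offline on generated inputs:

* `gen_cloud()` draws isotropic Gaussian point clouds with dispersion in
  *projected km* (not degrees), so AOO/EOO expectations are
  latitude-independent and closed-form tail bounds apply.
* `gen_toy_regions()` builds non-overlapping rectangular Level-3 regions.
* `gen_validation_table()` plants class structure for calibration tests: LC
  metrics are log-normal around comfortable multiples of the default
  thresholds, threatened metrics are scaled down by a configurable effect
  size (default medians: EOO 60,000 vs 3,000 km² at effect size 20), and
  optional outliers give threatened species LC-scale metrics to reproduce
  the wide-ranging-threatened failure mode.

These fixtures emulate cluster structure, class separation and service
response shapes — not sampling bias, spatial autocorrelation, duplicated
specimen digitisation or georeferencing error beyond what dedup and bounds
checks remove. Passing tests therefore demonstrate correctness of the
computations, not performance of the thresholds on real floras.

Problem sizes used by the test suite (hull/filter oracle comparisons at up
to 100 points over 200 instances each, 1,000-record calibration sweeps over
50-point grids, 500 bundle round-trips, an exhaustive 10⁴-case
classification grid) were chosen as the smallest sets that exercise every
code path and invariant densely.

## Bundle export

Species accepted as LC are documented in the seven cross-linked SIS Connect
CSVs plus a point-distribution CSV. Exact column schemas are not normative
anywhere in the public record, so they ship as a versioned YAML config
(`inst/extdata/sis_schema.yaml`) — operators should reconcile it against
current SIS Connect documentation; drift is a config change. Field
defaults: category `LC` (fixed), population trend `Unknown`, a single
configurable habitat row, bibliography citing the occurrence and checklist
sources, and points carrying presence/origin/seasonal = extant/native/
resident per mapping standards. The bundled Level-3-to-country lookup is a
small curated subset covering common regions; unmapped codes fall back to
the code itself so no species is silently dropped. The zip writer emits
standard STORE-method archives with CRC-32 checksums (readable by any unzip
implementation).

## Known limitations

* Geographic point-in-polygon treats degrees as planar; adequate at Level-3
  scale, wrong for fine-grained custom geometries near the poles.
* Name matching in the fixture backbone is Levenshtein-based with a simple
  confidence scale; a live backbone's scores will differ (the interface
  only requires a 0–100 ordering).
* The single-species workflow lets the caller act on any match candidate,
  while batch mode auto-excludes synonyms; the asymmetry is deliberate
  (batch must be unattended; single mode mirrors an interactive pick) but
  means the two modes can disagree on a synonym.
* Range-based screening is structurally blind to range-wide declines
  (criteria A, C, D, E triggers); the accept step exists precisely because
  a human must consider those.
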