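---
title: "Measuring individual-level environmental exposure: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring individual-level environmental exposure: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exposurekit)
```

## Why address-level measurement

Exposure measured over administrative zones inherits the modifiable areal
unit problem: the same person can look highly or barely exposed depending on
an arbitrary zoning. `exposurekit` measures exposure at the address and
propagates it through the ways a pedestrian actually reaches the
environment: along streets, to feature entrances, within catchments, and
along routes. The address, keyed by a property reference number (UPRN), is
also the linkage point to person-level records, so every output row carries
the UPRN plus a full description of *how* the value was measured: the
environmental domain, the spatial relationship (at the home, its street, its
block, a circular buffer, the nearest feature, all features, features within
a catchment, a route corridor, or a catchment buffer), the distance type
(straight-line, metric network, angular network, decay-weighted network) and
the radius or decay parameter.

## The street-network model

Street centerlines are noded at mutual crossings, then each piece is
dissected into `ceiling(L/20)` **equal-length** segments of at most 20 m.
Equal pieces rather than 20 m pieces plus a remainder avoid arbitrarily
short stubs, which would distort the turn-angle adjacency that the angular
analysis depends on; the total length is conserved to well below the 1e-3
relative tolerance the tests assert. Endpoints within 0.01 m merge into one
node (survey and synthetic data both carry float noise at far smaller
scales). Turn angles between adjacent segments are precomputed: continuing
straight is 0°, a right angle 90°, a reversal 180°.

Off-network points (addresses, feature entrances) snap to the nearest point
on any segment, with the straight *connector* recorded. Connectors count
toward metric distances — the walk starts at the front door, not at the
curb — but contribute no angular cost, since they are synthetic geometry.
This choice is configurable where it matters (catchments accept
`include_connector`).

Angular routing runs on the dual graph (segments as vertices, turns as
edges) with cost `angle/90`, the segment-analysis convention in which one
right angle costs 1. Ties between equal-angular routes break by metric
length, then by segment id, so routing is fully deterministic.

Catchments are metric: all segment portions reachable within a threshold,
split exactly at the distance frontier. Their buffers are corridor zones —
the union of capsules of a given half-width (default 25 m) around each
reachable portion — used both for zonal raster statistics and for route
exposure. Corridor areas are computed by grid integration (0.5 m default
cell) because a closed form exists only for isolated straight portions.

Urban blocks come from tracing the faces of the planar street arrangement
with a half-edge walk (clockwise-next edge from the reversed incoming
direction); interior faces are counter-clockwise and keep positive signed
area, the unbounded face is discarded. Tree-like networks yield zero blocks.

## Distance decay

Decay-weighted measures use `D = exp(-k d)` with network distance `d`. The
default grid `k ∈ {0.001, 0.002, 0.004, 0.008}` m⁻¹ spans half-weight
distances of roughly 700 m down to 90 m, bracketing the walking ranges of
faster and slower user groups (children, families with prams, the elderly).
The published method applies varying decay parameters without printing the
values, so the grid is an explicit configuration choice here, and every
output row records the `k` it was computed with. No alternative decay
families are offered: the literature finds little statistical difference
between them.

## Angular segment centralities

Closeness (integration) and betweenness (choice) are computed per segment
with a **hybrid radius**: the reach set of a segment is limited by *metric*
network distance (midpoint-to-midpoint step cost `(len_i + len_j)/2`) while
path cost is *angular* — the convention of space-syntax segment analysis.
Closeness is `1/Σ d_ik` over the reach set; a perfectly straight
neighborhood has an angular distance sum of zero, so closeness is reported
as missing with the reason `undefined-closeness` rather than dividing by
zero (consumers may substitute a capped value). Betweenness sums, over
unordered pairs within radius, the fraction of least-angular-cost paths
through a segment, with co-optimal paths splitting flow equally (cost ties
within 1e-6 turn units, i.e. about 1e-4 degrees — far below any genuine
angular difference yet far above the `acos()` rounding noise of surveyed or
rotated geometry, which keeps betweenness invariant under rigid motion). Pair paths are evaluated on the subgraph induced by the source's
reach set, and the unordered sum is the halved ordered sum.

Co-optimal counting needs care where turn costs are exactly zero: a
dissected straight street is a chain of segments linked by zero-cost edges
at equal angular distance, and a shortest path may enter such a chain at
either end and walk along it. Naive predecessor counting (the textbook
betweenness recursion) either drops or double-counts these paths because
the through-chain dependency is not proportional across all arriving paths.
The implementation therefore treats equal-distance zero-turn chains as
units, counts entries and exits explicitly, and propagates a per-entering-
path dependency. The test suite pins this down by comparing against
exhaustive simple-path enumeration on 100 seeded toy networks at 1e-9.

The centrality radius list is `{300, 500, 1000, 1500, 2000}` m by default.
One published radius table prints "15,000" in this position; we read that as
a typographic doubling of 1500 but the list is configurable, so either
interpretation is one argument away.

Address aggregation follows the convention of reporting the residential
segment's value plus the mean and maximum over segments intersecting the
300 m catchment.

## Rasters and zonal statistics

Rasters are single-band regular grids serialized as Esri ASCII text grids;
nodata cells are excluded from every statistic. Zonal statistics use the
cell-center rule (a cell belongs to a zone iff its center does): it is
deterministic, standard, and at the 5 m resolution of the synthetic
pollutant surfaces the difference from area weighting is immaterial. For
30 m NDVI cells the rule is coarser; this is documented behavior, not an
approximation we correct for. NDVI is `(NIR − RED)/(NIR + RED)`, undefined
(nodata) where the denominator is zero, always in [−1, 1].

Greenness is aggregated both over circular buffers (100–1500 m radii) and
over catchment-buffer corridors; the published indicator table is ambiguous
between the two relationships for this domain, so both are emitted and
distinguishable by the relationship code.

## Walkability and land-use intensity

Land-use intensity is Shannon's `H = −Σ pᵢ ln pᵢ` over the feature-class
composition within 300 m of each 25 m cell center, with the equitability
variant `H/ln(s)` also emitted (the published description is ambiguous
between the two, so consumers get both). The walkability surface is an
**equally weighted mean of z-standardized components** — land-use intensity,
transit accessibility (straight-line decay-weighted stop count), street
centrality (closeness of the nearest segment at 1000 m radius), and
residential address density — at 25 m resolution. This is a deliberately
simplified composite: it reproduces the component list and resolution of
calibrated pedestrian-demand models without their estimated weights, which
require licensed movement data. Components are computed directly at cell
centers (exact for synthetic inputs) rather than interpolated from scattered
samples; weights are configurable. Zero-variance components are dropped with
a warning rather than silently producing NaNs.

## Traffic

Traffic records arrive keyed by street (pre-dissection centerline) and
period — AM peak 07:00–09:00, off-peak 10:00–16:00, PM peak 16:00–19:00 —
already aggregated, as purchased GPS-probe data is; a helper averages finer
records. The congestion ratio is 1 at or above free flow and `x/a` below,
hence always in [0, 1]. Catchment aggregation (300 m) is unweighted by
segment length; a length-weighted variant would require attributing counts
to partial segments, which the upstream data does not support.

## Built form and dwellings

Building metrics are footprint, height, volume (footprint × height) and
gross floor area (footprint × floors). Block density uses the Spacematrix
definitions — GSI = Σ footprint / block area, FSI = Σ floor area / block
area, OSR = (1−GSI)/FSI, L = FSI/GSI — which the source method names but
does not print, deferring to the density-atlas literature; the algebraic
identity `OSR·L = (1−GSI)/GSI` is asserted in tests. Buildings straddling a
block boundary are clipped (Sutherland–Hodgman, valid for the convex blocks
a grid plan produces; non-convex blocks fall back to centroid assignment)
and floor area is pro-rated by the clipped fraction. Addresses inside a
block share its indices; flats in one footprint therefore share block
values.

Dwelling records pass through with vocabulary validation (built form,
dwelling type, tenure), an alias table for common spelling variants
("semidetached" → "semi-detached"), and non-negativity checks; invalid
entries are flagged with machine-readable reasons, never dropped.

## Address matching

Free-text addresses are uppercased, stripped of punctuation, abbreviation-
expanded (ST → STREET, ...) and postcode-canonicalized; normalization is
idempotent. Matching is exact on the normalized string when possible,
otherwise a multiset Sørensen–Dice token-set similarity — order-insensitive,
because field order in historical GP records is chaotic — with a hard ×0.5
penalty when both sides state different postcodes. Ties break by postcode
agreement, then smaller UPRN. The 0.85 acceptance threshold is a
configuration default, not a claim about any particular dataset. On the
generator's corruption model, case/punctuation/abbreviation noise is
recovered completely (normalization inverts it exactly) and adding token
transpositions keeps recovery above 95%, which the acceptance suite checks
at n = 500.

## The synthetic city

The generator emulates every input layer with known ground truth: an
orthogonal grid (1400 m extent, 100 m spacing by default — about 2200
segments after dissection) plus random diagonal shortcuts so both 0° and
oblique turns exist; 500 addresses 5–15 m off their streets with canonical
address strings; parks spanning one to four grid cells with entrance points;
bus stops, one rail station, food outlets with a 40% fast-food share
clustered toward the center; reflectance bands (30 m) that brighten in NIR
near parks; pollutant surfaces (5 m) decaying from the center; per-street
period traffic; one building and one EPC-style dwelling record per address;
and corrupted address strings paired with true UPRNs. All randomness flows
from one seed; regeneration is byte-identical.

What it does *not* emulate — and hence what green tests do not establish
about real data: realistic street-network morphology (real cities are not
grids), spatially correlated address density, satellite artifacts (clouds,
shadows, registration error), traffic count seasonality, or the genuinely
adversarial messiness of historical addresses (typos inside tokens,
vanished street names). The pipeline's correctness claims are geometric and
algorithmic; calibration claims would need real data.

Default problem sizes were chosen so the full pipeline (2200 segments ×
500 addresses × all eleven domains, 267 indicators per address) completes
in a couple of minutes on one CPU, and so the property suites (100 oracle
toys, 50 monotonicity cities) stay comfortably fast.

## Numerical choices and degenerate inputs

- Angular cost ties: 1e-6 turn-unit tolerance, both in routing tie-breaks
  and in co-optimal path detection; near-zero turn angles (< 1e-4 degrees)
  snap to exactly zero when the adjacency is built.
- Node merging: 0.01 m; collinear-overlap centerlines are not deduplicated
  (the generator never produces them; real inputs should be cleaned
  upstream).
- Empty reach sets, unreachable destinations, zero denominators, zones
  outside rasters, unsnappable addresses: all produce missing values with
  machine-readable reasons (`empty-reach`, `unreachable`,
  `zero-denominator`, `outside-raster`, `unsnappable`), never silent NAs —
  the pipeline asserts that every missing cell carries a reason.
- Geographic (degree) coordinates are rejected by a heuristic (extent inside
  the lon/lat box *and* spanning under one unit); all geometry is planar
  meters in one CRS per run.

## Known limitations

- No traffic-rule routing (one-way streets, turn bans) and no elevation;
  the pedestrian model treats all streets as walkable both ways.
- Centrality pair paths are computed within the source's reach subgraph;
  for asymmetric reach sets near the radius boundary this is a convention,
  not an approximation — the enumeration oracle implements the same rule.
- Corridor areas and masks are grid-rasterized; exact polygon unions are
  deliberately avoided (no polygon-clipping dependency), at the cost of
  sub-cell precision.
- The walkability composite is a documented stand-in with configurable
  weights, not a calibrated demand model.
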