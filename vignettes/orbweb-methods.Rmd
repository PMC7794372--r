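---
title: "Orb-web architecture: metrics, synthetic archetypes and the species comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orb-web architecture: metrics, synthetic archetypes and the species comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbweb)
```

## The scientific problem

Orb webs are a physical record of foraging behaviour: a hub, radial spokes,
a sticky capture spiral, and usually an enclosing frame moored to the
surrounding substrate. Because the geometry is easy to measure in the field,
differences in web architecture between species — or between habitats — can
be quantified and tested. The design this package supports is a three-species
comparison of a cave-dwelling orb weaver (*Meta menardi*) with two
surface-dwelling relatives (*Metellina mengei*, *Tetragnatha montana*),
where the striking contrast is structural: cave webs largely lack frame
threads, with radii attaching directly to the rock and thereby acting as
mooring threads.

## Derived web metrics

Five quantities are derived from each web's raw measurements (all lengths
in mm; `H` is the *diameter* of the hub + free zone, so the hub radius is
`H/2` everywhere):

* **Derived radii.** Only the upper vertical radius `r_u` and right
  horizontal radius `r_r` are measured; the opposite radii follow by
  subtraction: `r_l = d_v − r_u`, `r_le = d_h − r_r`. Records where the
  measured radius reaches or exceeds its diameter are rejected as
  geometrically impossible.
* **Capture area** (Ellipse–Hub): the ellipse spanned by the two diameters
  minus the central hub/free-zone disc,
  `A = (d_v/2)(d_h/2)π − (H/2)²π` (mm²). Tables report cm²; the factor of
  100 is applied at reporting only.
* **Vertical asymmetry** `(r_u − r_l)/(r_u + r_l)` ∈ [−1, 1]: 0 for a
  vertically symmetric web, negative when the hub sits above centre.
* **Shape** `(d_h − d_v)/(d_h + d_v)` ∈ (−1, 1): 0 for a circular web,
  negative when taller than wide.
* **Mean mesh height**: the average gap between adjacent spiral loops,
  taken over all four quadrants, `¼ Σ (r − H/2)/(s_Q − 1)` with the
  pairing Q1↔`r_u`, Q3↔`r_l`, Q2↔`r_r`, Q4↔`r_le`. A quadrant with fewer
  than 2 spiral turns has no inter-loop gap, so mesh height is undefined;
  such records keep `NA` mesh fields rather than being dropped, and the
  models downstream use available cases.

Relative metrics divide by cephalothorax width (`cw`) to remove spider-size
scaling: relative area `A/cw²`, relative mesh `m/cw`, relative leg lengths
`pt/cw`. Dimensional behaviour is tested as a property: scaling all lengths
by `k` scales area by `k²`, mesh by `k`, and leaves asymmetry, shape and the
relative metrics (with `cw` scaled too) unchanged.

## The synthetic archetypes

No raw data are deposited for the motivating study, so the generator
emulates its *published summary statistics* and sampling design. Each
species archetype stores target distributions (mean and per-observation SD)
for web area, asymmetry, shape, spiral turns, and four morphology variables,
plus structural rules and the location design:

* Means and SEMs are the published group values; SEMs become
  per-observation SDs via `SD = SEM·√n` at the printed group sizes
  (n = 19/29/25).
* The sampling design is 3 caves for the cave species, 10 and 5 transects
  for the surface species, with webs allocated round-robin.
* Leg patella–tibia means are **not** published; the defaults are
  calibration choices set to preserve the published ordination of relative
  leg lengths (leg I longest in *T. montana*; leg III shortest in
  *M. mengei*; the cave species exceeding *M. mengei* on both). They are
  documented as free parameters, not reference values.
* Radius count (Poisson mean 18) and hub fraction (`H = 0.1·d_v`) are also
  free parameters: the motivating study found no species difference in
  radius number and prints no count means.

### Sampling in metric space

Webs are drawn in metric space and the formulas inverted, so recomputing
the metrics from the emitted measurement table reproduces each web's drawn
targets to numerical precision: from drawn area `A` and shape `p`,
`d_v = sqrt(4·100A / (π[(1+p)/(1−p) − f²]))`, `d_h = d_v(1+p)/(1−p)`,
`H = f·d_v`; from drawn asymmetry `y`, `r_u = d_v(1+y)/2`. Spiral counts are
integers, so they use unbiased stochastic rounding of the drawn target plus
a ±½-turn quadrant jitter, floored at 2 — mesh height is therefore emergent
rather than exactly invertible.

Structural rules give the regime contrast: `eliminated` webs draw
`n_frame ∈ {0, 1, 2}` with weights (0.92, 0.06, 0.02) and set
`n_mooring = n_radii + {0, 1, 2}` (radii moor the web directly, so the two
counts are nearly collinear); `enclosed` webs carry a frame of roughly
`n_radii` sections and only 3–7 mooring threads.

### Truncation and location structure

Draws are truncated normals. Truncation bounds are *symmetric* about the
target mean — `mean ± min(3·SD, distance to the physical bound)` with
physical bounds such as asymmetry ∈ [−0.85, 0.85], shape ∈ [−0.6, 0.6],
spiral turns ≥ 2 — because symmetric truncation leaves the mean unbiased,
which is what the calibration round trip checks.

Location clustering is an additive Gaussian offset per (location, metric),
with the configured total SD decomposed as
`sd_loc = 0.3·sd_res`, `sd_loc² + sd_res² = sd_total²` so the emitted
per-observation SD matches the published one. By default the drawn offsets
are **centred to sum to zero within each species** (`center_locations =
TRUE`). This is a deliberate trade-off: with only 3 cave locations, iid
offsets leave the species sample mean with a standard error of
`sd_loc/√3` no matter how many webs are drawn, so a large calibration run
could not recover the configured mean; centring removes that bias term
exactly. The cost is that sum-to-zero offsets are negatively dependent, so
species-level F tests run on centred data are conservative. Simulations
whose *purpose* is inference calibration (type-I error of the species term)
therefore set `center_locations = FALSE`, restoring the exchangeable
random-effect structure the mixed model assumes. Both modes are exposed on
the archetype and documented here rather than hidden in test code.

### What the generator does and does not emulate

It reproduces the published group means, SEM-implied spreads, sample sizes,
location counts and the structural frame/mooring signature. It does **not**
model correlation among metrics within a web (larger webs getting more
spiral turns, for instance — the published tables carry no such
information, so metrics are drawn independently given the location), web
inclination, within-cave microhabitat, or measurement rounding to the
field's 1-mm precision (values are emitted continuous so the round trip is
exact). Passing tests on synthetic data therefore demonstrate that the
*pipeline* is calibrated and powered under the published effect sizes — not
that any particular biological conclusion transfers to new field data.

## The comparison workflow

Each response is modelled as `response ~ species + (1 | location)` by REML
(`lme4`). The species term is tested with a Type II Wald F test using
Kenward-Roger denominator degrees of freedom (`car::Anova` backed by
`pbkrtest`), matching standard practice for small, unbalanced
location-clustered designs. Where the omnibus P < α (default 0.05), all
three pairwise species contrasts are computed on the model scale with
Kenward-Roger df and Tukey (studentised-range) adjustment (`emmeans`);
contrasts are *not* reported for non-significant responses.

Transforms: relative web area and relative leg I length are natural-log
transformed (strictly positive, right-skewed); count responses (radii,
frame, mooring, spiral turns) are modelled untransformed on the Gaussian
scale — a fidelity choice mirroring how such field data are conventionally
analysed, not an endorsement of Gaussian models for counts.

Morphology is summarised by PCA on the four size variables. Variables are
centred and scaled to unit variance by default: they are all in mm but span
an order of magnitude (cephalothorax width ~2 mm, total length ~9 mm), and
a covariance PCA would be dominated by the longest variable. `scale = FALSE`
restores covariance PCA for users who want it.

Numerical and degenerate-input choices, in brief: a singular fit (location
variance at the boundary) is flagged with a warning but returned — it is
exactly the one-way ANOVA limit, and the package tests that the F statistic
then equals the closed-form ANOVA F; a response with zero variance is
flagged degenerate with `F = 0` rather than fitted; per-response failures
inside the batch runner are collected into the report instead of aborting
the other responses.

## Problem sizes used in validation

The package's own validation uses: exact reference cases for the four
formulas; a 10⁶-point Monte-Carlo rejection-sampling oracle for the
Ellipse–Hub area over 50 random webs (1% relative tolerance); calibration
round trips of 1,000 generated webs/spiders per archetype (2-SEM bands for
the acceptance round trip, 3-SEM in auxiliary per-metric sweeps, which
keeps the per-metric false-alarm probability below 0.3% at a fixed seed);
200 null studies for type-I error of the species test (band [0.02, 0.09]);
and 100 studies at the calibrated effect sizes and field sample sizes
(19/29/25) for power of the spiral-turn (≥ 80%) and frame/mooring (≥ 95%)
tests.

## Known limitations

* Counts are modelled with Gaussian LMMs (by design, for fidelity to field
  practice); a GLMM would be the principled alternative for `n_frame`,
  which is zero-inflated in the cave species.
* The generator's independence of metrics within webs understates realistic
  within-web correlation; between-species contrasts are unaffected, but
  within-species covariance structure should not be read off synthetic
  data.
* Kenward-Roger df with 3 locations in one species are small; omnibus
  denominator df of ~10–13 are expected and P values should be read
  accordingly.
* The SVG renderer is a schematic visual check of the frame/mooring
  contrast, not a geometric reconstruction.
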