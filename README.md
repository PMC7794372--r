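# orbweb

Quantitative analysis of orb-web architecture for comparative behavioural
ecology. The package targets a classic field design: calliper and count
measurements of orb webs (and of the resident spiders) collected for several
species across caves or transects, compared with mixed models to ask whether
a species — here, a cave-dwelling orb weaver versus two surface-dwelling
relatives — builds a structurally different web.

## What it computes

From the raw per-web measurements (vertical and horizontal capture-spiral
diameters `d_v`, `d_h`; upper and right radii `r_u`, `r_r`; hub + free-zone
diameter `H`; spiral-turn counts per quadrant `s_Q1..s_Q4`; radius, frame
and mooring counts) the package derives the standard web statistics:

- lower/left radii: `r_l = d_v − r_u`, `r_le = d_h − r_r`
- capture area (Ellipse–Hub): `A = (d_v/2)(d_h/2)π − (H/2)²π`
- vertical asymmetry: `(r_u − r_l)/(r_u + r_l)` (0 = symmetric, negative =
  hub above centre)
- shape: `(d_h − d_v)/(d_h + d_v)` (0 = circular, negative = taller than
  wide)
- mean mesh height, averaged over all four quadrants:
  `¼ Σ (r − H/2)/(s_Q − 1)`
- relative (size-normalised) metrics: area / cephalothorax-width², mesh and
  leg lengths / cephalothorax width

A seeded generator (`default_archetypes()`, `make_study()`) simulates
three-species studies calibrated to published group summaries for
*Meta menardi* (cave), *Metellina mengei* (woodland) and *Tetragnatha
montana* (riverside), including the cave web's structural signature: frame
threads eliminated, radii attaching directly to the rock and thereby acting
as mooring threads.

The comparison workflow (`compare_all()`) mirrors the field analysis:
principal component analysis of morphology; per-response linear mixed
models `response ~ species + (1 | location)`; Type II Wald F tests with
Kenward-Roger degrees of freedom; Tukey-adjusted pairwise contrasts where
the omnibus test is significant.

## Worked example

```r
library(orbweb)

study <- make_study(seed = 1)    # 19 + 29 + 25 webs, spiders paired
report <- compare_all(study)
print(report)
```

```
<comparison_report> Type II Wald F tests (kenward-roger df), alpha = 0.05

     response   transform      F df df_den        P sig
     rel_leg1 natural_log 118.46  2   11.8 1.57e-08   *
     rel_leg3        none  27.42  2   10.8 5.83e-05   *
      n_radii        none   1.10  2   11.1 3.67e-01
     area_cm2        none  14.65  2   10.4 9.45e-04   *
    n_mooring        none 128.52  2   11.9 8.71e-09   *
      n_frame        none  94.69  2   10.4 2.13e-07   *
    asymmetry        none   6.91  2   10.4 1.24e-02   *
        shape        none   1.08  2   12.0 3.70e-01
     rel_mesh        none  10.62  2   10.4 3.08e-03   *
     rel_area natural_log   9.73  2   12.8 2.72e-03   *
 spiral_turns        none  69.22  2   10.4 9.81e-07   *
```

Reading the table: each row is one web or morphology response; `F` is the
Type II Wald F statistic for the species term (numerator df = 2 for three
species, Kenward-Roger denominator df), and `sig` marks responses where the
species differ at α = 0.05. On this simulated study the cave species
separates sharply on the structural responses — frame-thread count,
mooring-thread count, spiral turns, relative web area — while radius count
and overall shape do not differ: the qualitative signature the generator is
calibrated to. Tukey-adjusted pairwise contrasts for the significant
responses and the morphology PCA (PC1 + PC2 ≈ 94% of variance here) are
printed below the table and stored in the report object.

The same pipeline runs from the shell:

```sh
orbweb=$(Rscript -e 'cat(system.file("scripts", "orbweb", package = "orbweb"))')
Rscript $orbweb simulate --seed 1 --out sim/
Rscript $orbweb metrics  --webs sim/webs.csv --morphology sim/morphology.csv --out sim/metrics.csv
Rscript $orbweb compare  --webs sim/webs.csv --morphology sim/morphology.csv --out sim/report
Rscript $orbweb render   --webs sim/webs.csv --row 1 --out sim/web.svg
```

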