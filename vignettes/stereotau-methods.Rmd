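---
title: "Quantifying tau pathology on serial sections: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tau pathology on serial sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereotau)
```

## The estimation problem

A tauopathy survey of a cortical region asks four quantitative
questions: how many tau-immunoreactive structures of each type the
region contains per unit volume; how those densities vary across
cortical layers I, II, III, IV–VI and the white matter; whether
pathology concentrates at the depths of sulci (the signature
distribution of trauma-associated tauopathy); and whether structures
cluster around blood vessels. The raw material is not an image but an
annotation export: marker points typed as neuropil threads, neuritic
thread clusters or neurons; layer contour polygons; vessel centres with
diameters; and sulcus landmarks — all planar coordinates in micrometres
on a serial section series. This package treats that export as the unit
of analysis and keeps everything downstream deterministic and testable.

## The optical fractionator and its one unidentifiable constant

Counting every structure in a known fraction of the tissue yields the
unbiased estimator $\hat N = \sum Q^- / (ssf \cdot asf \cdot tsf)$. Two
of the three fractions are fixed by the sectioning protocol: $ssf$ is
cut thickness over section period (50/500 = 0.1 by default) and $asf$
is the SRS grid coverage (1 for exhaustive counting; for partial grids
the counting-frame forbidden-line rule is implemented in
`frame_counted()`, counting the inclusion edges and excluding the
forbidden ones). The third, $tsf$ = dissector height / mounted section
thickness, depends on how much the section collapsed between cutting
and mounting — a measured quantity that annotation exports rarely
carry. `sampling_design()` therefore makes mounted thickness an
explicit field, defaulting to 15 µm, the minimum admissible value
(11 µm dissector plus two 2 µm guards). This choice rescales every
population estimate and density by a single constant; ratios between
layers, compartments or subjects are unaffected. Any analysis with a
measured mounted thickness should set it.

Unbiasedness is not taken on faith: the test suite and the acceptance
script place a fixed population of 1000 particles in a slab, section it
with uniformly random phase under the default design, and verify that
the mean of 500 replicate estimates sits within 2% of the truth.

## Precision: the Gundersen–Jensen CE

The precision of a systematic-series count is estimated as
$CE = \sqrt{n + \mathrm{Var}_{SRS}}/n$ with $n = \sum Q_i$ and
$\mathrm{Var}_{SRS} = (3(A - n) - 4B + C)/240$ for smoothness class
$m = 1$ (denominator 12 for $m = 0$), where $A, B, C$ are the sum of
squared counts and the lag-1 and lag-2 cross-products. We default to
$m = 1$, the conventional choice for smoothly varying biological
series, expose $m = 0$, and clamp a negative smoothness variance at
zero — visible in the flat-series oracle `gundersen_ce(rep(5, 10))`
$= \sqrt{50}/50 \approx 0.141$. A series of fewer than three sections,
or with no counts at all, has no defined CE; the function returns `NA`
rather than a silent zero, and `flag_high_ce()` flags such rows as
"insufficient counts" alongside rows at or above the 15% acceptability
limit. In practice only rare structures (tau-bearing neurons,
especially in white matter) trip the flag, which is exactly the caveat
the rule exists to express.

## Volumes, densities and the two unit scales

Layer volumes use the Cavalieri rule — summed contour areas times the
500 µm period — the only volume estimator consistent with exhaustively
counted serial sections. Densities are reported on two scales because
the field tabulates both: layer densities per cm³ and partition
(sulcal/gyral) densities per mm³. The `DensityRecord` rows carry the
scale explicitly and satisfy per-cm³ = 1000 × per-mm³ identically; no
attempt is made to adjudicate between the two conventions.

## Sulcal versus gyral partition

The sulcal compartment is defined by the bottom-third rule: sulcal
depth is the mean Euclidean distance from the annotated fundus to the
two mouth points, and a grey-matter marker is sulcal when its
straight-line distance to the fundus is at most `depth_fraction`
(default 1/3) of that depth. Straight-line distance — rather than
geodesic depth along the ribbon midline — is a deliberate choice: the
bottom-third convention has no universally computable geodesic
formulation on an annotation export, whereas the Euclidean rule is
exactly reproducible from the landmarks alone. Compartment areas come
from the exact disc–polygon intersection (Green's-theorem edge
decomposition, `circle_polygon_area()`), validated in the tests against
a fine-grid integration oracle to 1%.

## Perivascular association: boundary conventions

Eligibility is *strictly* greater than 30 µm diameter; association is
edge distance *at most* 100 µm, with edge distance floored at zero for
markers inside the lumen; the mean vessel–tau distance averages over
associated vessels only, each contributing its nearest marker. These
conventions are stated because published summary tables cannot
disambiguate them; the all-below-100 µm mean distances such tables
print are consistent with averaging over associated vessels and
inconsistent with averaging over all of them. All marker types are
pooled by default (`structures` filters when a restriction is wanted).
One published row (190 vessels, 8 associated, printed as 4.07% where
8/190 = 4.21%) is internally inconsistent and is carried as printed in
the bundled reference table, not reconciled.

## Heatmaps

Distribution heatmaps deliberately bin *raw pooled* marker coordinates
— the total distribution, not the fractionator-corrected population —
because that is what pooled serial-section maps show. Defaults: 250 µm
square bins and a Gaussian smoothing bandwidth of one bin, neither of
which is dictated by any protocol; both are parameters. Smoothing uses
a per-source renormalized kernel so the smoothed surface conserves
total mass exactly; the raw `counts` matrix always sums to the number
of binned markers, an invariant the tests assert.

## The synthetic generator as the testing ground

`synthetic_params()` encodes the generative model the analyses assume:

* a gyrus–sulcus ribbon built from a Gaussian infolding (default
  amplitude 3000 µm, half-width 500 µm, 8 mm of ribbon) with grey bands
  of 200/300/500/800 µm for layers I/II/III/IV–VI over a 700 µm white
  matter core, as vertical offsets of the pial curve — so band areas
  are exactly width × thickness and the laminar bookkeeping is
  closed-form;
* piecewise-constant laminar intensity $\lambda_0\,\alpha^{l-1}$
  (defaults $\lambda_0 = 200$/mm², $\alpha = 0.6$) with a white-matter
  floor of $0.02\,\lambda_0$ — piecewise-constant because densities are
  reported per layer, which keeps the recovery target exact;
* sulcal enrichment by thinning: candidates are generated at the
  $(1+\beta)$-inflated rate everywhere and kept with probability
  $1/(1+\beta)$ outside the sulcal compartment, so the compartment's
  intensity is exactly $(1+\beta)$-fold in expectation (default
  $\beta = 2$);
* log-normal vessel diameters (median 40 µm, sd-log 0.4) spanning the
  30 µm eligibility cut, and a `perivascular_fraction` (default 0.2) of
  markers drawn as Gaussian clusters (sd 50 µm) around uniformly chosen
  vessels;
* a single master seed with fixed substreams for geometry, vessels and
  markers, making every bundle byte-reproducible.

Recovery tests close the loop: the pipeline's per-layer density ratios
recover $\alpha$ and the sulcal/gyral ratio recovers $1+\beta$, each
within 10%, averaged over three seeded bundles. These two checks run
with `perivascular_fraction = 0`: perivascular clustering adds a
spatially uniform-in-layer marker component that flattens the laminar
profile by design, so it would confound the decay target it has nothing
to do with. The clustering mechanism is verified separately — the
association percentage rises monotonically over clustering fractions
0, 0.2 and 0.5 (about 75% → 99% → 100% under the defaults; the
background intensity alone nearly saturates the 100 µm rule, so the
informative contrast is at the low end).

What the generator does *not* emulate: curved or branching sulci,
anisotropic shrinkage, section-to-section misalignment beyond what the
affine transforms express, marker mislocalization, and any biophysics
of tau propagation. Passing recovery tests therefore demonstrates that
the estimators are faithful to their own model, not that the model
exhausts real histology.

## Numerical and degenerate-input choices

* Polygons are stored as open rings, outer boundary counter-clockwise,
  holes clockwise, winding normalized on construction; point-in-polygon
  is the even-odd rule, checked in the tests against an independent
  per-point crossing oracle on 10⁴ random points.
* Layer-overlap validation is exact rather than area-based: two layer
  interiors overlap when their boundaries properly cross or when a
  vertex or edge midpoint of one lies strictly inside the other
  (farther than a relative 10⁻⁶ from its boundary). Adjacent bands
  sharing a contour therefore never trigger; any constructed overlap of
  practical size does.
* A marker on a shared band boundary resolves deterministically to the
  more superficial layer (canonical order I, II, III, IV–VI, WM).
* Degenerate inputs fail loudly: zero volumes, zero partition areas,
  all-zero CE series, missing transforms, sub-3-section series and
  clustering without vessels all raise or signal rather than returning
  a quiet zero.
* Alignment is an affine per section (the least structured family that
  contains the rigid motions manual alignment produces); vessel
  diameters rescale by the isotropic factor $\sqrt{|\det|}$.

## Problem sizes

The default test and acceptance runs use 10-section bundles of roughly
15,000 markers and 1,000 vessels, three seeds per recovery check, 500
Monte-Carlo replicates for unbiasedness, and 10⁴-point oracle
comparisons — sizes at which every stochastic tolerance in the suite is
comfortably resolved while the full suite runs in well under a minute.

## Known limitations

Absolute densities are reproducible only up to the mounted-thickness
constant discussed above. The sulcal rule uses one fundus per section;
multi-sulcus sections need one annotation per sulcus and a split of the
ribbon. Vessel association is 2-D within-section; no attempt is made to
trace vessels across sections. The pipeline is descriptive throughout —
with three subjects there is no basis for inferential statistics, and
none are computed.
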