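---
title: "Methods: colony-array densitometry and light-sensitivity calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colony-array densitometry and light-sensitivity calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lightscreen)
```

# The measurement problem

Visible-light toxicity in pinned yeast colonies depends sharply on the
number of cells deposited at pinning: outer cells absorb the light and
shield inner cells, so sparse colonies die while dense colonies grow
almost normally. A screen for light-sensitivity genes therefore has to
(i) measure *cell density*, not colony area, from plate photographs,
(ii) condition every call on the initial density, and (iii) separate
light-specific growth defects from general slow growth. This vignette
describes how the package does each step, the parameters involved, and
what the synthetic validation data do and do not establish.

# Cell density estimation from plate images

A 16×24 array is photographed so that each colony row occupies a 30-px
band and colony centers are 60 px apart (`array_layout()` holds this
geometry and accepts other values). For one band:

1. **Column profile** — each of the band's columns is reduced to the sum
   of its 25 brightest pixels (`band_profile()`). Summing a fixed count
   of top pixels boosts the signal-to-background ratio for the faint
   colonies present right after pinning, and makes the profile linear
   under uniform illumination shifts (a shift of *c* adds exactly 25 *c*
   everywhere).
2. **Colony windows** — the profile is cut into consecutive 60-value
   windows, one per colony, colony centered (`colony_windows()`); the
   windows partition the profile exactly.
3. **Colony and background intensity** — within a window (positions
   1–60, 1-based inclusive), the colony intensity is the median of the
   10 largest values among the central 20 positions (21–40), and the
   background is the mean of the two flank minima over positions 5–20
   and 40–55 (`colony_intensity()`, `background_intensity()`).
4. **CDE** — their difference (`colony_cde()`). It is *not* clipped at
   zero: an empty position with a bright flank legitimately yields a
   negative value and the calling thresholds operate on the raw number.

Conventions the image format does not fix were settled as follows: all
pixel ranges are treated as 1-based inclusive at API boundaries; the
median of an even count is the mean of the two central order statistics
(base R's convention); ties in top-*k* selection use multiset semantics;
RGB photographs are collapsed by the unweighted channel mean (the camera
pipeline is not modelled, and all downstream thresholds are recalibrated
per dataset anyway). Images are expected pre-cropped to the grid with an
optional fixed `(row, col)` registration offset; automatic grid
detection is out of scope, so any registration beyond that offset is the
caller's responsibility.

These choices give three exact invariances that the test suite checks
property-style: uniform-offset invariance of every CDE (in integer
arithmetic, exactly), monotonicity in any central pixel, and locality (a
colony's CDE depends only on its own 60-column window of its own band).
`quantify_plate()` is additionally cross-checked value-for-value against
a deliberately naive loop reimplementation on 100 random rendered
plates.

# Calling light-sensitive and light-resistant strains

Scoring consumes four CDE tables — light day 0 and 6, dark day 0 and
1 — plus a layout marking control colonies. Light plates are read at
day 6 and dark plates at day 1 because growth under illumination is
much slower; the dark day-1 value serves as the strain's intrinsic
growth rate.

**Density bands.** Initial (day-0 light) CDE below 61 → `discarded`
(controls at such densities fail light growth too often for any call to
be meaningful); 61–120 → `moderate`; ≥ 121 → `high`. The printed band
edges are integers; for real-valued CDEs the moderate band runs up to
the high-band edge so the partition has no gap. Alternative band
definitions for the haploid confirmation assay (high ≥ 13, no moderate
band) and the diploid assay (high ≥ 105; moderate 45–104, cutoff 500)
are available as `screen_thresholds()` variants; every cutoff is an
argument.

**Criterion I.** Day-6 light CDE strictly below the band cutoff: 900
(high) or 400 (moderate).

**Criterion II.** The double-normalized light growth
$\mathrm{LGnorm}_j = \frac{\mathrm{LG}_j/\mathrm{DG}_j}
{\widetilde{\mathrm{LGctr}/\mathrm{DGctr}}}$,
where $\mathrm{LG}_j$ is strain $j$'s day-6 light CDE, $\mathrm{DG}_j$
its day-1 dark CDE, and the denominator the median of the same ratio
over the control colonies of the same plate and band (computed per band
because the control medians differ slightly between density ranges;
plates with no in-band control borrow the value from the nearest plate
by index, lower index on ties). A sensitive call requires
$\mathrm{LGnorm} < 0.75$ *and* criterion I. By construction the median
control LGnorm on every plate/band is exactly 1, which the acceptance
tests verify, and LGnorm is invariant under per-plate rescaling of the
light channel.

**Exclusions.** Strains missing any required measurement, or with
non-positive dark denominators, are excluded with a machine-readable
reason rather than aborting the run; strains with < 1.5-fold dark
growth over day 1 are excluded as slow growers (they would otherwise
masquerade as light-sensitive — the synthetic generator plants exactly
this failure mode). Every layout position receives exactly one verdict
plus an audit string.

**Resistance.** Day-0 CDE ≥ 61 and day-6 light CDE strictly above 1642.
The analytical window for resistance is much tighter than for
sensitivity, and on real screens the control distribution overlaps this
cutoff; the package reports the control fraction passing the criteria
(`estimate_false_positive_rate()` style) rather than asserting any
particular false-positive rate.

**Calibration.** Control colonies are scored like strains; the per-band
fraction of controls passing criterion I is the control-based
false-positive estimate reported alongside the calls.

# Drop-test quantification

Spot assays are quantified as integrated spot intensity minus spot area
times the local background, per mm² (INT/mm²). The background level is
the median of an annulus around the spot (width configurable, 5 px
default) — a robust choice given that only "background subtraction" is
inherent to the measure. The strain-specific light/dark ratio compares
the *first* light dilution against the *second* dark dilution of the
day-3 scan, offsetting the roughly tenfold slower growth under light;
for flagged slow growers the light value is read from the day-5 scan at
the same dilutions (the flag is a per-strain input: no operational
auto-detection rule exists). Each strain's per-experiment ratios are
tested against the wild-type reference from the same experiment batch
with a two-sided pooled-variance Student *t* test (significance at
*p* < 0.05); with two experiments per group this is the classical
df = 2 comparison, so effect sizes need to be large — which is the
regime the assay is used in.

# Enrichment

Term over-representation among called strains is tested against the
screenable reference set (strains with a comparable day-0 measurement,
i.e. scoreable initial density) with the hypergeometric upper tail
$P(X \ge k)$, term sizes counted *within the reference*, dubious ORFs
excluded from hits and reference alike, and terms with fewer than 25
reference genes skipped. FDR control is Benjamini–Hochberg (the
procedure is the standard choice; the flagging threshold default is
*q* ≤ 0.06). Depletion statements use the lower tail, available via
`tail = "lower"` but off by default: the calling question is
over-representation. The implementation uses `stats::phyper`; the test
suite checks it against exhaustive enumeration of all *n*-subsets for
every valid configuration up to a 12-gene universe.

# The synthetic generator

`simulate_screen_tables()` emulates the statistical structure the
scoring pipeline consumes, with these modelling choices (made once, on
field-realism grounds):

* **Initial density**: lognormal, meanlog = log 100, sdlog = 0.7. This
  is right-skewed with ≈ 24% of colonies below the scoreable range,
  ≈ 37% moderate and ≈ 39% high — the long-tailed spread a liquid-to-
  agar pinning robot produces. The exact family is immaterial to what
  the tests establish.
* **Light response**: expected day-6 light CDE of a neutral strain is
  logistic in initial density, $L_{max}/(1+e^{-(d_0-40)/15})$ with
  $L_{max} = 1500$: colonies above the shielding threshold grow well
  under light, colonies below it poorly — the near-binary control
  behaviour that motivates density banding. Strain effects multiply
  this curve (planted sensitive 0.2×, resistant 1.5×, slow growers
  0.4×).
* **Dark growth**: day-1 dark CDE is initial density × 3 for neutral
  strains, × 1.2 for planted slow growers (safely below the 1.5-fold
  exclusion boundary).
* **Noise**: additive Gaussian, sd 5 CDE units, on every emitted value.
  This is the *measurement* component only — propagating ~8-bit pixel
  noise through top-25 column sums and a 10-value median lands at a few
  CDE units — while biological spread is carried by the density law.
* **Planted strains** draw initial density from the same lognormal
  truncated to the scoreable range (≥ 61), since their phenotype is
  defined relative to their band's cutoffs; 76 controls per plate draw
  from the untruncated law.
* Seeds are explicit spec fields; identical specs produce identical
  tables.

`simulate_plate_image()` renders Gaussian-kernel colonies (confined to
their 30×60 grid cell, centered at column 30 + 60(i−1)) on a constant
background with optional linear gradient and additive noise, and returns
the true amplitudes. `simulate_droptest()` emits tenfold dilution series
in which the scored ratio recovers each strain's planted light/dark
ratio exactly at zero noise.

**What the synthetic data do not show.** The generator reproduces the
density dependence, the control asymmetry, and the slow-grower trap, but
not: spatial plate effects (edge colonies, illumination gradients across
a plate), correlated replicate structure, the heavy control tail that
overlaps the resistance cutoff on real screens (so synthetic resistant
precision is optimistic), or pinning failures. Passing the planted-
recovery tests therefore demonstrates that the *scoring logic* is
faithful, not that these thresholds would achieve the same
precision/recall on an arbitrary real dataset — on real screens the
thresholds are recalibrated from the control distribution.

# Validation scale and numerical notes

The acceptance checks run at these sizes, chosen to exercise every code
path at full array scale: 100 random bands for exact offset invariance;
100 full 16×24 rendered plates for the naive-oracle comparison; a
2000-strain screen (7 plates, 688 controls) with 200 planted sensitive,
50 resistant and 50 slow strains for recovery (exact at zero noise;
precision and recall ≥ 0.9 at the default noise); exhaustive
hypergeometric enumeration to N = 12. `scripts/acceptance.R` recomputes
all of these from scratch for any seed.

Degenerate inputs are handled conservatively: non-positive dark
denominators exclude the strain (reason logged); bands with no control
value on any plate raise an error only when a scored strain actually
needs them; drop-test groups need at least two ratios, and a zero dark
spot flags the strain instead of propagating an infinity. Known
limitations: no automatic grid registration or spot segmentation; PNG
output is 8-bit (use TIFF for 16-bit synthetic plates); the resistant
false-positive behaviour of real control tails is not emulated.
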