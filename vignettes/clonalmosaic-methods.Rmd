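---
title: "Methods: simulating and quantifying two-color tumor clonality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying two-color tumor clonality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalmosaic)
```

## The biological model

In a two-color mosaic mouse every intestinal crypt is heritably red
(tdTomato, Cre-negative) or green (EGFP, Cre-positive), with the
recombination pattern fixed during embryogenesis, before tumors arise.
Crypts are monoclonal, so the epithelium is a red/green patchwork whose
green fraction `p` varies along the tract: the proximal small intestine
is almost entirely red, the ileum about 12% green, and the colon about
37.6% green. A tumor founded by `N` crypts shows both colors — is
*heterotypic* — only when its founders span both lineages. clonalmosaic
implements the quantitative machinery around that observation:
simulation, image processing, patch-size measurement, per-tumor calls,
and the detection model.

## Synthetic mosaic generator

`generate_lattice()` places crypts on a jittered hexagonal packing
(default crypt radius 25 µm, spacing 2.4 radii, jitter bounded so
centres never approach closer than one crypt diameter). Lineages come
from thresholding a Gaussian random field: iid standard-normal noise on
crypt centres is smoothed with a Gaussian kernel of bandwidth
`correlation_length` and renormalised so each crypt's value is
marginally N(0, 1); a crypt is green when its value falls below the
p-quantile. This gives three properties the tests rely on: the expected
green fraction is exactly `p` at any correlation length, the empirical
fraction converges to `p` as the lattice grows, and patch size is a
monotone function of `correlation_length`.

The biology gives no spatial process for Cre mosaicism; the correlated
field is a deliberate stand-in calibrated only against the two summaries
the data constrain — the lineage fraction and the patch-size statistic.
The default `correlation_length` of 100 µm puts the rendered patch size
at one to two crypt diameters, matching the qualitative description of
small, evenly distributed patches in the distal tract. The
`tract_gradient_preset()` fixes section fractions at (0, 0.01, 0.02,
0.12, 0.376): interior values for sections 1–3 are nominal small numbers
consistent with an almost-entirely-red proximal intestine; sections 4
and 5 use the measured values.

`seed_tumor()` draws the first founder uniformly and recruits the
remaining founders without replacement within `recruitment_radius`
(default 150 µm) of it — a primogenitor/co-genitor picture. The tumor
region is the union of discs of that radius around the founders, which
is contiguous because every co-founder lies within one radius of the
first.

`render_whole_mount()` is the forward imaging model: crypt territories
are the Voronoi cells of crypt centres restricted to a tissue band
(0.7 × spacing around the lattice), tumor pixels take the lineage of
their nearest founder so multi-founder tumors show discrete clone
territories, and the channels receive a multiplicative linear
illumination field (default ±10% across the width) plus additive
Gaussian noise (default SD 0.08 against a foreground of 0.85). What the
generator does **not** emulate: autofluorescent debris, folds and
out-of-focus tissue, stroma and normal-crypt intermixing inside tumors,
vignetting beyond a linear ramp, or chromatic misregistration. Passing
round-trip tests therefore shows the pipeline is correct and robust at
realistic contrast, not that it would survive every real-world artifact.

## Image pipeline

The binarization chain mirrors a standard whole-mount macro: background
subtraction, CLAHE, auto-threshold, trinary conversion.

* `subtract_background()` uses grayscale morphological opening with a
  flat disc of the given radius (default 40 px) as the background
  estimate. Features narrower than the disc survive; anything wider is
  treated as background — which is why the defaults keep mosaic patches
  (~20–40 px) below the ball diameter.
* `enhance_local_contrast()` wraps EBImage's CLAHE, mapping a tile size
  in pixels and a clip fraction onto tile counts and a per-bin limit,
  padding by edge replication because the underlying routine needs
  dimensions divisible by the tile counts. A constant image is returned
  unchanged.
* `binarize()` defines tissue as pixels whose red+green sum exceeds
  `tissue_min_intensity` (default 0.5) times the Otsu threshold of the
  sum image; within tissue a pixel is GREEN when the green channel is
  above its own Otsu threshold and either red is below its threshold or
  green strictly exceeds red. Exact ties go to RED, deterministically;
  ties have measure zero for continuous intensities, which is why the
  channel-swap symmetry property still holds on real inputs. All
  thresholds are computed on 256-bin histograms spanning [0, max], so
  the label map is invariant to common intensity rescaling.

The tissue mask is computed on whatever channels `binarize()` receives.
The recommended path for clean synthetic renders is `binarize()`
directly; `process_whole_mount()` runs the full macro chain, which is
the right choice when illumination varies more strongly than the linear
ramp of the simulator.

## Patch-size statistic

`distance_map()` assigns every tissue pixel the Euclidean distance (in
µm, between pixel centres) to the nearest tissue pixel of the opposite
lineage. Non-tissue is transparent — excluded as source and target but
not a barrier — so D̄ is a pure property of the red/green mosaic; this
is also the only convention under which rescaling pixel size simply
rescales D̄. The exact Euclidean distance transform comes from
EBImage's `distmap`, composed once per lineage; the test suite holds it
to *exact* agreement (integer squared distances) with an O(n²)
brute-force nearest-opposite search on random mosaics.

`patch_size()` averages over all tissue pixels of both colors, and also
reports per-lineage means because patch sizes are asymmetric when
p ≠ 0.5 (the minority color sits closer to opposite-color pixels).
Whether to pool pixels across images or average per-image statistics is
not determined by the field's practice; `section_profile()` exposes
both, with all-pixel pooling as the default. Single-lineage maps are
degenerate — distances are infinite — and are reported as missing
rather than zero.

## Clonality calls

`classify_tumor()` calls a tumor heterotypic when each lineage's tissue
area inside the mask reaches `min_clone_area`. The default is one crypt
area (π·25² ≈ 1963 µm²): dysplastic crypts are wholly one color, so one
crypt is the smallest credible clone. This threshold is also the only
defence against normal-crypt contamination (a homotypic tumor overrun
with a few normal crypts of the other color); no neoplasia classifier
is attempted, since that requires histology. Raising the threshold can
only demote heterotypic calls to homotypic, never the reverse — a
monotonicity the tests check.

`count_discrete_clones()` labels minority-lineage tissue with
8-connected components, merges components whose minimal pixel-to-pixel
gap is below `min_separation` (default 100 µm, one to two crypt
diameters — the separation at which discrete areas were scored as
distinct clones), and adds one for the majority lineage. Merging uses
single-linkage closure, so a chain of close components counts once.

`tabulate_architecture()` reports counts and integer-rounded
percentages per pathological category to match the reporting convention
of the study tables; raw fractions are kept alongside, and all tests on
proportions are computed from unrounded counts.

## Detection model and statistics

With founders exchangeable and lineage-independent, a tumor with `N`
founders is heterotypic with probability `h(p, N) = 1 − p^N − (1−p)^N`.
The observed heterotypic count among `n` tumors is modeled
`Binomial(n, f·h)` where `f` is the true multi-ancestral fraction;
`estimate_multiancestral_fraction()` inverts this (MLE `min(1, x/(n·h))`,
Clopper–Pearson interval on `f·h` divided by `h`). The estimator is
conservative by construction and never falls below the raw heterotypic
fraction, which is the lower bound one would report without a model.
`detection_power()` is the probability of at least `min_detected`
heterotypic tumors, `1 − pbinom(min_detected − 1, n, f·h)`; with the
study-scale n = 144 and p = 0.376 it shows a 1-in-100 multi-ancestral
rate is detectable with ~50% probability per cohort under the
independent two-founder model, and more under larger N. The power
statement ties to a detection definition (≥1 heterotypic tumor), an
assumed N, and a cohort size; all three are parameters rather than
baked-in choices, because the informal "1 out of every 100" claim does
not pin them down.

Independence of founder lineages fails when mosaicism is patchy and
founders are recruited locally: `het_probability_mc()` quantifies this
by simulating tumors on lattices, and spatial correlation depresses `h`
below the closed form (neighboring founders share lineage). Because
tumors simulated on one lattice share its lineage realization, the
Monte-Carlo standard error is computed *across* independent lattice
realizations (8 by default), not from the pooled binomial count — the
pooled SE understates the error noticeably at small `p`.

`compare_proportions()` is a chi-square homogeneity test of the
heterotypic fraction across categories with a Fisher
(Freeman–Halton) fallback when any expected count drops below 5.
`rank_sum_test()` and `two_sample_t()` wrap the two-sided Wilcoxon
rank-sum and Welch t tests with explicit degenerate-input handling
(all-tied ranks → p = 1 with a warning; two constant samples → flagged).
The published per-mouse multiplicities and per-mouse green fractions
behind the study's printed p-values are not available, so the test
wrappers are validated by calibration instead: under simulated nulls at
the study's group sizes (18 vs 15 mice for green fractions, 20 vs 31
for multiplicities) both tests hold their 5% size within ±2 points over
1,000 replicates, and a simulated multiplicity shift of the reported
magnitude (means 11 → 15, SD 5) yields median p-values below 0.1.

## Numerical choices and problem sizes

* All randomness flows through explicit integer seeds; no global RNG
  state survives a call. Identical configuration + seed gives
  bit-identical CSV outputs from `run_pipeline()`.
* The Gaussian field is computed in row blocks (O(block × n) memory);
  10,000-crypt lattices fit comfortably.
* Voronoi rasterization uses seeded propagation with a large spatial
  weight; pixels equidistant from two crypts may land on either side of
  the bisector, which is immaterial because the rendered truth is
  defined as the rasterization itself.
* Test and acceptance problem sizes — 64×64 oracle mosaics,
  ~500–700 px renders, 1,200–5,000-crypt lattices, 200–1,000 replicate
  simulations — were chosen as the smallest sizes at which the checked
  quantities are stable relative to their tolerances.
* Degenerate inputs are contracts, not crashes: empty tissue masks warn
  and flag, single-lineage maps return infinite distances with a
  degenerate attribute, infeasible tumor geometry raises a typed error.

## Known limitations

* The lineage field is a stand-in; real Cre mosaicism may have
  anisotropy (crypt fission runs along the tract) and long-range
  structure the Gaussian field lacks.
* Clonality is scored from 2-D whole-mount label maps; histological
  confirmation and 3-D clone structure are out of scope, and a clone
  hidden beneath the surface would be missed.
* `min_clone_area` conflates minimum clone evidence with
  normal-crypt-contamination control; with real tissue the two may need
  separate handling.
* The closed-form detection model assumes exchangeable,
  lineage-independent founders and one `N` for all multi-ancestral
  tumors; the Monte-Carlo variant relaxes independence but not
  founder-count heterogeneity.
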