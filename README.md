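# clonalmosaic

Tools for studying the **clonal origin of intestinal tumors in two-color
mosaic mice**. In these animals a Cre reporter marks every intestinal
crypt heritably red (tdTomato, Cre-negative) or green (EGFP,
Cre-positive) before tumorigenesis, so a tumor containing neoplastic
tissue of *both* colors — a heterotypic tumor — is overt evidence of a
multi-ancestral (multi-founder) origin. The package is aimed at
researchers quantifying tumor clonality from two-channel whole-mount
fluorescence images, and at anyone planning such an experiment who needs
the detection/power arithmetic.

It provides, end to end:

* **Synthetic mosaics** — ground-truthed crypt lattices with tunable
  green-lineage fraction *p* and spatial patchiness, multi-founder
  tumors (1–4 founder crypts), and a forward imaging model, so every
  downstream stage is testable without real data.
* **Image pipeline** — rolling-ball background subtraction, CLAHE, and
  Otsu auto-threshold binarization of the red/green channels into a
  trinary label map {RED, GREEN, NON_TISSUE}.
* **Patch metrics** — the distance-map mosaic patch-size statistic: for
  each tissue pixel the Euclidean distance to the nearest
  opposite-color pixel; its tissue-wide mean D̄ measures the mosaic
  patch size.
* **Clonality calls** — per-tumor classification into heterotypic /
  homotypic-red / homotypic-green, discrete-clone counting with a
  minimum separation rule (default 100 µm), and architecture tables by
  pathological category (LGD, HGD, intramucosal, invasive).
* **Clonal statistics** — the heterotypic-detection probability
  `h(p, N) = 1 − p^N − (1 − p)^N` for a tumor with `N` independent
  founders; inversion of `x_het ~ Binomial(n, f·h)` to estimate the true
  multi-ancestral fraction `f` with Clopper–Pearson intervals; detection
  power `1 − P(no heterotypic among n)`; and the proportion/rank/t tests
  used for architecture and mosaicism comparisons.

## Worked example

```r
library(clonalmosaic)

# a synthetic colon section: 2,000 crypts, 37.6% green lineage
lat <- generate_lattice(mosaic_params(p = 0.376, n_crypts = 2000, seed = 1))
glance(lat)
#>   n_crypts green_fraction     p correlation_length crypt_radius
#> 1     2000          0.362 0.376                100           25

# seed three tumors (2, 3, 4 founders), render, and binarize
tumors <- lapply(1:3, function(i) seed_tumor(lat, founder_count = i + 1, seed = i))
img    <- render_whole_mount(lat, tumors, seed = 2)
labels <- binarize(img)
labels
#> <label_map> 612 x 446 px, 5 um/px | red 59.9%, green 33.7%, non-tissue 6.4%

patch_size(labels)
#>   n_tissue_pixels green_fraction mean_distance_um red_mean_um green_mean_um
#> 1          255439          0.360             80.6        94.3          56.3
```

The measured green fraction (36.0%) recovers the generating lineage
fraction, and the mean distance to the opposite color (~81 µm, one to
two crypt diameters) is the mosaic patch size.

```r
classify_tumor(labels, tumor_region("T001", img$tumor_id == 1, "LGD"))
#>   tumor_id phenotype       red_area_fraction n_discrete_clones ...
#> 1 T001     homotypic_green                 0                 1

# 84 heterotypic among 144 tumors at p = 0.376, assuming 3 founders:
tidy(estimate_multiancestral_fraction(x_het = 84, n = 144, p = 0.376, N = 3))
#>   term                    estimate conf.low conf.high
#> 1 multiancestral_fraction    0.829    0.708     0.945
```

This tumor happened to be founded by two green crypts, so it is called
homotypic green — multi-ancestral tumors are under-detected exactly by
the factor `h`, which is what the estimator corrects: a raw heterotypic
fraction of 58% becomes an estimated 83% multi-ancestral fraction under
a three-founder model.

`run_pipeline(pipeline_config(seed = 1))` chains
simulate → binarize → patch size → classify → tabulate → stats and
writes CSV/TIFF/JSON outputs plus a manifest; identical seeds give
bit-identical CSVs.

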