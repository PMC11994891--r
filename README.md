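# satquant

Semi-automated counting of Pax-7 and BrdU positive nuclei in multi-channel
immunofluorescence micrographs of skeletal muscle.

Histological quantification of satellite-cell activity asks three questions
of every section: how many nuclei are there (DAPI), how many carry the
satellite-cell marker Pax-7, how many carry the proliferation label BrdU,
and how many carry both — the newly generated satellite-lineage cells.
Counting these by hand across hundreds of 640 x 480 fields is slow and
observer-dependent. `satquant` replaces it with three fixed, fully
deterministic image-processing chains plus nucleus-gated co-positivity
counting, for muscle biologists who want reproducible counts with a
complete parameter audit trail.

## What it computes

Per channel, a binary object mask via a fixed stage sequence:

| channel | chain |
|---|---|
| DAPI | rolling ball -> 8-bit -> sharpen -> **mean threshold** -> erode -> dilate |
| Pax-7 | Sobel edges -> 8-bit -> min-max normalize -> watershed split -> rolling ball -> **Renyi-entropy threshold** -> close -> outline -> fill holes -> erode -> remove small |
| BrdU | 8-bit -> sharpen -> rolling ball -> kernel smooth -> watershed split -> **Intermodes threshold** -> remove small |

The rolling ball is an exact spherical-cap grayscale opening (background =
the surface traced by a ball rolled beneath the intensity landscape). The
three thresholds are pure functions of the 256-bin histogram: the mean gray
level; the maximizer of the two-class Renyi entropy sum
`H_A(t) + H_B(t)`, `H_A = 1/(1-alpha) ln sum_{i<=t} (P_i/P_A)^alpha`
(orders 0.5, 1, 2 plus their canonical weighted combination); and the
Intermodes midpoint `floor((m1+m2)/2)` after smoothing the histogram to
bimodality. Watershed splitting floods from the bright peaks (h-maxima
suppressed) and zeroes the valley lines between basins so touching nuclei
binarize apart.

Per section, `quantify_section()` reports
`n_nuclei, n_pax7, n_brdu, n_copositive` and the ratios over the nucleus
count, where positives are counted on the intersection of the marker mask
with the DAPI mask (median-filtered for BrdU/DAPI), dilated so fragments
within one nucleus count once. `validate_against_manual()` summarizes
agreement with manual counts by ordinary least squares
(slope, intercept, `R^2 = 1 - SS_res/SS_tot`).

A seeded synthetic-section generator (`generate_scene()`) with exact ground
truth backs the entire test suite; no real micrograph is required.

## Worked example

```r
library(satquant)

# a synthetic 640x480 section: 100 nuclei, 20 Pax-7+, 10 BrdU+, 5 co-positive
sc <- generate_scene(scene_params(), seed = 2)
q  <- quantify_section(sc$dapi, sc$pax7, sc$brdu, section_id = "demo")
q
#> section demo: 100 nuclei | Pax-7+ 20 (0.200) | BrdU+ 10 (0.100) | co-positive 5 (0.050)
q$thresholds
#> dapi pax7 brdu
#>   20   48  126
```

The printed line gives the four counts and the ratios over the nucleus
count: this section's 100 nuclei include 20 Pax-7 positive (ratio 0.200),
10 BrdU positive (0.100) and 5 BrdU/Pax-7 co-positive (0.050) — exactly
the generator's ground truth. `thresholds` records the gray level each
channel was binarized at (mean, Renyi-entropy and Intermodes thresholds
respectively), part of the per-section audit trail along with the config
hash.

Validating automated against manual ratios:

```r
fit <- validate_against_manual(auto = c(1, 2, 3), manual = c(1, 2, 4))
fit
#> validation_fit (n = 3): auto = 0.6429 * manual +0.5000, R^2 = 0.9643
```

A command-line interface wraps the same functions
(`inst/scripts/satquant quantify|batch|simulate|validate|dump-config`),
reading/writing TIFFs, manifest CSVs and JSON configs; batch runs isolate
per-section failures and embed the config hash and package version in
every results row.

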