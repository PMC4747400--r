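---
title: "Methods: quantifying nuclear area and perinuclear chromogen signal in brightfield IHC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying nuclear area and perinuclear chromogen signal in brightfield IHC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcmorph)
```

## Scope and model

`ihcmorph` measures two per-cell quantities from RGB brightfield scans of
hematoxylin-counterstained, DAB-developed immunohistochemistry: the nuclear
cross-sectional area in pixels, used as a surrogate of ploidy (hyperploid
cells carry more DNA and larger nuclei), and the chromogen intensity in a
ring immediately surrounding each nucleus, used as a surrogate of
perinuclear/ER-localized antigen — the motivating application is
phospho-eIF2α, an ER-stress marker that accumulates around the nucleus.

The optical model is ordinary brightfield absorbance. Hematoxylin is a blue
dye whose absorbance is strongest in the red channel, so nuclei are the
darkest structures in the red plane; DAB is a brown chromogen absorbing
most strongly in blue. The pipeline therefore builds two purpose-specific
maps from a scan normalized to $[0,1]$:

$$\mathrm{nuclear} = 1 - L(\mathrm{red}), \qquad
  \mathrm{signal} = 1 - L(\mathrm{blue}), \qquad
  L(x) = \frac{\log(1 + kx)}{\log(1 + k)}.$$

Segmentation runs on the nuclear map only; quantification reads the signal
map only. This pairing is a deliberate design choice: a full stain
deconvolution (Ruifrok-style unmixing with stain-vector estimation) is out
of scope, and the one-channel-per-stain pairing is the simplest physically
motivated separation that keeps each stage auditable.

Two properties of $L$ matter. It fixes the endpoints ($L(0)=0$, $L(1)=1$)
and is strictly increasing, so it is a bijection of $[0,1]$ and threshold
decisions are order-preserved; and it expands contrast at low transmission,
where stained structures live. The bounded inversion $1 - L(x)$ is used
instead of optical density $-\log x$ because 8-bit scans contain saturated
dark pixels where optical density diverges; the two are monotone-equivalent
for thresholding, so nothing is lost for segmentation.

## Tunable parameters

All knobs live in `analysis_config()` and mirror the YAML config and CLI
flags:

| parameter | default | unit | why |
|---|---|---|---|
| `ring_width_px` | 7 | px | width of the perinuclear ring; the reference perinuclear region of interest |
| `threshold_method` | `otsu` | — | parameter-free, standard for bimodal stain/background separation; `fixed` is offered for reproducibility across image batches |
| `min_nucleus_area_px` | 50 | px | debris floor; at 10–16 px nuclear radii, real nuclei are ≥ ~300 px |
| `max_nucleus_area_px` | unset | px | optional cap against stain blots |
| `split_touching` | `TRUE` | — | tissue fields contain abutting nuclei; per-cell readouts need separation |
| `exclude_border` | `TRUE` | — | border-truncated nuclei have censored areas and would bias the area distribution down |
| `log_constant_k` | 255 | — | one display-log unit per 8-bit gray level; exposed because enhancement strength interacts with very faint counterstains |
| `intensity_statistic` | `mean` | — | see below |

The ring is **Euclidean**: background pixels within Euclidean distance
`ring_width_px` of a nucleus, i.e. dilation by a disk structuring element,
chosen over city-block/chessboard for isotropy — a ring should not be wider
along the diagonals. Each ring pixel belongs to its *nearest* nucleus;
whether contested pixels between adjacent cells should be split, merged, or
discarded is genuinely open, and nearest-assignment was chosen because it
is deterministic, partition-like (no double counting of cytoplasm), and
symmetric between neighbours. Equidistant pixels go to the smaller label —
an arbitrary but fixed tie-break that makes the masks a pure function of
the nuclear mask.

Both the per-cell **mean** and the **integrated** (summed) ring signal are
always computed and written. Whether a per-cell "intensity" should be
normalized by ring size is a reporting decision, not a measurement one, so
the choice is a flag rather than silently fixed; the mean is the default
because ring size grows with nuclear perimeter and would otherwise leak
nuclear size into the signal readout.

## Segmentation details and numerical choices

* Thresholded masks are hole-filled before measurement: chromatin texture
  punches holes in the hematoxylin map, but the area surrogate must
  approximate the full nuclear cross-section.
* Touching nuclei are split by watershed on the negated exact Euclidean
  distance transform. Seeds are local maxima of the distance map detected
  within a radius of $\lfloor\sqrt{\texttt{min\_nucleus\_area\_px}}/2\rfloor$
  pixels (half the side of the smallest admissible nucleus), so two seeds
  cannot arise inside one admissible-size object.
* Object labeling is 8-connected — standard for blob-like nuclei — and
  final labels are renumbered contiguously in raster-scan order of each
  object's first pixel, which makes label geometry deterministic and
  reproducible across runs.
* Degenerate inputs are handled as data, not errors: a contrast-free
  (constant) nuclear map or a threshold that selects nothing returns an
  empty mask with a warning, and the downstream stages produce an empty but
  valid record set. An empty group is, however, a contract error for
  summaries and tests, because a mean of nothing is not a number the caller
  should silently receive.
* A cell completely enclosed by neighbours has an empty ring; its
  `perinuclear_mean` is undefined (`NA`), it is excluded from signal
  summaries and tests (the exclusion count is reported), and it still
  contributes its area.
* Ring construction computes one exact per-label distance transform on the
  label's bounding box padded by `ring_width_px + 1`, updating a global
  best-distance raster with strict improvements in ascending label order —
  which realizes the smaller-label tie-break without ever comparing
  floating-point distances for equality. The inversion `log_enhance_inverse`
  recovers channels to within $10^{-9}$; CSV floats are written with 17
  significant digits so a write–parse round trip is bit-exact.
* 0-based (row, col) coordinates throughout;
  `area_um2 = area_px × pixel_size_um²` when a pixel size is supplied,
  otherwise areas stay in pixels — bit depth and pixel size are treated as
  metadata, never assumed.

## What the simulator emulates — and what it does not

`render_scene()` implements Beer–Lambert transmission: each nucleus is an
ellipse (semi-major axis `radius_px`, eccentricity, orientation) filled
with hematoxylin concentration, wrapped in an annular DAB shell of
`ring_thickness_px` (default 5 px); channel $c$ transmits
$I_c = w_c \cdot 10^{-(c_h H_c + c_d D_c)}$ with unit-norm OD vectors $H$
(red-dominant, default $(0.74,0.60,0.30)/\lVert\cdot\rVert$) and $D$
(blue-dominant, $(0.27,0.57,0.78)/\lVert\cdot\rVert$), white level 0.95,
plus seeded additive Gaussian noise (sd 0.02 by default) clipped to
$[0,1]$. Ground truth carries the exact rasterization (pixel-center
inclusion test) of every nucleus, so recovery is measured against counts,
not approximations.

Default concentrations are chosen as a *well-stained slide*: per-cell
hematoxylin in $[0.7, 1.0]$ and DAB in $[0.15, 0.6]$ (an evenly spaced,
randomly permuted grid, so rank-correlation tests see the full dynamic
range). The DAB ceiling is deliberately conservative: DAB also absorbs some
red ($D_1 \approx 0.27$), and a chromogen load approaching the
counterstain's red absorbance would merge shells into nuclei at
segmentation — on glass that is an over-developed slide, and region
pre-selection, not the algorithm, is the remedy. With these defaults the
DAB shell's red OD stays well below hematoxylin's even when a simulated
"hyperploid" population doubles its signal.

`make_population_pair()` encodes the biology being modelled: a genome
doubling scales nuclear areas by `ploidy_ratio` (radii by its square root,
so the pre-rasterization area ratio is exact) and perinuclear signal by
`signal_ratio`, with layout, orientations and counterstain identical
between the two scenes. Placement is rejection sampling under a minimum
center spacing sized for the *scaled* population, so neither scene has
touching or border-truncated cells; a `touching` preset drops the spacing
to exercise watershed splitting.

The simulator does **not** emulate: tissue texture and stromal
architecture, uneven illumination or white-balance drift, out-of-focus
blur, stain co-localization within one compartment, or the
stromal-vs-malignant distinction. Passing its tests therefore demonstrates
that the *measurement chain* is correct (geometry exact, intensities
recovered, groups discriminated), not that segmentation is robust to every
histological artifact; on real sections the region of interest should be
delimited by a pathologist.

## Problem sizes and determinism

The validation suite runs: ring-mask exactness against a brute-force
nearest-nucleus oracle on 100 random masks up to 128×128 (pixel-for-pixel
identity, including the ≤ 7 px extent check on an isolated nucleus);
segmentation and intensity recovery on a 1024×1024 field of 100
well-separated nuclei (radii 10–16 px, noise sd 0.02), requiring ≥ 95%
matches at IoU ≥ 0.7, mean area error < 10% and Spearman ρ ≥ 0.9 against
true DAB concentrations; and a 100-cell parental/hyperploid pair
(`ploidy_ratio = 2`, `signal_ratio = 2`), requiring the measured mean-area
ratio in [1.7, 2.3] and one-tailed p < 0.001 on both readouts. Every
random draw is seeded; rendering, segmentation and the CSV/TIFF writers
are bit-deterministic, and repeated `cmd_analyze`/`cmd_simulate` runs are
byte-identical.

## Known limitations

* One channel per stain is an approximation; heavy chromogen deposits
  bleed into the red channel and can inflate nuclear masks on
  over-developed slides.
* Nuclear area correlates with, but is not identical to, DNA content —
  chromatin compaction varies.
* Watershed splitting assumes roughly convex nuclei; long nuclear chains
  may over-split.
* Stromal and malignant nuclei are measured alike; the tool quantifies, it
  does not classify.
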