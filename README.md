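# ihcmorph

Per-cell morphometry of brightfield immunohistochemistry (IHC) scans:
nuclear area as a surrogate of ploidy, and perinuclear chromogen intensity
as a surrogate of ER stress when the antibody reports phospho-eIF2α.

## The problem and who this is for

In hematoxylin-counterstained, DAB-developed tissue sections, two per-cell
quantities carry biological meaning: the cross-sectional area of each
nucleus (hyperploid cells have larger nuclei) and the intensity of the
chromogen immediately *around* each nucleus (phospho-eIF2α accumulates
perinuclearly at the endoplasmic reticulum). `ihcmorph` automates both
measurements from ordinary RGB TIFF/PNG scans, for pathologists and tumor
immunologists who need cell-by-cell readouts from paraffin sections rather
than bulk averages. Whole-slide containers (VSI) are out of scope — convert
to TIFF upstream.

## The method

For an RGB scan with values normalized to [0, 1]:

1. **Channel maps.** The red and blue planes are extracted and enhanced with
   `L(x) = log(1 + kx) / log(1 + k)` (default `k = 255`). Hematoxylin
   absorbs red light most, DAB absorbs blue most, so
   `nuclear_map = 1 − L(red)` highlights nuclei and
   `signal_map = 1 − L(blue)` highlights chromogen.
2. **Nuclear segmentation.** Otsu threshold on `nuclear_map` (or a fixed
   threshold), hole filling, watershed on the negated Euclidean distance
   transform to split touching nuclei, removal of objects below
   `min_nucleus_area_px` (default 50 px) and of border-truncated nuclei,
   then contiguous relabeling `1..N` (8-connected).
3. **Perinuclear rings.** Each cell's cytoplasmic region of interest is the
   set of background pixels within Euclidean distance `ring_width_px`
   (default **7 pixels**) of its nucleus, every pixel assigned to its
   *nearest* nucleus (ties to the smaller label), so rings never overlap
   nuclei or each other.
4. **Measurement and statistics.** Per cell: nuclear `area_px` (and
   `area_um2` when a pixel size is known), ring pixel count, mean and
   integrated `signal_map` over the ring. Per group: means, SEMs,
   histograms, and one-tailed Student's *t* tests (pooled variance; Welch
   by flag).

A Beer–Lambert simulator (`render_scene()`, `random_scene()`,
`make_population_pair()`) renders hematoxylin-stained elliptical nuclei
with perinuclear DAB shells and full per-cell ground truth, so the whole
pipeline is verifiable without any slide data.

## Worked example

```r
library(ihcmorph)

scn      <- random_scene(n_nuclei = 40, image_size = c(768, 768), seed = 7)
rendered <- render_scene(scn)
res      <- analyze_image(rendered$image)
res
#> IHC morphometry: 40 nuclei segmented
#> Group of 40 cells
#>   nuclear area:      559.02 +/- 19.76 px (mean +/- SEM)
#>   perinuclear mean: 0.0948 +/- 0.0049 (40 cells; 0 excluded)

head(res$records[, c("label", "area_px", "ring_pixels", "perinuclear_mean")], 3)
#>   label area_px ring_pixels perinuclear_mean
#> 1     1     538         691        0.1409236
#> 2     2     519         678        0.1255146
#> 3     3     656         745        0.1183727
```

All 40 simulated nuclei are recovered; `area_px` is each nucleus's pixel
count and `perinuclear_mean` the average inverted-log blue absorbance over
its 7-px ring (higher = more chromogen).

Comparing a simulated genome-doubled ("hyperploid") population against its
parental line:

```r
pp  <- make_population_pair(n_cells = 100, ploidy_ratio = 2,
                            signal_ratio = 2, seed = 1)
par <- analyze_image(render_scene(pp$parental)$image)$records
hyp <- analyze_image(render_scene(pp$hyperploid)$image)$records
compare_groups(hyp, par, "area", "greater")
#> One-tailed Student's t test on area (a greater b)
#>   t = 26.1939, df = 198.00, p = 1.485e-66
#>   mean a = 854.6500 (n = 100), mean b = 416.3200 (n = 100)
mean(hyp$area_px) / mean(par$area_px)
#> [1] 2.052868
```

The measured mean-area ratio (2.05) recovers the simulated ploidy doubling,
and both area and perinuclear signal separate at p ≪ 0.001.

### Command line

```sh
ihcmorph=$(Rscript -e 'cat(system.file("exec", "ihcmorph", package = "ihcmorph"))')
Rscript $ihcmorph simulate --scene well-separated --out sim --seed 4
Rscript $ihcmorph analyze  --image sim/scene.tif --out results
Rscript $ihcmorph compare  --a results/scene_cells.csv --b other/scene_cells.csv
```

`analyze` writes the per-cell CSV, a group-summary JSON, a QC overlay PNG
(nuclear contours green, ring contours magenta) and a run manifest; outputs
are byte-reproducible for fixed inputs and seeds.

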