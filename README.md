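# cfitkmeans

Segmentation and texture-trait analysis of chlorophyll-fluorescence
canopy images, for plant-phenotyping work that needs to separate the
photosynthetically active wheat canopy from the pot and background
before any trait is measured.

Fluorescence captures of potted wheat have three intensity strata: an
exact-zero background, the pot in a narrow low band (roughly 11–17 on
the 8-bit scale, and more exposed under water stress), and the canopy
above it.  A single global threshold handles this badly because the
canopy brightens over a 60-day timeline while the pot band stays put.
The package implements the hybrid **CFitK-means** segmenter:

1. a **dynamic elimination threshold** from a cubic fit over the capture
   sequence index *x*,

   *T(x) = p₁x³ + p₂x² + p₃x + p₄*,

   with p₁ = 2.273e−08, p₂ = −4.118e−05, p₃ = 0.01699, p₄ = 11.95,
   clamped into the 11–17 elimination band; pixels below *T(x)* are
   removed (pot and residual background);
2. **histogram-initialized 2-cluster intensity K-means** on the
   normalized survivors — the seeds are the mean and the minimum of the
   occupied intensity levels above the threshold, so initialization is
   deterministic; the brighter final cluster is the canopy.

Around the segmenter the package provides:

- baseline segmenters (global static threshold, Otsu, 4-centroid
  K-means) and an **IoU** evaluation protocol over mutually exclusive
  random samples;
- the **23-trait GLCM (Haralick) texture panel** (autocorrelation,
  contrast, correlation ×2, cluster prominence/shade, dissimilarity,
  energy, entropy, homogeneity ×2, maximum probability, sum/difference
  statistics and entropies, information measures of correlation,
  normalized inverse differences) computed on the quantized canopy
  region (9 grey levels, offset (0,1), symmetric);
- the trait-analysis layer: correlation-range categorization
  (Pearson/Spearman/Kendall), the Kaiser–Meyer–Olkin sampling-adequacy
  statistic, Bartlett's test of sphericity, and agglomerative clustering
  of the 23 traits under seven linkage rules (nearest, furthest,
  between-groups, within-groups, centroid, median, Ward) on squared
  Euclidean distances, with SPSS-style agglomeration schedules;
- a seeded **synthetic scene generator** (background/pot/canopy with
  ground-truth masks, control vs drought growth trajectories) and a
  block-correlated feature-table generator, so the whole pipeline is
  testable without external imagery.

## Worked example

```r
library(cfitkmeans)

# a drought scene at day 30 with ground truth, then segment it
sc  <- canopy_scene(day = 30, condition = "drought", seed = 7)
fit <- cfitkmeans(sc$image, x = 30, frame = NULL)
fit
#> CFitK-means canopy segmentation
#>   frame: 347 x 260 (w x h), sequence index x = 30
#>   elimination threshold: 12.423 (raw 12.423)
#>   final centroids: 0.0034, 0.1729 (normalized intensity)
#>   K-means iterations: 2 (converged)
#>   canopy pixels: 9991 of 90220 (11.1%)

iou(sc$canopy_mask, fit$mask)
#> [1] 0.9966085

# texture traits of the segmented canopy
fv <- canopy_traits(sc$image, fit$mask)
round(fv[c("contr", "energ", "entro", "homom", "corrm", "maxpr")], 4)
#>  contr  energ  entro  homom  corrm  maxpr
#> 0.1540 0.7269 0.9271 0.9256 0.0039 0.8488

# trait statistics on a block-correlated table (three planted families)
tab <- make_feature_table(200, within_r = 0.9, between_r = 0, seed = 7)
round(as.numeric(kmo(tab)), 3)
#> [1] 0.965
bartlett_sphericity(tab)
#> Bartlett's test of sphericity: chi2 = 7987.474, df = 253, p = 0
head(compare_linkages(tab, k = 3), 4)
#>   variable between within centroid furthest median nearest ward
#> 1    autoc       1      1        1        1      1       1    1
#> 2    contr       1      1        1        1      1       1    1
#> 3    corrm       1      1        1        1      1       1    1
#> 4    corrp       1      1        1        1      1       1    1
```

The worked numbers read as follows: at sequence index 30 the cubic gives
an elimination threshold of 12.4, inside the 11–17 band; the recovered
canopy overlaps the ground truth at IoU 0.997; the high KMO (0.965) and
the enormous Bartlett χ² say the planted trait table is dominated by
shared variance; and all seven linkage rules assign the traits to the
same three clusters.

End-to-end runs go through `run_pipeline()` (simulate or load a
manifest, segment, extract features, evaluate, analyse); a thin shell
wrapper lives at `inst/scripts/run_pipeline.R`.

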