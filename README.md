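# chorovol

Quantification of the choroidal vasculature in volumetric OCT scans.

The choroid — the vascular bed between retina and sclera — dilates in
pachychoroid disease (central serous chorioretinopathy, CSC) and swells
stromally in autoimmune uveitis (Vogt–Koyanagi–Harada disease /
sympathetic ophthalmia, VKH/SO). `chorovol` turns a single swept-source
OCT volume into three diagnostic metrics, measured in the central 6-mm
ETDRS circle:

* **choroidal volume** `Vc` — slab voxels between Bruch's membrane (BM)
  and the choroidal–scleral interface (CSI), times the voxel volume;
* **vessel volume** `Vv` — segmented vessel voxels times the voxel
  volume;
* **vessel index** `VI = 100 · Vv / Vc` (%), which falls in VKH/SO where
  stroma grows faster than vessels.

The pipeline: enhancement (3-D median despeckling → per-A-line shadow
reduction → depth attenuation compensation `I/(2·Σ_{z'≥z} I)` → log
CLAHE), BM-flattening and slab extraction, then a composite pixel-based
3-D segmentation of the hyporeflective vessel lumens — Niblack local
thresholding `T = m + k·s` in the B-scan and C-scan views plus a global
Otsu threshold, fused by majority vote with small-component cleanup.
En-face vessel/choroid volume maps, ETDRS regional tables, rendered
colormaps, and a binormal/Monte-Carlo ROC toolkit for cohort summary
statistics complete the workflow. Synthetic layered phantoms with exact
vessel ground truth (`π r² L` for straight tubes) support validation.

## Worked example

Segment the standard validation phantom (3 × 6 mm patch, 0.5 mm-thick
choroid, six vessels of radius 0.05–0.2 mm, 4-look speckle, two
retinal-vessel shadows, attenuation 0.5 mm⁻¹) and quantify it:

```r
library(chorovol)
ph  <- make_phantom(standard_phantom_spec(seed = 1))
enh <- enhance_pipeline(ph$volume)
seg <- segment_choroid(enh, ph$surfaces)
dice(seg$vessel, ph$vessel_truth)
#> 0.91
vmap <- vessel_volume_map(seg$vessel)
cmap <- choroid_volume_map(ph$surfaces, ph$volume$spacing)
region_metrics(vmap, cmap, etdrs_grid(diameters = c(1, 2, 3)))
#> # A tibble: 10 × 4
#>    region         Vc_mm3  Vv_mm3 VI_percent
#>    <chr>           <dbl>   <dbl>      <dbl>
#>  1 central         0.396 0.0550      13.9
#>  2 inner_superior  0.289 0.0334      11.6
#>  3 inner_inferior  0.289 0.0396      13.7
#>  4 inner_nasal     0.301 0.00347      1.15
#>  5 inner_temporal  0.301 0.0389      12.9
#>  6 outer_superior  0.483 0.0487      10.1
#>  7 outer_inferior  0.483 0.0448       9.26
#>  8 outer_nasal     0.494 0.118       23.9
#>  9 outer_temporal  0.494 0.00334      0.677
#> 10 circle_6mm      3.53  0.385       10.9
```

The Dice overlap against ground truth is 0.91 and the recovered total
vessel volume (0.385 mm³ in this 1.5-mm-radius grid; 1.05 mm³ over the
whole map) sits within 15% of the analytic `Σ π r² L = 0.947` mm³. The
`VI_percent` column is the regional vessel index; `outer_nasal` is high
here because the thickest phantom vessel drifts through that sector.

Diagnostic statistics from bundled cohort summaries (group mean ± SE
and n of each metric for healthy, CSC and VKH/SO eyes):

```r
cs  <- reference_cohorts()
sim <- simulate_cohorts(cs[cs$label == "CSC"     & cs$metric == "vessel_volume", ],
                        cs[cs$label == "healthy" & cs$metric == "vessel_volume", ],
                        n_reps = 10000, seed = 7, cutoff = 4.14)
sim
#> <cohort_sim> 10000 replicates; mean AUC = 0.8193 (closed form 0.8196)
#>   at cutoff 4.14: sens 65.58%, spec 84.27%
```

So a vessel volume above 4.14 mm³ separates CSC from healthy eyes with
AUC ≈ 0.82 and specificity ≈ 84% under the binormal completion of the
group summaries. `glance()`/`tidy()` return the same numbers as tibbles;
`autoplot()` draws ROC curves and en-face maps.

A command-line interface wraps the same functions
(`inst/cli/chorovol.R`; subcommands `phantom`, `enhance`, `slab`,
`segment`, `quantify`, `roc`, `run`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/chorovol.R", package = "chorovol"))')" \
  roc --cutoff 4.14 --reps 10000 --seed 7 --out roc.json
```

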