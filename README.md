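# cssi3d

Label-free segmentation of concave (cup-like) cell nuclei in 3D
refractive-index (RI) tomograms, with phantom-based validation, 3D
morphometry, population statistics and Fourier-coverage analysis of
tomographic acquisition geometries.

## Who this is for

Holographic tomography of suspended cells yields a 3D RI voxel grid per
cell. In NPM1-mutated acute myeloid leukaemia the nucleus is often
cup-shaped, and that concavity is a morphological biomarker — but it is
exactly what threshold-based segmentations miss and convex-closing
segmentations destroy. `cssi3d` is for quantitative-phase-imaging groups
who need a stain-free volumetric nucleus segmentation that *preserves*
concavities, plus the downstream shape/biophysical features to use it.

## The method

The nucleus has lower RI than the cytoplasm but the contrast is weak and
noisy, so single-voxel classification fails. CSSI (computational
segmentation by statistical inference) instead classifies small voxel
*sub-cubes*: every cube inside the cell is compared with a reference sample
known to lie in the nucleus by a two-sided rank-sum test, and cubes whose
distribution is statistically indistinguishable (p ≥ α) are accepted; the
reference is re-estimated from the most similar accepted cubes and the
selection iterated to stability. The concave variant then closes the
accepted set *locally*: outlier cubes are dropped, and each pair of cubes
whose centres lie within a connection radius is joined by the convex hull
of the pair. Concavities wider than the connection radius are never
bridged — unlike the global convex hull of the original (convex) algorithm,
which is kept as a baseline (`mode = "convex"`).

Morphometry implements the nine-feature panel: dry-mass density
ρ = (n̄ − n₀)/α (α = 0.19 mL/g), nucleus/cell volume and surface ratios,
normalized nucleus–cell centroid distance d/R with R = (3V/4π)^⅓,
convexity index V/V_hull, normalized concavity radius, and sphericity index
π^⅓(6V)^⅔/S, with surfaces measured on a marching-tetrahedra isosurface
mesh. Population discrimination ranks features by Fisher's discriminant
ratio (μ₂−μ₃)²/(σ₂²+σ₃²) with two-sample t-tests. The OTF module builds
the Fourier support of sample-rotation versus illumination-scanning
tomography from the Ewald-cap construction and reports per-axis cutoffs,
resolution ratios and support volumes.

## Worked example

```r
library(cssi3d)

# a 64^3 cup phantom: nucleus carved to sphericity 0.85
spec <- phantomSpec(gridShape = 64, pitch = 0.18, cellRadius = 4.4,
                    nucleusRadius = 2.6, indenterRadius = 2.0,
                    targetSphericity = 0.85, seed = 21)
bundle <- generatePhantom(spec)
bundle@achievedSphericity
#> [1] 0.8506

nucleus <- segmentNucleus(bundle@tomogram, "concave", cssiConfig(seed = 3))
f1Score(nucleus, bundle@nucleusMask)$f1
#> [1] 0.9191
sphericityIndex(nucleus)
#> [1] 0.8955
convexityIndex(nucleus)
#> [1] 0.9339

# the convex baseline fills the cup: sphericity is overestimated
hull <- segmentNucleus(bundle@tomogram, "convex", cssiConfig(seed = 3))
sphericityIndex(hull)
#> [1] 0.9548
```

The concave mode recovers the cup (estimated sphericity 0.90 against a
simulated 0.85, voxelwise F1 0.92 on a 14-voxel-radius nucleus), while the
convex baseline reports a nearly spherical nucleus. Feature extraction for
a cohort is one call per cell:

```r
feats <- featureRecord(bundle@tomogram, makeCellMask(bundle@tomogram), nucleus)
writeFeatureTable(feats, "features.csv")
```

OTF comparison of the two acquisition geometries:

```r
otfCutoffs(otfConfig(mode = "rotation"))
#>  cutoff_x  cutoff_y  cutoff_z  resolution_ratio
#>     2.444     3.123     3.123             0.782
```

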