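# splenvas

Serial-section 3D reconstruction of splenic red pulp microvasculature, as a
tested and reusable R pipeline.

Sheathed capillaries — post-arteriolar vessels wrapped by CD271⁺ stromal
cuffs and B cells — can only be understood in 3D: single sections cannot
show that one sheath covers up to four sequential bifurcations, that the
central capillary releases open-ended side branches crossing the sheath, or
that bypass capillaries connect arterioles to the cord network without a
sheath. `splenvas` rebuilds such microanatomy from stacks of triple-stained
serial brightfield sections (SMA brown + CD34 blue on every section, CD271
or CD20 red on alternating sections; 0.5 µm/pixel, 7 µm thick) and ships a
synthetic phantom generator with known vascular ground truth so that every
stage is verifiable without scanned data.

The pipeline: Reinhard color normalization → sparse stack-global rigid
registration on the σ=6-blurred deconvolved CD34 channel → Beer–Lambert
color deconvolution (OD = −log₁₀((I+1)/256), densities = OD·M⁻¹) and 8-bit
channel intensities → optical-flow z-interpolation (7→1 µm for SMA/CD34,
14→2 µm for CD271) → channel-specific grayscale morphology (e.g. CD34:
closing r=7, Gaussian σ=1) → crack-free marching-cubes iso-surfaces (iso
100/160) → watertight octree repair (depths 9/7/8) → Taubin smoothing,
small-component removal (2 %/5 %/10 % of the main diagonal), quadric
decimation (10 %/50 %) → SMA-proximity painting of the CD34 mesh (strictly
< 8.75 µm) → B-cell pruning (< 10 µm diameter) → ground-truth recovery
scoring, including the entry-to-exit surface geodesic of a designed
> 300 µm sheathed path.

## Worked example

```r
library(splenvas)

man <- runPipeline(defaultPipelineConfig(seed = 1L), verbose = TRUE)
man@outputs$report
#> RecoveryReport
#>   sheath detection:       1.00
#>   side-branch detection:  1.00
#>   bypass capillaries:     3 / 3
#>   venule contacts:        2 / 2
#>   geodesic entry-to-exit: measured 333.4 um vs true 338.6 um
```

The report reads: every ground-truth capillary sheath and every open-ended
side branch was recovered in the reconstructed meshes, the three bypass
capillaries and both capillary-venule contacts were found, and the designed
four-bifurcation sheathed path measured 333.4 µm entry-to-exit on the final
CD34 mesh against a ground-truth surface geodesic of 338.6 µm (−1.5 %).
`man@outputs$paint@mesh` holds the painted capillary mesh (about 150k
vertices at desk scale, white where arteriolar wall is near, blue
elsewhere).
Meshes are exportable as PLY (with per-vertex paint colors), OBJ and STL;
`writeSectionStack()`/`writeGroundTruth()` persist the phantom itself. A
thin CLI lives at `inst/cli/splenvas.R`
(`Rscript splenvas.R run --seed 1 --outdir out`).

Bookkeeping helpers reproduce the region-of-interest accounting of a full
study: `computeRoiVolume(83, 7, 2000, 0.5)` → `0.58` mm³ and
`cropAccounting(150, 84)` → `44` percent of a cut series cropped.

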