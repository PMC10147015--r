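# MicrogliaMorph

Unbiased single-cell morphometry of microglia in 3D confocal z-stacks.

Microglia report the state of their tissue through shape: compact
**ameboid** cells with few short processes mark phagocytic/pro-inflammatory
activation, the classically ramified **surveillance** form marks the
resting state, and bushy **hyper-ramified** cells appear under chronic
stimulation. MicrogliaMorph turns two-channel z-stacks (a
membrane/cytoskeletal marker such as Iba1 plus a nuclear stain such as
DAPI) into per-cell shape statistics and nonparametric group comparisons,
replacing a proprietary point-and-click reconstruction workflow with a
scriptable, seeded, bit-reproducible pipeline.

Per cell, the pipeline computes

* total filament (process) length (µm) and filament volume (µm³, conical
  frusta over intensity-fitted radii plus the soma body),
* the Sholl intersection profile and sum (shells every 1 µm centered on
  the soma; spherical by default, with a projected-2D mode for the
  classical flattened-circle convention),
* convex hull volume and area (the cell's territory) and the hull-derived
  sphericity `Ψ = π^{1/3} (6V)^{2/3} / A` (1 for a sphere).

The reconstruction chain mirrors the established filament workflow:
soma detection on a DAPI×Iba1 colocalization channel, nucleus-in-stack QC,
process seed detection, intensity-weighted geodesic tracing ("autopath"),
removal of branches bridged across over-long dim gaps, FWHM diameter
fitting, soma volume import, debris-surface masking (small+bright+round
deposits, stacked filters), a 10th-percentile union QC filter, and
Mann-Whitney / Kruskal-Wallis + Dunn-Bonferroni / Kolmogorov-Smirnov
statistics per cell and per animal.

A built-in parametric scene generator renders branching cells of the four
morphological states into realistic two-channel stacks (PSF blur, Poisson
and Gaussian noise, 16-bit quantization, saturating antibody-deposit
debris) together with their exact skeletons and analytic reference
metrics, so every stage of the pipeline is validated against ground truth.

## Worked example

Simulate one field, trace it, and measure the cell:

```r
library(MicrogliaMorph)

scene <- SceneSpec(fieldXYUm = 62, nSlices = 26, voxelXYUm = 0.25,
                   voxelZUm = 0.8, nCells = 1,
                   noiseGaussianSd = 0, noisePoissonScale = 0, seed = 11)
sim <- rasterizeScene(scene, list(morphologyPreset("transitional")),
                      centers = matrix(c(31, 31, 10.4), 1))
sim$stack
#> ImageStack: 26 x 248 x 248 (z,y,x), 2 channel(s): iba1, dapi;
#>   voxel 0.8 x 0.25 x 0.25 um; 16-bit

iba  <- getChannel(sim$stack, "iba1")
dapi <- getChannel(sim$stack, "dapi")
vs   <- voxelSize(sim$stack)
params <- TraceParams(startingDiameterUm = 10, seedDiameterUm = 1.2)

coloc  <- colocalizationChannel(dapi, iba)
starts <- filterByNucleus(detectStartingPoints(coloc, params, vs),
                          dapi, 0.3, vs)
seeds  <- detectSeedPoints(iba, params, starts, vs)
g <- traceFilaments(iba, starts, seeds, params, vs)[[1]]
g <- removeDisconnectedSegments(g, iba, voxelSize = vs)
g <- fitDiameters(g, iba, vs)
g <- importSomas(list(g), coloc, 0.35, vs)[[1]]

measureCell(g)
#> CellMetrics 'cell01': length 66.6 um, volume 694 um^3, Sholl sum 58,
#>   hull 737 um^3, sphericity 0.612

analyticMetrics(sim$truth@graphs[[1]])   # the generated ground truth
#> CellMetrics 'cell01': length 65.6 um, volume 626 um^3, Sholl sum 56,
#>   hull 874 um^3, sphericity 0.673
```

Traced length and Sholl sum sit within a few percent of the exact
skeleton — the accuracy the test suite demands over 50 such scenes.
Volume and hull differ somewhat more because the traced soma body is
measured from the colocalization image rather than taken from the
generator's parameters.

A full two-group study (ameboid vs surveillance presets, 3 animals per
group, 16 cells per animal) runs end to end with one call and writes every
artifact (scene TIFFs, SWC skeletons, tidy CSV tables, a JSON statistics
report, the effective config and a log) into the output directory:

```r
res <- runPipeline(defaultConfig(list(seed = 1, output_dir = "study")))
res$stats[, c("statistic", "p_value", "metric")]
#>    statistic      p_value             metric
#> 1   0.000000 3.312249e-13    total_length_um
#> 2   0.000000 3.147981e-13          sholl_sum
#> 3 1213.00000 1.659338e-10         sphericity
#> 4  27.000000 3.026229e-12    hull_volume_um3
#> 5   0.273206 0.000000e+00 sholl_distribution
```

The ameboid group shows lower total length (31.5 vs 99.3 µm), lower Sholl
sum (28.1 vs 76.1), smaller hull volume (346 vs 1068 µm³) and higher
sphericity (0.80 vs 0.66) — the canonical compact-versus-ramified
signature, each at p far below 0.05.

A thin command-line front-end is included:

```sh
Rscript inst/scripts/mgmorph.R config > my_config.yaml   # template
Rscript inst/scripts/mgmorph.R run --config my_config.yaml --seed 1 --out study
```

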