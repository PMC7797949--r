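# EVcoloc

Single-vesicle multi-channel co-localization profiling of extracellular
vesicles (EVs).

EVs imaged by multi-channel TIRF microscopy appear as diffraction-limited
spots in every channel whose marker (e.g. the tetraspanins CD9, CD63,
CD81) they carry. EVcoloc turns such images into subpopulation profiles:

* **simulate** — synthetic fields (and fiducial-bead calibration fields)
  with known ground truth: pixel-integrated Gaussian PSF, per-channel
  affine chromatic distortion, EMCCD-style Poisson + read noise;
* **localize** — spot detection and sub-pixel centring by integrated
  2D Gaussian fitting (`localizeSpots()`);
* **register** — bead-based estimation of per-channel transforms into a
  common reference frame (`calibrateChannels()`, `applyTransform()`);
* **colocalize** — cross-channel matching of corrected spot centres
  within 3 px (≈ 300 nm at 100 nm/px) and classification into the
  2^K − 1 marker-combination classes — 7 classes for 3 markers
  (`matchChannels()`);
* **profile** — per-sample fraction vectors with replicate mean ± SD,
  Venn overlap counts, two-tailed t-tests, linear regression, Euclidean
  hierarchical clustering and t-SNE (`buildProfile()`, `vennCounts()`,
  `compareGroups()`, `distanceCluster()`, `embedTsne()`);
* **io / pipeline** — 16-bit TIFF and CSV/JSON round-trips, YAML/JSON run
  configuration, an end-to-end driver (`runPipeline()`) with
  deterministic, logged runs, and a thin CLI (`inst/cli/evcoloc.R`).

Everything stochastic takes a seed and is reproducible byte-for-byte.
Because the simulator and the fitter share one forward model, each stage
is validated against ground truth, closed-form expectations or
brute-force oracles in the test suite.

## Worked example

Simulate a two-field sample with a known tetraspanin composition and a
chromatic shift on two channels, then recover the profile:

```r
library(EVcoloc)

channels <- c("CD9", "CD63", "CD81")
params <- acquisitionParams(
    fieldShape = c(256L, 256L),
    channelTransforms = list(CD63 = translationTransform(1.5, 0),
                             CD81 = translationTransform(-0.9, 1.2)))
spec <- hek293Spec(nVesicles = 60, meanBrightness = 1.2)

# channel registration from simulated bead fields
beads <- renderBeadFields(12, params, channels, seed = 99)
transforms <- calibrateChannels(beads$images)
transforms$CD63
#> ChannelTransform (affine)
#>   A = [ 0.999943 -0.000036;  0.000008  0.999946]  b = (-1.4820,  0.0063)
#>   fitted on 12 control points, RMS residual 0.01934 px

# localize -> correct -> match, per field
fields <- simulateSample(spec, params, nFields = 2, seed = 7)
vesicles <- lapply(fields, function(f) {
    spots <- lapply(channels, function(ch)
        applyTransform(localizeSpots(f$images[[ch]], detectionParams(), ch),
                       transforms[[ch]]))
    matchChannels(setNames(spots, channels))
})
vesicles[[1]]
#> VesicleSet: 59 records from 82 spots in 3 channels (CD9, CD63, CD81)
#>   CD63             26
#>   CD81             4
#>   CD9              9
#>   CD9∙CD63       2
#>   CD9∙CD63∙CD81 3
#>   CD9∙CD81       15

profile <- buildProfile(vesicles, "demo")
round(classFractions(profile), 3)
#>           CD9          CD63          CD81      CD9∙CD63      CD9∙CD81
#>         0.137         0.367         0.060         0.060         0.325
#>     CD63∙CD81 CD9∙CD63∙CD81
#>         0.000         0.051

colocalizationFraction(vesicles[[1]])
#> $recordFraction
#> [1] 0.3389831
#>
#> $signalFraction
#> [1] 0.5243902
```

The same chain runs from a YAML configuration via `runPipeline()`, or
from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli","evcoloc.R",package="EVcoloc"))')
Rscript "$CLI" simulate --config run.yaml     # write a synthetic dataset
Rscript "$CLI" run      --config run.yaml     # register -> detect -> match -> profile
```

Stage-wise subcommands (`register`, `detect`, `colocalize`, `profile`,
`compare`) exchange artifacts through `transforms.json` / `spots.csv` /
`records.csv`.

## Testing

```sh
R CMD INSTALL .
Rscript -e 'testthat::test_dir("tests/testthat", package = "EVcoloc",
                               load_package = "installed")'
```

The suite includes per-module tests and an acceptance file
(`tests/testthat/test-acceptance.R`) covering, among others: exact
seven-class coverage, ~100% signal-level co-localization of simulated
triple-labelled calibration particles after bead registration, end-to-end
recovery of generating class fractions within ±0.03, sub-0.3 px
registration residuals, agreement of greedy matching with an exhaustive
oracle, chance co-localization against the Poisson closed form
1 − exp(−λπr²), t-test/R² null calibration, and the detector
false-positive bound on noise-only fields.

## Documentation

The methods vignette
(`vignettes/single-vesicle-colocalization.Rmd`) documents the image
model, coordinate conventions, parameter defaults and their rationale,
the simulator's realism limits, and the declared design decisions
(matching semantics, denominators, registration direction, statistics).
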