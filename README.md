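# phageNucProfiler

Quantifying where fluorescently tagged proteins sit relative to the
**phage nucleus** — the proteinaceous, nucleus-like shell that jumbo
phages (ΦKZ, ΦPA3, 201Φ2–1) assemble at midcell in infected rod-shaped
*Pseudomonas* cells. The shell encloses the replicating phage DNA
(a bright, circular, central DAPI focus) and excludes most cytoplasmic
proteins while selectively importing others; deciding *imported vs
excluded*, per cell and per population, is the core measurement this
package automates.

For microscopists and phage biologists it provides, as composable R
functions behind S4 classes:

* **Axial intensity profiles** — each infected cell is bisected along
  its long axis and the reporter intensity I(s) is resampled onto
  s ∈ [0, 1] (normalization by cell length) and divided by the intensity
  at the initial measured end, Î(s) = I(s)/I(0⁺), so profiles are
  gain- and size-invariant. Per-cell tracings and the positionwise mean
  ± sd per condition mirror the standard presentation.
* **Phenotype calls** — score = mean Î over the central 20% of the cell
  divided by the mean over the two pooled end windows;
  score ≥ 1.2 → nucleus-imported, ≤ 0.8 → nucleus-excluded, otherwise
  mixed/ambiguous. `populationFractions()` turns calls into statements
  like "100% excluded (n = 177)".
* **DAPI nucleus quantification** — Otsu's threshold
  (σ²ᵇ(t) = ω₀ω₁(µ₀−µ₁)², maximized exhaustively) applied to the
  in-cell DNA channel gives the nucleus mask; the raw in-mask mean and
  the complementary-mask background are reported per cell, and
  `compareGroups()` gives the percent difference of group means with a
  shared histogram.
* **A synthetic micrograph generator** — seeded, deterministic scenes of
  spherocylindrical cells (~1 µm × 2–5 µm at 65 nm/px) with a midcell
  nucleus disk, Gaussian PSF, and Poisson + Gaussian camera noise, plus
  pixel-level ground truth (masks, axes, labels). Every pipeline stage
  is validated against this ground truth; real micrographs can enter
  through `roisFromLabels()` label images instead.

## Worked example

Simulate a 40-cell infected population, half with a nucleus-imported
reporter (contrast 3) and half excluded (contrast 0.2), then run the
full pipeline — render, segment, flag infected cells, profile, classify,
quantify nuclei:

```r
library(phageNucProfiler)

report <- runPipeline(runConfig(seed = 1, scene = list(
  n = 40, phenotypeMix = c(imported = 0.5, excluded = 0.5))))
report
#> phageNucProfiler run (v0.1.0): 40 generated, 40 detected, 40 processed, 0 skipped
#>   phenotype fractions (n = 40): imported 47.5%, excluded 52.5%, mixed 0.0%

head(report$calls, 4)
#>   cellId     score     call
#> 1      1 0.3724784 excluded
#> 2      2 0.3579649 excluded
#> 3      3 0.3683039 excluded
#> 4      4 2.6172629 imported
```

The detected fractions (47.5% / 52.5%) are exactly the realized label
counts of the seeded mixture — every cell is recovered and correctly
called. The score column is the center/ends intensity ratio: ≈ 0.37 for
excluded cells (central trough), ≈ 2.6 for imported ones (central peak).
Per-cell nucleus quantifications are in `report$quants`; comparing two
halves of the same population gives the expected null difference:

```r
compareGroups(report$quants[1:20], report$quants[21:40])
#> GroupComparison: A (n=20, mean 5630.8) vs B (n=20, mean 5650.0): -0.3% difference
```

`plotProfiles(report$profiles)` draws the per-cell tracings with the
average curve; `plotDapiHistogram()` draws the two-group intensity
histogram. A thin command-line wrapper with subcommands
(`synth`, `segment`, `profile`, `dapi-quant`, `run`, `accept`) is
installed at `inst/scripts/phagenucprofiler`.

See the vignette (`vignettes/phage-nucleus-profiling.Rmd`) for the image
model, parameter defaults and units, numerical conventions (Otsu
binning and tie-breaks, axis orientation, anchor window), calibration of
the infected-cell criteria, and known limitations.

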