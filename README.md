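# oxiring

Automated retinal oximetry analysis of dual-wavelength pseudocolor exports.

Retinal oximeters (e.g. the Oxymap T1 on a fundus camera) image the retina
at an oxygen-sensitive and an oxygen-insensitive wavelength and export a
fundus photograph whose vessel pixels are pseudocolored by oxygen
saturation (SatO₂). The clinical quantities — arteriolar SatO₂, venular
SatO₂ and the arterio-venous saturation difference AVSD = SatO₂(a) −
SatO₂(v) — are traditionally read inside an optic-disc-centered ring by
manually outlining the disc and marking every vessel. `oxiring` automates
that protocol end to end, for ophthalmic image-analysis researchers and for
anyone validating automated against manual oximetry readings.

## Method

1. **Optic-disc segmentation** — a three-parameter *active disc* (two
   concentric circles, radii R and R/√2, center (x_c, y_c)) minimizes the
   normalized contrast energy

   E = (E₁ − 2E₂) / R²,

   where E₁, E₂ are the image integrals over the outer and inner discs.
   For a bright disc of radius ρ the minimum is E = −π/2 at R = √2ρ, so
   the inner circle delineates the disc and the reported OD radius is
   R/√2. Minimization is gradient descent with monotone (step-halved)
   energies; the gradients are Green's-theorem contour integrals, e.g.
   ∂E/∂R = (1/R)(∮f(X₁,Y₁)dt − ∮f(X₂,Y₂)dt − 2E). Initialization is
   automatic, by normalized cross-correlation against bright-disc
   templates over a radius grid.
2. **Ring ROI** — the annulus between radii (50 + R) and 2(50 + R) pixels
   (1 px = 9 µm) concentric with the disc, split into supero-temporal,
   supero-nasal, infero-nasal and infero-temporal quadrants; temporal/nasal
   assignment follows eye laterality.
3. **Pseudocolor inversion** — per-pixel SatO₂ by the four published
   color-band conditions (e.g. r = 255, g ≠ 255, b = 0 → SatO₂ = 100 −
   0.1g); pixels matching no condition (background, optic disc, any gray)
   are undefined and excluded.
4. **Bimodal histogram analysis** — a least-squares polynomial of order
   twelve is fitted to the SatO₂ histogram of each region; its two dominant
   peaks are the venular (lower) and arteriolar (higher) modes, and AVSD is
   their difference. Mode-based estimates are insensitive to extreme
   values.
5. **Validation statistics** — ICC(2,1)/ICC(2,k) with exact 95% CIs and
   Bland-Altman bias / limits of agreement for paired manual-vs-algorithm
   readings.

A ground-truthed synthetic scene generator (`make_oximetry_scene()`)
renders decode-exact test scenes, so the whole pipeline is testable without
patient data.

## Worked example

```r
library(oxiring)

scene  <- make_oximetry_scene(scene_ground_truth(seed = 1))
report <- run_pipeline(scene$image, pipeline_config(laterality = "right"))
print(report)
#> Oximetry report (right eye), ring 110.0 - 220.0 px:
#>   region  n_pixels   venular arteriolar      AVSD
#>   ring       8802      58.0      92.4      34.4
#>   ST         2201      58.0      92.4      34.4
#>   SN         2198      58.1      92.4      34.3
#>   IN         2201      58.0      92.4      34.4
#>   IT         2202      57.9      92.4      34.5
print(report$fit)
#> Active-disc fit: center (255.99, 256.00), OD radius 59.98 px (scale R = 84.82)
#>   energy -219.51629 after 2 iterations (converged)
```

The scene encodes arterioles at 92.2% and venules at 57.9% SatO₂ (the
healthy-population means annotated on the pseudocolor map) with 1.5%
per-pixel jitter around a 60 px disc; the pipeline recovers the disc to
0.02 px / 0.03% and both modes to within 0.2%, in every quadrant. Reports
serialize with `write_oximetry_report(report, "report.json", "report.csv")`.

Agreement between paired readings:

```r
set.seed(7)
truth <- rnorm(44, 90, 5)
pr <- paired_readings(1:44, truth + rnorm(44, 0, 2), truth + rnorm(44, 0, 2),
                      "arteriolar")
print(icc(pr))
#> ICC, two-way random, absolute agreement (ICC(2,1) / ICC(2,k)) (n = 44, k = 2)
#>   single  0.882 (95% CI: 0.795 to 0.934)
#>   average 0.938 (95% CI: 0.886 to 0.966)
print(bland_altman(pr))
#> Bland-Altman (n = 44): bias -0.156, LoA [-5.206, 4.894], 3 outside
```

A thin command-line wrapper ships in `inst/scripts/oxiring.R`
(`run`, `synth`, `agree` subcommands; exit codes documented in the script
header), e.g.

```sh
Rscript inst/scripts/oxiring.R synth --seed 1 --out scene.png
Rscript inst/scripts/oxiring.R run --image scene.png --eye right --out report.json
```

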