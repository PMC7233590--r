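---
title: "Methods: automated ring-protocol retinal oximetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated ring-protocol retinal oximetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxiring)
```

## The measurement problem

Dual-wavelength retinal oximeters estimate per-pixel oxygen saturation
(SatO~2~) along retinal vessels and export the result as a pseudocolored
fundus image. The clinical protocol measures arteriolar SatO~2~, venular
SatO~2~ and their difference (AVSD) inside an annulus concentric with the
optic disc (OD), because the large vessels crossing that ring have stable
saturation. Done by hand this requires outlining the OD, delineating the
ring, and marking every vessel — slow and subjective. `oxiring` automates
the chain: OD segmentation, ring extraction, pseudocolor inversion, and
bimodal histogram analysis.

## Active-disc segmentation of the optic disc

The OD is modelled by an *active disc*: two concentric circles with unit
radii $1$ and $1/\sqrt 2$, scaled by $R$ and translated to $(x_c, y_c)$ —
three degrees of freedom. Writing $E_1$ and $E_2$ for the image integrals
over the outer and inner discs, the energy is the normalized contrast

$$E = \frac{E_1 - 2E_2}{R^2},$$

i.e. (annulus mean − inner mean) scaled by area: the annulus and the inner
disc have equal area $\pi R^2/2$, so a uniform image has $E = 0$, and a
bright disc on a dark background drives $E$ negative as the inner circle
locks onto it. For a unit-contrast disc of radius $\rho$ the minimum has
the closed form $E = -\pi/2$ at $R = \sqrt2\,\rho$, which is why the
**inner** circle is reported as the OD boundary and the OD radius is
$R/\sqrt2$. The test suite checks this closed form at $\rho = 120$ px; the
radius is chosen that large because a pixelated hard edge biases the
quadrature energy by roughly $0.8/\rho$.

Gradients are contour integrals obtained from Green's theorem:

$$\frac{\partial E}{\partial R} = \frac1R\Big(\oint f(X_1, Y_1)\,dt -
\oint f(X_2, Y_2)\,dt - 2E\Big), \qquad
\frac{\partial E}{\partial x_c} = \frac1R\oint\big[f(X_1, Y_1) -
\sqrt2 f(X_2, Y_2)\big]\cos t\,dt,$$

with $\sin t$ in place of $\cos t$ for $y_c$. Descent steps follow the
normalized gradient with separate step lengths for scale (0.5 px) and
translation (1 px); a step that would raise the energy is halved, so the
accepted energy sequence is non-increasing by construction. Iteration stops
when $|\Delta E| < 10^{-6}|E|$ or after 200 iterations; the scale is
clamped to $[20, \min(\text{dims})/4]$ px and a fit pinned at the clamp is
flagged non-converged.

### Numerical design

The decisive correctness check is that each analytic gradient component
matches a central finite difference of the energy to relative error
$10^{-3}$ on smooth images. That requirement drives three choices:

* the cumulative field $F(x, y) = \int^x f$ is the *exact* per-row
  trapezoid antiderivative (quadratic in $x$ within a pixel cell),
  interpolated across rows with a Catmull–Rom cubic, making $F$ a $C^1$
  function of position — and hence the energy a smooth function of the disc
  parameters;
* the gradient samples $f$ as the exact $x$-derivative of that same field,
  so the translation gradient in $x$ is the exact derivative of the
  discretized energy, and the remaining components agree with finite
  differences through the continuum Green identity;
* the energy line integral uses an angular grid 8× finer than the gradient
  (`energy_oversample`), because the quadrature error of the energy — not
  of the gradient — is what finite differences amplify.

With 720 contour samples the worst-case disagreement over a 20-image
ensemble of Gaussian-blurred ($\sigma = 3$ px) noise fields is
$1.6\times10^{-4}$; at 360 samples individual cases reached
$1.3\times10^{-3}$, which is why 720 is the default.

Initialization is automatic: a bright disc (radius $r$) on a dark surround
padded to $2.5r$ is matched by FFT-based normalized cross-correlation over
all valid integer positions and a radius grid (default 30–90 px in steps of
10, the plausible OD range at the 9 µm/px export scale). A zero-variance
image has no defined correlation and raises a flagged degenerate error.

## Ring ROI and quadrants

With OD radius $R_{od}$ (in px), the ring spans radii $50 + R_{od}$ to
$2(50 + R_{od})$, both bounds closed, distances taken from the continuous
center to pixel centers. The scale constant is 9 µm/px, so the
manual-protocol vessel cutoff of 8 px is 72 µm (`px_to_microns(8)`).

The ring is partitioned by the vertical and horizontal lines through the
center into four diagonal sectors labelled supero-temporal (ST),
supero-nasal (SN), infero-nasal (IN) and infero-temporal (IT). Superior is
the top of the image; for a right eye the temporal side is image-left (the
macula lies left of the disc in a standard non-mirrored right-eye export),
so ST is the top-left sector, mirrored for a left eye. Compound labels of
this kind require axis-aligned sector boundaries: a partition cut along the
±45° diagonals would produce sectors centered on single anatomical
directions (S/I/T/N) and could not swap ST↔SN under a laterality flip,
which is a tested invariant. Exports from devices with mirrored geometry
can set `swap_temporal`. Partially clipped rings are analyzed as-is, with a
warning once more than 20% of the ring area falls outside the frame.

## Pseudocolor inversion

The export encodes saturation piecewise linearly in one channel per color
band; inversion applies four published conditions in order (first match
wins), mapping e.g. $(255, g, 0) \mapsto 100 - 0.1g$. Pixels matching no
condition — all grays, in particular background and the OD — are
*undefined* and excluded from every statistic. Values are clamped to
$[0, 100]$ (the violet band formula goes negative for $r > 125$) and
clamped pixels are counted. The junction triple $(255, 255, 0)$ satisfies
neither red-band clause; it decodes to 75, the midpoint of the two clause
limits, and is counted separately.

The forward encoder (used by the scene generator) is the piecewise right
inverse. Two blue-band triples whose variable channel rounds to zero would
be undecodable (both blue-band conditions require that channel nonzero);
the encoder bumps the channel to 1, bounding the round-trip error by 0.2%
at $S = 25$ — the coarsest quantization anywhere on the map (0.05% away
from band edges, 0.1% throughout $(25, 100]$).

Conditions use exact equality on 0/255 as published. Anti-aliased exports
would need channel snapping before decoding; that is deliberately not
applied by default, and the undefined mask absorbs non-matching pixels
either way.

## Bimodal histogram analysis

Defined pixels inside a region are histogrammed over $[0, 100]$ (default
bin width 1%; the protocol fixes no width, and peak locations move by
under 0.5 between widths 0.5 and 1). A degree-12 polynomial is fitted by
least squares to **all** (bin center, count) pairs over the full axis. Two
numerical points:

* the abscissa is affinely mapped to $[-1, 1]$ and the solve uses an
  orthogonal-polynomial basis; a raw degree-12 Vandermonde on $[0, 100]$
  has condition number far beyond double precision, while the fitted curve
  is mathematically identical (the reported 13 coefficients are re-expanded
  in the monomial basis on $[-1, 1]$);
* the fit domain is fixed at $[0, 100]$ rather than the data support. A
  data-dependent domain makes peak positions move when a handful of stray
  pixels extend the support — a 1% contamination at extreme saturation
  then shifts peaks by up to ~1%, as much as a mean estimator. With the
  fixed domain the same contamination moves peaks by under 0.1, preserving
  the central robustness property of a mode-based estimate. The cost is a
  mild resolution limit: widely separated narrow modes carry a systematic
  location bias up to ~1%.

The polynomial is evaluated on a 0.1% grid over the hull of nonzero bins;
interior local maxima below 5% of the tallest peak are discarded as
degree-12 ripple, and the two tallest maxima at least 10% apart (ties
broken by height sum, then separation) become the venular (lower) and
arteriolar (higher) modes; AVSD is their difference. Fewer than 13 nonzero
bins is an under-determined fit and raises `insufficient-data`; fewer than
two admissible peaks raises `unimodal-data` carrying the single peak. The
same analysis runs on the full ring and on each quadrant, and a failing
region never aborts the others.

## Synthetic scenes and what they do (not) show

`make_oximetry_scene()` renders: gray background (level 40) and gray OD
disc (level 200) — both decode-undefined since $r = g = b$ — and straight
radial vessel segments of width 10 px crossing the ring, pseudocolored
pixel-by-pixel from $\mathcal N(\mu, 1.5^2)$ saturations clamped to
$[0, 100]$. Defaults: OD radius 60 px at the center of a 512×512 frame,
four arterioles at $\mu = 92.2$ and four venules at $\mu = 57.9$ — the
healthy-population means the pseudocolor map is annotated with — one of
each per quadrant at seeded angles kept 5° clear of quadrant boundaries.
Each vessel contributes ~1100 ring pixels, so both populations exceed 2000
ring pixels. All randomness flows through one seed and the session RNG
state is restored.

These scenes validate the geometry, the decode arithmetic, and the
histogram analysis against exact ground truth. They do **not** emulate
vessel curvature or branching, anti-aliased vessel edges, fundus texture,
uneven illumination, or the optic cup; passing on them shows the pipeline
is internally correct, not that it is robust to every artifact of real
exports.

## Agreement statistics

For paired manual/algorithm readings, `icc()` computes the two-way
random-effects absolute-agreement intraclass correlation — ICC(2,1) for a
single method and ICC(2,k), $k = 2$, for the method average — from the
balanced two-way ANOVA mean squares, with exact F-based 95% confidence
bounds (Satterthwaite degrees of freedom; the average-measure interval is
the Spearman–Brown transform of the single-measure interval). The protocol
literature does not name its ICC model; two interchangeable measurement
methods are naturally modelled as random raters under absolute agreement,
and the chosen form is recorded in the output. `bland_altman()` reports
bias = mean(manual − algorithm) and limits of agreement bias ± 1.96 × SD
(sample, $n-1$ denominator), with the count of points outside the limits.
Degenerate inputs (identical columns, constant differences) are flagged
rather than silently producing NaNs.

## Problem sizes and reproducibility

Scenes are 512×512, disc-fit test images 256×256, Monte-Carlo checks use
44 subjects × 500 replicates (ICC) and $10^4$ pairs (Bland–Altman) — sizes
at which every documented tolerance is comfortably resolved while the full
suite runs in about a minute. The pipeline itself contains no randomness:
identical input and configuration yield byte-identical reports, stamped
with the package version, a configuration hash, and the input checksum.

## Known limitations

* The decoder assumes exact 8-bit pseudocolor values; lossy-compressed or
  resampled exports will decode sparsely unless snapped first.
* The active disc is a circle; strongly elliptical discs are fitted by a
  compromise circle (cup segmentation and cup-to-disc ratios are out of
  scope).
* Peak locations inherit a small bias (up to ~1% for widely separated
  narrow modes) from the fixed-domain degree-12 fit; AVSD inherits at most
  the sum of both biases.
* The ICC confidence bounds assume the balanced two-rater design; readings
  with missing entries are dropped pairwise before analysis.
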