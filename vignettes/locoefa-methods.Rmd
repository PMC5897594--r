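---
title: "Lobe contribution elliptic Fourier analysis: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lobe contribution elliptic Fourier analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(locoefa)
```

## The problem

Pavement cells of the plant epidermis, amnioserosa cells of the fly embryo,
and many other cell types have jigsaw-like outlines whose biology lives in
the number, depth and regularity of their lobes. Classic scalar descriptors
(aspect ratio, form factor) collapse very different outlines onto the same
number, and landmark methods do not apply because such cells have no
landmarks. Elliptic Fourier analysis (EFA) describes the whole outline, but
its harmonics do not map onto lobe counts: a six-lobed cell appears as a
mixture of harmonics five and seven, the same outline has infinitely many
coefficient representations, and coefficient-space comparisons between cells
are therefore not meaningful.

This package implements lobe contribution elliptic Fourier analysis
(LOCO-EFA), which repairs all three defects by re-expressing the EFA series
in a lobe-number basis, plus the derived complexity metrics, synthetic-shape
generators and an extended cellular Potts simulator used to validate the
method on populations of cells with known, controllable shapes.

## From ellipse harmonics to lobe modes

A closed outline sampled as a polygon is decomposed with the exact
piecewise-linear EFA integrals: harmonic $n$ is the ellipse
$t \mapsto (a_n \cos n\omega t + b_n \sin n\omega t,\;
c_n \cos n\omega t + d_n \sin n\omega t)$, and the offset term is the curve
centroid of the traversal. Writing each harmonic as a complex signal
exposes it as the sum of two counter-rotating circles ("rotors"),

$$z_n(t) = \lambda^+_n e^{i(n\omega t + \varphi^+_n)}
         + \lambda^-_n e^{i(\varphi^-_n - n\omega t)},$$

with $\lambda^\pm$ and $\varphi^\pm$ in closed form from $(a,b,c,d)$; the
split is exact and exactly invertible (`decompose_rotors()`,
`rotors_to_coef()`).

For a counter-clockwise base traversal, a counter-clockwise rotor riding on
harmonic $n$ modulates the radius with $n-1$ maxima per revolution, and a
clockwise rotor with $n+1$. Lobe mode $l$ therefore collects the CCW rotor
of harmonic $l+1$ and the CW rotor of harmonic $l-1$ (`assign_modes()`).
Mode 1 is the base circle (the dominant rotor of harmonic 1) plus the CCW
rotor of harmonic 2; the CW rotor of harmonic 1 feeds mode 2; the offset
feeds no mode. The representational redundancy of EFA is removed by
re-parameterising the starting point so the dominant rotor of harmonic 1
has phase zero (`canonical_phase()`), which makes the representation unique
and independent of where the traced contour happened to begin.

The scalar amplitude of mode $l$ combines its two rotors by the law of
cosines,

$$L_l = \sqrt{r_{ccw}^2 + r_{cw}^2 +
        2\, r_{ccw}\, r_{cw} \cos\Delta_l},\qquad
  \Delta_l = \varphi_{ccw} + \varphi_{cw} - 2\zeta,$$

where $\zeta$ is the mode-1 reference phase. $\Delta_l$ is algebraically
invariant both to rigid rotation of the outline and to the starting-point
choice, so the $L$ spectrum is too (verified to $10^{-9}$ in the tests).
When one rotor vanishes, $L_l$ is the remaining radius.

Because every contour is first scaled to enclosed area $\pi$ (lengths in
units of the equivalent-circle radius), $L$ values read directly as
fractional radial amplitudes: the outline
$r(\theta) = 1 + 0.15\cos 6\theta$ yields $L_6 = 0.149$ (the deficit from
0.15 is the $\varepsilon^2$-order area-normalisation correction). Mode
bookkeeping is carried one mode past the truncation order so that the
all-mode reconstruction is exactly the full EFA reconstruction; reported
spectra use modes $1..N{-}1$ from $N$ harmonics (default $N = 51$, i.e. 50
lobe modes).

### Why the parameter runs uniformly over vertices

The EFA integrals need a parameterisation of the curve. The package default
advances the parameter by a constant step per supplied vertex. For traced
image outlines this *is* the cumulative arc-length parameterisation,
because `resample_contour()` spaces vertices uniformly in arc length before
analysis. For analytically generated polar shapes
($r(\theta)$ sampled uniformly in $\theta$) it keeps the native angular
parameterisation instead. The distinction matters for strongly lobed polar
shapes: forcing chord-length parameterisation there redistributes
$O(\varepsilon^2)$ of a mode-$l$ modulation into mode $2l$ (measured:
$L_6 = 0.143$ instead of $0.149$ at $\varepsilon = 0.15$), degrading the
amplitude calibration that makes $L$ values interpretable. An explicit
`parameterisation = "arc_length"` switch provides the strict chord-length
convention for users who want it.

## Derived complexity metrics

All four metrics are computed from truncated reconstructions rasterised
against the original shape (`xor_profile()`):

* **XOR difference** `XOR(n)`: symmetric-difference area between the
  original mask and the first-$n$-modes reconstruction, as a fraction of
  the original area; `XOR(0) = 1` by convention (empty reconstruction), so
  the profile decomposes completely.
* **Marginal difference** `md(n) = XOR(n-1) - XOR(n)`: the area newly
  explained by mode $n$; its peaks identify feature-carrying modes, and
  $\sum_n md(n) = 1 - XOR(N)$ holds exactly.
* **Cumulative difference** `cd`: $\sum_{n=2}^{50} XOR(n)$, a lobe-richness
  scalar; mode 1 is excluded so sheer size/roundness does not register.
* **Entropy** $E = -\sum_l f_l \log_2 f_l$ with $f_l = L_l / \sum L_l$ over
  modes 1..50: 0 bits for a single-mode spectrum, $\log_2 k$ for a spectrum
  uniform over $k$ modes. The normalisation uses amplitudes (not squared
  amplitudes) and base-2 logarithms; a squared-amplitude variant is
  available via `shape_entropy(weights = "power")`.

The grid matters. For image-derived cells the XOR grid is the source image
at its own resolution — on that grid the profile reaches exactly zero at a
finite mode (the **natural cut-off**): beyond it, additional modes move the
outline at sub-pixel scales that the image cannot support. For synthetic
polygons, which have no native grid, a $512^2$ grid with the shape spanning
about 60% of the field is used (even-odd fill, pixel-centre sampling,
reconstruction sampled at four points per grid-diagonal pixel). On such a
fine grid a deeply lobed shape can keep $XOR > 0$ through mode 50 — a
higher-resolution grid simply resolves more modes — so the cut-off is
reported as `NA` when it is not reached.

## Synthetic shapes

`superformula_shape()` generates the Gielis superformula
$r(\theta) = (|\cos(m\theta/4)/a|^{n_2} +
|\sin(m\theta/4)/b|^{n_3})^{-1/n_1}$; with $n_2 = n_3$ and integer $m$ the
shape has exact $m$-fold symmetry, so only lobe modes that are multiples of
$m$ are populated — a sharp, testable selection rule. A curated,
version-pinned table (`star_shape_params()`) provides 3–9-lobed stars at
three amplitude levels ($n_1 = 6$, $n_2 = n_3 \in \{6, 14, 30\}$); the
table's contract is behavioural (dominant mode equals the lobe count,
amplitude level orders the peak), not a particular silhouette.
`cosine_lobed_circle()` is the calibration fixture
$r = 1 + \varepsilon\cos l\theta$. `synthetic_tissue()` rasterises a
jittered-hexagonal seeded Voronoi diagram into confluent, convex,
4-connected label regions for pipeline tests.

These generators emulate clean segmentations of well-resolved cells. They
do not emulate segmentation errors, image noise, anisotropic resolution or
cell-boundary ambiguity, so green tests here certify the analysis chain,
not robustness to poor imaging.

## The extended cellular Potts simulator

Cells are label domains on a lattice evolving by Metropolis dynamics over
boundary copy events. The configurational energy is the standard coupling
term $J$ summed over unlike second-order (8-neighbour) site pairs plus
elastic terms $\lambda_a (a_c - A)^2 + \lambda_p (p_c - P)^2$ per cell,
with the perimeter $p_c$ counted as unlike 8-neighbour pairs. A proposed
copy is always accepted if it lowers the energy by at least the yield $Y$;
otherwise it is accepted with probability $e^{-(\Delta H + Y)/T}$.

Three per-event biases give cells specified shapes, each evaluated for both
cells involved (extension sign $s = +1$, retraction $-1$), with the copy
vector running from the cell's centre of mass to the evaluated site:

* lobes: $-s\,\nu \cos(n\theta)$, $\theta$ the angle to the nearest of $n$
  equally spaced target directions — extension on a target direction is
  maximally favoured, halfway between targets maximally suppressed;
* elongation: $-s\,\chi \cos(2\alpha)$, $\alpha$ the angle to the
  elongation axis (bipolar, since an axis favours both ends);
* roundness: $+s\,\mu\,\mathrm{sign}(r - R)(r - R)^2$ with
  $R = \sqrt{A/\pi}$, penalising extension beyond the equivalent-circle
  radius and retraction inside it, which keeps cells coherent.

Target directions are not fixed: every 100 Monte Carlo steps the lobe phase
is re-fitted as the offset maximising the circular cross-correlation
between the cell's radial boundary profile and $\cos(n(\beta - \phi))$, and
the elongation axis as the principal axis of the second area moment, so
each cell accommodates its lobes to its neighbours. A 4-connectivity audit
runs at the same cadence; fragmentation is logged as a warning count, not
an error. One time step is one Monte Carlo step (as many elementary
evaluations as lattice sites); a single seeded R RNG stream drives site
choice, neighbour choice and acceptance, so trajectories are bit-identical
for a fixed seed.

### Study conditions for the tissue experiment

`tissue_experiment()` compares the specified-mode amplitude between
confluent and isolated conditions at desk scale: 16 cells on a $100^2$
lattice for 2,000 steps against single cells on $60^2$ relaxed for 10,000
steps (an isolated cell needs the longer relaxation to express its
specified shape fully; the isolated reference is the median of three
replicates to suppress run-to-run variation). The six-lobe parameter set
(`cpm_params_sixlobe()`: $J = 4$, $A = 500$, $P = 213$, $\lambda_a = 1$,
$\lambda_p = 0.2$, $\nu = 40$, $n = 6$, $\mu = 2$, $T = 10$, $Y = 0$)
produces an isolated cell with dominant mode 6 and $L_6 \approx 0.15$.
Within the tissue, packing frustrates the periodic lobe placement: the
median $L_6(\text{tissue})/L_6(\text{isolated})$ falls below one, which is
the directional claim the package tests. Full-scale population
distributions would need larger fields, longer runs and many more cells.

## Numerical choices

* Boundary tracing: marching squares at iso-level 0.5 of each region's
  indicator (via `grDevices::contourLines()`), giving sub-pixel vertices on
  pixel-edge midpoints; the outer loop is kept, oriented counter-clockwise.
  Connected components come from `EBImage::bwlabel()`.
* Resampling density: 1000 points by default — at 50 modes that is more
  than 10 samples per shortest resolved wavelength. No smoothing is applied
  to traced outlines.
* Area normalisation target $\pi$ rather than 1, so lengths are in units of
  the equivalent-circle radius and $L$ values read as
  fraction-of-radius amplitudes.
* Ties in dominant-mode reports break to the lowest mode, for determinism.
* Degenerate inputs error early: contours need three distinct vertices,
  nonzero area and (for canonicalisation) simplicity; an all-zero spectrum
  has no entropy; a zero first harmonic has no canonical phase.
* Cells touching the image border are flagged and excluded from metrics by
  default (their outlines are clipped artefacts), but stay listed with the
  exclusion reason; `include_border = TRUE` overrides.

## A worked example

```{r example}
star <- star_shape(6, "medium")
fit <- loco_efa(star, n_modes = 20, normalise = FALSE)
glance(fit)
autoplot(fit)
```

```{r xor}
prof <- xor_profile(fit, n_max = 15)
argmax_marginal(prof)
autoplot(prof)
```

## Known limitations

* The lobe-mode reassignment assumes a counter-clockwise dominant
  traversal; clockwise input is reoriented upstream, and outlines whose
  first harmonic vanishes (space-filling or degenerate traces) are
  rejected.
* $L_1$ is reported as the base-circle radius (close to 1 after area
  normalisation); the 1-fold asymmetry rotor (CCW of harmonic 2) is carried
  for reconstruction but does not enter $L_1$.
* The amplitude calibration is exact to first order in lobe depth; at
  $\varepsilon = 0.2$ the area-normalisation correction reaches about 1% of
  the value.
* The cellular Potts extension is phenomenological: it specifies shape
  tendencies directly and contains no wall mechanics or biochemical
  signalling, so its tissues inform about packing geometry, not mechanism.
* Entropy with mode 1 included rates strong elongation (a large $L_2$
  rivalling $L_1$) as high-entropy; comparisons of elongation-dominated
  against multi-lobed cells should read entropy alongside the marginal
  difference profile.
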