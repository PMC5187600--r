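---
title: "Localized patch-based fuzzy active contours: model, numerics, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localized patch-based fuzzy active contours: model, numerics, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzac)
```

## The model

`fuzzac` segments a grayscale image into two phases with a *fuzzy
region-based active contour*.  Instead of a signed level-set function, the
contour is carried by a membership field $u(x) \in [0,1]$: the contour is
the set $\{u = 0.5\}$, the foreground is $\{u > 0.5\}$, the background
$\{u < 0.5\}$ (a *pseudo level set*).

Each pixel $x$ owns a disc patch $\Omega_x = \{y : |y - x| \le r\}$,
selected by the mask $W(x,y)$.  With the fuzzifier $m > 1$, the patch's
fuzzy fitting statistics are

$$
c_1(x) = \frac{\sum_y W(x,y)\, u(y)^m I(y)}{s_1(x)},\qquad
s_1(x) = \sum_y W(x,y)\, u(y)^m,
$$

and analogously $c_2(x), s_2(x)$ with $(1-u)^m$.  The total energy is the
sum of the patch-local fitting residuals

$$
F(u, c_1, c_2) \;=\; \sum_x \sum_y W(x,y)\Big[\,u(y)^m (I(y)-c_1(x))^2 +
(1-u(y))^m (I(y)-c_2(x))^2\,\Big],
$$

with **no length/regularization term**.  Because every pixel carries its
own prototypes, objects whose intensity drifts across the image (intensity
inhomogeneity) can still be fit locally, where a single global prototype
pair — the FEAC baseline, $c_1 = \sum u^m I / \sum u^m$ over the whole
image — fails.

## Direct minimization instead of a PDE

Minimizing $F$ in a single membership value with prototypes fixed gives the
closed-form candidate

$$
u_n = \frac{1}{1 + \big((I_0-c_1)^2/(I_0-c_2)^2\big)^{1/(m-1)}},
$$

with explicit limits: $I_0 = c_1 \ne c_2 \mapsto 1$, $I_0 = c_2 \ne c_1
\mapsto 0$, $I_0 = c_1 = c_2 \mapsto 0.5$.

Two exact update rules make the optimization fast without solving an
Euler–Lagrange equation:

1. **Prototype update.** If one pixel with intensity $I_0$ changes
   membership $u_0 \to u_n$ inside a patch, the patch's prototypes move by
   $\hat c_1 = c_1 + \frac{\Delta_1}{s_1 + \Delta_1}(I_0 - c_1)$ with
   $\Delta_1 = u_n^m - u_0^m$ (and the complement form for $c_2$).  No
   re-summation over the patch is needed.
2. **Energy change.** The total energy change of that single-pixel move is
   $$\Delta F = \sum_{x:\,|x-P|\le r}\Big[ s_1(x)\tfrac{\Delta_1}{s_1(x)+\Delta_1}(I_0-c_1(x))^2
   + s_2(x)\tfrac{\Delta_2}{s_2(x)+\Delta_2}(I_0-c_2(x))^2 \Big],$$
   where the sum ranges over exactly the patch centers whose footprint
   contains the changed pixel $P$ — an exact algebraic restriction, since
   every other patch is untouched.

The solver visits the pixels of a narrow band around the current contour in
raster order; each candidate is **accepted iff $\Delta F < 0$** (strict
decrease), and on acceptance all affected patch statistics are updated
immediately, so the closed forms remain exact for the next pixel
(Gauss–Seidel style).  Both rules are verified in the test suite against
brute-force recomputation (`1e-12` absolute for the prototypes, `1e-8`
relative for $\Delta F$ against a quadruple-loop energy oracle).

Two published descriptions of this scheme conflict and we resolved them as
follows, because only this choice yields the claimed monotone, stable
evolution:

* the acceptance sign is $\Delta F < 0$ (the algorithm is a minimization;
  an "accept if $\Delta F \ge 0$" reading would increase the energy);
* statistics are updated immediately after each accepted single-pixel move
  (a deferred "Jacobi" schedule would invalidate the exactness of the
  $\Delta F$ formula, which presupposes current statistics);
* ties ($\Delta F = 0$) keep the old membership, which guarantees
  termination ($F \ge 0$ decreases strictly at every accepted move).

The second $\Delta F$ term uses $s_2$ in its denominator, consistent with
the $c_2$ update rule; the oracle tests confirm this form against the
direct before/after energy difference.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `radius` (r) | 20 px | localization scale; the disc patch radius.  Small radii see only nearby intensity structure (risking "too local" failures when the initialization is far from the boundary); very large radii approach the global model. |
| `m` | 2 | fuzzifier; weights memberships in the energy.  $m \to 1^+$ approaches crisp assignments; the candidate formula requires $m > 1$. |
| `band_width` | 2 px | Chebyshev half-width of the narrow band around the 0.5-level; rebuilt before every sweep so it always covers the full transition set.  2 px is the smallest width that lets the contour advance more than one pixel per sweep with a safety margin. |
| `max_iterations` | 200 | hard cap on sweeps (the radius-sensitivity protocol runs exactly 200). |
| `energy_tolerance` | 1e-10 | relative stop: halt when a full sweep decreases $F$ by less than `energy_tolerance * F_initial` (or when no move is accepted at all). |

The FEAC baseline adds class weights `lambda1`, `lambda2` (default 1, the
values used in the comparison experiments) and an optional length weight
`mu` (default 0; the discrete length surrogate is the count of 4-neighbor
edges crossing 0.5, recounted locally in $\Delta F$).

## Numerical and interface choices

* **Coordinates are 1-based (row, col)** — the native convention of R
  matrices and of every R imaging package this package interoperates with.
* **Intensities are min–max normalized to [0,1] on load** (constant images
  map to zeros).  The energies are scale-covariant, so this only makes
  tolerances and defaults portable across bit depths; 8/16-bit PNG, TIFF
  and PGM inputs all land on the same scale.
* **Initial memberships are crisp**: $u_{in} = 1$ inside the seed
  rectangles (or mask), $u_{out} = 0$ outside.  Only $u_{in} > 0.5 >
  u_{out}$ is required by the model; with $m = 2$ the crisp choice causes
  no singularity and matches the usual crisp initial partition of fuzzy
  region-based contours.
* **Patches are clipped at the image border** (sums run over in-image
  pixels only; no padding), which keeps prototypes unbiased.  The patch
  footprint uses the Euclidean disc $dy^2 + dx^2 \le r^2$.
* **Empty-class patches** ($s_1 = 0$ or $s_2 = 0$): the corresponding
  prototype is defined as the unweighted patch mean.  Any finite value
  works — the class's energy weight is zero — and the patch mean avoids
  manufacturing extreme membership candidates.
* **Degenerate incremental updates** (a move that would empty one class of
  a patch, denominator $\le 0$): the affected patch is re-evaluated
  directly from the membership field instead of incrementally.
* **Floating-point drift**: incrementally maintained statistics are
  resynchronized from scratch every 50 sweeps.  The energy trace is
  accumulated from the accepted $\Delta F$ values, so it is exactly
  non-increasing by construction.
* **RGB inputs** are collapsed by the channel mean; the model treats only
  gray-level images.

## The synthetic phantoms

Real validation images of the original study (animals, pelvis, spine) are
not redistributable, so validation uses seedable phantoms with exact ground
truth.  Three presets reproduce the *structure* of the study's experiments;
their geometry is this package's own (documented) stand-in, and the ground
truth is always noise- and bias-free.

* `three_object_phantom()`: three objects with pairwise-distinct levels
  (0.90, 0.65, 0.20; gaps ≥ 0.15) straddling a mid-gray background (0.45),
  one object with two punched interior holes and one annulus.  Because the
  dark object lies on the opposite side of the background from the bright
  ones, no single global prototype pair can capture all three — the
  localized model recovers them all from one enclosing seed rectangle while
  the global baseline loses at least one.
* `circle_rectangle_phantom(noise_variance, seed)`: a bright circle (0.95)
  and a dimmer rectangle (0.70) on a dark background (0.05), plus additive
  zero-mean Gaussian noise of the requested **variance on the [0,1] scale**
  (clipped).  The distinct object levels make the global baseline's single
  threshold sit near the dim object's intensity, which is what degrades it
  under noise.  The default initialization is a tight rectangle (~4 px
  margin) around each shape so membership updates stay near the true
  boundary.
* `inhomogeneous_phantom(seed)`: two elongated bars whose intensity ramps
  linearly (0.10 ↔ 0.85) *through* the background level (0.46), under a
  multiplicative Gaussian-bump bias field (amplitude 0.35, scale 40 px) and
  light noise.  No global threshold reaches Dice 0.95 on it (the package's
  `best_threshold_dice()` oracle certifies this), so global-prototype
  models fail structurally.  The default initialization is deliberately
  loose (~20 px margin): with a localization radius of 10 px the objects
  are invisible from the initial contour (the "too local" failure), radii
  20–25 work best, and a radius of 30 px degrades again as patches blend
  the bias field and both bars ("too global") — reproducing the reported
  unimodal radius sensitivity.

What the phantoms deliberately do **not** emulate: textured backgrounds,
partial-volume boundaries, multiplicative (speckle-like) noise, and the
anatomical geometry of the original medical images.  Passing the phantom
suite therefore shows correctness of the energies, the update lemmas and
the optimizer, and qualitative reproduction of the localization phenomena —
not clinical-grade performance.

## Known limitations

* **Interior holes behind a shrinking front.**  The narrow band only moves
  with the contour.  A contour initialized *around* an object settles on
  its outer boundary; background pockets fully interior to the object
  (holes) are never visited and stay foreground.  Fronts that *expand*
  across an object flow around its holes correctly.  The multi-object
  replication quantifies this: with an enclosing seed, union Dice ≈ 0.96
  with the hole interiors as the only systematic false positives.
* **Heavy noise.**  Every membership decision compares the pixel's *own*
  intensity with (local or global) prototypes; with no regularization term
  there is no spatial smoothing of decisions.  The per-pixel
  misclassification probability under additive noise of standard deviation
  $\sigma$ at class contrast $\Delta$ is $\Phi(-\Delta/2\sigma)$ per tail,
  which for variance 0.10–0.20 on [0,1] (σ ≈ 0.32–0.45) exceeds 10–20%
  even at maximal contrast.  Two consequences, both visible in the
  noise-robustness experiment: (i) wrong flips recruit their neighborhoods
  into the band, so errors are not confined to the initially swept ribbon;
  (ii) the achievable Dice is bounded by the pixelwise (threshold-oracle)
  ceiling, about 0.6–0.8 at variance 0.20 — for any model of this family.
  At variance 0.01 (σ = 0.1) both models segment essentially perfectly.
  The `run_noise_robustness()` harness reports what the models actually do
  at the higher levels rather than idealized values, and
  `best_threshold_dice()` computes the ceiling for any given phantom.
* **Label symmetry.**  The energy is invariant under $u \mapsto 1-u$, so
  "foreground" is defined only relative to the initialization.
  Disconnected seed regions in unrelated parts of the image can adopt
  inconsistent local labelings; use one connected seed (or seeds per
  object) rather than a scattered grid.
* Two-phase only; no multiphase extension, no 3-D volumes, no sub-pixel
  contour extraction.

## Problem sizes used in the shipped experiments

The replication experiments run on 128×128 phantoms (the lemma oracles on
12×12 and 16×16 instances, the global-limit check on 32×32), with 5 noise
seeds and the radius grid {10, 15, 20, 25, 30} at 200 iterations — sizes
chosen so the full suite re-runs from scratch in minutes on one CPU while
keeping every object large relative to both the patch radius and the
band width.

## A worked example

```{r example, eval = FALSE}
ph <- three_object_phantom()
res <- segment(ph$image, ph$init, model_params(radius = 20))
dice_coefficient(res$binary_mask, ph$truth)
baseline <- feac_segment(ph$image, ph$init, feac_params())
dice_coefficient(baseline$binary_mask, ph$truth)
```

The localized run recovers all three objects (union Dice ≈ 0.96, each
object's component Dice ≥ 0.92); the global baseline finds only the
objects brighter than the background and misses the dark one
(Dice ≈ 0.71).
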