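---
title: "Quantifying monocyte recruitment and chemotaxis in vascularized tumor-on-chip assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying monocyte recruitment and chemotaxis in vascularized tumor-on-chip assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monorecruit)
```

## The biological readouts

Vascularized tumor-on-chip devices grow a self-assembled microvascular bed
(vessel diameter around 40 µm) in a fibrin gel around a central well
(~1.5 mm punch) into which a tumor spheroid or patient tissue fragment is
inserted. Monocytes perfused through the vasculature can extravasate and
migrate toward the tumor. Two quantitative readouts drive the analysis:

1. **Compartment counts.** On a confocal max-projection with a vasculature
   channel and a monocyte channel, every detected monocyte is *luminal*
   (inside a vessel lumen), *extravasated* (in the gel, outside vessels), or
   *recruited* (inside the central tumor well). The recruited fraction per
   field, tracked over days 1–3, is the recruitment readout.
2. **Motility coefficients.** In a simpler three-channel device, monocytes
   enter a gel channel of length $L = 1300$ µm from one side and their
   positions are read at a fixed endpoint. A one-dimensional Keller–Segel
   model separates undirected random motility ($D$) from gradient-directed
   chemotaxis ($\chi$).

Both tracks are fully testable against the package's synthetic generators,
which carry per-cell ground truth.

## Compartment pipeline

The pipeline mirrors the morphological procedure used on the microscope
data: collapse the z-stack to a per-pixel max projection; threshold the
vasculature channel (Otsu by default — the projection is strongly bimodal);
close the small inter-vessel gaps by `n_iterations` dilations followed by
the same number of erosions with a disk element; invert; take the largest
interior background component above a minimum area as the well; dilate it
slightly; and classify each detected monocyte spot by mask lookup, with the
well taking precedence over the vessel mask. The luminal test uses the
*original* (unclosed) vessel mask restricted outside the well, because the
closed mask contains filled gel gaps that are not lumen.

Parameters that matter, with defaults:

* `n_iterations = 10` and `element_radius_px = 3` (at 3 µm/px a ~90 µm
  closing reach): inter-vessel gaps in these beds are typically well under
  180 µm across and close completely, while a 1.5 mm well cannot close.
* `min_hole_area_um2 = 2e5` (0.2 mm²): any gel lacuna that survives closing
  is far smaller than this, so well selection is robust even when closing is
  imperfect.
* `well_dilation_um = 20`: the inverted hole already includes the avascular
  margin out to the nearest vessel ribbons, so only a small dilation (about
  one cell diameter) is needed to capture cells adhering to the gel rim.
  Larger values systematically reassign extravasated cells near the rim to
  the recruited compartment.
* `prominence = 0.65` and `min_separation_um = 12` for spot detection: the
  detector min–max normalizes the channel and keeps local maxima above the
  prominence cut-off with a minimum pairwise separation of one cell width,
  ties resolved by intensity and then (row, column) order. At a
  signal-to-noise ratio of 10 on a megapixel field, a cut-off of 0.65 sits
  roughly five noise standard deviations above the background maxima while
  the dimmest true spots remain well above it. Detection is invariant to
  affine intensity rescaling by construction.

Counts always satisfy `luminal + extravasated + recruited = total` exactly,
and the recruited fraction is defined as 0 on an empty field.

Pixel indices in all tables are 1-based (row, column), the R convention;
physical coordinates are microns from the image's top-left corner.

## The Keller–Segel model and its estimators

Cell density $n(x,t)$ on $[0, L]$ follows

$$\frac{\partial n}{\partial t} = \frac{\partial}{\partial x}\left(
  D\,\frac{\partial n}{\partial x} - \chi\, n\, \frac{\partial c}{\partial x}
\right),$$

with zero-flux boundaries (cells cannot leave the gel) and all mass at
$x = 0$ at $t = 0$, where perfused monocytes accumulate on the endothelial
interface before invading. The chemoattractant field $c$ is prescribed, not
solved: conditioned-media assays compare conditions rather than absolute
molar levels, so $c$ is normalized to $[0,1]$ (`zero`, `uniform`, or
`linear_gradient`, $c(x) = x/L$) and $\chi$ carries units of µm²/h per unit
normalized concentration. The induced drift is $v = \chi\,\partial c /
\partial x$, i.e. $\chi / L$ for the linear gradient. The linear flux form
$-\chi n\,\partial c/\partial x$ (not logarithmic sensing) is the minimal
classical form and is the one used here.

Estimation follows the subtraction logic of the assay design:

* **$D$ from controls.** In zero or uniform fields the model is pure
  diffusion. The *moment* estimator is $\hat D = \overline{x^2}/(2t)$,
  valid while $\sqrt{2\hat D t} < L/4$ (flagged otherwise); the *likelihood*
  estimator bins positions into 26 equal bins and maximizes the multinomial
  likelihood of the counts under the forward solution, by Brent search on
  $\log_{10} D$. Binned likelihood is robust to the pixel-level jitter of
  image-derived positions. Control fits are pooled as an unweighted mean
  and that single value is frozen in every $\chi$ fit.
* **$\chi$ per condition.** With $D$ fixed, $\chi$ maximizes the same
  binned likelihood, searched on $[-\chi_{\max}, \chi_{\max}]$. The default
  $\chi_{\max} = 2L^2/t$ corresponds to a drift displacement of two channel
  lengths over the observation time — far beyond any physical monocyte
  drift, while keeping the solver's advective time-step practical. A
  negative $\hat\chi$ indicates repulsion. In a uniform or zero field
  $\chi$ does not enter the model; requesting it raises an
  unidentifiability error.
* **Migrating percentage.** The model-free readout
  $100 \cdot \#\{x > L/2\}/N$ (cells exactly at the midline count as not
  migrated).

Note one asymmetry worth remembering when reasoning about sanity checks:
because all cells start at $x = 0$, the model is *not* symmetric under
mirroring positions about $L/2$. A population piled against the far wall is
best explained by a strong positive drift, not a negative one.

### Chemotaxis vs chemokinesis

A higher migrating percentage under a conditioned-media gradient could mean
directed chemotaxis or merely chemokinesis — uniformly stimulated random
motility. `compare_chemokinesis()` separates them using all three arms:
chemokinesis appears as $D_{\text{uniform}} > D_{\text{control}}$ with
$\chi$ unidentifiable, whereas chemotaxis leaves the $D$ pair equal and
yields $\hat\chi > 0$ in the gradient arm.

Which $D$ to freeze for the gradient-arm $\chi$ fit is a genuine design
choice. Freezing the control-arm $D$ is the plain subtraction logic, but if
the stimulus itself elevates motility, the gradient arm shares the elevated
$D$ of the uniform arm, and fixing the lower control value misreads the
extra spread as outward drift at the reflecting origin (in synthetic
pure-chemokinesis data with doubled $D$, the spurious drift lands well
outside the ±2 µm/h null band). The default `d_policy = "auto"` therefore
re-fits the gradient arm
with the uniform-arm $D$ whenever $D_{\text{uniform}}/D_{\text{control}} >
1.5$; `"control"` restores the plain subtraction.

## Numerical scheme

`solve_forward()` uses a conservative finite-volume discretization on a
uniform node grid with half-width boundary cells, so the trapezoid integral
of the returned density *is* the conserved mass. The combined
diffusive-plus-advective face flux uses Scharfetter–Gummel exponential
fitting,

$$J_{i+1/2} = \frac{D}{\Delta x}\left[B(-\mathrm{Pe})\,n_i -
  B(\mathrm{Pe})\,n_{i+1}\right], \qquad
  B(z) = \frac{z}{e^z - 1},\ \mathrm{Pe} = \frac{v\,\Delta x}{D},$$

which reduces to central differencing at zero drift and to upwinding in the
strong-drift limit without first-order numerical diffusion (plain upwinding
would add $v\Delta x/2 \approx 5\%$ of $D$ at the default grid and visibly
shift the fitted coefficients). Time stepping is Crank–Nicolson with a
four-step backward-Euler start-up to damp the ringing the near-delta
initial condition would otherwise excite; round-off negatives below
$10^{-10}$ are clamped to zero. Defaults are $\Delta x = L/130 = 10$ µm and
$\Delta t = \min(0.05\ \mathrm{h},\ 0.45\,\Delta x / v_{\max})$; the
advective Courant number is checked and violations raise an error naming
the offending step. Against the reflected-Gaussian closed form at
$D = 1000$ µm²/h, $t = 6$ h, the solution is accurate to $2.6\times10^{-4}$
of the peak; mass is conserved to better than $10^{-8}$ over $10^4$ steps;
and halving $\Delta x, \Delta t$ moves day-2 bin masses by far less than
the 0.5% self-consistency bound the tests enforce.

The microscopic simulator (`simulate_migration()`) integrates the matching
biased random walk by Euler–Maruyama with mirror reflection at both walls,
default $\Delta t = 0.01$ h, so the per-step displacement stays far below
the channel length (a hard precondition). Moments of the simulated
endpoint distribution match the reflected-Brownian closed forms within
Monte-Carlo error, which is the bridge that lets the PDE-based estimators
be validated on simulated cells.

## What the synthetic data does and does not emulate

The image generator builds the vessel texture as the dilated edge set of a
random Voronoi tessellation (mean lacuna spacing 170 µm), which reproduces
the connectedness, ribbon width (40 µm median) and lacunar structure of
self-assembled beds, clears a vessel-free disk for the well, renders cells
as isotropic Gaussian spots (FWHM 12 µm, the scale of a dye-labelled
monocyte) with at least two spot-widths separation and one cell radius of
margin from compartment borders, and adds Gaussian read-out noise at a
chosen SNR. It does **not** emulate: curved or tapering vessels, intensity
heterogeneity along lumens, out-of-focus haze, overlapping or clumped
cells, or partial-volume effects of the z-collapse. Passing the recovery
tests therefore demonstrates the pipeline's correctness and its behaviour
under Gaussian noise, not robustness to every microscopy artifact; on real
data the prominence and closing parameters are the knobs to revisit.

The migration generator prescribes a steady linear gradient (the
conditioned-media source is continuously replenished and the channel is
short) and a sharp $t = 0$ seeding; snapshot times 24/48 h stand in for
day-1/day-2 imaging. It does not model gradient build-up transients,
cell–cell interactions, proliferation, or death.

Default study conditions used by the tests and the acceptance script:
fields of 3×3 mm at 3 µm/px with 100 cells (30/40/30 across compartments)
at SNR 10; migration arms with $D = 1000$ µm²/h, $\chi = 13000$ µm²/h
(drift 10 µm/h), 1500–5000 cells per ROI, read at 24 or 48 h. Problem
sizes (20 image seeds; a 3×3 grid of $D \in \{500, 1000, 2000\}$ ×
drift $\in \{0, 5, 10\}$ µm/h at $n = 5000$) keep the full suite and the
acceptance run within a few minutes on a single core while leaving
Monte-Carlo error well inside the tested tolerances.

## Known limitations

* Compartment calls are projection-based; a monocyte above or below a
  vessel is counted as luminal. Per-slice 3D lumen tests are out of scope.
* $\chi$ is only comparable across conditions sharing the same normalized
  concentration scale; no absolute molar calibration is attempted.
* $D$ and $\chi$ are never fit jointly from a single treated condition — by
  design, matching the assay's subtraction logic; a condition that changes
  both cannot be resolved without its own uniform arm.
* The estimators assume endpoint snapshots of independent cells;
  trajectories, if available, would be strictly more informative.

## Reproducing the numbers

`scripts/acceptance.R --seed 1 --out results/acceptance.json` regenerates
every headline quantity from scratch (synthetic bundles, solver-vs-closed
form error, recovered $D$, $\chi$, chemokinesis ratio, migrating
percentages, demo determinism). The numbered drivers under `analysis/` walk
the same pipeline as a narrative: generate images, quantify recruitment,
simulate the migration assay, fit the coefficients, and screen chemotaxis
against chemokinesis.
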