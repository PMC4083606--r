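---
title: "Methods: spline geometry of helix pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spline geometry of helix pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groovegeom)
```

## The model

groovegeom describes an α-helix not atom by atom but by a smooth space
curve, and a pair of helices by the surface spanned between their curves.
The target application is the MHC class I binding groove, whose two
antiparallel helices (G-ALPHA1 and G-ALPHA2) frame the peptide that a T-cell
receptor inspects; the same machinery applies to any helix pair.

**Reference frame.** For one helix in one frame, the Cα coordinates
$x_1,\dots,x_n$ are centred at their centroid and eigendecomposed
(`compute_frame()`): the eigenvectors of the $3\times3$ coordinate
covariance, ordered by descending eigenvalue, are the local axes PC1, PC2,
PC3.  For anything helix-shaped, PC1 is the axis direction: the axial spread
of a 30-residue helix (variance $\approx 170\ \text{Å}^2$) dwarfs the
lateral spread ($\approx r^2/2 \approx 2.6\ \text{Å}^2$), so the ordering is
unambiguous.  Eigenvectors have arbitrary sign, so the frame is pinned
deterministically: PC1 points from the N- to the C-terminus, PC2 is chosen
so the first residue has non-negative PC2 coordinate, and PC3 = PC1 × PC2
makes the frame right-handed.  The global curve downstream is invariant to
these conventions; they exist so that coefficient-level regression tests are
reproducible.  Degenerate cases: coincident points are rejected; for a
perfectly straight trace PC2/PC3 are an arbitrary orthonormal pair in the
normal plane (tied zero eigenvalues) and are accepted as the eigensolver
returns them, which is harmless because the fitted lateral polynomials are
then identically zero in any such frame.

**Spline fit.** In the local frame the helix is the parametric curve
$c(z) = (z, f_2(z), f_3(z))$, $z$ the PC1 coordinate.  $f_2$ and $f_3$ are
single-segment polynomials of degree $m$ (no interior knots), so the fit
(`fit_spline()`) is two independent one-dimensional linear least-squares
problems over the $n$ Cα points, solved jointly through one QR
factorisation.  Explicit normal equations are never formed in package code —
they exist only as an independent oracle in the test suite.  Preconditions:
$n \ge m + 2$ (at least one residual degree of freedom) and full column
rank of the Vandermonde design (violated only when distinct points collapse
onto too few distinct $z$ values, which is reported as a conditioning
error).  The residual sum of squares is pooled over both planes.

Treating $z$ as a fixed abscissa (ordinary regression of $y_2, y_3$ on $z$)
rather than orthogonal-distance regression is a modelling choice: it is the
direct reading of "fit $f_2$ in the PC1–PC2 plane", it is linear and
deterministic, and for helix-like data the PC1 direction is so dominant that
the distinction is negligible.

**Discretisation.** `evaluate_spline()` samples the curve at $M$ positions
uniform in $z$ between the extreme fitted $z$ values, position $i$ at
$z_i = z_{\min} + \frac{i-1}{M-1}(z_{\max}-z_{\min})$, and maps them back to
global coordinates.  Uniform-in-$z$ (rather than uniform arc length) is the
direct reading of the curve parameterisation; for nearly straight helices
the two coincide to first order.  Cumulative chord lengths are returned so
users can resample by arc length if they prefer.

**Rulings and distances.** With both splines discretised at a common $M$,
ruling $i$ joins the equal-parameter points and
$d(u_i) = \lVert c_2(u_i) - c_1(u_i) \rVert$ (`build_rulings()`).
Correspondence is strictly by parameter — no closest-point reprojection —
because reprojection would make the surface definition non-symmetric and
iteration-dependent.  Antiparallel pairs are handled by reversing curve 2
when that lowers the total ruling length; the criterion needs no sequence
metadata and is decisively unambiguous for groove-like geometries (the two
sums differ by orders of magnitude).  The distance profile is probed at
five positions, by default 1, 369, 737, 1105, 1471 for $M = 1500$ — the two
flanking points plus three central points of the groove.

**Surface area.** Consecutive rulings bound a skew quad; each is split
along the fixed diagonal $c_1(u_i) \to c_2(u_{i+1})$ and the two triangle
areas are summed (`ruled_surface_area()`), $2(M-1)$ triangles in total.  A
fixed diagonal keeps the estimator deterministic; the alternative diagonal
is exposed as an argument and changes the total by an amount that grows
roughly quadratically with helix bow — measured on synthetic pairs at
$M = 1500$: ~5·10⁻⁷ relative at 1 Å bow over a 44 Å helix, ~5·10⁻⁶ at 2 Å,
~4·10⁻⁵ at 5 Å — far below the frame-to-frame variation the statistic is
meant to track.  The area estimator converges as $M$ grows; at $M = 1500$
it agrees with a 100 000-ruling refinement to well under $10^{-4}$ relative
on smooth pairs.

**Model comparison.** Degrees are compared per helix by
$\mathrm{AIC} = n\ln(\mathrm{rss}/n) + 2p$ with $n = 2\,n_\text{points}$
residuals (both planes) and $p = 2(m+1)$ coefficients (`aic_score()`).
This Gaussian least-squares form is the package's documented convention.  A
perfect fit returns $-\infty$ with a warning.  Note that on residuals that
are *purely* Gaussian the plain AIC picks the true lower degree only ~80–85%
of the time (the classic overfitting probability of nested model selection);
on real or realistic helices the residuals are dominated by the helical coil
itself, which higher-degree polynomials cannot absorb, and the lower degree
wins essentially always.  Across a trajectory, `compare_degrees()` reports
the percent change of the *time-averaged* area relative to a reference
degree, $100(\bar A_m - \bar A_\text{ref})/\bar A_\text{ref}$.

**Summaries.** Per probe position, `summarize_geometry()` computes the
five-number summary of $d$ over time with whiskers as true extremes (not
1.5·IQR fences) and quartiles by linear interpolation between order
statistics (`stats::quantile()` type 7) — a convention that had to be picked
and is stated rather than hidden.  Time stamps are carried as metadata only
and never affect computation; frames are processed independently, so frame
order permutes the series and changes no summary.

## The synthetic generator

`helix_spec()` encodes an ideal α-helix: 1.5 Å rise per residue, 3.6
residues per turn, 2.3 Å Cα radius — standard textbook backbone geometry —
with the axis optionally bent by polynomial lateral displacements in two
perpendicular directions (so a degree-$m$ fit has an exact ground truth),
plus isotropic Gaussian coordinate noise as the simplest stand-in for
thermal fluctuation.  `pair_trajectory_spec()` places two such helices at a
centroid separation that oscillates sinusoidally over frames ("breathing"),
antiparallel by default via a proper 180° rotation (chirality preserved),
with independent per-frame noise.  Ground-truth separations are returned
with the frames.

Typical magnitudes used throughout the tests: 24–36 residues per helix,
12 Å separation, bows of ~1 Å (bend coefficient 2·10⁻³ Å⁻¹), breathing
amplitude 2 Å over a period of 8 frames, coordinate noise 0.1–0.3 Å,
trajectories of 4–64 frames; these sizes make every property checkable in
seconds while staying in the regime of real groove geometry.

What the generator does *not* emulate: full-atom backbones and side chains,
force-field physics, solvent, correlated (non-isotropic) thermal motion,
per-frame changes in helix secondary-structure assignment, and helix
unwinding at the termini.  Passing the recovery tests therefore shows the
*geometry pipeline* is correct and well-conditioned, not that any particular
biological system behaves like the generator.

## Input conventions

`read_frames()` reads multi-model PDB files through bio3d, one MODEL at a
time, so a selection that fails in a specific MODEL is reported with its
frame index.  Helix residue ranges are fixed user input (YAML config),
constant across frames: re-classifying helices per frame would change the
spline support length between frames and silently reshape the time series.
Author residue numbering is used as-is; only Cα atoms are read; altloc
records other than blank/'A' are ignored; insertion codes inside a selected
range are rejected rather than silently ordered.  The shipped example
config is an illustration of the format, not a validated assignment for any
particular structure.  Units are Å and Å² throughout (PDB native); the CSV
writer can convert to nm for comparison with nm-convention tooling.

## Known limitations

- Single-segment polynomials only: no interior knots, no smoothing
  penalties, no curvature/torsion profiles.
- Equal-parameter ruling correspondence is a convention; strongly sheared
  pairs (helices sliding along each other) shift which points face each
  other, and the area then depends on that convention.
- The five probe positions are literal defaults for $M=1500$, not an even
  spacing rule.
- The PCA axis degrades as a helix bends toward a horseshoe; the method is
  intended for gently bent helices where PC1 is clearly dominant.
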