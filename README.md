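# groovegeom

Geometric analysis of α-helix pairs over conformational trajectories, built
for the two antiparallel helices (G-ALPHA1, G-ALPHA2) that flank the peptide
binding groove of MHC class I molecules.  The groove's width and shape govern
how a T-cell receptor docks onto the peptide–MHC surface, so compact global
descriptors of the helix pair — the interhelical distance profile and the
area of the surface spanned between the helices — are useful summaries of
groove dynamics in molecular-dynamics trajectories.

## The method

For each trajectory frame and each helix:

1. **Reference frame.** The Cα coordinates of the helix are subjected to a
   principal component analysis.  The centroid is the origin; the orthonormal
   axes PC1, PC2, PC3 (descending variance) form a local coordinate system in
   which PC1 approximates the helix axis.
2. **Spline fit.** The helix shape is represented by the parametric curve
   c(z) = (z, f₂(z), f₃(z)) in that frame, with z the PC1 coordinate.  f₂
   (PC1–PC2 plane) and f₃ (PC1–PC3 plane) are single-segment polynomials of
   degree m (no interior knots, K = 0), fitted by two independent 1-D least
   squares over the Cα points.  Degrees m = 2, 3, 4 are the ones of practical
   interest; the Akaike information criterion (`aic_score()`) compares them.
3. **Rulings.** Both splines are discretised at M points (default M = 1500)
   under a common parameter u ∈ [0, 1], and straight rulings join
   equal-parameter points, with curve 2 reversed automatically when the pair
   is antiparallel.  The ruling lengths give the interhelical distance
   profile d(uᵢ) = ‖c₂(uᵢ) − c₁(uᵢ)‖, probed by default at positions
   1, 369, 737, 1105, 1471.
4. **Surface area.** Consecutive rulings bound quads that are triangulated
   along a fixed diagonal; the total area A of the resulting ruled surface is
   a global measure of groove width.

Over a trajectory these yield per-frame time series of d at the probe
positions and of A, summarised by boxplot five-number statistics per
position, the time-averaged area, and percent changes of the time-averaged
area across polynomial degrees.

A synthetic generator (`generate_helix()`, `generate_pair_trajectory()`)
builds ideal α-helices (1.5 Å rise, 3.6 residues/turn, 2.3 Å radius) with
configurable polynomial axis bend, sinusoidal "breathing" of the pair
separation, and Gaussian coordinate noise, providing exact ground truth for
every stage.

## Worked example

```r
library(groovegeom)

spec <- pair_trajectory_spec(
  helix_spec(30, bend_coeffs_y = c(0, 0, 0.002), seed = 1),
  helix_spec(30, bend_coeffs_y = c(0, 0, -0.0016), seed = 2),
  separation = 12, n_frames = 16, breathing_amplitude = 1.5,
  breathing_period = 8, frame_noise_sigma = 0.1, seed = 3)
traj <- generate_pair_trajectory(spec)

series <- analyze_degrees(traj, degrees = c(2, 3, 4))
summarize_geometry(series$m2)
#> <geometry_summary> m=2 over 16 frames
#>   time-averaged A: 522.97 A^2 (sd 46.97)
#>          pos1 pos369 pos737 pos1105 pos1471
#> min     9.774 10.937 11.132  10.509   9.002
#> q1     10.380 11.329 11.519  10.922   9.588
#> median 11.359 12.366 12.585  12.009  10.663
#> q3     12.403 13.412 13.618  13.053  11.680
#> max    12.929 13.871 14.063  13.500  12.258

compare_degrees(series, reference_degree = 2)
#> <degree_comparison> reference m=2
#>   m=2: A = 522.97 A^2 (+0.00%)
#>   m=3: A = 523.00 A^2 (+0.00%)
#>   m=4: A = 523.14 A^2 (+0.03%)

fit_breathing(series$m2$distance_series[, 3])[c("amplitude", "period")]
#> $amplitude
#> [1] 1.466941
#> $period
#> [1] 8
```

The five-number rows are boxplot statistics of the interhelical distance at
each probe position over the 16 frames: the groove here is widest near the
centre (position 737, median 12.6 Å) and narrowest at the flanks, and the
±1.5 Å breathing imposed by the generator is visible in the min–max spread
and is recovered from the central distance series (amplitude 1.47 Å — the
mid-helix separation oscillates slightly less than the centroid separation —
period exactly 8 frames).  The time-averaged area barely moves between
degrees 2 and 4 for this gently bent pair.

Real trajectories enter the same pipeline through multi-model PDB files:

```r
sels <- read_selection_config(system.file("extdata", "example_selection.yaml",
                                          package = "groovegeom"))
frames <- read_frames("trajectory.pdb", sels)
series <- analyze_degrees(frames)
```

A thin command-line wrapper ships in `inst/cli/groovegeom`
(`groovegeom simulate ...`, `groovegeom analyze --pdb ... --config ...`).

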