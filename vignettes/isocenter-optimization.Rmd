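---
title: "Choosing a single isocenter for multiple cranial targets under nonuniform setup margins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing a single isocenter for multiple cranial targets under nonuniform setup margins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomargin)
```

## The problem

In single-isocenter multi-target (SIMT) stereotactic radiosurgery, one
machine isocenter serves several brain metastases at once. Translational
setup error displaces every target identically, but a small residual
*rotation* about the isocenter displaces each target point in proportion to
its distance from the isocenter. A clinical target volume (CTV) far from
the isocenter therefore needs a thicker CTV-to-PTV margin than one nearby,
and the total volume of expanded margin shell -- healthy tissue that will be
irradiated to high dose -- depends on where the isocenter is placed. This
package measures that margin volume as a function of isocenter position and
finds the position that minimizes it.

## The margin model

Translational setup error is modelled as an isotropic 3-D Gaussian with SD
$\sigma_S$ (mm); the rotational error as independent per-axis Gaussian
rotations with SD $\sigma_D$ (degrees). A point at distance $d$ from the
isocenter is displaced by the rotation with an isotropic SD of

$$\sigma_R(d) = 0.816 \,\frac{\pi}{180}\, d\, \sigma_D \approx 0.01424\, d\, \sigma_D \ \mathrm{mm},$$

where the factor $0.816$ projects the three independent axis rotations onto
a net displacement. To cover the true point position with probability
$\alpha$, an isotropic SD is scaled by $\chi_\alpha = \sqrt{Q_{\chi^2_3}(\alpha)}$,
the square root of the $\alpha$-quantile of the chi-squared distribution with
three degrees of freedom ($\chi_{0.95} \approx 2.795$). The combined margin
at boundary point $i$ is the Pythagorean sum

$$M_i = \chi_\alpha \sqrt{\sigma_S^2 + \left(0.01424\, d_i\, \sigma_D\right)^2}
      = \sqrt{M_S^2 + M_{iR}^2},$$

with $M_S = \chi_\alpha \sigma_S$ the familiar uniform translational margin.
Both constants are computed at full float precision (`chi_alpha()`,
`rotational_sd()`); the printed three- and five-decimal values are their
roundings. The canonical stored parameter is $\sigma_S$; $M_S$ is a derived
view, so the two clinical parameterizations round-trip exactly.

The model is taken as given: we do not re-derive the coverage-probability
recipe, nor simulate patient shifts to verify it.

## The objective and its discretization

For an isocenter $\vec s_0$, the planning target volume (PTV) is the CTV
expanded nonuniformly: the union of the CTV with a ball of radius
$M_i(d_i)$ around every boundary sample $\vec s_i$. The objective is the
margin volume

$$V(\vec s_0) = V_\mathrm{PTV} - V_\mathrm{CTV},$$

minimized over $\vec s_0$. Union-of-balls expansion is chosen (rather than
offsetting along surface normals) because $M_i$ is the radius of the
isotropic coverage region of the *combined random displacement* at that
point; the displacement has no preferred direction, so the protected region
around a boundary point is a ball.

Volumes are measured by voxel counting on an isotropic lattice whose voxel
centers lie on integer multiples of the spacing. Alignment to this global
lattice means a structure's count does not depend on the bounding box used
by a particular evaluation. Membership is decided at the voxel center with
no partial-volume weighting. Spheres are rasterized analytically; closed
triangle meshes (OFF/ASCII-STL input) by ray-crossing parity along a
slightly skew ray that avoids grazing axis-aligned faces. Well-separated
targets are voxelized on their own local grids (a single global lattice for
targets 100 mm apart would be >90% empty); groups whose expanded bounding
boxes intersect share one grid so overlapping expansions are counted once.

Boundary samples are vertices of a subdivided icosahedron projected onto
the sphere: deterministic, quasi-uniform, and inversion-symmetric, which
makes mirror-symmetric phantoms produce exactly mirror-symmetric objective
values. The default density is the smallest subdivision level with at least
one sample per mm^2 of surface.

## Reference isocenters

The optimized position is benchmarked against the conventional candidates:
the center of geometry (unweighted mean of target centroids), center of
volume (centroids weighted by target volume $k_i$), and center of surface
(weighted by surface area $a_i$). All reported margin volumes are
normalized to the COG value evaluated on the same final grid.

## Optimizers

**Exhaustive grid search** (`grid_search_isocenter()`) scans a lattice over
the bounding box of the target centroids -- the documented solution space --
or, for two targets, the segment joining the two centroids, where the
optimum lies by rotational symmetry of the margin model about that axis.
Ties are broken deterministically by scan order.

**Adaptive simulated annealing** (`asa_optimize()`) is the fast global
optimizer for three or more targets, when the search space is genuinely
three-dimensional. It is a self-contained, seedable implementation of the
fast-annealing family: per-dimension generating temperatures follow
$T_k = T_0 e^{-c\,k^{1/D}}$; candidates are drawn from the heavy-tailed ASA
generating distribution; acceptance is Metropolis under a separately
annealed temperature; and every 50 accepted moves the per-dimension
annealing times are rescaled by finite-difference sensitivities of the
objective (reannealing), keeping flat directions exploratory. The search
starts from the COG. Identical seeds give bit-identical trajectories, and
the incumbent trace is monotone by construction.

## Two-stage resolution and the finalist band

Optimization uses 1 mm voxels; reported comparisons use 0.5 mm. The margin
volume of the smallest (5--6 mm) spheres carries discretization noise of a
few tenths of a percent at 0.5 mm and several percent at 1 mm, while the
objective's basin is extremely flat (a 20 mm shift can change the true
value by under 1%). Two consequences are handled explicitly:

* A coarse-grid argmin can sit many millimetres from the fine-grid argmin.
  The grid search therefore re-evaluates at the final resolution every
  candidate whose coarse value is within 5% of the coarse minimum, a band
  chosen to exceed the largest coarse-grid distortion we measure for the
  smallest targets (~4%), and returns the best finalist. The ASA optimum is
  polished the same way by a bounded Nelder--Mead pass on the fine grid.
* For congruent targets the continuum optimum is exactly the midpoint, but
  any discrete pipeline reports the minimum of a noisy symmetric curve, so
  the normalized optimum for equal spheres is 1 only to within the
  discretization noise (about 0.5% at 0.5 mm). Tests assert exact mirror
  symmetry of the sampled curve (a property the icosahedral sampling and
  aligned lattice preserve to float precision) and value-coincidence with
  the midpoint, rather than positional equality.

Halving the spacing from 0.5 to 0.25 mm changes margin volumes by under 1%
for the benchmark configurations; this is verified in the test suite.

## The phantom generator

`phantom_targets()` produces the sphere configurations used in every
simulation: two spheres 100 mm apart with diameters swept over
5--40 mm; three spheres at (100,0,0), (0,100,0), (0,0,100) mm; and a
six-sphere set with diameters 4--18 mm. The six-sphere centers
($\pm 60$ mm on each axis, separations 85--120 mm) are this package's own
choice of a skull-scale layout; only the diameters are prescribed by the
benchmark. Setup uncertainty for all benchmarks is $M_S = 2$ mm,
$\sigma_D \in \{0.5^\circ, 1.0^\circ\}$, $\alpha = 0.95$.

Spheres emulate the geometry of typical metastases but not their
irregularity: real contours have anisotropic extents, slice-wise sampling,
and occasionally concavities. Mesh targets are supported end-to-end
(volume, area and centroid by signed tetrahedra; rasterization by ray
casting), but the quantitative benchmarks in the tests are sphere-based, so
passing them demonstrates correctness of the model and machinery, not
agreement with any clinical dataset.

## Defaults that matter

| Parameter | Default | Why |
|---|---|---|
| `alpha` | 0.95 | conventional 95% coverage; $\chi_{0.95}=2.795$ |
| sampling density | 1 point / mm^2 | sag of the ball union between samples stays below ~0.04 mm for $M \ge 2$ mm |
| final spacing | 0.5 mm | ~1% volume accuracy for 5--40 mm targets |
| scan spacing | 1.0 mm | 8x cheaper; corrected by the finalist band |
| finalist band | 5% | upper-bounds measured coarse-grid distortion |
| ASA budget | 2000 evaluations, stop after 300 without improvement | converges in a few hundred evaluations on the benchmark scale |
| ASA $T_0$, $c$ | 1, 3 | temperatures are in box-width units; $c=3$ cools to sub-mm moves within ~150 accepted steps |
| search bounds | centroid bounding box, no padding | the documented solution space; optional `pad` for extreme size ratios |

## Worked example

```{r example, eval = FALSE}
ts <- phantom_targets("pair-6-15")
u <- setup_uncertainty(m_s = 2, sigma_d = 0.5)
opt <- grid_search_isocenter(ts, u, step = 1, spacing = 1, spacing_final = 0.5)
v_cog <- margin_volume(ts, center_of_geometry(ts), u, spacing = 0.5)$v_margin
100 * (1 - opt$v_margin / v_cog)  # percent reduction below the COG placement
```

## Known limitations

* The margin recipe assumes isotropic, independent Gaussian errors and
  small rotations; per-axis anisotropy and systematic/random decomposition
  (van Herk-style) are out of scope.
* Margin volume is the only criterion: organ-at-risk proximity, collision
  clearance and dose calculation are not modelled, so the reported optimum
  is a geometric, not a clinical, recommendation.
* Point clouds without connectivity are not accepted as targets; closed
  triangle meshes are required so that volume and area weights exist.
* Wall-clock performance depends on target size and spacing; the voxel
  engine is written in C++ and evaluates a benchmark-scale objective in
  tens of milliseconds at 1 mm.

## Problem sizes used by the tests

Unit and property tests run on low-subdivision spheres (42--162 boundary
samples) at 1--2 mm spacing so the whole suite stays in the minutes range;
the benchmark reproductions use the default density and the 1 mm / 0.5 mm
two-stage protocol exactly as described above.
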