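---
title: "Continuous flexibility in cryo-EM with Zernike3D deformation fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous flexibility in cryo-EM with Zernike3D deformation fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zflex)
```

## The model

Single-particle cryo-EM images a population of molecules that, for flexible
specimens, do not share one conformation. zflex describes the conformation
behind each observation as a smooth displacement field applied to a common
reference density $V$: the deformed map is $V(r + g(r))$, and the field is
expanded on the unit ball as

$$
g(r) \;=\; \sum_{l=0}^{L}\sum_{n}\sum_{m=-l}^{l}
\begin{pmatrix}\alpha^x_{l,n,m}\\ \alpha^y_{l,n,m}\\ \alpha^z_{l,n,m}\end{pmatrix}
Z_{l,n,m}(r),
\qquad
Z_{l,n,m}(r) = \bar R^1_{l,n}(\lVert r\rVert)\, y_l^m(\theta,\phi),
$$

where $\bar R^p_{l,n}$ are normalized generalized Zernike radial polynomials
(Jacobi form $R^p_{l,n}(x) = x^l P_n^{(0,\,l+p/2)}(2x^2-1)$, with
normalization $\sqrt2\sqrt{2n+l+p/2+1}$ giving unit $L^2(x^2\,dx)$ norm for
$p=1$) and $y_l^m$ are real spherical harmonics. The admissible indices
satisfy $l \le L$, $2n + l \le N$ and $|m|\le l$; for the default $N=3$,
$L=2$ this gives 13 triples, i.e. a 39-dimensional coefficient vector per
conformation. The basis is orthonormal on the unit ball, which the test
suite verifies by spectral quadrature, and which gives two exact shortcuts
used throughout: the deformation energy $\int \lVert g\rVert^2\,dV$ equals
the sum of squared coefficients, and rotating a coefficient set reduces to
one small rotation matrix per harmonic degree.

The admissibility rule deserves a note: enumerating the full printed lattice
$l\le L$, $n\le N$ would give 36 triples for the default truncation, while
the joint constraint $2n+l\le N$ — the natural degree bound of the
generalized Zernike family — gives exactly the 13 triples (39 components)
that one coefficient set is expected to carry. The package adopts the joint
constraint.

Coefficients in zflex are **dimensionless unit-ball displacements**; the
`scale_radius` field (Angstrom) maps the unit ball onto the physical box
(by default the inscribed ball, `box/2 * voxel_size`). One sign convention
is fixed package-wide: coefficients are the displacement added to the
*sampling* point of a gather warp, `out(r) = v(r + g(r))`. Density content
therefore moves by approximately $-g$, and functions that must co-deform
material points (atomic models tracking the density, the ZART back-warp)
negate the coefficients internally or via `negate_coefficients()`.

## Estimating a field from one particle image

A particle image $I$ with known pose $\theta$ and CTF $C$ constrains the
field through the forward model $C P_\theta\!\left(V(r+g(r))\right)$. The
estimator maximizes

$$
\rho\!\left(I,\; C P_\theta(V(r+g(r)))\right) \;-\;
\lambda_1 \int \lVert g(r)\rVert^2\, dr
$$

over the coefficients by Powell's conjugate-direction method from the
all-zero start (no deformation), with $\rho$ the Pearson correlation.
Two practical points:

* **Penalty units.** The penalty integral is evaluated with the field in
  voxel units of the estimation grid
  ($\lambda_1\, r_\mathrm{vox}^2 \sum \alpha^2$, with
  $r_\mathrm{vox}$ the unit-ball radius in voxels). Coefficients are
  resolution-dependent quantities — that is why they must be rescaled when
  moving between grids — and the recommended range
  $\lambda_1 \in [0.001, 0.01]$ refers to this scale. Evaluated on
  dimensionless coefficients the same range would be some two orders of
  magnitude too weak to regularize anything. The penalty is added with a
  minus sign: a bound-above correlation plus an unbounded positive
  deformation reward has no finite maximizer, so the anti-overfitting
  reading is the only coherent one.
* **Filtering and the working box.** Following standard practice the
  driver low-pass filters both sides of the correlation (raised-cosine
  cutoff at 0.4 Nyquist by default) and can Fourier-crop particles and
  reference to a working box (`box_work`); cropping preserves the physical
  box extent, so the dimensionless coefficients transfer to the full-size
  frame unchanged. `rescale_coefficients()` implements the exact scaling
  law $\alpha_o = k\,\alpha_d$ for grids whose physical scale genuinely
  differs.

Volume-to-volume estimation (`estimate_volume`) shares the objective but
correlates in 3D. Its defaults differ deliberately: a map constrains the
field with $\sim 10^5$ low-noise voxels rather than one noisy projection,
so the penalty is weaker (`lambda1 = 1e-4`) and the tolerance tighter
(`1e-6`, 8 sweeps) because informative gains sit in the fourth decimal of a
correlation already near 1.

### The unobservable subspace

Deformation along a particle's viewing axis cannot be inferred from that
image. `cancel_projection_component()` removes it by the closure route:
rotate the coefficients so the viewing direction becomes +Z (one exact
rotation in coefficient space), zero every z-component, rotate back. The
result satisfies $g(r)\cdot d = 0$ identically, is idempotent, and never
increases the deformation magnitude. The rotation matrices for the real
harmonics are obtained per degree by solving the exact linear relation
$y_l^m(A^{-1}u) = \sum_{m'} D_{mm'}\, y_l^{m'}(u)$ on a fixed
Fibonacci-sphere point set; the continuous-space closure oracle in the test
suite holds to $10^{-10}$. In continuous space the basis closes under
rotation exactly; through a voxel grid the same comparison picks up
interpolation error, which is why cancellation always happens in
coefficient space and only the final field touches the grid.

A caution that the test suite quantifies rather than hides: the axial
component is not the only unobservable one. Any part of the field that
varies along the viewing ray is first-order invisible in that projection —
a bending displacement $g_x \propto z$ seen down the z-axis only blurs the
image symmetrically, leaving even its sign undetermined. A single image
therefore supports reliable recovery of the ray-constant part of the
in-plane field, not the full 3D field; pointwise field errors against a
volumetric ground truth remain substantial per particle even with noiseless
data (a linearized least-squares oracle plateaus near 60% relative error on
the default scene). Per-particle coefficient sets should be read as a
noisy embedding of conformational state — which is how the landscape
machinery treats them — not as per-particle displacement maps. The
parameter-recovery test states the stricter pointwise criterion and reports
it as measured.

## Reconstruction: ART and ZART

`art_reconstruct` applies the classic per-image corrective update
$V \leftarrow V + \lambda P^{*}(I - C P V)$ over the shuffled particle set
(the corrective sign; the opposite sign diverges). The projector is
real-space — rotate the sampling grid, trilinear interpolation, sum — and
the backprojector is its exact transpose, so the adjoint identity holds to
machine precision by construction. The CTF enters the forward model and,
being a real even Fourier multiplier, is self-adjoint in the residual
backprojection.

`zart_reconstruct` threads each particle's deformation through the update:
project the warped reconstruction ($P \circ W_{g_k}$), backproject the
residual and map it back through the approximate inverse warp $W_{-g_k}$.
That back-warp is the adjoint of the deformed projector only to first order
in the field (the exact adjoint of a gather warp is a scatter with Jacobian
weighting); the dot-product test validates it at $10^{-2}$ relative in the
small-field regime and the mismatch grows linearly with the field's
divergence. With all-zero coefficient sets ZART reproduces ART bit for bit.
Defaults: $\lambda = 10^{-3}$, per-epoch decay 0.9, optional positivity
clamp.

## Landscapes

`assemble_landscape` flattens coefficient sets of any provenance
(particles, maps, models) into one table — the practical value of a shared
coefficient space is exactly that class averages, fitted maps and single
particles become comparable points. Distances are plain Euclidean on the
flattened vector, which by orthonormality is the $L^2$ distance between
fields. `cluster_representatives` runs KMeans (on raw coefficients, not on
an embedding) and returns the medoid of each cluster, so every
representative is a realized conformation that `synthesize_state` can turn
into a map (and co-deformed model) without any resampling of the
reference. `embed_2d` provides exact PCA as the tested path and UMAP via
uwot as the conventional visualization.

## The synthetic scene

All tests run on data from `make_phantom`/`make_dataset`, which realize
the forward model with the same operators used in estimation (a separate
brute-force ray-marching oracle guards the projector itself). The default
scene is a 48-voxel box at 1.5 Å/voxel containing three Gaussian domains,
each with four satellite Gaussians (15 blobs). The substructure matters: a
bare three-blob map leaves the deformation field unobservable over most of
the molecular mask — real macromolecules have internal features at many
scales, and a phantom without them understates what the method can see.
The stock ground-truth motion is a bending-like mode built from
$(l{=}1,n{=}0)$ and $(l{=}2,n{=}0)$ terms, scaled to a stated mean
displacement; heterogeneity laws are uniform (continuum) or two-cluster
Gaussian mixture (discrete states). SNR is defined as in-support signal
variance over noise variance, the support being pixels above 1% of the
clean image's maximum. What the passing tests do *not* show about real
data: structured noise, CTF estimation error, pose error, and molecules
whose motion leaves the span of a low-order basis.

Problem sizes in the routine suite were chosen to exercise every claim at
desk scale: parameter recovery uses 100 particles at SNR 0.5 on the default
scene (working box 32), the landscape analogue uses an 80-particle
two-state mixture plus volume-mode class maps, the blur-reduction analogue
uses 300 particles at SNR 2 with amplitudes uniform in $\pm 5\%$ of the box
radius, and the ART sanity run uses 200 noiseless projections of a
32-voxel phantom.

## Numerical choices and degenerate inputs

* Trilinear interpolation everywhere; out-of-box samples read 0; voxels
  outside the unit ball are never displaced. An all-zero coefficient set
  short-circuits to an exact copy, which underwrites the ZART/ART
  equivalence contract.
* The box centre (`floor(box/2)`, 0-based) is the rotation origin and ball
  centre on every grid; Euler angles are ZYZ intrinsic (RELION
  convention); in-plane shifts are applied as Fourier phase ramps
  (sub-pixel exact, exactly unitary, hence trivially adjointed).
* The CTF filter is symmetrized on the DFT grid: the astigmatic phase is
  not exactly even on the unpaired Nyquist lines of an even box, and the
  symmetrized filter is exactly real-to-real and self-adjoint.
* Powell line searches use Brent's method on a fixed bracket (±0.15 in
  coefficient units, tolerance 2×10⁻³); the optimizer never returns an
  objective below its start, and cancellation is applied after each sweep
  and to the final iterate.
* Degenerate inputs fail loudly: blank (constant) particles, empty masks,
  empty particle lists, non-cubic maps, mismatched coefficient tables and
  non-rotation matrices all raise errors naming the offence.

## Limitations

Per-particle pointwise field accuracy is bounded by the information
argument above; pose and CTF parameters are taken as given; the elastic
energy of the field is controlled only through the quadratic norm penalty;
warped atomic models get no stereochemical regularization — bonded
geometry is preserved only to the extent the field is smooth. Basis
truncations far beyond $N, L \approx 10$ would need numerically hardened
radial recurrences that this implementation does not attempt.
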