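---
title: "Volumetric CSD reconstruction: model, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric CSD reconstruction: model, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `vcsd`, the parameters a
user may want to touch, the numerical strategy, and what the synthetic
validation can and cannot establish about real recordings.

## The model and its assumptions

Under the quasi-static approximation, extracellular potential and current
source density (CSD) are related by the Poisson equation
$\nabla \cdot (\sigma \nabla \phi) = -C$. Discretizing the source volume
into $M = m_x \times m_y \times m_z$ cubic cells of side $d$ (point
current $I_j = C_j d^3$ at each node) and solving the forward problem for
each electrode gives the linear model $\Phi = G C$, where $G$ is the
$N \times M$ lead-field matrix of the chosen volume conductor.

Because source nodes far outnumber electrodes ($M \gg N$), the inverse is
rank-deficient. The package assumes that cortical current sources are
*spatially smooth over extended regions*, encoded by the discrete
Laplacian penalty $\lambda \lVert L C \rVert^2$ with
$L = (6/d^2)(W - E)$, $W_{ij} = 1/6$ at face-adjacent node pairs. Two
consequences of writing $L$ exactly this way:

* boundary rows keep fewer off-diagonal entries and are **not**
  renormalized, so the penalty also shrinks the solution toward zero on
  the grid boundary (the LORETA-style "minimal on the boundary"
  behavior);
* on a bounded grid $L$ is strictly nonsingular, which the solver
  exploits (below).

Guard planes — by default the outermost 3 node planes in $x$ and $y$ and
2 in $z$ — remain in the inverse as a free boundary that can absorb
currents from outside the recorded volume, but are excluded from every
reported metric. The symmetric 2/2 split of the four $z$ guard planes
between top and bottom is a package choice (the asymmetry is not
determined by anything in the problem) and is configurable per axis in
`build_grid()`.

Time enters nowhere: the estimator is applied independently per time
instant, and one factorization is reused across all instants at fixed
$\lambda$.

## Volume conductors

**InfH** (infinite, homogeneous, isotropic) has the closed-form kernel
$1/(4\pi\sigma r)$; default $\sigma = 0.3$ S/m, a standard order of
magnitude for gray matter.

**SphIh** models the cortex as concentric spherical shells, each with its
own radial and tangential conductivity, around an isotropic core and
inside an *unbounded* outer medium. The open outer boundary is a modeling
requirement, not a convenience: monopolar point sources have no steady
state inside a perfectly insulated sphere, so the region above the pia is
represented as a homogeneous medium of low conductivity (default
0.1 S/m) with the potential vanishing at infinity.

The shipped six-shell profile (`inst/extdata/sphih_profile.yaml`; pia at
4000 µm radius, shells for layers 1 through 6 plus a subcortical core,
conductivities 0.25–0.45 S/m with radial ≥ tangential) is **synthetic
and plausible, not measured**. Every validation experiment is
profile-agnostic — the same model is used for the forward projection and
the inversion — so conclusions do not depend on the particular numbers;
for interpretation of real data the profile should be replaced by
measured values via `read_conductor_profile()`.

Registration of the Cartesian ROI to the sphere: the ROI center axis
passes through the sphere center, depth $z$ maps to radius $R - z$, and
$(x, y)$ are chordal offsets perpendicular to the axis at that depth.
Points therefore keep their depth-derived radius exactly, at the cost of
a small tangential arc distortion ($\lesssim (x^2+y^2)/2R^2$, i.e.
below 1% over a ±600 µm footprint).

## Computing the layered-sphere kernel

For each Legendre order $n$, the radial factor of the potential solves a
two-point boundary-value problem: within a shell with anisotropy ratio
$\kappa = \sigma_t/\sigma_r$ the fundamental solutions are $r^{p}$ and
$r^{-(p+1)}$ with $p(p+1) = \kappa\, n(n+1)$. The solution regular at the
center and the solution decaying at infinity are propagated through the
interfaces (continuity of potential and radial current), and the source
enters through the Wronskian jump at the source radius. Numerical
choices:

* **Rescaling.** The state is renormalized at every interface and
  evaluation radius, with sub-steps inserted whenever
  $p \,\lvert \Delta \log r \rvert$ would exceed ~500, so arbitrarily
  high orders stay inside double-precision range.
* **Tail acceleration.** Electrode–node pairs at similar radii converge
  slowly (the terms decay like powers of the radius ratio, which
  approaches 1). After `max_terms` (default 512) series terms the
  remaining tail is fitted as a geometric sequence and summed in closed
  form through the Legendre generating function
  $\sum_n t^n P_n(u) = (1 - 2tu + t^2)^{-1/2}$. In the
  homogeneous-isotropic limit the coefficients are exactly geometric, so
  the accelerated series reproduces $1/(4\pi\sigma r)$ to machine
  precision — this limit is a test invariant. The correction is skipped
  when the estimated tail is below `series_tolerance` (default 1e-8)
  relative to the leading terms, where applying it would only amplify
  rounding error.
* **Failure mode.** If the fitted ratio exceeds 1 (terms still growing at
  the cap) a classed convergence error carrying the term count is
  raised rather than returning a silent partial sum.
* Radial coefficients depend only on the (few) unique radius pairs of a
  lattice geometry and are shared across all electrode–node pairs; the
  angular summation is the only $O(N M \cdot \text{terms})$ loop and runs
  in C++.

## Solving the inverse and choosing $\lambda$

The normal-equations form
$\hat C = (G'G + \lambda L'L)^{-1} G' \Phi$ is evaluated through the
push-through identity
$(G'G + \lambda B)^{-1} G' = B^{-1} G' (G B^{-1} G' + \lambda I)^{-1}$
with $B = L'L$, which is symmetric positive definite because $L$ is
nonsingular. One sparse Cholesky factorization of $B$ and one symmetric
eigendecomposition of the $N \times N$ kernel $G B^{-1} G'$ then give
solutions and GCV scores for *every* $\lambda$ and every time instant in
$O(N^2)$ each. This is algebraically identical to the dense expression
(the equivalence is asserted to 1e-8 in the test suite) and is what makes
$M = 25\,200$, $N = 128$ problems interactive.

* $\lambda = 0$ is accepted only if $G'G$ is numerically invertible
  (condition number below 1e12), which requires $M \le N$; otherwise a
  rank-deficiency error advises a positive $\lambda$.
* The default search grid is 40 log-spaced points spanning
  $[10^{-6}, 10^{4}] \times \mathrm{tr}(G'G)/\mathrm{tr}(L'L)$ — a
  scale-aware bracket around the point where data fit and penalty have
  equal magnitude. GCV ties break toward the larger (smoother) $\lambda$,
  a conservative choice under flat GCV valleys.
* With noiseless data GCV drives $\lambda$ to the bottom of the grid,
  approaching the minimum-seminorm solution; this is the expected
  inverse-crime behavior, not a defect.

## The approximate iCSD3D baseline

The comparison baseline parameterizes the CSD by one value per electrode
of a full equidistant lattice, with step (default) or trilinear basis
support of pitch-sized extent, assembles the $N \times N$ forward matrix
by fixed-order Gauss–Legendre quadrature (4³ points per cube) of the
homogeneous kernel, and inverts directly with **no regularization**. It
is labelled *approximate*: the published formulation uses 3D spline
bases, which are intentionally out of scope here, and all comparative
claims made with it are qualitative (orderings, not values). An
ill-conditioned forward matrix triggers a warning with the condition
estimate rather than an error, since amplified solutions are exactly the
phenomenon the noise sweep studies.

## What the synthetic data emulate — and what they do not

The generators reproduce the study conditions of the validation design:

* smooth charge-balanced (sinusoid × tangential Gaussian) and
  charge-unbalanced (Gaussian) phantoms; width parameter $l$ enters as
  $\exp(-\cdot/2l^2)$. For the mismatch experiment, which prints no
  source sizes, the package fixes small ($l = 150$, $T = 500$ µm) and
  large ($l = 300$, $T = 1000$ µm) variants — comparable to and a few
  times larger than the inter-electrode distance. The noise sweep fixes
  $l = 400$ µm.
* phantom centers drawn uniformly: over the middle two-thirds of the
  grid's depth extent (mismatch experiment; the depth range is otherwise
  unspecified) or over the whole non-guard ROI (noise sweep).
* channel noise i.i.d. Gaussian per channel and instant with variance
  $\beta \cdot \widehat{\mathrm{var}}(\Phi)$, the sample variance across
  channels at that instant, $\beta \in \{0.01, 0.05, 0.1, 0.5\}$.
* the noise × pitch sweep observes through the probe's own 4 × 4 × 8
  lattice format at 200–600 µm pitch (the layout for this sweep is a
  package choice), grid 24³ at $d = 50$ µm; the mismatch experiment uses
  the 9 × 9 × 15 / 100 µm array with a 16 × 16 × 28 / 50 µm grid; the
  barrel benchmark uses the 128-site probe with a 30 × 30 × 28 / 50 µm
  grid. The test suite runs the sweep at 5 trials per cell and the
  benchmark at 5 phantoms — sizes chosen so the whole suite stays
  desk-scale — while the experiment functions default to the full
  trial counts.

They deliberately do **not** emulate: correlated or 1/f physiological
noise, electrode impedance variation, tissue heterogeneity beyond the
radial shell structure, probe insertion artifacts, or histological
co-registration error. Passing phantoms therefore demonstrates that the
estimator, regularization and model-mismatch machinery behave as
designed — not that real-tissue reconstructions reach the same accuracy.
The synthetic barrel phantom (a cylindrical sink in a layer-4 depth
band, with its geometric footprint as the "anatomical" mask) stands in
for a cytochrome-oxidase-stained gold standard; it is labelled synthetic
everywhere it appears.

## Barrel localization conventions

Physiological sinks are *negative* CSD, while the max-normalization of
the thresholding step only makes sense on a sink-positive plane; the
pipeline (`localize_barrel()`) therefore flips the sign of the extracted
layer-4 plane before normalizing. Threshold selection minimizes the area
mismatch with the anatomical barrel exactly, by searching the sorted
unique plane values (the thresholded set is piecewise constant in
$\alpha$, so this is the exact argmin); ties break toward the larger
threshold. The localization error is the literal 2-norm ratio
$\lVert A - F(\alpha^*) \rVert_2 / \lVert A \rVert_2$, whose value for
fully disjoint equal-area barrels is $\sqrt 2$ — the error is *not*
rescaled into $[0, 1]$ even though perfect and disjoint are often
described as 0 and 1.

## Signal front-end conventions

* Band separation: LFP 1–500 Hz, unit 500 Hz–8 kHz, Butterworth order 4
  per section, applied zero-phase (forward–backward) so ERP latencies
  are preserved. Each filter is factored into exact second-order
  sections and channels are demeaned first: at a 1 Hz corner five
  decades below the 25 kHz sampling rate, the expanded-polynomial filter
  cannot null DC in double precision.
* ERP window: −50 ms to +100 ms around the stimulus (the window notation
  is read as pre/post bounds), averaging over all events.
* Spike detection: threshold −4 SD per channel (robust MAD estimator by
  flag), 1.5 ms dead time, trough = minimum within the dead-time window,
  20-sample snippets with the trough counted among the twelve posterior
  samples (eight prior). Spike classification is accepted from external
  tools as labels; only per-class averaging is done here.
* Spike-triggered averages are computed on whichever recording object is
  passed (wide-band or LFP-band) — an explicit caller choice rather than
  a hidden flag.

## Degenerate inputs and edge cases

Zero-variance potentials with $\beta > 0$, zero-energy truth in the
reconstruction error, empty anatomical masks, guard-plane extraction,
double average-referencing, electrode–node proximity below $d/10$, and
non-lattice arrays passed to the baseline all raise classed errors early
rather than propagating NaNs.

## Known limitations

* The shell profile is a placeholder; absolute SphIh potentials are only
  as good as the profile supplied.
* The spherical registration assumes the recorded volume is small
  relative to the sphere; strongly curved or non-spherical geometry is
  out of scope (no FEM conductor).
* The iCSD3D baseline is a step/trilinear approximation of the published
  spline method: ordering comparisons are meaningful, absolute baseline
  errors are not bit-comparable to the original.
* The Laplacian prior favors smooth sources; highly focal or
  discontinuous CSD (e.g. the hard-edged barrel phantom) is recovered
  blurred, which inflates area-matched localization thresholds under
  noise.
* Monopolar sources and a static conductor: no dipole bases, no
  frequency-dependent conductivity, no coupled-in-time priors.
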