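---
title: "Testing sparse 3D nuclear point patterns against spatial randomness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing sparse 3D nuclear point patterns against spatial randomness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Nuclear compartments such as PML nuclear bodies appear in fluorescence
microscopy as a handful of puncta per nucleus — typically 5 to 30 once the
image stack has been segmented and each body reduced to its centroid. A
routine question is whether these points show any spatial preference:
attraction to the nuclear periphery, to the centre, to the poles, or mutual
repulsion. The standard formalisation is a hypothesis test against complete
spatial randomness (CSR), the homogeneous Poisson process on the nuclear
volume. With so few points per nucleus, single-nucleus tests have little
power, and the obvious fixes — normalising distances and aggregating curves
across nuclei — interact badly with the substantial shape heterogeneity of
real nuclei. `spatnuc` implements the full simulation-and-testing machinery
needed to study this quantitatively: a synthetic-nucleus generator, thinned
point processes with known spatial preference, Monte-Carlo F-function
estimation, three envelope-test variants, the Spatial Distribution Index
(SDI) population test, and a power-study runner.

## Synthetic nuclei

A synthetic nucleus is a piecewise ellipsoid: eight ellipsoid fragments, one
per octant, glued so the surface is continuous. The octant containing a
point with coordinate signs $(s_x, s_y, s_z)$ uses semi-axes
$(a_{s_x}, b_{s_y}, c_{s_z})$, and the interior is

$$\left(\frac{x}{a_{s_x}}\right)^2 + \left(\frac{y}{b_{s_y}}\right)^2 +
  \left(\frac{z}{c_{s_z}}\right)^2 \le 1 .$$

Because fragments meeting at a coordinate plane share the two semi-axes of
that plane, this is the unique continuous piecewise-ellipsoid form. The
volume is the sum of eight ellipsoid octants,
$V = \tfrac{\pi}{6}(a_+ + a_-)(b_+ + b_-)(c_+ + c_-)$.

Four shape classes cover the qualitative range of adherent-cell nuclei: a
unit sphere; an ellipsoid extruded along the positive x-axis ($a_+ = 2$);
and both with the underside flattened ($c_- = 0.5$). Each class has a
*thick* variant and a *thin* variant with both $c$ semi-axes divided by 5,
matching the height-to-diameter ratio of flat fibroblast nuclei. Populations
are built by multiplying each of the six semi-axes independently by
$1 + \varepsilon$, $\varepsilon \sim N(0, \sigma^2)$ with $\sigma = 0.2$,
redrawing any factor at or below 0.2. The scale 0.2 produces visibly
variable but non-degenerate shapes; the floor is a pathology guard that in
practice fires on well under 1% of draws.

All coordinates are in dimensionless model units (the baseline sphere has
radius 1); user data in micrometres works identically since every statistic
is either unit-free or normalised by the region's maximum chord. Segmented
real nuclei enter as voxel masks (`mask_region()`, `read_mask_region()`)
with voxel-centre membership.

## Point processes

The null is CSR: uniform points in the region, drawn by rejection from the
bounding box (acceptance is exactly $\pi/6$ for every piecewise ellipsoid).
Alternatives with spatial preference are produced by thinning CSR proposals:
a candidate at feature distance $d$ is retained with probability
$e^{-kd}$. The three feature distances are

* **polar** — distance along the x-axis to the nearer of the two poles
  where the surface crosses the x-axis;
* **center** — Euclidean distance to the mean of the boundary surface
  (area-weighted boundary centroid, which differs from the volumetric
  centroid for flattened shapes);
* **boundary** — distance to the nearest boundary point.

$k = 0$ recovers CSR exactly; the studies use $k = 1$, which produces
preferences too weak to spot by eye — the regime in which test power
matters. Pattern sizes follow a Poisson law truncated to at least 5 points;
the quoted expected size is the mean of the truncated law itself (the
underlying rate is adjusted by root finding, a negligible correction for
means of 16 and above).

## The F-function and envelope tests

The empty-space function $F(r)$ of a pattern is the distribution function of
the distance from a uniform random location in the region to the nearest
pattern point. It is estimated by Monte Carlo: draw `n_ref` CSR reference
points (10,000 at full protocol) and record the fraction whose
nearest-pattern distance falls below each $r$ on a 100-point grid from 0 to
the region's maximum chord. No edge correction is applied; every test
compares the observed curve with CSR curves estimated in the *same* region,
so boundary effects cancel.

The individual envelope test builds 500 CSR realisations with the observed
pattern size, takes pointwise 2.5% and 97.5% empirical quantiles, and
rejects when the observed curve strictly exits the band. A curve *above*
the band means empty-space distances are shorter than CSR predicts — a
spread-out, regular pattern; a curve *below* means large empty gaps — a
clustered pattern. The tests with known generating processes confirm this
labelling (centre-clustered patterns exit below).

Two conventions matter numerically. Values exactly on a bound are not
exits. And grid points where the band has zero width — $r = 0$, and the
saturated tail where every null curve equals exactly 1 — are not scanned:
a degenerate empirical band carries no quantile information, and without
this rule the aggregate test rejects everything through differences of
order $10^{-4}$ against a zero-width band at saturation.

Pointwise bands scanned over ~100 correlated grid distances over-reject
globally: the test suite measures the global type-I error of the individual
test on CSR patterns and finds roughly a third of sparse (16-point) CSR
patterns rejecting, against the nominal 5% pointwise level. This inflation
is a known property of envelope procedures and is reported rather than
corrected; all power comparisons in the package are internally consistent
because every variant inherits it.

## Aggregation variants

For replicated nuclei, curves are made commensurate by dividing distances
by each region's maximum chord, putting every curve on $[0, 1]$ (values are
estimated directly on the scaled grid, so no interpolation error enters).
The *modified individual* test replaces each nucleus's own envelope with
quantiles of the normalised null curves pooled across nuclei — either
within a shape class or across all of them. The *aggregate-distance* test
averages the normalised observed curves into one population curve and
compares it against that same pooled null envelope. Because the pooled band
carries full between-nucleus and between-shape variation while an average
of 200 curves is far less variable, the aggregate test is deeply
conservative on heterogeneous collections — it fails to reject even
strongly non-CSR collections, which is precisely the methodological warning
the synthetic study quantifies. (A paired construction that averages one
fresh CSR realisation per nucleus into each null curve is available as
`null_aggregation = "round_mean"` for users who want a calibrated test of
the mean curve.)

## The Spatial Distribution Index

The SDI turns each nucleus into a single goodness-of-fit rank. Stage one:
estimate the mean CSR F-curve from 500 realisations with the observed
pattern size and compute $\delta_{obs}$, the signed difference
observed − mean evaluated where its absolute value is largest. Stage two:
compute the same dissimilarity for 500 further CSR realisations against the
same mean curve; the SDI is the fraction of them strictly below
$\delta_{obs}$. Under CSR the SDI is uniform on $[0, 1]$ (the suite checks
this by self-calibration), so a population of nuclei is tested with a
two-sided one-sample Kolmogorov–Smirnov test against uniformity — asymptotic
p-values by default, exact available for small collections. Keeping the
sign of the largest separation matters: centre-clustered patterns sit below
the CSR mean curve, get negative $\delta$, and pile up at low SDI. The
phrase "largest signed separation" could also be read as the supremum of
the signed difference; the two readings coincide whenever one curve
dominates, and the signed-value-at-argmax reading is the one that produces
the low-SDI concentration for clustered patterns.

## Numerical choices

* **Boundary geometry.** Each piecewise-ellipsoid region caches 2048
  boundary points on a deterministic Fibonacci direction lattice, weighted
  by the surface-area Jacobian. The boundary centroid is the weighted mean
  (deterministic, accurate to well below the Monte-Carlo error of random
  sampling). Vectorised boundary distances take the minimum of the
  distance to the cached samples (exact in the interior) and a first-order
  level-set estimate $(1 - f)f/|\nabla f|$ (exact on spheres, second-order
  accurate near any smooth piece); single-point calls refine by Nelder-Mead
  on the surface parametrisation to tolerance $10^{-10}$.
* **Maximum chord.** Exact axis-aligned candidates, the best pair among
  the cached samples, and a four-angle local refinement; scaled copies of a
  shape reproduce the chord linearly to $10^{-6}$.
* **Pattern sizes.** Truncated-Poisson rate calibrated by `uniroot` so the
  truncated mean equals the requested mean.
* **Strict ECDF.** $F$ values count distances strictly below $r$, so
  $F(0) = 0$ holds by construction; monotonicity and range are hard
  assertions on every curve.
* **Reproducibility.** Study runners derive one RNG stream per nucleus
  from the study seed, so any single nucleus can be recomputed without
  re-running the study, and results do not depend on evaluation order.

## Study sizes

The full protocol uses 10,000 reference points per F estimate and 500
realisations per envelope or SDI stage. The package's scaled mode — used by
the test suite and the acceptance script — uses 2,000 reference points and
200 realisations with the same 200-nucleus collections. At these sizes the Monte-Carlo error of a K-S statistic over
200 SDI values is dominated by the sampling of the 200 nuclei themselves
(sd about 0.06), not by the per-nucleus Monte Carlo, so scaled and full
protocols agree to well within that sampling error while running an order
of magnitude faster.

All stochastic checks in the test suite run at fixed, committed seeds. The
policy for a failing stochastic check is to diagnose it at that seed — a
seed is never re-rolled to turn a red check green, and tolerances encode
the comparison each check is meant to make, not the spread of any
particular run.

## What the generator does and does not emulate

The simulator reproduces the features that drive the methodological
problem: sparse patterns, truncated-Poisson counts, smooth convex-ish
boundaries with realistic height-to-width ratios, and strong between-nucleus
shape heterogeneity. It does not attempt nuclear texture, non-convex or
lobed boundaries, segmentation noise in the centroids, multiple compartment
types, or inter-point interactions (no Strauss/Gibbs processes). Passing
the synthetic study therefore demonstrates properties of the *tests* under
known truth; it does not certify any particular biological dataset, where
segmentation quality and boundary model fidelity add further uncertainty.

## Known limitations

* The pointwise envelope's global type-I inflation is reported, not
  corrected; a global rank envelope would be a natural extension.
* The vectorised boundary-distance path is approximate near octant seams
  (the surface is only $C^0$ there); errors are below $10^{-2}$ on
  unit-scale shapes and do not affect the polar or center processes.
* Voxel-mask regions use voxel-centre geometry throughout; sub-voxel
  accuracy would require a marching-cubes surface, which is out of scope.
* The K-S uniformity test treats per-nucleus SDI values as exchangeable;
  SDI ties from the finite (500-draw) rank transform are handled by the
  asymptotic test and are immaterial at population sizes of 50–200.

## A worked example

```{r, eval = FALSE}
library(spatnuc)
set.seed(1)

# one synthetic thin nucleus and a centre-clustered pattern
reg <- pe_region(perturb_params(shape_class_params("flat_sphere", "thin")))
pat <- sample_thinned(reg, "center", expected_n = 32)

# individual envelope test
obs <- estimate_F(pat, reg, n_ref = 2000)
env <- pointwise_envelope(null_F_curves(reg, nrow(pat), 200, n_ref = 2000))
glance(envelope_test(obs, env))

# population-level SDI study over 200 nuclei
coll <- build_collection("thin", n_per_class = 50, seed = 7)
study <- run_sdi_study(coll, "center", expected_n = 32,
                       n_reps = 200, n_ref = 2000, seed = 11)
glance(study)
autoplot(study)
```
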