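---
title: "Methods: outline shape variables, ordinations and the shared-Pmax question"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: outline shape variables, ordinations and the shared-Pmax question}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapevar)
```

## The question the package addresses

Multivariate ordinations are how morphometric differentiation between
populations is seen and interpreted. The three standard choices answer
subtly different questions:

* **PCA** eigen-analyzes the total variance-covariance matrix
  $\mathbf{T}$ and shows directions of maximal variance among all
  specimens;
* **bgPCA** eigen-analyzes the between-group matrix $\mathbf{B}$ (group
  means weighted by sample size) and shows maximal variance *among group
  means*, leaving within-group variance untouched;
* **CVA** eigen-analyzes $\mathbf{B}\mathbf{W}^{-1}$ and maximizes the
  between- to within-group variance *ratio* — it standardizes every
  direction by the within-group variance it carries.

When all groups share a pronounced direction of maximal within-group
variance — **Pmax**, the first eigenvector of a group's phenotypic
covariance matrix $\mathbf{P}$, a candidate "line of least resistance" to
evolution — the three pictures diverge systematically: PCA and bgPCA
emphasize divergence along Pmax, while CVA compresses exactly that
direction and pushes other, subtler contrasts to the front. `shapevar`
implements the full tool chain to quantify this: outline descriptors,
the three ordinations, a bootstrap test of Pmax sharing, Procrustes
(Protest) comparison of the resulting group-mean configurations, and a
simulation study that deletes the anisotropy and measures what changes.

## From outlines to shape variables

A specimen enters as a closed 2D contour (an `outline`). The
digitization chain (`outline_to_descriptor()`) is:

1. **Resampling** (`resample_equal_arclength()`): 64 points at equal
   steps of cumulative chord length. The contour is treated as a closed
   polygon with linear interpolation between vertices; no smoothing is
   applied.
2. **Orientation** (`efa_orient()`): an elliptic Fourier decomposition
   (`elliptic_fourier()`, exact Kuhl–Giardina integrals of the
   piecewise-linear contour) supplies the first-harmonic ellipse. The
   outline is rotated so this ellipse's major axis lies along $+x$ and
   re-indexed so the starting point sits where the contour meets that
   axis — the major elongation of the object. Seven harmonics are used
   here, matching the radial step. Of the two major-axis ends we keep
   the one whose full-harmonic reconstruction reaches the larger $x$
   after rotation, with ties resolved toward the input starting point;
   this makes orientation deterministic and insensitive to the
   digitization starting index. Outlines whose first-harmonic axis
   ratio is within `1e-6` of circular have no defined major axis and
   are returned unchanged with a warning. Contours are forced
   counterclockwise first so sine coefficients keep a consistent sign.
3. **Radial decomposition** (`radial_fourier()`): the distance
   $r_j$ of each of the $N$ points to the outline's center of gravity
   is expanded as $A_h = \frac{2}{N}\sum_j r_j \cos(2\pi h j/N)$,
   $B_h = \frac{2}{N}\sum_j r_j \sin(2\pi h j/N)$. The zero harmonic
   $a_0 = \bar r$ is proportional to size; dividing every coefficient
   by it leaves 14 dimensionless shape variables (7 harmonics × 2),
   rigorously invariant under uniform scaling. The $2/N$ normalization
   and the plain mean for $a_0$ are this package's documented
   conventions; any fixed alternative would rescale all variables
   jointly and leave every downstream percent-of-variance unchanged.

`inverse_radial_fourier()` rebuilds mean shapes for display by
evaluating the truncated series at equal *angular* steps. That is an
approximation of the arc-length parameter and is intended for figures
only; it is exact for the size term (coordinates are linear in $a_0$)
and warns if a reconstructed radius goes non-positive.

Note that the first-harmonic ellipse of the arc-length parameterization
is not the geometric ellipse: for a 2:1 ellipse its semi-axes are
≈ 1.83 and 1.07, not 2 and 1. Tests therefore validate the elliptic
coefficients against a dense numerical-integration oracle rather than
against naive axis lengths.

## Variance decomposition and the three ordinations

`variance_decomposition()` uses divisor $n$ for $\mathbf{T}$ and
$\mathbf{B}$, with the grand mean taken over specimens (equivalently the
sample-size-weighted mean of group means), so $\mathbf{T} =
\mathbf{B} + \mathbf{W}$ holds to floating-point accuracy and is
asserted by the test suite on every random input. CVA standardizes by
the *pooled* within-group covariance with divisor $n - g$, the
discriminant-analysis convention. Percent-of-variance outputs are
invariant to these divisor choices.

`cva()` solves the generalized eigenproblem by whitening:
$\mathbf{W}_p = U\Lambda U'$, data mapped by $U\Lambda^{-1/2}U'$, the
mapped $\mathbf{B}$ eigen-analyzed. Canonical scores then have unit
pooled within-group variance per axis. Reported percentages are the
eigenvalues of $\mathbf{B}\mathbf{W}_p^{-1}$ (the discriminant roots)
over their sum. An alternative scale in circulation reports canonical
eigenvalues of $\mathbf{B}$ relative to $\mathbf{T}$, i.e.
$\mu/(1+\mu)$ after rescaling; the test suite verifies the exact
algebraic correspondence between the two against an independent
implementation, so either can be derived from the returned eigenvalues.

Degenerate inputs fail loudly rather than silently: CVA refuses to run
when $n - g < p$ or when the within-group matrix's smallest relative
eigenvalue is below $10^{-10}$ (advice: reduce dimensionality first —
with Fourier variables, drop harmonics). Eigenvector signs follow one
convention everywhere: per axis, the largest-magnitude loading is
positive. Eigenvalue ties keep the decomposition's native order.

`pcoa()` embeds a distance matrix by Gower double-centering (via
`stats::cmdscale`). Negative eigenvalues (non-Euclidean inputs) are
reported through a warning with their total mass and dropped; no
Cailliez or Lingoes correction is applied, so what is analyzed is the
metric part of the supplied matrix, not an adjusted relative.

## Pmax and its bootstrap comparison

`estimate_pmax()` returns the first eigenvector of a group's covariance
matrix. Below 30 specimens a warning flags the estimate as fragile;
three specimens is the hard floor. `bootstrap_pmax()` resamples the
group with replacement (100 replicates by default), re-estimates Pmax
each time, and records the correlation of each bootstrap estimate with
the original. The 5th percentile of that distribution, $r_{95}$, bounds
the correlation loss attributable to estimation noise alone; the bound
is one-sided because only *low* correlations can indicate disagreement.
`compare_pmax()` then declares two groups' Pmax distinguishable only if
their between-group correlation falls below the smaller (looser) of the
two $r_{95}$ values — the less robustly estimated group governs.

The correlation between eigenvectors is the absolute Pearson
correlation of the loading sequences by default, with the absolute
cosine available via `method = "cosine"`. The two differ unless
loadings are centered; Pearson is degenerate for near-constant loading
vectors (it centers them first), which the cosine is not — a reason to
switch methods when a Pmax loads almost evenly on all variables.

## Protest

`procrustes_statistic()` centers both group-mean configurations, scales
each to unit total sum of squares, and finds the optimal orthogonal
superimposition (rotations *and* reflections) by singular value
decomposition: $d = 1 - (\sum_k \sigma_k)^2$, $r = \sqrt{1 - d}$. Rows
are matched by group label, never by order, and configurations of
unequal axis counts are zero-padded after a warning (a method with
fewer non-null axes than requested — e.g. bgPCA with few groups — still
yields a comparable 4-axis configuration). `protest()` permutes the
rows of one configuration (999 times by default) and reports
$p = (\#\{d_{perm} \le d_{obs}\} + 1)/(n_{perm} + 1)$; ties count
against significance, and the smallest attainable $p$ is
$1/(n_{perm}+1)$. The statistic is symmetric in its arguments and
invariant to similarity transforms of either configuration; the
identity $r = \sqrt{1-d}$ holds by construction. (Literature labels for
this correlation vary, up to calling it a squared quantity; in this
package `r` always means $\sqrt{1-d}$.)

## The homogenized-variance simulation

`simulation_study()` asks: how much of the disagreement between
ordination pictures is caused by the orientation of within-group
variance? It keeps each group's observed mean vector and sample size
but replaces its covariance with $\sigma^2 I$ — exactly isotropic, no
sampled covariance structure — where $\sigma^2$ is the mean over groups
of the geometric mean of the per-variable within-group variances
(divisor $n_i - 1$; a zero variance anywhere is an error naming the
group and variable). Each of the 999 replicates re-runs PCA, bgPCA and
CVA and records the three pairwise Procrustes distances; the observed
distances are located within these null distributions
(`observed_quantile`). An observed bgPCA–CVA distance in the far upper
tail, with PCA–bgPCA inside its null, is the signature of shared
anisotropic within-group variance reshaping the CVA picture.

Reproducibility uses one root seed: replicate $r$ draws from a derived
sub-stream (`(seed + 48271·r) mod (2^31 - 1)`), so any single replicate
can be regenerated in isolation. The study runs on all groups of the
input by default; a `groups` argument restricts it to a subset (e.g.
only densely sampled populations), and both the full-set and subset
readings of "observed" distances are therefore available.

## The synthetic generator: what it emulates and what it does not

`generate_grouped_shapes()` draws multinormal groups sharing one
covariance $V\,\mathrm{diag}(\lambda)\,V'$ whose leading eigenvector is
a configurable shared Pmax. Defaults were fixed once, as the package's
reference conditions: $p = 14$ variables; seven groups with sizes
68/13/15/7/18/14/14 mirroring a realistic continental sampling design;
anisotropy $\lambda_1/\lambda_2 = 10$ (a strongly but not implausibly
oriented $\mathbf{P}$); residual spectrum decaying geometrically with
ratio 0.7, a typical eigenvalue profile for size-standardized Fourier
coefficients; and a smooth fixed Pmax direction weighting low harmonics
most. `island_config()` displaces group means along Pmax only, spread
over ±1.5 within-group standard deviations in that direction, so
between-group and within-group variance along the line of least
resistance are comparable; `clade_config()` displaces means along one
fixed orthogonal axis instead, small in absolute terms but large
relative to the within-group variance it meets.

The generator emulates the *covariance geometry* of real data — shared
Pmax, its anisotropy, mean displacement along or across it — and
deliberately nothing else. Real datasets also carry non-Gaussian
variation, group-specific covariance differences, measurement and
wear-related error, and allometric residuals; none of these are
simulated. Tests passing on synthetic data therefore validate the
algebra and the statistical mechanics of the methods, not the
biological conclusions one would draw from any particular empirical
dataset.

## Problem sizes and numerical tolerances

The test suite exercises the full design at the package's reference
conditions: the simulation signature is checked with 999 replicates on
7 × 40 specimens and 14 variables, Protest calibration with 200 null
replicates of 199 permutations, and Pmax recovery with 100 groups of
200 specimens. Unit tests use smaller fixtures. Key tolerances:
$T = B + W$ to $10^{-10}$ relative; CVA invariance under random
invertible variable maps to $10^{-8}$; agreement of coefficients with
brute-force oracles to $10^{-12}$; scale invariance of radial
coefficients to $10^{-12}$; bgPCA/CVA eigenstructure against an
independent implementation to $10^{-8}$.

## Known limitations

* Outline input assumes an already-extracted, ordered contour; image
  segmentation, landmark methods and wear scoring are out of scope.
* The radial descriptor requires the centroid to see the whole contour
  (star-shaped outlines); strongly re-entrant shapes violate the
  method's premise and surface as degenerate-reconstruction warnings.
* `pcoa()` does not correct non-Euclidean distance matrices.
* The Pmax bootstrap quantifies estimation noise, not biological
  equivalence: "not distinguishable" is a failure to reject, and is
  sensitive to the correlation flavor chosen for near-constant
  loadings.
* No significance testing of group separation (MANOVA) or
  classification-rate machinery is included; the package compares
  *pictures* of differentiation, not discriminatory power.
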