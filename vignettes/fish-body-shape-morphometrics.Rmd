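---
title: "3D landmark morphometrics of fish body shape: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3D landmark morphometrics of fish body shape: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finmorph)
```

## The analysis in one paragraph

`finmorph` analyses adult fish body shape from configurations of homologous
3D landmarks, one configuration per specimen. The default scheme has eleven
landmarks — tip of snout, left/right eyes, left/right pectoral (P1) and
pelvic (P2) fin insertions, the dorsal-fin (DF) and anal-fin (AF) anterior
insertions, and the left/right posterior hypural margins — digitised on 3D
surface models and exported as 3D Slicer markups fiducial (`.fcsv`) files.
Generalized Procrustes Analysis (GPA) removes position, size and orientation;
principal component analysis (PCA) of the aligned coordinates yields a
metric morphospace; a variance-weighted eigenvector-magnitude table
quantifies how much each landmark contributes to each shape axis; and a
per-axis variance sum decomposes total shape disparity into its
anteroposterior (length), dorsoventral (depth) and mediolateral (width)
anatomical components. A synthetic fauna generator with known ground truth
exercises the whole pipeline at desk scale.

## Generalized Procrustes Analysis

Each configuration is a $p \times 3$ matrix $X$. Its centroid size is
$CS(X) = \sqrt{\sum_l \lVert x_l - \bar{x} \rVert^2}$, the root summed
squared distance of the landmarks from their centroid. GPA (`gpa()`):

1. centres every configuration at the origin and scales it to unit centroid
   size;
2. initialises the consensus as the first configuration (dataset order);
3. rotates every configuration onto the consensus with the proper-rotation
   Kabsch solution (SVD of the cross-product matrix, smallest singular
   direction sign-corrected so $\det R = +1$);
4. re-estimates the consensus as the arithmetic mean of the rotated
   configurations, rescaled to unit centroid size;
5. repeats 3–4 until the Procrustes distance between successive consensus
   estimates falls below `tolerance` (default `1e-8`, `max_iterations = 100`).

Reflections are excluded deliberately: left and right landmarks are
digitised explicitly, so a mirror alignment would be anatomically wrong. The
summed squared distance of the configurations to their mean is
non-increasing across iterations (recorded in `objective_trace`), and on
tiny instances the fixed point coincides with a brute-force joint
minimisation over all per-specimen rotations (checked in the tests to
`1e-6`).

**Canonical output orientation.** The converged shape space is only defined
up to one global rotation, inherited from whatever pose the first specimen
happened to be digitised in. `gpa()` therefore finishes by rotating the
whole sample so the consensus sits in its principal-axes frame, ordered by
decreasing extent. For fish-like configurations this is anatomically
meaningful, because body length exceeds depth, which exceeds width: axis 1
is anteroposterior, axis 2 dorsoventral, axis 3 mediolateral. Axis signs are
fixed by the skewness of the consensus coordinates along each axis (falling
back to making the largest-magnitude coordinate positive when the skewness
vanishes, as it does exactly for the mirror-symmetric mediolateral axis,
whose sign is then forced by $\det = +1$). This makes results deterministic
and independent of specimen pose, which the tests rely on: without it,
neither "the consensus is insensitive to input order" nor any anatomical
reading of the per-axis variance sums would be well defined. `orient =
"first"` disables the step.

**Tangent-space projection** is available (`tangent = TRUE`) but off by
default; plain Procrustes coordinates feed the PCA, matching the upstream
convention of the morphometrics toolchains this package interoperates with.
At the dispersions relevant here the difference is far below every
tolerance used.

## The morphospace

`fit_pca()` eigendecomposes the covariance matrix of the flattened aligned
coordinates (landmark-major order), centred at their sample mean. It is a
covariance PCA, never a correlation PCA: Procrustes coordinates share one
scale, and rescaling per coordinate would destroy the metric property of
the morphospace. All $3p$ components are kept; `K_retained` is the smallest
number of leading components reaching 95% cumulative variance
(configurable), echoing the usual reporting convention for such analyses.
Each eigenvector is oriented so its largest-magnitude entry is positive
(ties towards the lowest index), making loadings reproducible across
numerical backends.

Because seven degrees of freedom (three translations, one size, three
rotations) are removed, the aligned data occupy at most $3p - 7$
dimensions. The translation constraints are exactly linear; unit size and
rotation fit are constraints on a curved manifold, so the trailing
eigenvalues vanish only to second order in the shape dispersion. The test
asserting the $3p-7$ rank therefore uses a small-dispersion sample
(landmark noise sd $10^{-6}$ at unit centroid size, $n = 40 > 3p$), the
regime in which the linearised statement is exact.

Species-level scores are arithmetic means of specimen scores (equivalently,
by linearity, scores of species-mean shapes). `nearest_to_mean()` reports
the specimen or species of minimal Euclidean norm in retained score space —
the taxon that best approximates the fauna's mean body shape — with ties
broken by dataset order under a warning. `centroid_outlier_score()` is the
sum over components of the variance fraction times the absolute score; by
default it uses all retained components, since the quantity is described as
a sum over all the weighted PC values; `K_use` exposes the choice.
`shape_at_pc()` generates configurations along a component about the score
origin (the arithmetic mean of the aligned configurations, which differs
from the unit-rescaled consensus only by a pure scale factor of order the
total shape variance); displacements can be given in Procrustes units or in
standard deviations along the axis. Minimum convex hulls of species means
per nested clade group (`group_occupancy()`) quantify morphospace
occupancy; degenerate groups (one point, collinear species) return the
point or segment with zero area.

## Landmark contributions and the axis decomposition

The contribution analysis weights each unit eigenvector by the proportion
of variance its component explains, and summarises each landmark by the 3D
magnitude of its weighted eigenvector block:

$$m_{lk} = w_k \sqrt{e_k[l,1]^2 + e_k[l,2]^2 + e_k[l,3]^2}, \qquad
  w_k = \lambda_k / \textstyle\sum_j \lambda_j .$$

Two normalisations matter and both are checked as invariants. First, the
weights $w_k$ are proportions (0.511), not percentages (51.1): with a unit
eigenvector split into $p$ blocks, the column sum $\sum_l m_{lk}$ must lie
in $[w_k, w_k\sqrt{p}]$ by Cauchy–Schwarz, and published tables of this
form are consistent with that band only under the proportion convention.
Second, $w_k$ is taken over the full decomposition (all nonzero
components), because "variance explained by a component" is a property of
the whole spectrum, while the landmark-level percentage
$N_l = 100 \sum_k m_{lk} / \sum_{l,k} m_{lk}$ normalises over the displayed
top-$K$ columns only — that is how a displayed table's Sum and Norm columns
relate. `landmark_totals()` and `group_fraction()` accept any non-negative
magnitude matrix, so a published table can be fed straight in; the package
ships one such reference table for Lower Mississippi Basin fishes
(`lmb_magnitude_table()`) as a worked example.

The axis decomposition sums, for each coordinate axis $d$, the per-landmark
sample variances of the aligned coordinate $(l, d)$ over specimens, and
reports the three sums under the anatomical role each axis plays
(length/depth/width). It is computed from the raw aligned coordinates,
i.e. over all components; an algebraically identical eigen-route
$V_d = \sum_k \lambda_k \sum_l e_k[l,d]^2$ is implemented and the identity
is asserted to $10^{-9}$, and that route also allows restricting to the
leading $K$ components, since published figures of this kind do not always
state which convention they use.

Reports (`render_contribution_report()`) round magnitudes to 3 decimals and
percentages to 2, rank rows by total magnitude, and round-trip through the
package's readers.

## The synthetic fauna generator

`generate_fauna()` draws species $s$ of group $g$ with mode amplitudes
$a_{sm} \sim \mathcal{N}(\mu_{gm}, \sigma_m)$ and builds specimens as

$$X_i = T + \sum_m a_{sm} M_m + \varepsilon_i,$$

with a template $T$, unit-norm orthogonal displacement fields $M_m$, iid
landmark noise $\varepsilon_i$, and (optionally) an arbitrary proper
rotation, translation, and positive scale per specimen, the scale
log-uniform in $[0.5, 2]$ to avoid degenerate centroid sizes. Random-number
streams are split per species and per specimen, so changing
`specimens_per_species` never perturbs the species-level draws. A fixed
seed gives byte-identical output.

**Template.** An idealised fusiform fish with standard length 1.0, dorsal-
and pelvic-fin insertions vertically aligned near midbody, dorsal-fin
insertion depth 25% of standard length, a head of roughly 30% standard
length, and bilateral pairs mirrored across the midsagittal plane — the
plesiomorphic teleost proportions that temperate freshwater faunas centre
on.

**Modes are tangent-space fields.** Each raw field (elongation of the fin
landmarks along the body axis; deepening of the DF/AF/P2 insertions;
mirror-antisymmetric widening; snout/eye displacement for relative head
size) is projected orthogonal to the similarity group at the template —
translations, the scale direction, and the three rotation generators —
inside an axis- and landmark-restricted subspace, then the set is
Gram–Schmidt orthonormalised. This is not cosmetic: a displacement field
with a component inside the similarity group is partially absorbed by the
translation/scale/rotation steps of GPA (a naive uniform "elongation" is
mostly a size change, and a naive "deepening" has a large component along
the scale direction), which would bias every recovery test. The
restrictions keep the fields interpretable: widening is exactly
mediolateral, deepening exactly dorsoventral.

**Defaults.** Four nested clade groups with (12, 84, 55, 15) species — 166
species total, the size of the fauna this package's reference table comes
from; the per-group split is not published and was fixed once to echo that
fauna's composition narrative. One specimen per species by default
(`specimens_per_species` raises it). Mode dispersions (0.072, 0.040, 0.037,
0.025) were fixed once so the leading shape axes carry variance shares
comparable to those reported for fish faunas (roughly 59/18/16/7% across
the four modes). Landmark noise sd 0.005 (half a percent of standard
length, a plausible digitising error). Group offsets default to zero;
occupancy experiments pass explicit offsets.

**What the generator does not emulate.** Modes are axis-pure by design, so
synthetic faunas do not reproduce the empirical pattern in which depth
variance dominates total disparity while loading across several mixed-axis
components — real growth fields mix anatomical axes. It also does not model
photogrammetric error structure, preservation artifacts (bending), or
tree-based trait evolution; species are exchangeable within groups.
Passing recovery tests therefore demonstrates the correctness of the
superimposition, decomposition and bookkeeping — not that real fish data
satisfy the generator's additive, Gaussian, axis-pure assumptions.

## Numerical choices and regimes

- GPA tolerance `1e-8` on the consensus change, cap 100 iterations;
  convergence is typically reached in 3–6 iterations.
- Rank-deficient rotation problems (collinear configurations) return one
  minimiser with a warning.
- Missing or mislabelled landmarks are hard errors naming the specimen and
  labels, never imputed — taxa lacking homologous fin landmarks are
  excluded via the manifest's `excluded` group instead.
- fcsv files declaring LPS (or the legacy numeric `0`) have their first two
  coordinate columns negated to the RAS-like internal convention; applying
  the conversion twice is the identity. The coordinate columns themselves
  are never permuted; a scheme's `axis_roles` records which anatomical role
  each column plays, and after principal-axes orientation the aligned
  columns are anteroposterior / dorsoventral / mediolateral.
- Several recovery statements are linearisations, exact only for small
  dispersion relative to the curvature of the unit-size shape sphere: the
  per-landmark loading-norm recovery test runs at amplitude sd $10^{-5}$
  (absolute agreement to $10^{-6}$), the single-mode variance-concentration
  tests at amplitude sd 0.03, where the quadratic leakage
  $\approx (\sigma/\lVert T\rVert)^2/2 \approx 4\times10^{-4}$ stays below
  the 0.999 thresholds.
- The four-mode variance-share recovery runs at $n = 2000$ species so that
  the amplitude-sampling error ($\approx\sqrt{2/n} \approx 3\%$) sits well
  below the 10% recovery tolerance; at a few hundred species the tolerance
  would mostly measure sampling noise of the generator itself, not the
  method. The isotropic-noise axis check also uses $n = 2000$; the small
  residual anisotropy it tolerates ($\pm 0.03$ about $1/3$) is real, not
  sampling error: removing seven similarity degrees of freedom takes
  slightly different variance shares from each axis depending on the
  template's geometry.
- Problem sizes throughout the suite (tens to a couple of thousand
  specimens, $p = 11$) keep the full test run and the acceptance script in
  the tens of seconds.

## Known limitations

- The canonical orientation assumes the three principal extents of the
  consensus are distinct (true for fish bodies); near-spherical consensus
  shapes would make the axis ordering unstable.
- Axis-role interpretation of the aligned columns relies on the
  length > depth > width ordering of fish bodies.
- No weighted or robust Procrustes variants, no sliding semilandmarks, and
  no phylogenetically-corrected ordination — fixed homologous landmarks
  only, matching the analysis this package operationalises.
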