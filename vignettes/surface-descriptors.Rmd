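---
title: "Surface descriptors and interpretable HAC-protein classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface descriptors and interpretable HAC-protein classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, numerical methods and design choices
behind `hacsurf`: what each surface descriptor measures, how it is
estimated, which parameters matter, and what the synthetic-data module
does and does not emulate.

## The problem and the model

Highly abundant cytoplasmic (HAC) proteins live in a densely crowded
environment; their solvent-exposed surfaces are expected to differ
systematically from those of extracellular proteins.  The package frames
this as a binary classification problem (HAC = 1, extracellular = 0) over
ten per-protein surface descriptors and reads feature importance from an
unpenalized logistic model

$$\ln\frac{P}{1-P} = \beta_0 + \sum_i \beta_i x_i,$$

fitted by maximum likelihood (IRLS, log-likelihood tolerance $10^{-8}$,
at most 100 iterations).  Standard errors come from the inverse observed
Fisher information; odds ratios are $e^{\beta_i}$ with 95% Wald intervals
$e^{\beta_i \pm 1.96\,SE_i}$.  Because Wald inference requires the
unpenalized MLE, the inference fit is always $\lambda = 0$; the
model-comparison logistic learner may tune a small ridge penalty in its
grid, and the two fits are kept distinct.  Complete separation is
detected (diverging coefficient norm, or a perfect fit with a large norm)
and reported as an error rather than silently returning meaningless
standard errors.

## Structures and inclusion filters

Input structures are AlphaFold-dialect PDB files: one model, one chain,
per-residue confidence (pLDDT, 0-100) stored in the B-factor column.
Parsing is delegated to `bio3d`; on top of it the package validates the
dialect (pLDDT clamped to [0, 100] with a warning, per-residue value read
from the CA atom when atoms disagree, multiple chains concatenated with a
warning) and ignores HETATM records.  A structure enters the analysis if
its modelled length is 100-700 residues and its mean pLDDT is strictly
above 50; below that threshold a model is expected to be largely
intrinsically disordered.  "Sequence length" is operationalized as the
modelled residue count — predicted models are full length, so the two
coincide.  Hydrogens, when present, are kept in the structure but
excluded from all surface computations; nonstandard residues are kept for
geometry but excluded from residue-type-keyed descriptors.

## Solvent-accessible surface and the surface mask

SASA uses the Shrake-Rupley construction with a deterministic
golden-spiral lattice (default 960 points per atom) instead of random
sampling, so results are exactly reproducible and the isolated-sphere
closed form $4\pi(r+r_p)^2$ is recovered without sampling error.  Default
van der Waals radii are C 1.70, N 1.55, O 1.52, S 1.80 Å and the probe is
1.4 Å — the conventional water-molecule radius, which the source analysis
implies but never states numerically.  Because any fixed lattice breaks
rotational symmetry, coordinates are first rotated into a canonical frame
(principal axes of the atom cloud, signs fixed by third moments), which
makes SASA, SES and volume invariant under rigid motions of the input to
floating-point accuracy.

A residue is a *surface residue* when its SASA is at least 30% of the
maximum SASA of its type in a Gly-X-Gly tripeptide.  The denominator is
the published theoretical maximum-ASA table (Tien et al. 2013), shipped
as a data file; a `computed` mode builds an extended Gly-X-Gly tripeptide
and measures it directly, but since synthetic side chains are single CB
pseudo-atoms this mode underestimates long side chains and serves only as
a geometric cross-check.

## Solvent-excluded surface, volume and roughness

The SES (Connolly surface) bounds the volume inaccessible to the probe:
the morphological closing of the van der Waals envelope by the probe
sphere.  The estimator works on a voxel grid (default 0.5 Å):

1. the exact signed distance $d(x)$ to the union of atom spheres is
   evaluated at voxel centres;
2. free voxels near the boundary of the allowed probe-centre region
   $\{d \ge p\}$ carry margin balls $B(y,\, d(y)-p)$ that lie exactly
   inside the region ( $d$ is 1-Lipschitz with unit gradient), and the
   distance field $F(x) = \min_y (|x-y| - m(y))$ reconstructs the
   distance to the region with $O(h^2)$ accuracy;
3. the SES is the iso-surface $\{F = p\}$, and its area is integrated by
   a smoothed-delta (co-area) estimator whose kernel has a vanishing
   second moment, cancelling the leading curvature bias.  The kernel
   half-width is $\min(2h,\, 0.75p)$ so the stencil never touches the
   free region.

On a single atom (where the SES is the atom's own sphere, independent of
the probe) the estimator is accurate to a few percent at the default
voxel and converges as the voxel shrinks; the corresponding tests compare
fused-sphere configurations against an independent Monte-Carlo shell
oracle built on the exact two-sphere distance geometry.

Roughness is the fractal dimension estimated from the probe sweep
$R = 1.0, 1.2, \ldots, 3.6$ Å (14 areas):

$$D_i = 2 - \frac{\log A_i - \log A_{i-1}}{\log R_i - \log R_{i-1}},
\qquad FD = \frac{1}{13}\sum_i D_i .$$

Logs are base 10; any base cancels in the ratio.  The first difference
uses the pair (1.0, 1.2) and the endpoints are inclusive, giving exactly
13 terms.  A smooth sphere gives $FD = 2$; realistic structures fall in
[2, 3].  The protein volume (denominator of the exposure degree
`s_sf`) integrates the vdW envelope with a smoothed-Heaviside count on
the same grid, second-order accurate in the voxel size.

## Secondary structure

Assignment is a simplified Kabsch-Sander: amide hydrogens are rebuilt on
each nitrogen 1.0 Å along the preceding C=O direction, the electrostatic
hydrogen-bond energy
$E = 0.084 \cdot 332\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
kcal/mol is thresholded at $-0.5$, two consecutive $n \to n{+}k$ turns
($k = 3, 4, 5$) mark helices (3₁₀ and π folded into `H`), and the
parallel/antiparallel bridge patterns mark beta structure (`E`);
everything else, including residues with incomplete backbones, is `L`.
The original analysis used a molecular viewer's assignment, which cannot
be reproduced bit-exactly; a published, geometry-only criterion that
provably labels ideal helix and hairpin fixtures correctly was chosen
instead.  "Disordered region" is operationalized as the loop label `L`;
an alternative reading (low-pLDDT segments) exists, and the package does
not assert which the original authors meant.

## Pseudo-B-factors and charge

pLDDT maps to a positional error estimate
$\Delta = 1.5\,e^{4(0.5 - \mathrm{pLDDT}/100)}$ Å and then to a
Debye-Waller pseudo-B-factor $B = 8\pi^2\Delta^2/3$.  The composition is
strictly monotone and sends pLDDT = 50 exactly to $6\pi^2 \approx 59.2$,
which is why the $\Delta \le 1.5$ Å inclusion filter is "almost
equivalent to B ≤ 60"; the implemented filter is exactly
$\Delta \le 1.5$.  Normalization $B_{norm} = (B - \langle B\rangle)/\sigma$
uses the mean and *population* standard deviation over the whole
structure (the stated whole-structure normalization), and `norm_s_b` is
the mean of $B_{norm}$ over surface residues passing the filter.  When
every residue shares one pLDDT, $\sigma = 0$ and $B_{norm}$ is defined as
0 with a warning; when no surface residue passes the filter the
descriptor is undefined and the protein is excluded with a logged reason.

Charged-area fractions use whole-residue SASA of Asp/Glu (negative) and
Lys/Arg (positive) at pH 7; His is excluded from the area fractions
(side-chain pKa ≈ 6) but participates in the Henderson-Hasselbalch net
surface charge, where each ionizable surface residue contributes its
fractional charge ( $+1/(1+10^{pH-pK_a})$ basic,
$-1/(1+10^{pK_a-pH})$ acidic; default pKa set D 3.65, E 4.25, C 8.5,
Y 10.07, K 10.53, R 12.5, H 6.0; termini excluded).  The exact published
rearrangement of the Henderson-Hasselbalch equation is not available in
the main text, so this default is stated as the package's own convention.
Hydrophobicity is the residue-count-weighted mean of the Eisenberg
normalized consensus scale over surface residues; an area-weighted
variant sits behind a flag.

## Preprocessing and model comparison

Screening runs in two passes: (1) descriptors whose point-biserial
correlation with the label is not significant at $\alpha = 0.05$
( $t$-test, $n-2$ df) are dropped; (2) within each descriptor category,
while any pair has $|r| \ge 0.8$, the member with the largest mean
absolute within-category correlation is dropped, ties broken by name
order — a deterministic operationalization of "highly linearly
correlated within its category".  The 0.8 cut is a conventional choice
(the source states no number) and is configurable.

Outliers are removed once (no iteration) by the conjunction of influence
and outlyingness: Cook's distance
$D_j = r_j^2 h_j / (p\,(1-h_j)^2) > 4/n$ *and* standardized Pearson
residual $|r_j/\sqrt{1-h_j}| > 2$, with leverages from the weighted hat
matrix of the logistic fit.  The conjunction mirrors "highly influential
and outliers simultaneously"; the exact thresholds are again the
package's own documented defaults.  On overlapping-class data this rule
removes a few percent of points near the decision boundary — the
reference analysis reported about 1% — and necessarily inflates the
refitted coefficients somewhat; the removal fraction is always reported.

Model comparison repeats a stratified 80/20 split five times (seeds
0-4 by default; every random draw flows from an explicit seed), fits the
scaler on each training portion, tunes KNN ($k \in \{3,5,\ldots,15\}$),
random forest (trees $\in \{100, 300\}$, `maxnodes` as a depth proxy),
RBF-SVM ($C \in \{0.1,1,10\}$, $\gamma \in \{d^{-1}\mathrm{var}^{-1},
0.01, 0.1\}$) and ridge-logistic ($\lambda \in \{0, 0.1, 1, 10\}$) by
stratified 5-fold CV accuracy, refits the winner on the full training
set, and reports held-out accuracy and trapezoidal ROC-AUC (equal to the
Mann-Whitney statistic with ties counted one half).  The original
hyperparameter grids are not available; these defaults are configurable
and deliberately small.

## The synthetic-data module

The generators define the study conditions for every test:

* **Geometry fixtures.**  Ideal backbones are built from internal
  coordinates (N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 Å; N-CA-C
  111.2°, CA-C-N 116.2°, C-N-CA 121.7°; ω = 180°): helices at
  φ = −57°/ψ = −47°, antiparallel hairpins at φ = −139°/ψ = 135° joined
  by a type-II′-like turn (45°, −120°, −80°, 0°), extended chains at
  180°/180°, and seeded random-torsion coils.  Side chains are single CB
  pseudo-atoms: the descriptor arithmetic is residue-keyed, not
  rotamer-sensitive, so sequence choice exercises hydrophobicity, charge
  and max-ASA lookups without rotamer modelling.  Sphere clusters bypass
  residue typing entirely and feed the geometry oracles.
* **Feature tables.**  Two-class multivariate Gaussians with shared
  covariance.  The benchmark spec sets the class-mean shift proportional
  to the published coefficient vector (two positive charge descriptors,
  five negative) and scales it so the 7-descriptor Gaussian Bayes
  accuracy $\Phi(|\delta|_\Sigma/2)$ equals the published 80.2%
  classification accuracy; 334 samples per class match the 668-protein
  dataset scale.  With identity covariance the true logistic
  coefficients equal the shifts, making sign recovery well defined.  The
  `full` variant appends the three redundant columns eliminated in the
  original screening — `s_charge_avg` as the sum of the charge
  fractions, `s_ah` as the linear complement of the other structure
  fractions, and a null `s_sf` with equal class means — and sets
  within-category correlations of 0.35 so the derived columns exceed the
  0.8 elimination cut, emulating the reported correlation structure.

What the generators do *not* emulate: realistic globular packing and
buried cores (fixtures are single helices/hairpins, so buried fractions
are small), rotamer-dependent solvent exposure, heavy-tailed or skewed
descriptor distributions, and any correlation between geometry and the
class label beyond the Gaussian shifts.  Passing tests therefore
demonstrate that the estimators and the statistical machinery are
correct and calibrated under controlled conditions — not that real
proteome-scale data would reproduce any particular coefficient value.

## Problem sizes and tolerances used by the test suite

The suite runs on one CPU in a few minutes: sphere-cluster oracles with
Monte-Carlo references ($2\times10^5$ to $6\times10^5$ samples),
15-30-residue fixtures for the descriptor stack, 60-70-residue fixtures
with a 3-probe roughness sweep for the pipeline orchestration,
668-sample feature tables for inference, a 50 000-sample 1-D parameter
recovery, 20 seeded sign-recovery datasets, and one 5 000-sample 1-D
task whose analytic Bayes accuracy (0.80) anchors the tuned accuracy of
all four algorithms.  Grid-based geometry estimates are asserted at
2-5% against closed forms and Monte-Carlo oracles (voxel 0.2-0.25 Å for
sphere fixtures), exact arithmetic identities at $10^{-8}$ to
$10^{-12}$, and the single-sphere fractal dimension at $|FD - 2| <
0.02$ at the default 0.5 Å voxel.

## Known limitations

* The SES estimator is a grid method: absolute areas carry a few percent
  of voxel noise, which the finite-difference roughness partially
  averages out; very deep, probe-scale crevices are resolved only to the
  voxel size.
* The Kabsch-Sander simplification collapses the eight DSSP states to
  three and does not reproduce any particular viewer's assignment
  bit-exactly.
* Multimeric assemblies are not modelled; HETATM content is ignored.
* The Cook's-distance conjunction and the collinearity cut are
  conventional defaults, not values recovered from the reference
  analysis, and both are configurable.
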