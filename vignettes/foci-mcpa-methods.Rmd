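---
title: "Methods: ALE meta-analysis and multi-coordinate pattern analysis of foci"
author: "fociMCPA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ALE meta-analysis and multi-coordinate pattern analysis of foci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fociMCPA)
```

# What the package models

Functional neuroimaging studies report their results as *foci*: peak
activation coordinates $(x, y, z)$ in integer millimetres of a standard
stereotactic space (MNI or Talairach). Coordinate-based meta-analysis pools
such foci across studies to locate consistently activated regions, and this
package implements two complementary engines over one foci data carrier:

1. **Activation likelihood estimation (ALE)** — a spatial meta-analysis
   that asks *where* studies converge, with permutation-based cluster-level
   family-wise error (FWE) control.
2. **Multi-coordinate pattern analysis (MCPA)** — a supervised method that
   asks *which coordinates discriminate* two groups of studies (e.g. two
   task families), by one-hot encoding the coordinates into three per-axis
   binary blocks and fitting a multi-block sparse partial least squares
   discriminant analysis (sPLS-DA), followed by a relevance network over
   the selected coordinate variables whose cross-block triangles decode
   back into candidate foci.

A synthetic foci generator with planted spatial clusters makes every stage
testable end to end without any external data.

# The ALE engine

## Model

For study $i$ with foci $x_{ik}$, each focus is smoothed with an isotropic
3-D Gaussian kernel

$$L_{ik}(\nu) = c\,\phi_3(\nu \mid x_{ik}, \sigma_i^2 I),$$

where $\nu$ is a voxel and $c$ normalises the kernel so that its mass sums
to one over the voxel lattice (so a modelled activation is a probability
distribution over voxels). The study's modelled-activation (MA) map takes
the voxel-wise maximum over its foci, $MA_i(\nu) = \max_k L_{ik}(\nu)$ —
several nearby foci from one study count once, not cumulatively. The ALE
map is the probabilistic union across studies,

$$ALE(\nu) = 1 - \prod_i \bigl(1 - MA_i(\nu)\bigr),$$

the probability that at least one study's true activation lies at $\nu$.

## Inference

Significance is assessed against a permutation null in which every study's
foci are redrawn independently and uniformly over in-mask voxels and the
null ALE map $ALE^*$ is recomputed. Two statistics are recorded per
permutation: the maximum voxel value, and the maximum 26-connected cluster
size above the cluster-forming threshold. Voxel-wise p-values are
empirical, computed against the *pooled* in-mask null ALE values across
permutations with the add-one rule $p = (r + 1)/(n + 1)$ so that $p$ is
never zero. Pooling across voxels is what makes a forming threshold of
$p < 0.001$ reachable with 200–1000 permutations — a per-voxel null at
1000 permutations cannot resolve $p$ below $10^{-3}$ — and is justified
because in-mask voxels are close to exchangeable under uniform resampling.
Clusters whose size *strictly* exceeds the $(1 -$ FWE$)$ quantile of the
null maximum-cluster-size distribution survive (strict exceedance is the
conservative reading of a tie).

## Parameters and defaults

* **Kernel width**: FWHM 10 mm by default
  (`sd = fwhm / (2 sqrt(2 ln 2))` ≈ 4.25 mm). When per-study subject
  counts are available, `fwhm_from_sample_size()` applies the standard
  empirical convention (between-subject Euclidean uncertainty 11.6 mm
  shrinking with $\sqrt{n}$, between-template 5.7 mm; Eickhoff et al.
  2009), which returns ≈ 10.0 mm at $n = 10$ — consistent with the fixed
  default.
* **Grid and mask**: 2 mm isotropic lattice over a shipped ellipsoidal
  brain envelope (centre $(0, -18, 18)$, semi-axes $(70, 86, 78)$ mm), so
  the tool needs no template download. Analyses in this vignette and in the
  test-suite benchmarks use 6–8 mm lattices; the grid only has to resolve
  the 10 mm kernel.
* **Thresholds**: cluster-forming $p < 0.001$, cluster-level FWE
  $p < 0.05$, permutation count 1000 (the conventional run configuration;
  tests use 40–200 permutations and correspondingly coarse grids).
* **Kernel truncation**: kernels are evaluated on a cube of half-width
  `truncate * sd` (default 5 sd, > 99.999 % of mass) and renormalised over
  that support, so each kernel still sums to exactly one. `truncate = Inf`
  disables truncation; the equivalence tests against the brute-force oracle
  use that exact mode.
* **Connectivity**: 26-neighbour, the common neuroimaging default.

## Numerical notes

Normalising each kernel over its in-grid support means foci near the grid
boundary keep unit mass (the constant $c$ grows); MA values are therefore
slightly larger near edges than an infinite-lattice kernel would give, and
identically so in the observed and null maps, which is what the empirical
p-values compare. Exact zeros produced by truncation create an atom of
p-values at 1; that is harmless for thresholding but means p-value
*uniformity* diagnostics should be run with `truncate = Inf`.

# The MCPA engine

## One-hot coordinate blocks

Every focus becomes a row of three binary blocks, one per axis; the block
for axis $q$ has one column per *observed* distinct value on that axis and
the row carries a single 1 in the matching column ("X_9", "Y_m88", "Z_0";
ASCII `m` encodes a minus sign). Whole-brain 1 mm resolution would need
$151 \times 188 \times 154 = 4{,}371{,}752$ columns as a full grid
one-hot; the per-axis construction needs at most $151 + 188 + 154 = 493$
and in practice only the observed values (typically 100–150 per axis). The
vocabulary is fitted on training data; a test focus with an unseen value
gets an all-zero row in that block (counted and warned about, never an
error), which still classifies via the latent projection.

## Multi-block sparse PLS-DA

With blocks $X^{(q)}$ ($q = 1 \dots Q$, here the three axes) and outcome
dummy matrix $Y$, each component $h$ maximises the design-weighted
covariance sum

$$\max_{a_h^{(1)} \dots a_h^{(Q)},\, b_h} \;
  \sum_{q \ne j} c_{q,j}\,\mathrm{cov}\bigl(X_h^{(q)} a_h^{(q)},
  X_h^{(j)} a_h^{(j)}\bigr) + \sum_q c_{q,Y}\,
  \mathrm{cov}\bigl(X_h^{(q)} a_h^{(q)}, Y_h b_h\bigr)$$

subject to $\lVert a_h^{(q)}\rVert_2 = \lVert b_h\rVert_2 = 1$ and a
per-block cardinality bound: at most `keep` nonzero entries of
$a_h^{(q)}$, the variable-count reading of an L1 constraint (sparsity is
tuned as "number of retained variables", which is the axis practitioners
report). The solver alternates power-style updates with soft-thresholding
at the $(keep{+}1)$-th largest magnitude, is initialised from the leading
singular direction of $X^{(q)\top} Y$ (deterministic — no random
restarts), and deflates each block and the outcome by regression on their
own scores, which makes successive scores within a block exactly
orthogonal. The largest-magnitude entry of every loading is made positive
so fits are sign-stable across runs. In the single-block non-sparse case
the component-1 loading equals the leading left singular vector of
$X_c^\top Y_c$, and the implementation reproduces mixOmics' single-block
`splsda` loadings to $10^{-8}$ in both sparse and non-sparse settings
(used as an independent cross-check in the tests, not as the
implementation).

**Design matrix.** The default is the *discriminant* design: every block
connected to the outcome with weight 1 and no block–block connections.
This is a deliberate departure from a fully connected weight-1 design, and
it matters specifically for one-hot coordinate blocks: whenever a focus
carries a coordinate value observed nowhere else, its x-, y- and z-block
indicator columns are *identical vectors*, so their cross-block
correlation is exactly 1. Under any appreciable block–block weight the
covariance objective can latch a whole component onto such duplicated
singleton columns (we observed loadings of 0.999 on a single
one-focus column, and association scores of exactly 1.0) instead of the
class signal. With the discriminant design components stay aimed at class
separation, at no measurable cost in test error. Any symmetric design in
$[0,1]$ can still be supplied.

**Scaling.** Columns are centred and unit-variance scaled by default
(binary columns included), matching the model family's convention; the
outcome dummies are scaled the same way. Zero-variance columns are dropped
with a warning.

**Components.** $H = 2$ by default. For a two-class outcome only one
latent dimension is genuinely discriminative (the centred dummy matrix has
rank 1); the second component refines the within-block representation and
the centroid geometry but adds little explained variance.

## Prediction and evaluation

Test rows are centred/scaled with the training parameters, projected
through the fitted deflation sequence, and each block assigns the nearest
training class centroid in latent space (Euclidean distance). Blocks vote;
ties break by smallest mean centroid distance and then by the first class
level, so prediction is deterministic. Accuracy is summarised as the
balanced error rate (BER), the mean of per-class misclassification rates,
which weighs imbalanced groups equally: a perfect prediction gives 0, a
constant predictor over two present classes gives 0.5.

`tune_keep()` fits one model per candidate variable count (shared across
blocks and components, the convention for this tuning axis), evaluates BER
on a held-out encoding, and returns the trajectory plus the argmin
(smallest count on ties). Tuning on a held-out split rather than by
cross-validation reflects how near-constant binary columns behave: many
folds would lose rare columns entirely.

## Relevance network and focus reconstruction

For variables in different blocks, both blocks are decomposed over a
*shared* latent variable per component — estimated as the sign-aligned
bisector $U_l \propto t_l^{(q)} + t_l^{(r)}$ of the two blocks' score
vectors — and the association score is

$$M_{kj} = \sum_{l \le d} \mathrm{cor}(X_j, U_l)\,\mathrm{cor}(X_k, U_l),$$

which for standardised variables equals
$\sum_l u_l^2 \phi_{jl} \varphi_{kl}$ with $u_l$ the training standard
deviation of $U_l$ and $\phi, \varphi$ the regression coefficients of the
variables on it. The score approximates the direct correlation of the pair
whenever the $d$ retained dimensions span their cross-block covariance
(verified to within 0.1 on full-rank toys in the tests). Only variables
with a nonzero loading on some component enter $M$ — the network describes
the *selected* model, mirroring the convention of sparse multi-block
software. Scores are clamped to $[-1, 1]$: the sum over dimensions can
overshoot a correlation by a rounding-level amount.

**Depth $d$.** The approximation requires $d$ below the full decomposition
depth, and a $G$-class outcome supports only $G - 1$ discriminative latent
dimensions; for the usual two-class fit the second component tracks
sampling noise, and summing it inflates $M$ with chance correlations (we
measured noise-pair scores up to 0.7 at $d = 2$ against 0.2 genuine signal
at $d = 1$). The default is therefore $d = \max(1, H - 1)$, overridable.

`build_network()` keeps cross-block pairs with $|M| \ge$ cutoff (0.11 and
0.13 are the conventional renderings; raising the cutoff never adds
edges). `reconstruct_foci()` enumerates node triples with exactly one node
per axis block whose three pairwise edges all exist *with positive
scores* — positive products mean the three coordinate values co-vary with
the same class direction — decodes each triple back to an $(x, y, z)$
coordinate, and scores it by its weakest edge (the weakest link bounds the
joint relevance). Ties sort by ascending coordinate, so output is
deterministic.

# The synthetic benchmark

`default_benchmark()` emulates a two-group foci corpus of realistic shape:
12 "branded" studies totalling exactly 562 foci and 20 "unbranded" studies
totalling 469 (per-study counts are fixed vectors summing to those
totals), with

* one **shared** cluster at $(-4, 40, -8)$ — a ventromedial prefrontal
  overlap motif present in both groups,
* one **branded-only** cluster at $(6, -88, 4)$ — a lingual/occipital
  motif, the planted discriminative signal,
* isotropic cluster sd 6 mm, and 15 % uniform background over the brain
  envelope.

Mixture weights are branded $= 0.50$ branded-only $+\,0.35$ shared
$+\,0.15$ background and unbranded $= 0.85$ shared $+\,0.15$ background:
the branded literature emphasises its distinctive region, the unbranded
group concentrates on the overlap, and both carry the same background
rate. Gaussian samples are truncated to the envelope by rejection (foci
are brain locations) and rounded half-away-from-zero to integer mm, the
fixed rule needed for reproducibility. Everything is seeded; equal seeds
give identical datasets.

## What the benchmark does and does not show

On this benchmark, across the repeated-run tests: ALE on the branded group
recovers a surviving cluster whose peak lies within 10 mm of the planted
branded centre in 20/20 runs (6 mm lattice, 40 permutations), and the
tuned MCPA test BER is below 0.35 in 20/20 runs (typical values 0.23–0.33,
against 0.5 chance). Explained variances per component are of order 0.01 —
one-hot blocks are wide and nearly isotropic, so no single direction
explains much variance even when it discriminates well; discriminant
performance, not explained variance, is the relevant figure of merit for
this model family.

The *relevance-network* recovery property is verified on a dedicated
compact fixture (one cluster, sd 4 mm, weight 0.7, driving one of two
groups), where the top reconstructed candidate falls inside the cluster's
±1 sd box in ≥ 80 % of simulations. On the default benchmark itself the
top candidate lands in the correct neighbourhood but not reliably within
±6 mm on all three axes: the two planted centres are only 10 mm apart on x
and 12 mm on z, so those blocks' indicator columns mix both clusters, and
a 6 mm sd spreads each cluster over ~25 integer values per axis, diluting
per-column class correlations (~0.1) to the level of chance extremes among
~350 columns. That is a property of one-hot encoding under spatial
dispersion — a genuine limitation users should expect on real foci data
with diffuse convergence — not of the reconstruction algorithm, which
matches exhaustive enumeration exactly.

The generator emulates counts, planted overlap/specific structure, and
integer reporting. It does **not** emulate: study-level kernel
heterogeneity (different subject counts), anisotropic or non-Gaussian
spatial dispersion, correlated foci within a study (multiple peaks of one
blob), coordinate-space conversion error between MNI and Talairach
reports, or publication bias. Passing the benchmark therefore shows the
machinery is correct and calibrated, not that any particular real corpus
will separate.

# Scope notes and other design choices

* Talairach-tagged data are accepted and never converted; mixing spaces in
  one analysis is an error. Conversion belongs to upstream tooling.
* The proportional `stratified_split()` rounds by largest remainder
  (per-group counts within 1 of exact proportionality); a named per-group
  count vector reproduces published bookkeeping such as a 117/83 test
  split of a 562/469 corpus, which no proportional rule produces — the
  exact historical split procedure behind such numbers is typically
  unreported, so it is accepted as an input rather than re-derived.
* The full-grid ("pattern 1") encoding is deliberately not implemented —
  4.4 M near-empty columns serve no tested code path; the
  `coordinate_universe()` helper documents its size instead. The raw
  coordinate passthrough ("pattern 2") is included for comparison
  experiments only.
* Problem sizes in the tests (6–8 mm lattices, 40–200 permutations,
  10–50 simulation replicates) were chosen so the whole suite and the
  acceptance script each run in minutes on one CPU while keeping every
  statistical check at its stated confidence; the tool defaults (2 mm,
  1000 permutations) are the conventional analysis configuration.
* One run seed is fanned out to per-module substreams (`derive_seed()`),
  so CLI artifacts are byte-reproducible from the manifest.

# Known limitations

* The permutation null treats in-mask voxels as exchangeable under uniform
  resampling; masks with strong boundary effects at coarse spacing bend
  voxel-wise p-values slightly near the edge (cluster-level FWE control,
  which is what the tool reports, is unaffected — calibration holds at the
  nominal 0.05 in the tests).
* Nearest-centroid prediction with majority vote is deliberately simple;
  probabilistic posteriors are out of scope.
* Association scores are in-sample quantities on the training encoding;
  they are reported for model interpretation, not inference, and carry no
  multiplicity control.
* With more than two classes the discriminant design, vote tie-breaking
  and `d = G - 1` depth all generalise, but the package's benchmarks and
  calibration tests cover the two-class case only.
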