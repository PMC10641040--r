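---
title: "Methods: shape analysis and classification of flatfish vertebrae"
author: "flatmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shape analysis and classification of flatfish vertebrae}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical machinery in `flatmorph`: the
superimposition and shape-space model, the two-stage classifier, the
fragment-aware identification protocol, the synthetic data generator and
its assumptions, and the numerical and design choices made where more
than one defensible option existed.

## The data model

A vertebra is observed as one or two 2D landmark configurations
(anterior and sinistral photographic views). Landmark schemes are fixed
per view and vertebra class: 13 (anterior) and 9 (sinistral) landmarks
for the atlas, 19 and 12 for cervical, precaudal and caudal vertebrae.
Three structural index sets matter throughout:

- *arch tips* (anterior 1–3, sinistral 1–2; atlas 1 in both views) are
  landmarks on the tips of the neural/haemal arches. They are the first
  casualties of taphonomic fragmentation and are excluded from every
  analysis subset.
- *cervical-absent* landmarks (anterior 2, 3, 9–12; sinistral 11, 12)
  sit on the haemal processus, which cervical vertebrae lack; cervical
  configurations carry them as missing.
- the *across-type shared* set (anterior 4–8 and 13–19, sinistral 3–10)
  is the subset homologous across cervical, precaudal and caudal
  vertebrae, used when classifying vertebra type.

Coordinates are stored in cm: TPS files carry image-unit coordinates and
a per-record `SCALE` factor applied on read. The package takes the TPS
y-axis as-is (no flipping): generalized Procrustes analysis without
reflection is handedness-sensitive, and sidedness — left- versus
right-eyed flatfish are near mirror images — is a biological signal the
analysis deliberately preserves. All configurations in one analysis must
therefore come from the same digitising convention.

## Superimposition

Each configuration is *preshaped*: translated to zero centroid and
scaled to unit centroid size (the square root of the summed squared
landmark distances to the centroid — sizes are retained separately in
cm). GPA then iterates: rotate every preshape onto the running
consensus by the closed-form least-squares 2D rotation, re-estimate the
consensus as the arithmetic mean, renormalise it to unit size, and stop
when its root-mean-square movement falls below `tol = 1e-10` (cap 100
iterations; non-convergence returns a flagged result with a warning).
This is a shape-only (full Procrustes) analysis: the study material is
scaled photographs, and size is not a usable signal across cameras and
specimens.

Two conventions make the output well-defined rather than "defined up to
rotation":

- the iteration starts from the normalised mean of the preshapes, which
  is invariant to input order;
- after convergence the whole ensemble is rotated so the consensus'
  first used landmark lies on the +x half-axis.

Together these make GPA output reproducible to ~1e-10 under input
permutation and under arbitrary per-configuration rotation, translation
and positive scaling — a property the test suite asserts end-to-end
(through PCA scores and classifier posteriors). The canonical
orientation is unstable only if the first used landmark sits at the
centroid, which no vertebral scheme approaches.

Downstream PCA treats the aligned coordinates as first-order tangent
coordinates about the consensus: no separate orthogonal projection is
applied. Vertebral shape variation is small (Procrustes distances ≲ 0.2
in the synthetic regime and in practice), where the linear approximation
is adequate; this is an approximation, not an exact tangent projection.

The stored consensus is the arithmetic mean of the aligned
configurations (its centroid size is marginally below 1 whenever there
is shape variation); PCA centres on exactly this mean, so the eigenvalue
sum equals the mean squared deviation of the flattened coordinates from
the consensus (eigenvalues use the divisor *n*).

## Missing landmarks and outliers

Missing landmarks are estimated before any screening: the consensus of
the complete configurations is warped onto each incomplete configuration
by a 2D thin-plate spline (`U(r) = r^2 log r^2` kernel plus affine part)
through the shared present landmarks, and gaps are filled from the
warped consensus. The spline reproduces affine maps exactly, so a purely
affinely deformed configuration is recovered to machine precision. At
least 4 non-collinear shared landmarks are required (`min_present`);
with exactly 3 the warp degenerates to the exact affine map, which is
allowed but flagged. Filled landmarks are marked in a separate
`estimated` mask. Under isotropic landmark noise of SD σ the recovery
error (RMSE over coordinate residuals, which includes the deleted
landmark's own noise) measures ≈ 1.6 σ in simulation; exact
interpolation through noisy neighbours contributes the part above 1 σ.

Outlier screening uses the interquartile-range rule on Procrustes
distance to the consensus: flag d > Q3 + 1.5·IQR (one-sided, strict
inequality, quantile type 7). Procrustes distance is the natural
univariate shape summary for this rule; the multiplier 1.5 is the
conventional choice. Flags are returned, not applied — the pipeline
removes flagged vertebrae per analysis subset and logs the removals.
Estimation precedes screening so that a vertebra is judged on its
completed shape rather than on an artefact of which landmarks survived.

## Two-stage classification

For each view: GPA on the level's landmark subset, then PCA (all axes
above the numerical-rank cutoff `1e-12 × trace` retained; axis signs
fixed so the largest-magnitude loading is positive). The per-view score
blocks of each vertebra are concatenated unweighted — the combined view
is a plain inner join on the vertebra, with vertebrae missing a view
dropped and logged. An optional eigenvalue weighting of the blocks
exists but is off by default, as no weighting is part of the method.

A second, centred (not variance-scaled) PCA condenses the combined
scores; it retains the axes reaching 99% cumulative variance, capped at
`n_train − n_classes` so the subsequent pooled covariance stays
invertible. LDA uses class centroids, a pooled within-class covariance
(divisor `n − C`), and priors proportional to training class frequencies
(uniform optional). If the pooled covariance's condition number exceeds
1e10, a ridge of `1e-8 × trace/p` is added. Posteriors are normalised
Gaussian densities; the predicted label is the argmax with exact ties
going to the lexicographically smallest class. Classes with a single
vertebra are removed before fitting.

Test material never touches the training statistics: each test
configuration is preshaped, rotated (never reflected) onto the *frozen*
training mean shape of its view, projected on the frozen PC basis, the
blocks concatenated, and pushed through the frozen second-PCA rotation.

Accuracy is the proportion of correct test classifications over
repeated stratified 70:30 train/test splits (default 100 repetitions;
per-class training counts round up). Stratification is the default
because unstratified splits at these class sizes routinely leave test
classes empty; an unstratified mode exists. The split unit is the
vertebra (its photo pair); an optional specimen-level grouping is not
applied by default, so vertebrae of one fish can straddle the split —
faithful to the evaluation design this package reproduces, but worth
remembering when reading absolute accuracies. Hierarchical decision
chains (type → family → species) multiply their stage accuracies under
assumed stagewise independence: `hierarchicalAccuracy(c(0.8953, 0.9569))`
= 0.8567.

## Identifying archaeological samples

Each sample is analysed individually against the modern reference
(completed by missing-landmark estimation beforehand). Per chain level:

1. choose the reference subset — all cervical + precaudal + caudal
   references with the across-type shared landmarks for the type step;
   then references of the (predicted or given) type with the
   type-specific subset; then references of the predicted family. Once
   the type is decided the type-specific landmark set replaces the
   reduced across-type set: more landmarks are available and the
   references are homogeneous, so discarding them would waste signal.
2. drop every landmark absent from the sample from all references;
   a view with fewer than 3 usable landmarks is dropped (flagged), and a
   sample with no usable view is reported unidentifiable.
3. joint GPA and first PCA of sample + references per view — unlike the
   modern evaluation, the single sample joins the superimposition, since
   one configuration among dozens of references barely moves the
   consensus;
4. second PCA and LDA fitted on reference rows *only* (the sample never
   influences the classifier), the sample's scores pushed through, and
   the winning label and posterior recorded.

Reference classes reduced below 2 members are dropped (flagged); if
fewer than two classes remain the chain truncates with a flag rather
than fabricating a decision. Atlas samples always run in `given_type`
mode (the across-type classifier excludes the atlas), and `given_type`
is the default for reporting since vertebra type is usually clear
visually; `full_chain` serves the type-success statistics. The chained
confidence (product of level posteriors) is reported alongside the
per-level posteriors.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
at the scale of the modern reference collection the method was designed
around: 19 taxa in 5 families with per-taxon specimen counts
(3,2,5,7,5,6,7,10,6,1,3,4,3,1,1,1,1,2,5 — 73 specimens), 10 vertebrae
per specimen (1 atlas + 3 each of cervical/precaudal/caudal), and mirror
forms in 40% of the largest taxon's specimens (the left-eyed flounder
analogue). All counts are parameters.

Per view and vertebra class, a deterministic, deliberately asymmetric
ring-plus-appendages polygon (unit centroid size) is the base template.
Gaussian offsets are drawn once per spec seed: vertebra-type offsets
scaled to `type_effect`, and taxon offsets nested in family offsets
(variance split equally) scaled so the mean pairwise between-taxon
template distance is `separation × within_sd`; offsets are drawn
independently per view, so the two views carry independent taxon
signal. Each simulated configuration adds isotropic Gaussian landmark
noise (`within_sd`), is mirrored (x-negation) if its specimen is a
mirror form, and receives digitisation nuisance: rotation U(−π, π),
translation U(−5, 5) cm, a physical size factor U(0.75, 1.25), and a
digitiser resolution U(50, 200) units/cm stored in TPS as
`SCALE = 1/resolution`. Cervical configurations mark the structurally
absent landmarks as missing, as a digitiser would.

Defaults fixed a priori as field-realistic where no study value exists:
`within_sd = 0.02` shape units (≈2% of centroid size, typical of
biological plus digitisation variation at this scale), `separation = 4`
(taxa overlap but are statistically separable, matching the
imperfect-but-useful accuracies the method reports), `type_effect = 6`
(vertebra types separate more readily than taxa). Degradation drops
landmarks independently — uniformly, or with doubled probability on
arch/spina tips (`tip_biased`), mirroring fragmentation concentrating on
arches and spines — and can add small Gaussian deformation.

What the generator does **not** emulate: correlated (low-rank) shape
variation along anatomical gradients, within-specimen correlation
between vertebrae of one fish, allometry, and non-Gaussian digitisation
error. Green tests on synthetic data therefore demonstrate the
*pipeline's* correctness and statistical behaviour under its stated
assumptions, not field accuracy on real bone. RNG is R's default
Mersenne-Twister; every generator output is a pure function of the spec
(including its seed), and the degradation step takes its own seed.

## Numerical choices and edge cases

- GPA: tol 1e-10 on RMS consensus movement, max 100 iterations;
  degenerate (all-coincident) configurations and sets with fewer than 2
  members error out; fewer than 3 present landmarks is an error in
  preshape.
- TPS: collinear or duplicated source landmarks give a singular-system
  error rather than a garbage warp.
- Second PCA retention: cumulative variance ≥ 99% with the
  `n_train − n_classes` cap; at least 1 axis is always kept.
- LDA ridge: `1e-8 × trace/p` on condition number > 1e10.
- Ties in posteriors resolve to the lexicographically smallest label,
  making predictions deterministic.
- The IQR rule needs ≥ 4 values; distances exactly on the fence are not
  flagged.

## Design notes for the test suite

Two choices in the validation deserve explanation. First, the
combined-view property ("fusing views does not lose accuracy") is tested
with equal-size 8-landmark subsets per view: the native schemes have 19
vs 12 landmarks, and at moderate sample sizes the higher-dimensional
view is weaker purely through covariance-estimation burden, which
confounds the fusion effect the property is about. With the views
symmetric in dimension, fusion shows its expected gain. Second,
separable-limit checks (perfect recall at large separation) use 20+
vertebrae per taxon; with fewer, the second-stage LDA estimated in up to
`n_train − n_classes` dimensions occasionally misclassifies even
well-separated taxa — a finite-sample effect, not a pipeline defect.

Problem sizes in the shipped tests and the acceptance script were chosen
as the smallest at which the statistical properties under test are
stable: 4 taxa × 40 vertebrae for label-recovery and fusion checks, 100
reference vertebrae and 200 degraded samples for the fragmentation
curve, 200 deletions for missing-landmark recovery, and 40 vertebrae
(half mirrored) for sidedness.

## Known limitations

- 2D, fixed-scheme landmarks only: no semilandmarks/sliding, no 3D.
- The tangent-space approximation is first-order; it is fine for the
  small shape variation of vertebrae but would bias analyses of wildly
  varying shapes.
- Missing-landmark estimation assumes the consensus is a sensible prior
  for the incomplete specimen; for a taxon far from the consensus the
  fill is biased toward the mean.
- Accuracy estimates ignore within-specimen correlation (see the split
  unit above) and the chained hierarchical accuracy assumes stagewise
  independence.
- The identification posterior is an LDA posterior under Gaussian
  pooled-covariance assumptions; it is a ranking score, not a calibrated
  probability on real archaeological material.
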