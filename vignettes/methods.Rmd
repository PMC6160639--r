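---
title: "Methods: simulating and measuring executive-task similarity in activation and connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring executive-task similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(execonn)
```

# The scientific question

Executive functions — dividing attention, inhibiting distractors, holding
items in working memory, switching between input modalities — recruit a
common frontoparietal network, but how *similar* their neural signatures
are appears to change across adolescent development. Two observable
quantities operationalize that similarity:

1. **Activation-topography overlap.** Fit a voxelwise GLM per executive
   contrast, threshold the group t maps with a height + extent rule, and
   compute the percentage of suprathreshold voxels two contrasts share.
2. **Connectivity-pattern similarity.** Extract mean BOLD time courses
   from eight spherical frontoparietal ROIs, correlate every ROI pair
   within each task (28 connections, Fisher z), and ask how correlated
   these 28-value patterns are *across* the four task types. Embedding
   the 28 connections with classical MDS on `1 - r` turns "more similar
   across tasks" into "smaller inter-node distances".

`execonn` implements this full pipeline, and — because no raw data from
the motivating developmental study are deposited — a seeded synthetic
cohort generator whose planted ground truth makes every stage testable:
cohort-dependent activation overlap, cohort-dependent cross-task
connectivity similarity, and cohort-dependent behavioral accuracy.

# The synthetic world

The generator's defaults mirror the acquisition and task structure of the
motivating study:

* **Acquisition**: TR 2.5 s, 4 dummy volumes; three attention runs of 222
  volumes; two n-back runs of 155 volumes. The default grid is a
  desk-scale 24x28x24 lattice of 3 mm voxels with a midline-symmetric
  affine (a stand-in for a 64x64x43 EPI matrix; everything scales with
  the grid).
* **Attention task**: each run has one rest block plus seven task blocks
  (two undistracted conditions, three distracted conditions, divided
  attention twice), 12 sentence trials per block, 2.5 s stimulus followed
  by a 1.5 s response window (the source protocol specifies only the
  2.5 s sentences; the response window is a package choice that keeps 8
  blocks plus 2.5 s inter-block instruction periods and a 6 s run
  instruction inside the 545 s post-dummy window). Block order is
  randomized per seed, block composition is fixed.
* **n-back task**: three blocks (0-, 1-, 2-back) of 32 vowels, 0.5 s
  stimulus + 2.5 s retention; the stimulus modality switches after runs
  of 3, 4, 5 or 7 trials (drawn uniformly), and trials are flagged
  pre-switch / post-switch / nonswitch. All three levels carry switch
  flags: the first-level model splits every level by switch status and
  modality, and the working-memory contrast needs the 0-back nonswitch
  columns.
* **Behavior**: per-block accuracy is drawn from a truncated normal and
  trials are Bernoulli within block. Grand task means are the published
  adult-sample values (DivA 73.82, DistrA 88.33, WM 86.23, ModSwi 90.08
  percent correct); cohort shifts (-4.5 / +1.5 / +3.0 points), a small
  gender effect (±0.9), a participant ability SD of 5 and a block SD of 5
  are package defaults chosen to reproduce the qualitative pattern
  (middle adolescents lowest, cohort effect size η² ≈ 0.2) rather than
  any printed statistic.
* **Noise**: baseline 100, white temporal noise, slow drift spanned by
  the analysis' discrete-cosine basis, random-walk motion parameters
  (synthesized for nuisance regression and QC only — they do not move
  the object), and two corner "background" boxes acting as white-matter
  and CSF proxy regions so the denoising contract is identical for real
  and simulated data.

## Planted activation and the detection-set definition of "truth"

Each executive contrast gets one spherical blob (12 mm radius, softened
edge). A contrast's *planted truth* is deliberately **not** the blob's
amplitude support: a t-threshold detection region is intrinsically a
function of the noise level, so an amplitude-only "true region" can never
meet a quantitative overlap contract. Instead the truth is the
**expected-detection set**

$$ t_{\exp}(x) = \frac{\sqrt{n}\, m(x)}{\sqrt{\tau^2 m(x)^2 + \sigma_w^2}} > t_{\min}, $$

where $m$ is the analysis-smoothed amplitude map, $\tau$ the
between-participant multiplicative amplitude SD (default 0.5, a realistic
between-subject variability for task fMRI), $\sigma_w$ the deterministic
standard error of a participant's smoothed contrast estimate (computable
exactly from the design matrices, the smoothing kernel's L2 norm, and the
temporal noise SD), and $n$ the cohort size. The sample group-t map
converges to $t_{\exp}$, so the thresholded estimate fluctuates around
this set rather than being systematically biased. Pairwise overlap
targets are met by bisecting on blob-centre displacement (overlap is
monotone in distance), embedding the implied 4-point distance matrix
(infeasible target combinations fail the Euclidean-realizability check
before any simulation), and refining against overlap measured on the
actual voxel grid to within ±0.03.

Two consequences worth noting:

* The temporal noise SD defaults to "auto": it is calibrated once, per
  configuration, so that the expected group-t contour sits at half the
  planted amplitude — the spatially most stable choice (the contour then
  lies mid-edge, where discretization and sampling move it least).
* The four contrasts' design efficiencies differ by a factor of ~6
  (the modality-switch contrast compares few post-switch against few
  pre-switch events). Planted amplitudes are therefore scaled per
  contrast in proportion to the contrast SE; the scale factor cancels in
  $t_{\exp}$, giving all four maps the same detection geometry. This is
  a statement about the synthetic world (effect sizes that are equally
  detectable), not a change to the analysis.

## Planted connectivity structure

The four task correlation matrices over the 8 ROIs are assembled in
connection space (28 off-diagonal entries) as

$$ g_k = \mu \mathbf{1} + L(\sqrt{s}\, Q_0 + \sqrt{1-s}\, E_k) + b_k \mathbf{1}, $$

with $Q_0, E_1..E_4$ *exactly* orthonormalized centred random vectors,
$\mu = 0.30$ and a 0.15 entry SD (typical frontoparietal coupling
values). Pearson correlation centres each vector, so the uniform terms
drop out and the pairwise similarity of off-diagonal entries equals the
target $s$ *exactly* — this is why the construction check passes at
±0.05 without retries. Positive definiteness is enforced by uniform
shrinkage toward the identity, which rescales each matrix's off-diagonal
entries by a constant and therefore leaves the similarity contract
untouched.

The uniform task offsets $b_k$ (pattern $(1,1,-1,-1)$, amplitude
`tau_mod * sd_entry`, zero only at the degenerate $s = 1$ where the four
matrices must coincide) model a global task-level modulation of coupling
strength. They are what connects the *planted* similarity to the
*observable* MDS geometry: connection-specific task deviations shrink as
$s$ grows while the shared modulation does not, so connection-by-
connection correlations across tasks rise with $s$, the
connection-similarity matrix fills in, and the embedded cloud contracts
— mean embedded distance decreases monotonically in $s$. Without such a
shared component the mean cross-task correlation of connections is ~0
for *every* $s$ and no distance ordering exists; with an $s$-proportional
component the high-similarity cohort becomes noise-dominated and the
ordering inverts. The constant-magnitude choice is the only one of the
three that is monotone under estimation noise.

During simulation, ROI voxels share latent series drawn with the task's
matrix in the frames belonging to that task's blocks (post-switch windows
take precedence inside the 1-/2-back blocks, mirroring the analysis'
frame ownership); remaining task frames use the average matrix, rest
frames plain white noise.

# Analysis choices

* **GLM**: condition regressors are stimulus-duration boxcars convolved
  with the canonical double-gamma HRF; attention conditions split by
  sentence congruency, n-back conditions by level x switch status x
  modality; nuisance regressors are convolved response events, convolved
  instruction periods, six motion parameters, a DCT drift basis up to
  1/128 Hz (the high-pass filter lives in the design, keeping degrees of
  freedom exact), and an intercept. Response regressors are convolved
  like conditions (the protocol is silent; flagged as an assumption).
  Ordinary least squares with df = T - rank(X); no AR(1) prewhitening
  (the claims tested here are topological/relational — documented
  deviation).
* **Contrasts**: DivA = divided - mean(distracted); DistrA =
  mean(distracted) - mean(undistracted); WM = mean(1-,2-back nonswitch)
  - 0-back nonswitch; ModSwi = mean(1-,2-back post-switch) -
  mean(pre-switch); each side averages its member columns with equal
  weight. Participant maps average contrast estimates across runs; the
  group map is a voxelwise one-sample t (zero-variance voxels are capped
  at ±1e6 with a warning rather than ±Inf).
* **Thresholding**: strict `t > t_min` and `k > k_min` (following the
  printed "t > 2.7, k > 250" convention), 26-neighbour connectivity by
  default (18 available), cluster centres reported as centre of mass
  (robust on plateaus; the peak is also reported). At desk scale the
  extent thresholds are k > 25 (group) and k > 10 (participant),
  scaled to the ~250-voxel detection sets of the small grid. Cluster-level
  FWE p-values via random field theory are not re-derived; extent
  thresholding is the operative rule (documented deviation).
* **Overlap**: the percentage for a contrast pair is the mean of the two
  directional percentages `100·|A∩B|/|A|` and `100·|A∩B|/|B|` (reads
  "average percentage" literally and keeps the matrix symmetric);
  Jaccard and both directional variants are co-emitted as attributes. A
  pair with an empty set scores 0.
* **Connectivity**: spheres of 7 mm; unweighted voxel means; confound
  regression against motion, WM/CSF proxies, outlier indicators and the
  task/rest design columns (residual correlations are *background*
  connectivity); frames per task are the task's block frames shifted by
  2 frames (5 s hemodynamic lag), and for the event-type ModSwi "task"
  the 3-frame windows after each post-switch trial (the source protocol
  never defines connectivity for an event type; flagged as an
  assumption). Fisher z with |r| clipped at 1-1e-7.
* **Similarity and MDS**: dissimilarity `1 - r` (RSA convention;
  `sqrt(2(1-r))` behind a flag); classical Torgerson embedding with
  negative eigenvalue mass truncated and logged; distances for the
  ANOVA are computed in the 2-D plane (matching the published figures;
  the embedding dimension used for the published ANOVA is unstated).
  A distance-table row inherits a hemisphere/range type only when both
  endpoint connections share it; mixed rows form an explicit stratum
  excluded from the type factor.
* **Cohort comparison tests**: the published "differed significantly"
  test is unnamed, so two complementary permutation tests are reported:
  (a) a paired sign-flip test on the entrywise differences of the two
  connection-similarity matrices (sensitive to a level offset), and
  (b) a participant-relabelling test whose statistic is the structural
  disagreement `1 - cor` between recomputed cohort matrices (sensitive
  to pattern differences). Either can dominate depending on how the two
  cohorts differ; the pipeline's headline decision uses the Bonferroni
  union (twice the smaller p), which is valid at level α and powerful
  against both alternatives. `matrix_similarity_test()` additionally
  reports a node-relabelling p for "the matrices share structure".
* **Behavioral statistics**: blocks more than 3 SD below the task-family
  mean (pooled across participants — the printed cutoffs are single
  global numbers) are excluded, with strict inequality at the boundary
  and cutoffs frozen from the first pass; the repeated-measures ANCOVA
  uses Type-III sums of squares via orthonormal within-subject
  contrasts, Greenhouse-Geisser ε = (tr S)² / ((a-1) tr S²) applied when
  Mauchly's test rejects, η² against the total sum of squares, and
  Bonferroni post hocs. The GPA-like covariate enters as a
  between-subject continuous covariate on the participant means
  (classical split-plot ANCOVA); participants with a missing task score
  are dropped listwise with a message.

# What a green test does and does not establish

The generator emulates block/event structure, hemodynamics, drift,
motion nuisance, ROI-structured latent noise and cohort-dependent truth;
it does *not* emulate physiological noise spectra, field inhomogeneity,
spatial autocorrelation of the noise, head-motion-induced signal change,
or realistic anatomy. Green recovery tests therefore establish that the
*estimators are faithful to their definitions* and that the pipeline
recovers planted truth through its own forward model — not that the
published numbers from the real 167-participant sample are reproduced
(they depend on undeposited data and are explicitly out of reach; the
acceptance suite is property-based for exactly this reason).

# Numerical and degenerate-input policy

Gaussian smoothing kernels are truncated at 4σ and row-renormalized at
grid boundaries (constants pass through unchanged; interior mass is
conserved to ~1e-10). Zero-variance voxels in group t maps are capped
with a warning; zero-variance connections yield 0 similarity entries
with a warning; `atanh` inputs are clipped at |r| = 1-1e-7 with a
message. Master seeds expand to counter-based substreams
(`child_seed()`), so adding a participant or cohort never reshuffles
existing streams, and every generator output is bit-reproducible under a
fixed (config, seed).

# Known limitations

* The overlap estimate inherits a small negative bias at desk scale
  (sampling fragments the detection-set boundary and the extent rule
  trims fragments); it stays well inside the ±8-point recovery contract.
* Correlations across only 4 task values per connection are honoured as
  described despite their 2 degrees of freedom; this is the dominant
  noise source in connection-similarity matrices at small n.
* The desk grid cannot contain the published MNI ROI coordinates (their
  x-span plus sphere radius exceeds the 72 mm field of view), so the
  printed-coordinate fixture lives on a dedicated covering grid and the
  desk simulations use synthetic frontoparietal-like centres with the
  same hemisphere/region structure.
* `rm_ancova()` implements the balanced split-plot decomposition; it
  does not handle missing within-cells (listwise deletion) or unbalanced
  within designs.
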