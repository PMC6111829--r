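---
title: "Surface registration with median-weighted ICP and stochastic restarts"
author: "iicp package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface registration with median-weighted ICP and stochastic restarts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iicp)
```

## The problem

Image-guided surgery systems need to place pre-operative imaging (a
CT-derived head surface, say) in the same coordinate frame as the patient on
the table, observed by a depth sensor. Both sides reduce to 3-D point
clouds in millimetres: a dense *reference* surface and a sparser, noisy,
partially overlapping *floating* scan. The task is rigid registration —
find the rotation $R$ and translation $t$ mapping the floating cloud onto
the reference — and the clinically relevant yardstick is not the fitting
residual but the *target registration error* (TRE): the distance by which
named landmarks miss their true positions after alignment.

Classic point-to-point ICP alternates two steps until the objective stops
changing: match every floating point to its nearest reference point, then
solve the weighted least-squares (Kabsch) problem for the best rigid
transform given those matches. It is fast and locally excellent, but it
inherits two well-known failure modes: a poor starting position lands it in
a locally optimal alignment, and points without a true counterpart (the
non-overlapping part of a single-view scan, plus outliers) drag the
estimate. This package implements an improved variant, I-ICP, that
addresses both, together with the classic baseline, marker-based
evaluation, and a synthetic scan generator with known ground truth.

## The I-ICP procedure

**Median weighting.** After matching, let $d_i$ be the match distances and
$m$ their median, taken — following the source procedure literally — as the
sorted value at 1-based index $N/2$ for even $N$ and $(N+1)/2$ for odd $N$
(not the conventional averaged midpoint; that is available via
`medianRule = "midpoint"`). Each correspondence receives the weight

$$\delta_i = \begin{cases} 1 & d_i \le m \\ m / d_i & d_i > m,\end{cases}$$

so the half of the matches that fit worse than typical — predominantly
wrong matches from non-overlapping regions, and many-to-one pile-ups — are
damped in proportion. The two branches agree at $d_i = m$, so the weight
function is continuous. If $m = 0$ (perfect overlap after convergence),
zero distances keep weight 1 and positive ones get a floor of $10^{-6}$,
which keeps the weighted estimate defined. The weights enter both the
objective and the transform estimate (`weightedEstimation = FALSE`
restricts them to the objective).

**The objective.** The evaluation value per round is
$\mathrm{RMS} = \frac{1}{N_F}\sum_i \delta_i d_i$ — by its conventional
name a weighted *mean* of distances rather than a root-mean-square, but it
is kept under the field's label and as printed. A true RMS variant
$\sqrt{\frac{1}{N_F}\sum_i \delta_i d_i^2}$ sits behind
`objective = "rms"`. One consequence worth knowing: the alternation
argument that makes classic ICP monotone applies to the summed *squared*
error, so within an inner loop the printed mean-distance objective can
tick upward transiently even though $\sum d_i^2$ falls; the test suite
asserts exact monotonicity for the true-RMS variant and the outer
accepted-best trace is monotone by construction (elitism).

**Inner loop.** From a starting transform: move, match, weight, score,
estimate, compose; stop when the objective changes by less than
`innerDeltaTol` (default $10^{-6}$ mm) or after `maxInnerIterations`
(default 100). With uniform weights this is exactly classic ICP, and
`registerICP()` is implemented as that configuration of `registerIICP()`.

**Outer loop and escape mechanism.** Each outer round runs the inner loop
from a restart point; a result that beats the best so far replaces it. The
search stops when the best objective falls below `rmsThreshold` (default
$10^{-4}\times$ the reference bounding-box diagonal) or after
`maxOuterRounds` rounds. Otherwise a perturbation proposes the next
restart:

1. $\gamma$ is the six-vector of absolute parameter differences (extrinsic
   XYZ Euler angles, wrapped to $(-\pi,\pi]$, and translations) between the
   round's starting transform and its converged result — the step the
   search just took. Zero components are floored (1° per rotation axis, 1%
   of the bounding-box diagonal per translation axis) so the mechanism
   never dies.
2. Each of the six parameters of the best transform receives an independent
   draw from the *parabolic* density
   $p(y) = 3y^2 / \left(2(\alpha\gamma_k)^3\right)$ on
   $(-\alpha\gamma_k, \alpha\gamma_k)$, sampled by inversion
   ($y = \mathrm{sign}(2u-1)\,\alpha\gamma_k\,|2u-1|^{1/3}$). Mass
   concentrates near the interval ends: large jumps, the ones that can
   clear a basin, are favoured.
3. A golden-section search (ratio $\varphi = (\sqrt 5 - 1)/2 \approx
   0.618$) minimizes the one-shot objective along the parameter-space
   segment from the best transform (s = 0) to the proposal (s = 1), over
   $s \in [0.5, 1.25]$, and the minimizer becomes the restart point.
4. The range factor $\alpha$ starts at 1, multiplies by 1.5 each round
   without improvement (capped at 20), and resets to 1 on improvement.

The best transform ever seen is always retained, so the accepted-best
trace is non-increasing regardless of how wild the restarts get. Restart
rounds whose correspondences degenerate (a jump so large that every
floating point matches one corner of the reference, making the rotation
unidentifiable) are counted as failed rounds rather than errors.

### Design choices that were genuinely open

*Where the golden-section attaches.* The source procedure presents
golden-section as a bracketing speed-up without stating its operand. We
searched the best-to-proposal segment. Bracketing the *whole* segment
(including the incumbent at $s=0$) turns out to be self-defeating: the
incumbent's basin is locally deepest at the first interior comparison, so
the search collapses every restart back to $s \approx 0$ and exploration
stops. Restricting the bracket to $s \in [0.5, 1.25]$ — the proposal's
neighbourhood, ignoring the already-explored region near the incumbent —
preserves the escape behaviour the restarts exist for. Both bounds are
configurable (`gsLower`, `gsUpper`).

*What $\gamma$ compares.* $\gamma$ is computed from the round's starting
transform and its result. Comparing consecutive accepted bests instead
collapses $\gamma$ toward zero as soon as improvements become incremental,
freezing the perturbation at its jitter floor and leaving the search
trapped. The start-vs-result reading keeps
the range self-sustaining: a restart that jumps far and falls back yields a
large $\gamma$ for the next proposal.

*Round budget.* The escape mechanism descends in many small accepted steps
(one to a few degrees per round on large displacements). The default
`maxOuterRounds = 100` is sized so that displacements up to 50° per axis
plus 200 mm — the classic benchmark protocol — have room to complete the
descent; a substantially smaller budget risks stalling mid-descent on such
displacements. For small displacements the threshold stop ends the search
long before the budget.

*The parabolic density.* The printed form of the perturbation density
(an odd cubic) cannot be a probability density; the surrounding description
calls it parabolic, and the normalized even parabola above is the unique
parabola on the stated support with that character. Its second moment is
$3(\alpha\gamma)^2/5$, which the test suite verifies by moment matching
and a goodness-of-fit test.

*Numerical details.* Euler convention is extrinsic fixed-axis X→Y→Z,
radians internally, degrees at the interfaces; `toParameters()` raises an
explicit error within $10^{-6}$ of gimbal lock and the perturbation
re-samples such proposals (at most 100 attempts). Nearest neighbours come
from an exact KD-tree (compiled code) with ties broken deterministically to
the smallest reference index. The weighted Kabsch estimate corrects
reflections by a sign flip and raises a degenerate-geometry error when the
second singular value of the weighted cross-covariance vanishes
(collinear correspondences). All stochastic draws flow from the single
`seed` in the configuration through a private RNG stream, so results are
bit-reproducible and the caller's RNG state is untouched.

## Evaluation

`targetRegistrationError()` matches markers *by label* (fiducials are
identified, never nearest-neighbour matched) and reports
$TRE_i = \|p_i^{valid} - p_i^{f}\|$ per marker, signed per-axis errors
(registered minus validation), and per-axis averages of *absolute* errors —
signed entries with absolute-value averages is the convention the per-axis
error tables in this literature follow. `benchmarkRun()` repeats
registration with seeds derived from a master seed and aggregates the
per-run records it also returns.

## The synthetic generator

`makeSurfaceCloud()` samples closed star-shaped surfaces: a
`head_ellipsoid` with semi-axes 100/75/90 mm (bounding box roughly
200×150×180 mm, head-like) and a near-symmetric `bumpy_sphere`
(85/75/65 mm). Both carry five Gaussian bumps of distinct amplitude at
fixed latitudes; the asymmetry plays the role of facial features — it
defeats spurious symmetry solutions and provides reproducible marker loci
(the bump apexes, labelled M1–M5) across seeds.

`makeRegistrationCase()` emulates a single-view scan: a half-space crop of
the reference (a depth sensor sees one side; the plane orientation is
randomized per seed) keeps `overlapFraction` of the surface, a random
subsample of the *kept reference points* of size `nFloating` is perturbed
with per-axis Gaussian noise (`noiseSigmaMm`, default 1 mm — consumer
depth-camera noise at arm's length), a fraction is replaced by uniform
outliers in the bounding box, and everything is pushed through the inverse
of the ground-truth transform. Because the floating points are a subsample
of the reference cloud itself, noise-free cases admit an exactly-zero
objective, which is what makes sub-0.1° parameter-recovery checks
meaningful. The defaults are the package's headline scenario: 2,000
reference and 500 floating points, 70% overlap, 1 mm noise, 2% outliers,
30° rotation about the (1,1,1) diagonal plus 100 mm translation along it.

`localMinimumFixture()` builds the adversarial case: the near-symmetric
bumpy sphere under a 50°-per-axis rotation, certified at generation time by
running `registerICP()` and requiring a ground-truth rotation error above
10°; seeds advance until the certificate holds and the accepted seed is
recorded in the generator echo.

What the generator does *not* emulate: structured depth-sensor noise
(quantization, distance-dependent variance, edge artefacts), surface
self-occlusion beyond a single half-space cut, non-rigid anatomy, and
marker localization error (markers ride noise-free, so TRE isolates
alignment error). Passing tests on these surfaces therefore demonstrate the
optimizer's behaviour — escape from local minima, robustness to partial
overlap and outliers at the stated rates — not sensor-specific performance.

## Problem sizes used by the checks

The bundled checks run at the scale of the scenarios they probe: the
headline scenario at 2,000/500 points over ten cases; the benchmark-style
protocol (100-point subsample, 50°/axis + 200 mm) on a 2,000-point surface;
parameter recovery over 100 seeded 500/120-point noise-free cases; the
local-minimum fixture at 500/120 points over 20 seeds; sampler
distribution checks at $10^5$ draws. `scripts/acceptance.R` recomputes the
headline quantity — the grand mean per-marker TRE over ten cases — from
scratch at exactly those conditions.

## Known limitations

Point-to-point matching only (no point-to-plane or normal-space metrics);
rigid transforms only (no scale or non-rigid deformation); the perturbation
is a heuristic global search — it carries no optimality certificate, and on
strongly self-similar surfaces (near-spheres with faint features) its
success rate degrades with the feature-to-radius ratio. Runtime scales
linearly in the outer-round budget when the noise floor keeps the objective
above the stop threshold, because every budgeted round is spent.
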