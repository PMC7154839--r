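---
title: "Discovering and aligning articulated-object behaviors with potkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and aligning articulated-object behaviors with potkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

potkit organizes a collection of video shots of one articulated object
class (an animal, typically) with only the class label as supervision. From
per-shot dense point trajectories, foreground masks and optical flow it
(1) discovers the recurring behaviors of the class as clusters of temporal
intervals, and (2) recovers pixel-level spatial alignments between pairs of
behavior instances. This vignette explains the models behind each stage,
the tunable parameters, the numerical choices, and what the synthetic test
scenes do and do not demonstrate.

## The PoT motion descriptor

Articulated motion is captured by ordered *pairs of trajectories* (PoTs).
For a pair (anchor $a$, swing $s$) tracked over $n$ frames, let
$r^k = s^k - a^k$ be the anchor-to-swing vector at frame $k$ and
$d^k = r^k - r^{k-1}$ the relative displacement. The descriptor is

$$P = \left(\theta,\ \frac{d^2}{D},\ \ldots,\ \frac{d^n}{D}\right),
  \qquad D = \sum_{k=2}^n \lVert d^k\rVert ,$$

with $\theta$ the anchor-to-swing angle in the first frame. Its length is
$2(n-1)+1$ (19 for the default $n = 10$). Because $d^k$ cancels any motion
common to both trajectories, the descriptor is exactly invariant to camera
panning; recording only the angle (not the distance) between the pair and
normalizing by $D$ makes it scale invariant. Pairs with $D = 0$ are rigid
and carry no articulation signal; they are discarded rather than emitted as
zero vectors.

**Selection.** Candidate pairs at frame $f$ are all ordered pairs of
foreground trajectories alive on $[f, f+n-1]$. A pair is scored by
$S(\{a,s\}) = \sum_k \lVert v_s^k - v_m^k\rVert - \lVert v_a^k -
v_m^k\rVert$, where $v_m$ is the per-frame median foreground flow — an
estimate of whole-object motion. High scores mean the swing moves against
the body while the anchor rides with it, which preferentially samples pairs
across joints without any skeletal model. The top $\theta_P = 0.15$
fraction per frame is kept (ties broken by anchor/swing id so extraction is
deterministic). Velocities are per-frame displacements; the $n$-th term
reuses the last displacement so that the sum has $n$ terms while only
window points are touched.

**Frame pruning.** Frames without articulated motion are skipped:
$\sigma_f$ is the population standard deviation of foreground flow
magnitudes divided by their mean (defined as 0 when the mean is below
$10^{-6}$ px — a still frame), and a window score
$s(f) = \tfrac1n \sum_{i=f}^{f+n-1}\sigma_i < \theta_F = 0.1$ prunes the
frame. The population form of the standard deviation is used so that a
two-valued flow field (half the mask still, half at speed 2) has
$\sigma = 1$ exactly.

A trajectory counts as foreground only if every point of its span lies
inside the mask — a conservative rule, which is the safe direction because
background trajectories poison pair scores while losing a few border
trajectories only thins the candidate set.

## Temporal partitioning

Shots are cut into single-behavior intervals with two motion cues.

**Pauses** are maximal runs of at least `min_pause = 3` frames with
$\sigma_f < \theta_F$. Pause frames are dropped from the output intervals:
by definition they carry no articulated motion, and keeping them would only
dilute the interval BoWs.

**Periodicity.** Each codeword of a per-frame PoT bag-of-words gives a time
series; their FFT power spectra are summed, the DC bin dropped, and the
rest normalized to total energy 1. A window is periodic when the highest
admissible bin (at least 3 cycles in the window, period at least 5 frames)
reaches $\theta_H = 0.1$. Power (squared magnitude) rather than raw
magnitude is summed: energy concentrates quadratically at a genuine shared
frequency while a broadband baseline stays flat, which is what lets one
fixed threshold separate gaits from noise. The search slides windows of
every length from `min_window` up to the segment length (start positions on
a 5-frame grid plus the flush-right position), labels the best window if it
clears $\theta_H$, and recurses on the remainders so consecutive behaviors
with different periods (a walk followed by a run) split even without a
pause.

`min_window` defaults to 40 frames. The hard floor of the spectrum test is
15 frames (3 cycles of a 5-frame period), but a 15-frame window has only a
handful of admissible frequency bins, so even a featureless spectrum puts
$\gtrsim 1/6$ of its energy in one of them — no threshold can be calibrated
there. At 40 frames the admissible-bin count is large enough that an
i.i.d.-random bag-of-words essentially never reaches 0.1, while three-cycle
gaits concentrate 0.2–0.4 of their energy in the fundamental. The
consequence is that periodic bouts shorter than 40 frames are not split
off; they simply remain part of their surrounding interval. Leftover
segment pieces shorter than 15 frames can never be certified as distinct
behaviors and are merged into their neighbor, so no returned interval is
shorter than 2 frames.

## Clustering intervals into behaviors

Intervals are represented as L1-normalized bags-of-words over a k-means
codebook of PoT descriptors (Euclidean distance, 8 restarts keeping the
lowest within-cluster energy, sample capped at $10^6$ descriptors). The
distance between intervals is $d(I_u, I_v) = -\exp(-(1 -
\mathrm{HI}(b_u, b_v)))$ with HI the histogram intersection; it lies in
$[-1, -e^{-1}]$, reaching $-1$ only for identical histograms. Several
feature channels combine as $-\exp(-\sum_i (1-\mathrm{HI}_i)/A_i)$, where
$A_i$ is the average $(1-\mathrm{HI})$ of channel $i$ over the collection
being clustered — computed on the input itself, since a held-out estimate
would change nothing for ranking and complicates the interface. Clustering
is agglomerative with complete linkage, cut at $k$ clusters ($k$ defaults
to a fourth of the number of intervals); merge tie-breaking is delegated to
`stats::hclust`, whose deterministic behavior is sufficient for
reproducibility. Intervals whose BoW is empty (no PoTs survive pruning) are
excluded and reported rather than forced into a cluster.

## Consistent motion pairs

Within a behavior cluster, two intervals are scanned for pairs of $T = 10$
frame subsequences whose per-frame motion agrees: $d_{ij}$ is the
multichannel distance between the frame-level BoWs (PoT channel plus a
motion-boundary-histogram channel — orientation histograms of the spatial
flow derivatives in a 16 px patch around each track point), and a
subsequence pair scores $\sum_{t=0}^{T-1} d_{(i+t)(j+t)}$, which preserves
temporal order. The most negative sums win; among the top candidates, any
pair whose two start offsets both lie within $T/2$ of an already selected
pair is suppressed as a near-duplicate. Frames with an empty BoW get the
maximally dissimilar value $-e^{-1}$ so they cannot fake similarity.

## Homography alignment

The coarse alignment of a CMP fits a single homography $u = Hv$ mapping the
second sequence onto the first, estimated from trajectory matches. Each
trajectory is described by its frame-to-frame displacements plus the vector
from its start point to the foreground center of mass, normalized by the
mask bounding-box diagonal — this appended context disambiguates
trajectories with identical shape (all points on a rigid torso move alike).
Matching is nearest-neighbor between sequences, restricted to windows
starting at the same within-CMP frame, so each match yields $T$ point
correspondences.

RANSAC samples either 4 points (independent matching, IM) or 4 trajectory
matches solved in least squares over their $4T$ points (temporal matching,
TM); a TM match is an inlier only when more than half of its points
reproject within threshold. The inlier threshold defaults to 0.05 of the
mean foreground bounding-box diagonal — scale-adaptive, so the same setting
works for large and small subjects. Iterations adapt to the inlier ratio at
0.99 confidence with a ceiling of 2000; degeneracy is judged on one point
per sampled trajectory, since a single trajectory's points are typically
near-collinear by themselves. With foreground regularization, the per-frame
bounding-box corner correspondences join every least-squares fit with unit
weight; with no trajectory matches at all this degenerates gracefully to
the bbox-only fit. Models whose outlier fraction exceeds the allowed
maximum return nothing — that knob is the operating point of the
precision–recall sweep. The returned matrix is normalized to unit Frobenius
norm with a positive bottom-right element.

## TPS, TPS-RPM, and the temporal TPS

A thin-plate spline $f$ (affine part plus radial warp) minimizes
$\sum_i \lVert u_i - f(v_i)\rVert^2 + \lambda\,L(f)$, solved in closed form
from the kernel system; as $\lambda \to \infty$ the warp vanishes and the
solution tends to the least-squares affine fit, as $\lambda \to 0$ it
interpolates. Per-pair weights enter as $K + \lambda\,\mathrm{diag}(1/w)$;
the weight floor is $10^{-12}$, only to avoid division by zero — a
vanishing weight must genuinely remove its pair, or the alternation below
loses its monotonicity.

TPS-RPM alternates a soft-correspondence update and a weighted TPS fit
under deterministic annealing. The correspondence matrix gets Gaussian
affinities $\exp(-\lVert u_i - f(v_j)\rVert^2 / 2T)$ plus an outlier row
and column at $e^{-1/2}$ (the affinity of a point at squared distance $T$),
balanced by iterative row/column scaling. Temperature starts at the mean
squared nearest-neighbor distance, anneals by 0.93 per level down to 1 px²,
with 5 alternations per level; $\lambda = \lambda_0 T$ with $\lambda_0 = 1$
ties smoothness to temperature in the usual robust-point-matching way. The
quantity reported in `energy_trace` is the annealing free energy — data
term, outlier cost, bending, and the entropic term
$2T\sum m(\log m - 1)$ over the full balanced matrix. That exact form
matters: the scaled soft-assign update is the KKT point of this functional
(with the $-m$ term), so the trace is non-increasing across alternations at
fixed temperature, which the tests assert with essentially zero slack.

The temporal TPS aligns all $T$ frames with one correspondence matrix
shared across time. Exact inference is intractable, so for each anchor
frame $\tau$ the edge points extracted at $\tau$ are matched by TPS-RPM
(initialized by pre-warping the second sequence's points through the
homography), the correspondences are frozen, both point sets are propagated
to every other frame with optical flow (points that leave the image retire
from all frames), and a per-frame TPS is fitted to the propagated pairs at
$\lambda = \lambda_0 T_{\mathrm{final}}$. Each $\tau$ yields a candidate;
the lowest total energy (summed weighted residuals plus bending over all
frames, on identical point budgets) wins, and the tests assert the argmin
contract exhaustively. Edge points come from an edge-strength map (the
package default is the normalized gradient magnitude; any detector mapping
into $[0,1]$ can be plugged in) multiplied by a distance-transform weight
$\exp(-\mathrm{DT}/(0.1\,\mathrm{diag}))$, so on-mask points weigh 1 and
the 0.2 pruning threshold has a scale-free meaning; survivors are uniformly
subsampled to at most 1000 per frame with a per-CMP seed. Before spline
fitting the points are additionally thinned to a 3 px minimum spacing: edge
maps deliver bands of directly adjacent pixels, and the final annealing
temperature (1 px²) can only resolve individual correspondences when
neighboring samples sit a few standard deviations apart — without thinning
the soft-assign blends sub-spacing neighbors and the identical-sequences
fixed point is visibly bent. The same per-anchor-frame seed subsamples both
sequences, so identical inputs reduce to identical point sets.

## Evaluation

Purity and the adjusted Rand index score discovered clusters against
per-frame ground-truth labels (an interval's label is its modal frame
label); ARI is computed by `mclust::adjustedRandIndex`. Interval uniformity
is the modal-label fraction of an interval's frames. The alignment error of
a CMP maps each co-visible landmark in both directions, normalizes each
directional distance by the object scale of its target frame (the maximum
pairwise distance among visible landmarks — each direction uses its own
frame's scale, the stricter reading when the two instances differ in size),
and averages. An alignment is *correct* when the error is below 0.18 and
the intersection-over-union of the landmark-name sets visible anywhere in
each sequence exceeds 0.5; the set-level IOU (rather than per-frame) is the
stricter reading and is what blocks accidental alignments of a few
landmarks. A CMP is *alignable* when even the homography fitted to its
ground-truth landmark correspondences passes that rule. Precision is
(correct / returned) — defined as 1 when nothing is returned, the usual
curve-endpoint convention — and recall is (correct / alignable); average
precision is the trapezoidal area over recall.

## The synthetic scenes

The generator renders a 2-D side-view quadruped of 11 rigid capsules
(torso, neck, head, four two-segment legs) driven by behavior programs:
walking and running are sinusoidal gaits with lateral-sequence phase
offsets (periods 12 and 6 frames, translation 1 and 2 px/frame), pausing
freezes all joints, head-turning oscillates the neck and head, and sitting
ramps the hind legs and pitch monotonically — articulated but aperiodic.
Masks are exact capsule rasterizations; flow at each pixel is the analytic
rigid displacement of the body point occupying it, defined on a 2 px halo
around the body so that bilinear interpolation at the silhouette never
mixes in zero background flow. Trajectories are seeded on segment interiors
and advected through that flow; since a rigid motion's displacement field
is affine in position and bilinear interpolation is exact for affine
fields, advection reproduces the analytic kinematics, and
flow/trajectory consistency holds to machine precision by construction.
Landmarks are the joint positions (nose, eye, neck, tail, hips, knees,
hooves). `warp_scene` produces geometrically transformed copies under known
homographies or TPS warps (with optional positional noise), and
`degrade_scene` erodes/dilates masks and adds flow noise for robustness
experiments.

What the scenes do **not** emulate: appearance and texture (all matching is
motion- and silhouette-based), occlusion and viewpoint change, tracking
failures, and segmentation errors beyond the synthetic degradation knobs.
Tests passing on these scenes therefore validate the algorithmic
contracts — descriptor invariances, selection and partitioning logic,
estimator correctness, energy monotonicity — not performance on real video,
where mask quality and tracker noise dominate.

## Problem sizes and numerical choices

The test and acceptance runs use scenes of 80–120 trajectories on 96 × 200
to 96 × 320 px frames, 20–96 frames per shot, codebooks of 20–100 words,
and 120–250 edge points per frame for the spline stages — sizes at which
every stage completes in seconds while all contracts remain binding.
Homography estimation uses normalized DLT; the TPS kernel system falls back
to a ridge-regularized solve (with a warning) if singular; reverse TPS
mappings are computed numerically (an inverse-spline initial guess refined
by damped Gauss–Newton with a finite-difference Jacobian, accurate to
machine precision inside the control domain); k-means restarts are seeded
`seed + restart` so codebooks are bit-reproducible; RANSAC and all
subsampling take explicit seeds. Known limitations: edge-based
correspondence slips tangentially along smooth silhouettes, so TTPS gains
over the homography are largest when the true deformation is strongly
non-projective; behavior programs switch instantaneously at schedule
boundaries (one high-motion frame, no co-articulation); and the
periodicity stage cannot certify bouts shorter than `min_window` frames.
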