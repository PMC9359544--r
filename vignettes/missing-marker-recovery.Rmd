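---
title: "Missing-marker recovery by locally weighted PCA regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missing-marker recovery by locally weighted PCA regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mocapfill)
```

## The problem and the model

A marker-based capture take is a matrix $A \in \mathbb{R}^{m \times 3n}$ of
$m$ frames by $n$ markers (x, y, z per marker). Human motion is highly
redundant: marker trajectories are smooth and strongly correlated across the
body, so $A$ is well approximated by a low-rank factorisation. A *gap* is a
contiguous run of frames over which one marker is unobserved; gap
granularity is the whole marker, since an optical system loses all three
coordinates together. The package treats three corruption patterns: a single
gapped marker, several simultaneously gapped markers, and wholly missing
frames.

The regressors assume training samples of the *same shape* as the test
sample ($m \times 3n$ windows, typically cut from longer recordings of the
same subject and activity with `make_training_windows()`), complete
(ungapped), and sharing the test sample's correlation structure. The key
device is gap transplantation: the test sample's gaps are copied verbatim
onto every training window, so the relationship between gapped and complete
motion can be *learned* where the ground truth is known, then applied where
it is not.

### The gap regression

For each gap $g$ alone, applied to all $K$ training samples, two principal
bases are extracted: $U$ from the complete stack and $\tilde U^g$ from the
single-gap stack (top-$k$ right-singular vectors; missing entries sit at the
column mean after de-meaning, i.e. at zero). A $k \times k$ mapping $T^g$
aligns the projections, $A_i U \approx \tilde A_i^g \tilde U^g T^g$, solved
in closed form by stacked least squares. The per-gap reconstruction operator
is $P^g = \tilde U^g T^g U^\top$.

The residual $B = \sum_g \sum_i (A_i - \tilde A_i^g P^g)$ measures where
this family of operators fails; the eigenvalues $\delta_i$ of $B^\top B$
define the diagonal weight matrix $W = \mathrm{diag}(1/\max(\delta_i,
\text{floor}))$. Directions of small residual get large weight — weighted
least squares, the standard correction for heteroscedastic residuals.

Finally one scalar coefficient per gap combines the operators. The
coefficients minimise $\sum_i \mathrm{tr}(R_i W R_i^\top)$ with $R_i = A_i -
\tilde A_i \sum_g \alpha_g P^g$, where $\tilde A_i$ now carries **all** test
gaps at once — the fit sees exactly the corruption pattern it must undo. The
objective is quadratic in $\alpha$, so the solution is a $G \times G$
normal-equation solve. Reconstruction multiplies the mean-centered,
zero-filled test sample by $\sum_g \alpha_g P^g$ and restores the means;
only missing entries are replaced.

### Local weighting

Weighted least squares copes with noise but underfits where the motion near
a gap fluctuates sharply while distant markers dominate the global
least-squares fit. The locally weighted variant tapers the data around each
gap with a Gaussian mask over (frame, marker) cells,

$$Q^g_{ij} = \exp\{-(d_t(i)^2 + d_s(j)^2)/\sigma^2\},$$

where $d_t$ is the distance (in frames) to the gap interval, zero inside it,
and $d_s$ is the shortest-path distance from marker $j$ to the gap marker on
the skeleton connectivity graph — body topology, not Euclidean space, so a
hand marker is "far" from a foot marker even when the pose brings them
close. Frames and skeleton hops are incommensurate; both are divided by
configurable unit scales before the Euclidean combination (see Parameters).

Each gap's mask multiplies the complete and gap-group stacks elementwise
before the eigen-decompositions, so the per-gap bases $U^g, \tilde U^g$
describe the motion *near* the gap; the same mask weights the residual
accumulated into $B$, and the coefficient solve masks its residual by the
normalised sum $\bar Q$ of all gap masks. Since every mask entry is at most
1, tapering only removes energy: the tapered covariance is effectively
sparse, and distant erratic motion cannot steer the fit. The mapping $T^g$
is fit on the **raw** centered samples against the tapered bases: the taper
belongs to the covariance (basis) estimation, and fitting the mapping on raw
samples keeps the composite operator consistent with the raw test sample it
is later applied to. (Fitting the mapping on tapered samples as well was
measured 4–6× worse and is not what the formulation prescribes — only the
covariance step is "updated" by $Q$.)

With $\sigma = \infty$ every mask is identically 1 and the tapered fit
reproduces the untapered one exactly (verified to machine precision in the
tests).

### Wholly missing frames

When entire frames are dropped there is nothing to condition on in marker
space, but frame-to-frame correlation remains: the Gram matrix $AA^\top$ of
the horizontally concatenated training samples ($m \times 3nK$) defines a
frame-space basis $V$. Partitioning rows into observed (1) and missing (2)
parts, a sample in the span of $V$ satisfies $P_2 =
V_2 (V_1^\top V_1)^{-1} V_1^\top P_1$ — missing rows follow from observed
ones. Each missing frame is one gap with a temporal-only taper; per gap the
complete and row-zeroed stacks give bases $V^g$ and $\tilde V^g$ and a
mapping $T^g$, and one coefficient per missing frame is solved by weighted
least squares (the weight matrix here has one entry per missing frame, from
the eigenvalues of $BB^\top$).

One representational point deserves note: the rows of the gapped-stack basis
$\tilde V^g$ vanish identically at the missing frames (those rows of the
data are zero, and left-singular vectors with nonzero singular value are
linear images of the data columns), so the missing-row block of the gapped
basis carries no information. The predictor therefore takes its missing-row
block from the complete-data basis through the mapping — under an exact
mapping $V = \tilde V T$ the two forms are algebraically identical, and the
resulting estimator
$V_2^g\,(T^{g\top} \tilde V^{g\top} \tilde V^g T^g)^{-1} T^{g\top}
\tilde V_1^{g\top} M_1$
recovers representable noiseless frames to machine precision (tested).

### Recovery error

Error is reported as
$\epsilon = \lVert (M^* - M_{\mathrm{grd}}) \circ \text{Mask} \rVert_F^2 / m$
with $m$ the **number of missing entries** — not the frame count — so
figures are comparable across gap counts and lengths. The measure is in
squared position units of the data; errors from differently scaled datasets
are not comparable.

## Parameters

* `k` / `var_fraction` — retained subspace dimension. Default: smallest $k$
  capturing 95 % of the eigenvalue mass of the complete-data stack; the same
  $k$ is imposed on every gap-group basis so the mapping is square. A fixed
  `k` override is available and is what the tests use (the synthetic rank is
  known there). `k` is silently capped at the numerical rank, with a
  warning.
* `delta_threshold` (default `1e-3`, relative) — floor for the residual
  eigenvalues, as a fraction of the largest; prevents division by zero and
  caps the dynamic range of the weights. An absolute variant is available.
  When the residual vanishes entirely (noiseless exactly-representable
  data) the floor falls back to a small absolute constant, giving uniform
  weights.
* `taper_config(sigma, temporal_scale, spatial_scale)` — `temporal_scale`
  (default 10 frames) and `spatial_scale` (default 1 hop) make the two
  distance terms dimensionless; `sigma` (default 3) is the Gaussian window
  in those units. The defaults are package choices tuned on synthetic data:
  at 120 Hz, 10 frames ≈ 80 ms of motion context, and 3 window units reach
  roughly 3 bones / 30 frames before the weight drops below
  $e^{-1}$. For whole-frame recovery the tests and the acceptance study use
  `temporal_scale = 30`: with no spatial term, recovery leans on a wider
  temporal context, and a narrow taper was measured to bias it. `sigma =
  Inf` disables tapering.
* `window` / `stride` in `make_training_windows()` — training windows are
  non-overlapping 400-frame cuts by default, the conventional working size
  for gap filling; all regressors require training and test windows of
  equal length.

## The synthetic generator

`generate_motion()` emulates what the regressors exploit in real optical
captures: smooth, body-wide correlated motion. Latent sinusoidal time
courses (seeded random frequencies of 0.5–3 cycles per take, random phases)
times a Gaussian loading matrix give an *exactly* rank-`latent_rank` signal;
white Gaussian noise models sensor jitter (default amplitude two orders
below the motion); an optional `burst` injects a Hann-windowed
high-frequency oscillation at one marker — the sharply fluctuating joint
regime. The skeleton is a chain or a binary tree. All randomness flows
through one seed; identical configurations reproduce identical samples.

It does **not** emulate bone-length rigidity, ground contact, nonstationary
activity switches, or correlated (non-white) sensor error. Passing tests
therefore demonstrate the correctness and the qualitative behaviour of the
machinery — exactness on representable data, trend directions, ordering
against baselines — not absolute error levels on real captures, which
depend on units, subject and activity.

Windows cut from one generated take share their loading matrix, so every
window's rows lie in one `latent_rank`-dimensional coordinate subspace (and
their frame profiles in a `2 × latent_rank` frame subspace, sine and cosine
per frequency). The exactness oracles in the test suite rely on both facts.

## Numerical choices

* All subspaces come from thin SVD of the data stacks (not from forming the
  covariance explicitly) — the numerically stable route to the same
  eigenvectors; eigenvalues are squared singular values.
* SVD sign ambiguity is fixed deterministically: each basis column is
  flipped so its largest-magnitude entry is positive, first occurrence
  winning ties; repeated fits are bit-identical.
* Least-squares solves go through QR with a Moore–Penrose fallback when
  rank-deficient; the normal-equation solve for the coefficients
  pseudo-inverts a singular system.
* Missing entries are zero-filled after de-meaning (mean imputation) — the
  fill that leaves column means unchanged. Test samples are centered with
  the *training* means, never their own, so heavily gapped columns are
  centered consistently.
* Degenerate inputs: a column observed nowhere raises an error (no mean can
  be estimated); a training set whose projections are entirely masked
  raises a degenerate-system error; all frames missing is refused.

## Design decisions

* Frames are 1-based with closed intervals `[start, end]`, the idiomatic R
  convention; a 380-frame gap is `gap_spec(j, 11, 390)`.
* A non-finite value in any one coordinate masks the whole marker at that
  frame (whole-marker gap granularity).
* The per-gap residual accumulated into $B$ uses the single-gap training
  samples for both variants, which keeps the tapered fit a strict
  generalisation of the untapered one.
* File formats: TRC and CSV, read and written losslessly (missing entries
  as blank/`NaN`). C3D is out of scope — it is a binary industry format
  whose faithful support is a project of its own; export to TRC first.
* The evaluation CLI (`exec/mocapfill`) is a thin wrapper over the exported
  functions; the package API is the primary interface.

## Test study conditions

The stochastic properties in the test suite run at reduced scale so the
whole suite stays fast: windows of 50–100 frames, 8–12 markers, latent rank
4–6, 3–5 windows per take, 10–60 seeds per property (stated in each test).
The acceptance study in `scripts/acceptance.R` uses 20 markers, 100-frame
windows, 5 training windows, 95-frame gaps and 10 trials per protocol.
These sizes are the package's own choices; the defaults of
`synth_config()` (41 markers, 400-frame windows) reproduce the conventional
full-body geometry when wanted.

## Known limitations

* **Simultaneous gaps are not recovered exactly even on noiseless
  representable data.** Each per-gap basis is estimated with the *other*
  gap markers observed; at test time all gaps are missing at once, which
  perturbs every per-gap projection, and $G$ scalar coefficients cannot
  cancel the cross-terms. The residual shrinks rapidly with marker
  redundancy (measured relative MSE $2.8\times10^{-2}$ /
  $9.3\times10^{-4}$ / $3.1\times10^{-5}$ at 8 / 20 / 41 markers for three
  whole-window gaps) but does not vanish. Single whole-window gaps *are*
  recovered exactly.
* **Partial-window gaps mix observed and masked rows of the same marker**
  in one gap-group stack, which a rank-$k$ basis cannot represent both of;
  recovery of, e.g., a 95 %-length gap is approximate even without noise.
* **Tapering is a bias–variance trade.** On clean, globally low-rank data
  the untapered fit is better (the acceptance study shows this ordering);
  tapering pays off when distant markers misbehave — its error *variance*
  is consistently the lowest in the erratic-marker study. Recovering a
  disturbance confined to the missing marker itself is impossible for any
  method: nothing observed carries it.
* **A marker missing for an entire session** cannot be handled: no mean or
  correlation for it can ever be estimated. A marker missing for a whole
  *window* is fine as long as training windows cover it.
* Error figures are in the squared units of the input coordinates; compare
  only within one dataset.
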