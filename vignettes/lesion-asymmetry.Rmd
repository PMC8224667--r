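---
title: "Shape asymmetry indices and FFBPN classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape asymmetry indices and FFBPN classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionasym)
```

## Scope and model

`lesionasym` takes already-segmented binary lesion masks (foreground = 1)
and answers two questions: *how asymmetric is this lesion?* (four scalar
indices A1–A4) and *which class is it?* (nevus, melanoma or dysplastic
nevus, via a small feedforward network on those indices). Segmentation
itself is out of scope: masks arrive from whatever pipeline produced
them, and color or texture information is ignored except for an optional
grayscale companion image used to weight centers of mass.

Coordinates are 0-based `(row, col)` with the origin at the top-left
corner; every user-facing quantity (centroids, orientations, fold lines)
uses this frame.

## Geometric normalization

All indices are defined relative to the lesion's principal axes.
`shape_frame()` computes the centroid, the intensity-weighted center of
mass (identical to the centroid for binary-only input), and the
orientation

$$\theta = \tfrac12\,\mathrm{atan2}\!\left(2\mu_{11},\ \mu_{20}-\mu_{02}\right) \in (-\pi/2, \pi/2],$$

from the second central moments of the foreground pixel set, plus the
axis lengths of the circumscribing ellipse from the moment-matrix
eigenvalues. When the moment matrix is isotropic
($\mu_{11}=0$, $\mu_{20}=\mu_{02}$ — squares, crosses, disks) any axis is
principal; we define $\theta = 0$ so behavior is deterministic.

`align_to_axes()` rotates the mask by $-\theta$ about the sub-pixel
centroid with nearest-neighbor resampling, which preserves binarity and
avoids gray interpolation artifacts. The output canvas is a square of
side $\lceil\sqrt{M^2+N^2}\rceil + 2$ so no realistic lesion is clipped.
Two numerical details matter:

* rounding is half-**up** (`floor(x + 0.5)`), not R's half-to-even:
  consistent rounding keeps a grid translated by half-integer offsets
  rigid, whereas banker's rounding would duplicate some rows and drop
  others, visibly distorting symmetric shapes;
* sines/cosines within `1e-9` of $0$ or $\pm 1$ are snapped exactly, so
  quarter-turn rotations are rigid permutations of the grid and preserve
  area exactly.

If the realigned mask's recomputed orientation still exceeds the angular
tolerance (0.05 rad — nearest-neighbor quantization shifts moments
slightly), one corrective second pass is applied.

## The four indices

**Fold indices A1, A2.** After alignment the major axis is horizontal.
`fold_overlap()` reflects the foreground set about a horizontal line
(major fold) and a vertical line (minor fold) and counts the mismatch
$\Delta A$ = half the symmetric-difference (XOR) between the set and its
reflection; reflections landing outside the canvas are mismatches. Then

$$A_1 = \frac{\Delta A_{minor}}{A_L} + \frac{\Delta A_{major}}{A_L},
\qquad
A_2 = \frac{\min(\Delta A_{minor}, \Delta A_{major})}{A_L}.$$

"Maximum overlap" is realized by trying a small set of candidate fold
lines — floor, round and ceiling of the sub-pixel centroid coordinate,
plus the half-integer midline between floor and ceiling — and keeping
the best. The half-integer candidate is essential: a shape of even
extent (e.g. a 20-pixel-diameter digital disk) is mirror symmetric about
a line *between* two pixel rows, which no integer line can realize; with
integer lines only, such a disk would score $A_1 \approx$ two boundary
bands instead of 0. Reflections about half-integer lines still land
exactly on the grid ($r \mapsto 2L - r$ with $2L$ integer), so the XOR
count stays exact. An exhaustive shift search would also work but buys
nothing: folding about a line further than one pixel from the centroid
strictly increases the mismatch for any blob-like lesion.

**Quadrant index A3.** The aligned lesion is split about its centroid
into quadrants Q1 (top-right) through Q4 (bottom-right), pixels exactly
on the centroid row/column going to the bottom/right side. Per quadrant
we record the area $\Delta A_i$, the distance $dD_i$ from the quadrant
centroid to the lesion centroid and its center-of-mass analogue $mM_i$.
The per-quadrant term has three selectable readings (the composition is
genuinely ambiguous in the literature this index descends from):

| formula | $\lambda_i$ | notes |
|---|---|---|
| `ratio-product` (default) | $(\Delta A_i/A_L)\cdot(dD_i/mM_i)$ | scale-free; ratio defined as 1 when $mM_i < 10^{-9}$ |
| `area-ratio-only` | $\Delta A_i/A_L$ | |
| `difference-product` | $(A_L-\Delta A_i)(dD_i-mM_i)$ | not scale-free |

$A_3$ is the mean of the four $\lambda_i$. Empty quadrants get
$\Delta A_i = 0$, $dD_i = mM_i = 0$, ratio term 1, and are flagged.
An important consequence: **on binary-only input the default reading is
identically 0.25** — the area fractions sum to 1 and every distance
ratio degenerates to 1 ($dD_i = mM_i$ exactly). A3 only becomes
informative when a grayscale image supplies independent centers of mass,
or under the alternate readings. This matches the behavior of the
quadrant index in the applied literature, where it is consistently the
weakest of the four, and it is why the classifier treats A3 as a
degenerate (constant) feature on synthetic data: the input scaler flags
it and maps it to 0 rather than failing.

**Projection index A4.** The mask is cropped to its foreground bounding
box; `H` holds per-column and `V` per-row foreground counts (both sum to
$A_L$). Since the box is generally non-square, both profiles are
linearly resampled to a common length (`n_bins = 64` by default — finer
than any lesion's pixel profile we generate, and the result is
insensitive to the choice because Pearson correlation is scale- and
location-invariant) and correlated. Conventions for degenerate profiles:
both constant → 1 (a rectangle is "perfectly symmetric"), exactly one
constant → 0.

## The classifier

`ffbpn()` fits a single-hidden-layer network: min–max input scaling to
$[-1,1]$ learned on the training block only (constant features flagged
and mapped to 0), tanh hidden layer, linear outputs, one-hot class
coding, MSE loss. Training is full-batch Levenberg–Marquardt:

$$\Delta w = -(J^\top J + \mu I)^{-1} J^\top e,$$

with $J$ the analytic Jacobian of all per-sample per-output residuals
with respect to the flattened weights (verified against central finite
differences to below $10^{-5}$ relative error in the test suite). A step
is accepted only if the training MSE decreases — so the accepted-step
trajectory is strictly monotone — after which $\mu \leftarrow \mu/10$;
otherwise $\mu \leftarrow 10\mu$ and the step is retried. Stopping:
1000 accepted iterations, $\mu > 10^{10}$, gradient $\infty$-norm below
$10^{-7}$, or six consecutive validation-MSE increases (the weights with
the best validation MSE are returned). Defaults follow the conventions
of the classical MLP toolboxes this design imitates: initial damping
$\mu_0 = 0.01$ (the role the "learning rate" plays in LM), damping
factor 10, patience 6, weight initialization $U[-0.5, 0.5]$ from a user
seed. Identical seeds and data give bit-identical trajectories.

The companion heuristic `suggest_hidden_neurons()` ships in two
variants: the `printed` rule $\lceil (N_{in}+N_p)/L \rceil$, which for
typical study sizes ($N_{in}=4$, $N_p$ of a few hundred) yields hidden
layers in the hundreds, and a `sqrt` variant
$\lceil \sqrt{N_{in}+N_p}/L \rceil$ that yields the tens reported as
sensible in the literature. The two disagree by an order of magnitude;
neither is asserted as ground truth, and the sweep sizes
$\{8, 12, 16, 20\}$ are the primary mechanism for choosing the hidden
layer.

Evaluation uses one-vs-rest confusion counts per class and the metric
suite sensitivity, accuracy, precision, Dice and the closed-form
AUC $= 1 - \tfrac12(\mathrm{FPR} + \mathrm{FNR})$, which is exactly
balanced accuracy $(\mathrm{TPR}+\mathrm{TNR})/2$ — a design identity
the suite asserts, not a rank-based AUC. Zero-denominator metrics are
returned as `NA` and flagged, never silently coerced.

## The synthetic-shape generator

`make_dataset()` stands in for dermoscopy datasets in every test. A
shape is star-convex about its center with boundary radius

$$\rho(\varphi) = r_{ell}(\varphi)\,\Big(1 + \sum_k a_k \cos(k\varphi + \psi_k)\Big) + \mathrm{jitter}(\varphi),$$

an ellipse modulated by low-order radial harmonics plus a smooth seeded
Fourier ripple. Odd harmonics break mirror symmetry; their amplitude is
a dial that provably controls the fold indices, which the test suite
exploits (median A1/A2 increase monotonically along the
`lobe_family()` amplitude ramp).

The default class recipes form an asymmetry gradient — nevus:
near-elliptical (even harmonic ≤ 0.02); dysplastic: moderate mixed
harmonics (orders 2/3/5, amplitudes 0.03–0.13); melanoma: strong odd
harmonics (orders 3/4/5, amplitudes 0.06–0.38) plus boundary jitter.
Three quantitative choices were calibrated once, against the target that
class-conditional A2 distributions overlap below 5% (measured as the
best single-threshold misclassification rate between class pairs at 200
shapes per class), and then frozen:

* radii 18–26 px on a 100 px canvas: fold quantization puts a floor of
  roughly 0.03 under A2 for ~400-pixel shapes, which would swamp the
  nevus/dysplastic gap at smaller sizes;
* a fifth-order harmonic in the dysplastic recipe, lifting its lower
  tail above the nevus quantization floor;
* odd-harmonic phases anchored away from the ellipse axes
  (`phase_margin` 0.45 rad): an odd harmonic contributes
  $\propto|\sin(k\gamma+\psi_k)|$ to one fold and
  $\propto|\cos(k\gamma+\psi_k)|$ to the other, so an unconstrained
  phase occasionally makes one fold almost symmetric and collapses the
  *minimum*-fold statistic A2; bounding the phase away from every
  quarter-turn removes that heavy lower tail.

What the generator does **not** emulate: real segmentation noise
(ragged Graph-Cut boundaries, holes, satellite regions), intensity
structure, class-imbalanced priors, or lesions that are not star-convex.
Passing tests therefore demonstrate that the pipeline measures and
separates *shape asymmetry* as specified — not that these accuracy
figures transfer to clinical images, where published results with this
family of methods report held-out accuracies near 0.97 rather than the
1.00 typical of the cleanly separated synthetic classes.

## Experiment harness

`split_dataset()` produces disjoint, exhaustive train/validation/test
splits: fractions mode takes `floor(0.70 n)` / `floor(0.15 n)` /
remainder, and an explicit-counts mode exists because historical study
bookkeeping (765/165/165 of 1095) is not any rounding of 70/15/15.
Splits are stratified by class via largest-remainder allocation plus a
repair pass that guarantees every class is within one sample of its
proportional share in every block — stratification is this package's
convention for making per-seed results comparable, not a claim about
the original experimental protocol.

`enumerate_plan()` crosses all $2^D-1$ non-empty dataset combinations
with the hidden sizes (and optional feature subsets) in a deterministic
order; four datasets × sizes $\{8,12,16,20\}$ give the canonical 60
configurations. `run_sweep()` trains one network per configuration
(dataset subsets whose samples span only two classes automatically get
two-output networks), records test MSE, accuracy and stop reason, skips
configurations with fewer than 10 training samples with a warning, and
flags the minimum-test-MSE row as the best architecture. `comparators()`
fits an RBF-kernel SVM and a k-NN (k = 5; both hyperparameters are
config defaults, unstated in the source literature) on the identical
split, dropping features that are constant on the training block, and
reports the same metric suite — so network and baselines are compared
on equal footing.

## Problem sizes and determinism

The shipped tests run the fold oracle on 200 random masks, the index
bounds on 500 generated shapes, and the end-to-end classification on
200 shapes per class — sizes at which every distributional property the
suite asserts has been stable across seeds while the whole suite stays
under a minute. Every stochastic step (shape generation, weight
initialization, splitting, k-NN tie-breaking) is seeded; the acceptance
script derives all of them from its single `--seed` argument.

## Known limitations

* A3 is uninformative (constant 0.25) without grayscale input under the
  default reading — inherent to the formula, documented above.
* Nearest-neighbor rotation loses or duplicates boundary pixels
  (bounded ~1% of area for the shapes the generator produces; the area
  invariance test asserts <10% for any ≥100-pixel shape).
* The fold search examines lines within one pixel of the centroid; a
  lesion whose best mirror line lies further away (e.g. a crescent) is
  scored against the centroid lines, by design.
* Masks with several equally plausible lesions are resolved by largest
  component only; multi-lesion images are out of scope.
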