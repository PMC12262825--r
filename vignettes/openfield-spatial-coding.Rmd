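---
title: "Models and methods: single-neuron spatial coding in the open field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: single-neuron spatial coding in the open field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(openfieldr)
```

# Scope

`openfieldr` analyzes single-neuron recordings made while an animal forages
in a square open-field arena containing an uncued goal zone and a movable
visual cue card. It answers two families of questions:

1. **What does each cell encode?** A penalized Poisson encoding model with
   cross-validated forward selection classifies each cell's significant
   behavioral covariates (2D location, head direction, egocentric bearing of
   the arena center, center distance, running speed), and map-based scores
   (grid score, border score, spatial information, tuning-curve mean vector
   lengths) refine those classes into the canonical cell types: grid,
   border, non-grid spatial, head-direction (HD), center-bearing (CB),
   center-distance (CD), conjunctive CB x HD, and landmark-modulated HD
   (LM-HD) cells.
2. **Which reference frame anchors that code?** Circular statistics on
   preferred-direction shifts, bidirectionality indices, bidirectional
   von Mises fits and rotated-map correlations quantify how each cell
   responds when the cue card is rotated to an adjacent wall or duplicated
   on the opposite wall.

Because no public recordings accompany the experimental design the package
emulates, a first-class synthetic module generates complete sessions
(trajectory plus spike trains) with known ground truth; every downstream
stage is validated against that ground truth.

# Coordinate and angle conventions

The origin is the southwest corner of the arena; x grows east, y grows
north; all angles are degrees counterclockwise from the positive x axis
(east). Egocentric bearing is 0 degrees directly ahead and +90 degrees to
the animal's left; bearings are wrapped to `[-180, 180)`. These conventions
are applied uniformly; one consequence is that a counterclockwise cue
rotation (south wall to east wall) predicts a +90 degree shift in the
preferred direction of a cue-following cell.

# The synthetic session generator

`simulate_trajectory()` produces a goal-biased correlated random walk at
30 Hz. Speed follows an Ornstein-Uhlenbeck process (default mean 20 cm/s,
SD 10 cm/s, time constant 1 s — typical of foraging rats); heading
accumulates wrapped-Gaussian turning noise (SD 12 degrees/frame) and is
steered toward the current target with per-frame gain
`0.15 * goal_bias`. Targets alternate between the goal zone and a
uniformly scattered pellet location after each simulated reward, mirroring
a task in which zone entry scatters 1-4 food pellets. Walls reflect the
path. Head direction is the movement heading plus von Mises jitter
(concentration 50), conflating head and body axes; LED-tracking noise is
not modeled. The task protocol itself fixes the study conditions: 120 cm
arena, 15 cm goal zone centered 35 cm from the west wall and 45 cm from
the north wall, 20-minute sessions, 10 s reward timeout.

`generate_spikes()` evaluates each tuning model's rate at every frame and
draws per-frame Poisson counts with uniform jitter inside the frame. At the
33 ms analysis resolution a Poisson count per frame is exact, so no
thinning loop is needed. Seeds are explicit arguments everywhere; fixed
seeds give bit-identical sessions.

Generative tuning models are intentionally simple closed forms: a
three-cosine lattice for grid cells (40 cm spacing default, squared to
narrow the fields), exponential wall-distance decay for border cells, sums
of Gaussians for non-grid spatial cells, von Mises curves for HD/CB/LM-HD
cells, and linear or Gaussian distance profiles for CD cells. What the
generator does *not* emulate — theta rhythmicity, conjunctive speed
modulation, slow drift, tracking artifacts — bounds what passing tests
show: they validate the statistical machinery on data satisfying the
models' assumptions, not robustness to every pathology of real recordings.

## Conjunctive cells and identifiability of the reference point

The conjunctive CB x HD model multiplies a von Mises bearing profile about
an offset reference point with a von Mises HD profile. Its defaults are
bearing-dominant (bearing concentration 4, HD concentration 1) for a
substantive reason: the egocentric MVL-map estimator cannot localize the
reference point of an HD-dominant conjunctive cell. For a distant candidate
reference point the bearing is approximately (direction to the point minus
head direction), and the direction term is nearly constant, so pure HD
tuning masquerades as bearing tuning near the arena edge. In the noiseless
limit with equal concentrations (both 2), the MVL-map argmax settles about
30 cm outside the true reference point — a property of the statistic, not
of noise. With bearing-dominant cells, which also match the empirical
picture in visually driven cortex (stronger CB than HD tuning), the
reference point is recovered to within one or two grid steps. Reference
points for recovery benchmarks are scattered over the central 60% of the
arena; localization degrades toward the walls for the same reason.

# Tuning machinery

Rate maps use 2.5 cm bins (48 x 48) smoothed with an edge-truncated,
renormalized Gaussian kernel (SD 3.75 cm); unvisited bins are missing and
excluded from the smoothing support, so rates are not suppressed along
walls. Spikes are assigned to the frame whose `[t, t + dt)` window contains
them. Circular tuning curves use 12-degree bins (30 bins); tuning strength
is the mean vector length (MVL) of the *binned, occupancy-corrected* curve,
not of raw spike angles. Center-distance curves use 4 cm bins spanning
`[0, side/sqrt(2)]` with least-squares linear and Gaussian
(amplitude/mean/width/offset) fits.

Significance thresholds come from a within-cell shuffle: the spike train is
circularly shifted by at least 30 s (uniformly up to duration minus 30 s),
400 times, and the 99th percentile of the statistic's null distribution is
the cell's threshold. The linear and Gaussian distance-fit R-squared values
each get their own null distribution computed on a shared set of shifts; a
pooled maximum was rejected because a 4-parameter Gaussian fits near-flat
shuffled curves with R-squared up to ~0.95, which would swamp genuine
linear distance tuning.

Occupancy resampling (`resample_equal_occupancy()`) tiles the arena with
15 cm bins (64 on the default arena), finds the minimum occupancy over
visited bins, and subsamples frames per bin to that minimum. Never-visited
bins are excluded from the minimum — including them would force the target
to zero and delete the session.

# The encoding model and forward selection

The firing-rate vector is modeled as `r = exp(sum_i X_i' b_i)` over one-hot
state matrices: 400 location bins (20 x 20), 30 HD bins, 30 center-bearing
bins, 10 center-distance bins and 10 speed bins. Parameters maximize the
Poisson log-likelihood minus a smoothing penalty
`P = sum_i S_i sum_j (b_{i,j+1} - b_{i,j})^2 / 2` with `S = 2` for 2D
location and `S = 20` for the other variables. Adjacency is circular for
angular variables, a chain for distance and speed, and the 4-neighbor grid
for location (the penalty's linear index is extended to two dimensions in
the natural way). Optimization is L-BFGS-B with the analytic gradient,
zero initialization, and a projected-gradient tolerance of 1e-6 capped at
500 iterations; fold fits warm-start from the full-session fit purely as a
computational device.

Model selection uses 10 contiguous folds (train on 9/10, test on 1/10).
Per fold, the full five-variable model is fit on the training data, and
every variable subset is evaluated on the test fold using the relevant
parameter blocks of that full fit, with the subset's rate rescaled so its
training-set time-average matches the training mean rate (evaluating
subset blocks from the full fit reduces correlative artifacts between
covariates; the rescaling keeps subsets on a common rate scale). Forward
selection compares the best (m+1)-variable subset against the best
m-variable subset with a one-sided Wilcoxon signed-rank test across folds
(alpha 0.05); the winner must finally beat a mean-rate-only model or the
cell is unclassified. Cells with fewer than 100 spikes are not classified;
penalized fits on fewer spikes are degenerate. Raw per-fold log-likelihood
sums are compared without per-spike normalization.

A note on calibration: with `S = 20` and realistic spike counts
(~100-200 spikes per angular bin over 20 minutes), the penalized fit of a
constant-rate cell retains a relative range of roughly 10-30% — the Poisson
noise floor — rather than being numerically flat. The penalty suppresses
bin-to-bin jaggedness, and selection correctly rejects such cells, but the
smoothing strength is far too weak to iron a 30-bin curve flat.

# Map scores and classification

The spatial autocorrelogram is the Pearson correlation of the smoothed map
with itself at every integer shift over the overlapping visited bins
(shifts with fewer than 20 overlapping bins are missing); it is computed
with masked FFT cross-correlations and verified in the tests against an
explicit shift loop. The grid score correlates the autocorrelogram's ring
with itself at 3-degree rotational offsets and subtracts the highest
correlation at 30/90/150 degrees from the lowest at 60/120 degrees. The
ring radii come from the radial profile: the inner radius is the first
local minimum after the central peak, the outer radius 1.5 times the
radius of the next local maximum, capped at half the map extent, with a
fallback of `[2 bins, half extent]` — the "most probable" radii are
otherwise unspecified, so this heuristic is a package design choice.

The border score removes bins below 20% of the peak, keeps 4-connected
fields of at least 200 cm^2, and computes `(c - d) / (c + d)` with `c` the
maximum fraction of one wall's adjacent bin row covered by a single field
and `d` the rate-weighted mean nearest-wall distance of field bins
normalized by 60 cm. Coverage is judged over the *visited* bins of the
wall row: on real data with dense wall coverage the two readings coincide,
but on synthetic trajectories the innermost 2.5 cm row is sparsely visited
and the all-bins reading would push `c` toward zero for genuine border
cells. Field detection for centroid analyses uses a 30% threshold and a
150 cm^2 minimum. Spatial information is Skaggs' bits/spike over smoothed
rate and occupancy maps (the occupancy histogram reuses the 3.75 cm
smoothing width).

Classification composes the GLM selection with the scores: grid requires
GLM-location and grid score > 0.4; border requires GLM-location and border
score > 0.5, with grid taking precedence when both pass (the non-grid
definition implies mutual exclusivity but no tie rule, so precedence is a
package choice); non-grid spatial requires GLM-location, spatial
information above its shuffle threshold, and neither grid nor border; HD
and CB require their GLM variable, MVL above both the shuffle threshold
and a fixed 0.2 floor, and a peak rate above 1 Hz; CD requires
GLM-distance, either fit's R-squared above its own shuffle threshold, and
a peak rate above 1 Hz. POR cells passing the HD rule are labeled LM-HD.

# Egocentric reference-point analysis

For each of 400 candidate reference points (centers of a 20 x 20 partition,
6 cm pitch, 3 cm inset from the walls), a 12-degree egocentric-bearing
tuning curve is built and summarized by its MVL; samples within 1 cm of
the reference point are excluded (the bearing is singular at zero
distance), and points whose curve leaves more than half the bearing bins
unoccupied are missing. The argmax (ties broken by smallest column-major
index) is the cell's preferred reference location; rotations of that
location about the arena center quantify cue-driven remapping.

# Cue-manipulation statistics

Preferred-direction shifts are signed circular differences of tuning-curve
preferred directions, counterclockwise positive. The bidirectionality
index doubles each frame's head direction before re-binning:
`BI = (MVL_doubled - MVL_normal) / (MVL_doubled + MVL_normal)`. For a
noiseless von Mises curve the doubled-curve MVL is the second circular
moment `I2(k)/I0(k)`, so at concentration 2 the index is
`(I2/I0 - I1/I0) / (I2/I0 + I1/I0) = -0.396` — the package's tests pin BI
to this Bessel-function value. Bidirectional von Mises fits share one
concentration across two lobes exactly 180 degrees apart with separate
amplitudes (the functional form is otherwise underdetermined by a 30-bin
curve), are restarted from 12 initial lobe directions, and in trough mode
fit inverted lobes — used for cells whose peak points away from the
original cue. Cue modulation indices normalize the fitted lobe depth by the
fitted maximum; the lobe circularly nearest (within 90 degrees of) the
standard-session preferred direction is attributed to the original cue.
Rotated-map correlations compare two smoothed maps at 0/90/180/270-degree
rotations over mutually visited bins. The Rayleigh test uses
`Z = n r^2` with the first-order correction
`P = exp(-Z) (1 + (2Z - Z^2)/(4n))`; the V test uses the one-sided normal
approximation of `u = V sqrt(2/n)`.

# Numerical choices and degenerate inputs

* Undefined statistics are `NA` and propagate as explicit missingness:
  MVL of an all-zero curve, border score with no qualifying field, grid
  score when the autocorrelogram is constant, bearings within 1 cm of a
  reference point.
* Argmax ties break to the smallest column-major index; component labels
  are numbered by smallest contained index.
* FFT round-off in the autocorrelogram is clamped to `[-1, 1]` and the
  central value set to exactly 1.
* Zone membership uses half-open bounds so edge frames are counted once;
  a session that starts inside the zone records no entry until the animal
  leaves and returns.
* Shuffle thresholds error out if more than 10% of null statistics are
  undefined rather than silently using a truncated distribution.

# Problem sizes

Tests exercise the full pipeline at the study's native scale: 20-minute
sessions at 30 Hz (36,000 frames), 400 shuffles per threshold, 20 cells
per type for recovery benchmarks, 100 null cells for shuffle calibration,
and 30-cell cue-rotation triplets. The acceptance script reproduces the
same quantities with 6 cells per type, 50 calibration cells, and
10-15-cell triplets, which keeps a complete from-scratch run near five
minutes on one core; recovery fractions at those sizes have coarser
granularity but the same expectations.

# Known limitations

* The generator's behavioral realism is limited: no thigmotaxis beyond
  wall reflection, no grooming bouts or immobility, no tracking dropout.
  Wall-adjacent map bins are therefore sparser than in real data (the
  border-score coverage definition accounts for this).
* The MVL-map reference-point estimator is biased outward for HD-dominant
  conjunctive cells (see above); reported MVL_max locations near walls
  should be interpreted cautiously in any dataset.
* The bidirectional von Mises fit assumes lobes exactly 180 degrees apart;
  cells with asymmetric lobe spacing are fit at the nearest antipodal
  compromise.
* Repeated-measures ANOVA, post-hoc corrections and mixed models over
  sessions are deliberately out of scope: the pipeline emits tidy per-cell
  tables for those off-the-shelf analyses.
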