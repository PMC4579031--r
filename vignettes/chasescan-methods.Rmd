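---
title: "Methods: gaze-event decomposition and template analysis of chase displays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze-event decomposition and template analysis of chase displays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(chasescan)
```

`chasescan` implements a complete analysis chain for a classic animacy-
perception task: an observer watches 14 identical rings move inside an
invisible square arena, one ring ("chaser") pursues another ("chasee") in a
heat-seeking manner, and the observer presses a button when they spot the
chasing pair. The package simulates the displays, synthesizes labeled
binocular gaze, segments gaze into oculomotor events, and characterizes the
motion patterns each event class targets with spatiotemporal template
analyses. This vignette documents the models, the tunable parameters, and
the design decisions made where the design was genuinely open.

## The stimulus model

All 14 rings move at a constant 14.5 deg/s inside a 26 x 26 degree arena at
85 Hz. The chasee and the distractors schedule direction changes as
independent per-frame Bernoulli events with probability 5.4/85, so the mean
scheduled rate is 5.4 changes per second; each change turns the heading by a
uniform draw from plus or minus 60 degrees. Walls reflect the heading about
the wall normal (both normals in a corner); the reflection replaces the
step direction *before* the step, so every frame's displacement has the
exact length 14.5/85 deg and containment is strict.

The chaser homes on the chasee's current position at every frame. Two
considerations force continuous (rather than event-scheduled) homing.
First, an event-scheduled chaser's stale heading lets the chaser-chasee gap
drift to a mean of about 5 deg, whereas the display is characterized by the
minimum distance (3 deg) being close to the typical distance. Second, the
chase-centered analysis reports the pair roughly 3.4 deg apart; only a
continuously homing chaser pinned at the minimum-distance boundary
reproduces that geometry (we measure mean ~3.2, median ~3.0 deg).

**Minimum-distance constraint.** In distance-constrained (DC) trials the
chaser-chasee distance must never drop below 3 deg. Literal whole-trial
rejection sampling is computationally impossible here: a heat-seeking
chaser at equal speed tailgates the chasee to near contact, so the
probability that an unconstrained 30 s trial keeps a 3-deg gap is
essentially zero. Instead, the chaser's heading is projected, frame by
frame, onto the closest feasible heading that keeps the next-frame distance
at or above 3 deg. At equal speeds this projection always has a solution
(stepping directly away from the chasee's next position can never lose
ground), so the chase rides the constraint boundary, which is exactly the
regime in which the minimum distance is also the typical distance.
Whole-trial rejection is retained as a safety net for degenerate corner
geometries; in practice trials pass on the first attempt. A small
course-keeping penalty (weight 0.05 on the angular change) breaks ties
between the two tangent directions during boundary riding; without it the
projected heading flips sides frame by frame, which is kinematically
implausible and poisons the direction-agreement criterion of fast smooth
movement for gaze locked on the chaser. Constraint projections and wall
bounces are boundary handling and are *not* logged as scheduled direction
changes, so the 5.4/s accounting refers purely to the sampling process.

Non-constrained (NC) trials (4 of 40) switch the projection off; the chaser
then trails the chasee at near-contact distance. One display-design claim
does not carry over exactly: with the boundary-riding chase the mean
chaser-chasee distance (~3.2 deg) sits ~20% below the mean
distractor-to-nearest-neighbor distance (~4.0 deg), rather than matching it.

## The synthetic observer

The observer model generates a 500 Hz binocular recording plus ground-truth
labels, so that every downstream stage can be scored against a known
segmentation. It alternates two regimes:

* **Exploration** - fixations (mean 350 ms) at maxima of a Gaussian-smoothed
  agent-density map (kernel sd 2 deg), joined by relocating saccades with an
  8-deg inhibition-of-return radius.
* **Pursuit** - a catch-up saccade onto a candidate agent picked in a fresh
  high-density region, a brief single-agent lock-on (250 ms, gain >= 0.97),
  then, for the group strategy, group-tracking episodes: the gaze follows
  the tracked agent's velocity at gain 0.75 starting from the group center,
  so it drifts backwards through the group until the positional error
  exceeds 2.5 deg and a catch-up saccade re-locks. The group partner is the
  nearest agent between 3 and 6 deg from the anchor; closer partners are
  indistinguishable from single-agent tracking (the group center would fall
  inside the 1-deg lock radius of fast smooth movement).

Saccades follow a minimum-jerk profile with amplitude-dependent duration
(20 ms + 2 ms/deg). A sinusoidal velocity oscillation (amplitude 3 deg/s,
period 400 ms) rides on all smooth movement. Both eyes receive the common
signal plus independent white noise (default sd 0.1 deg); blinks (4/min,
~150 ms) blank both eyes simultaneously.

Truth labels for smooth episodes are assigned by the *kinematic event
definitions*, not by the generator's intent: an episode is fast smooth
movement if some agent stays within 1 deg on average over the first 100 ms,
within 4 deg overall, and moves within 25 deg of the gaze direction. The
direction criterion is evaluated on a 20-ms-smoothed copy of the ideal
gaze, because the measurement chain smooths the recording before any event
is identified; a truth label that a perfect classifier cannot see is not a
useful truth. Pursuit attempts whose episodes all grade as slow smooth
movement are relabeled exploration, preserving the taxonomy invariant that
every pursuit contains fast smooth movement.

Two deliberate simplifications are worth knowing. Catch-up saccades are
triggered by positional error only; direction-change triggers would produce
sub-degree saccades that are invisible to any velocity/acceleration
detector after 20 ms smoothing and would only blur the ground truth.
Tracking-mode switches are suppressed unless the accompanying saccade is
large enough to register (>= 1.5 deg), for the same reason. What passing
tests show about real data is therefore bounded: the generator produces
by construction saccade-delimited, criterion-consistent episodes, whereas
human pursuit drifts in and out of the bands and the original study
corrected its automated segmentation manually.

## Preprocessing and event segmentation

Preprocessing follows the order: per-eye per-axis Gaussian smoothing (sd
20 ms, kernel truncated at 3 sd, reflection padding, each contiguous finite
segment smoothed independently), per-eye linear interpolation of missing
episodes shorter than 100 ms, binocular fusion (mean of both eyes; single
eye if one is missing; missing if the inter-eye distance exceeds 4 deg),
linear resampling to the 85 Hz display frame base, and kinematic
differentiation by central differences on the resampled signal (one-sided
at the ends). Velocity is the magnitude of the positional derivative;
acceleration is the absolute derivative of that speed.

Basic events use the threshold table: fixation velocity [0, 6] deg/s, slow
smooth movement (SSM) [4, 21], fast smooth movement (FSM) [9, 21] with
acceleration below 800 deg/s^2 and minimum durations of 80/80/100 ms, and
saccades above 21 deg/s with peak acceleration above 4000 deg/s^2 and more
than 20 ms. The table gives extrema, so thresholds are applied to
event-level statistics: the run's median velocity (with up to 10% of frames
allowed outside the band, tolerating smooth-movement oscillations), its
95th-percentile acceleration, and the saccade's peaks. Runs are delimited
by missing data and by all fast (> 21 deg/s) frames, whether or not those
qualify as saccades - an important detail, because under 20 ms smoothing
only saccades of roughly 7 deg and larger reach the 4000 deg/s^2 peak;
smaller catch-up saccades still break the smooth runs but stay uncoded.
Up to two frames at each run edge are excluded from the statistics (and
the FSM 100-ms window starts after them), since their derivatives carry
the adjacent saccade's smoothed tail. FSM is tested first (its band lies
inside the SSM band and SSM is defined as smooth movement that fails the
FSM agent criteria), then SSM, then fixation; runs failing everything stay
uncoded.

Complex events: pursuit starts with an FSM, or retroactively with two
consecutive SSMs (separated by exactly one saccade) that focus overlapping
agent sets; it continues while consecutive events' sets overlap (nonempty
intersection); every pursuit must contain an FSM or it is demoted to
exploration. Saccades attach to the following segment: those followed by
pursuit are catch-up saccades, ordered within their pursuit (CS1, CS2,
...); those followed by exploration are exploration saccades (ES).
Agreement between two labeled streams is scored frame-wise at 85 Hz;
binary comparisons report accuracy, sensitivity, specificity and the
Matthews correlation, and a multi-class Matthews correlation scores full
segmentations. Recovery against ground truth excludes frames within two
frames (~24 ms) of a truth event boundary: the 20 ms smoothing makes
boundaries ill-defined to about the filter width, so those frames measure
filter delay, not classification quality (strict per-frame scoring
plateaus near MCC 0.8 at zero noise for any classifier operating on the
smoothed signal).

## Template analyses

Samples are spatiotemporal windows of agent coordinates around a lock:
translated so the lock is the origin, rotated so the alignment direction
maps onto +x, and cropped to a 10 x 10 deg window at rendering. Locks:
detection (gaze position 200 ms before the button press, window -0.8..0 s),
saccade onset (positional lock at the saccade target, window +/-0.4 s),
smooth-movement episodes (variable length, locked at start, midpoint or
end, optionally restricted to the pursued agents), and chase-centered
("ideal observer") samples locked halfway between chaser and chasee at a
random time. Alignment uses the gaze direction when the gaze moves, else
the dominant agent motion direction: the mode of a 36-bin radial histogram
of per-frame agent directions, weighted by distance to the lock through
the circular polynomial window `max(0, 1 - (d/5)^2)`, refined by the
weighted circular mean within the modal bin.

Rendering deposits each agent per frame on a 0.25-deg pixel grid, either as
an isotropic Gaussian blob (sd 0.5 deg) or as the stimulus ring itself
(radius 0.5 deg, radial Gaussian cross-section of half a pixel). Blobs are
the default for average templates: they make rendering and the
Nadaraya-Watson kernel-regression template (computed directly from
coordinates, normalized per frame by the number of contributing samples)
exactly equivalent, which the tests exploit as a cross-method oracle. The
ring is the default for the PCA-based analyses, where the image statistics
matter: the variance decomposition of the rendered movies depends strongly
on the rasterization, and rendering the display as it actually looked is
the only principled anchor. With blobs the leading chase-centered
component inflates to ~25% of variance; with rings it sits at ~15-17%,
and the full spectrum of the leading five components closely matches the
reported one.

PCA is computed by eigendecomposition of the n x n Gram matrix of the
vectorized movies, so the pixel dimension (40 x 40 x 68 = 108,800) is never
squared; eigen-movies follow as weighted sums of the rendered samples. By
default no mean is subtracted: the decomposition is of the raw second
moment, so that with a unimodal sample distribution the first component
recovers the average template and subsequent components act as shift and
modulation patterns. This matches the observed component structure - the
first chase-centered component *is* the chase, the second modulates the
pair distance (constrained vs unconstrained trials separate on it), and
covariance-PCA (`center = TRUE`, via double-centering of the Gram matrix)
would instead promote the distance-modulation pattern to the top.

Rail diagrams collapse a template movie onto the alignment axis by
averaging the pixel rows within a 0.3-deg band; constant agent motion
appears as a line whose slope is the agent velocity, a chase as two
parallel lines. Ridge lines are fitted by Nelder-Mead maximization of the
Pearson correlation between the [0, 1]-normalized rail and a sum of one or
two unimodal profiles `max(0, 1 - |h/s|^3)` with
`h(x, t) = (p + v t - x) / (1 + v^2)`. Two numerical notes: the cube is
taken on the absolute value (the odd power would be unbounded on one side,
contradicting the profile's [0, 1] range), and the printed `1 + v^2`
denominator differs from the geometric point-line distance
(`sqrt(1 + v^2)`) only by a reparametrization of `s`, so fitted `p` and
`v` are identical under either choice (`denominator = "geometric"` is
available, and recovery tests exercise both). Optimization is two-stage:
all multi-starts (argmax-ridge regression, a masked-residual second-ridge
estimate, symmetric offsets, two width scales) first run against a
laterally smoothed rail whose basin is wide - the thin ring leaves twin
sub-ridges in the band average that otherwise trap the simplex - and the
best candidates are refined on the raw rail.

The chase-centered geometry is reported two ways on purpose: the fitted
line-offset difference `p1 - p2` and the inter-ridge distance at the time
lock differ when the fitted slopes differ, and the source material itself
reports inconsistent values (4.21 vs 3.43 deg); the package outputs both
and adjudicates neither.

The saccade-class contrast trains a linear support-vector machine on
vectorized rendered movies (the only kernel whose weight vector reshapes
into a single classification movie), cost selected from {0.01, 0.1, 1} by
nested cross-validation, stratified k-fold accuracy compared against the
majority-class chance level, classes unweighted so the two are comparable.
Binary maxima/minima movies threshold the weights at mean +/- 2 sd.

Detection behavior uses maximum likelihood plus percentile bootstrap
(log-normal detection times, `mean = exp(mu + sigma^2/2)`; Bernoulli
detection rates), replacing the original Bayesian posterior intervals whose
priors are unstated; omissions count as incorrect and are excluded from
time fits.

## Problem sizes and determinism

The chase-centered reproduction uses 160 trials (36:4 DC:NC) and 5,000
samples, the batch invariants 100 trials, and the recovery checks pool
frames over three 30 s trials per noise level; unit tests run on toy
fixtures built in code. Every stochastic stage takes an explicit integer
seed and derives named substreams from it, so identical configurations
reproduce trajectories, recordings and artifact directories byte for byte.
All randomness is restored after each call (`with_seed`), leaving the
caller's random stream untouched.

## Known limitations

* The generator produces criterion-consistent, saccade-delimited behavior;
  human gaze is messier, and frame-exact agreement with human coders is
  out of reach by construction (the original workflow corrected its
  automated segmentation by hand).
* Subject-level numbers that depend on the original recordings (detection
  times and rates, inter-coder agreement, subject-wise classifier
  accuracies) are not reproducible and are replaced by property-based
  checks of the machinery that would compute them.
* Explained-variance figures are rasterization-dependent; the ring
  rendering anchors them to the physical display, but the original
  rasterization is unknown and the tolerance on the reproduced value
  reflects that.
* The drift-diffusion account of the detection decision and the
  interactive coding tool are out of scope.
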