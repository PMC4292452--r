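---
title: "Interaction patterns, time-to-go planning, and operator attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interaction patterns, time-to-go planning, and operator attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(fig.width = 6.5, fig.height = 4.5)
library(ipguidance)
```

## The model

Goal-directed spatial guidance is modeled as a closed agent–environment
loop $\dot x = f(x, k(x, h(g(x))))$: the environment function $g$ maps
the vehicle state onto a motion gap, the perceptual function $h$
extracts a guidance variable from that gap, and the control policy $k$
turns it into actuation. The package implements this loop as three
nested levels over a planar vehicle state $x = [s_x, s_y, v, \psi]'$
(position, speed, course):

1. **Planning** — a subgoal state machine over an ordered plan
   $g_1, \dots, g_K$ (the last subgoal is the goal). The machine
   advances when the vehicle enters the capture radius of the active
   subgoal; the final subgoal uses the goal's position and
   terminal-speed tolerances instead.
2. **Perceptual guidance** — the active subgoal defines the gap
   $e = x - g_k$. The course reference points along the gap. On
   intermediate legs the speed reference is the cruise speed; on the
   terminal leg, once the gap falls below a braking distance, it
   follows constant-$\dot\tau$ closure: holding
   $\dot\tau = k_\tau \in (0, 1)$ for $\tau = d/\dot d$ gives
   $v(d) = v_c (d/d_b)^{1 - k_\tau}$ and the analytic gap trajectory
   $d(t) = d_0 (1 - t/T)^{1/k_\tau}$ with $T = d_0 / (k_\tau v_0)$,
   which drives speed and gap to zero together.
3. **Tracking** — saturated proportional feedback on speed and course
   error with a deceleration feedforward on the terminal leg (the
   dynamic-inverse member of the "traditional feedback" class; without
   the feedforward the tracked speed lags the braking profile by
   $a/k_v$ and the terminal tolerances are never met simultaneously).

Vehicle kinematics ($\dot s_x = v\cos\psi$, $\dot s_y = v\sin\psi$,
$\dot v = a_t$, $\dot\psi = a_n/v$) are integrated with fixed-step RK4
(default $\Delta t = 0.02$ s) so that trajectories are bitwise
reproducible and alignable. A speed floor $v_{\rm floor} = 0.05$ m/s in
the turn-rate term avoids the singularity at rest.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `tau_dot` ($k_\tau$) | 0.5 | — | terminal coupling; 0.5 gives constant deceleration |
| `cruise_speed` | 0.6 | m/s | speed on non-terminal legs |
| `brake_frac` | 0.5 | — | commanded terminal deceleration as a share of `a_t_max`; sets $d_b = v_c^2/(2\,\mathrm{frac}\,a_{t,\max})$ |
| `k_track_v`, `k_track_psi` | 3, 4 | 1/s | tracking bandwidths |
| `a_t_max`, `a_n_max` | 2, 2.5 | m/s² | actuation limits |
| `capture_radius` | $2\times$ pos. tol. | m | subgoal switch radius |

The defaults describe a laboratory-scale vehicle (meter-scale
workspace, sub-m/s cruise). `brake_frac = 0.5` leaves half the
tangential authority as headroom for the tracking loop during braking.

## Interaction patterns

Two equivalence relations define the IP:

* **Subgoal equivalence**: histories with identical futures from a
  shared state. Exact identity is unobservable in finite noisy data, so
  the package uses a merge-point surrogate: for every trajectory pair,
  the earliest state after which the paths coincide within `merge_dist`
  (0.1 m) for at least `merge_len` (0.5 m) of arc length, with the
  coincidence persisting to the records' ends. Pairs that were *never
  separated* by more than $2\times$ `merge_dist` contribute nothing —
  repeated runs from one start are trivially coincident and would
  otherwise plant a spurious "subgoal" at every start point. Merge
  states are clustered (complete linkage, 0.5 m cut) and clusters with
  enough support become subgoal regions; the goal always is one.
* **SE(2) symmetry**: segments are compared after arc-length resampling
  to $N = 50$ points by closed-form planar Procrustes (rotation +
  translation, no scaling, no reflection — reflection is not a rigid
  motion of the vehicle). Candidate IPs — bundles of segments
  terminating at one subgoal region with a common approach course
  (circular clustering, 30° cut) — are grouped into the IP library by
  complete linkage on pairwise alignment residuals. Complete linkage
  guarantees the maximum within-class residual stays below the cut;
  the default cut is $3\times$ the median within-candidate residual,
  which scales with the noise level rather than with the workspace.

Positions carry the shape: course and speed residuals are reported but
not minimized. Whether control histories must also superimpose is left
open by the theory; on the simulated fixtures position congruence
suffices.

## Time-to-go learning

`empirical_ttg()` labels every state of a segment with its remaining
time to segment end and computes features in the subgoal-centered frame
(rotated to the approach course), which makes the learned function
SE(2)-invariant by construction — the property the planner needs to
reuse one function at every spawned subgoal. `fit_ttg()` performs
forward stepwise selection over the basis
$\{d, \beta, |\beta|, v, \kappa, d|\beta|, \beta^2, |\Delta\psi_{togo}|\}$,
adding at each step the term that minimizes 5-fold cross-validated
RMSE and stopping when the relative improvement drops below 1%; the
final coefficients are refit on all data. The basis is linear in
parameters, so selection is well defined and the fit deterministic
under a fixed fold seed. Predictions are clamped at zero, are exactly
zero at zero gap, and carry an extrapolation flag outside the training
domain (max $d$, max $|\beta|$). On uniform-motion data the procedure
selects $d$ first with coefficient $1/V$; appended pure-noise features
do not enter.

## Wavefront planning

The planner rasterizes free space (cell-centered grid, default
resolution 1/100 of the workspace diagonal) and propagates TTG level
sets from the goal with *visibility-restricted* claiming: a source
claims exactly the cells it can see, at value
$\text{spawn} + T(\text{cell in source frame})$, because the learned
function lives in the source's subgoal frame. When a front reaches an
obstacle vertex that is visible and locally occluding (both incident
edges on one side of the viewing ray — the silhouette condition), a
subgoal is spawned there and a new front starts at the arrival time;
sources are finalized in spawn-time order, which is Dijkstra over the
visibility graph of goal plus occluding vertices. Cells whose two best
incoming values agree within 2% of the local value are flagged as
ridge; the per-cell best source is the predicted behavioral partition.

Numerical choices:

* Only *convex, occluding* vertices spawn; other vertices never alter
  the reachable front.
* A corner that cannot be rounded with any clearance (its exterior
  bisector offset lands in an obstacle or outside the workspace at all
  tried margins) spawns nothing: no flyable path wraps around it.
* Plan waypoints use the vertex offset outward along the exterior
  bisector by `corner_margin` (0.22 m) so that simulated paths clear
  the corner at the capture radius; the map itself propagates from the
  exact vertex.
* The learned TTG's domain clips propagation (with 5% slack); cells
  claimed by no source are unreachable and get `+Inf`.
* Ties between sources resolve to the earliest-finalized (lowest-id)
  source, deterministically.

The independent check is a grid shortest-time Dijkstra
(`grid_time_oracle()`, built on igraph). The 8-neighbor stencil's
chordal metric overestimates Euclidean time by up to 8.2% (median ≈ 4%
over directions), which would swamp a percent-level comparison, so the
oracle also offers a knight-move (16-neighbor) stencil whose bias is
below 2.8% (median well under 1%); percent-level certification uses
the latter, while the 8-neighbor values still provide a one-sided
guard: Euclidean shortest time never exceeds the 8-connected metric,
so map values above it would reveal optimistic bias (for example
behind obstacles).

```{r wavefront-plot}
env <- fixture_world()
map <- propagate_wavefront(env, ttg_uniform(0.6))
plot(map)
```

## Gaze analysis

Gaze samples carry a world-frame head pose (position + unit quaternion)
and a glasses-frame gaze direction. Registration intersects the world
gaze ray with the horizontal flight plane; the scene-camera model is a
pinhole with the principal point at the image center and focal lengths
from the field of view (defaults 1280 × 960 px, 60° × 46°).

Classification is velocity–duration thresholding on world-frame angular
gaze speed (head motion is already compensated by registration):

* **Saccades** — samples above `saccade_speed` (150 °/s, below the
  200–600 °/s saccadic range and above pursuit speeds) seed an event
  that extends over the contiguous run above a fixed onset threshold
  (100 °/s). Events must last 20–200 ms and relocate the gaze by at
  least 3°; the duration and amplitude gates reject single-sample
  tracker spikes, so no velocity pre-filter is needed (a 3-point median
  filter was tried and found to clip the velocity peak of 50-ms
  saccades whenever noise dents one in-flight sample).
* **Smooth pursuit** — a stabilized run is pursuit when the fovea is
  locked on the vehicle: median gaze–vehicle angular separation below
  `pursuit_lock` (3°), mean separation inside the 15° foveal sector,
  and the fitted angular drift of the (smoothed) gaze matching the
  vehicle's apparent angular velocity in magnitude and direction. The
  drift test alone cannot separate a sub-second fixation near a slowly
  moving target from tracking — at 60 Hz with 0.5° noise the slope
  estimate over 0.25 s has a standard error near the vehicle's angular
  speed itself — hence the foveal-lock gate.
* **Fixations** — stabilized runs of at least 150 ms whose RMS angular
  dispersion about the mean direction stays below 1°. Thresholds live
  in gaze-angle space, not on the plane: at grazing ray incidence a
  0.5° angular wobble smears into half a meter of on-plane scatter.

Invalid samples split events; events tile the stream without overlap.
Attention metrics score the model's signature: the pursuit time share,
pursuit–vehicle coincidence, fixation overlap with subgoal regions, and
anticipatory saccades — saccades landing within `r_subgoal` of subgoal
$k{+}1$ while the active subgoal is $k$, with lead time measured to the
subsequent switch.

## Synthetic fixtures and what they do (not) show

`make_world()` rejection-samples disjoint rectangular obstacles;
`fixture_world()` is a fixed 12 × 8 m single-wall course with four
start bundles — two occluded (funneled around the wall corner from
approach courses ≈ 40° apart) and two with direct line of sight from
well-separated directions. `make_ensemble()` plans each start with the
wavefront and simulates repeated closed-loop runs with seeded
initial-course jitter (σ = 0.1 rad) and actuation jitter
(σ = 0.03 m/s², applied to the commands so dynamics invariants still
hold). `make_gaze()` scripts the model-predicted attention pattern at
60 Hz: pursuit of the vehicle, a saccade to the next subgoal 1.2 s
before each switch, a fixation there (0.2–0.5 s), and a saccade back,
with fixation durations inside 150–600 ms, saccade speeds inside
200–600 °/s and durations 50–180 ms (sub-50-ms saccades span fewer
than three samples at 60 Hz and are unresolvable by any
velocity-threshold classifier; anticipation targets closer than 12° to
the vehicle are skipped because no admissible kinematics exist for
them). Head yaw low-passes the vehicle bearing (0.4 s time constant);
0.5° angular noise is added.

Ground truth for extraction scoring comes from the plans themselves,
with one reduction: a plan waypoint passed by a single funneled stream
(for instance the second of two consecutive corner waypoints, whose
only predecessor is the first) is not identifiable by any
convergence-based extraction, so the recoverable truth is the set of
*convergence regions* — waypoints with at least two distinct
predecessors across bundles — plus the goal.

Passing tests on these fixtures show that the pipeline recovers planted
structure under its own closed-loop dynamics and noise model. They do
not show robustness to human motor variability, to gaze-tracker
dropout structure beyond random validity gaps, to non-rectangular
obstacles, or to tasks where behavior overlaps with different subgoal
values (multi-valued TTG sheets are out of scope and flagged, not
resolved). A single IP family with near-constant cruise speed underlies
the fixtures; richer primitive libraries with heterogeneous dynamics
per leg are not exercised.

## Problem sizes

The test suite and the acceptance script run at desk scale: planner
grids of 50–80 cells per side with an oracle at 4× finer resolution,
20 random worlds for the oracle comparison, ensembles of 8 runs
(4 bundles × 2 repetitions), 20 seeded gaze streams, 1000 Procrustes
noise replicates, and 30 sampled starts for the convergence rate.
These sizes were chosen so the full evidence chain reruns in a few
minutes; all of them scale up by changing the corresponding arguments.

## Known limitations

* The merge-point surrogate lags the true convergence state by up to
  the coincidence tolerance; recovered subgoal regions sit a fraction
  of the capture radius downstream of the geometric corner.
* Visibility-restricted propagation assumes the TTG function is valid
  across the whole visible region of a source; strongly anisotropic
  primitives would need domain clipping in angle as well as range.
* The course-based candidate split uses a fixed 30° cut; approach
  bundles separated by less than that merge into one candidate.
* Pursuit classification makes a kinematic claim only — whether the
  eye tracks the vehicle to estimate its state or engages in
  visuo-motor control is not decidable from gaze geometry.
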