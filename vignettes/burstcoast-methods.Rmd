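---
title: "Burst-and-coast swimming: model, segmentation and interaction inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burst-and-coast swimming: model, segmentation and interaction inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Small schooling fish such as the rummy-nose tetra swim in a
burst-and-coast style: brief accelerations ("kicks"), during which the
heading changes, separated by passive, nearly straight glides. This
package treats each kick as one behavioural decision, which turns a
continuous trajectory into a discrete sequence of stimulus–response
pairs: the stimuli are the fish's geometric relation to the arena wall
and to a neighbour at the moment of the kick, and the response is the
heading change the kick produces. Around that idea the package provides
three connected tools:

* an event-driven stochastic **simulator** of the kick model for one or
  two fish in a circular arena;
* a **segmentation** pipeline that recovers kicks from 50 Hz tracked
  positions;
* an **inference** procedure that measures the interaction functions
  directly from kick tables by a symmetry-constrained product
  factorization, plus parametric **fits** that condense the tabulated
  functions into named parameters.

The closed loop — simulate with known parameters, segment, infer, fit,
and compare with the generating values — is the package's validation
strategy, exercised by the test suite and by `scripts/acceptance.R`.

## The kick model

At the $n$-th kick a fish at position $\vec x_n$ with heading
$\phi_n$ draws a peak speed $v_n$, a kick length $l_n$, and a new
heading $\phi_{n+1} = \phi_n + \delta\phi$. During the glide the speed
decays as $v(t) = v_n e^{-t/\tau_0}$ with a dissipation time
$\tau_0 = 0.8$ s, so length and duration are linked by
$l_n = v_n \tau_0 (1 - e^{-\tau_n/\tau_0})$ and the position advances
along the straight heading by the corresponding fraction of $l_n$
(`glide_position()`). The heading change is a sum of four terms:

$$\delta\phi = \delta\phi_R(r_w) + \delta\phi_W(r_w, \theta_w)
  + \delta\phi_{Att}(d, \psi, \Delta\phi)
  + \delta\phi_{Ali}(d, \psi, \Delta\phi).$$

* **Spontaneous turning** $\delta\phi_R = \gamma_R\,[1 - \alpha
  f_w(r_w)]\,g$ with $g$ standard normal. Far from the wall the turn
  scale is $\gamma_R$ (0.35 rad for a fish alone, 0.45 rad in a pair);
  close to the wall it is reduced by up to the factor $1-\alpha$,
  because the fish has less room to manoeuvre. The per-condition
  $\alpha$ follows from the near-wall scale
  $\gamma_{R,0} = (1-\alpha)\gamma_R$ of each arena
  (`preset_params()`).
* **Wall avoidance** $\delta\phi_W = \gamma_W\,O_w(\theta_w)\,
  f_w(r_w)$, with range factor $f_w(r) = e^{-(r/l_w)^2}$,
  $l_w = 60$ mm (about two body lengths), and an odd angular shape
  $O_w(\theta) \propto \sin\theta\,(1 + 0.7\cos 2\theta)$: no
  deterministic response when heading straight at or away from the
  wall (left/right symmetry), maximal response at oblique incidence,
  and a reduced response when swimming parallel to the wall.
* **Attraction** $\delta\phi_{Att} = \gamma_{Att}\,\hat F_{Att}(d)\,
  O_{Att}(\psi)\,E_{Att}(\Delta\phi)$ with
  $\hat F_{Att}(d) \propto (d - d_0)/(1 + (d/l_{Att})^2)$: repulsive
  below the comfort distance $d_0 = 30$ mm ($\approx$ 1 body length),
  growing to a maximum and decaying like $1/d$ as the visual angle of
  the neighbour shrinks; $l_{Att} = 200$ mm.
* **Alignment** $\delta\phi_{Ali} = \gamma_{Ali}\,\hat F_{Ali}(d)\,
  O_{Ali}(\Delta\phi)\,E_{Ali}(\psi)$ with
  $\hat F_{Ali}(d) \propto (d + d_0')\,e^{-(d/l_{Ali})^2}$,
  $l_{Ali} = 200$ mm, and an even factor $E_{Ali}$ that nearly
  vanishes when the neighbour is behind the focal fish — a fish can
  hardly match the orientation of a neighbour it cannot see.

All four angular shapes are short cosine series on top of the leading
$\sin$ (odd factors) or constant (even factors), normalized so their
mean square over the circle is 1 (`shape_odd()`, `shape_even()`). This
convention, enforced by quadrature at parameter construction, makes the
distance factors carry the physical scale in radians and makes the
printed harmonic coefficients comparable across factors. Odd/even
parity is not cosmetic: mirror symmetry of swimming in a circular arena
*requires* $\delta\phi(r_w, -\theta_w, d, -\psi, -\Delta\phi) =
-\delta\phi(r_w, \theta_w, d, \psi, \Delta\phi)$, and the separable
forms are the simplest products obeying it.

Kicks that would carry the fish out of the arena are handled by
rejection: a proposed move is accepted only if the look-ahead point
$\vec x + (l + l_c)\,\vec e(\phi + \delta\phi)$ stays inside, where the
comfort length $l_c$ (about one body length, per-arena values in
`preset_params()`) accounts for the fish's body extending ahead of its
centre of mass. On rejection the kinematics and the spontaneous turn
are redrawn; after `max_rejections` (default 1000) failures the
spontaneous turn falls back to a uniform draw on $[-\pi, \pi]$, which
is both biologically sensible (fish trapped heading at the wall execute
large turns) and guarantees termination; an absolute cap of $10^6$
attempts turns pathological configurations into an error rather than a
hang. Two-fish simulation is event-driven: whichever fish's next kick
comes first decides, evaluating its partner's pose by glide
interpolation along the partner's current kick segment, with the
partner's heading taken as that segment's direction.

### Reproducibility and mirror equivariance

A run is a deterministic function of `(seed, params, kin)`. The
`angle_sign` argument flips the sign of every random angular draw;
running with mirrored initial poses and `angle_sign = -1` produces the
exact mirror image of the original run. The tests use this to verify,
bit for bit, that the whole model (including the rejection procedure)
commutes with reflection.

### What the generator emulates, and what it does not

The kinematics configuration (`kick_kinematics()`) draws $v_n$ and
$l_n$ from log-normal distributions. The defaults are calibrated on
*in-arena* statistics, because wall rejections preferentially discard
long kicks and shorten what is accepted: with the defaults
(`v_mean_mm_s = 200`, `v_cv = 0.15`, `l_mean_mm = 82`,
`l_cv = 0.25`), a single fish in the 250 mm arena produces a mean
inter-kick duration close to 0.5 s and a mean kick length close to
70 mm; within-kick mean travel speed is then about 150 mm/s. Pairs use
slightly shorter kicks (`preset_kinematics(2)`, `l_mean_mm = 65`).

The pair amplitudes $\gamma_{Att} = 0.30$ and $\gamma_{Ali} = 0.16$ are
not printed quantities; they were calibrated once against two
qualitative observations: the two fish stay cohesive, with a typical
(median) inter-fish distance near 75 mm and only a small fraction of
kicks beyond the 280 mm range where the interaction cannot be measured;
and alignment dominates attraction below about 75 mm (with the
normalized profiles, equality of the two amplitudes falls at 75 mm for
this ratio). One honest caveat: the simulated distribution of $d$ rises
sharply above the short-range repulsion and then declines slowly, so
its histogram mode is plateau-like — at 10 mm bins the argmax wanders
between roughly 35 and 75 mm from seed to seed, while the median sits
stably near 75 mm. The model, at these parameters, does not reproduce a
sharply peaked distance distribution.

Simulated trajectories (`resample_trajectory()`) are exact glide
interpolations plus optional isotropic Gaussian position noise. Real
tracking data differ in ways the generator does not emulate: bursts
have a finite rise time rather than an instantaneous speed jump,
positional error is correlated in time and worse near occlusions, fish
pause and stop (the activity-selection rules exist for this), and body
orientation is not identical to displacement direction. Closed-loop
tests therefore validate the pipeline's internal consistency, not its
robustness to every artefact of video tracking.

## Segmentation

`estimate_speed()` forms the raw speed by a centred position difference
over a 0.08 s window (4 frames at 50 Hz, one-sided at the boundaries)
and smooths it with a degree-3 Savitzky–Golay filter. The nominal
0.36 s span corresponds to 18 frames at 50 Hz; a centred filter needs
an odd count, so 19 frames are used. `classify_kicks()` labels samples
accelerating where the forward difference of the smoothed speed is
positive (exact zeros continue the previous phase), merges
accelerations separated by decelerations shorter than 0.08 s, then
discards accelerations shorter than 0.08 s; merging precedes
discarding. Kick onsets are the first samples of the surviving
acceleration runs, and the first and last 9 frames (where the speed
estimate is one-sided) are never onsets.

Because the smoothing window is wide compared with the instantaneous
speed jump of a simulated kick, the first accelerating sample of the
smoothed series precedes the true minimum by several frames. The
default `refine = TRUE` therefore moves each onset to the raw-speed
minimum within 0.12 s, advanced by half the differencing bandwidth (the
centred difference leads a jump by two frames), and re-enforces the
0.08 s minimum spacing afterwards. On simulated data this removes the
bias entirely (median onset error below one frame).

Two quantified limitations, measured in the test suite's closed loop at
0.5 mm tracking noise, should be kept in mind. First, kicks whose
deceleration interval disappears inside the smoothing window are merged
into their neighbour: about one kick in five is lost this way, mostly
kicks that follow a short kick, and a few percent of kicks produce no
speed rise at all (the new peak speed falls below the previous glide's
end speed) and are undetectable in principle by any speed-based
detector. Aggregate per-kick means of $l$ and $\tau$ from segmented
data are therefore biased upward by roughly the inverse recovery rate
(~25%), while matched kicks individually reproduce the generated
$(l, \tau, \delta\phi)$ to a few percent, 0.01 s, and well under
0.02 rad at the median. Second, heading (and so $\delta\phi$) error
grows as the inverse segment length, so very short segments carry
noisy turn angles. The inference stage is insensitive to the missed
kicks (they thin the sample without biasing the stimulus–response
relation), which is why interaction measurement does not require
perfect segmentation.

`activity_bouts()` implements the activity selection used for long
recordings: frames where the (fastest) fish swims slower than 0.5 body
lengths per second for more than 4 s are *stopping* and removed;
shorter slow intervals are *pausing*; the active remainder is cut into
disjoint 120 s sections with the trailing remainder dropped.

## Measuring the interactions

`symmetrize_kicks()` doubles a kick table with its mirror image
(negating $\theta_w$, $\psi$, $\Delta\phi$, $\delta\phi$), which both
halves angular statistical error and makes the binned counts exactly
mirror-symmetric — the property that turns the parity projections below
into exact constrained least squares.

**Wall.** `bin_wall_response()` partitions $(r_w, \theta_w)$ into a
$40 \times 30$ mesh ($r_w$ over $[0, R]$, $\theta_w$ over
$[-\pi,\pi]$, bins left-closed right-open with the last closed) and
stores per-cell counts $\epsilon_{ij}$ and mean heading changes
$\overline{\delta\phi}_{ij}$. `factorize_wall()` then minimizes

$$\Delta = \sum_{ij} \epsilon_{ij}\,
  (\overline{\delta\phi}_{ij} - f_i O_j)^2$$

over the tabulated factors with $O$ odd. Each iteration computes the
exact weighted least-squares update of each factor given the other and
moves a fraction $p = 0.25$ of the way (damping), then anti-symmetrizes
$O$, rescales it to unit mean square $\tfrac1J\sum_j O_j^2 = 1$
(absorbing the scale into $f$, which carries radians), and fixes the
sign so $O$ has non-negative mean on $(0, \pi]$. Iteration stops when
the maximum relative change of any tabulated value,
$|x' - x| / (|x| + 10^{-12})$, drops below $10^{-6}$ (default cap 2000
iterations; non-convergence is flagged in the result rather than
raised). No smoothing or regularization is applied anywhere: empty
cells simply carry no weight, and the smoothness of the recovered
factors is evidence, not an assumption. One conditioning caveat
follows from that stance: the loss is count-weighted but the
unit-mean-square constraint is not, so on small samples (a few times
$10^4$ kicks) the angular factor can slowly drift its norm onto
near-empty noise cells, inflating the distance factor to compensate.
The `min_count` argument of the binning functions zeroes the weight of
cells below a record floor; the default 1 keeps every occupied cell,
and analyses of small kick tables should set a floor of a few
records. If the binned table is exactly
a product, the iteration recovers the factors exactly (up to the
conventions); the suite also cross-checks the damped iteration against
an independently written brute-force alternating least-squares
minimizer on small meshes, to $10^{-8}$.

**Pair.** `bin_pair_response()` first excludes kicks with
$r_w \le 60$ mm (two body lengths), where the wall dominates, then bins
$(d, \psi, \Delta\phi)$ on a $40 \times 30 \times 30$ mesh with
$d \le 280$ mm — beyond that the pair statistics are too thin to
measure. `factorize_pair()` minimizes the analogous error for the
two-term sum $F_{Att,k} O_{Att,l} E_{Att,m} + F_{Ali,k} O_{Ali,m}
E_{Ali,l}$, cycling damped updates through the six tabulated functions;
each update subtracts the current estimate of the *other* term from the
data (the counter-term), so attraction is measured on the
alignment-corrected response and vice versa. Parity projection
(odd/even), unit-mean-square normalization and the sign conventions are
re-applied every cycle. The two terms are identifiable because their
angular structure lives in orthogonal parity sectors — odd in $\psi$
$\times$ even in $\Delta\phi$ for attraction, even $\times$ odd for
alignment. If one distance factor collapses to zero the result is
flagged `degenerate` rather than raised, since on weak data the
decomposition genuinely loses its second term. Initialization defaults
($O \propto \sin$, $E \equiv 1$, distance factors solved from the first
update) follow the same logic; the `init` argument exposes them so
init-independence can be tested.

**Fits.** `fit_wall_range()`, `fit_attraction_profile()` and
`fit_alignment_profile()` are free-amplitude nonlinear least squares
(Levenberg–Marquardt) on the tabulated distance factors, so all
recovered shape parameters are invariant under rescaling of the input;
starting values come from log-linear regression or the observed zero
crossing. `fit_fourier()` is a *weighted linear* regression on the
basis $\{\sin\theta, \sin\theta\cos k\theta\}$ (odd) or
$\{1, \cos k\theta\}$ (even), reporting coefficient ratios to the
leading term — the same normalization-free quantities whatever the
amplitude; at most two harmonics are fitted, and a declared parity
inconsistent with the data (checked on symmetric meshes) is an error.
All fits default to weighting bins by their record counts, because
large-$d$ and large-$r_w$ bins are noise-dominated; unweighted mode is
available. `fit_exponential_decay()` recovers the glide time
$\tau_0$ from a mean speed-decay profile; `speed_decay_profile()`
restricts the average to kicks that outlast the fit window (0.4 s by
default), since otherwise the surviving-kick population changes with
time-since-kick — long-lived kicks come from slower draws — and the
apparent decay no longer reflects $\tau_0$.

## Known biases of the closed loop

Two systematic effects, both quantified by the tests, are worth
stating plainly.

* **Residual wall leakage.** The 2-body-length cutoff does not remove
  the wall's influence completely ($f_w(65\,\mathrm{mm}) \approx
  0.31$), and the leftover wall response is correlated with the pair
  geometry through the way pairs swim along the wall. In the in-arena
  closed loop this inflates mainly the even viewing-angle factor of
  alignment (its first harmonic recovers high by roughly +0.1 to
  +0.15). A control with the wall interaction disabled in a very large
  arena recovers *all* printed harmonic coefficients to within ±0.08,
  isolating the leakage as the cause; that control is part of the test
  suite.
* **Rejection contribution to the measured wall response.** The
  measured wall interaction is the sum of the explicit turning rule
  and the effective avoidance created by rejection of wall-crossing
  moves. The latter acts only when heading wallward, adding an odd
  $\sin\theta\cos\theta$-type component absent from the generating
  $O_w$; a single-harmonic fit of the recovered angular factor
  therefore reads the $\cos 2\theta_w$ modulation somewhat above the
  generating 0.7. Similarly, the spontaneous-turn scale estimated from
  kicks beyond 60 mm sits below $\gamma_R$ (about 10% low), because
  the noise-reduction factor $1 - \alpha f_w$ still bites just beyond
  the cutoff. These are properties of the measurement in a finite
  arena, not of the estimator: they would equally affect the analysis
  of real data with the same geometry.

## Problem sizes and runtime choices

The package-level validation uses $2\times10^5$ kicks for each
closed-loop inference (single fish at $R = 353$ mm for the wall;
two fish at $R = 250$ mm for the pair), $10^5$ kicks for the scalar
calibration checks, and $10^4$ glide draws for the $\tau_0$ recovery;
a factorization on the full meshes converges in a few hundred
iterations in about a second, and a $2\times10^5$-kick simulation takes
under a minute on one core. Unit tests run reduced versions (a few
thousand kicks) of the same loops. These sizes were chosen to keep
Monte-Carlo error comfortably below each recovery tolerance.

## Limitations and non-goals

The simulator covers one or two fish only: the pairwise interactions
measured here do not by themselves determine how multiple neighbours
combine, and no combination rule is implemented. Arenas are circular —
the symmetry argument that restricts the wall interaction to
$(r_w, \theta_w)$ relies on it. Hydrodynamic coupling, 3-D motion,
body-shape effects and the upstream video-tracking problems (wall
detection from images, fish shape and heading from pixel blobs) are out
of scope; the package starts from tracked planar positions. Inference
uses exactly one attraction and one alignment term: a longer expansion
$\sum_i F_i O_i E_i$ risks overfitting and was deliberately not
implemented. Uncertainty quantification beyond residual norms
(e.g. bootstrap over kicks) is a documented extension, not included.
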