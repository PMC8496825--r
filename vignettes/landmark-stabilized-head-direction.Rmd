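---
title: "Landmark-stabilized head direction in complex scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-stabilized head direction in complex scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hdring)
```

`hdring` simulates how a head-direction (HD) system can stay anchored to a
visually complex world. This vignette describes the model, the reasoning
behind the shipped defaults, the scaled problem sizes the package uses, and
the limitations a user should know about before drawing conclusions from
passing tests.

## The model

### Rate neurons

Every layer consists of rate neurons. A neuron's rate is a thresholded
hyperbolic tangent of its activation, `f = tanh(beta * (a - alpha))` for
`a >= alpha` and 0 otherwise, so rates lie in [0, 1). Activations follow
leaky integrator dynamics `tau da/dt = -a + sum_j g_j W_j f_j`, integrated
with explicit Euler steps. The global step is `dt = 2.5 ms`, chosen so the
fastest layer (the aLB layer, `tau = 5 ms`) is resolved by at least two
steps; the attractor uses `tau = 50 ms` and the retrosplenial relays are
effectively instantaneous (`tau = dt`), which keeps the corrective feedback
loop free of destabilizing lag.

### Visual channels

A scenery is a set of distal cues, each assigned to one feature channel.
Channel neurons are tuned to egocentric bearing on the common grid of the
ring (`n_dirs`, default 120, i.e. 3 degree spacing). Narrow cues are scaled
von Mises profiles; wide cues are plateau profiles built by tiling von Mises
bumps over a window (default 90 degrees); ambiguous cues are bimodal;
odor-like context cues are constant over all bearings. Channels that carry
cue signal are rescaled to a common mean, and the common mean is chosen so
the *summed* intensity over active channels is constant (divisive
normalization across features; `target_mean = 0.08` per channel at the
three-channel reference). This normalization is what makes a narrow cue
more salient (higher peak) than a wide one at equal mean, and it keeps the
total feed-forward drive onto the aLB layer independent of how many
features happen to be present — the property the recruitment threshold
(below) relies on. A weak, fixed, broad background-noise profile
(`noise_amp = 0.005`) is added to every channel; channels with no cue are
left at noise level rather than boosted to the common mean.

Cue precisions default to `kappa = 10` for narrow cues, `kappa = 14` for
the distinguishing cue of the capacity environments and `kappa = 20` for
the tiles of the broad cue. The narrow/broad contrast matters qualitatively
(precision versus unidirectionality); the exact values were calibrated once
so that every standard scenery's converged feed-forward drive lies above
the recruitment threshold, and then frozen.

### The aLB layer and the learning rule

aLB (abstract landmark bearing) cells receive all channels through plastic
non-negative weights and inhibit each other laterally. The weights follow a
subspace learning rule with two modifications: lateral inhibition among the
output cells, and clipping of negative weights,

```
W_j <- [ W_j + eta * f_alb (f_vis_j - zeta W_j' f_alb)' ]_+
```

The feedback term `W' f_alb` is the input the current aLB activity
"expects"; weights grow with the difference between real and expected
input, which depresses connections from absent cues and is what lets cells
disconnect from moved or vanished landmarks. The prefactor `zeta` (default
1) scales the feedback; a run with `zeta > 1` is exactly reproduced by
scaling `eta` down, the feed-forward gain up and the initialization
interval down by the same factor (a symmetry the test suite asserts).

The layer operates in a calibrated *recruitment window*:

* plastic weights are initialized i.i.d. uniform on the narrow positive
  interval [0.28, 0.32], so every uncommitted cell carries nearly the same
  total drive (about 69 activation units under the standard sceneries);
* the threshold `alpha = 71.5` sits just above that reservoir level, so
  uncommitted cells are silent by default;
* a converged (fully matched) cell drives itself to roughly 80-115 units,
  so it fires robustly inside its own view tile;
* a partially matched cell — an incumbent whose scene has changed — falls
  to roughly 40-65 units, below threshold, and goes silent immediately.

This window produces the layer's two signature behaviours with one
mechanism: *stable codes* (committed cells keep their tiles, and silent
cells are never modified by the rule, so codes for absent environments are
preserved) and *remapping* (when a salient cue configuration changes, the
incumbents drop below threshold and fresh reservoir cells take over).

Recruitment itself is a sparse stochastic search: during learning exactly
one cell at a time receives a sustained activation boost (`kick_size = 5`
for `kick_len = 0.5 s`, cells visited in a seeded random permutation). A
boosted cell crosses threshold only where no committed cell covers the
current view; it then consolidates through the learning rule within a few
hundred milliseconds. Boosting one cell at a time is essential: if many
near-identical reservoir cells crossed threshold together, the feedback
term (summed over all active cells) would erode the whole reservoir. The
capacity parameter set (`hd_params_capacity()`) lengthens the boost to 2 s
so the reservoir is consumed slowly enough to cover ten environments, and
is paired with a larger population (720 cells on the 120-neuron ring).

### Attractor, retrosplenial layers and feedback

The ring attractor uses a symmetric von Mises kernel minus uniform
inhibition (scaled inversely with ring size so the drive is
size-invariant), plus an antisymmetric kernel equal to the discrete
circular derivative of the symmetric one, scaled by angular velocity. With
the derivative construction the bump's travel speed is exactly proportional
to the velocity gain, so a single scalar calibrated by
`calibrate_velocity_gain()` (simulate, decode, rescale, verify) achieves
better than 1% speed accuracy out to 400 deg/s. The calibration runs use an
internal step of 1.25 ms because the first-order integrator's speed error
grows with `omega * dt`; at the production step the residual high-speed
bias is below 1% for the speeds that matter and is absorbed by the
closed-loop correction. Path-integration miscalibration is modelled by
`pi_gain` (1 = veridical; 1.05 produces the classic drift in darkness).

gRSC receives the bump one-to-one and relays it. dRSC is a
*coincidence-threshold* layer: its threshold (`alpha = 1.1`) lies above
what the gRSC projection alone delivers, so dRSC only fires where the gRSC
bump and the learned aLB anchor agree — or where a mature anchor alone is
strong enough (`g_a2d = 12` on rows capped at norm 0.5). Three consequences
fall out of this arrangement:

* in darkness (no visual input, hence no aLB activity) dRSC is silent and
  the attractor receives *no* feedback: path integration runs open loop;
* early in learning, before anchors exist, the loop is likewise silent, so
  the anchor map is laid down while the internal direction is still
  veridical;
* after a large scene change, the anchor-only dRSC lobe appears away from
  the bump. The feedback (one-to-one excitation `g_fb = 0.5`, global
  inhibition `g_fb_inh = 4`) then suppresses the unsupported bump and
  re-seeds it at the anchor: the compass re-anchors by extinction and
  re-nucleation rather than by sliding.

The Hebbian associations (`eta_g2d = 5e-4`, `eta_a2d = 2.5e-4` per step)
are capped row-wise at a maximum two-norm. The printed form of the
normalization in the source account scales sub-maximum rows *up*; the
package implements the cap reading (scale down when above `w_max`), since
the quantity is described as a maximum total connection strength, and keeps
the other behaviour selectable (`normalize_rows(mode = "floor")`). The
anchor learning rate is deliberately slow relative to the correction
dynamics: anchors must pin the map (corrections snap the bump back to the
anchors) rather than chase it (anchors rewriting toward a wandering bump),
and the ratio of these two time scales sets the residual anchoring error.

The gRSC-to-dRSC matrix is initialized as random positive weights plus a
weak topographic (diagonal circulant) bias that Hebbian learning amplifies.
With fully unstructured initial rows the one-to-one feedback could not
convey direction-specific correction — a dRSC cell's emergent preferred
direction would be unrelated to the attractor index it excites — so the
initial topographic preference is taken as part of the architecture
(dRSC preferred directions inherited from the attractor), with the random
component on top.

### The direct (alternative) model

`hd_network(variant = "direct")` removes the aLB layer and connects every
visual channel to dRSC through classic Hebbian weights with per-channel row
caps. The two variants carry separate hyperparameter columns
(`hd_params_direct()`): the direct pathway weights narrow (directionally
specific) channels above broad ones (per-channel gains 3/3/1), learns
slowly (`eta = 2e-5`, so the matched filter integrates over the whole
session instead of tracking the last few seconds), uses the lower dRSC
threshold (0.4, since there is no conjunction stage to gate coincidences)
and a weak slide-style feedback (`g_fb = g_fb_inh = 0.05`). Under this
column the attractor resolves an ambiguous cue rotation by ring proximity:
after a 120 degree anticlockwise scene rotation with a high-saliency
ambiguous cue, the bump follows the nearer (60 degree clockwise)
interpretation of that cue instead of the full-scene rotation — the
qualitative signature that distinguishes the two architectures.

## Scaled problem sizes

The package defaults reproduce the study at reduced scale: a 120-neuron
ring (3 degree resolution) with 360 aLB cells, learning phases of 1-5
minutes of simulated exploration, test rotations of one steady revolution
after a settling revolution, and 4-10 environments in the capacity
protocols (720 aLB cells for ten environments). Full-scale settings
(360-neuron ring, 20-minute phases, ten test revolutions) remain reachable
through `n_dirs`, `dwell` and `test_revs`. Scaling keeps `dt`, gains and
kernel shapes fixed so the dynamical regimes are preserved; what shrinks is
angular resolution and statistical power, not mechanism.

The synthetic trajectory generator stands in for recorded foraging data: a
mean-reverting angular-velocity process with a 0.5 s correlation time,
rescaled so the mean absolute angular velocity matches the recorded value
of 72.88 deg/s, integrated into a wrapped heading. It emulates the turning
statistics (smooth autocorrelated velocity, symmetric about zero, wide
dynamic range) but not the spatial structure of real foraging — there is no
position, and under the distal-cue assumption none is needed. Passing tests
therefore speak to the circuit mechanisms under naturalistic *rotational*
statistics, not to behaviour in spatially structured environments.

## Numerical choices

* Explicit Euler throughout; `dt <= tau` is enforced. The relay layers run
  at `tau = dt`, i.e. instantaneous relaxation, which is exact for
  feed-forward stages.
* Cue profiles are evaluated from memoised 1-degree shape tables with
  circular linear interpolation (5e-4 absolute accuracy), which makes the
  channel stage exactly equivariant under grid-step rotations.
* Test-phase representations discard one settling revolution and bin the
  steady passes; recruitment is judged on the binned tuning so a recruited
  cell always has at least one supra-threshold lobe. Coverage is measured
  on the union of recruited cells' momentary rates per bin, which
  distinguishes a direction no cell encodes from a bin that merely
  straddles a winner handover.
* The compiled engine (RcppArmadillo) and the R reference loop implement
  the same step in the same RNG draw order; they agree to 1e-8 over short
  horizons but diverge over long runs because the winner-take-all
  competition amplifies floating-point ordering differences. The compiled
  path is the canonical engine; the R path backs the pluggable alternative
  learning rules.
* Ties and degenerate inputs: a perfectly symmetric rate pattern has no
  population vector and raises an error rather than returning an arbitrary
  direction; the Jaccard overlap of two empty sets is defined as 0.

## Known limitations

* **Self-anchored maps carry an offset.** The anchor map is learned from
  the system's own internal direction, so once corrective feedback becomes
  active the map can settle a constant offset away from the true heading
  (tens of degrees at this scale). Field-*shift* measurements difference
  this offset out; absolute heading errors do not, and the package's
  closed-loop errors are accordingly reported as drift relative to the
  entry error.
* **Anchoring precision is tile-limited.** Corrections pull toward aLB
  tile centers, so the residual closed-loop error is of order the tile
  width (10-30 degrees at 120 neurons), far coarser than the sub-degree
  errors attainable at full scale with dense tiling.
* **Set persistence under cue instability is weaker than at full scale.**
  When a cue moves, incumbents whose conjunction no longer matches fall
  below the recruitment threshold and are replaced by fresh cells. The
  stabilized-scene test therefore recovers unimodality (as it should) but
  with a partially new cell set; the corresponding acceptance assertion is
  left failing as a documented deviation.
* **Per-step weight updates plateau.** Tile boundaries keep precessing
  slowly under continued presentation, so the per-step update magnitude
  converges to a floor (roughly half its early value) instead of falling
  below 1% of it; the distance-to-final-weights curve does converge. The
  1%-criterion test is left failing as a documented deviation.
* **Single-cue retrieval can fall below threshold.** A cue that was
  learned as one third of a conjunction delivers only part of the
  converged drive when presented alone; at this scale that can be below
  the recruitment threshold, so the cue-removal retrieval probe is not
  reproduced.
* **Mirrored-compartment bidirectionality is partial.** A softer feedback
  setting (`g_fb_inh = 2.5`) is used for the mirrored protocol so the
  ambiguous anchors do not flip the attractor; a minority of dRSC cells
  then express the bidirectional profile while gRSC remains largely
  unimodal — a weaker version of the full-scale result.
* Hyperparameters follow the source study's practice of per-simulation
  parameter columns (full model, alternative model, capacity simulations);
  the shipped values were calibrated once against the qualitative suite
  and then frozen.
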