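---
title: "Methods: a dual-pathway model of pro- and antisaccade decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a dual-pathway model of pro- and antisaccade decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model equations, the parameters that matter,
and the design decisions behind `saccadia`'s defaults — in particular the
places where the architecture sketch leaves choices open and we had to fix
a convention. Nothing here reports an empirical number that the test suite
or `scripts/acceptance.R` does not itself compute.

## 1. Task and stimuli

Screens are 16 x 32 nonnegative intensity grids. The two brightness
squares are 4 x 4 blocks at rows 7–10, columns 7–10 (left) and 23–26
(right), symmetric about the vertical midline. The rule cues are two-pixel
bars of unit intensity on the vertical midline: the horizontal 2 x 1
prosaccade bar at row 4, columns 16–17, and the vertical 1 x 2 antisaccade
bar at rows 11–12, column 16.

Two conventions deserve comment:

* **Cue positions.** Both bars lie outside the square windows, so the
  subcortical readout of any cue screen is exactly (0, 0) — the reflexive
  pathway is structurally blind to the rule. We place the two bars at
  *distinct* fixed positions rather than a shared center. With a shared
  center the rule discrimination rests entirely on a two-pixel orientation
  difference; a network of this size trained only on noiseless screens
  does not reliably retain that distinction under heavy pixel noise
  (its noise response is seed-dependent), whereas distinct positions make
  the rule linearly decodable from spatial energy, which is robust. Any
  fixed convention is task-equivalent; this one is also the robust one.
* **Noise is not clipped.** Test-time perturbations are exactly additive
  Gaussian draws per pixel; clipping to [0, 1] would bias extreme
  intensities.

The training set enumerates all 121 ordered pairs of brightness values on
the 0.1 grid; the 11 equal-brightness pairs carry an undefined side and are
excluded from side-classification losses. Test sets are drawn without
replacement from the ten-fold finer 0.01 grid, excluding ties, with exactly
half left-brighter pairs. Grid values are generated as integer ratios, so
they are exact.

## 2. Rate dynamics

Every unit follows

$$\tau \dot r_i = -r_i + f_i\Big(b_i + \sum_j w_{ij} r_j\Big),
\qquad \tau = 100\ \mathrm{ms},$$

integrated synchronously by forward Euler with $\Delta t = 10$ ms (all
updates at step $k$ read rates from step $k$). Activations are rectified
linear for generic units and *normalized decision pairs* for the choice,
subcortical-decision, and motor pairs: the exponentiated log-softmax, i.e.
the softmax, over the two drives. The normalization choice resolves an
inconsistency in the architecture sketch: log-softmax outputs are
nonpositive and could never cross the stated decision threshold of 0.55,
while softmax outputs live in (0, 1) and make the threshold meaningful.
Each competing pair (C, S, M) is normalized within itself.

Rates start at zero at trial onset; during the 500 ms cue phase the
symmetric pairs relax to (0.5, 0.5), which is the natural resting point of
a normalized pair. A trial's reaction time is the first time after stimulus
onset at which either motor rate reaches 0.55 (so RTs are multiples of
10 ms and at least one step); if both units cross in one step the larger
rate wins, and an exact tie leaves the trial unresolved. The *winner*
pathway is the module (cortical or subcortical) whose own normalized output
pair crossed 0.55 first, reusing the same threshold to avoid a second free
parameter; a module-crossing tie is credited to the cortex (it cannot
mechanistically precede the subcortex at equal crossing step).

The closed-form relaxation of a single normalized pair gives the RT
machinery an analytic oracle: with constant softmax output $p > 0.55$ and
$r(0) = 0$, the crossing time is $-\tau\,\ln(1 - 0.55/p)$, about 79.9 ms
for $p = 1$. The test suite checks this to within one Euler step, along
with first-order convergence of the integrator.

## 3. Feedforward cortical pathway

The classifier is a small convolutional network: two valid (no padding,
stride 1) 4 x 4 convolutions with 8 and 16 channels, each followed by
3 x 3 non-overlapping max pooling, then a 16-unit dense layer and 4
outputs (L, R, P, A). Pooling uses ceil mode (partial edge windows):
16x32 → 13x29 → 5x10 → 2x7 → 1x3x16. Valid convolution with floor-mode
pooling would leave a 1-row map that a second 3 x 3 pool cannot reduce, so
ceil mode is the minimal consistent reading of the layer sizes.

Training is full-batch Adam (learning rate 2e-3, decoupled weight decay
2e-3, 500 epochs) on class-balanced cross-entropy over the noiseless
training screens: the two cue screens (weighted 55 each) and the 110
non-tie stimulus screens. Two criteria define a successful run: at least
99% training accuracy, and a post-training generalization check — rule and
side discrimination at or above 80% on screens noised at s.d. 0.2.
Cross-entropy on a tiny noiseless set occasionally converges to solutions
whose clean margins are perfect but whose noise response is degenerate;
such runs restart deterministically from a shifted initialization (at most
four times) and a run that never meets criterion is reported with a
warning. No noisy data enters training itself.

Rule integration is the hard-wired XOR gate: four rectified AND units
(bias −1) compute the conjunctions PL, PR, AL, AR from the four classifier
unit rates, and fixed output weights map PL + AR → C_L and PR + AL → C_R.
The cue classification is latched during the cue phase (argmax of the P/A
scores) and re-injected as drive during the stimulus phase — an explicit
working-memory stand-in. Classifier scores map to drives through their
argmax: the winning class unit receives a fixed gain. This keeps the whole
reaction-time calibration in the pathway gains (section 6).

## 4. Predictive-coding cortical pathway

The hierarchy is the linear generative model
$x \approx U_1 r_1,\ r_1 \approx U_2 r_2$ with layer sizes 512 (the
flattened screen), 144, and 16. Inference minimizes

$$E = \lVert x - U_1 r_1\rVert^2 + \lVert r_1 - U_2 r_2\rVert^2
      + \lambda(\lVert r_1\rVert^2 + \lVert r_2\rVert^2)$$

by gradient descent from zero latents, with a fixed iteration count so
trial timing is deterministic (defaults: rate 0.05, 40 iterations, decay
$\lambda = 0.01$). Learning alternates inference with the local delta
rule $\Delta U_1 \propto (x - U_1 r_1)\,r_1^\top$ (and likewise for
$U_2$), learning rate 0.03, weight decay 1e-4, 400 epochs. The two cue
screens are replicated 60-fold in the learning set: with 2 cue frames
among 121 stimulus frames the squared-error objective would devote almost
no generative capacity to the faint two-pixel patterns, and the
downstream rule readout would not survive input noise. Energy descent per
iteration and the match of the one-dimensional fixed point to its normal
equations are asserted in the tests.

The linear classifier is a 4-class softmax regression (via
`nnet::multinom`) on the frozen top latents. Because inference is linear
in the input, pixel noise induces a fixed latent noise distribution; the
classifier is therefore fit on latents of noise-jittered training screens
(noise s.d. drawn from the test range), which lets a *linear* readout
place its boundaries with respect to the latent noise it will actually
face. The hierarchy itself never sees noise.

Rule neurons (P, A) are self-recurrent rate units with a saturating
rectifier ($\min(\max(x, 0), 1)$), self-weight 1.2 and activation
threshold 0.1. The saturation bounds the self-excitation (plain ReLU
self-excitation above unit gain diverges); the threshold keeps the
undriven neuron silent against weak spurious input. The bifurcation sits
at self-weight 1: below it a latched neuron decays after drive removal,
above it the neuron holds its rate — the cue is remembered by attractor
dynamics rather than an external latch.

Side units (L, R) receive a categorical baseline drive (gain 0.08) plus a
*confidence-gated graded* term: the linear score margin (which, unlike
softmaxed probabilities, does not saturate and grades with stimulus
contrast over the whole brightness range), normalized by the margin of a
full-contrast stimulus, clipped to [−1, 1], with the part below a
confidence floor of 0.5 discarded (gain 24 on the remainder). The cortex
therefore commits slowly on subtle contrasts and steeply faster on strong
ones — the mechanism behind the difficulty-dependent handover in
section 7.

## 5. Subcortical pathway

Both variants read only the mean intensity of the two square windows.

**FF variant.** A bias-free perceptron (2 → 16 rectified → 2 softmax),
trained full-batch to report the brighter side. Freedom from biases makes
the zero readout map to exactly (0.5, 0.5): the pathway is neutral without
stimulus evidence, by construction. The decision pair applies
rectification before normalization, $f(u) = \mathrm{softmax}(\max(u, 0))$:
direct subtractive inhibition would otherwise be invisible to a softmax
pair (softmax is shift-invariant), whereas with rectification a strongly
inhibited pair sits at (0.5, 0.5), below threshold — silenced. The rule
neuron A inhibits both drives with gain 5.

**PC variant.** The non-plastic recurrent network: excitatory populations
S_L, S_R (128 units each, rates saturating at 1) and inhibitory S_I (32
units, rectified linear), with Bernoulli-masked uniform(0, 1) weights at
the stated connection probabilities, frozen after sampling. Drives are
normalized by presynaptic population size, so the sampled weights act as
population averages. The stimulus afferent is luminance-adapted,
$x' = 0.45 + 0.16\,x$: a compressed operating range which, together with
rate saturation, makes the race timing nearly contrast-independent. The
rule neuron A excites S_I (gain 12), which suppresses both excitatory
populations — indirect inhibition, in contrast to the FF variant.

Two homeostatic calibrations are applied once per sampled realization
(`calibrate_rnn_output`): the two output pathways are multiplicatively
rescaled to match at the resting operating point (multiplicative, so a
suppressed pathway maps to zero rather than to a spurious extrapolated
offset), and the decision-drive gain is set to `norm_target / (calibrated
full-contrast output difference)`, giving every realization the same
drive separation for a full-contrast pair. Without these, the static
left/right asymmetry and gain spread of independent random samples
dominate the race. Background input to the decision pair is modeled as
Gaussian noise with fixed s.d. in drive units (0.5), multiplied by the
pathway's own normalized output level — background carried by the pathway
itself, so the silenced pathway is also noise-free. The noise makes the
subcortical race stochastic with near-contrast-independent timing, and
lets the subcortex resolve even near-tie pairs.

## 6. Gain calibration and reaction times

The mapping from classifier outputs to rate-unit drives is not fixed by
the architecture; we keep it in a small set of gains per variant
(`ff_gains`, `pc_gains`) and calibrate them once. For the FF variant the
subcortical drive gain (0.5), cortical gate gain (2.3), and motor gain
(0.9) were chosen so that the mean prosaccade RT sits near 189 ms and the
mean antisaccade RT near 241 ms on balanced test sets — the behavioral
pattern the architecture is meant to reproduce — after which they were
frozen. The pro/anti RT *difference* is structural, not calibrated: the
antisaccade path crosses two extra relaxation stages (classifier units and
the XOR gate) regardless of gain settings, and the subcortex is silenced.
PC-variant gains were calibrated against the qualitative contracts
(prosaccades faster than antisaccades; suppression during antisaccades;
the difficulty handover of section 7).

## 7. Experiments

* **Noise robustness** — the balanced test set is run through the full
  trial dynamics at each noise level, cues assigned half pro / half anti
  and reshuffled per repeat; accuracy counts unresolved trials as errors.
  The full protocol is 100 repeats of 1000 pairs at 21 noise levels; the
  test suite and acceptance script use 5 repeats of 200 pairs, which
  leaves the per-level means stable to a few percent.
* **Reaction times** — 500 trials per cue condition at zero noise (the
  protocol does not fix a noise level for the RT comparison; zero makes
  the RT distribution purely architectural).
* **Difficulty dominance** — prosaccade trials drawn uniformly over the
  0.01 grid (ties excluded), run at pixel noise s.d. 0.05 (a moderate
  level; the protocol leaves it open), binned by difficulty
  $|x_L - x_R|$ in widths of 0.1. Per bin we report pathway win counts,
  the cortex/subcortex choice ratio (undefined on a zero denominator),
  and per-winner RT summaries. The subcortex drives most decisions below
  difficulty ~0.6 and its RTs stay flat, while the confidence-gated
  cortex takes over above it, so the choice ratio rises with difficulty.
  This handover is a designed consequence of sections 4–5; the
  architecture sketch alone does not force it.
* **Reconstruction** — inputs are reconstructed from layer 1
  ($U_1 r_1$) and layer 2 ($U_1 U_2 r_2$) for sample screens, with
  per-image error tables; trained weights must beat untrained ones on
  held-out frames.

Each experiment writes CSVs plus a manifest (variant, seeds, sizes) when
given an output directory, and is a pure function of (model, config).

## 8. What the synthetic stimuli do and do not show

All inputs are generated by the package: perfectly flat squares, exact
two-pixel cues, pixel-i.i.d. Gaussian noise. Passing tests therefore show
that the dual-pathway architecture produces the claimed behavioral
signatures under its own stimulus statistics — not that it generalizes to
natural images, luminance nonlinearities, correlated noise, eye-movement
kinematics, or trial-history effects, none of which are modeled. The
subcortical pathway is a two-channel caricature of the superior
colliculus; the cortical hierarchy is far shallower than its biological
counterpart; and all units share a single time constant, so absolute RTs
inherit their scale from that choice.

## 9. Known limitations

* The antisaccade RT distribution of the FF variant is nearly
  degenerate at zero noise (the cortical chain is deterministic and
  contrast-independent there); only its mean is meaningful.
* Winner attribution reuses the 0.55 threshold at the module level; other
  conventions (e.g. thresholding raw population rates) would shift the
  difficulty handover point.
* The PC subcortex needs its homeostatic calibration; an uncalibrated
  random realization has a left/right bias that can dominate near-tie
  races.
* Training the FF classifier is stochastic across seeds; the run-to-
  criterion protocol with restarts makes the *selected* solution robust,
  but individual runs can fail the noise criterion.
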