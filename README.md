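# pvrnnagency

Predictive-coding variational recurrent networks (PV-RNN) for multimodal
imitative interaction, with per-layer complexity regulation and
shifting-window error-regression inference.

## The problem

How strongly should an agent trust its own predictions versus revising them
from what it senses?  In predictive-coding / active-inference accounts of
social cognition, this trade-off is carried by the *complexity* term of the
evidence lower bound: the KL divergence between the inferred posterior over
latent states and the network's own learned prior.  This package implements
a multimodal model of that idea for visuo-proprioceptive imitation:

- a hierarchy of five leaky-integrator (MTRNN) recurrent layers — one
  associative layer over slow/fast proprioception and vision branches —
  with time constants τ = 15/8/2/8/2 inducing a temporal hierarchy;
- at each step and layer, a stochastic latent `z_t` with a learned
  *sequential prior* `p(z_t | d_{t-1})` and an approximate posterior
  parameterized by free per-step *adaptive variables* `a`;
- a weighted objective

  cost = Σ_t ‖p_t − p̄_t‖²/(2Rᵖ) + ‖l_t − l̄_t‖²/(2Rˡ)
         + Σ_layers (wˡ/Rˡ_z) · KL[q ‖ p]

  where the per-layer **meta-prior** `wˡ` sets how tightly complexity is
  regulated: small `w` = observation-adaptive dynamics, large `w` =
  prior-dominated ("egocentric") dynamics — the operational knob for the
  *strength of agency*;
- a static convolutional codec (CoordConv encoder/decoder) so that vision
  prediction errors live in a low-dimensional latent space rather than in
  pixels;
- offline training by BPTT (Adam, α = 0.001) of weights *and* per-sequence
  adaptive variables, and online inference by **error regression**: with
  weights frozen, the posterior over the last T′ steps is re-inferred at
  every sensory step by iterated forward/BPTT cycles (Adam, α = 0.2)
  updating only `a`.

Because the original human recordings are not public, the package includes
a first-class synthetic generator: a probabilistic finite state machine
over three movement primitives (A waving; B/C torso rotations; A→{B,C} at
50%, B/C→A at 100%), smooth 16-joint trajectories in [−1, 1], and
stick-figure grayscale frames whose noise far exceeds the proprioceptive
noise.

## Worked example

```r
library(pvrnnagency)

# 1. synthetic corpus: 6 sequences of 4 primitives x 25 steps, 16 px frames
ds    <- build_dataset(n_sequences = 6, n_segments = 4, segment_len = 25,
                       seed = 1, image_size = 16)
codec <- train_codec(ds[1:4], codec_config(16, latent_dim = 8),
                     epochs = 40, seed = 1, alpha = 3e-3)
ds    <- encode_dataset(ds, codec)

# 2. train a half-width model, 500 epochs
net <- build_network(network_config_scaled(l_dim = 8), seed = 7,
                     meta = meta_priors_w1())
fit <- train(net, ds[1:4], train_config(epochs = 500, seed = 11))
tail(fit$history$total, 1) / fit$history$total[1]   # 0.0492: < 20% of initial

# 3. pseudo-imitative interaction on a held-out sequence,
#    sweeping the meta-prior scale
for (f in c(0.01, 1, 100)) {
  cfg <- er_config(window_len = 12, iters = 10,
                   meta = rescale_meta_priors(net$meta, f))
  s <- run_interaction(fit$net, ds[[5]], cfg, seed = 3)$summary
  cat(sprintf("w x %-6g recon %.4f  total KLD %.3f\n", f,
      s["prop_err"] + s["vis_err"],
      sum(s[grep("^kld_", names(s))])))
}
```

On the development machine step 3 printed:

```
w x 0.01   recon 0.0204  total KLD 26.773
w x 1      recon 0.0376  total KLD 1.765
w x 100    recon 0.1703  total KLD 0.147
```

Reading: with loose complexity regulation (large `w`) the posterior is
pinned to the prior — KL divergence collapses and reconstruction error
grows (the agent acts egocentrically, resisting the observed sequence);
with tight regulation (small `w`) the posterior tracks the observations
(large KL, small error).  Exact values vary with the training seed; the
monotone trade-off is the tested invariant.

## Experiments

- `run_experiment1(spec)` — trains the tight-vision and swapped
  modality-specific meta-prior settings across seeds and reports the test
  metric table plus the direction-of-effect comparison (vision
  reconstruction error and associative-layer KL expected lower under
  tight vision regulation).
- `run_experiment2(spec, fit, test_set)` — sweeps the five meta-prior
  rescalings `W1`..`W5` (×10^(k−3), four orders of magnitude) over a
  trained model and reports the per-setting panels with Spearman
  monotonicity statistics.

A CLI wraps the same functionality (`inst/cli/pvrnn-agency`):
`gen-data | codec | train | interact | exp1 | exp2`, options as
`--key=value`.

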