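---
title: "First-spike coding for event streams: model, training rules and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{First-spike coding for event streams: model, training rules and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fscoding)
```

## The problem

Neuromorphic sensors emit asynchronous events: a dynamic vision sensor
produces `(t, x, y, p)` tuples when a pixel's brightness changes (polarity
`p = ±1`), a silicon cochlea produces `(t, channel)` tuples per frequency
band. Spiking neural networks (SNNs) are the natural classifiers for such
data, but most are trained with *rate coding*: the class read out from the
output layer is the neuron that fires the most spikes in the observation
window. Rate readouts ignore spike timing, need many spikes, and keep firing
after the decision is clear.

This package implements an alternative *first-spike (FS)* decision scheme:
the predicted class is the output neuron that fires **earliest**, and
training optimizes the first-spike times directly. Unlike classical
time-to-first-spike schemes there is no one-spike-per-neuron constraint, so
the network can process continuous event streams; only the output readout is
temporal. The firing-rate (FR) readout and loss are implemented alongside as
the baseline.

## Model

### Input representation

An event stream is binned at resolution $\Delta t$ into a count tensor: bin
$k$ (0-based) covers $[k\Delta t, (k+1)\Delta t)$ — the half-open histogram
convention; events at exactly $T\Delta t$ fall outside. Vision streams give
a $2 \times H \times W \times T$ tensor (polarity channels separated), audio
streams an $F \times T$ matrix. Spatial downsampling, when requested,
block-sums counts (padding the bottom/right edge with zeros when the frame
is not divisible), so the total event count — the quantity the
representation is defined on — is preserved; plain subsampling would not be
count-conserving, which is why we chose block-summation.

### Neuron and discretization

Neurons are current-based leaky integrate-and-fire (CUBA-LIF) units with
tied time constants $\tau = \tau_m = \tau_s$, resting potential 0 and an
instant multiplicative reset. With decay factors
$\alpha = \beta = e^{-\Delta t/\tau}$, one simulation step of layer $l$ is,
in this order:

$$U^{n+1} = \alpha\, U^{n} (1 - s^{n}) + (1-\alpha)\, I^{n}$$
$$s^{n+1} = \Theta(U^{n+1} - \theta)$$
$$I^{n+1} = \beta\, I^{n} + W s^{(l-1),\,n+1} + V s^{l,\,n+1}$$

The update order $U \to s \to I$ is normative in this package: it resolves
the apparent same-step circularity of the recurrent term (a spike emitted at
$n+1$ enters the current at $n+1$, hence the membrane at $n+2$ and spiking at
$n+3$ at the earliest). States start at $I^0 = U^0 = 0$. The first layer
receives raw integer counts; every later layer receives binary spikes.
Max-pooling layers are stateless: the max of a $\{0,1\}$ block is a logical
OR applied per step. `tau = 0` is accepted as the memoryless limit
($\alpha = 0$, the membrane relays the previous step's current).

### Readout

Output spike trains are encoded into discrete times: step $n$ maps to
$n\Delta t$ if the neuron spiked, otherwise to the sentinel
$t^{\inf} = (T+1)\Delta t$ — finite, but beyond any observable time. The
first-spike time is the minimum of these codes; it equals $t^{\inf}$ iff the
neuron is silent. `predict_fs()` takes the argmin of first-spike times; when
*all* outputs are silent it falls back to the neuron with the largest
membrane-potential maximum over time (the closer a membrane came to
threshold, the earlier that neuron would have fired). First-spike ties at
the same step are broken by the higher membrane potential at that step and
then by the lower index — the same "higher potential, earlier spike"
heuristic; the readout needs *some* deterministic rule and this is the one
consistent with the fallback. `predict_fr()` takes the argmax rate with
ties broken by membrane maximum, then index.

## Losses

The FS loss is a cross-entropy over softmaxed negative first-spike times
plus a penalty that only a *silent target* neuron can incur:

$$\mathcal{L}_{FS} = -\sum_i y_i \log
  \frac{e^{-\alpha_0 t^F_i}}{\sum_j e^{-\alpha_0 t^F_j}}
  + \lambda_t \sum_{i:\, t^F_i > T} y_i \left(e^{\beta_0 t^F_i} - 1\right)$$

**Units.** $t^F$ enters the exponentials in *steps* ($t/\Delta t$), not
seconds. With the typical scales $\alpha_0 \approx 0.1$–$0.2$,
$\beta_0 = 0.02$ and windows of 50–250 steps, step units keep both
exponents in a sane range; with millisecond-scale second units the penalty
exponential would overflow and the softmax would flatten to uniform. Since
only the sentinel $T+1$ can exceed $T$, the penalty condition is
implemented as $t^F = T+1$ exactly. The FR loss is the standard
cross-entropy over softmaxed rates $\alpha_1 f_i$. Softmaxes are computed
with max-subtraction; the optional spike-count constraint
$L_s = \lambda_s |N_s - \tilde N_s|$ can be added to either mode.

## The backward pass

Three pieces make the non-differentiable chain trainable.

**From the first-spike time to output spikes.** For an *active* output
neuron the first-spike time depends only on the step $m^*$ where it
occurred, but optimizing that single spike (and its weights) alone is
unstable: neighbouring spikes should move too, with influence decaying in
distance. The time error is therefore spread over neighbouring steps through
a *negative* Gaussian window

$$\frac{\partial t^{L,m}}{\partial s^{L,n}} = g(m-n), \qquad
g(x) = -\frac{A}{\sqrt{2\pi}\,\sigma} e^{-x^2/2\sigma^2},$$

applied around $m^*$ and truncated at the 3-sigma limit
($|n - m^*| \le 3\sigma$). The sign is negative because firing *earlier*
means pushing spike variables *up* at earlier steps. For an *inactive*
neuron the time error is assigned to every step (the window sum over all
$m = 1..T$, same truncation per term): a silent target is nudged toward
firing anywhere, a silent non-target is reinforced in its silence. The
truncation for the inactive sum keeps the cost at $O(TW)$ and is our choice;
the window width itself follows $\sigma = \lfloor T/D \rfloor$,
$W = \min\{6\sigma + 1,\ T\}$.

Two boundary conventions: $\sigma \ge 1$ automatically whenever $D \le T$;
for $D > T$ the window degenerates to a single step ($W = 1$) and the
assignment uses the unit-width weight $-A/\sqrt{2\pi}$ — the delta limit
without a division by zero. $A$ defaults to $2T$; much smaller values scale
the whole pseudo-gradient down and stall training. Because $\sigma$ is tied
to $T$, the window configuration is rebuilt whenever the training window
changes — in particular after the empty-sequence extension below.

**Through the spike nonlinearity.** The step function's derivative is
replaced by the fast sigmoid surrogate
$f'(U) = (1 + \rho|U - \theta|)^{-2}$ with slope $\rho = 5$.

**Reverse-time accumulation.** Within each layer, for $n = T..1$:
$\partial L/\partial I^n = (1-\alpha)\,\partial L/\partial U^{n+1} +
\beta\,\partial L/\partial I^{n+1}$;
$\partial L/\partial s^n$ collects the upstream error plus the recurrent
term $V^\top \partial L/\partial I^{n}$;
$\partial L/\partial U^n = \partial L/\partial s^n f'(U^n) +
\alpha(1-s^n)\,\partial L/\partial U^{n+1}$. Weight gradients sum
$\partial L/\partial I^n$ against presynaptic (for $W$) or same-layer (for
$V$) spike trains; the error handed to the layer below is
$W^\top \partial L/\partial I^n$. The reset factor $(1-s^n)$ is treated as a
*constant* during differentiation — no gradient flows through the reset's
own spike. This matches common surrogate-gradient practice and is a design
decision of this package, not a property of the equations. Max-pool layers
route their error to the argmax input of each block, first index on ties.
In FR mode the output error is simply
$\partial L/\partial s^{L,n} = \partial L/\partial f_i \cdot 1/T$ at every
step — no Gaussian.

The entire backward pass is verified in the test suite against an
independent, unvectorized reverse-accumulation oracle (and the loss
gradients against central finite differences) to $10^{-6}$ relative error.

## Training strategies

* **Layer-specific parameters.** Feature-extraction layers (convolutional
  and pooling layers of a convnet; hidden layers of a fully connected net)
  use a small time constant and threshold $(\tau_1, \theta_1)$ — short
  memory, high firing rate, good local-feature transmission. Decision
  layers use $\tau_2 = \mu \tau_1$ and $\theta_2$ with $\mu \ge 1$ — long
  memory so the output neuron can integrate evidence before committing to a
  first spike. $\mu$ is the main knob trading accuracy against decision
  delay.
* **Empty-sequence extension.** In FS mode every training input is extended
  by $T_E$ all-zero bins, so output spikes delayed past the stimulus still
  fall inside the observable window instead of leaving the neuron formally
  inactive. Evaluation uses the configured test window as-is.
* **Optimizer.** Adam with L2 weight decay $10^{-4}$ folded into the
  gradient, $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$ (the
  conventional defaults; only the learning rate and decay are exposed).
  Weights are Xavier-uniform initialized; one integer seed fixes
  initialization and batch order bit-reproducibly.

## Metrics

* `accuracy_vs_window()` evaluates with the input truncated to
  $T' = 1..T$ steps. Because the simulation is causal, the truncated
  trajectory is a prefix of the full one, so a single forward pass per trial
  suffices; the readout is recomputed per prefix (it can never see past
  $T'$).
* `time_delay()` reports $t_d(p\%)$: the smallest $T'\Delta t$ at which the
  curve reaches $p\%$ of its *peak over the evaluated range* (reported in
  both steps and seconds; an all-zero curve reports the full window).
* `mean_spike_count()` ($N_s$) divides all spikes after the input layer by
  the number of neurons (pooling outputs included — they are the spikes the
  next layer actually consumes; input counts are not spikes and are
  excluded). $N_s$ is the energy proxy for neuromorphic deployment.

## The synthetic task

Real neuromorphic benchmarks need downloads and long training runs, so the
package generates labeled event streams with controllable temporal
structure, mirroring the qualitative dichotomy seen in real data:

* **repetitive** (gesture-like vision): a class-specific pixel template (a
  moving diagonal bar) repeated every `period` steps;
* **nonrepetitive** (spoken-digit-like audio): every class opens with the
  *same* onset sweep over the low channels for the first quarter of the
  trial — mimicking words that share initial phonemes — and then diverges
  into a class-specific sweep with its own start channel, direction and
  tempo (later classes traverse faster and fall silent earlier).

Event counts per active (cell, bin) are Poisson(`signal_rate`) on top of
Poisson(`noise_rate`) background, with Gaussian timing jitter — count-valued
inputs with graded difficulty rather than exact binary templates. The shared
onset is deliberate: without it, class identity is readable from the first
bin or two, the accuracy-vs-window curve saturates immediately, and delay
metrics cannot respond to $\tau_2$. Tempo differences make *timing*, not
just channel occupancy, class-discriminative — which is what makes the
FS-vs-FR comparison meaningful at this scale.

Default study conditions: 3 classes, $F = 20$ channels, $T = 50$ bins of
10 ms, 100 trials per class, `signal_rate` 2 (a busy cochlea channel emits a
few events per 10 ms), `noise_rate` 0.02, jitter 1 step, 80/20 stratified
split; network `20-FC64(R)-3`; training defaults $\tau_1 = 50$ ms,
$\theta_1 = 0.3$, $\theta_2 = 1$, $\mu = 4$, $T_E = 10$, $D = 24$,
$A = 2T$, $\alpha_0 = 0.2$, $\beta_0 = 0.02$, $\lambda_t = 0.01$,
$\alpha_1 = 20$, $\eta = 10^{-3}$, batch 16, 50 epochs. The neuron and loss
scales follow the published audio settings with thresholds rescaled to the
20-channel input (a 700-channel net sees ~35× the drive), and $D = 24$
keeps the window-to-length ratio in the small-window regime that
non-repetitive data favors ($\sigma = 2$, $W = 13$ at the extended
$T = 60$). Under these conditions both codings reach ≥ 90 % held-out
accuracy within 50 epochs, FS-trained non-target output neurons emit fewer
test-set spikes than FR-trained ones in most seeds, and $t_d(50\%)$ grows
monotonically with $\mu \in \{1, 4, 12\}$ — the package's test suite checks
exactly these properties at exactly these sizes.

What the generator does *not* emulate: realistic DVS noise (hot pixels,
refractory effects), cochlea filter-bank dynamics, inter-trial speaker or
speed variability beyond Poisson/jitter noise, and class structure that is
not a channel sweep. Passing tests therefore demonstrate that the training
machinery optimizes what it claims to optimize on data with controlled
temporal structure — not benchmark-level performance on real recordings.

## Worked example

```{r example, eval = FALSE}
ds <- generate_events(synth_spec(seed = 0))
sp <- train_test_split(ds, 0.8, seed = 1)
btr <- bin_dataset(sp$train)
bte <- bin_dataset(sp$test)

cfg <- train_config(loss_mode = "fs", seed = 1)
net <- build_network("20-FC64(R)-3", dt = 0.01, cfg)
fit <- train(net, btr$x, btr$labels, cfg)

evaluate(fit, bte$x, bte$labels)
curve <- accuracy_vs_window(fit, bte$x, bte$labels)
time_delay(curve, 50, dt = 0.01)
```

(Executed output for this exact script is shown in the README; the chunk is
not evaluated here to keep vignette builds fast.)

## Numerical and design notes

* **Time indexing.** Equations are 1-based ($n = 1..T$); internal arrays are
  0-based in the state (step $k$ column holds $n = k$); exported rasters use
  the 1-based convention.
* **Recurrent self-connections** are allowed (the diagonal of $V$ is not
  masked); the current equation does not exclude them.
* **Pooling dynamics.** Pooling layers accept $(\tau_1, \theta_1)$ in their
  constructor for interface parity, but have no state equations of their own; we
  implement them stateless (OR over the block). This is an explicit
  interpretation choice where the published description assigns them
  parameters without dynamics.
* **Window-arithmetic caveat.** The published width table reports $W = 120$
  at $D = 4$ for both of its columns, which is inconsistent with
  $W = \min\{6\lfloor T/D\rfloor + 1, T\}$ for the $T$ values implied by the
  other rows; this package implements the printed formula verbatim, and the
  self-consistent rows are the ones checked in the tests.
* **Serialization.** Spike tensors and weight checkpoints use R's native
  serialization (single-file containers, bit-exact round-trips); event data
  use plain CSV with 17-significant-digit times, so the CSV round-trip is
  also bit-exact.
* **Divergence.** Training aborts with a diagnostic on a non-finite loss
  rather than continuing silently.

## Limitations

Adaptive (AdLIF) neurons, trainable time constants, batch
normalization/dropout, native AEDAT/DAT sensor formats and GPU execution are
out of scope. The simulator is vectorized over batch and neurons but is
plain R: it is sized for method study (hundreds of trials, tens of
channels, $T \lesssim 250$), not for benchmark-scale training.
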