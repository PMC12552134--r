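---
title: "Methods: activation-function inductive biases in trained recurrent networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activation-function inductive biases in trained recurrent networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(actbias)
```

# The scientific question

Recurrent rate networks trained on cognitive tasks are a standard modelling
tool in systems neuroscience. A unit's activation function — rectified
linear (ReLU), logistic sigmoid, or hyperbolic tangent — is usually treated
as an interchangeable implementation detail. This package implements a
pipeline for testing that assumption: train many networks per architecture
on the same tasks, compare the geometry of their solutions (population
trajectories, single-unit selectivity, fixed-point and trajectory-endpoint
configurations), distill each network into a small interpretable circuit,
and probe behaviour on out-of-distribution stimuli. The headline phenomenon
the pipeline exposes is that tanh networks solve context-dependent decision
making (CDDM) with a different circuit mechanism than ReLU and sigmoid
networks — saturation-based gating of the irrelevant stimulus rather than
inhibition-based suppression — and that only the inhibition-based mechanism
breaks down when irrelevant stimuli exceed the training range.

# Model and training

Networks follow the continuous-time rate equation
$$\tau\,\dot{y} = -y + f(W_{rec}\,y + W_{inp}\,u),$$
discretized by the first-order Euler scheme with $dt = 1$ ms and process
noise injected each step:
$$y_{t+1} = (1-\gamma)\,y_t + \gamma\, f\!\Big(W_{rec}y_t +
W_{inp}\big(u_t + \sqrt{2\gamma\sigma_{inp}^2}\,\zeta_t\big) +
\sqrt{2\gamma\sigma_{rec}^2}\,\xi_t\Big), \qquad \gamma = dt/\tau.$$
The sigmoid uses slope 7.5, $f(x) = 1/(1+e^{-7.5x})$. Six architectures are
crossed from three activations and Dale's law on/off; under Dale's law
every recurrent column keeps the sign of its (excitatory or inhibitory)
unit, with excitatory:inhibitory ratio 4:1 for ReLU/sigmoid and 1:1 for
tanh. Initialization: recurrent weights $N(1/\sqrt{N}, 1/N^2)$ (absolute
values with the appropriate sign under Dale's law, inhibitory mean scaled
by the E/I ratio), rescaled to spectral radius 1.2; input and output
weights are non-negative and stay so throughout training.

The loss is the masked squared output error plus an activity penalty
$\lambda_r\langle\|y\|^2\rangle$ and an input-column orthogonality penalty
$\lambda_\perp$. We read every $\langle\|\cdot\|^2\rangle$ as a plain mean
over all elements of the tensor involved, the convention of a standard
mean-squared-error loss implementation. The distinction matters: summing
norms over units instead multiplies the activity penalty by $N$ relative to
the output term, which at our scale prevents tanh networks from reaching
the saturation-based solution at all (their masked error plateaus at about
four times the level reached under the per-element convention) and erases
the out-of-distribution dissociation. All empirical statements below are
therefore made under the per-element convention.

Optimization is full-batch Adam (learning rate $10^{-3}$, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-8}$) over the complete condition set
each iteration. After every update, negative input/output entries are
zeroed and, under Dale's law, recurrent entries that switched sign are
zeroed. One numerical choice is ours: gradients are clipped to a global
norm of 1 (`clip_norm` in `train_rnn()`). Backpropagation through 300
steps of the initially expansive ReLU dynamics (spectral radius 1.2 with
no saturation) produces exploding gradients; without clipping,
unconstrained ReLU networks essentially never stabilize, while clipping
leaves well-conditioned gradients untouched. $\lambda_r = 0.5$ for CDDM
and Go/NoGo (5000 iterations at full scale); the memory task trains in two
phases, $\lambda_r = 0$ then $0.3$ (6000 + 6000). Parameters the source
study leaves unstated are package defaults, chosen once: $\tau = 10$ ms
($\gamma = 0.1$), $\sigma_{inp} = \sigma_{rec} = 0.01$,
$\lambda_\perp = 0.1$, initial state $y_0 = 0$, output read out as
$\hat{o} = W_{out}\,y$.

# Tasks (the synthetic-data stage)

All data are generated internally; the generators are first-class, tested
code.

* **CDDM.** Six input channels: two mutually exclusive context cues (on at
  amplitude 1 for the whole 300 ms trial) and right/left evidence channels
  for two modalities. A signed coherence $c \in [-1,1]$ maps to channel
  amplitudes $((1+c)/2, (1-c)/2)$; the training grid is the 15-value set
  $\{0, \pm.01, \pm.03, \pm.06, \pm.13, \pm.25, \pm.5, \pm1\}$, giving
  $2 \times 15 \times 15 = 450$ conditions. Sensory channels switch on at
  100 ms. Targets: the right (left) output steps to 1 from 200 ms onwards
  when the cued modality's coherence is positive (negative); both stay 0
  at zero coherence. The mask covers $[0,100) \cup [200,300)$ ms, leaving
  an unpenalized integration period.
* **Go/NoGo.** Value channel constant over the 60 ms trial, sustained Go
  cue from 30 ms, constant bias 1. Target: 0 before the cue, then
  $\Theta(\mathcal{I} - 0.5)$ (0.5 at exactly 0.5). We encode the cue as
  sustained rather than a single 1-ms pulse — a one-step pulse at
  $\gamma = 0.1$ injects almost no signal — and mask out a 5-step grace
  window after cue onset, paralleling the CDDM grace period.
* **Memory number.** The value appears for only 10 ms at an onset drawn
  uniformly from [0, 20] ms; Go cue at 70 ms; trial length set to 100 ms
  (unstated in the source; the response window is then [70, 100) ms).
  Target: 0 before the cue, the presented value afterwards.
* **3-bit flip-flop.** Three input channels carry transient $\pm 1$
  pulses; each output must hold the sign of the last pulse on its channel.
  Used by the hand-crafted construction below, not for the main training
  study.

What the generators do *not* emulate: reaction times, trial-to-trial
adaptation, or continuous coherence sampling. A passing test suite
therefore speaks to the model study itself, not to fits of behavioural or
neural recordings.

# Analysis stages

**Representation summaries.** From a noiseless pass over all conditions we
form the $(N, T\times K)$ response matrix and reduce it four ways:
population trajectories (PCA across population-state samples to 10
components), single-unit selectivity (PCA across the time-by-trial axis to
10 components, one point per unit), trajectory endpoints (last step of
each trial, 10 components), and fixed-point configurations (7 components).
PCA centers across samples; every summary is then divided by the square
root of its total variance, giving unit total variance so summaries from
different networks share scale (the source text's "normalized by its
variance" is ambiguous between variance and its square root; unit total
variance is the reading that makes scales comparable).

**Distances.** Trajectory and endpoint summaries are compared by
regressing each summary onto the other with least squares (no intercept —
the data are centered), averaging the two residual mean squared errors;
this is symmetric by construction and zero under any invertible linear
map. Selectivity and fixed-point summaries are point clouds without unit
correspondence, compared by iterative closest point (ICP): random
orthogonal initialization, nearest-neighbour matching (one-to-many
allowed; restricted to equal (input, stability) tags in fixed-point mode),
orthogonal-Procrustes update, iterated to relative convergence $10^{-6}$
(cap 100 iterations), best of 60 restarts, both directions averaged. A tag
present in only one cloud is excluded from matching with a warning — the
source does not address this case. Distances feed a metric MDS
implemented as SMACOF majorization (classical-scaling start plus 8 random
restarts, 500 iterations, stress-1 reported); no installed package
provides metric-stress MDS, so the Guttman iteration is written out here.

**Fixed points.** For each constant input (50 CDDM combinations: 2
contexts × 5 relevant × 5 irrelevant coherences, default subset
$\{-1,-0.25,0,0.25,1\}$ — the exact 5-value subsets are not printed in the
source, ours is declared; for the cued tasks, every training value with
cue off/on) we run a damped Newton search with the analytic Jacobian
$J = -I + \mathrm{diag}(f'(a))\,W_{rec}$ from random trajectory points in
the second half of random trials plus $N(0, 0.01)$ (variance) coordinate
noise, accept $\|F\|^2 \le 10^{-12}$, discard duplicates within $10^{-7}$,
and stop after 100 accepted points or 100 consecutive misses. Stability:
principal eigenvalue of $J$ (largest real part, ties by larger imaginary
magnitude), stable iff $\Re(\lambda_0) \le 0$ (marginal cases count as
stable per the printed rule).

**Latent circuits.** Responses are reduced to $N_{PC} = 30$ components
over the unit axis using the uncentered second-moment basis: both the
source network and the latent circuit start at the zero state, so the
embedding $Qx$ must match projections taken from the same origin (the
geometry module keeps centered PCA). An 8-node circuit with the same
activation and $\gamma$, non-negative input/output weights, and each input
channel wired to exactly one latent node (channels 1-6 to nodes 1-6;
nodes 7-8 are unwired choice nodes) is fitted by Adam on the masked output
error plus $\lambda_{emb}\langle\|Qx - z\|^2\rangle$ plus
$\lambda_w$-weighted mean squared weights, with $Q$ re-orthonormalized by
QR retraction after every step and sign constraints re-imposed. The
optimizer applies $\lambda_{emb}$ *relative to the signal power of* $z$
(dividing by $\mathrm{mean}(z^2)$): activity amplitudes differ by an
order of magnitude across activations (tanh+Dale networks run at
$\mathrm{mean}(z^2) \approx 0.016$), and with an absolute weight the
embedding gradient is negligible for low-amplitude networks and the fit
collapses onto the output term. Defaults $\lambda_{emb} = 1$,
$\lambda_w = 0.01$, 30 restarts at full scale; fit quality is reported as
$R^2$ with a grand-mean baseline over all tensor entries, for the
dynamics ($Qx$ vs $z$) and the behaviour ($w_{out}x$ vs the masked
targets). The output term uses the training mask (the target is undefined
during the grace period).

**Behaviour.** Task performance is the masked mean squared error of a
noiseless pass (used to rank networks; "top-performing" is ours to
define). Psychometric maps simulate noisy trials per coherence cell and
take the choice as the sign of the (right − left) output averaged over
the final 100 ms; sensitivity to the irrelevant stimulus is the linear
least-squares slope of the right-choice fraction on the irrelevant
coherence with the relevant coherence as covariate (a logistic fit adds
nothing at the grid sizes used and the linear fit is deterministic). The
out-of-distribution grid extends coherences to $\pm 2$. Output-subspace
alignment uses $\rho = \|W_{out}X\|_F / (\|W_{out}\|_F\|X\|_F)$ over the
decision epoch ([200, 300) ms for CDDM, post-cue otherwise). The
hand-crafted flip-flop is three self-exciting tanh units ($w_{self} = 2$,
pulse gain 2, identity readout): each unit is bistable at the roots of
$y = \tanh(2y)$ ($\approx \pm 0.9575$), and pulses of width ~20 ms move it
between basins; the identical ReLU construction has no negative state to
hold (and its positive state is not even bounded), so it fails.

# Problem sizes and reproducibility

Every stochastic stage takes an explicit seed; child seeds derive from a
master seed through a fixed splitting rule, so reruns are bit-identical.
The full study conditions (100-unit networks, 100 networks per
architecture, printed iteration counts, 60 ICP restarts, 30 latent
restarts) are available through the `"paper"` profile of
`experiment_config()`. The test suite and the worked examples run a
desk-scale profile chosen once for a single-CPU workstation: 30-unit
networks, three per architecture and three master seeds on the
$\{-1,0,1\}$ coherence grid (800 iterations) for the embedding analyses;
30-unit networks on the $\{-1,\pm0.25,0,1\}$ grid (2000 iterations) for
latent circuits and psychometrics; one 50-unit network (600 iterations)
for the variance-capture checks; 10 latent restarts. At this scale the
qualitative results reproduce — trained networks concentrate >93% (10
components) and >99% (30 components) of response variance, tanh networks
separate from ReLU/sigmoid in all four MDS embeddings, the best latent
fits land near the reference accuracy cells, and the out-of-distribution
dissociation has the expected direction — but individual numbers carry
more run-to-run spread than the full-scale study.

Two desk-scale caveats deserve explicit mention. Sensitivity to irrelevant
out-of-distribution stimuli is probed with the relevant axis inside the
training range and only the irrelevant axis amplified (the full
$\pm2 \times \pm2$ map remains available for visualization); at this scale
the ReLU-vs-tanh dissociation has the expected direction, but sigmoid
networks gate amplified irrelevant stimuli about as well as tanh networks,
so the sigmoid half of the full-scale claim should not be expected from
the reduced profile. Unconstrained (no-Dale) tanh networks also train
poorly at 30 units and are not used for the focused latent/behavioural
analyses.

# Known limitations

* The exact training hyperparameters the source leaves to supplementary
  tables ($\tau$, noise levels, $\lambda_\perp$, latent-fit penalties and
  iteration counts) are package defaults, not recovered values.
* Gradient clipping and the relative embedding weight are this package's
  numerical choices; both are documented above and configurable.
* The fixed-point finder, like any multi-start Newton method, can miss
  saddle points whose basins of attraction under the solver are small;
  counts per input are therefore lower bounds.
* No topological (graph-based) fixed-point analysis, no CKA-style
  similarity alternatives, no nonmetric MDS, and no reaction-time or
  psychophysics modelling.
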