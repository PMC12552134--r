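# actbias

Tools for studying how single-unit activation functions (ReLU, logistic
sigmoid with slope 7.5, tanh) and Dale's-law connectivity constraints bias
the circuit solutions that continuous-time recurrent neural networks
discover when trained on cognitive tasks. The package is aimed at
computational neuroscientists who train rate RNNs as models of cortical
computation and want to know whether their architectural choices are
innocuous.

The pipeline: generate task trial batches (context-dependent decision
making, Go/NoGo, memory number, 3-bit flip-flop), train networks of six
architectures ({ReLU, sigmoid, tanh} × {Dale, no Dale}) with Adam under
sign constraints, find and classify the fixed points of the trained
dynamics, compare networks through four geometric summaries (population
trajectories, single-unit selectivity, fixed-point and trajectory-endpoint
configurations) using regression and iterative-closest-point distances
embedded with metric MDS, distill each network into an 8-node latent
circuit, and probe out-of-distribution generalization with psychometric
maps.

## The model

Networks obey the rate equation, integrated by forward Euler
(dt = 1 ms, gamma = dt/tau) with process noise:

    tau dy/dt = -y + f(W_rec y + W_inp u)

trained by minimizing

    Loss = <|| o[mask] - W_out y[mask] ||^2> + lambda_r <||y||^2>
           + lambda_perp <|| W_inp' W_inp - diag(W_inp' W_inp) ||^2>

with non-negative `W_inp`/`W_out` and, under Dale's law, a fixed sign per
recurrent column (violations are zeroed after every optimizer step).
Recurrent weights initialize from N(1/sqrt(N), 1/N^2), rescaled to
spectral radius 1.2.

## Worked example

Train a small CDDM network, inspect its fixed points and distill it:

```r
library(actbias)

batch <- build_cddm_batch(enumerate_cddm_conditions(c(-1, -0.25, 0, 0.25, 1)))
net0  <- initialize_rnn("tanh", dale = TRUE, N = 30, n_in = 6, n_out = 2, seed = 11)
net   <- train_rnn(net0, batch, lambda_r = 0.5, n_iter = 2000, seed = 301)$params

task_performance(net, batch)
#> [1] 0.02198082      # masked mean squared error after training

resp <- simulate_batch(net, batch)
reduce_trajectories(resp)$variance_captured
#> [1] 0.9995179       # 10 PCs capture nearly all trajectory variance

fps <- fixed_point_survey(net, "cddm", resp$activity, seed = 3,
                          max_points = 20, patience = 20)
table(fps$tags$stability)
#>   stable unstable
#>       34       20  # attractors flanked by saddles across the 50 inputs

red <- reduce_for_fit(resp, n_pc = 30)
fit <- fit_latent_circuit(red, batch, "tanh", n_restarts = 4,
                          n_iter = 1000, lr = 0.03, seed = 17)
fit
#> <latent_fit> 8 nodes (tanh), loss 0.1492, R2 dynamics 0.885, R2 behaviour 0.783
```

The masked error near 0.02 means the network produces the required 0/1
decision outputs on cued-modality trials; the latent fit says an 8-node
circuit embedded linearly into the 30-dimensional response space largely
reproduces the network's dynamics (more restarts and iterations, as used
in the full study profile, push both scores higher).

Out-of-distribution probe (the headline dissociation): with irrelevant
stimuli at twice the training amplitude, ReLU networks' decision
boundaries rotate while tanh networks keep ignoring the irrelevant
modality:

```r
m <- psychometric_map(net, "motion", seq(-1, 1, length.out = 9),
                      seq(-2, 2, length.out = 11), n_reps = 16, seed = 5)
irrelevant_sensitivity(m)
#> [1] 0.05839646      # small for tanh; larger for relu under the same probe
```

A full study (training, controls with shuffled connectivity, all four MDS
embeddings, latent circuits, alignment tables) runs through
`run_study(experiment_config(task = "cddm", profile = "scaled_down"))`;
the `"paper"` profile holds the full-scale conditions. A thin CLI wrapper
lives at `inst/cli/actbias.R`.

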