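# relinf — collective relational inference for heterogeneous interacting systems

Interacting systems — particles coupled by springs or charges, crystallizing
mixtures, coupled time series — are usually observed only through the states
of their entities over time. Which pairs interact through which kind of
interaction, and what law governs each kind, is hidden. `relinf` infers both
at once: a latent categorical type for every directed edge of the
interaction graph and a learned interaction function (a small neural
network) per type.

The package is aimed at researchers studying interacting particle systems
and network/causality structure learning who want a self-contained,
CPU-scale implementation with fully simulated benchmarks and honest
evaluation metrics.

## The method in brief

A node's observed state increment (its acceleration, for particles) is the
*sum* of all incoming interactions, so single edges are never identified in
isolation. `relinf` therefore treats each node's incoming-edge subgraph as
one collective latent variable over all `K^|Γ(i)|` joint type assignments
and computes its exact posterior by enumeration. With the physics-consistent
decoder the predicted increment under a realization `z` is

    x̂¨_i = (1/m_i) Σ_{j∈Γ(i)} NN^{φ_z(j)}(x_i, x_j),

the observed increment is Gaussian around it (`σ² I`), and the model —
per-type networks `NN^1…NN^K` plus a prior over realizations — is fit by
generalized EM: exact posteriors in the E step, the analytic prior average
plus one Adam gradient step on the networks in the M step. Decoded types are
the argmax realization per subgraph mapped through `φ`.

For systems whose interaction graph changes over time (nearest-neighbour
interactions), each directed pair instead carries a per-edge categorical
posterior updated sequentially at every time step, with the other active
edges of the receiver marginalized out under their current posteriors.

Evaluation is by permutation-invariant type accuracy (labels are only
identified up to relabeling), rollout state error, pairwise-force error
against the true law, and the mean violation of Newton's third law by the
learned forces. See `vignettes/collective-inference.Rmd` for the complete
account.

## Worked example

Five particles, every pair connected by one of two spring types
(`k, L = 0.5, 2.0` or `2.0, 1.0`), 100 simulations of 100 steps — then
infer every edge's type and both force laws from the trajectories alone:

```r
library(relinf)

train <- simulate_springs(100, seed = 7001)
cfg <- cri_config(epochs = 150, lr = 1e-2, lr_decay = 12000,
                  hidden = c(32, 32), sigma2 = 0.01, n_init = 2, seed = 1)
fit <- fit_cri(train, K = 2, cfg)

truth <- unlist(lapply(train, function(s) s$graph$true_types))
permutation_accuracy(unlist(fit$types), truth, K = 2)$accuracy
#> [1] 0.98
```

so 98% of the 2,000 directed edges are assigned the correct spring type
(after matching the arbitrary label order). The same fitted networks
transfer to larger systems without retraining — inference on freshly
simulated ten-particle systems runs the E step with the trained networks,
now over the 512 joint realizations of each degree-9 subgraph:

```r
test10 <- simulate_springs(30, n_nodes = 10, seed = 7050)
post <- compute_posteriors(test10, fit$bank, uniform_prior(2, 9), cfg$sigma2)
types10 <- decode_edge_types(post, test10)
truth10 <- unlist(lapply(test10, function(s) s$graph$true_types))
permutation_accuracy(unlist(types10), truth10, K = 2)$accuracy
#> [1] 0.8919
```

89% of the 1,350 edges of the unseen, twice-as-large systems are typed
correctly at this desk scale; cross-size transfer improves steadily with
the training scale (about 93% with 300 training simulations) and is the
headline strength of the collective approach at full scale. Learned forces
can be read out per edge (`pairwise_force_eval`) and scored against the
generating law (`mae_ef`, `mae_symm`).

An occasional seed fails to break the type symmetry (a known EM failure
mode); `n_init = 2` screens initializations by marginal likelihood, and
experiments report five independent seeds (`run_experiment`).

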