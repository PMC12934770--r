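# cbgtclaw

Reward learning does not just change *which* action a decision circuit
favors — it reshapes *how* each decision unfolds in time.  `cbgtclaw`
studies this in the cortico-basal ganglia-thalamic (CBGT) circuit: a
reduced stochastic firing-rate model of the two-channel CBGT loop learns a
two-choice task through dopamine-modulated corticostriatal plasticity, and
a chain of analyses traces how learning moves decisions from deliberation
to commitment.  The package is aimed at computational neuroscientists
modelling basal ganglia decision dynamics and at analysts who want to run
the same discrete-state machinery on their own firing-rate tables.

Four analysis layers are provided on top of the simulator:

* **CLAW** (Circuit Logic Assessed via Walks): per-trial firing rates of
  the N = 10 state-defining populations ({dSPN, iSPN, GPi, GPeP, Th} for
  both channels) are averaged in Δt = 10 ms bins, binarized at
  histogram-antimode thresholds, and encoded as base-2 network states
  `s_k ∈ {0,1}^N`.  The empirical state-transition chain is pruned to its
  high-probability subgraph, states are partitioned into six functional
  zones (I launching, II deliberation, III/IV left/right commitment,
  V deep deliberation, VI reversal), and every trial is classified as
  deliberative (A), deliberative→committed (B), committed (C) or
  committed→reversal (D).
* **Control ensembles**: canonical correlation analysis between
  per-network activity summaries (channel sums L+R and differences L−R of
  the eight channelized cell types, plus CxI and FSI; 18 elements) and the
  four static drift-diffusion parameters (a, v, tr, z) yields the choice,
  responsiveness and pliancy components; within-trial activity changes
  ΔF_k are projected as `W_k = ΔF_kᵀU` and `P_k = W_k Vᵀ`.
* **Drift-diffusion modelling**: an analytic Wiener first-passage-time
  likelihood (symmetric bounds ±a, start a(−1+2z), σ = 1) for static
  maximum-likelihood fits, and a zone-constrained piecewise DDM in which
  (vᵢ, aᵢ) switch at stochastic zone transitions under the time-weighted
  constraint `Σ (tᵢ/DT) aᵢ = a_static`, with boundary collapse counting
  as a decision.
* **Learning statistics**: linear mixed-effects models (random intercept
  per network, BIC selection between linear and quadratic time trends,
  Bonferroni threshold 0.05/4 = 0.0125) test when learning reshapes the
  engagement time courses.

## Worked example

Simulate one network through a 20 pre / 30 training / 20 post session
(training rewards the left choice deterministically):

```r
library(cbgtclaw)
cfg <- default_config()
ses <- run_session(cfg, session_plan(n_pre = 20, n_train = 30,
                                     n_post = 20, seed = 42))
b <- session_behavior(ses)
aggregate(cbind(p_left = choice == "L", dt = decision_time_ms) ~ block,
          b, mean)
#>   block    p_left       dt
#> 1  post 0.8000000  82.7000
#> 2   pre 0.5000000 153.3500
#> 3 train 0.7333333 105.4667
```

Before training the network picks left at chance with slow decisions;
after 30 rewarded trials it chooses left 80% of the time (90% when pooled
over many networks) and decides ~70 ms faster.  The discrete-state view of
the same dynamics:

```r
trials <- lapply(1:200, function(i) simulate_trial(cfg, seed = i))
ca <- claw_analysis(trials)
ca
#> CLAW analysis: 200 trials, 143 visited states, baseline 198
#>
#>            A            B            C            D unclassified
#>          140            1           12            4           43
round(ca$zone_tm, 2)
#>          I   II   IV    V other
#> I     0.79 0.03 0.00 0.00  0.18
#> II    0.01 0.96 0.00 0.01  0.03
#> IV    0.00 0.00 0.64 0.23  0.13
#> V     0.00 0.25 0.00 0.72  0.04
#> other 0.04 0.12 0.03 0.13  0.69
```

Most pre-learning trials are deliberative (class A), a minority commit
directly (C), and a few reverse an initial commitment (D); the zone table
shows the launching state feeding deliberation loops with occasional
committed excursions.  Downstream, `fit_cca()` links these dynamics to
drift-diffusion policies, `solve_phase_params()` +
`simulate_dynamic()` fit the piecewise model, and
`fit_learning_model()` tests learning effects; `pipeline_run()` chains
all five stages and writes CSV/JSON artifacts with a reproducibility
manifest.

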