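---
title: "Decision dynamics in a plastic CBGT circuit: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision dynamics in a plastic CBGT circuit: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: what the reduced
circuit model is and what it is calibrated to reproduce, how each analysis
layer works, which choices were genuinely open and how we resolved them,
and what the results do and do not show about real basal ganglia data.

## The reduced CBGT network

The simulator (`simulate_trial()`, `run_session()`) is a stochastic
firing-rate network over 18 population streams: eight channelized cell
types — cortex (Cx), direct- and indirect-pathway spiny projection neurons
(dSPN, iSPN), prototypic and arkypallidal external pallidum (GPeP, GPeA),
subthalamic nucleus (STN), internal pallidum (GPi) and thalamus (Th) —
each with a left and a right action-channel copy, plus cortical
interneurons (CxI) and striatal fast-spiking interneurons (FSI) shared
across channels.  Each stream obeys

$$\tau_p\,\dot r_p = -r_p + \phi\Big(\sum_q w_{q\to p}\,r_q + I_p +
  \xi_p\Big),$$

with rectifier $\phi(x) = \max(0, x)$, Ornstein–Uhlenbeck noise $\xi_p$
(stationary SD per stream, correlation time 20 ms), and Euler–Maruyama
integration at 1 ms.  Edge signs follow the canonical pathway diagram:
corticostriatal, corticothalamic, thalamocortical and STN projections are
excitatory; striatal, pallidal and interneuron projections inhibitory.
Baseline inputs $I_p$ are solved so that the configured baseline rates
(e.g. GPi 60 Hz, Th 16 Hz, SPNs 4 Hz) are the noise-free pre-stimulus
equilibrium — also after learning, so plasticity expresses itself only in
the stimulus-driven transient.  A trial applies an equal constant stimulus
to both cortical populations from cue onset; an action is selected when
one thalamic rate first reaches 30 Hz.  The post-decision consolidation
interval is drawn from a normal distribution with mean 250 ms and SD
1.5 ms — we read the dispersion parameter as an SD; reading it as a
variance would change the SD from 1.5 to 1.2 ms and nothing else
downstream.

Two structural choices matter for the dynamics:

* **Winner-take-all amplification.**  The within-channel loop
  dSPN → GPi → Th → Cx → dSPN, combined with the shared CxI feedback,
  amplifies small channel asymmetries.  Without it the two channels ramp
  in lockstep and the binarized states never show channel dominance; the
  calibrated loop gain (Th→Cx 0.6) produces distinct committed states
  while keeping the baseline stable.
* **Rate-limited commitment.**  The stimulus amplitude (11.25 Hz) puts
  the symmetric ramp just below threshold, so the crossing time is set by
  noise-seeded symmetry breaking — this is what spreads decision times
  over ~60–400 ms and produces both fast committed and slow deliberative
  trials.

### Plasticity

Learning is a trial-level abstraction of dopamine-modulated
spike-timing-dependent plasticity.  After each rewarded trial the reward
prediction error $\delta = r - V$ updates a shared value estimate
($V \leftarrow V + \alpha_V\,\delta$, $\alpha_V = 0.25$, $V_0 = 0$) and
the four plastic corticostriatal weights:
$\Delta w_{\mathrm{dSPN},c} = +\eta\,\delta\,e_c$ and
$\Delta w_{\mathrm{iSPN},c} = -\eta\,\delta\,e_c$ per channel $c$, clipped
to [0.2, 2.5], with $\eta = 0.024$.  The eligibility $e_c$ mixes the
baseline-subtracted trial-mean dSPN activity of each channel with a choice
indicator (weight 0.7).  The indicator term reflects that partial cortical
input to the *selected* channel is sustained through consolidation, so the
chosen channel's corticostriatal synapses remain coactive with the phasic
dopamine signal; with a purely activity-based trace the near-symmetric
pre-decision activity lets rewarded trials potentiate both channels and
the learned choice bias saturates far below the calibration target.

### Calibration contract and what the generator does not emulate

The shipped `default_config()` is calibrated, at the protocol of 20
jittered instances × (50 pre / 30 training / 50 post) trials, to: chance
pre-learning choice (≈50%), ≈90% post-learning left choice, pre-learning
mean decision time ≈130 ms, post-learning ≈95 ms, and the presence of all
four trajectory classes before learning.  The post-block accuracy and
speed anchors trade off through $\eta$: at any learning rate that holds
accuracy near 90%, the post mean decision time settles at 91–96 ms, a few
ms below the nominal 100 ms anchor but inside the ±15 ms band.  Network
instances are drawn by jittering every type-level weight ±3% uniformly
(`sample_network()`), which preserves exact left/right symmetry before
learning.

The generator is a rate model: it has no spiking statistics, no
conductance or bursting dynamics, no hyperdirect pathway timing, and no
tonic dopamine.  Passing tests therefore show that the *analysis chain*
behaves correctly on data with the study's structure (channel symmetry,
threshold decisions, learning-induced bias and speed-up), not that the
reduced network reproduces biophysical CBGT activity.

## CLAW: discrete states, zones, trajectories

`claw_analysis()` runs the full chain.  Numerical choices:

* **Binning and thresholds.**  Rates are averaged in Δt = 10 ms bins
  (trailing partial bins dropped; trials are recorded ~10 ms past
  threshold so the decision bin is complete).  Per-stream thresholds are
  the minimum-density antimode between the two largest modes of the
  Freedman–Diaconis histogram of all pooled binned rates; the histogram is
  smoothed with a running mean (width = bins/15) before mode-finding,
  otherwise sampling noise inside the baseline mode creates spurious
  antimodes.  Unimodal histograms fall back to median + 2·MAD; constant
  streams are flagged degenerate.
* **States.**  The 10 state bits are ordered dSPN-L, iSPN-L, GPi-L,
  GPeP-L, Th-L, then the right-channel counterparts, most significant
  first; indices are 0-based in [0, 1023].  The specific integers are an
  artifact of this (configurable) order, so tests and fixtures key states
  by bit patterns, never by integers.
* **Graph and zones.**  The transition chain keeps states visited ≥20
  times and edges with probability ≥0.01 (the source literature gives no
  values; these keep the graph readable at desk scale).  Zones are
  assigned by rule: I is the modal pre-stimulus state; III/IV require that
  channel's dSPN and Th bits on, its GPi bit off, and the opposite dSPN
  off; VI captures dominance flips after commitment; V is a strongly
  connected deliberation cycle (≥3 states) not entered directly from the
  baseline; remaining non-baseline states with bilateral iSPN engagement
  or no channel dominance are II, anything else "other".  A user-supplied
  state→zone map overrides the classifier.
* **Trial paths.**  A trial's launching point is its modal pre-stimulus
  state; a state within Hamming distance 1 of the baseline still counts
  as launching (single-bit noise flips are common at 10 ms resolution).
  Commitment is history-dependent: once a path has committed to one
  channel, a later committed pattern of the opposite channel — or a final
  choice opposite to the first commitment — is a reversal (zone VI).
  The global state→zone map cannot carry this history, and at Δt = 10 ms
  the flipped committed pattern often fails to fill a whole bin, so
  without the path-level rule the reversal class all but disappears
  (≈1/800 trials) even though ~8% of trials behaviorally reverse.
* **Statistics.**  Per-state/zone decision-time divergence between left-
  and right-choice visitors uses a shared 20-cell histogram grid,
  additive smoothing 1e-9, natural log.  Zone-table comparisons flag
  relative changes above 10%, reporting transitions appearing from zero
  probability as "new" rather than dividing by zero.

## Control ensembles

`fit_cca()` standardizes both blocks, solves the canonical system via the
regularized SVD of $\Sigma_{xx}^{-1/2}\Sigma_{xy}\Sigma_{yy}^{-1/2}$
(ridge 1e-8 on rank deficiency, with a warning), and reports **structure
correlations** — the correlation of each variable with its canonical
variate — rather than raw weights, which matches how loadings tables are
usually read and is stable when activity elements are collinear.  The
per-network activity vector is the trial-and-time mean of the 18-element
summary over the decision period (cue to decision); the summary window was
not prescribed, and the decision period is the span the ensembles are
meant to explain.  Components are labelled by signature: choice is
dominated by channel differences and drift rate (sign fixed so it
correlates positively with leftward drift); the remaining two are signed
so engagement speeds onset, and then responsiveness is the one whose
engagement lowers the boundary, pliancy the one that raises it.  A
`labels` argument overrides the automation.  Engagement time courses are
reported as percent of the cross-network SD of the corresponding variate:
since $W_0 \equiv 0$ at cue onset rules out self-relative percentages,
a cross-network scale is the natural denominator.  Averaging across
trials aligns to cue onset (first 50 ms) and to decision (final 30 ms);
the variable-length middle of the trial is omitted.

With ~20–30 desk-scale networks rather than hundreds, canonical
correlations are optimistically biased (a warning is raised below 30
networks), and component labels should be checked against the loadings
before interpretation.

## Static and piecewise drift-diffusion models

The static model uses symmetric bounds ±a, start $a(-1+2z)$, diffusion
σ = 1 and onset time tr.  The first-passage density is computed by the
small-time/large-time series with adaptive term counts (absolute error
≤1e-8); `fit_static()` maximizes the joint choice/RT likelihood by
L-BFGS-B from five fixed-seed starts within a ∈ (0.1, 5), v ∈ (−8, 8),
tr ∈ (0, min RT), z ∈ (0.05, 0.95), flagging fits that end on a box
bound.  Densities are floored at 1e-300 inside the optimizer so box
searches never see non-finite objectives.

The piecewise model (`solve_phase_params()`, `simulate_dynamic()`)
converts zone-to-zone activity changes, projected through the canonical
loadings and expressed as percent of the static fit, into per-phase
$(v_i, a_i)$ under the exact time-weighted constraint
$\sum_i (t_i/DT)\,a_i = a_{\mathrm{static}}$ (identically for $v$).
Simulation choices:

* Phase-transition times are drawn per path by sampling a zone index for
  each 10 ms slot of the mean decision period from the categorical
  distribution weighted by relative dwell times; the implied slot counts
  give that path's transition times.
* A path that crosses its boundary before a *parameter-changing*
  transition is discarded — such a crossing contradicts the zone sequence
  the parameters were inferred from.  A transition that changes nothing
  cannot be contradicted, so with all percent changes zero the simulator
  reduces exactly to the static single-phase process (this reduction is
  tested by a Kolmogorov–Smirnov comparison).
* At a transition, a path sitting between the old and the new (smaller)
  boundary registers an immediate boundary-collapse decision at the sign
  of the evidence.

Model comparison evaluates the static likelihood analytically and the
dynamic likelihood by simulation (kernel density per boundary, Silverman
bandwidth, outcome-probability weights), with BIC parameter counts 4 and
4 + 2·(phases − 1).  The simulation-based likelihood inherits Monte-Carlo
error; with the default path counts this is far smaller than the BIC
differences the comparison is meant to detect.

## Learning-effect statistics

`fit_learning_model()` fits value ~ time × learning × type with a random
intercept per network, by maximum likelihood (not REML, so BIC is
comparable across fixed-effect structures), in linear and quadratic time
variants, selecting by BIC.  Interaction p-values use Satterthwaite
degrees of freedom; with a two-level trajectory type each interaction has
a single contrast, and with more levels the worst-case (smallest)
contrast p-value is reported.  The full-trajectory threshold is
0.05/4 = 0.0125 (four decision classes analysed in parallel); pointwise
follow-up at α = 0.05 is gated on a significant omnibus and mirrors only
the significant omnibus terms in its per-bin models, returning contiguous
significant windows.  Calibration of the omnibus type-I rate at the
corrected threshold is verified by a 500-replicate null simulation in the
test suite.

## Problem sizes and reproducibility

Test and acceptance runs use desk-scale sizes chosen to make the
statistical checks decisive: 20 network instances × 130-trial sessions
for the behavioral calibration (≈1 minute), 300-trial batches for CLAW
property checks, 2 000 trials for static-fit recovery, 5 000–6 000 paths
for simulator comparisons, and 500 replicates for the type-I calibration.
Every stochastic step takes an explicit seed; `pipeline_run()` derives
per-stage seeds from a single master seed and writes MD5 hashes of all
artifacts to a JSON manifest, so identical configuration + seed give
byte-identical outputs.

## Known limitations

* The rate network is a structural, not biophysical, stand-in; absolute
  firing rates and time constants are calibrated, not measured.
* Zone assignment is a rule-based classifier; the original procedure it
  stands in for is defined only in prior work on the spiking model, so
  zone V/VI boundaries in particular should be treated as heuristic.
* The CCA layer assumes a linear activity→parameter map; the percent
  scaling of engagement is a documented convention, not an identified
  quantity.
* The dynamic-model likelihood is simulation-based; BIC comparisons at
  very small trial counts will be noisy.
* STN and GPeA activation probabilities are binarized with the same
  antimode rule as the state-defining populations.
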