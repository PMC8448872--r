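---
title: "Cross-species locomotion feature discovery: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species locomotion feature discovery: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Behavioral phenotypes of a disease — Parkinsonian dopamine deficiency being
the motivating case — show up in the locomotion of species as far apart as
humans, mice, and nematodes. Comparing their trajectories directly is
hopeless: a worm crawls tenths of millimetres per second on an agar plate, a
mouse runs hundreds of millimetres per second in an arena, and the recordings
differ in sampling rate and duration. `locodann` implements a procedure for
*discovering* locomotion features shared across two such species: train a
classifier to separate affected from unaffected animals while making it
provably bad at telling the species apart, ask its attention mechanism where
in each time-series the decisive information lives, compress those attended
segments into an if-then rule via decision trees, and finally validate the
rule as an ordinary two-sample hypothesis test on a derived per-animal
statistic.

## Representation

A trajectory $P = [(t_1,x_1,y_1),\dots,(t_T,x_T,y_T)]$ is converted to a
speed series $S = [s_2,\dots,s_T]$ with
$s_i = \mathrm{Dist}(P_i,P_{i-1})/(t_i - t_{i-1})$, then z-scored per series
(population standard deviation; the choice is fixed and documented because
the z-scores feed a fixed-weight network). Speed is used because absolute
coordinates are meaningless across rigs; z-scoring removes the ~100-fold
scale gap between species. The faster-sampled species is undersampled by
even-stride index selection — not interpolation — so all inputs share one
length $l = T-1$. Long recordings can be split into fixed-duration segments,
dropping segments whose path length indicates no movement. Human gait
recordings enter the same pipeline through stride times: per-foot contact
onsets are threshold crossings of the summed vertical ground-reaction force
(default threshold 5% of the per-foot maximum, since heel-strike detection is
not standardized), stride time is the interval between consecutive onsets of
the same foot, and the two per-foot sequences are merged by onset timestamp.

## The network

Two 1D-convolutional blocks read the speed series (stride 1, zero "same"
padding so per-timestep outputs align with input timesteps — required because
attention and the per-timestep domain predictor are per-timestep; width
$F_t = 5$ filters, rectifier activations, dropout 0.5 after each feature-block
convolution during training). The attention block's feature matrix $Z$ yields

$$a = \mathrm{softmax}(W_{a2}\,\tanh(W_{a1} Z^\top)),$$

a distribution over timesteps (both dense layers bias-free). The feature
block's output is weighted by $a$ and summed over time; a two-layer dense
head (tanh, then 2-way softmax) predicts the class, and a parallel head
behind a gradient reversal layer predicts the domain (species). A second
per-timestep domain head, also behind a reversal layer, reads $Z$ directly so
that the *attention computation itself* carries no species information.

The gradient reversal layer is the identity forward and multiplies gradients
by $-\mu$ backward. Training iterates three phases per epoch, each with its
own Adam state: (1) class loss with the per-timestep domain head adversarial
at weight $\lambda_1$; (2) the series-level domain head's loss through its
reversal layer; (3) class loss with the series-level head adversarial at
weight $\lambda_2$. All losses are binary cross-entropy on the positive-class
softmax probability, clipped at $10^{-7}$. Reported phase objectives are
$E_1 = \bar L_c - \lambda_1 \bar L_{d2}$, $E_2 = \bar L_{d1}$,
$E_3 = \bar L_c - \lambda_2 \bar L_{d1}$; gradient flow follows reversal
semantics (each domain head descends its own loss, the blocks beneath receive
$-\mu$ times that gradient), which is what makes the heads competent
adversaries rather than self-sabotaging ones. The reversal strength ramps as

$$\mu(i) = \begin{cases} 0 & 0 \le i < T_1\\
\frac{L+1}{L\,\alpha^{-\beta (i-T_1)/(T_2-T_1)} + 1} - 1 & T_1 \le i < T_2\\
L & T_2 \le i \end{cases}$$

with $\alpha = 1.4$, $\beta = 10$, $T_1 = \text{epochs}/10$,
$T_2 = \text{epochs}/1.2$ (kept fractional, compared against a real-valued
epoch index). The ramp is continuous at $T_1$ and jumps by
$O(\alpha^{-\beta})$ at $T_2$ for finite $\beta$; the closed form is
implemented exactly as stated. Early epochs train the feature extractor
un-adversarially, which matters: reversing gradients against random features
prevents convergence.

### Defaults and why

| parameter | default | rationale |
|---|---|---|
| filters per conv layer | 16 | CPU-only R training; see below |
| $F_t$ (filter width) | 5 | ~5 s receptive context per layer at 1 Hz |
| dense hidden sizes | 32 | matched to filter count |
| dropout | 0.5 | fixed by the method |
| $\lambda_1, \lambda_2, L$ | 1.0 | equal weighting; upper ramp bound 1 |
| learning rate / batch | 1e-3 / 16 | standard Adam regime |
| epochs | 100 | $\mu$ ramp spans epochs 10–83 |

Filter counts and dense sizes are free choices of the architecture;
64 filters is a common choice but costs ~16x the FLOPs of 16 at these input
lengths, which matters for a pure-R backpropagation implementation on one
CPU. All sizes are configuration, not constants; the recovery experiments in
the test suite use an even smaller 8-filter network and still separate
classes perfectly on the synthetic cohort. Dropout is not applied in the attention block. The three phases use separate
Adam states; the
80/20 train/test split is stratified by class-by-domain and seeded.

## Explanation layer

Attention values above the uniform level $1/l$ (strict inequality, so exactly
uniform attention attends nothing) label timesteps "attended". Per-timestep
interpretable features are speed, acceleration (first difference,
zero-padded), a local-minimum flag, and centered rolling
mean/min/max/std/skewness/kurtosis of speed and acceleration at window
lengths {5, 11, 21}, edges truncated, all min-max normalized per trajectory.
There is no canonical feature table for this kind of analysis; this set is a
documented choice covering every feature the explanation layer is expected to
surface (rolling minimum of speed, skewness, acceleration). Skewness is adjusted Fisher–Pearson with 0
returned for zero-variance windows; kurtosis is excess kurtosis with the same
convention.

Two CART trees (Gini impurity, depth 4, minimum leaf 5; only the top
two levels are interpreted — deeper structure mostly fits noise) are fitted: one on pooled per-timestep rows against
attended/none (pooled across domains, consistent with domain-independent
attention), one on per-series attention-weighted feature averages against
class. The weighted average is convex (attention sums to 1), so each averaged
feature stays within the range of its per-timestep values. In both trees
instances with feature values smaller than the threshold go to the left
child. `rpart` is not assumed; the tree is implemented in-package.

## Validation layer

Three derived per-animal statistics mirror the hypotheses the attention
analysis generates: mean within-window minimum speed over the top-20%
fastest windows ("can the animal hold high speed?"), the same with windows
ranked by mean acceleration ("is speed stable while accelerating?"; a series
with exactly zero acceleration everywhere falls back to all windows), and
mean |acceleration| in the window before turns, where turns are speed local
minima below the 25th percentile (direction changes happen at slow points;
turn detection is not standardized, so the
quantile is a documented default, as is the 10-timestep window which should
scale with sampling rate). The window length interacts with the top-20%
selection in a way worth knowing: when the window is shorter than the spacing
of the speed instabilities being measured, destabilized windows have visibly
lower mean speed and are excluded by the selection itself, hiding the effect.
On the synthetic cohort (dips every ~20 s inside fast bouts) a 10-step window
shows no group difference while a 20-step window separates the classes
decisively — choose the window at the scale of the behavioral episode, not of
the anomaly. Group comparison uses Welch's t when both samples
pass Shapiro–Wilk at 0.05, otherwise the Brunner–Munzel test; the BM effect
size is the stochastic-superiority estimate $P(X<Y) + \tfrac12 P(X=Y)$ and
the Welch effect size is reported *signed*, $r = t/\sqrt{t^2+\mathrm{df}}$
(the sign preserves the direction of the group difference; the magnitude
equals the usual $\sqrt{t^2/(t^2+\mathrm{df})}$).

## The synthetic cohort

Because the animal datasets cannot be redistributed, every claim the test
suite makes is exercised on a generated two-species cohort. The base process
is a two-state semi-Markov bout model: speed alternates between a slow
(0.25 units/s) and a fast (1.0 units/s) state with uniformly distributed bout
durations, 3 s linear ramps between them, 10% multiplicative Gaussian speed
noise, and a heading random walk that turns mostly during slow bouts; speeds
are integrated to 2D positions. Domain 0 is worm-like (1 Hz, scale 1);
domain 1 is mouse-like (5 Hz, spatial scale 100, undersampled back to
$l = 599$). Crucially the domains also differ in bout-duration statistics
(high bouts 30–80 s vs 20–60 s): that is a genuine, scale-free species
signal, so a non-adversarial classifier *can* learn the domain and the
domain-accuracy criteria are a real test of the reversal machinery rather
than a tautology.

Class 1 carries one of three planted signatures, default magnitude 1:
short multiplicative speed dips (3–7 s, factor 0.3–0.6) inside high-speed
bouts; extra speed noise during acceleration ramps; or compressed braking
ramps before slow turns. Ground truth records the affected segment per
series — for the dip effect, the destabilized high-speed bout (the dips are
only defined relative to their bout, and a bout is the unit attention can
resolve). What a green recovery test establishes: the pipeline separates
classes across a 100-fold scale gap while both domain predictors stay near
chance, and attention mass concentrates on the affected bouts well above the
uniform baseline. What it does not establish: biomechanical realism,
robustness to tracking artifacts, or behavior on label noise — the generator
plants clean effects at known places.

## Numerical choices and degenerate inputs

Probabilities are clipped at $10^{-7}$ before logs; z-scoring a
zero-variance series, resampling beyond the original length, gait records
with fewer than two contacts per foot, attention vectors that do not sum
to 1, single-class tree labels, samples with zero rank variance (complete
separation in Brunner–Munzel) and turn detection finding no turns all raise
errors rather than returning values. Min-max normalization maps constant
feature columns to 0. Training requires both classes and both domains.
All randomness — initialization, shuffling, dropout, the generator — flows
from explicit integer seeds, and identical seeds reproduce checkpoints
bitwise.

## Known limitations

Pure-R training is practical up to tens of filters and a few hundred epochs,
not beyond; there is no GPU path. Heads are strictly binary (two classes,
two domains), as in the method being implemented. The per-epoch "class loss
decreases under ablation" property is asserted as final-below-initial rather
than per-epoch monotonicity, which minibatch optimization does not provide.
Test statistics for real animal cohorts depend on deposited datasets that
cannot ship with the package; the test surface is property-based instead.
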