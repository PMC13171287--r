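---
title: "Population coupling and ON/OFF state analysis: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population coupling and ON/OFF state analysis: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popstate)
```

## The scientific problem

Neurons in a cortical column differ in how strongly their firing follows the
surrounding population: at one extreme sit *soloists*, whose spikes are
nearly independent of the local population rate, at the other *choristers*,
who fire when the population fires. At the same time, columnar population
activity in awake visual cortex alternates between *ON* periods of vigorous
spiking and *OFF* periods of faint spiking. `popstate` implements the
analysis chain that connects these two descriptions in laminar V1/V4
recordings: per-neuron population coupling, a multichannel Poisson hidden
Markov model (HMM) of the ON/OFF process, per-neuron ON/OFF rate ratios,
attention modulation indices, and spike-count noise correlations — plus a
synthetic-session generator so every stage can be tested against ground
truth without access to recorded data.

## Population coupling

For a single unit with 1 ms binned spike train $x[n]$ and population rate
$y[n]$ (the summed single- and multi-unit counts of all *other* included
contacts), both smoothed and mean-subtracted, the spike-normalised
cross-correlation is

$$R_{xy}[k] = \frac{1}{\lVert x \rVert}\sum_n (x[n+k]-\bar x)(y[n]-\bar y),$$

with $\lVert x\rVert$ the unit's spike count in the analysed window. The raw
coupling is $C[0] = R_{xy}[0]$. The *normalised* coupling is implemented as
the plain Pearson correlation

$$C_\mathrm{norm} = \frac{\sum (x-\bar x)(y-\bar y)}
 {\sqrt{\sum (x-\bar x)^2 \sum (y-\bar y)^2}},$$

and $Z = \operatorname{atanh}(C_\mathrm{norm})$ is its Fisher transform.
A leading $1/\lVert x\rVert$ factor on the normalised form would break the
$[-1,1]$ bound that `atanh` requires, so that factor is kept only in the raw
$C[0]$. This is a deliberate design choice: $Z$ is only meaningful for a
bona fide correlation coefficient.

**Smoothing kernels.** "Half-width" is interpreted as the Gaussian standard
deviation $\sigma$ in ms; kernels are truncated at $\pm 4\sigma$ and
renormalised to unit area, so constants map to constants away from edges.
The population rate uses $\sigma = 12$ ms. The unit train uses
$\sigma = 12/\sqrt{2}$ ms: the narrower unit kernel and the 12 ms population
kernel together act like a single 12 ms smoothing of the cross-product.
`coupling_options(unit_kernel_mode = "strict")` instead applies
$12/\sqrt 2$ to both signals; the default (`"literal"`) keeps the
population kernel at 12 ms. Both behaviours are selectable because the
source convention is ambiguous.

**Trial handling.** Trials are concatenated window-by-window with *no*
smoothing across segment boundaries: each trial segment is smoothed and
mean-subtracted independently, and only the cross-products are accumulated.
This prevents artifactual correlations from rate steps between trials. Mean
subtraction uses the within-segment mean — the only reading under which
$R_{xy}$ is a covariance.

**Leakage control.** Spikes of one unit can bleed into the multi-unit
activity of the neighbouring contact (150 µm away). The default population
rate excludes only the unit's own contact
(`leakage_min_separation_um = 150`); setting 300 additionally removes both
adjacent contacts. Intermediate thresholds (e.g. 200 µm) are accepted; no
single value is asserted as canonical.

## The Poisson HMM of ON/OFF states

Spike counts $n_{tj}$ in 10 ms bins on channel $j$ are modelled as Poisson
with mean $\lambda_{js}$ conditional on a latent phase $s_t$ shared by all
channels,

$$P(n\mid s) = \frac{\lambda_{js}^{\,n}}{n!}e^{-\lambda_{js}},$$

where $s_t$ evolves as a first-order Markov chain (transition matrix $P$,
initial distribution $\pi_0$; dwell times geometric). Parameters are
estimated by Baum–Welch EM; decoding uses the Viterbi algorithm in log
space.

Numerical and procedural choices:

* **Termination.** EM stops when the relative log-likelihood change
  $|{\rm new}-{\rm old}|/|{\rm old}| < 10^{-3}$ *and* the largest absolute
  elementwise change of $\Lambda$ and $P$ is $< 10^{-5}$, or at 500
  iterations. The matrix criterion is interpreted as a max-norm on absolute
  changes (the norm is otherwise unspecified).
* **Restarts.** `multi_restart_fit()` draws 10 random initialisations —
  flat Dirichlet ($\alpha = 1$, the natural unparameterised default) for
  $\pi_0$ and each row of $P$, and $\mathrm{Unif}(0, 2\bar n_j)$ for each
  emission entry — and keeps the highest-likelihood fit.
* **Floors.** Emission means are floored at $10^{-8}$ inside EM so channels
  silent in a phase cannot produce $\log 0$; this is a numerical guard, not
  a model change.
* **Ties.** Viterbi ties break toward the lower phase index, and the
  ON/OFF labelling of a two-phase model (larger mean emission across
  channels = ON) refuses exact ties rather than guessing.
* **Implementation.** The forward–backward and Viterbi recursions are
  compiled (Rcpp) with per-bin scaling; the E-step is batched over all
  trials in one call. Likelihoods are validated against exhaustive path
  enumeration in the tests.

**Model selection.** `select_num_phases()` fits $S = 1\ldots 8$ (any
subrange is allowed) under fourfold cross-validation: trials are shuffled
once with the run seed and split into four equal folds; each fold's model is
trained on the other three quarters. On held-out trials the phase path for
channel $j$ is decoded from *all channels except* $j$
(leave-one-channel-out — implied rather than spelled out by the antecedent
method, and implemented as such), and the error
$\sum_t (n_{tj}-\lambda_{j s_t})^2$ is accumulated. Per-channel errors are
normalised to the one-phase model, then averaged over channels, then folds,
then (when present) conditions — the averaging order is our choice, as only
the set of averages is stated. A recording passes the inclusion rule when
the second phase reduces the normalised error by ≥ 10% and no later phase
adds another ≥ 10% reduction.

## Windows, filters, controls

All intervals are half-open $[{\rm start}, {\rm end})$ in ms so adjacent
windows never double-count a spike. Events are stored per trial; times are
floating-point ms from session start. Named windows: *spontaneous*
(monkey-specific: 200–500 ms after fixation onset for profile M1, 100–400 ms
for M2), *cue-to-dimming* (cue + 400 ms to first dimming + 30 ms),
*pre-dimming* (500–0 ms before first dimming; hosts the noise-correlation
counts), *baseline* (−250–0 ms) and *onset response* (50–300 ms). The last
two anchor at cue onset — the stimulus-locked event available in the trial
table; sessions with a separate stimulus-onset event would anchor there.

* **Inclusion.** A unit needs ≥ 5 Hz mean rate in at least one window of
  interest and ≥ 10 trials per attention condition.
* **Response control.** Paired two-sided Wilcoxon signed-rank between
  per-trial baseline and onset counts at $\alpha = 0.05$ (the conventional
  default; the source states significance without a level). All-tied
  samples are treated as $p = 1$.
* **Stability.** The visual stability inspection is replaced by a
  reproducible rule: a trial is stable on a channel when its energy
  $E = \sum_t V[t]$ lies within 3 robust SDs ($1.4826\cdot$MAD) of that
  channel's median energy; the longest contiguous all-channel-stable run is
  kept. A plain median is used rather than a running median: a moving
  reference tracks slow drifts and would never flag them.
* **Rate matching.** Trials are removed one at a time — always the
  lowest-activity trial of whichever condition currently has the *lower*
  mean, the only direction that converges — until the relative difference
  of condition means (denominator: their average, symmetric in conditions)
  drops below 2%, or a floor of 10 trials is reached and the unit is
  flagged unmatched. Flagged units must be excluded from matched analyses;
  they are never silently retained.
* **attMI.** $(A_\mathrm{RF}-A_\mathrm{away})/(A_\mathrm{RF}+A_\mathrm{away})$
  on mean rates; the two non-RF cue locations are pooled into
  `attend_away`. The activity window defaults to cue-to-dimming (the
  attention period) and is configurable — the defining window is not pinned
  down by the source.
* **ON/OFF ratio.** Per trial, ON-bin rate over OFF-bin rate on the decoded
  trajectory; trials lacking a phase or with zero OFF rate are excluded
  (counted, never mapped to infinity) before averaging.

## The synthetic world

`generator_config()` states the world once; tests and the acceptance
script run in it. A 16-contact, 150 µm probe; latent two-state Markov
dynamics at 10 ms; per-channel Poisson multi-unit counts at 20 Hz (OFF) and
200 Hz (ON) — about 110 Hz time-averaged, matching the ~100 Hz target of
the HMM input; self-transition probability 0.98 per bin in both states
(geometric dwell, mean 500 ms); task epochs drawn from the monkey-specific
delay distributions of the attention task. Single units get a base rate of
15 Hz and a state ratio $\rho \in \{1, 2, 4, 8\}$, realised as
$r_\mathrm{off} = 2r_\mathrm{base}/(1+\rho)$, $r_\mathrm{on} = \rho\,
r_\mathrm{off}$, so the state-average rate is $\rho$-independent at 50% ON
occupancy; $\rho = 1$ is a soloist. Spikes are generated at 1 ms resolution
by thinning within the 10 ms latent bins. Attention (`attend_RF`) raises
`p_stay_on` from 0.98 to 0.995 (longer ON periods) and scales unit rates by
$1+g$ with $g = 0.1$ — attention is reported to lengthen ON periods and
raise rates in both phases; the magnitudes are free parameters chosen once
here, not estimates. Single-unit spikes are *not* added into their host
contact's multi-unit train, so excluding the unit's own contact removes its
spikes from the population rate exactly.

What the generator deliberately does not emulate: spike sorting and its
failure modes, non-Poisson count dispersion, rate drifts and electrode
movement, >2-phase nested state structure, realistic LFP/MUAe beyond two
parametric test profiles, and eye-movement or behavioural covariates. A
green test therefore establishes correctness of the *analysis* under the
stated model, not robustness to these real-data features.

## Laminar utilities

The current source density is the plain second spatial difference
$\mathrm{CSD}(x) = [\varphi(x+h) - 2\varphi(x) + \varphi(x-h)]/h^2$ exactly
as printed (no minus sign); `sink_negative = TRUE` flips to the
physiological sink-negative convention. SNR is $({\rm Signal}-{\rm
Noise})/\sigma_{\rm noise}$ over eight 50 ms response windows with a strict
$>3$ pass rule. The response-latency model is the sum of an exponentially
dissipating and a sustained cumulative-Gaussian component; it is fitted by
multi-start Nelder–Mead least squares (20 starts spanning the rise region),
and the latency is the earliest crossing of 33% of the earliest fitted
peak — a relative rule, invariant to amplitude. Layer compartments follow
the area-specific depth bands around the granular reference channel, with
spiking-based overrides; the interactive sink-identification step is *not*
reproduced, the reference channel is an input. Receptive-field z-maps use a
4-connected component at $z \ge 3$ around the peak (connectivity
unspecified in the source; documented here).

## Known limitations

* Redundant extra phases ($S$ above the true phase count) sit on a
  likelihood ridge; such EM runs legitimately hit the 500-iteration cap,
  which makes wide `S_range` scans on long recordings expensive.
* The CLI covers simulation, staged runs and the full pipeline but is a
  thin dispatcher, not a workflow manager; stages are resumable only by
  rerunning from their inputs.
* Magnitudes reported on synthetic sessions (coupling values, attMI sizes,
  CV-error reductions) are properties of the stated world; only their
  signs, orderings and procedural guarantees are asserted as tests.
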