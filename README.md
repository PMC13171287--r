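# popstate

Analysis of single-neuron **population coupling** and its relation to
**ON/OFF cortical state dynamics** and **spatial attention** in laminar
multielectrode recordings from visual cortex (V1/V4).

Cortical neurons span a continuum from *soloists* (spiking almost
independently of their neighbours) to *choristers* (spiking with the local
population). Columnar population activity itself alternates between ON
periods of vigorous spiking and OFF periods of faint spiking. `popstate`
implements the full chain linking the two descriptions, plus a synthetic
session generator with known ground truth so every stage is testable
without recorded data.

## What it computes

**Population coupling.** For a unit's 1 ms binned, Gaussian-smoothed
(σ = 12/√2 ms), mean-subtracted spike train *x* and the matching population
rate *y* (summed single-/multi-unit counts of all other included contacts,
σ = 12 ms):

    R_xy[k] = (1/‖x‖) Σ_n (x[n+k] − x̄)(y[n] − ȳ)

with ‖x‖ the unit's spike count. Raw coupling C[0] = R_xy[0]; normalised
coupling C_norm is the Pearson correlation of *x* and *y*; Z = atanh(C_norm)
is its Fisher transform. Leakage control: population rate from contacts
≥ 300 µm away only.

**ON/OFF states.** A multichannel Poisson hidden Markov model on 10 ms
spike counts: emission matrix Λ (λ_js = mean count of channel *j* in phase
*s*), transition matrix P, initial distribution π0. Fitted by Baum–Welch EM
(10 random restarts; Dirichlet inits for π0 and P rows, Uniform(0, 2·mean)
for Λ; stop at relative log-likelihood change < 1e−3 and matrix change
< 1e−5, max 500 iterations), decoded by Viterbi. The number of phases is
selected by fourfold **leave-one-channel-out cross-validation**: channel
*j*'s held-out counts are scored against the rates predicted from states
decoded without channel *j*, errors normalised to the one-phase model; a
recording passes when a second phase cuts the error by ≥ 10% and further
phases do not.

**State and attention metrics.** Per-unit ON/OFF firing-rate ratio on
decoded trajectories; attention modulation index
attMI = (A_RF − A_away)/(A_RF + A_away); pairwise spike-count noise
correlations in the 500–0 ms pre-dimming window; iterative rate matching
(< 2% mean-rate difference between conditions); cross-metric correlation
and regression summaries.

**Laminar utilities.** Finite-difference CSD
(φ(x+h) − 2φ(x) + φ(x−h))/h², channel SNR with the strict > 3 rule,
parametric visual-latency fits (dissipating + sustained cumulative-Gaussian
model, latency at 33% of the earliest peak), depth-band layer assignment,
receptive-field z-maps thresholded at z = 3.

## Worked example

```r
library(popstate)

cfg <- generator_config(seed = 42,
                        n_trials = c(attend_RF = 15L, attend_away = 15L))
gen <- generate_session(cfg)          # 16-channel session + ground truth
session <- gen$session

## population coupling per unit (attend-away trials, cue-to-dimming window)
pc  <- session_population_coupling(session, condition = "attend_away")
tab <- coupling_table(pc)
tab$state_ratio <- default_unit_table(16)$state_ratio
aggregate(cbind(C_norm, Z) ~ state_ratio, tab, median)
#>   state_ratio C_norm      Z
#> 1           1 0.0657 0.0658
#> 2           2 0.1741 0.1759
#> 3           4 0.2876 0.2960
#> 4           8 0.4117 0.4377

## two-phase Poisson HMM on the multi-unit counts
set.seed(1)
counts <- hmm_count_trials(session, condition = "attend_away")
fit <- multi_restart_fit(counts, S = 2, n_restarts = 10)
sort(rowMeans(fit$lambda))   # OFF / ON mean counts per 10 ms bin
#> 0.202 1.983                 # generator truth: 0.2 / 2.0
diag(fit$P)                  # self-transition probabilities
#> 0.979 0.977                 # generator truth: 0.98 / 0.98

## attention modulation
attmi <- sapply(sprintf("su%02d", 1:16),
                function(id) unit_attmi(session, id)$attMI)
mean(attmi)
#> 0.15
```

Units were generated with ON/OFF rate ratios ρ ∈ {1, 2, 4, 8}: median
coupling rises monotonically from ≈ 0.07 (soloists) to ≈ 0.41 (choristers),
the HMM recovers the generating emission and dwell parameters, and the
attend-RF gain (longer ON periods plus a 10% rate gain) yields a positive
mean attMI.

## Command line

```sh
inst/cli/popstate simulate   --out session_dir --seed 7
inst/cli/popstate run        --config run.json --out results
inst/cli/popstate fit-hmm    --session session_dir --out hmm_out
inst/cli/popstate compute-pc --session session_dir --out pc_out
```

See `vignettes/population-coupling-on-off-states.Rmd` for the model
assumptions, parameter conventions, the synthetic world's scope, and known
limitations.
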