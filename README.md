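# dynbmi

Latent-dynamics decoders for intracortical brain–machine interfaces (BMIs),
built around one question: when an electrode array degrades and most of its
informative channels are gone, can a decoder be rescued by *remembering*
the neural population dynamics it learned years earlier, when many more
electrodes were available?

The package is aimed at computational neuroscientists and BMI engineers who
want to study decoder robustness to electrode loss with a fully specified,
reproducible synthetic ground truth.

## The model and the decoders

Binned spike counts `y_k` (threshold crossings, 15 ms bins) are modeled as
noisy linear observations of a low-dimensional latent neural state `s_k`:

```
s_k = M s_{k-1} + n_k,   n_k ~ N(0, N)        (dynamics process)
y_k = P s_k     + r_k,   r_k ~ N(0, R)        (observation process)
```

with `N`, `R` diagonal. Parameters are identified by EM with exact Kalman
smoothing (compiled core) and factor-analysis initialization; decoding runs
the steady-state Kalman filter followed by a linear kinematic readout with
a 97.5% velocity-integration position blend.

Five decoders share this infrastructure:

| kind | dynamics `(M, N)` | observation `(P, R)` | readout |
|------|-------------------|----------------------|---------|
| NDF | fit fresh (EM) | fit fresh | fresh |
| HNDF | **remembered** | re-fit (constrained EM) | fresh |
| MNDF | **remembered** | **remembered** (restricted) | fresh |
| FIT-KF | kinematic-state Kalman filter on intention-transformed kinematics | | |
| OLE | least squares on causally smoothed counts (100 ms Gaussian) | | |

Around the decoders: mutual-information electrode ranking on the count
support `{0,1,2,3,4,5+}` with a drop-most-informative-first loss protocol;
offline metrics (lagged velocity correlation, position error with
per-trial reset); and rotational-dynamics analyses — eigenspectra of
`(M - I)/dt`, maximum oscillation frequency with a 20 ms time-constant
screen, the jPCA `R²(skew)/R²(best)` ratio, and per-eigenmode
contributions to the decoded output with a 10 cm/s regularizer.

## Worked example

Generate a synthetic center-out-and-back session, train an NDF and an
HNDF after heavy electrode loss, and compare held-out decoding:

```r
library(dynbmi)

cfg   <- synth_config(seed = 2)              # 96 electrodes, 500 trials, d = 20
truth <- make_ground_truth(cfg)
today <- generate_session(truth, cfg)

# historical full-array session -> remembered dynamics
cfg_hist <- cfg; cfg_hist$seed <- cfg$seed + 7919L
remembered <- em_fit(generate_session(truth, cfg_hist)$spikes, d = 20,
                     opts = list(steady_state = TRUE, max_iter = 100))

# drop the 70 most informative electrodes, train both decoders
lost  <- drop_electrodes(today, drop_order(today)[1:70])
split <- split_train_test(lost, 0.8)
opts  <- list(steady_state = TRUE, max_iter = 100)
ndf   <- train_ndf(lost, split, d = 20, opts = opts)
hndf  <- train_hysteresis(lost, split, remembered, "hndf", opts = opts)

dplyr::bind_rows(score_decoder(ndf,  lost, split$test_trial_ids),
                 score_decoder(hndf, lost, split$test_trial_ids))
#> # A tibble: 2 × 6
#>   kind  velocity_correlation best_lag_s   r_x   r_y position_error_cm
#>   <chr>                <dbl>      <dbl> <dbl> <dbl>             <dbl>
#> 1 ndf                  0.164      0.015 0.180 0.149              3.47
#> 2 hndf                 0.400      0.015 0.413 0.388              3.33
```

With 70 of 96 electrodes gone, the freshly fit NDF has collapsed to a
held-out velocity correlation of 0.16 while the HNDF, which remembers the
historical dynamics process and re-fits only the observation model on the
surviving channels, holds 0.40 — the rescue that motivates decoder
hysteresis. The fitted dynamics show why:

```r
max_frequency(eigenmodes(ndf$lds$M))     # 0.67 Hz  (re-learned: slowed down)
max_frequency(eigenmodes(hndf$lds$M))    # 2.43 Hz  (remembered rotations)
```

The multi-seed experiment behind the headline claims is one call:

```r
sweep <- run_loss_experiment(synth_config(), drop_counts = c(0, 60, 70, 80),
                             seeds = 1:10,
                             opts = list(steady_state = TRUE, max_iter = 100))
autoplot(sweep)                             # decline + crossover figure
compare_decoders(sweep)                     # paired Wilcoxon per drop count
```

A thin command-line wrapper over these functions is installed at
`inst/cli/dynbmi.R` (subcommands `simulate`, `train`, `decode`,
`rank-electrodes`, `analyze-dynamics`, `sweep`).

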