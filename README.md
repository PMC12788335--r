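# sprintgc

Ground-contact detection in sprint acceleration from shank-mounted IMUs.

## The problem

Sprint performance analysis hinges on ground-contact (GC) times: the
interval from the initial contact of the foot (IC) to its toe-off / terminal
contact (TC). In the acceleration phase of a sprint, contact times shrink
from roughly 184 ms at the first step to ~104 ms by steps 9–10, and
heuristic peak/threshold detectors on IMU signals become unreliable exactly
there. `sprintgc` is for biomechanists and sports scientists who want a
deep-learning detector for this regime, together with the complete
evaluation and method-comparison toolchain.

## The method

The detector is a per-timestep binary classifier over two resultant shank
IMU channels at 250 Hz, a(RES) (resultant acceleration) and ω(RES)
(resultant angular velocity). It stacks *inception blocks*:

    R(x) = BN(W_r * x)
    I(x) = BN([ b1(x) ‖ b3(x) ‖ b5(x) ‖ b7(x) ])
    y    = ReLU( I(x) + R(x) )

with branches `b1(x) = W_{1,1} * x` and `bk(x) = W_{k,2} * (W_{k,1} * x)`
for kernel sizes k ∈ {3, 5, 7}. Each branch outputs 32 channels (the
pointwise `W_{k,1}` act as bottlenecks from the 128-channel block input),
the concatenation is 128 channels, the pointwise residual projection keeps
dimensions consistent, and a pointwise 128 → 1 convolution with sigmoid
yields one contact probability per timestep. Sequence length is preserved
throughout. The network, backpropagation, batch norm and Adam are
implemented in RcppArmadillo — no deep-learning framework required — and
the backward pass is verified against finite differences in the test suite.

Runs are min–max scaled to [−1.5, 1.5] per run, sliced into overlapping
fixed windows (tuned: window 100, stride 15), and predictions are
reassembled by overlap averaging. Postprocessing binarizes at 0.5 and
removes contacts shorter than 12 frames (48 ms). Evaluation uses mean and
median Hausdorff distances over IC/TC transitions, event-level
precision/recall, the frame-level Rand index, and agreement statistics
(Bland–Altman bias and limits of agreement, Spearman, Wilcoxon signed-rank
with effect size, MAPE/RMSE, step-wise contact-time tables).

Because the original athlete recordings are not public, the package ships a
seeded synthetic sprint-signal generator that reproduces the study design
(12 athletes × 3 runs × 2 legs, one excluded run; 40 TRAIN / 20 VAL /
10 TEST streams) and the published step-wise contact-time distributions, so
the whole pipeline is testable end to end.

## Worked example

```r
library(sprintgc)

study  <- generate_study(gait_sim_config(seed = 11))
splits <- study_splits(study)

fit <- fit_gc_model(
  inception_model(model_spec(n_blocks = 6, lr = 0.01), seed = 11),
  build_dataset(splits$TRAIN, window = 100, stride = 15),
  build_dataset(splits$VAL,   window = 100, stride = 15),
  train_config(max_epochs = 30, batch_size = 50, patience = 5),
  seed = 11
)
glance(fit)
#> # A tibble: 1 x 8
#>   n_blocks window stride    lr epochs_run best_epoch best_val_loss stopped_early
#>      <int>  <dbl>  <dbl> <dbl>      <int>      <int>         <dbl> <lgl>
#> 1        6    100     15  0.01         13          8        0.0197 TRUE

metrics <- evaluate_runs(fit, splits$TEST)
aggregate_metrics(metrics)
#> # A tibble: 5 x 7
#>   metric           center  spread center_ms spread_ms     n n_missing
#>   <chr>             <dbl>   <dbl>     <dbl>     <dbl> <int>     <int>
#> 1 mean_hausdorff    0.215 0.0851       0.86     0.341    10         0
#> 2 median_hausdorff  0     0            0        0        10         0
#> 3 precision         1     0           NA       NA        10         0
#> 4 recall            1     0           NA       NA        10         0
#> 5 rand_index        0.986 0.00547     NA       NA        10         0
```

Every true contact in the held-out synthetic TEST split is found (recall
1), nothing spurious survives postprocessing (precision 1), predicted and
true transitions differ by 0.215 frames (0.86 ms) on average, and the
frame-level Rand index is 0.986. Agreement statistics on the matched
contact pairs:

```r
preds <- lapply(splits$TEST, function(r) predict_contacts(fit, r))
agreement_report(pair_study(preds, splits$TEST))
#> <gc_agreement> n = 100 contact pairs
#>   bias -0.84 ms, LOA [-6.55, 4.87] ms
#>   Spearman rho 0.989 (almost perfect), Wilcoxon p 0.001, ES 0.322 (small)
#>   MAPE 1.36%, RMSE 3.02 ms
```

The bias means predicted contacts run on average 0.84 ms (about a fifth of
a frame) shorter than the truth, with 95% limits of agreement well inside
two frame periods; the exact values depend on the seed.

`autoplot()` methods exist for runs, fits and Bland–Altman results;
`plot_identity()` draws the predicted-vs-true contact-time scatter.

A thin command-line wrapper (`inst/cli/sprintgc`) exposes `simulate`,
`train`, `tune`, `predict`, `evaluate` and `stats` subcommands over the
same functions for file-based experiments.

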