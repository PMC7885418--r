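# myodecode

Simultaneous and proportional decoding of wrist/hand movement intent
from multichannel surface EMG (sEMG), calibrated with categorical
prompts only — plus the standard motion-normalized LDA benchmark and a
closed-loop Fitts's-law testbed to compare the two.

## Who this is for

Researchers in myoelectric control / neural engineering who want a
self-contained, dependency-light reference implementation of:

* **envelope preprocessing** — rectification, causal moving average
  (length `W`, group delay `(W-1)/(2Fs)`), per-channel 1%/99% percentile
  rescaling, clipping, square root; batch and bit-identical streaming;
* **a multitask regression network** — shared encoder (`N` blocks,
  widths `2^K … 2^(K-N+1)`) with per-DoF decoder branches; blocks are
  affine → leaky ReLU → parameter-free layer norm;
* **contractive calibration** — minimize `L = L_i + α_c L_c`, where
  `L_i` is the mean per-sample L1 error against ternary DoF labels
  `y ∈ {-1,0,1}^J` and `L_c = mean_(t,i,j) (∂ŷ_j/∂e_i)²` is the mean
  squared Jacobian entry; Gaussian input corruption, AdamW, lookback
  early stopping. The double backprop through the Jacobian is analytic
  (pure-R reference + RcppArmadillo engine, cross-pinned by tests);
* **the benchmark** — Hudgins time-domain features (MAV/ZC/SSC/WL) on
  32-sample windows, 9-class LDA, and the proportionality scalar
  `PC_m = ((1/C_m) Σ_i S_im MAV_i)²`;
* **closed-loop evaluation** — 40-target acquisition test (0.3 s dwell,
  20 s timeout, 540 px/s at unit command), a scripted predictive user,
  synthetic 8-channel sEMG, and the five session metrics CR/CT/PE/O/T
  with `ID = log2(D/W + 1)`, the ID-vs-CT regression and Cohen's d.

No dataset ships with the method, so a synthetic sEMG generator
(amplitude-modulated Gaussian noise with subject-specific channel gain
patterns, 8-bit quantization, scripted 3×5 s calibration protocol at 50%
MVC) makes everything runnable end to end.

## Worked example

```r
library(myodecode)

prof <- make_subject_profile(seed = 1)                    # simulated subject
ses  <- generate_calibration_session(prof, seed = 11)     # 38,400 samples
pre  <- preprocess_emg(ses$recording)                     # envelopes + stats

topo <- mrl_topology(first_layer_log2 = 5, encoder_depth = 3,
                     decoder_hidden_log2 = 4)             # scaled-down net
cfg  <- mrl_config(batch_size = 256, max_iterations = 400,
                   lookback = 150, learning_rate = 3e-3, seed = 5)
fit  <- mrl_calibrate(pre$envelopes, ses$stimulus, topo, cfg)
fit
#> <mrl_fit> 390 iterations, stopped on lookback - best validation loss 0.1349 at iteration 361

ws    <- window_stream(ses$recording, ses$stimulus)       # LDA benchmark
model <- lda_fit(ws$features, ws$labels)

targets <- make_target_set()
mrl <- session_metrics(run_session(mrl_controller(fit$params, pre$stats),
                                   targets, simulated_user(), prof, seed = 21))
lda <- session_metrics(run_session(lda_controller(model),
                                   targets, simulated_user(), prof, seed = 22))
mrl
#> <metric_set> CR 90.0% | CT 0.97 s | PE 71.0% | O 4.250 | T 1.795 bits/s (36/40 targets)
lda
#> <metric_set> CR 100.0% | CT 7.11 s | PE 100.0% | O 0.000 | T 0.260 bits/s (40/40 targets)
```

The regression decoder completes targets several times faster (higher
throughput T, the bits-per-second figure of merit) because it moves the
cursor in arbitrary directions with speed proportional to contraction
intensity, while the classifier-based controller must chain axis/diagonal
moves; its zero-speed rest class makes it slow but very steady (high CR,
no overshoot). Numbers above were printed by this exact script on the
scaled configuration; the reference hyperparameter defaults
(`mrl_config()`, `mrl_topology()`) are much heavier to train.

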