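# pulsepol

Single-particle polarimetric classification of suspended particles —
microalgae, microplastics and sediment — from densely sampled polarized
light pulses.

## The problem

In-situ optical monitoring of seawater needs to tell particle types apart
one particle at a time. A polarimetric flow instrument illuminates a tiny
scattering volume with polarized laser light; each particle transit scatters
light whose polarization state encodes the particle's size, shape and
microstructure. A polarization state analyzer splits the scattered beam
into four channels (0° linear, 45° linear, left-/right-circular), digitized
at 200 kS/s. The channel vector $c$ relates to the Stokes vector
$S = [I,Q,U,V]$ through the instrument matrix $A$ (obtained by
calibration): $c = A S$. The classification features of one sampling are

```
q = Q/I,  u = U/I,  v = V/I,  DOP = sqrt(Q^2 + U^2 + V^2) / I
```

A 2 ms transit yields a *polarized light pulse* of ~400 samplings. The
package implements and tests the central methodological question: is it
better to average the whole pulse into one feature row (PLP-Ave), or to
sample it densely — 4, 10, 100 segments, or every sampling (PLP-All) — so
that the classifier sees the particle's transient orientation states?

`pulsepol` provides, end to end:

* **Stokes–Mueller core** — the analyzer model, least-squares instrument
  calibration, inversion with physicality flags (`ideal_psa_matrix()`,
  `calibrate_instrument()`, `invert_stokes()`, `stokes_to_features()`);
* **virtual instrument** — labeled synthetic four-channel traces of
  single-particle transits: exact Lorenz–Mie spheres plus parametric
  depolarizing microalgae analogs with within-pulse orientation dynamics
  (`preset_class_library()`, `simulate_trace()`, `simulate_mixture()`);
* **pulse processing** — zero-phase low-pass filtering, background
  subtraction, hysteresis threshold detection, and the dense-sampling
  featurization family (`lowpass_filter()`, `detect_pulses()`,
  `densify()`, `build_dataset()`);
* **classification & evaluation** — the small sigmoid backpropagation
  network (5 → 5-6-4 → K), an SVM comparator, pulse-grouped splits,
  confusion-matrix metrics, mixed-suspension count prediction, and the
  scheme-comparison experiment (`train_bpnn()`, `train_svm()`,
  `evaluate()`, `predict_mixture()`, `run_scheme_comparison()`);
* **orchestration** — YAML run configs, a reproducible pipeline runner and
  a thin CLI (`run_pipeline()`, `inst/cli/pulsepol`).

## Worked example

Simulate pure suspensions of the four microalgae presets, build PLP-Ave and
PLP-All datasets from the same traces, train the network on each and
compare:

```r
library(pulsepol)

lib <- preset_class_library(c("DS", "CP", "CD", "PG"))
traces <- lapply(seq_along(lib), function(i)
  simulate_pure(lib[[i]], n_pulses = 60, duration = 3, seed = 1000 + i))

for (scheme in c("ave", "all")) {
  tab <- build_dataset(traces, scheme)
  parts <- split_dataset(tab, train_frac = 0.7, seed = 1)
  fit <- train_bpnn(parts$train, bpnn_config(4, seed = 1))
  print(evaluate(fit, parts$test))
}
#> plp_eval_report (PLP-Ave)
#>   row-level accuracy:   0.4444 (MSE 0.1313)
#>   pulse-level accuracy: 0.4444 (majority vote, 72 pulses)
#> plp_eval_report (PLP-All)
#>   row-level accuracy:   0.8390 (MSE 0.0579)
#>   pulse-level accuracy: 1.0000 (majority vote, 73 pulses)
```

One pulse-averaged row per particle leaves the three look-alike species
(DS, CP, PG) nearly indistinguishable — their orientation-averaged
signatures alias — while per-sampling features recover the particles'
transient polarization states and a majority vote over each pulse's rows
classifies every test particle correctly. The full five-scheme experiment
is one call:

```r
cmp <- run_scheme_comparison(lib, seeds = 1:5)
cmp
#> plp_scheme_comparison over 5 seeds
#>   scheme mean_accuracy_pulse sd_accuracy_pulse mean_accuracy_row mean_mse
#>  PLP-Ave              0.4972          0.066173            0.4972  0.12957
#>    PLP-4              0.6000          0.053251            0.5875  0.11996
#>   PLP-10              0.6812          0.088184            0.6249  0.11233
#>  PLP-100              0.9890          0.011598            0.8486  0.05768
#>  PLP-All              0.9945          0.007561            0.8540  0.05401
#> dense-sampling gain (PLP-All - PLP-Ave): +49.7 points
```

Mean test accuracy is non-decreasing in the sampling number, PLP-All leads,
and the mean squared training error falls with sampling density. A trained
PLP-All model also counts mixed suspensions: `predict_mixture()` detects
pulses in a mixture trace, classifies each by majority vote, and reports
per-class counts with relative errors against the preset composition.

The methods vignette (`vignettes/dense-sampling-methods.Rmd`) documents the
simulator's physics, every default, and the design decisions.

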