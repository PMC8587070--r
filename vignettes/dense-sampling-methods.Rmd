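---
title: "Dense sampling of polarized light pulses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dense sampling of polarized light pulses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsepol)
```

## The measurement this package models

A polarimetric single-particle instrument illuminates a small scattering
volume with light of a known polarization state. When a suspended particle
— a microalgal cell, a microplastic bead, a sediment grain — transits the
volume, its side-scattered light is split by a polarization state analyzer
(PSA) into four channels (0° linear, 45° linear, left- and right-circular),
digitized at 200 kS/s. Each transit produces a *polarized light pulse*
(PLP) a few hundred samples wide; the pulse width is the particle's settling
time in the volume (about 2 ms, i.e. ~400 samples).

The four channel intensities relate linearly to the Stokes vector
$S = [I, Q, U, V]$ of the scattered light through the instrument matrix
$A$: $c = A S$. Inverting $A$ recovers $S$, from which the classification
features are the intensity-normalized parameters

$$q = Q/I,\quad u = U/I,\quad v = V/I,\qquad
\mathrm{DOP} = \sqrt{Q^2+U^2+V^2}/I .$$

Each sampling therefore yields one descriptor row $[I, q, u, v, \mathrm{DOP}]$.

The question the package is built around: given that one pulse contains
hundreds of samplings of the *same* particle, how should they be reduced to
classifier input? The pulse-average (**PLP-Ave**) uses one averaged row per
pulse; the dense-sampling family splits the pulse into $k$ equal segments
(**PLP-4**, **PLP-10**, **PLP-100**) or keeps every sampling (**PLP-All**).
Denser sampling preserves the *transient states* of the moving, reorienting
particle at the cost of less noise averaging per row.

## The virtual instrument

No measured traces are distributed with the instrument literature, so the
package includes a forward simulator whose output feeds the same processing
chain a real record would.

**Scattering models.** Spheres (polystyrene standards PS-02 and PS-10,
silica SD-10) use exact Lorenz–Mie theory at the 120° collection angle
(520 nm, medium index 1.334). Microalgae have no published Mueller
matrices; they are *synthetic analogs* built from a depolarizer × retarder
× diattenuator composition in the particle's body frame. For right-circular
incidence, such a particle shows per-sample
$\mathrm{DOP} = 1-\Delta$ (depolarization $\Delta$), a rotation-invariant
circular residue $v = (1-\Delta)\cos\delta$ (retardance $\delta$), and a
linear residue of radius $(1-\Delta)\sin\delta$ that rotates with the body
axis.

**The look-alike trio.** The presets DS, CP and PG share brightness and are
placed on the iso-$v$ curve $(1-\Delta)\cos\delta \approx 0.30$:
$(\Delta, \delta)$ = (0.25, 66.4°), (0.40, 60°), (0.55, 48.2°). Their
orientation-*averaged* signatures therefore alias, while per-sample DOP
(0.75 / 0.60 / 0.45) separates them cleanly — the trio is distinguishable
exactly to the extent that the processing preserves within-pulse temporal
resolution. CD is deliberately distinct (low depolarization, strong
diattenuation, strongest orientation sensitivity), mirroring a long oval
flagellated cell.

**Orientation dynamics.** During a 2 ms transit the particle's body axis
evolves as a slow random walk (default step 0.08 rad/sample) punctuated by
Poisson-distributed discrete reorientation events (default rate
0.1/sample, uniform jump). The jump component reflects how elongated
particles behave in shear flow — long dwells near an alignment with fast
flips between them (Jeffery-orbit-like dynamics) — and it is what gives the
averaging question its structure: a jump corrupts every averaging window
that straddles it, with probability growing with window length, while an
individual sampling is never split by one. A smooth walk alone degrades
all sub-pulse averaging scales together and cannot distinguish the densest
schemes.

**Noise and background.** Channels carry a constant background offset
(0.05 detector units) plus i.i.d. Gaussian noise whose amplitude is set
from a target SNR, defined as (mean pulse peak − background mean) /
background s.d. on the channel sum. The emulated instrument class
guarantees SNR above 5; the default of 60 represents the bright-particle
regime of a sub-watt focused laser on micrometre-scale scatterers, in which
individual samplings carry usable polarization information. At SNR near
the floor of 5, per-sampling features are noise-dominated and *no* dense
scheme beats coarse averaging — the regime where the method is interesting
is the bright one.

**Other draws.** Brightness is log-normal per class (spread 0.25 log
units); settling time is log-normal around 2 ms (spread 0.15); per-particle
depolarization and retardance jitter (s.d. 0.03 and 5°) model biological
variability. Transit envelopes are peak-normalized Gaussians truncated at
±3σ — a particle crossing a focused Gaussian spot. Event times are Poisson
(`simulate_trace()`) or exact-count uniform (`simulate_mixture()`), with
rejection sampling enforcing the single-particle condition (no overlaps).
Every simulation takes an explicit seed; identical seed and configuration
reproduce a trace bit-for-bit.

**What the simulator does not emulate.** Real microalgae of the named
species (parameters are illustrative, tuned only for the separability
structure above); hydrodynamics of the flow cell; optical aberrations;
wavelength dependence; multi-particle coincidences. Passing tests on this
generator demonstrate that the *processing and classification chain*
behaves as designed under a controlled, physically plausible signal model —
not that the named species are classifiable at the reported rates.

## Processing chain

1. **Zero-phase low-pass filtering** (`lowpass_filter()`): forward–backward
   order-4 Butterworth, default cutoff 60 kHz. The cutoff trades noise
   suppression against temporal resolution: a zero-phase low-pass averages
   over roughly $f_s / 2 f_c$ samples (~1.7 at the default), and a cutoff
   low enough to average many samples would silently turn per-sample
   features into coarse-segment features, defeating the densest schemes —
   the averaging window must stay below the ~3.5-sample segments of
   PLP-100 for "every sampling" to mean anything beyond "100 segments".
   60 kHz is still two orders of magnitude above the ~500 Hz band of a
   2 ms envelope. Reflection padding removes the filter's edge
   transients.
2. **Background subtraction** (`subtract_background()`): per-channel
   medians over the trace head. Without it, the unpolarized background
   pedestal makes every normalized feature depend on where in the transit
   envelope a sample was taken; after it, $q,u,v,\mathrm{DOP}$ are
   properties of the particle alone.
3. **Threshold detection with hysteresis** (`detect_pulses()`): a pulse
   starts when the channel sum crosses background + 5σ and extends to where
   it falls below background + 2σ; background statistics are the median and
   MAD of a configurable head segment. Sub-50 µs candidates are rejected as
   noise spikes; regions separated by sub-50 µs dropouts are merged, since
   a fast reorientation can dip the (linearly-weighted) channel sum for a
   few samples inside one transit. All counts are logged.
4. **Dense-sampling featurization** (`densify()`): segments are contiguous
   and as equal as possible (the first `width mod k` segments get one extra
   sample); averaging is done in channel space *before* Stokes inversion.
   The inversion is linear, so channel-space and Stokes-space averaging
   give the same mean state; the distinction matters only in that DOP is
   computed from the averaged state, which is precisely what makes the
   pulse-average lossy for a reorienting particle. Rows whose inverted
   intensity falls below twice the detection threshold margin are dropped
   and counted, extending the non-positive-intensity drop rule: in the
   extreme pulse wings the ratio features are not merely noisy but
   *biased* — the DOP of a noisy state is inflated by a term of order
   $(\sigma/I)^2$, so dim samplings systematically masquerade as less
   depolarizing particles.

Indexing is 0-based and half-open throughout the pulse bookkeeping.

## Classifier and evaluation protocol

The reference classifier is the small all-sigmoid backpropagation network
5 → 5 → 6 → 4 → K on inputs $[I, q, u, v, \mathrm{DOP}]$ (intensity
z-scored from training statistics), trained 100 epochs on squared error
against one-hot targets. Mini-batch gradient descent uses learning rate 0.5
with classical momentum 0.9 (batch 32). The rate deserves a note: sigmoid
layers trained on squared error sit on a long flat plateau, and at rates an
order of magnitude smaller this topology does not leave it within 100
epochs — it classifies at chance while a margin classifier on the same rows
does not. An SVM comparator (`train_svm()`, radial kernel, cost 1,
untuned) runs on identical rows to check that conclusions about sampling
schemes do not hinge on the network.

Datasets are split 70/30 by *pulse*: all rows derived from one pulse land
on one side. A plain row shuffle would place near-identical neighboring
samplings of the same particle in both training and test for the dense
schemes, leaking identity information; `split_dataset()` exposes the
row-level mode for comparison but defaults to grouped.

Evaluation reports both row-level and pulse-level confusion matrices;
pulse-level predictions are the majority vote over a pulse's row
predictions, ties broken by the larger summed activation. Overall accuracy
is the confusion-matrix trace over the total; per-class one-vs-rest
accuracies $(TP+TN)/(TP+FP+FN+TN)$ are also reported. The one-vs-rest
form follows the standard confusion-matrix convention for TP/FP/TN/FN.
MSE is the mean squared difference between activations and one-hot targets.

Mixture composition (`predict_mixture()`) classifies each detected pulse by
majority vote and counts pulses per class; relative errors versus the
preset counts are reported under both conventions — |predicted−preset| /
preset (the headline) and |predicted−preset| / predicted, since both appear
in practice.

## The canonical comparison experiment

`run_scheme_comparison()` is the experiment the acceptance checks run: per
seed, one labeled pure-suspension trace per class (60 transits per class in
3 s at 200 kS/s), pulses detected once, then each scheme featurized, split,
trained and evaluated. Schemes keep their natural row counts (no cap by
default), so the per-sample scheme both trains on more rows within the
fixed 100 epochs and casts more votes per pulse — that asymmetry is part of
what "dense sampling" means, not a confound. Five seeds give the reported
means. On these conditions the pulse-level accuracy is non-decreasing
across PLP-Ave → PLP-4 → PLP-10 → PLP-100 → PLP-All with a dense-sampling
gain (PLP-All − PLP-Ave) of several tens of points, and the gain collapses
when orientation dynamics and noise are switched off — every sampling of a
static particle carries the same information, so the schemes tie. The
frozen-orientation control equalizes the row budget across schemes (one
row per pulse for the dense scheme) and uses 200 pulses per class so both
networks converge within the fixed 100 epochs; otherwise the
pulse-average arm would be data-starved and the check would measure
trainability rather than information. These sizes (60 pulses/class, 5
seeds for the main comparison) were chosen to give stable means on a
single workstation; the same function scales to larger runs.

```{r, eval = FALSE}
lib <- preset_class_library(c("DS", "CP", "CD", "PG"))
cmp <- run_scheme_comparison(lib, seeds = 1:5)
cmp
```

Mixture counting trains on 40 pulses/class (2,500-row/class cap) and
predicts a 4 × 100-pulse mixture over three seeds.

## Numerical choices and degenerate inputs

* **Unphysical Stokes states** (DOP > 1) arising from noise are flagged,
  never projected onto the physical cone — projection would bias the linear
  estimator. DOP values within 0.05 of 1 are clipped to 1 and counted;
  larger excesses keep their value and carry the flag.
* **Non-positive inverted intensity** cannot be normalized; such rows are
  dropped and counted (single-vector input errors instead).
* **Calibration** solves the least-squares system over at least four
  reference states (H, V, +45°, right-circular by default); rank-deficient
  state sets name the unspanned Stokes subspace in the error; condition
  numbers above a bound attach a warning flag.
* **Segment remainders**: deterministic front-loading (first `w mod k`
  segments one sample longer).
* **Pulses narrower than `k`** are skipped and counted by default; a `pad`
  policy falls back to one row per sample.
* **Ties in the majority vote** go to the class with the larger summed
  activation over the pulse's rows.
* **Seeds are mandatory** wherever randomness exists (simulation, splits,
  subsampling, weight initialization); there is no hidden global RNG use.

## Open choices made here

* The incident (PSG) state is configurable with right-circular default —
  circular illumination makes the rotation-invariant $v$/DOP structure of
  the class models explicit.
* Channel order is fixed as (0° linear, 45° linear, left-circular,
  right-circular) and recorded in file headers.
* Averaging happens in channel space (a switch to per-sample Stokes
  averaging is not provided; linearity makes the mean identical, and DOP of
  the mean is the intended semantics of an averaged row).
* Row-level and pulse-level accuracies are both reported wherever a scheme
  produces multiple rows per pulse; the pulse level is the headline, since
  particles, not samplings, are what a deployment counts.

## Known limitations

* The microalgal presets are stand-ins with documented parameters, not
  fitted to any organism; absolute accuracies on this generator should not
  be quoted as expected field performance.
* The BPNN is deliberately small and untuned beyond the documented
  defaults; it is the protocol's reference classifier, not a recommendation.
* Overlapping-pulse deconvolution is out of scope — the single-particle
  concentration condition excludes coincidences by design, and the
  simulator enforces it.
* At sampling rates or cutoffs where the filter window approaches the
  segment length, PLP-100 and PLP-All become informationally equivalent;
  the package documents rather than hides this interplay.
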