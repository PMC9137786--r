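---
title: "Glucose forecasting for virtual pediatric T1D patients: models, simulator and quantization emulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glucose forecasting for virtual pediatric T1D patients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cgmcast` implements a complete, reproducible study of 30-minute-ahead
continuous glucose monitoring (CGM) forecasting in pediatric type 1
diabetes, including the parts that are usually hidden inside proprietary
tools: the metabolic simulator that generates the virtual patients, and the
8-bit quantization arithmetic that a deployed edge model would run. This
vignette documents the models, the assumptions, every tunable parameter
that matters, and the numerical choices — it is the package's record of
*why* things are the way they are.

## 1. The forecasting task

Each model is a sequence-to-label regressor: the input is a 3 × 30 matrix
holding the last 30 minutes of three per-minute features — CGM glucose
(mg/dL), insulin-on-board (U) and ingested carbohydrates (g) — and the
output is a single scalar, the CGM value 30 minutes ahead. The feature row
order is fixed as (cgm, iob, carbs) throughout the package.

Insulin-on-board condenses recent dosing into the amount of rapid-acting
insulin still active, using a linear 3-hour action profile:

$$\mathrm{IOB}(t) = \sum_{i=0}^{179} \left(1 - \tfrac{i}{180}\right) u(t-i),$$

where $u$ is the delivered insulin per minute. Only past values enter the
sum, so the first 180 minutes of every simulated series are warm-up and are
excluded from modelling.

Data are split chronologically into contiguous train (70%), validation
(20%) and test (10%) blocks, per patient. A chronological split is the only
defensible choice for time-series forecasting — shuffled windows would leak
near-duplicate samples across blocks — and it is also what calibration of
integer quantization later requires (ordered data). Validation and test
sizes are floor-rounded with the remainder assigned to train.

## 2. The virtual-patient simulator

Real studies of this kind use a licensed metabolic simulator. The package's
generator is an open stand-in with a documented minimal-model core; it is
*not* a re-implementation of any proprietary product, and its purpose is to
produce realistic meal/bolus dynamics with known ground truth, not to be
physiologically exhaustive.

States (per patient): plasma glucose $G$ (mg/dL), remote insulin action $X$
(1/min), subcutaneous and plasma insulin $I_{sc}, I_p$ (U), and a
two-compartment gut $Q_1, Q_2$ (g):

$$
\begin{aligned}
\dot G &= -s_g (G - G_b) - X G + k_{carb}\, k_{abs} Q_2 \\
\dot X &= -p_2 X + p_2 s_i (I_p - I_{p,b}) \\
\dot I_{sc} &= u(t) - k_a I_{sc}, \qquad \dot I_p = k_a I_{sc} - k_e I_p \\
\dot Q_1 &= -k_{gut} Q_1, \qquad \dot Q_2 = k_{gut} Q_1 - k_{abs} Q_2
\end{aligned}
$$

Meals add their grams to $Q_1$ at the meal minute (the carbohydrate channel
records the impulse); boluses add units to $I_{sc}$; basal insulin is a
constant infusion folded into the same single insulin channel as the
boluses. Integration is fixed-step RK4 at the 1-minute output resolution,
which keeps the simulator exactly deterministic.

Two calibrations tie the physiology to the therapy parameters so that the
scenario protocol behaves sensibly:

* insulin sensitivity $s_i = \mathrm{CF} \cdot k_e / 140$, so that one
  bolus unit lowers glucose by roughly the patient's correction factor CF
  at mid-range glycemia;
* carbohydrate impact $k_{carb} = \mathrm{CF} / \mathrm{CR}$, so that the
  standard bolus calculator (carbs/CR + (G − target)/CF, clipped at 0)
  is near-optimal. Under optimal boluses the "ideal" scenario then stays
  close to euglycemia, as it should.

Population draws (fixed seed): carb ratio 10–20 g/U, correction factor
35–65 mg/dL/U, basal 0.5–1.2 U/h, target 110–130 mg/dL, body mass 25–55 kg,
$s_g \in [0.0015, 0.0025]$, $p_2 \in [0.010, 0.016]$,
$k_a \in [0.015, 0.025]$, $k_e \in [0.06, 0.08]$,
$k_{gut} \in [0.025, 0.045]$, $k_{abs} \in [0.012, 0.022]$ (all 1/min).
The $s_g$ and $p_2$ bands are at the insulin-dependent end of plausible
pediatric values; with stronger glucose effectiveness the restoring term
cancels most of the bolus-noise effect and the realistic scenario loses its
hypoglycemic tail, which is the clinically interesting regime.

**Scenario protocol.** Every day has five baseline meals — 45, 20, 70, 20,
80 g at 08:00, 10:30, 13:00, 17:00, 20:00 — each shifted by a uniform draw
of ±60 min and ±20 g (carbs clipped at 0; two meals landing on the same
minute re-draw the later shift). The *ideal* scenario delivers the optimal
bolus exactly and reads the sensor without error. The *realistic* scenario
perturbs every bolus by $\hat I = \max(0, I + z)$ with $z \sim U(-3, 3)$
units (delivered insulin cannot be negative) and adds CGM sensor error.
Under these defaults the realistic scenario shows both hypoglycemic
(< 70 mg/dL) and hyperglycemic (> 180 mg/dL) minutes for the population,
and strictly more out-of-range minutes than the ideal scenario.

**Sensor error.** The error model is additive AR(1) Gaussian noise,
coefficient 0.7, clipped to the CGM reporting range 10–600 mg/dL. The `sd`
parameter (default 2 mg/dL) is the *stationary* standard deviation of the
noise process (innovation sd $2\sqrt{1-0.7^2} \approx 1.43$); defining it
marginally makes "noise sd 2" mean what it says about the observed
cgm − true differences. AR noise mimics the strong lag correlation of real
CGM error; white noise would be too easy to average away.

**What the generator does not emulate:** exercise, stress, circadian
variability of insulin sensitivity, sensor dropouts and compression
artifacts, or the 13-state physiology and FDA-accepted parameter
populations of full metabolic simulators. Passing tests on this synthetic
population therefore demonstrates the *pipeline's* correctness and the
*relative* behavior of models and quantization modes — not clinical
performance on real patients. Absolute errors here are smaller than
published real-data figures because the stand-in dynamics are smoother.

## 3. The forecasters

**CNN.** Input 3 × 30 (× 1 channel) → convolution with 26 maps, 1 × 5
kernel, valid padding, ReLU → 1 × 2 max-pool → convolution with 20 maps,
1 × 5, ReLU → 1 × 2 max-pool → flatten (3 · 4 · 20 = 240) → dense 64, ReLU
→ linear output neuron. The 1 × k kernels slide along time only, so
convolutions mix timestamps within one feature row, never across features;
time lengths shrink 30 → 26 → 13 → 9 → 4. Valid (no) padding is the
simplest reading of a shrinking-stage architecture, and pooling
floor-divides odd lengths. The dense width (unstated in the reference
architecture, which tuned only kernel size and map counts) is fixed at 64
to mirror the LSTM head.

**LSTM.** The 30-step, 3-feature sequence feeds one LSTM layer (64 units,
standard gates, unit forget-gate bias) → dense 64, ReLU → linear output.

**Training recipe** (`train_control()` defaults): SGD with learning rate
1e-4, momentum 0.9, element-wise gradient value clipping at ±0.5, MSE loss,
mini-batches of 1400 samples (about one day of data), at most 200 epochs,
early stopping after 10 epochs without validation improvement with
best-weight restoration. The patience value is a conventional choice; the
early-stopping contract (never return weights worse than the best
validation epoch observed) is tested. Weight initialization is
Glorot-uniform, seeded; the seed is part of every experiment record, and
identical seeds reproduce identical weights.

**Grid search** (`grid_search()`): kernel ∈ {3, 5, 7}, first-layer maps ∈
{16, 26, 32}, second-layer maps ∈ {10, 20, 26} for the CNN; state and dense
widths ∈ {32, 64, 128} for the LSTM. Selection is by validation RMSE, ties
broken by fewer parameters, then grid order. Search is per patient
(precision-medicine style); the package reports per-patient winners and
does not assume a single global optimum.

**Engine.** No deep-learning framework is involved: forward, backward and
the optimizer are implemented in the package, with a pure-R reference
engine and compiled (RcppArmadillo) fused kernels that are
cross-checked against the R engine and against finite-difference gradients
in the test suite. The compiled path is used for training and plain
prediction; the R path carries the activation hooks that the full-integer
quantization emulation needs.

## 4. Quantization emulation

The package emulates two post-training 8-bit schemes at the arithmetic
level (per-tensor affine quantization with calibrated clamping). It does
not reproduce any vendor runtime byte-for-byte; the claims it supports are
about accuracy-degradation patterns, which this level of emulation
captures.

* **Dynamic range** (`quantize_dynamic()`): weight matrices stored as
  signed 8-bit with per-tensor scale/zero-point (the represented range
  always includes 0; an all-zero tensor gets scale 1 to avoid division by
  zero); biases stay float, activations are computed in floating point.
  Each dequantized weight is within one quantization step of the original.
* **Full integer** (`quantize_full_int()`): additionally, every inter-layer
  activation — model input, post-activation conv/dense outputs, LSTM hidden
  and cell states, and the output — is re-quantized onto an unsigned 8-bit
  grid whose range is calibrated as the min/max observed on a
  representative set. The representative set (`select_calibration()`) is
  the last 100–500 windows of train+validation *in chronological order*:
  ordered data are required because the task is a time series — a random
  subset can miss the recent activation ranges the model actually visits.
  A collapsed calibration range is widened by one step with a warning.
  Out-of-range activations saturate at 0/255; a wraparound switch exists on
  the output tensor only, to exercise the overflow reconstruction below.

**The uint8 output problem.** Glucose spans 10–600 mg/dL but uint8 spans
256 levels, so a full-integer output at 1 mg/dL granularity overflows above
255. Two remedies are implemented:

1. **Overflow reconstruction** (`reconstruct_overflow()`): post-process the
   predicted level series, adding back 255 where a wraparound must have
   occurred, using the physiological fact that glucose cannot drop 50 mg/dL
   in one minute. A boolean overflow state is maintained; elements at or
   above level 240 toggle it — off when the element sits ≥ 50 above its
   predecessor (exit), on when it sits ≥ 50 above its successor (entry) —
   and the toggling elements themselves are emitted unshifted, while all
   other elements gain 255 while the state is on. The printed form of this
   procedure computes the shift *after* the toggle, which would corrupt the
   boundary samples themselves (a true 250 at an overflow entry would
   become 505); the package implements the reading in which toggle elements
   pass through unshifted, because it is the unique reading that makes
   reconstruction an exact inverse of the subtract-255 wrap. That exactness
   holds on the admissible class — values in [10, 510] (single wrap),
   per-minute changes below 50 levels, and boundary crossings passing
   through a sample in [240, 255] — and is property-tested on 1,000 random
   admissible series. Boundary elements lacking the examined neighbour skip
   that check (the first/last element would otherwise index out of range).
2. **Level normalization** (`normalization_spec()`): remap 10–600 mg/dL
   affinely onto levels 0–255 before training, so the uint8 output can
   never overflow, at the cost of a prediction granularity of
   (600 − 10)/255 ≈ 2.31 mg/dL per level. (With 256 levels spanning the
   range the exact step is 590/255 = 2.3137; quoting "about 2.33" would
   correspond to a slightly different mapping — the spec of the affine map
   here is explicit and the step is configurable.) Encode/decode round-trip
   error is at most half a step; `encode(decode(k)) = k` for every level.
   The IOB and carbohydrate rows are remapped on fixed physiological ranges
   (0–20 U, 0–200 g).

## 5. Evaluation

`rmse()` implements the PH-shifted root-mean-square error in mg/dL.
`ceg_zone()` implements the Clarke Error Grid with the canonical piecewise
boundaries written out in one place (evaluated A, then E, then C, then D,
with B as remainder):

* **A**: |P − R| ≤ 0.2 R, or both below 70;
* **E**: R ≥ 180 & P ≤ 70, or R ≤ 70 & P ≥ 180;
* **C**: R ∈ [70, 290] & P ≥ R + 110, or R ∈ [130, 180] & P ≤ (7/5)R − 182;
* **D**: R ≥ 240 & P ∈ [70, 180], or R ≤ 70 & P ∈ [70, 180];
* **B**: everything else.

Zone assignment is a total function (every pair gets exactly one zone,
verified on the full 1-mg/dL grid over [10, 600]²), the diagonal is always
zone A, and ~30 boundary cases are pinned in the tests. Reports
(`build_report()`) give per-patient RMSE aggregated as population mean ±
*sample* standard deviation (n − 1 denominator — a documented convention),
and CEG percentages pooled over all test predictions of a configuration.
CEG is reported for the realistic scenario, where hypo/hyperglycemia
actually occur.

## 6. The scaled reference study

The full-size protocol (10 patients × 30 days, 200-epoch budget) and the
package's scaled reference study (3 patients × 10 days, 18 epochs) share
everything but size. The scaled study — used by the test suite and
`scripts/acceptance.R` — makes three deliberate choices:

* **Level-normalized features** (the 0–255 remap of Section 4), so one set
  of trained models serves the float, dynamic-range and full-integer
  comparisons, including the no-overflow claim.
* **Internal standardization + learning rate 0.05.** With ~8× fewer
  mini-batches per epoch than the full-size protocol, the reference recipe
  (1e-4 with clipped gradients) leaves the optimizer far from convergence;
  standardizing features and target inside the model and raising the rate
  restores a converged fit in 18 epochs. Predictions are always returned on
  the original scale, and the reference recipe remains the package default.
* **Reduced epochs (18, patience 10).** Chosen once for the problem size;
  both architectures comfortably beat the persistence baseline there.

On this study the expected pattern holds and is asserted by the tests: both
models beat persistence on every patient; pooled CEG A+B exceeds 90% (in
practice ≈ 100%); dynamic-range quantization changes RMSE by well under
1 mg/dL; full-integer quantization degrades more than dynamic-range but,
with level normalization, produces zero zone-E predictions.

## 7. Numerical and design notes

* **Determinism.** Every stochastic stage draws its seed from one global
  seed via integer arithmetic fan-out (no hashing dependency); simulator
  output, training, grid-search selections and reports are reproducible
  checksum-for-checksum. RNG state of the caller is never disturbed.
* **Online/offline equivalence.** `glucose_stream()` updates IOB through
  the same dot-product kernel as the batch path (exactly identical values)
  and forms the same windows; its per-minute predictions match batch
  predictions to ~1e-13 — the residual difference is BLAS accumulation
  order between batch-of-1 and batched matrix products, not arithmetic.
  The stream's first prediction appears after 210 minutes of history
  (180-min IOB warm-up + 30-min window); a gap in the minute sequence
  pauses the stream and restarts the warm-up.
* **Ties and degenerate inputs.** Max-pooling ties take the earlier
  element; grid-search ties prefer fewer parameters, then grid order;
  all-zero weight tensors quantize with scale 1; collapsed calibration
  ranges widen by one step with a warning; a diverging simulation
  (G > 1000 or < 1 mg/dL) aborts naming the patient and minute;
  non-finite training loss aborts with diagnostics.
* **Serialization.** All artifacts are text: per-minute CSVs and model/
  config archives in YAML with 17-significant-digit formatting, so
  round-trips are bit-exact.
* **Timing harness.** `measure_inference()` reports wall-clock per-window
  latency and asserts only the application bound — below the 60-s CGM
  sampling period — never hardware-specific numbers.

## 8. Known limitations

* The simulator omits circadian and behavioral variability (Section 2);
  absolute RMSE values are optimistic relative to real pediatric data.
* The quantization emulation is per-tensor affine fake-quantization; kernel
  fusion, per-channel scales and integer accumulator widths of specific
  runtimes are out of scope, and LSTM gate internals are computed in float
  between the quantized state tensors.
* Overflow reconstruction assumes a single wrap (true values ≤ 510 levels);
  values above that cannot be disambiguated with one 255-level shift.
* Per-patient models only: no transfer or population pre-training, and no
  online re-training after deployment (the test block is strictly
  subsequent data of the same patient).
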