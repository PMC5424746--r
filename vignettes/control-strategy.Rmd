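---
title: "Gesture classification and control strategy: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gesture classification and control strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgctl)
```

`emgctl` simulates a wearable myoelectric hand controller end to end. This
vignette is the package's account of the science inside it: the signal
model behind the synthetic generator, the classifier and its packed
representation, the finite-state control strategy, the transfer protocol,
and — importantly — which design parameters were genuinely open, what we
chose, and what the synthetic results do and do not say about real use.

## The signal model

Active surface-EMG sensors used in prosthetics deliver a rectified,
filtered and integrated *envelope* of the raw myoelectric signal, so the
classifier input needs no further feature extraction: each frame is simply
the vector of channel voltages. The simulation therefore operates directly
at the envelope level and models, per channel:

- a **rest baseline** of 0.05 V with additive Gaussian noise. The
  acquisition chain's statistics at rest are not documented for the sensor
  family we emulate; a small positive level is what a single-ended
  integrating front end produces in practice.
- a **gesture plateau**: a per-gesture vector of steady activation levels
  (V). The four default patterns (`default_profiles()`) are shaped after
  the muscles a 4-electrode forearm armband targets — extensor-dominant
  for hand opening, flexor-dominant for the power grasp, mixed for
  pointing and the precision grasp. The exact numbers are a modeling
  choice; what matters downstream is that patterns are distinct and their
  separation-to-noise ratio is controlled by one knob, `noise_sd`
  (default 0.15 V, the package's "healthy subject"; larger values emulate
  the more confused activation patterns of a compromised forearm).
- an **onset transient**: a raised-cosine ramp from baseline to plateau
  over `rise_time_ms` (default 200 ms). Only the *existence* of a
  rest-to-contraction transient is physiologically given; the integrator
  time constant of the analog front end is not published, so the ramp
  shape and duration are stand-ins. All channels ramp proportionally,
  which preserves the relative activation pattern during the transient —
  a favourable property real transients only approximate.
- **ADC constraints**: 500 Hz frame rate, hard clipping to the 0–3.3 V
  span, and (upstream of the stream representation) 16-sample averaging,
  exposed as `acquire_frame()`.

Sessions follow the experimental protocol: 3 s contractions separated by
3 s of rest, each non-open gesture followed by an interleaved open-hand
movement, so 10 repetitions of 3 gestures give 60 consecutive movements.

What the generator deliberately does **not** model: raw EMG synthesis,
motion-artifact physics beyond a rectangular additive spike, electrode
shift, fatigue drift within a session, and amputee-specific muscle
degradation (only `noise_sd` stands in for it). Passing tests on this
generator therefore demonstrate the *control strategy's* correctness and
robustness margins, not clinical accuracy on amputees.

## The classifier and its flash image

The classifier is a one-vs-one multiclass SVM with RBF kernel
`K(x, s) = exp(−γ‖x − s‖²)`. We store `γ = 1/(2σ²)` directly — one
symbol, one convention. For each ordered class pair (j, k), j < k, the
decision value is

> f(x) = Σᵢ Cᵢ K(x, sᵢ) − ρ₍ⱼₖ₎,

summed over the support vectors of the two participating classes only,
with pre-computed coefficients `Cᵢ = yᵢαᵢ`; `f(x) > 0` votes j, otherwise
k (so an exact zero votes the second class, consistent with the sign
convention that assigns positive margins to the first class). The
predicted gesture maximizes the vote vector; ties resolve to the lowest
stored class index. `train_model()` sorts training frames by gesture id
before calling the solver, so stored order equals ascending id and the
tie-break is stable and documented. Vote totals always equal
NCl(NCl−1)/2 — every pair votes exactly once.

Margin optimization is delegated to libsvm (via `e1071`), which is
standard practice; the *prediction path is our own* and is verified two
ways: against a brute-force evaluator written independently from the
decision-function definition (zero label disagreements over 200 random
models × 100 inputs), and against the solver's own predictions on
training data. Raw envelope voltages are classified without normalization
— the embedded pipeline feeds ADC means straight to the classifier — and
hyperparameters default to `cost = 1`, `gamma = 1/NF` (the solver's
convention) since no tuned values are published for this setup.

The packed model mirrors a static flash allocation: a 20-byte header
(magic, NF, NCl, γ, NS), per-class bookkeeping (4 bytes per class,
packed as int16 gesture id + uint16 SV count), the ρ block, a contiguous
row-major SV block and a contiguous column-major coefficient block, all
little-endian single precision. Model objects are quantized to single
precision at construction, so serialization, file round trips and
packet-level transfer are all bit-exact (`identical()`); decision sums
still accumulate in double precision. The footprint formula

> 20 + dtype·[NS·NF + NS·(NCl−1) + NCl(NCl−1)/2] + 4·NCl

equals the serialized length by construction; the largest healthy-subject
COMPLETE shape reported for this setup (404 SVs, 4 features, 4 classes)
packs to 11 372 bytes, inside a 12 kB flash budget.

## The control strategy

Prosthetic hands execute every grasp from the open (reset) position, so
hand state can be tracked without encoders. The FSM exploits this:

1. **Spike removal.** An activation measure (default: max over channels;
   mean and sum are available) must exceed `activation_threshold`
   (default 0.3 V) for 100 ms — 50 consecutive frames, boundary
   *inclusive*; one frame either way is physiologically irrelevant, so the
   boundary is pinned for testability. Shorter bursts are involuntary
   artifacts and leave the executed sequence provably unchanged.
2. **Voting.** Once triggered, every frame is classified (regardless of
   threshold dips — the transient is precisely when dips occur) and 20
   consecutive outputs are pooled by majority; the decision lands exactly
   40 ms after voting starts. The window is contiguous and non-overlapping:
   one decision per onset.
3. **Actuation.** The decided gesture drives its finger set (all fingers
   for the power grasp; thumb + index for precision; all but the extended
   index for pointing) until each motor stalls — fully open, fully closed
   or object-blocked — modeled as a constant-speed position integrator
   (full travel 0.5 s) with a two-level current curve and threshold stop.
   Only the threshold-stop *contract* is hardware-specified; the curve
   shape is a stand-in.
4. **Hold and reset.** After actuation the user may relax; the hand holds
   its configuration with no supra-threshold signal required (the
   anti-fatigue property). A decontraction (below 0.2 V; the 0.1 V
   hysteresis gap prevents chatter — neither threshold is published, both
   are configurable) re-arms the controller. From a held gesture the only
   reachable position is the reset: in REDUCED mode any subsequent
   contraction triggers it directly without classification; in COMPLETE
   mode the contraction is classified and only an open-hand decision
   moves the hand — anything else is deliberately ignored (the hand
   holds), which we treat as a no-op rather than an error state, and the
   controller records it as an unactuated decision episode. A direct
   gesture→gesture transition is never allowed, matching the mechanical
   reset constraint.

On noiseless sessions COMPLETE and REDUCED provably execute identical
movement sequences; REDUCED simply does it with a 3-class model (fewer
support vectors, smaller footprint, no open-hand classification risk).

## Transfer protocol

Models reach the node as 2 + NS packets (CONFIG, MODEL_PARAMS, one per
SV) under stop-and-wait: the gateway sends the next packet only after an
ACK and retransmits on NAK, up to 5 retries (no failure path is
specified for the real link; 5 is our bound). The checksum is a one-byte
two's-complement sum over header and payload — it detects every
single-byte corruption, which the tests verify exhaustively per byte
position — behind a small interface so a CRC-8 could be swapped in. Field
encodings equal the flash serialization, so an assembled transfer is
`identical()` to the sent model. Packet framing errors (corrupted length
fields) surface as undecodable deliveries and are NAK-equivalent.

## Evaluation and the metric

The gesture-level **end-to-end error** counts wrong movements over
intended movements, resets included: a wrong gesture is one error, a
missed movement one error, an extra movement one error. Alignment is by
order of actuation, with unactuated decision episodes reported as `NA`
placeholders so positional comparison never desynchronizes — a pinned,
deterministic reading of "count wrong gestures as executed". Accuracy is
the exact complement (their sum is 100 by identity). One error in 10
movements is a 10% error rate; one in 60 is 1.67% (reported at full
precision; printed two-decimal equivalences are matched to |Δ| ≤ 0.01).

Sample-level accuracy uses stratified k-fold cross-validation (k = 5
default; plain vs stratified was unspecified, stratified is the safer
default for 3–4 balanced classes). Folds are assigned after a canonical
row ordering, so the estimate is invariant to input sample order.

## Problem sizes and numerical choices

Training sets decimate plateau frames by `stride = 20` (25 Hz): 500 Hz
envelope samples are strongly autocorrelated, and a few hundred distinct
frames per class match the "few repetitions per gesture" calibration
workflow while keeping solver input well-conditioned. The default
experiment uses 4 training contractions per gesture, 60-movement
sessions (6 min of signal, 180 000 frames), and the headline synthetic
check averages 20 independently seeded subjects in REDUCED mode — a
problem size chosen to give a stable mean while a full run stays
comfortably interactive. Degenerate inputs are rejected loudly:
single-class training sets, empty vote buffers, out-of-span profile
levels, spikes outside the stream, mode/model class-set mismatches.

## Known limitations

The generator's favourable transient geometry (proportional ramps) and
i.i.d. noise mean the synthetic 0% error at the healthy profile is an
upper bound on what identical code achieves on real envelopes; the
package's claims are about the correctness, timing and robustness
properties of the control strategy, which are exactly what the test suite
pins down. Proportional force control, simultaneous multi-DoF control and
online/incremental training are out of scope by design.
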