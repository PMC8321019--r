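---
title: "Measuring tongue-tip velocity from dynamic MRI: models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring tongue-tip velocity from dynamic MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement problem

During a stop consonant such as /t/ the tongue tip rises, presses
against the alveolar ridge, holds through the stop closure, and releases
into the following vowel. Peak tip speeds during /tata/ are of the order
of 10–25 cm/s, with the whole gesture lasting a few hundred
milliseconds. `articuvel` implements two independent MRI routes to the
tip's velocity along a chosen spatial direction, plus the audio
synchronization and descriptive statistics needed to compare them:

1. **Real-time route.** An ungated fast acquisition in the mid-sagittal
   plane (≈20 ms per frame) is pre-filtered, a dense displacement field
   is estimated across the whole series by regularized registration, a
   user-selected tongue-tip point is propagated through the fields, its
   distance to the upper edge of an oblique reference slice is
   differentiated, and the result is a velocity in cm/s, positive
   upwards (towards closure).
2. **Phase-contrast route.** A velocity-encoded cine acquisition in an
   oblique slice perpendicular to the tip motion measures through-plane
   velocity directly: tissue velocity along the encoding direction is
   proportional to image phase, with ±VENC mapping to ±π. Decoding the
   12-bit phase payload and averaging over a magnitude-masked 5×5 ROI
   yields a velocity curve without any tracking.

Audio recorded simultaneously (16 kHz) provides the linguistic
landmarks: onsets and offsets of the two vowels (q1–q4), located by
envelope segmentation and aligned to the MRI clock through the scanner
noise ending and TTL-recorded stimulus pulses.

## Models

### Pre-filtering

Each real-time frame `I` passes through: background subtraction
`I' = I − 0.1·max(I)`; suppression of pixels not strictly above
`0.1·max(I')` (the defining inequalities are strict on both sides, so a
pixel exactly at the threshold is conservatively zeroed); a 3×3 median;
edge-preserving texture smoothing; and a 5×5 Gaussian with
`σ = radius/3 = 5/3`. All thresholds are relative, making the chain
invariant to positive intensity rescaling. The edge-preserving stage is
our interpretation of an operator whose original definition is not
public: pixels whose gradient magnitude reaches `edge_strength` (0.1)
times the maximal gradient are kept, the edge set is dilated by half
the minimal edge distance (3 px) so nearby edges merge, and everything
else is replaced by a 3×3 box mean. It is configurable so alternative
readings can be swapped in. Windowed filters use symmetric reflect
padding to avoid dark rims.

### Spatio-temporally regularized registration

The displacement field `u = (u_x, u_y)` over the whole series (one
field per frame transition, `N = Nx·Ny·Nt` unknowns per component)
minimizes

```
C(u) = S(u) + λ R(u)
S(u) = Σ_k Σ_p ( I_{k+1}(p + u_k(p)) − I_k(p) )²
R(u) = ‖(Gx, Gy, Gt/v0) u_x‖² + ‖(Gx, Gy, Gt/v0) u_y‖²
```

with `Gx, Gy, Gt` sparse forward-difference operators on the space–time
grid (replicated boundary) and `λ = 0.01`. The residual warps the
*successor* frame backwards, so `u_k(p)` is the forward motion of the
pixel at `p` — the convention point propagation needs; the literature
leaves the warp direction open and this choice is ours. The nonlinear
least-squares problem is solved by a multiresolution (3 levels, ×2)
Gauss–Newton scheme: image-gradient Jacobians, normal equations
`(JᵀJ + λLᵀL)δ = −(Jᵀr + λLᵀL u)` solved by Jacobi-preconditioned
conjugate gradients (tolerance 1e−6, ≤100 iterations), a backtracking
line search that keeps the cost non-increasing, and bilinear upsampling
(with displacement rescaling) between levels. A safeguard resets a
level's initialization to zero if the upsampled coarse solution costs
more than the zero field, so the returned field never costs more than
`u = 0`.

**The `v0` parameter.** `v0` sets the exchange rate between spatial and
temporal smoothness (pixels of spatial variation per frame of temporal
variation); no reference value exists. We default to `v0 = 5` px/frame
rather than 1: at 20 ms frames the tip moves up to ~2 px per transition
and accelerates from rest to peak within ~5 frames, so a v0 of order 1
penalizes the *genuine* acceleration of the gesture. On the phantom,
v0 = 1 clips recovered velocity peaks to ~60–75 % of truth while
pairwise (temporally uncoupled) registration recovers 95 %, isolating
the temporal term as the cause; v0 = 5 restores peaks to ~90 % while
keeping plateau noise suppressed. Both `λ` and `v0` are exposed.

### Velocity extraction

The tracked trajectory maps to patient coordinates through the slice
origin/orientation metadata, and the signed perpendicular distance to
the upper edge of the oblique slice (the plane offset by +thickness/2
along the up-positive normal) is differentiated by central differences
(one-sided at the ends). The edge choice (upper vs lower) shifts the
distance by a constant and leaves the derivative untouched. An optional
moving-average smoother exists but is off by default, keeping the
baseline faithful to "the derivative of the coordinate".

The phase-contrast decoder assumes a right-aligned 12-bit payload:
`φ = −π + code/(2¹² − 1)·2π`, `v = φ·VENC/π`. Per frame, ROI pixels
with magnitude below 5 % of that frame's maximum are excluded
(per-frame rather than per-series maximum, robust to intensity drift;
configurable); if all 25 pixels are masked the frame is reported
missing (`NA`), never zero, and the missing marker propagates to the
feature statistics.

### Features and statistics

Zero-velocity stop points t0–t5 are located by linear interpolation of
the sampled curve. Because the gesture holds true zero-velocity
plateaus at the closures, raw sign-change detection would fire
repeatedly inside noise; runs with `|v|` below a 0.5 cm/s floor are
collapsed to a single instant (midpoint of the floor-crossing edges, or
the exact-zero sample's time). A sub-floor run truncated by the window
start yields the movement onset t0; one truncated by the window end
yields the stop t5. Consequence of the floor: t0/t5 carry a bias of
order floor/acceleration (~10–15 ms on the phantom), while t1–t4
(plateau midpoints and trajectory extrema) are recovered exactly. A
1.56 s cine window inside a 2 s cycle cannot contain t5 at all; such
five-crossing repetitions keep t0–t4 and are excluded only from
statistics that need t5.

Peaks are the extrema of the sampled curve on (t1,t2), (t2,t3), (t3,t4)
— no re-interpolation — giving the characteristic (−, +, −) pattern.
Phase means are sample means of `|v|` over the same intervals (equal to
time-weighted means for uniform sampling). Timing statistics report
mean and sample standard deviation (n−1) of `q_i − t_i` in ms;
single-repetition aggregates omit the deviation.

## The phantom: what it emulates, what it does not

No subject data were deposited, so validation rests on a seeded
synthetic world with exact ground truth, generated from one closed
form: per 2 s cycle the tip rests 10 mm below the palate, rises to
contact, holds (/t/), descends 16 mm (/a/), re-closes (/t/), descends
again (/a/), and returns to rest. Transitions are quintic smoothsteps,
so the trajectory is C¹, plateaus are exact, and the analytic
derivative is available everywhere; the default 15 cm/s peak speed sits
inside the range reported for /tata/ gestures. The motion direction is
tilted 5° from the oblique slice normal, so the transverse-velocity
error obeys the 1 − cos θ law at a realistic slice-positioning
imperfection.

The real-time renderer draws a Gaussian-profile tongue blob whose
apex rides the true tip (3 mm intensity falloff above the apex — a
sharp air–tissue boundary — and 6 mm below), a static bright palate
band, temporal-average motion blur over each 20 ms window, and seeded
Gaussian noise (2 % of peak intensity). An early design with a 12 mm
below-tip falloff taught us a real lesson about the method: a strongly
one-sided intensity profile makes SSD matching systematically cheaper
when the estimate errs toward the shallow side, under-tracking upward
motion by ~8 % per phase and accumulating ~2 px of downward drift per
cycle. The published method's own automatic-vs-manual discrepancies are
consistent with boundary effects of this kind. The final profile keeps
the anatomy plausible while bounding the bias; the acceptance
thresholds themselves were never adjusted.

The cine renderer shows a tongue cross-section disc whose magnitude
dips (but stays above the 5 % mask) as the tip descends — a mild
partial-volume stand-in — with uniform tissue velocity codes and
uniformly random codes on near-zero-magnitude air, exercising the mask
rule. The audio renderer emits a 1 kHz beep per cycle, two 4 kHz
band-limited vowel bursts lagging the kinematic stop points by 50 ms
(matching the observed positive q−t differences), scanner noise with a
sharp ending, and TTL/generator timestamp channels.

Not emulated: k-space physics (radial undersampling, nonlinear
inversion artifacts), coil inhomogeneity, through-plane anatomy, real
articulatory variability between repetitions, eddy-current phase
offsets, and reverberant scanner acoustics. A green phantom test
therefore establishes correctness of the *computational pipeline* —
filtering, optimization, decoding, segmentation, statistics — not
robustness to every in-vivo artifact.

## Numerical choices and degenerate inputs

- Threshold tie (pixel exactly at 0.1·max): mapped to 0.
- Segment of exactly 0.1 s: rejected (strict inequality).
- Equal-level segments: all labelled speech, with a warning.
- All-masked ROI frame: `NA`, propagated, never interpolated.
- Zero peak speed: constant trajectory, all velocities zero.
- Velocity at VENC: rejected by the encoder unless aliasing is
  explicitly enabled, in which case the *phase* wraps by 2π (4095 code
  steps).
- Registration non-convergence: best iterate returned with a warning
  flag; cost never exceeds the zero field.
- The cine frame grid samples a ~200 ms transition every 35.52 ms, so a
  decoded peak can sit up to ~4–6 % below the continuous-time peak with
  a decode error of only one quantization step (VENC/4095 ≈ 0.007
  cm/s); recovery checks against ground truth on the same grid isolate
  decoder error from sampling, and this sampling effect is worth
  remembering when comparing cine peaks with higher-rate real-time
  peaks on real data too.

## Known limitations

- The registration under-tracks advancing tissue boundaries by a few
  percent — inherent to SSD flow at object boundaries; tracked peaks on
  the phantom recover ~90 % of truth, inside the 15 % acceptance band
  but not unbiased.
- The edge-preserving filter stage is an interpretation, not a
  reproduction, of the original (non-public) operator.
- The 12-bit payload is assumed right-aligned in its 16-bit container;
  left-aligned vendor variants need a shim at read time.
- Audio segmentation assumes pre-denoised speech; only a simple
  threshold/envelope path is provided, and manual marks can be supplied
  as CSV.
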