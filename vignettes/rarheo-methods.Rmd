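---
title: "Resonant acoustic rheometry: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resonant acoustic rheometry: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarheo)
```

# The measurement

Resonant acoustic rheometry (RAR) infers the viscoelasticity of a small
liquid or gel sample — ~100 µl in a well of a 96-well microplate — without
touching it. A focused ultrasound transducer below the well transmits a long
"push" tone burst whose radiation force perturbs the sample's top (air–sample)
surface, then switches to pulse-echo mode and fires a train of short
detection pulses. Each returned A-scan carries an echo from the surface;
as the surface oscillates, the echo's round-trip delay shifts by
$\Delta t = 2S/c$, where $S$ is the surface displacement and $c$ the sound
speed (1480 m/s by default). Tracking $\Delta t$ across the pulse train gives
the surface motion $S(\tau)$ on the *fast-time* grid
$\tau_n = n/\mathrm{PRF}$; repeating the whole measurement every
$\Delta T$ seconds gives the 2-D matrix $S(T_m, \tau_n)$ over *slow time*
— the observable from which everything else follows.

The perturbed surface rings at the resonant frequency of its fundamental
standing surface-wave mode. In a cylindrical well the wavenumber is fixed by
geometry, $k = \alpha/R$; the default mode constant $\alpha = 2.4048$ is the
first zero of $J_0$, i.e. the fundamental axisymmetric mode with a pinned
contact line. Which boundary condition a given well/sample combination
realises is genuinely open — a free contact line or a higher mode would give
a different constant — so `mode_constant` is a configuration field, not a
hard-wired number.

Two dispersion relations connect the resonant frequency to material
properties:

* **capillary waves** (liquid, restoring force = surface tension):
  $f_{CW} = \frac{1}{2\pi}\sqrt{\sigma k^3 / \rho}$;
* **Rayleigh waves** (soft solid, restoring force = elasticity):
  $f_{RW} = \frac{1}{2\pi}\sqrt{G k^2 / \rho}$.

Both are exactly invertible: `invert_surface_tension()` and
`invert_shear_modulus()` are the closed-form inverses and round-trip to
machine precision. The two branches cross at $G = \sigma k$; the package
treats the regimes separately (as the dispersion relations are stated) rather
than modelling a combined capillary–elastic relation — during the
liquid→solid transition neither limit is exact, and the extracted frequency
is reported as the primary observable precisely so users can apply whichever
inversion their regime justifies.

During coagulation the sample passes from liquid (capillary regime,
low frequency, light damping, large oscillation) to solid (Rayleigh regime,
higher frequency, strong damping, small oscillation). The kinetic signature
is a lag phase, a rapid frequency rise with concurrent amplitude/duration
collapse, and a plateau.

# The synthetic-data generator

No public RF datasets exist for this instrument class, so the package ships
a first-class simulator; every downstream stage is tested against its
planted ground truth.

**Echo model.** An A-scan is modelled as a gated RF record containing two
static plate echoes and one surface echo, each a Gabor pulse
$e^{-t^2/2w^2}\cos(2\pi f_c t)$ at the 5 MHz carrier with a −6 dB envelope
duration of 0.6 µs (the printed detection-pulse duration). The surface echo
is placed at delay $t_0 + 2S/c$ — evaluated *analytically* at the exact
continuous-time delay, not on an oversampled grid. Closed-form placement is
exact by construction, which is strictly tighter than any
oversample-and-decimate scheme and guarantees that sub-sample displacements
are never quantized into triviality for the tracking tests. Default gate
geometry places the plate echoes at 0.5/1.0 µs and the surface at 3.0 µs of
a 5 µs gate: the 2 µs clearance keeps static plate-echo energy out of the
±3-pulse-duration correlation window (closer spacing measurably biases the
correlation peak toward zero lag — "clutter bias" — which we observed as a
0.23 µm RMS systematic error before fixing the spacing).

**Trajectory.** A planted `coagulation_trajectory()` drives frequency,
amplitude and damping through a shared logistic in slow time, frozen at the
liquid state before `lag`:
$f(T) = f_{liq} + (f_{sol}-f_{liq})\,\mathrm{logistic}((T-T_{mid})/\mathrm{width})$,
with amplitude decreasing and damping increasing along the same schedule —
the three changes are concurrent in real clotting data. Defaults: f
100→300 Hz, lag 90 s, midpoint 120 s, width 10 s, amplitude 5→0.5 µm,
damping 20→150 1/s, noise 30 dB SNR (relative to the surface-echo peak),
chosen once to match the qualitative phenomenology of normal plasma: a
~90 s lag, a transition complete within a minute, a final stiffness in the
kPa range (300 Hz at the default geometry inverts to ≈6.5 kPa). Setting
`f_solid = f_liquid` (with matching amplitude/damping endpoints) produces a
non-clotting control.

**Per-push motion.** Within a measurement the surface moves as a damped
harmonic oscillation $S(\tau) = A(T)\,e^{-\beta(T)\tau}\sin(2\pi f(T)\tau)$,
sampled at the 10 kHz detection PRF for 500 pulses. Where the protocol's
printed detection window (0.1 s) and pulse count (500 at 10 kHz = 0.05 s)
disagree, the explicit pulse count wins; both are configurable.

**What the simulator does not model**: diffraction and focusing, attenuation,
speckle/clutter from within the sample, radiation-force magnitude, spatial
mode shapes (only the centre point is simulated, matching the single-point
measurement), digitizer quantization. Noise is additive white Gaussian
specified as SNR in dB. Passing tests therefore demonstrate the correctness
of the *signal-processing chain* under a faithful echo/kinematics model —
they do not validate robustness to beam misalignment, reverberation, or
non-Gaussian clutter in real recordings.

# Displacement tracking

Tracking is baseline-referenced: the `n_baseline = 20` pre-push scans are
averaged into a template (cutting template noise variance by the scan
count), the surface echo is auto-located as the *latest* envelope peak above
30% of the global maximum (the plate echoes arrive earlier), and each
detection scan is compared to the template by normalized cross-correlation
inside a window of ±3 pulse durations around the echo.

The correlation is normalized per lag by the energies of the overlapping
segments and computed via FFT with enough zero padding to be exactly linear
over the searched lag range (±16 samples by default); a brute-force
time-domain oracle pins this equality to 1e-9 in the tests. The integer-lag
peak is refined by three-point parabolic interpolation — chosen because it
needs no tuning and behaves well on a carrier-dominated correlation peak
(12.5 samples per carrier period at 62.5 MHz sampling; the analytic
interpolation bias is below 0.01 samples). Delays convert to displacement as
$S = c\,\Delta t/2$, positive = surface rising away from the transducer
(this sign convention is stamped into the container metadata).

Numerical behaviour, measured on planted signals: noise-free recovery is
exact to ≈0.08 µm RMS (parabolic residual bias); at 30 dB SNR the per-sample
error is ≈0.21 µm RMS, essentially at the matched-filter Cramér–Rao bound
for this pulse (≈0.20 µm). A correlation peak below the quality floor
(default 0.5) *flags* the sample rather than failing the run — hour-long
acquisitions must survive transient dropouts — and missing measurements
become all-NA rows so the displacement matrix stays rectangular.

# Spectral analysis

Each matrix row is mean-removed, zero-padded (×8 by default) and Fourier
transformed; the one-sided magnitude-squared spectrum is scaled so that the
unpadded spectrum sums to the trace energy (Parseval, asserted at 1e-6).
Mean removal is the only detrending: traces start at $S=0$ by construction,
and higher-order detrending risks distorting the low-frequency capillary
peaks. The peak frequency is refined by parabolic interpolation of
log-power around the maximum bin — skipped when the neighbouring bins sit at
the numerical noise floor, where interpolation is meaningless — and the
peak width is read off as the FWHM by linear interpolation at half the peak
power. The spectrogram normalizes each valid column to unit maximum (the
conventional display); raw power is retained alongside. The peak series is
median-filtered (window 3, killing single-column outliers) with masked gaps
linearly interpolated; monotonicity is deliberately *not* enforced.

Damping is estimated two ways. Primary: a linear fit to the log envelope
(modulus of the FFT-constructed analytic signal), trimmed at the record
edges and restricted to the first contiguous three decay constants — below
$e^{-3}$ of the peak, and again near the edges, the discrete envelope is
dominated by a leakage pedestal that flattens the tail and biases the slope.
Secondary cross-check: $\pi \cdot \mathrm{FWHM}$ of the spectral peak (the
Lorentzian line width). The two agree only when line broadening dominates
the observation window: for $\beta T_{obs} \gtrsim 3$ they match within
25%, while at $\beta T_{obs} \lesssim 1$ the rectangular-window mainlobe
($\approx 0.886/T_{obs}$) floors the measured FWHM far above $\beta/\pi$ —
a window limit, not an estimator defect, and the reason the time-domain
value is the one reported.

# Coagulation kinetics

From the tracked series $f(T)$:

* $f_{int}$ = mean over the first minute ($T \le \min T + 60$ s, closed
  window: 11 samples on the 6 s grid);
* $f_{end}$ = mean over the last five minutes ($T \ge \max T - 300$ s,
  closed window: 51 samples). Both windows are anchored to the *observed*
  grid rather than the nominal run length, which makes the sample counts
  well-defined, and both exclude masked points;
* $T_{int}$ = earliest $T$ with $f(T) \ge 1.05 f_{int}$ *sustained for the
  next consecutive sample* — the 5% figure alone would let a single noisy
  sample trigger the start, so the rule requires a 2-sample run
  (configurable);
* $T_{end}$ = earliest $T$ with $f(T) \ge 0.95 f_{end}$, likewise
  sustained; for a constant series this is degenerately the first sample;
* clotting duration $= T_{end} - T_{int}$; the final clot stiffness is the
  Rayleigh inversion of $f_{end}$.

Non-clotting samples (anticoagulated plasma may legitimately never clot in
an hour) return `NA` sentinels with `clot_detected = FALSE` — never an
error. Reported times are referenced to the first measurement; a
sample-preparation dead time can be added via `time_offset` for
trigger-referenced times, but is not added by default.

A practical noise limit worth knowing: once the oscillation amplitude has
collapsed (defaults: 0.5 µm against ≈0.2 µm per-sample tracking noise at
30 dB SNR, with the transient occupying only ~30 of 500 fast-time samples),
the per-column peak estimate jitters by ~10 Hz, and dividing by the
trajectory slope at the 95% crossing this translates to ±10–15 s of
irreducible $T_{end}$ jitter on the 6 s grid. $T_{int}$ is unaffected (the
oscillation is still large when clotting starts). Resolving $T_{end}$ to
one measurement interval requires either a stronger plateau oscillation,
higher SNR, or a steeper transition.

# Containers, configuration, reproducibility

Datasets live in an HDF5 container (`/meta` with the canonical-JSON config,
its MD5 hash and the seed; `/channels/<i>/` with RF arrays, truth,
displacement, spectrogram and parameters; every array carries its axis-step
attributes). Partial pipelines leave later groups absent; unknown extra
groups survive read–modify–write untouched; a schema-version mismatch is an
explicit error reporting both versions. Flat exports (parameter CSV/JSON,
heatmap and spectrogram figures) embed the config hash so outputs of
different configurations cannot be silently mixed. All simulation is
deterministic under a fixed seed, and the simulator restores the session
RNG state.

The command-line front end (`inst/cli/rar`) is a thin Rscript over the
exported functions with subcommands `simulate`, `track`, `analyze`,
`extract`, `report`, `pipeline`; exit codes are 0 (success), 2
(configuration error), 3 (stage failure).

# Problem sizes used in the tests

The test-suite simulations use 10–160 measurements (1–16 minutes of slow
time) with the full default fast-time protocol (20 baseline + 500 detection
pulses) where a stated bound depends on it, and lighter 64–256-pulse
protocols elsewhere; the multi-seed recovery check runs 20 independent
600 s acquisitions. These sizes were chosen as the smallest at which every
quantity under test reaches its asymptotic behaviour — the estimators are
O(M · N log N) in the measurement count M and trace length N, so the
results scale directly to full hour-long, 600-measurement runs.

# Known limitations

* Single dominant spectral mode: no multi-mode identification, no combined
  capillary–elastic dispersion across the transition.
* Constant, uniform sound speed; temperature drift is out of scope.
* The echo model carries no speckle/clutter or reverberation; quality
  flagging is exercised by synthetic dropouts, not by realistic artefacts.
* The $T_{end}$ noise limit in the collapsed-amplitude regime, above.
* Group-level statistics across samples are deliberately not implemented;
  the parameter tables are the tidy interface to external statistics tools.
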