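# rarheo — resonant acoustic rheometry in R

`rarheo` implements the full computational chain of resonant acoustic
rheometry (RAR), a non-contact ultrasound technique for monitoring the
viscoelasticity of small, temporally evolving samples — its flagship
application being real-time tracking of blood-plasma coagulation in the
wells of a standard 96-well microplate, several wells at once.

A focused transducer below each well emits a long "push" tone burst whose
radiation force perturbs the sample's top surface, then fires a train of
short pulse-echo detection pulses. The surface rings at the resonant
frequency of its fundamental surface-wave mode, and each echo's round-trip
delay shift encodes the instantaneous surface displacement, S = c·Δt/2.
For a liquid the resonance is a capillary wave,

    f_CW = (1/2π) √(σ k³ / ρ),

and for a soft solid a Rayleigh wave,

    f_RW = (1/2π) √(G k² / ρ),

with k = α/R fixed by the well radius and the resonant mode (α = 2.4048 by
default, the first zero of J₀). Measuring f therefore yields the surface
tension σ of a liquid or the shear modulus G of a gel — and following f
through clotting yields the coagulation kinetics: the initial and final
resonant frequencies (f_int, f_end), the clotting start time T_int (first
sustained 5% rise above f_int), the clotting end time T_end (first
sustained arrival at 95% of f_end), the clotting duration T_end − T_int,
and the stiffness of the formed clot via the Rayleigh inversion of f_end.

The package provides, as separately usable modules:

* **physics** — dispersion relations and their exact inversions,
  well/sequence objects, protocol timing arithmetic;
* **synthesis** — a deterministic multichannel RF pulse-echo simulator with
  planted coagulation trajectories (no public RF datasets exist for this
  instrument class; the simulator supplies ground truth for every stage);
* **tracking** — baseline-referenced normalized cross-correlation with
  sub-sample parabolic refinement, assembling the displacement matrix
  S(T_m, τ_n);
* **spectral** — power spectra, per-column-normalized spectrograms, peak
  tracking and damping (peak-width) estimation;
* **kinetics** — the threshold rules above, with non-clotting sentinels;
* **io** — an HDF5 container with config-hash provenance, a pipeline
  orchestrator, CSV/JSON/figure exports, and a CLI (`inst/cli/rar`).

## Worked example

Simulate a 10-minute single-channel coagulation run (logistic transition
100 → 300 Hz centred at 150 s after a 90 s lag, 30 dB SNR), run the full
pipeline, and read off the coagulation parameters:

```r
library(rarheo)

geom <- well_geometry()
geom
#> Well geometry: R = 0.00325 m, alpha = 2.4048
#>   density = 1000 kg/m^3, sound speed = 1480 m/s, k = 739.9385 1/m

cfg <- list(
  sequence = list(total_duration_s = 600),
  simulate = list(noise_snr_db = 30, channels = list(
    as.list(unclass(coagulation_trajectory(t_mid = 150, width = 20,
                                           lag = 90))))),
  seed = 42)

container <- run_pipeline(cfg)
#> [simulate] 1 channels x 100 measurements in 1.4 s
#> [track] channel 1: 100 x 500 matrix, median quality 0.992, 0.8 s
#> [spectral] channel 1: 100/100 valid columns, 0.0 s
#> [kinetics] channel 1: f 99.4 -> 299.1 Hz, clot T_int 90 s, T_end 198 s

container$channels[[1]]$parameters
#> Coagulation parameters:
#>   f_int = 99.37 Hz, f_end = 299.05 Hz
#>   T_int = 90.0 s, T_end = 198.0 s, duration = 108.0 s
#>   final shear modulus = 6448.6 Pa
```

The tracked resonant frequency sat near 100 Hz through the lag phase, began
its sustained 5% rise at T_int = 90 s, reached 95% of its final value at
T_end = 198 s (a 108 s clotting duration), and the 299 Hz endpoint inverts
to a clot shear modulus of ≈6.4 kPa. `write_rar(container, "run.h5")`
persists everything (RF, displacement, spectrogram, parameters, planted
truth) to HDF5, and `export_reports(container, "reports/")` writes the
parameter CSV/JSON plus displacement heatmaps and spectrograms.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/rar pipeline --config cfg.yaml --out run.h5 --outdir reports
```

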