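# tdsencode

Interval-wise linear encoding for temporal diffusion spectroscopy (TDS).

## The problem

Diffusion MRI with time-varying gradients measures the frequency-dependent
diffusion coefficient D(ω), a microstructural fingerprint of tissue.
Standard practice represents each measurement by a single attributed
frequency — 0 Hz for pulsed gradients (PG), the spectral centroid for
oscillating gradients (OG) — even though the true spectral response,
|Q(ω)|², has finite bandwidth and side lobes. Encodings assigned to the same
frequency can therefore yield different diffusivities, biasing spectrally
derived metrics.

`tdsencode` implements a more holistic representation for researchers
designing and analysing TDS experiments. Each measurement is represented by
its encoding power over N contiguous frequency intervals,

    ln(S0/Sm) = Σn Em,n Dn,   Em,n = (1/π) ∫ over interval n of |Qm(ω)|² dω,

so that M ≥ N spectrally distinct measurements form a linear system
S = E D, inverted with the pseudoinverse R = (EᵀE)⁻¹Eᵀ to give interval
diffusivities D̂ = R S. The package provides:

* **waveform synthesis** under amplitude/slew/duration constraints (PG,
  trapezoidal-cosine OG with matched/unmatched pulse polarities,
  double-bipolar), with q-trajectories, encoding spectra, b-values,
  centroid/FWHM diagnostics;
* the **encoding algebra**: interval schemes, E and R matrices, spectral
  response functions (SRFs), noise amplification σₙᴰ = σˢ√((RRᵀ)ₙₙ), and a
  voxel-wise tensor pathway producing per-interval MD/AD/RD;
* a **greedy experiment-design optimizer** that selects, from a library of
  feasible waveforms, the M encoding spectra minimizing
  (total noise amplification) × (total out-of-interval SRF power), by both
  prune-from-library and grow-from-best-pair variants;
* **theoretical diffusion spectra** (power-law dispersion; impermeable
  spheres in extracellular water) and a **simulation harness** comparing
  interval-wise estimation against single-frequency attribution in
  noiseless and Monte-Carlo noisy measurements.

## Worked example

Design a 7-measurement protocol for 10-Hz intervals up to 50 Hz under
whole-body-insert-grade hardware (Gmax = 200 mT/m, slew 600 mT/m/ms,
b = 1000 s/mm², encoding ≤ 90 ms), then estimate a power-law D(ω) from
noiseless synthetic measurements:

```r
library(tdsencode)
cn     <- tds_constraints()                       # 200 mT/m, 600 mT/m/ms, 1000 s/mm2, 90 ms
scheme <- interval_scheme(c(0, 10, 20, 30, 40, 50))
lib    <- build_library(cn)
#> <tds_library> 269 members (double_bipolar:40 OG_trapcos:167 PG:62), b=1000.0 s/mm2, 73 excluded

cache <- gram_cache(lib, scheme)
sel   <- select_best(greedy_prune(lib, scheme, cache),
                     greedy_grow(lib, scheme, cache, m_max = 12))
sys   <- system_from_library(lib, selected_set(sel, 7), scheme)
#> <tds_system> M=7 measurements, N=6 intervals, b=1000.0 s/mm2
#> noise amplification: 1.08 1.67 1.66 1.55 1.45 1.10

srf(sys)
#>  interval centroid_hz peak_hz fwhm_hz
#>   0-10 Hz        3.61    0.00    6.50
#>  10-20 Hz       15.13   14.27    9.38
#>  20-30 Hz       25.42   24.95    9.96
#>  30-40 Hz       35.99   34.71    9.39
#>  40-50 Hz       46.08   44.71    9.47
#>    50+ Hz       63.08   59.51   13.27

model <- tds_scenarios(1)$scenario1               # D0 + 8.5 um2/s^0.5 * sqrt(w)
S     <- vapply(sys$spectra, function(s) attenuation(model, s), numeric(1))
estimate_dspec(sys, S, sigma_s = 0.01)
#>  interval ref_freq_hz   D_mm2_s sd_mm2_s
#>   0-10 Hz        3.61 0.0007380 1.08e-05
#>  10-20 Hz       15.13 0.0007847 1.67e-05
#>  20-30 Hz       25.42 0.0008077 1.66e-05
#>  30-40 Hz       35.99 0.0008275 1.55e-05
#>  40-50 Hz       46.08 0.0008441 1.45e-05
#>    50+ Hz       63.08 0.0008683 1.10e-05
```

Reading the output: the selection concentrates each encoding's power in one
interval (noise amplification close to 1 at the band edges), the SRFs are
sharply confined to their intervals with centroids near the interval
centers, and the estimated diffusivities track the dispersive ground truth
(e.g. D(15.1 Hz) truth 7.83×10⁻⁴ mm²/s vs estimate 7.85×10⁻⁴) far better
than a 0-Hz attribution of the PG measurement would. `sd_mm2_s` propagates
a per-measurement noise of σˢ = 0.01 through R.

Voxel-wise application to fitted diffusion tensors (signal entries b·D per
measurement) goes through `tds_apply()` / `apply_to_tensor_series()`, which
append per-interval MD/AD/RD. The CLI wrapper exposes the same pipelines as
`design`, `simulate`, `apply` and `fixtures` subcommands.

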