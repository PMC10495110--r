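# dcvflux

Quantification of neuronal dense-core-vesicle (DCV) secretion, Golgi flux
and axonal transport from fluorescence time-lapse imaging — with a
synthetic-movie generator that provides ground truth for every stage.

DCVs carry neuropeptides and neurotrophins through the regulated secretory
pathway: biogenesis at the trans-Golgi network, microtubule transport along
axons, and activity-evoked fusion with the plasma membrane. Each step has a
standard live-imaging assay, and each assay needs a quantification
procedure that is rarely published as runnable code. `dcvflux` provides
those procedures as a tested R package, for cell biologists analyzing
NPY-pHluorin fusion recordings, RUSH (Retention Using Selective Hooks)
pulse-chase movies, or kymograph-based transport data — and for anyone who
wants to validate such a pipeline against movies with known ground truth.

## What it computes

**Fusion events.** pHluorin dequenches on fusion, so an event is a sudden
punctate rise in fluorescence. Traces from 3×3-px ROIs are normalized as
R(t) = F(t)/F₀ (F₀ = mean of the first 10 frames); with baseline mean and
SD (μ_b, σ_b) over the 30 s pre-stimulation window, an event is a maximal
run of the 3-frame median-filtered trace above μ_b + 2σ_b whose amplitude
exceeds 2σ_b over the local pre-run level and whose onset→peak rise is
completed within 1 s. Cumulative counts, per-window splits and mean peak
F/F₀ are summarized per neuron.

**Pool and released fraction.** A terminal NH₄Cl pulse dequenches all
vesicles; puncta in mean(NH₄Cl) − mean(pre) are counted after
difference-of-Gaussians band-passing (8-connected components), with
overlapping puncta corrected by the area quotient against the median
isolated-punctum area. Released fraction = evoked events / corrected pool.

**RUSH Golgi kinetics.** After phase-correlation drift registration, the
baseline-normalized Golgi-mask trace I(t) is fitted past its peak with
I(t) = plateau + (peak − plateau)·e^(−k(t − t_peak)), k > 0,
0 ≤ plateau ≤ peak, giving the time-to-peak and the first-order export
rate constant k (per min).

**Transport.** Kymographs (max over a 3-px perpendicular band along the
resampled neurite path) are traced by a deterministic greedy
nearest-neighbor tracker; tracks are classified anterograde / retrograde /
stationary by signed net displacement and speed = |net| / duration.

**Statistics.** SuperPlot-style nested comparisons (pooled t-test on
biological-replicate means), 2^−ΔΔCt qRT-PCR fold changes with statistics
on log2 FC, and EM morphometry derivations (volume change = 100·(1 −
(d_t/d_c)³); relative abundance changes; half-open diameter bins).

## Worked example

Simulate a neuron with 50 labeled vesicles, 4 evoked fusion events and an
NH₄Cl pulse, then run the full pipeline:

```r
library(dcvflux)
set.seed(1)
ev <- data.frame(punctum_id = sample(50, 4),
                 onset_s = c(33, 38.5, 44, 50),
                 peak_ratio = c(2, 2.5, 3, 2), rise_s = 0.4, decay_tau_s = 3)
sim <- simulate_fusion_movie(sim_config(image_shape = c(96, 96),
  n_puncta = 50, event_table = ev, nh4cl_window = c(100, 118),
  noise_gaussian_sd = 15, noise_poisson_scale = 2, rng_seed = 1))
res <- run_pipeline(sim$movie, pipeline_config(nh4cl_window = c(100, 118)))
res$summary
#> NeuronEventSummary: 4 events (pre 0 / stim 4 / post 0)
#>   mean peak F/F0 = 2.088
res$pool
#> PoolEstimate: 45 raw components, 50 after overlap correction (single-punctum area 21.0 px)
res$released$fraction
#> [1] 0.08
```

All 4 configured events are recovered, the 50-vesicle pool is counted
exactly after 5 merged pairs are split by the overlap correction, and the
released fraction comes back at the configured 0.08. A RUSH trace
round-trips the same way:

```r
rush <- simulate_rush_movie(k_true = 0.08, t_peak_true = 45, plateau = 0.1,
                            noise_sd = 40, rng_seed = 1)
fit_golgi_kinetics(golgi_trace(rush$movie, rush$golgi_mask, rush$biotin_frame))
#> RushKinetics: t_peak = 45.00 min, k = 0.0807 /min, plateau = 0.410 (RSS 0.00128)
```

(The fitted plateau is in peak-normalized intensity units; 0.41 of a
4.1-fold peak ≈ the simulated 10% residual.)

The numbered scripts under `analysis/` run each assay's validation study
and write tables to `results/`:

```sh
Rscript analysis/01_simulate.R          # example datasets with ground truth
Rscript analysis/02_fusion_detection.R  # detection recall / specificity
Rscript analysis/03_pool_released_fraction.R
Rscript analysis/04_rush_kinetics.R
Rscript analysis/05_kymograph_transport.R
Rscript analysis/06_statistics.R
```

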