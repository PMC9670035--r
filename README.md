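# restpisa

Residence-time analysis of PISA (proteome integral solubility alteration)
experiments: from reporter-ion intensities to drug–target dissociation
kinetics and a ranked target-prioritization score.

## The problem

Classical thermal/solubility proteome profiling answers *whether* a drug
engages a protein (a solubility shift, ΔSm, between drug- and
vehicle-treated samples), but not *for how long* the complex lives.
Residence time — the reciprocal of the dissociation rate constant — is
often a better predictor of in-vivo efficacy than affinity. Measuring PISA
repeatedly after drug washout turns the decaying shift into an
**off-curve**, from which kinetics can be fitted proteome-wide; pooling
all time points of a replicate into a single *compressed* sample
(cResT-PISA), and a concentration series into another (conc-PISA), gives
one-sample surrogates for residence time and potency that multiplex into
a single labeled set.

This package implements the complete analysis for such experiments and a
ground-truthed simulator of them, so every stage is verifiable by
parameter recovery. It is aimed at chemical-biology / proteomics groups
running washout PISA screens, and at methodologists studying the assay's
statistical behavior.

## The model

Engagement after washout decays with an asymptote:

    E(t) = (1 − b)·exp(−k_d·t) + b,     τ = 1/k_d

with `k_d` (1/h) the dissociation rate constant and `b ∈ [0,1]` the
non-recovering (covalent-like) fraction. The soluble pool at partial
occupancy is a two-state mixture, so the measured fold change over
vehicle is `FC(t) = 1 + (2^ΔSm − 1)·E(t)`. The analysis pipeline:

1. **Reporter extraction** — most intense peak in a closed ±20 ppm window
   around each channel's theoretical m/z; missing (never zero) for empty
   windows (`extract_reporters()`, `extract_batch()`).
2. **Shifts** — normalize each drug sample to its time-matched vehicle,
   equal-variance two-tailed t-test on log2 intensities, hits at
   |log2FC| ≥ 0.3 and p < 0.05 (`compute_shifts()`, `call_hits()`).
3. **Kinetics** — scale off-curves to the drug-maintained T0 mean,
   `S = (FC − 1)/(FC0 − 1)`; route to the exponential model when the
   last-time-point mean is below 0.6 (linear otherwise); bounded
   least-squares fit; per-replicate AUC as the model-free residence proxy
   (`fit_kinetics()`).
4. **Scoring** — scale compressed cResT/conc readouts to the reference
   PISA level, filter (replicate sd > 3× mean, or scaled values outside
   [0,1]), then sum three max-normalized components — |ΔSm|, conc-PISA,
   cResT-PISA — into a combined score in [0,3] and rank
   (`filter_targets()`, `combined_score()`).

## Worked example

Simulate a 100-protein experiment (30% true targets) at 5% measurement
CV and run every stage:

```r
library(restpisa)
cfg <- pipeline_config(n_proteins = 100, noise_cv = 0.05, seed = 1)
res <- run_pipeline(cfg)
res
#> <pipeline_result> 100 proteins; 30 T0 hits; 30 kinetic fits; 29 scored targets

kin <- res$kinetics
head(kin[order(-kin$residence_time_h),
         c("protein","model","k_d","b","residence_time_h","auc_mean","auc_norm")], 5)
#>    protein       model    k_d     b residence_time_h auc_mean auc_norm
#> 27   P0027 exponential 0.0829 0.390            12.07     4.11    1.000
#> 8    P0008 exponential 0.2766 0.394             3.62     3.33    0.811
#> 24   P0024 exponential 0.2902 0.304             3.45     3.06    0.744
#> 18   P0018 exponential 0.3073 0.200             3.25     2.69    0.654
#> 5    P0005 exponential 0.5884 0.000             1.70     1.62    0.394

head(as.data.frame(res$scores), 3)
#>   protein delta_sm sign alteration_score concentration_score residence_score combined rank
#> 1   P0002    1.060    1            1.000               0.812           0.533     2.34    1
#> 2   P0023    0.821    1            0.775               0.858           0.635     2.27    2
#> 3   P0008    0.932    1            0.879               0.611           0.760     2.25    3
```

Reading the output: `P0027` is the slowest unbinder the run detects — its
fitted dissociation rate of 0.083/h means a residence time of ~12 h, and
its AUC (sum of the scaled off-curve over {0, 1.5, 3, 7, 24} h) is the
largest in the set, hence `auc_norm = 1`. Its simulated truth was
`k_d = 0.119/h, b = 0.32`, i.e. the fit recovers slow kinetics from noisy
data to the precision the 5-point design supports. The top-ranked protein
`P0002` (planted ΔSm ≈ 0.97, EC50 ≈ 1.5 nM) wins on the combined score
because it pairs the largest solubility alteration with high potency and
a sizable residence readout. All tables land in `cfg$out_dir` as TSV when
that is set, together with a JSON run manifest.

Lower-level entry points (`simulate_offcurve_experiment()`,
`normalize_to_vehicle()`, `scale_profile()`, `fit_offcurve()`,
`compute_auc()`, `scale_compressed()`) expose each stage separately; the
vignette in `vignettes/rest-pisa-methods.Rmd` explains the model,
conventions and limitations in detail.

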