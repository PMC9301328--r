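# trfnet

Brain-network analysis of natural-speech EEG in source space, built around
temporal response functions (TRFs), for researchers studying how cortical
activity tracks continuous speech.

When listeners hear a story once (no repeated trials), single-trial EEG is
too noisy for source reconstruction.  This package implements a pipeline
that substitutes **cross-subject** averaging for trial averaging:

1. **Functional hyperalignment** — multi-set canonical correlation analysis
   (MCCA) finds per-subject spatial filters `w_i` maximizing the summed
   between-subject correlation, via the generalized eigenproblem
   `B w = λ R w` (`B`: between-set covariance blocks, `R`: block-diagonal
   within-set covariances).  Each subject is denoised by truncating to the
   leading canonical components and the reconstructions are averaged.
2. **Source reconstruction** — the sLORETA standardized minimum-norm
   inverse `T = Lᵀ(LLᵀ + αI)⁻¹` with per-source standardization by the
   resolution-matrix diagonal, then region-of-interest (ROI) time series as
   plain means over member sources.
3. **TRF estimation** — per-ROI ridge-regression encoders
   `x(t, ROI) = Σ_τ r(τ, ROI) s(t − τ)` on lags 0–800 ms, and a joint
   backward decoder reconstructing the envelope `s(t)` from all ROIs, with
   leave-one-out evaluation (Pearson r, Fisher z).
4. **Networks and communities** — Pearson correlations between ROI TRF
   lag-courses (2,278 edges for 68 ROIs), density thresholding with sign
   retention, and Louvain maximization of the asymmetric signed modularity
   `Q = Q⁺ − (v⁻/(v⁺+v⁻)) Q⁻` at resolution γ = 1.
5. **Scale selection** — a density scan (0.01–0.50) scored by the variation
   of information `VI = H(X) + H(Y) − 2 I(X;Y)` between partitions at
   consecutive densities, jointly with the k-means/F1 separability of the
   two listening conditions.

Because no public recordings accompany the method, the package ships a
seeded forward simulator (`make_ground_truth()`, `simulate_study()`) that
plants known community structure, response kernels, a smooth lead field and
per-subject electrode misalignment, so every stage is verifiable by
parameter recovery.  See `vignettes/methods.Rmd` for the models,
assumptions and design choices.

## Worked example

A reduced study (10 subjects, 20 trials of 6 s, 64 channels, 34 ROIs) runs
in well under a minute:

```r
library(trfnet)

cfg <- study_config(seed = 1, n_subjects = 10, n_trials_per_condition = 10,
                    duration_s = 6, n_channels = 64, n_sources = 250,
                    n_roi = 34, t_grid = seq(0.05, 0.5, by = 0.05),
                    scan_runs = 20, kmeans_reps = 200)
rep <- run_pipeline(cfg, verbose = FALSE)
print(rep)
#> Pipeline run report
#>   mean Fisher z by pathway: single_trial=0.492, naive_average=0.976, hyperaligned=1.031
#>   full-network separability F1: hyperaligned=0.664, single_trial=0.691
#>   condition A: density 0.15, Q 0.598, 5 communities
#>   condition B: density 0.15, Q 0.643, 6 communities
```

Reading the output: envelope reconstruction (mean Fisher z over
leave-one-out folds) already shows the ordering the method predicts —
single-trial decoding is poor, cross-subject averaging helps, hyperaligned
averaging helps more — and the signed-modularity communities sit in the
0.3–0.8 band that indicates real community structure.  Network-level
*condition separability*, by contrast, needs the full-size study: at 10
subjects both pathways' per-trial networks cluster near the
best-permutation chance level (~0.65), while at the default 21 subjects
the hyperaligned pathway reaches F1 = 0.97 against 0.63 for single-trial
networks (see the acceptance run below).

The numbered scripts under `analysis/` run the same stages at the full
default study size (21 subjects, 48 trials, 122 channels, 68 ROIs) and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate_study.R    # planted structure, study summary
Rscript analysis/02_hyperalign_decode.R # MCCA spectrum, decoding comparison
Rscript analysis/03_source_trfs.R       # TRF window statistics
Rscript analysis/04_networks_scales.R   # density scan, VI/F1, partitions
Rscript analysis/05_recovery_windows.R  # kernel recovery, window specificity
```

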