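# megmyelin

Cortical current estimates from MEG and myelin estimates from quantitative
MRI describe the same tissue from two sides: the apical dendrites of
pyramidal cells generate the currents that MEG sees, and their density
co-varies with local intracortical myelin. `megmyelin` implements, as a
tested R pipeline on synthetic data, the inference chain that links the two:

1. **Forward model** — the analytic field of a current dipole in a
   homogeneous conducting sphere (tangential sensitivity, radial silence),
   assembled into leadfields for quasi-uniform helmet arrays of
   magnetometers or axial gradiometers.
2. **Sensor-space preprocessing** — peak-to-peak artifact rejection
   (5 pT), trial averaging, zero-phase 20 Hz low-pass, baseline correction
   to the 100 ms before the noise-to-pitch transition, and peak picking by
   global field power.
3. **Variational-Bayes dipole fitting** — two equivalent current dipoles
   fitted simultaneously to the peak topography under Gaussian location
   priors (bilateral auditory means, sd 10 mm) and moment priors
   (0 ± 100 nAm per axis, no rank reduction), maximising a free energy
   F = accuracy − complexity; moment magnitudes are read off the
   minimal-variance plane of the posterior moment covariance.
4. **Quantitative-map handling** — R2\* estimation by log-linear
   regression over the 8-echo grid (2.39–18.91 ms), 3 mm FWHM Gaussian
   smoothing, GM (>0.2) and WM (>0.8) probability masks, 5 mm spherical and
   atlas ROIs, grey-matter-masked ROI averaging.
5. **The summed-correlation permutation test** — Spearman correlations
   between dipole moments and myelin estimates over 3 maps × 6 auditory
   ROIs, summed into one omnibus statistic
   `S = Σ_{map, roi} r_s(moment, myelin)`, with a one-tailed p-value from
   5000 random re-assignments of the hemisphere labels.
6. **Bayesian GLMs and family comparison** — variational linear models
   (moments ~ intercept + one standardised myelin regressor) whose free
   energies approximate log model evidence; spatial-extent comparison
   (TE1.2 vs whole koniocortex TE1 vs whole hemisphere) and family-level
   posteriors over ROIs (prior 1/6 each) and maps (prior 1/3 each).

A synthetic-data generator produces every input under a single seeded
configuration — sensor arrays, epochs from known dipoles, quantitative
volumes with realistic GM/WM means, multi-echo decays, and hemisphere
records with a controlled monotone myelin–moment association — and ships
the ground truth alongside, so every stage is testable by parameter
recovery.

## Worked example

```r
library(megmyelin)

cfg <- sim_config(seed = 101, association_rho = 0.9, n_hemispheres = 10,
                  n_channels = 64, n_trials = 8, snr_db = 10,
                  grid_shape = rep(32, 3), voxel_size_mm = 2)
res <- run_pipeline(cfg, n_perm = 500, n_restarts = 1)
res
#> <pipeline_result> stages: simulate, preprocess, fit_dipoles, roi_extract, stats, model_compare
#>   summed r = 17.78  permutation p = 0.002
#>   top ROI family: TE1.0 (0.1667) ; top map family: R1 (0.3333)

glance(res$dipole_fit)
#> # A tibble: 1 × 6
#>   free_energy variance_explained n_dipoles n_channels converged winning_restart
#>         <dbl>              <dbl>     <int>      <int> <lgl>               <int>
#> 1        3.52              0.990         2         64 TRUE                    1
```

With an association of 0.9 shared by every cell, the summed statistic
(17.78 of a maximal 18) is far outside its permutation null (p = 0.002 at
500 permutations, the add-one floor), and the two-dipole fit explains 99%
of the sensor variance at 10 dB trial-averaged SNR on a 64-channel array.
Because all 18 cells then carry the same information, the family
posteriors stay uniform (1/6 and 1/3). When the association is planted in
a single cell instead (R1 at TE1.2), they concentrate on that ROI and map:

```r
sim <- simulate_hemisphere_records(sim_config(seed = 60001,
                                              association_rho = 0.95),
                                   plant = "R1:TE1.2")
family_comparison(model_evidence_set(sim$records))
#> <family_posterior>
#>   ROI families:
#>     Patt    0.0000
#>     Post    0.0031
#>     TE1.0   0.0001
#>     TE1.1   0.0001
#>     TE1.2   0.9966
#>     TE3     0.0001
#>   map families:
#>     MT      0.0001
#>     R1      0.9967
#>     R2star  0.0032
```

The printed reference table of 18 Spearman coefficients from the study the
defaults emulate is shipped as data:

```r
summed_r(reference_correlation_table())
#> [1] 7.5637
```

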