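# gsbias

Resting-state global brain activity biases the rigid-body motion parameters
that fMRI pipelines estimate by intensity-based volume registration — and
then regress out of the data. `gsbias` implements, end to end on synthetic
multi-echo data with known ground truth, the detection of that bias, the
spatial mechanism behind it, and its downstream effect on functional
connectivity (FC). It is aimed at fMRI methods researchers who want a
testable, self-contained implementation of the two-echo bias statistic and
its analysis chain.

## The method

BOLD signal changes scale with echo time TE; head motion does not. Modeling
the motion estimate of one axis from echo *i* as

```
me_i = a_i * m_h + b_i * TE_i * gs + e_i        (a_1 ~ a_2)
```

the per-axis difference **dm = me2 − me1** cancels true head motion `m_h`
and isolates the BOLD-weighted global-signal (GS) bias `(b_2 TE_2 −
b_1 TE_1) gs`. The package:

- renders two-echo EPI-like runs from a mono-exponential signal law
  `S_i(v,t) = s0 exp(−TE_i [R2* − c(v) gs(t)])` with a GS coupling map
  `c(v)` whose superior–inferior / anterior–posterior asymmetry is
  controllable, plus rigid ground-truth motion and noise;
- estimates motion per echo by uniform-weight Gauss–Newton least squares
  (cubic interpolation, derivative-image Jacobian with steps 2.1 mm /
  0.4°);
- tests `r(dm, GS)` per run against an empirical null built from all
  `n(n−1)` cross-run pairings of GS and dm, Bonferroni-corrected across
  runs;
- approximates `r(dm, GS) ≈ (‖gs‖/‖dm‖) (β_e2ᵀ d_e2/‖d_e2‖² −
  β_e1ᵀ d_e1/‖d_e1‖²)` from GS beta maps and the registration derivative
  images, the broken-symmetry mechanism of the bias;
- quantifies the FC impact: ROI–ROI Fisher-z connectivity after e1- vs
  e2-based motion regression (censored at FD > 0.2 mm), its difference
  `dz`, FD-by-aGS group stratification with ANOVA and post-hoc t-tests,
  and a two-group permutation comparison with Cohen's d.

## Worked example

```r
library(gsbias)

# one biased run: superior/posterior-weighted coupling, low drift motion
run <- simulate_run(master_seed = 42, run_id = 1,
                    asym_coeffs = c(0.5, 0.5), motion_amplitude = 0.1)
pr <- process_run(run)   # registers both echoes, GS, dm, FD

pearson_r(pr$dm[, "Tz"], pr$gs)
#> [1] 0.4284197
sd(pr$dm[, "Tz"]); sd(unclass(pr$me1)[, "Tz"])
#> [1] 0.002684311
#> [1] 0.03941358
```

The Tz component of `dm` is an order of magnitude smaller than the motion
estimate itself, yet strongly correlated with the GS — the signature of
BOLD-weighted bias. The estimates themselves are accurate: against the
simulator's ground truth this run's echo-1 RMSE is at most 0.015 mm/deg per
axis and the recovered GS correlates with the true driver at r = 0.998.

At cohort level (20 runs, same conditions):

```r
ex <- run_bias_experiment(20, c(0.5, 0.5), master_seed = 7)
print(ex$bias)
#> Two-echo GS-bias detection over 20 runs
#> Bonferroni-corrected p threshold: 0.0025
#>                     Rx     Ry     Rz     Tx      Ty      Tz
#> median r(dm,GS) -0.015 -0.020 -0.031 -0.015   0.384   0.436
#> r threshold      0.232  0.216  0.213  0.209   0.235   0.207
#> % significant    0.000  0.000  0.000  0.000 100.000 100.000
```

Only the axes aligned with the coupling asymmetry (Ty, Tz) are flagged;
regressing the e1 motion regressors out first raises the median Tz
correlation from 0.436 to 0.464, the same direction the method reports on
real data.

The numbered scripts under `analysis/` walk the same pipeline as a
narrative: `01_simulate.R` (render runs to NIfTI), `02_register.R`
(recovery vs ground truth), `03_bias_detection.R` (permutation nulls and
percentages), `04_decomposition.R` (beta/derivative product maps),
`05_fc_impact.R` (FC attenuation and group effects). Each writes its tables
under `results/`.

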