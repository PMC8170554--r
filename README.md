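# rnflcomp

Covariate compensation of circumpapillary retinal nerve fiber layer
thickness (RNFLT) profiles, for researchers working on OCT-based glaucoma
detection in populations with a wide range of ocular geometry — myopic and
highly myopic eyes in particular.

The RNFLT profile (768 thickness values on a 3.4-mm circle around the
optic disc) is the workhorse biomarker for glaucoma, but its shape depends
on age, gender, axial length (AL), disc-fovea distance (DFD) and
disc-fovea angle (DFA).  Long eyes are thinner with temporally converged
bundle peaks, so against a one-size-fits-all normative band they look
diseased when healthy and their true defects hide in an inflated band.
`rnflcomp` removes the covariate-attributable deformation in two phases
before detection:

1. **Age** — a per-point relative loss field ρ with circular smoothness,
   fit in closed form by penalized least squares on log thickness
   (`log y[n,i] = mu[i] − rho[i]·(age − ref)`, penalty
   `lambda·Σ (rho[i−1] − 2 rho[i] + rho[i+1])²` with circular indices);
   compensation multiplies by `exp(rho[i]·(age − ref))`.
2. **Ocular geometry** — a small fully connected network maps
   (AL, DFD, DFA, gender) to a per-eye vertical log-scale `s` and circular
   shift `delta`, trained by minimizing the across-subject per-point
   variance of `exp(−s)·y(i + delta)` on healthy eyes; a radial basis
   function network then removes the remaining smooth covariate-correlated
   residual field `r[i](x) = Σ v[k,m]·phi_k(x)·psi_m(i)` via an exact
   ridge solve with eye-wise cross-validated shrinkage.

Detection uses the field-standard rule: score an eye by the longest
*circular* run of consecutive points strictly below the per-point
one-sided 95% normative limit, sweep the run length for the ROC, and
compare original vs compensated arms overall and in the longest-AL
percentile subgroups.  Because no suitable dataset is publicly deposited,
the package also ships a synthetic cohort generator with realistic
covariate marginals and effect couplings (see the methods vignette in
`vignettes/compensation-methods.Rmd`).

## Worked example

Simulate the default experiment (2223 training normals; 254 glaucoma +
254 normal validation eyes), train the compensator, and evaluate:

```r
library(rnflcomp)

train  <- generate_cohort(2223, 0,   seed = derive_seed(1, 1))
val    <- generate_cohort(254, 254,  seed = derive_seed(1, 2))
params <- train_compensator(train,   seed = derive_seed(1, 3))
evaluate_compensation(train, val, params)
#> evaluation_report (limits: empirical_p5 ; run threshold: 30 )
#>   top_10pct  n=  51  AUROC 0.753 -> 0.902  (gain +19.8%)  |comp| 9.83 um
#>   top_20pct  n= 102  AUROC 0.811 -> 0.899  (gain +10.8%)  |comp| 9.42 um
#>   top_30pct  n= 153  AUROC 0.883 -> 0.933  (gain +5.6%)  |comp| 9.08 um
#>   top_100pct n= 508  AUROC 0.938 -> 0.961  (gain +2.5%)  |comp| 8.38 um
```

Reading the report: each row is an axial-length percentile subgroup of the
validation cohort (`top_10pct` = the 51 longest eyes).  `AUROC a -> b`
compares glaucoma discrimination of the run-length detector before and
after compensation; `gain` is the relative AUROC increase in percent; and
`|comp|` is the mean absolute difference between compensated and original
profiles.  Compensation helps everywhere, helps most in the longest eyes
(+19.8% vs +2.5% overall), and moves long-eye profiles the most — exactly
the behavior the compensation is designed for, since covariate-driven
deformation concentrates in long eyes.

The same pipeline is available from the shell:

```sh
Rscript exec/rnflcomp simulate --dir out --seed 1
Rscript exec/rnflcomp train    --dir out
Rscript exec/rnflcomp evaluate --dir out   # writes out/evaluation.json
```

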