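# landmem

Ideal-observer modelling of landmark effects in visuospatial working memory.

When people memorize locations on a circle and later reproduce them, a
task-irrelevant but stable visual landmark makes recall more precise for
items in its vicinity — and when the landmark is covertly displaced between
study and test, responses are dragged in the direction of the displacement.
`landmem` is for researchers who want to model such continuous-report
localization data: it implements the cue-integration ideal observer that
accounts for both effects, the trial schedules of the four landmark
experiments used to probe them, and the estimation, model-comparison and
summary machinery around it.

## The model

The observer combines two independent estimates of the target location *x*:

- an **egocentric** estimate, mean *x*, precision *P*<sub>ego</sub>
  (rad⁻², independent of the landmark);
- an **allocentric** estimate anchored to the landmark, mean *x* (or
  *x + s* after a landmark shift *s*), with precision decaying exponentially
  with target–landmark distance *d*:

  *P*<sub>allo</sub>(*d*) = *A*<sub>max</sub> · exp(−*A*<sub>scale</sub> · *d*).

Fusion is by precision weighting:

  μ<sub>MLE</sub> = (*P*<sub>ego</sub>·μ<sub>ego</sub> + *P*<sub>allo</sub>·μ<sub>allo</sub>) / (*P*<sub>ego</sub> + *P*<sub>allo</sub>),  *P*<sub>MLE</sub> = *P*<sub>ego</sub> + *P*<sub>allo</sub>,

and the response follows a lapse-contaminated von Mises distribution,

  p(x̂) = (1 − λ)·ϕ(x̂; μ<sub>MLE</sub>, *P*<sub>MLE</sub>) + λ/2π.

Under a shift the predicted bias is *s*·*P*<sub>allo</sub>(*d*) /
(*P*<sub>ego</sub> + *P*<sub>allo</sub>(*d*)) — maximal at the landmark,
vanishing far from it — while response variability (median absolute
deviation) drops near the landmark and plateaus at the landmark-free level.
Models are fitted per participant by constrained maximum likelihood with
declarative parameter tying across conditions and set sizes, and compared by
AICc (full vs reduced no-allocentric vs egocentric-cost variants).

## Worked example

Simulate the shifted-landmark experiment (E3: 684 trials; 216 each of
LM-PRESENT, LM-GAP, LM-SHIFT and 36 LM-ABSENT), fit the observer, and test
whether the allocentric component is needed:

```r
library(landmem)

dat <- simulate_responses(generate_design("E3", seed = 11),
                          default_cell_params("E3"), seed = 12)
fit <- fit_observer(dat, n_starts = 10, seed = 13)
fit
#> Observer model fit (S01): logLik 120.58, k = 4, n = 684, AICc -233.10
#>   p_ego[ss4]   a_max[ss4] a_scale[all] p_lapse[ss4]
#>      43.7466     229.7788       9.9216       0.0623

red <- fit_observer(dat, tying_reduced(dataset_cells(dat)),
                    n_starts = 5, seed = 14)
compare_fits(list(red), list(fit))$delta_aicc
#> 20.23   # positive: AICc favours the full (allocentric) model
```

The fitted egocentric precision (43.7 rad⁻², generating value 45) sets the
far-from-landmark error floor; the allocentric peak and decay rate describe
a benefit confined to the landmark's neighbourhood; the lapse rate (0.06)
absorbs random responses. The binned summaries show the two signatures —
variability that rises with landmark distance up to the landmark-absent
level:

```r
s <- binned_summary(dat, fold = TRUE)
subset(s, condition == "LM_PRESENT" & bin_center_deg %in% c(0, 90, 180))
#>   condition set_size bin_center_deg  n bias_deg mad_deg
#>  LM_PRESENT        4              0 18     0.93    4.08
#>  LM_PRESENT        4             90 36    -1.14    6.72
#>  LM_PRESENT        4            180 18    -1.97    6.99
subset(s, condition == "LM_ABSENT")
#>   condition set_size bin_center_deg  n bias_deg mad_deg
#>   LM_ABSENT        4             NA 36      0.6    5.95
```

and, in LM-SHIFT, a response bias toward the displaced landmark that decays
with distance (shift magnitude 6°; the model's peak prediction is
`predicted_bias(0, deg2rad(6), default_params(4))` = 4.8°, i.e. 80% of the
shift):

```r
ss <- binned_summary(dat, shift_align = TRUE)
subset(ss, condition == "LM_SHIFT" & bin_center_deg %in% c(0, 15, 90))
#>  condition set_size bin_center_deg  n bias_deg mad_deg
#>   LM_SHIFT        4              0 18     5.22    4.48
#>   LM_SHIFT        4             15 36     3.57    4.64
#>   LM_SHIFT        4             90 36     0.48    4.39
```

See the vignette (`vignettes/landmark-observer.Rmd`) for the model's
assumptions, the design generators, the tying/AICc machinery and all
numerical choices.

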