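# crowdmix

Mixture-model analysis of orientation-report errors in visual crowding.

In continuous-report crowding experiments an observer estimates the
orientation of a peripheral target presented either alone or surrounded by
four flanker shapes that jointly form a *global configuration* (e.g. an
illusory rectangle) with its own orientation. The distribution of report
errors on the 180°-periodic orientation circle then mixes several sources:
reports of the target, random guesses, misreports of a flanker's (local)
orientation, and misreports of the global-configuration orientation.
`crowdmix` decomposes that distribution with three nested probabilistic
models and a matching statistical pipeline.

## Models

With θ the target orientation, θ̂ the report, φᵢᴸᵒᶜ the four flanker
orientations (diagonally paired, m = 4) and φᴳˡᵒ the global orientation,
and φ_σ a von Mises density (mean 0, SD σ) on the orientation circle:

- **Standard Mixture** (2 parameters γ, σ):
  p(θ̂) = (1 − γ)·φ_σ(θ̂ − θ) + γ/180
- **Local** (3 parameters, + βᴸᵒᶜ):
  adds βᴸᵒᶜ·(1/m)·Σᵢ φ_σ(θ̂ − φᵢᴸᵒᶜ)
- **Global–Local** (4 parameters, + βᴳˡᵒ):
  adds βᴳˡᵒ·φ_σ(θ̂ − φᴳˡᵒ)

The target-report rate is P_T = 1 − γ − βᴸᵒᶜ − βᴳˡᵒ. Periodicity is
handled by angle doubling (x → 2x maps the orientation circle onto the
standard circle), so σ is expressed directly in degrees of orientation.
Models are fitted per observer × condition by multi-start maximum
likelihood and compared with AICc; a control fit places the global
component at the orientation perpendicular (+90°) to the true global
configuration, where its rate should collapse to zero. Group-level
inference uses repeated-measures ANOVAs with Greenhouse–Geisser correction,
Bonferroni pairwise comparisons, and paired t-tests with Cohen's d.

A synthetic-data generator emulates the experimental design (orientations
drawn from 180 values between 1° and 180°, flankers rotated in diagonal
pairs, global orientation varying independently, 27 observers × 200 trials
per condition) so the whole pipeline can be exercised without any external
download.

## Worked example

```r
library(crowdmix)

# simulate a small study: 5 observers, 150 trials per condition
cfg <- design_config(n_observers = 5, trials_per_condition = 150, seed = 42)
ds  <- gen_dataset(cfg)

# fit one observer's flankers-aligned trials with the full model family
cell <- subset(ds$trials, observer == "obs01" & condition == "FA")
fits <- fit_models(cell, models = c("standard", "local", "global_local"),
                   seed = 1)
fits$global_local
#> MLE fit: global_local model, n = 150 trials
#>   gamma = 0.0158  sigma = 6.88 deg  beta_loc = 0.1211  beta_glo = 0.0953
#>   logLik = -601.81  AICc = 1211.89  (best start 1/21, converged)
compare_models(fits)
#> # A tibble: 1 × 4
#>   delta_gl_std delta_gl_local winner       tie
#>          <dbl>          <dbl> <chr>        <lgl>
#> 1        -33.7          -25.6 global_local FALSE
```

`gamma` is the guessing rate, `sigma` the report variability in degrees,
`beta_loc`/`beta_glo` the local and global misreport rates. The negative
AICc differences mean the Global–Local model fits this observer better than
both nested alternatives even after its extra parameters are penalized.

The full pipeline (descriptives, all fits, model comparison, group tests,
perpendicular control, report files) is one call:

```r
report <- run_pipeline(ds$trials, seed = 1, out = "analysis_out")
report
```

A thin command-line launcher with `simulate` / `fit` / `analyze`
subcommands is installed at `inst/scripts/crowdmix`.

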