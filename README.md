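# avrabbit

Bayesian causal inference (BCI) modeling of audiovisual numerosity
perception in the "audiovisual rabbit" paradigm, where beeps change how
many flashes people see: an extra beep can conjure an illusory flash
(`F2B3`), and a missing beep can hide a real one (`F3B2`). The paradigm
contrasts stimuli swept across the retinal blind spot with a matched,
fully visible control location, asking whether perceptual filling-in
changes how the brain binds sound and vision.

The package is for researchers who want to fit and validate the BCI
observer model on trial-level count reports: it provides the generative
model, maximum-likelihood fitting with BIC model comparison across four
model variants and three decision strategies, signal-detection and
behavioral summaries, and a synthetic-data generator that emulates the
full factorial design so that the entire pipeline is testable by
parameter recovery.

## The model

Flashes and beeps produce noisy sensations
`x_V ~ N(s_V, sigma_V)`, `x_A ~ N(s_A, sigma_A)`. The observer combines
them with a Gaussian numerosity prior `N(mu_p, sigma_p)` and a causal
prior `p_common` over whether the two streams share one cause. The causal
posterior follows from Bayes' rule with closed-form likelihoods; estimates
under common/independent causes are reliability-weighted averages; a
decision strategy (model averaging, model selection, or probability
matching) produces the final continuous estimate, which is binned into
the reported count (0-5). Model variants fix parameters: forced fusion
(`p_common = 1`), full segregation (`p_common = 0`), and MLE
(`p_common = 1` with a flat prior, `sigma_p = 4000`, `mu_p = 1.5`).

## Worked example

Simulate one observer from the representative across-blind-spot
parameter set, look at the model's predicted response distribution for
the illusory-rabbit condition, and refit the model:

```r
library(avrabbit)

params <- reference_observer_params("across_blind_spot")
params
#> BCI observer parameters:
#>   p_common = 0.5  mu_p = 1.9  sigma_p = 1.19  sigma_v = 2.35  sigma_a = 0.21

predict_response_distribution(stimulus_condition(2, 3), params,
                              "model_averaging")
#> Predicted response distribution (F2B3, model_averaging):
#>          0     1     2     3     4 5
#> visual   0 0.033 0.545 0.422 0.000 0
#> auditory 0 0.000 0.011 0.985 0.004 0

trials <- simulate_participant(
  list(across_blind_spot = params, control = params),
  strategy = "model_averaging", seed = 101)
nrow(trials)
#> [1] 480

illusion_frequency(trials)
#>   participant          location illusory_rate invisible_rate
#> 1         P01           control          0.35           0.90
#> 2         P01 across_blind_spot          0.40           0.95

fit <- fit_model(trials, model_variant("bci"), "model_averaging",
                 n_starts = 10, seed = 201)
fit
#> BCI fit: variant = bci, strategy = model_averaging
#> BCI observer parameters:
#>   p_common = 0.4998  mu_p = 1.96  sigma_p = 1.435  sigma_v = 3.7  sigma_a = 0.1852
#>   nll = 155.488  k = 5  n = 400  BIC = 340.933  R2 = 0.9942  converged = TRUE
```

The predicted `F2B3` visual distribution puts 42% of responses on "3"
although only two flashes were shown — the illusory rabbit — while the
auditory reports stay veridical; the simulated observer reports the
illusory third flash on 35-40% of `F2B3` trials and misses the middle
flash on 90-95% of `F3B2` trials. The refit recovers the causal prior, prior
mean and auditory noise closely; the visual noise s.d. is the one weakly
identified parameter at this trial count (see the vignette's discussion).
`compare_models()` runs all variant-by-strategy fits and flags the
minimum-BIC winner, and `sdt_summary()`, `accuracy_by_condition()`, and
`position_distribution()` produce the standard behavioral summaries.

A YAML-configured end-to-end pipeline (simulate -> fit -> report) is
available as functions (`pipeline_simulate()`, `pipeline_fit()`,
`pipeline_report()`, `pipeline_recover()`) or via the thin wrapper
`scripts/rabbit_pipeline.R`.

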