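# hierbias

Temporal biases in evidence integration from approximate hierarchical
inference — simulation, estimation, fitting, and attribution.

## The problem

In sequential perceptual decisions (ten evidence frames, one binary
choice), observers often weight frames unequally over time: a **primacy**
effect (early frames dominate) or a **recency** effect (late frames
dominate). `hierbias` implements a computational account in which the
direction of the bias is determined by how a task splits its information
between two levels of a hierarchical generative model
\(C \to x_f \to e_f\):

- **category information** — how well one frame's latent feature \(x_f\)
  predicts the category \(C\) (the per-frame match probability
  \(q \in [0.5, 1]\));
- **sensory information** — how well one evidence sample \(e_f\) determines
  its feature (\(\Phi(2/\sigma_e) \in (0.5, 1)\)).

Approximate hierarchical observers that feed their current categorical
belief back into sensory inference under-correct for that feedback, which
self-reinforces early beliefs — a *confirmation bias* that produces primacy
when category information is high (LSHC regime) and gives way to
leak-driven recency when it is low (HSLC regime). The package provides:

- observer simulators: exact ideal observer, importance-sampling observer,
  mean-field variational observer, and an Extended integration-to-bound
  (ITB) accumulator \(LPO_f = (1-\alpha)LPO_{f-1} + LLO_f + \epsilon_f\)
  with sticky bound \(\pm B\) and lapse/temperature choice rule;
- psychophysical-kernel estimation (`fit_weights`): free logistic
  regression with ridge/curvature penalties, and exponential
  (\(w_f = a e^{\beta f}\)) or linear shape-constrained fits, with
  bootstrap slope intervals and cross-validation;
- exact-likelihood Bayesian fitting of the seven ITB parameters by
  Metropolis–Hastings (`fit_itb`), using discretized propagation of the
  accumulator distribution (bins \(\le 0.01\)) instead of stochastic
  likelihood estimates;
- mechanism attribution (`ablation_analysis`): posterior-predictive
  re-simulation with the leak or the bound ablated, and a hierarchical
  zero-intercept regression whose slope yields an **ablation index**
  (1 = the ablated mechanism carried the temporal bias, 0 = it did not);
- a synthetic-data module that calibrates ground-truth observers to the
  reference criteria (70% accuracy; slope \(\beta = -0.1\) in LSHC,
  \(+0.1\) in HSLC) and sweeps accuracy/bias maps over the task space.

## Worked example

Calibrate a bounded-integration ground truth, simulate choices, estimate
its temporal weights, and fit the Extended ITB model back:

```r
library(hierbias)

spec <- calibrate_ground_truth(ground_truth_spec("itb", "LSHC"))
spec
#> Ground-truth spec: itb / LSHC (targets: accuracy 0.70, beta -0.10)
#>   resolved: category_info = 0.9000, sensory_info = 0.7019
#>   itb: bound = 0.922, leak = +0.100, noise = 0.150

data <- generate_choice_dataset(spec, 2000, seed = 1)
data
#> Choice dataset: 2000 trials x 10 frames (model = itb, LSHC)
#>   accuracy: 0.707

fit_weights(data, shape = "exponential")
#> Temporal weights (exponential fit, 2000 trials x 10 frames)
#>   normalized weights: 1.468 1.337 1.218 1.110 1.011 0.921 0.839 0.764 0.696 0.634
#>   slope beta = -0.0932 (primacy)
#>   log-likelihood: -700.06
```

The observer performs at ~70% and over-weights early frames (primacy,
\(\beta < 0\)) — here produced mechanically by its small absorbing bound
\(B \approx 0.9\): once the accumulator sticks, later frames are ignored.
A short MH run recovers that mechanism from the choices alone:

```r
task <- spec$resolved$task
set.seed(7)
fit <- fit_itb(data, task$category_info, n_chains = 2, n_steps = 150,
               n_adapt = 50, n_scan = 100,
               logodds_signals = 2 * data$signals /
                 (task$sigma_x^2 + task$sigma_e^2))
round(coef(fit), 3)
#> category_prior          lapse    temperature          noise          bound
#>          0.509          0.015          0.066          0.154          0.916
#>           leak   signal_scale
#>          0.107          1.000
```

The posterior medians put the bound near its true value 0.92 — far below
the Gamma(2, 3) prior median of about 5 — with a small positive leak: the
fit attributes the primacy to bounded integration, not to a confirmation
bias (negative leak). `ablation_analysis` formalizes that attribution
across a cohort of such fits.

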