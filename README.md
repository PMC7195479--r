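# divnorm

Dynamic divisive normalization as a model of perceptual evidence
accumulation, with the drift-diffusion-family competitors it is compared
against.

## The problem

In pulse-based perceptual decisions — here, a fixed-grid auditory clicks
task (20 clicks over 1 s, one every 50 ms, each landing on the "correct" ear
with probability 0.55) — people do not weight all evidence equally. The
weight each click carries, the *integration kernel*, varies across
individuals: some overweight early clicks (primacy), some late clicks
(recency), some weight evenly (flat), and many weight the middle of the
stimulus most (a bump). This package implements a circuit model in which all
four phenotypes arise from one mechanism: two excitatory pools `R_left`,
`R_right` (leak time constant `τ_R`) integrating the click streams, divisively
inhibited by a gain unit `G` (time constant `τ_G`, drive weight `ω_I`):

    τ_R dR_i/dt = −R_i + C_i / (1 + G)
    τ_G dG/dt   = −G + ω_I (R_left + R_right)

The decision variable `δ = R_left − R_right` admits an analytic per-click
kernel, `K(T, t_i) = (1/τ_R) · exp(−(T−t_i)/τ_R) / (1 + G(t_i⁻))` — a rising
exponential (the leak forgets early clicks) times the falling `1/(1+G)`
(inhibition discounts late clicks). Choices follow
`logit(p_left) = δ′(T)/σ + bias` with `δ′(T) = Σ_i (K_i + μ)·sign_i`, giving
a six-parameter observer (`τ_R, τ_G, ω_I, σ, μ, bias`). The balance
`τ_R/τ_G` moves the kernel through primacy → bump → flat → recency.

The package is aimed at researchers modelling pulse-based decision tasks
who want to simulate this task and observer family, estimate model-free
kernels by logistic regression, classify kernel phenotypes, fit the
divisive-normalization observer and its competitors — basic DDM, the leaky
competing accumulator (LCA), a bounded accumulator with per-side sensory
adaptation solved by Fokker–Planck density propagation — by multi-start
maximum likelihood, and compare them with AIC/BIC.

## A worked example

```r
library(divnorm)

protocol <- task_protocol()      # 20 clicks / 50 ms / 1 s / p = 0.55
observer <- divnorm_params(tau_R = 1.596, tau_G = 6.5, omega_I = 1.2,
                           sigma = 0.05, mu = -0.32, bias = 0)

trials <- generate_trials(protocol, n_trials = 5000, seed = 1) |>
  simulate_choices(divnorm_observer(observer), seed = 2)

mean(trials$choice == trials$correct_side)
#> [1] 0.6452

est <- fit_logistic_kernel(trials)
classify_kernel_shape(est)
#> <kernel_shape> bump (early 0.584 / middle 0.824 / late 0.570; theta = 0.104)

fit <- fit_model(trials, "divnorm", n_starts = 50, seed = 3)
fit
#> <accum_fit> divnorm: LL = -1614.69, AIC = 3241.38, BIC = 3280.48 (k = 6, n = 5000, 50 starts)
#>   tau_R = 1.757, tau_G = 1.138, omega_I = 0.2527, sigma = 0.03192, mu = -0.3148, bias = -0.07102
```

The observer above sits in the model's bump regime: the fitted, model-free
kernel rises from the early clicks (mean weight 0.584) to the mid-stimulus
clicks (0.824) and falls again (0.570), so the shape rule labels it a bump.
The six-parameter fit returns the maximized Bernoulli log-likelihood of the
5000 choices with its AIC (`2k − 2LL`) and BIC (`k·log n − 2LL`).

The analytic phase sweep needs no simulation at all:

```r
sweep <- kernel_shape_sweep(shape_sweep_path())
rle(sweep$shape)$values
#> [1] "primacy" "bump"    "flat"    "recency"
```

As `τ_R/τ_G` decreases along the documented path, the classified kernel
shape passes through the four phenotypes in order.

Synthetic cohorts with ground truth (mixtures of the four phenotypes,
defaults mirroring a 133-participant reference cohort at 31/53/12/4%) come
from `make_synthetic_cohort(cohort_spec(...))`; `recovery_experiment()`
chains generation → refitting → kernel reconstruction → classification into
a truth-versus-estimate report, and `compare_models()` aggregates
per-participant fits into a cohort comparison table. `autoplot()` methods
cover kernels, psychometric curves and simulated trajectories, and a thin
command-line front end (`inst/cli/divnorm-cli.R`) exposes
simulate/kernel/fit/compare/recover for shell pipelines.

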