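# fkmr — functional kernel machine regression with sparse feature selection

`fkmr` models a scalar outcome as a *nonlinear, non-additive* function of
several functional predictors (densely sampled curves — for example daily
accelerometer activity-count profiles) in the presence of scalar
covariates, and simultaneously selects which functional predictors, and
which features within them, matter. It is aimed at biostatisticians
analysing wearable-device or other high-frequency curve data against a
health outcome such as BMI.

## The model

For subject *i* with curves *Z*<sub>iℓ</sub>(t), ℓ = 1,…,p, each curve is
reduced by functional principal component analysis to standardized scores
ξ̂<sub>ijℓ</sub>, probit-transformed to ζ̂<sub>ijℓ</sub> = Φ(ξ̂<sub>ijℓ</sub>) ∈ (0,1),
and stacked into a feature vector z⃗<sub>i</sub> of length s = Σ s<sub>ℓ</sub>. The model is

y<sub>i</sub> = x<sub>i</sub>ᵀβ + h(z⃗<sub>i</sub>) + ε<sub>i</sub>,  ε<sub>i</sub> ~ N(0, σ²),

where *h* lives in the RKHS of the Gaussian kernel applied to
garrote-scaled features,

K(γ∘u, γ∘v) = exp{ −(1/p) Σ<sub>j</sub> γ<sub>j</sub>² (u<sub>j</sub> − v<sub>j</sub>)² },

with bandwidth denominator fixed at the feature count. The fit minimizes

(1/2n) ‖Y − Xβ − K(γ)α‖² + (λ₁/2) αᵀK(γ)α + λ₂ ρ(γ; δ),

with the sparse-group penalty ρ(γ; δ) = (1−δ) Σ<sub>ℓ</sub>‖γ<sub>ℓ</sub>‖₂ + δ‖γ‖₁.
Zero entries of γ delete features; zero blocks delete whole functional
predictors. At fixed γ the problem is the least-squares kernel machine,
solved through its linear mixed-model form with λ₁ estimated by REML; at
fixed (α, β) the scaling vector is updated by a proximal Gauss–Newton
scheme on the linearized problem, with backtracking that guarantees a
monotone objective. Penalty level and scaling magnitude are tuned by
cross-validation of the whole pipeline (see the methods vignette,
`vignettes/fkmr-methods.Rmd`, for why the obvious shortcuts fail).

## Worked example

```r
library(fkmr)

# four functional predictors, 100 time points each; predictors 1 and 2
# carry the signal through 5 of the 36 FPC features
sim   <- simulate_dataset(scenario_config(2, n_subjects = 400), seed = 3)
feats <- fpca_features(sim$curves, n_components = 9,
                       train_index = sim$train_index)

tr <- sim$train_index; te <- sim$test_index
set.seed(3)
fit <- fkmr_fit(feats$blocks$matrix[tr, ], sim$scalars$y[tr],
                x = matrix(sim$scalars$x[tr], ncol = 1),
                groups = sim$group_sizes)
fit
#> Functional kernel machine regression fit
#>   n = 300 subjects, s = 36 features in 4 group(s); penalty: sgl
#>   lambda1 = 1.139e-05, lambda2 = 8.543, tau = 3177, sigma2 = 10.85
#>   selected: 4 / 36 features, groups {Z1, Z2}
#>   beta: 1.840

tidy(fit) |> dplyr::filter(selected)
#> # A tibble: 4 × 4
#>   feature  group gamma selected
#>   <chr>    <chr> <dbl> <lgl>
#> 1 zeta_1_1 Z1    7.79  TRUE
#> 2 zeta_1_3 Z1    6.54  TRUE
#> 3 zeta_1_4 Z1    0.624 TRUE
#> 4 zeta_2_7 Z2    7.06  TRUE

yhat <- predict(fit, feats$blocks$matrix[te, ],
                matrix(sim$scalars$x[te], ncol = 1))
quasi_r2(sim$scalars$y[te], yhat)
#> [1] 0.903
```

The fit recovers the two signal functional predictors and four of the
five generating features at this modest sample size (the fifth, a weak
signal, needs larger n); the scalar-covariate coefficient is near its
true value 2, and the held-out quasi-R² of 0.90 says the selected
nonlinear surface explains most of the outcome variance. `autoplot(fit)`
draws the marginal effect of each selected feature with the others held
at 0.5; `replicate_study()` repeats simulate → FPCA → fit → evaluate
across seeds and tabulates accuracy and selection frequencies
(`glance()`, `selection_frequencies()`).

A thin command-line wrapper with `simulate`, `fpca`, `fit`, `predict` and
`replicate` subcommands ships in `inst/cli/fkmr.R`.

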