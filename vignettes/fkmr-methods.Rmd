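---
title: "Functional kernel machine regression with bi-level feature selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional kernel machine regression with bi-level feature selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fkmr)
```

## The model

`fkmr` fits a semi-parametric regression of a scalar outcome $y_i$ on $p$
functional predictors $Z_{i\ell}(t)$ (densely observed curves, e.g.
accelerometer activity counts over a day) in the presence of scalar
covariates $x_i$:

$$y_i = x_i^\top\beta + h(\vec z_i) + \epsilon_i, \qquad
  \epsilon_i \sim N(0, \sigma^2).$$

Each curve is first reduced by functional principal component analysis
(FPCA) to standardized scores $\hat\xi_{ij\ell}$, which are mapped onto
$(0,1)$ by the probit transform $\hat\zeta_{ij\ell} =
\Phi(\hat\xi_{ij\ell})$; $\vec z_i$ stacks the $s = \sum_\ell s_\ell$
features of all functional predictors. The surface $h$ is an element of
the reproducing kernel Hilbert space of the Gaussian kernel and is allowed
to be nonlinear and *non-additive* across features and across functional
predictors — this is what distinguishes the model from functional linear
or functional additive models.

Selection of whole functional predictors and of individual FPC features
happens through a non-negative-garrote-style scaling vector $\gamma \in
\mathbb R^s$ inside the kernel,

$$K(\gamma \circ \vec z_i, \gamma \circ \vec z_k)
  = \exp\Big\{-\tfrac1p \sum_j \gamma_j^2 (z_{ij} - z_{kj})^2\Big\},$$

penalized by a sparse-group penalty
$\rho(\gamma;\delta) = (1-\delta)\sum_\ell \|\gamma_\ell\|_2 +
\delta\|\gamma\|_1$. A zero entry $\gamma_j$ deletes feature $j$ from the
fitted surface; a zero block $\gamma_\ell$ deletes the whole functional
predictor. The objective is

$$J_2(\alpha, \beta, \gamma) = \frac{1}{2n}\big\|Y - X\beta -
  K(\gamma; Z)\alpha\big\|^2 + \frac{\lambda_1}{2}\,\alpha^\top
  K(\gamma; Z)\,\alpha + \lambda_2\,\rho(\gamma;\delta),$$

with $h(\cdot) = \sum_k \alpha_k K(\cdot, \gamma\circ\vec z_k)$ by the
representer theorem.

At fixed $\gamma$ the problem is a least-squares kernel machine, which is
the BLUP of the linear mixed model $Y = X\beta + h + \epsilon$ with
$h \sim N(0, \tau K)$; REML estimation of $(\tau, \sigma^2)$ tunes the
smoothing parameter $\lambda_1 = \sigma^2/(n\tau)$ without
cross-validation. At fixed $(\alpha, \beta, \lambda_1)$, minimizing $J_2$
over $\gamma$ is equivalent (up to a $\gamma$-constant) to

$$\min_\gamma\; \frac{1}{2n}\|F(\gamma) - \tilde Y\|^2 +
  \lambda_2 \rho(\gamma;\delta), \qquad F(\gamma) = K(\gamma;Z)\alpha,
  \quad \tilde Y = Y - X\beta - \tfrac{n\lambda_1}{2}\alpha,$$

which the package solves by a proximal Gauss–Newton scheme: linearize
$F$, solve the resulting standard sparse-group least-squares problem with
proximal-gradient (FISTA) iterations, and step-halve back toward the
working point whenever the candidate fails to decrease the true
objective. The halving safeguard enforces the descent property
$J_2^{(r+1)} \le J_2^{(r)}$ that the alternating scheme is designed
around; the trace is stored in `objective_trace` and checked in the test
suite.

## Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `p` (bandwidth denominator) | Gaussian kernel scale | total feature count $s$ | held fixed: a free bandwidth is unidentifiable against $\gamma$ |
| `delta` | SGL mixing | 0.05 | weight on the $\ell_1$ part; 0 = group lasso, 1 = lasso |
| `lambda1` | smoothing | REML | re-estimated at the final scaling |
| `lambda2` | selection penalty | pipeline CV | 12 log-spaced levels over 3 decades |
| `scale_grid` | magnitude multiplier on $\gamma$ | $\{1,2,4,6,8\}$ | CV-calibrated; see below |
| `cv_folds` | internal CV folds | 2 | `cv_lambda()` for the linear baselines uses 5 |
| `mcp_a` | MCP concavity | 3 | MCP families only |
| `tol_select` | zero threshold on $|\gamma_j|$ | 1e-6 | |

## Design choices that were genuinely open

**Tuning $\lambda_2$ by pipeline cross-validation.** The natural-looking
procedure — K-fold CV of the linearized subproblem — is structurally
invalid here: the working response $\tilde Y$ is built from the
full-sample dual coefficients $\alpha$, so held-out folds are not
independent of the "training" response and the CV error decreases
monotonically in the penalty, always preferring the densest scaling. The
package instead cross-validates the whole pipeline: per fold, the kernel
machine is solved at $\gamma = 1$, the scaling update is run at the
candidate level, the machine is re-fitted at the updated scaling, and the
*real* held-out outcomes are scored.

**Calibrating the magnitude of $\gamma$.** Because the bandwidth
denominator is fixed, the overall magnitude of $\gamma$ is the effective
inverse bandwidth of the fitted surface. The penalized update determines
the support and relative weights of $\gamma$ reliably, but anchors its
magnitude near the all-ones initialization: once the REML level of
smoothing is reached, the dual coefficients nearly interpolate the
training outcome, every $\gamma$ becomes an approximate stationary point
of the in-sample objective, and the alternating scheme cannot move the
scale (the in-sample fit is flat in directions that matter only out of
sample). A scalar multiplier on $\gamma$ is therefore calibrated on the
same CV folds (`scale_grid`), which recovers the accuracy that a full
grid search over $(\lambda_1, \lambda_2)$ pairs attains at roughly ten
times the compute. `fkmr_fit_grid()` retains the full grid-alternation as
the reference implementation.

**A capped, CV-consistent final update.** Proximal Gauss–Newton zeros are
absorbing (the gradient column of a zeroed feature vanishes identically),
so the converged update at a given penalty level can over-prune relative
to the capped update that the CV actually scored. The final update
therefore runs exactly the iteration budget used during tuning (5 steps
by default): the fitted object is the object the tuning validated.

**Sign and convention choices.** Eigenfunctions are flipped to a positive
quadrature integral (largest-magnitude element positive as tie-break);
flips only relabel $\zeta \leftrightarrow 1-\zeta$ and the kernel machine
refits either orientation. $\gamma$ is unconstrained during optimization
(the objective depends on $\gamma_j^2$) and reported as $|\gamma|$. The
SGL convention puts $1-\delta$ on the group norm, $\delta$ on the
$\ell_1$ norm, with $\delta = 0.05$ (group-dominant) by default.

## Numerical details

- **FPCA** uses the dense design directly: pointwise mean, sample
  covariance, and a quadrature-weighted symmetric eigenproblem
  ($B = W^{1/2} C W^{1/2}$), with trapezoid weights; no covariance
  smoothing. Eigenvalues are floored at $10^{-12}$ before score
  standardization. FPCA is estimated on training subjects only; test
  subjects are projected onto the training basis.
- **Gram matrices** are computed by the squared-distance expansion on
  scaled features, symmetrized, and the diagonal clipped to one; REML adds
  a $10^{-10}$ ridge before the spectral decomposition. The REML criterion
  is optimized over $\log\theta \in [-12, 12]$, $\theta = \tau/\sigma^2$,
  with $\sigma^2$ profiled out; boundary optima are flagged
  (`no_kernel_effect`) and trigger a fallback to fixed-$\lambda_1$
  solves.
- **The penalized least-squares solver** precomputes Gram matrices (cost
  per iteration $O(s^2)$), uses FISTA with monotone restarts for the
  convex families and plain ISTA with firm thresholding for the MCP
  families, and exact all-zero bounds ($\lambda_{\max}$) — for the SGL by
  per-group bisection on the KKT condition.
- **Degenerate inputs**: a kernel numerically proportional to the
  identity raises an unidentifiability warning; an outcome fitted exactly
  by the fixed effects flags "no kernel effect"; an all-zero scaling in
  the CV loop falls back to the constant-kernel machine.
- The jittered sampling grid is clipped to $[0,1]$ and sorted; tied
  points created by clipping are spread evenly toward the next distinct
  point so the grid stays strictly increasing (a requirement of the
  quadrature).

## What the simulation generators emulate

`simulate_dataset()` reproduces two benchmark designs. Curves follow a
Karhunen–Loève expansion in the orthonormal Fourier system on $[0,1]$
($\phi_1 \equiv 1$, then $\sqrt2\sin(2\pi kt), \sqrt2\cos(2\pi kt)$),
with component standard deviations $\varsigma_j = 45 \times 0.64^j$,
independent standard-normal scores, and a common jittered grid of 100
points (jitter variance 0.001). Scenario 1 has one functional predictor
(15 components; features 2 and 9 drive the outcome); Scenario 2 has four
(9 components each; features 1, 3, 4 of predictor 1 and 2, 7 of
predictor 2 are signals), with a strongly nonlinear, non-additive true
surface and outcome noise $N(0,1)$. Subjects are split 75/25 into
training and test sets in simulation order. The scores being exactly
standard normal makes $\zeta_j = \Phi(\xi_j)$ exactly uniform — real
curves deliver only approximately uniform features, and real designs may
need irregular-grid FPCA, which this package deliberately does not
implement. Passing the simulation benchmarks therefore demonstrates
correct methodology on dense, noise-free-at-curve-level designs, not
performance on sparse or irregular real-world recordings.

The replicate study (`replicate_study()`) runs 20 replicates at
$n = 1000$ by default (the problem sizes used throughout the package's
own evaluation; means of accuracy metrics stabilize to about $\pm 0.01$ at
this size), derives per-replicate seeds from the master seed by fixed
offsets, and evaluates everything on the held-out 250 subjects:
quasi-$R^2$, adjusted quasi-$R^2$ with $k$ = number of selected features
plus the number of scalar covariates (the size penalty that makes fits of
different sparsity comparable), the concordance regression of the
centered true surface on the estimated one (centered because the level of
$h$ is absorbed by the kernel machine), and selection indicators.

## Known limitations

- Dense, common-grid curves only; no PACE-style conditional-expectation
  scores for sparse designs.
- Gaussian outcomes only; no GLM or survival extensions.
- The optimization is non-convex: the fit is a stationary point reached
  from $\gamma = 1$, not a certified global minimum, and zeroed features
  cannot re-enter within an update.
- With `delta` at either extreme the SGL reduces to the group lasso or
  the lasso; the group-MCP composite applies MCP to group norms and
  inherits MCP's sensitivity to its concavity parameter.
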