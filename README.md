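# dcefit

Voxelwise hemodynamic parameter estimation for dynamic contrast-enhanced
(DCE) MRI, built to compare two curve-fitting back-ends on equal terms: the
conventional **penalized Levenberg-Marquardt** least-squares fitter (LM) and
a **Bayesian expectation-maximization** estimator on log-transformed
parameters (BM). It is aimed at perfusion-imaging researchers who need
parameter maps that are robust to noise — and at anyone who wants to
quantify, on simulated data with known truth, why least-squares leakage maps
sprout "spurious voxels" and Bayesian ones do not.

## What it computes

Two compartmental forward models map an arterial input function (AIF)
`Cp(t)` to tissue concentration:

* **Extended Tofts (ETM)** —
  `C(t) = vp Cp(t−δ) + Ktrans ∫ Cp(τ−δ) exp(−kep (t−τ)) dτ`,
  with leakage constant `Ktrans`, interstitial volume `ve`
  (`kep = Ktrans/ve`), plasma volume `vp`, and bolus delay `δ`.
* **Two-compartment exchange (2CXM)** — impulse response
  `Fp [A e^{−αt} + (1−A) e^{−βt}]`, separating plasma flow `Fp` from the
  permeability flow `Fe` (reported as the `K1` map), with
  `Ktrans_equiv = Fp·Fe/(Fp+Fe)`.

Both are fitted per voxel from a Patlak/SVD/AUC starting guess, either by
LM (sum of squares plus a constant 100,000 penalty outside the
physiological ranges `Fp` 0–500, `K1` 0–100 ml/100g/min, `ve`, `vp` 0–1) or
by BM (Gaussian prior on log parameters, Laplace posterior, noise variance
re-estimated each EM step, no upper bounds). A digital reference phantom
(white matter / tumor rim / tumor core / vessel, 150 frames at 2 s, Parker
population AIF) provides ground truth; evaluation utilities supply recovery
metrics (bias, RMSE, out-of-range "spurious voxel" fractions), ROC/AUC,
exact Wilcoxon statistics, and a repeated-split L1-logistic experiment that
asks whether reader scores alone identify the generating algorithm.

## A worked example

Fit a noisy tumor-rim curve (SNR 10) with the Bayesian back-end:

```r
library(dcefit)

tt    <- seq(0, 298, by = 2)                      # 150 frames at 2 s
aif   <- population_aif(tt)                       # Parker-form plasma AIF
truth <- c(Fp = 60, vp = 0.08, Fe = 12, ve = 0.4, delay = 0)
curve <- tcxm_concentration(truth, aif, tt)
set.seed(7)
noisy <- dce_curve(tt, curve$values + rnorm(length(tt), 0, max(curve$values) / 10))

fit <- dce_fit(noisy, aif, model = "2cxm", method = "bayes")
summary(fit)
#> Kinetic model fit: 2CXM via Bayesian EM (MAP, Laplace posterior)
#>
#>       estimate       units    ci_lo   ci_hi
#> Fp    72.38900 ml/100g/min 58.71154 89.2528
#> vp     0.08799        ml/g  0.07598  0.1019
#> Fe    10.79254 ml/100g/min  9.52378 12.2303
#> ve     0.42485        ml/g  0.37137  0.4860
#> delay -0.33786           s -1.14152  0.4658
#>
#> Derived: Ktrans_equiv = 9.392
#> Noise variance 0.0005098; cost -493.574; 7 iterations; converged
```

All five parameters land near truth (`Fp` 60, `vp` 0.08, `Fe` 12, `ve`
0.4), with credible intervals from the log-domain Laplace posterior mapped
back to natural units. `dce_fit(..., method = "lm")` returns the same
interface for the least-squares route, and `plot(fit)`, `predict(fit)`,
`residuals(fit)`, `simulate(fit)` behave as for any fitted R model.

Map-level comparison on a noisy phantom:

```r
ph <- generate_phantom(phantom_spec(shape = c(16, 16, 1), snr = 10, seed = 42),
                       model = "2cxm")
lm_maps <- fit_volume(ph$series, ph$aif, model = "2cxm", method = "lm")
bm_maps <- fit_volume(ph$series, ph$aif, model = "2cxm", method = "bayes")
recovery_report(ph$truth, lm_maps)   # ve RMSE inflated by spurious voxels
recovery_report(ph$truth, bm_maps)   # bounded errors, zero out-of-range ve
```

Thin command-line wrappers live in `inst/cli/`
(`dce-phantom.R`, `dce-fit.R`, `dce-eval.R`) for running the same chain on
NIfTI volumes from a shell.

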