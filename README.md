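# frailmix

Is physical frailty a **syndrome**? The classic phenotype scores older
adults on five components — unintentional weight loss, exhaustion, weakness
(grip strength), slowness (gait speed) and low physical activity — and
classifies them robust (0 deficits), prefrail (1–2) or frail (3+). The
syndrome claim is structural: the population should split into latent
classes that every component orders along one shared severity gradient.
`frailmix` implements the statistical machinery to test that claim against
its two rivals — a **homogeneous** population, and a **categorical
approximation of a continuum** — for epidemiologists and biostatisticians
working with frailty or comparable multi-component constructs.

At its core is the factor mixture model (FMM). Given class $k$ and factor
score $\eta_i \sim N(\alpha_k, \psi_k)$,

$$y_{ic} = I_{kc} + F_{kc}\,\eta_i + e_{ic},\qquad e_{ic}\sim N(0,\theta_{kc}),$$

with mixing proportions $\pi_k$: classes act through the intercepts
$I_{kc}$, the continuum through the loadings $F_{kc}$. Equality constraints
across classes define the family — latent profile analysis (LCA, no
factor), strict/strong measurement invariance (SiMI/SoMI: intercepts and
loadings equal, classes differ only in factor mean — the
continuum-approximation null), weak invariance (WMI: intercepts vary) and
no invariance (NMI) — each with equal (`ev`) or unequal (`uv`) residual and
factor variances. Estimation is by EM with exact analytic factor
marginalization (one-factor Woodbury identity), a Tobit left-tail term for
the censored gait item, and a two-part (occurrence + log-magnitude)
weight-loss item. Models are compared with BIC differences and the
parametric bootstrap likelihood-ratio test (BLRT), checked with Monte Carlo
acceptability diagnostics (bias, SE bias, coverage, power), and screened by
a component-ordering test; `run_eight_steps()` chains the whole procedure
and emits a `syndromic` / `categorical-approximation-of-continuum` /
`homogeneous` verdict.

Because the motivating cohort data are not publicly deposited, the package
includes a fully parameterized synthetic-cohort generator
(`generate_cohort()`, `default_config_frele()`) that reproduces the study
conditions: published loadings (1.00, 4.10, 1.21, 2.17), class shares,
sex/height/BMI-stratified component distributions, a left-censored gait
item, class-wise weight-loss occurrence, and class-profiled covariates
including 3-year mortality.

## Worked example

```r
library(frailmix)

cohort <- generate_cohort(default_config_frele(n_subjects = 800), seed = 1)
bin <- dichotomize(cohort, derive_cut_points(cohort))
table(frailty_index(bin)$frailty_class)
#>   robust prefrail    frail
#>      445      228      127

items <- encode_fmm_items(cohort)
fit <- fit_fmm(items, fmm_spec("SoMI", 4, "uv", items),
               n_starts = 10, seed = 1)
fit
#> <fmm_fit> SoMI-uv K = 4: loglik = -14518.664, BIC = 29304.71, entropy = 0.474
#>   pi: 0.295 0.200 0.332 0.173
```

The frailty index splits this 800-subject synthetic cohort into 445 robust,
228 prefrail and 127 frail (15.9% frail, close to the generator's study
conditions). The four-class strong-invariance fit reports the maximized
log-likelihood, BIC and a relative entropy of 0.47 — modest class
separation, as expected for classes that slice a continuum. The fitted
loadings sit close to the generating values (activity 4.03, grip 1.19,
gait 2.09 against the true 4.10, 1.21, 2.17), while class shares are
recovered much more noisily — weakly separated mixtures identify their
measurement block far better than their mixing.

```r
report <- run_eight_steps(cohort, pipeline_control(K_max = 3, B = 99, seed = 1))
report$verdict
render_report(report, "report/")   # report.json + report.md
```

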