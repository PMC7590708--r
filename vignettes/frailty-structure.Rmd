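---
title: "Testing the syndromic structure of the frailty phenotype with factor mixture models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing the syndromic structure of the frailty phenotype with factor mixture models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailmix)
```

## The scientific question

The physical frailty phenotype scores older adults on five components —
unintentional weight loss, exhaustion, weakness (grip strength), slowness
(gait speed) and low physical activity — and labels them robust (0
deficits), prefrail (1–2) or frail (3+). Calling frailty a *syndrome* is a
claim about latent structure: the population should split into two or more
classes, and every component should separate those classes along one shared
severity gradient. Two rival readings must be ruled out: the population may
be *homogeneous* (no classes at all), or apparent classes may be a
*categorical approximation of a continuum* — slices of a single continuous
dimension rather than qualitatively distinct groups.

`frailmix` operationalizes this test as a family of factor mixture models
(FMMs) and an eight-step decision pipeline, together with a synthetic-cohort
generator so that the whole procedure is reproducible and testable without
access to restricted cohort data.

## The model family

Write $y_{ic}$ for subject $i$'s score on component $c$. An FMM combines a
latent class model with a one-factor measurement model: given class $k$ and
factor score $\eta_i \sim N(\alpha_k, \psi_k)$,

$$ y_{ic} = I_{kc} + F_{kc}\,\eta_i + e_{ic}, \qquad
   e_{ic} \sim N(0, \theta_{kc}), $$

with mixing proportions $\pi_k$. The intercepts $I_{kc}$ are the
*classification* parameters — classes act on the components through them —
while the loadings $F_{kc}$ carry the shared continuum. Constraining which
blocks may vary across classes yields the family:

| member | intercepts | loadings | role |
|--------|-----------|----------|------|
| LCA (latent profile analysis) | vary | none (no factor) | non-null |
| SiMI (strict invariance, ev only) | equal | equal | categorical-approximation null |
| SoMI (strong invariance) | equal | equal | categorical-approximation null |
| WMI (weak invariance) | vary | equal | non-null |
| NMI (no invariance) | vary | vary | non-null |

Each non-LCA member comes in an equal-variance (`ev`) and unequal-variance
(`uv`) flavour, where `uv` lets the residual variances *and* the factor
variance differ by class; strict invariance is strong invariance plus `ev`,
so `SiMI-uv` is rejected as a specification. Any one-class member is the
homogeneity null. Under SoMI/SiMI the classes differ only in their factor
means — precisely the "categorical rendering of a continuum" null.

Identification: the exhaustion loading is fixed at 1 (the anchor); under
SoMI/SiMI the lowest class factor mean is fixed at 0; under WMI/NMI all
factor means are 0, absorbed by the class intercepts. Bernoulli items carry
no loading and no residual variance.

### Items

The measurement block has six items: exhaustion (SF-36 vitality), physical
activity (PASE), grip strength (vigorimeter) — Gaussian; gait speed (cm/s) —
Gaussian, left-censored at a floor representing inability to walk the
course, entering the likelihood through the normal left tail; and a
two-part weight-loss item — a Bernoulli occurrence indicator plus a
conditional Gaussian magnitude, fitted on log kg. The log scale is a
deliberate choice: weight lost is strongly right-skewed in kg, and fitting
a Gaussian magnitude on the raw scale lets skewness masquerade as spurious
latent classes; on the log scale the generator's log-normal magnitudes are
exactly Gaussian.

## Estimation

`fit_fmm()` maximizes the observed-data likelihood by EM. Because the model
has a single factor, the factor integral is analytic for any row whose
Gaussian-type cells are fully observed (Woodbury identity on
$\Sigma_k = \Theta_k + \psi_k F F'$), and the conditional factor posterior is
normal, giving exact E-step moments. Only rows containing a censored gait
cell are integrated numerically, with Gauss–Hermite quadrature recentred at
the posterior implied by the row's uncensored cells (61 nodes by default; only censored rows pay this cost).
The M-step solves the constrained weighted least-squares updates in closed
form, pooling across classes for invariant blocks and using truncated-normal
moment imputation for censored cells. The log-likelihood trace is stored and
is non-decreasing up to quadrature error on censored rows (order $10^{-6}$).

Starting values come from perturbed k-means assignments; each of `n_starts`
starts is run briefly and the best continued to convergence (short-run /
long-run). Runs in which a class's expected count falls below 5, or a
variance hits its floor ($10^{-4}$ of the item's marginal variance), are
flagged as degenerate and discarded — mirroring the stopped searches that
occur on real cohorts — and if every start degenerates the best flagged run
is returned rather than an error. Classes are reported frailest-first
(ascending factor mean, or ascending anchor-item mean when factor means are
fixed).

Relative entropy, $1 - \sum_{ik} -p_{ik}\ln p_{ik} / (n \ln K)$, summarizes
class separation; it is undefined at $K = 1$ and reported as `NA`.

## Model comparison

Fits are compared with BIC differences and the parametric bootstrap
likelihood-ratio test (`blrt()`): both models are fitted to the data, `B`
datasets are simulated from the fitted null and both models refitted to
each, and $p = (1 + \#\{LRT_b \ge LRT_{obs}\})/(B_{used}+1)$. Replicates that
fail or degenerate are dropped and counted; more than 20% failures flags
the result unreliable. `B = 1000` reproduces the reference procedure;
tests use 19–99. With `alpha_stop` set, replication halts as soon as
rejection has become impossible — the decision is unchanged, only the
p-value resolution drops. Replicate fits deliberately use fewer starts and a
coarser tolerance than observed fits; the observed fits must be converged
tightly, since an under-converged null inflates both the BIC difference and
the observed ratio.

Some published comparisons (profile analysis against the strong-invariance
null) are not nested; the bootstrap machinery is well-defined regardless and
the result records `nested = FALSE`.

`monte_carlo_diagnostics()` implements the simulation-based acceptability
check: relative bias (absolute where the true value is 0), standard-error
bias against the replication SD (flagged above 10%), 95% coverage, and
power against zero, with standard errors from the numerically differentiated
observed information.

## The eight-step pipeline

`run_eight_steps()` chains: (1) stratified cut points, dichotomization, the
0/1–2/3+ index and a 3-class binary LCA with its $\chi^2$ goodness of fit
over the 32 response patterns (df $= 31 - (6K-1)$, i.e. 26/20/14 for
$K = 1/2/3$); (2) a one- versus two-factor maximum-likelihood factor
analysis (parameter-count df difference 4 at five indicators); (3) the
$K=1$ null against $K=2$ for every family member; (4) the minimal acceptable
class count per member — grow $K$ while the BLRT rejects $K-1$ and no
degeneracy stop occurs; (5) `ev` versus `uv` within each family line;
(6) ordering checks; (7) surviving non-null models against the selected
strong-invariance null; (8) class profiles on components and risk factors
for the final model and the frailty index.

Decision rules, where BIC and BLRT can disagree:

* *Class counts* (steps 4–5) are governed by the BLRT alone.
* *Population homogeneity* (step 3) is rejected only when BIC **and** BLRT
  agree. Two reasons: eight member-level tests at $\alpha = 0.05$ would
  otherwise false-reject a homogeneous population about a third of the
  time, and the homogeneity verdict is evaluated on the factor-model
  members only — a homogeneous one-factor population always rejects the
  one-class *profile-analysis* null, because independent items cannot carry
  the continuum's correlation, and that rejection says nothing about
  latent classes.
* *Step 7* uses a configurable rule (default: both statistics must favour
  the non-null model). Under that rule a bootstrap run that cannot change
  the decision (BIC already favours the null) is skipped and the ledger row
  says so.

The ordering check (step 6) ranks classes on each component's class-specific
means after direction alignment (higher vitality/PASE/grip/gait = healthier;
weight loss reversed; ties within $10^{-6}$ collapse). Components grouping
into more than one ordering contradict a single syndromic gradient, and such
models are excluded from step 7 — the step-monotonicity the procedure
requires. Verdicts: **homogeneous** if no factor-model member rejects
$K = 1$; otherwise **categorical-approximation-of-continuum** if the
strong-invariance null survives step 7; otherwise **syndromic**.

## The synthetic cohort generator

`generate_cohort()` draws class-first cohorts with exactly the structure the
analysis assumes: a categorical class, a within-class normal factor score,
the four continuous components through the invariant loadings
$(1.00, 4.10, 1.21, 2.17)$, gait left-censored at 20 cm/s, a two-part
weight-loss item (class-wise occurrence rates 38.6/21.8/9.5/3.2%,
log-normal magnitudes), exogenous sex with additive male shifts
(PASE $+7$, grip $+12$, gait $+3$ — so the sex-stratified cut-point
machinery has real structure to find), heights and BMI on the published
stratum boundaries, and covariates (age, education, self-rated health,
chronic disease count, cognition, depression, IADL/ADL disability, 3-year
mortality) drawn from class profiles, conditionally independent of the
components given class. Class shares are (2.7, 25.1, 53.4, 18.8)% at the
default $n = 1643$, and class factor means (0.05, 6.85, 22.25, 34.15) were
derived from the published class component means against the printed
intercepts. Fields no table prints — residual variances
(class-scaled $1.4/1.2/1.0/0.8$ of base $(100, 900, 150, 100)$), factor
variances $(80, 70, 60, 50)$, the censoring floor, magnitude dispersion
(CV 0.6) — were fixed once at field-plausible scales and are documented
here rather than tuned.

Two default features deliberately violate strict measurement invariance:
the additive sex shifts and the class-wise weight-loss occurrence and
magnitude. They make dichotomization realistic, but they mean the *default*
cohort is not generated by a SoMI-uv model — and a correct procedure
detects that (weak-invariance members pick up the class-varying occurrence).
Experiments that require data truly generated under strong invariance —
parameter recovery, pipeline self-consistency — therefore use
`default_config_frele(strict_invariance = TRUE)`, which zeroes the sex
shifts and sets the occurrence rate (13.3%) and magnitude law (7.37 kg)
to their cohort-level values.

What the generator does **not** emulate: longitudinal follow-up and
attrition, sampling weights, missing data, item non-normality beyond the
two-part magnitude, and covariate–component dependence within class.
Passing tests therefore demonstrate internal consistency of the machinery
under the stated generative model, not robustness to everything real
cohort data can do.

## Cut points and the frailty index

`derive_cut_points()` reproduces the classic operationalization: first
quintiles (empirical 20th percentile, linear interpolation between closest
ranks — the printed reference values cannot disambiguate the estimator, so
one convention is fixed) of vitality (unstratified), PASE (by sex), gait
speed (by sex × height half, split at the sex-specific mean height
recomputed per cohort) and grip strength (by sex × BMI quintile); weight
loss uses the fixed $\ge 10\%$-of-usual-weight-or-$\ge 4.5$ kg rule and
never an empirical threshold. Deficits are boundary-inclusive
(score $\le$ threshold), and slowness thresholds are always stored on the
speed (cm/s) scale — the reference table mixes a time label with speed
units, and one convention is enforced. A published-dialect threshold file
ships in `inst/extdata/` for serialization tests.

## Numerical choices and problem sizes

* EM stops when the Aitken-accelerated estimate of the remaining
  log-likelihood gain falls below `tol` ($10^{-6}$ for reference fits;
  coarser inside bootstrap replicates, whose refits start from the observed
  estimates).
* Quadrature: 61 nodes for observed fits, 9 inside bootstrap replicates
  (only censored rows are affected; likelihood-ratio errors cancel within a
  replicate).
* Probability floors ($10^{-6}$) on Bernoulli cells keep the likelihood
  finite; this is a documented deviation from unconstrained ML at the
  boundary.
* Modal assignment breaks posterior ties toward the lowest class index.
* The test suite and acceptance experiments run at deliberately chosen
  sizes: recovery at the study size $n = 1643$ over 20 seeds; BLRT
  calibration at $n = 300$, $B = 99$, 200 replications with early stopping;
  pipeline self-consistency over 10 seeds per generating condition at
  $n = 1643$ (strong-invariance arm), $n = 600$ (one-class arm) and
  $n = 800$ (separated latent-profile arm), with $B = 19$ and `K_max = 3`. These sizes are the
  package's test profile; the defaults (`B = 1000`, `K_max = 4`, 50 starts)
  reproduce the reference analysis conditions.

## Known limitations

* The one-factor FMM family only; bifactor or multi-factor mixtures are out
  of scope (the two-factor check appears only in the dimensionality step).
* The weight-loss occurrence item never loads on the factor; an
  inflated-count magnitude model is not implemented.
* Standard errors come from the numerically differentiated observed
  information; no sandwich or sampling-weight corrections.
* Class-count search is greedy in $K$ and stops at the first non-rejection
  or degeneracy, as in the reference procedure; it does not revisit larger
  $K$.
* Mixtures along a weakly separated continuum are intrinsically hard:
  class shares and factor means are recovered far more noisily than
  loadings, and one-class/two-class decisions near the detection boundary
  are sensitive to $n$.
* Item intercepts are identified only jointly with the factor location:
  pinning the reference class at $\alpha = 0$ fixes the scale, but when
  that class is small and overlaps its neighbour the fitted reference point
  wanders by a few factor units, moving every intercept by $F_c\,\delta$.
  The location-invariant contrasts $I_c - F_c I_{\text{anchor}}$ (and the
  loadings) are the stably recovered part of the measurement structure, and
  recovery experiments evaluate those.

## A worked example

```{r example, eval = FALSE}
cohort <- generate_cohort(default_config_frele(n_subjects = 800), seed = 1)
cuts <- derive_cut_points(cohort)
bin <- dichotomize(cohort, cuts)
table(frailty_index(bin)$frailty_class)

items <- encode_fmm_items(cohort)
fit <- fit_fmm(items, fmm_spec("SoMI", 4, "uv", items),
               n_starts = 10, seed = 1)
fit
relative_entropy(fit$posteriors)

report <- run_eight_steps(cohort,
                          pipeline_control(K_max = 3, B = 99, seed = 1))
report$verdict
render_report(report, "report")
```
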