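---
title: "Location-scale-shape reference models for adult spirometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Location-scale-shape reference models for adult spirometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiroref)
```

## The modelling problem

A spirometric reference equation answers one question: for a healthy person
of this sex, height and age, what distribution of FEV1 (or FVC, FEV1/FVC,
FEF25-75) should we expect? Clinical interpretation then reduces the
measured value to a Z-score under that subject-specific distribution, a
percent of the predicted median, and a comparison against the lower limit
of normal (LLN, the 5th centile). Because lung indices are positive and
right- or left-skewed, and because their spread and skewness change with
age, a Gaussian regression on the mean is not enough: the location, scale
and shape all need their own models.

## The distribution families

Two families cover the package's needs.

**BCCG (Box-Cox Cole-Green; the LMS method).** With median `mu > 0`,
coefficient of variation `sigma > 0` and Box-Cox power `nu`,

$$ Z = \frac{(Y/\mu)^{\nu} - 1}{\nu\,\sigma}, \qquad
   Z = \frac{\log(Y/\mu)}{\sigma} \ \text{when}\ \nu = 0, $$

and `Z` is standard normal when the model holds. `nu < 0` captures
left-skewness on the raw scale (typical for volumes), `nu = 1` is an
ordinary normal with SD proportional to the median.

**BCPE (Box-Cox power-exponential).** The same transform, but the
transformed variable follows a standardized power-exponential law with
kurtosis parameter `tau > 0` (`tau = 2` Gaussian and identical to BCCG,
`tau = 1` Laplace-tailed, large `tau` platykurtic). Its CDF has an
incomplete-gamma form; the Z-score is the normal deviate of that CDF.

Two numerical conventions matter:

- **The Box-Cox truncation is ignored.** Formally the transform confines
  `Z` to a half-line so that `Y > 0`; like all LMS-style growth and lung
  reference work, we treat `Z` as fully normal (or power-exponential). The
  mass this ignores is `Phi(-1/(|nu| sigma))` per subject. For the packaged
  equations it is below `1e-5` almost everywhere; the worst corner is the
  male FEF25-75 model at age 18, where it reaches `2.7e-4` — still far
  below clinical relevance, and the test suite asserts the `< 1e-3` bound
  over a sex x index x age grid. A corollary: a Z-score is an *exact* CDF
  inversion only where this mass is negligible, which is how the
  quadrature-oracle tests sample their parameters.
- **Tail-stable evaluation.** BCPE Z-scores and quantiles are computed
  through log tail probabilities of the gamma integral (plus a two-step
  Newton refinement of the quantile), so values stay finite and accurate
  far into the tails; `nu` within `1e-5` of zero switches to the lognormal
  limit; `tau = 2` short-circuits to the BCCG expression exactly. The
  normal 5th-centile deviate is carried at double precision
  (-1.6448536270), not as a tabled constant. Probability-mediated round
  trips (`quantile(pnorm(zscore))`) are exact to `1e-9` for `|Z| < 6`;
  beyond that the upper-tail probability itself is no longer representable
  to that relative precision in doubles.

## The equation set and its serialization

A `parameter_model` is one printed equation row:
`linkinv(intercept + b_h log(height) + b_a log(age) + spline(age))`, with
natural logarithms, height in centimetres, and identity or log link. An
`equation_set` bundles, per sex, the family and the mu/sigma/nu(/tau)
models of the four indices, plus a valid age range (18-70 y; outside it
evaluation warns and clamps splines rather than refusing — standard
practice when equations are applied slightly beyond their derivation
range).

The packaged ISE sets were transcribed from the published sex-specific
tables. Units and log conventions were fixed by self-consistency: only
natural logs with height in cm reproduce the derivation cohort's medians
(e.g. male FVC 4.68 L predicted vs 4.64 L observed at the median subject;
base-10 logs or metre heights give absurd values). One printed equation is
ambiguously parenthesised (the male FEV1/FVC median); the sign chosen
(-0.007171 on log age) is the one matching the cohort median 0.86, the
alternative predicts 0.907. All equations are BCCG except female FEF25-75,
the only index whose printed equation carries a kurtosis row, which is
therefore BCPE.

The published age-spline terms (`Mspline`/`Sspline`) are declared in six of
the eight equations but their knot tables were never published. The
equation-set format carries splines as knot tables (natural-cubic
interpolation, flat extrapolation outside the knots); the packaged sets
ship with those terms *declared but empty*, and evaluating such a set
requires the explicit `splines_omitted_acknowledged` flag so the
approximation is a conscious choice, never a silent one. Refitting on
cohort data repopulates them (`fit_parameter_models()` samples the fitted
smooth onto integer-year knots). Serialization is a versioned JSON schema
(`spiroref-equation-set`, full double precision, exact round trips);
comparator sets such as GLI-style coefficients use the same schema but are
user-supplied, never bundled.

## The synthetic cohort generator

`generate_cohort()` exists so that every downstream stage is testable
without the original study data. Its defaults are the derivation study's
conditions, chosen once:

- **Sex**: Bernoulli with female fraction 0.331 (the derivation phase).
- **Age**: shifted log-normal, `age = 18 + X`, with `X` calibrated to the
  sex-specific median and upper quartile (males 28.57 / 40.68 y, females
  34.79 / 45.92 y), truncated to 18-70 y. The study reports only that ages
  were right-skewed with these quartiles; any right-skewed family matching
  them is acceptable, and the choice is recorded in the cohort metadata.
  The lower quartile is then implied (about 23 y males, 28 y females)
  rather than matched exactly — a two-parameter family cannot hit three
  quantiles.
- **Height**: normal with SD matched to the interquartile range (5.93 cm
  males, 5.19 cm females), truncated to the observed ranges (155-193 /
  154-176 cm). Because the female range truncates asymmetrically, the
  pre-truncation centre is solved (by `uniroot`) so the *post-truncation*
  median equals the study median (174 / 157 cm); without this the female
  median drifts about 2 cm high.
- **Outcomes**: FVC, FEV1/FVC and FEF25-75 are drawn from the truth
  equation set's family at each subject's parameters (inverse-CDF draws;
  the negligible truncation region is redrawn; ratios are capped at 1).
  **FEV1 is then derived as ratio x FVC**, which enforces the physical
  constraint FEV1 <= FVC exactly.

That last choice has a consequence worth stating plainly: the derived FEV1
does *not* follow the truth set's FEV1 model. The printed medians are not
multiplicatively consistent (for the median male subject,
mu_FVC x mu_ratio = 4.02 L against mu_FEV1 = 4.08 L), so FEV1 Z-scores
computed against the truth set carry a built-in offset of roughly -0.14
and an inflated SD. The generator therefore guarantees exact standard
normality of in-sample Z-scores only for the three directly drawn indices;
FEV1 still sits comfortably inside the +/-0.5 suitability band, and the
tests assert exactly that split. Deriving the ratio instead would move the
same inconsistency onto the ratio, with a larger Z offset; sacrificing the
FEV1 <= FVC invariant was judged worse than a small known bias in one
derived index.

The eligibility filter mirrors the recruitment questionnaire: a record is
kept iff the subject is 18 or older and none of the six exclusion flags
(current smoker, lives with a smoker, former smoker, chronic disease,
recent surgery or acute respiratory symptoms, pregnancy) is raised; the
reported reason is the first matching criterion in that order. Flag
prevalences default to zero (an already-screened cohort) and are free
parameters — the study reports only its total exclusion count, not the
per-criterion breakdown.

What the generator does **not** emulate: device measurement error (the
spirometer's +/-3% volume accuracy) as a separate noise layer,
within-subject blow-to-blow variability, secular height trends, or any
dependence between indices beyond the FEV1 identity. Passing tests on
synthetic cohorts therefore demonstrate the *pipeline's* correctness under
the stated model, not the clinical adequacy of any equation set on real
Iraqi data.

## Fitting: penalised backfitting with a joint polish

`spiro_gamlss()` maximises the (penalised) likelihood of one index by
cyclic updates over the distribution parameters, the standard
location-scale-shape strategy:

1. For the current parameter, compute per-observation first and second
   derivatives of the log-likelihood with respect to its linear predictor
   by central finite differences (step `1e-4 * max(1, |eta|)`); clamp
   non-positive curvatures and oversized working steps.
2. Solve the penalised weighted least squares problem on that parameter's
   link scale; accept the update (with step-halving) only if the penalised
   deviance does not increase.
3. Age smooths use a centred cubic P-spline basis (dimension 20,
   second-order difference penalty, constraints absorbed — built with
   `mgcv::smoothCon`, which is basis plumbing, not the fitter). The
   penalty `lambda` is chosen by `uniroot` so the smooth's effective df
   (trace of its block of the hat matrix) hits the target, default 3
   per spline term; `lambda` freezes after the third cycle. A
   penalty-optimised (rather than fixed-df) roughness mode was considered
   and left out: the candidate menus this package ranks are distinguished
   by structure, not by fractional df.
4. When the cyclic updates plateau (penalised-deviance change below
   `1e-3`), a joint BFGS step over *all* coefficients — with an analytic
   chain-rule gradient — removes the residual coordinate coupling between
   `mu` and `nu`, which are strongly correlated in Box-Cox families and
   make pure coordinate ascent crawl. Convergence is declared only when a
   repeated joint step can no longer improve the penalised deviance by
   more than the tolerance; otherwise the fit is returned flagged
   non-converged, never silently.

The `1e-3` default tolerance is the conventional global-deviance criterion
for this class of algorithms; an absolute `1e-6` sits below the practical
resolution of coordinate updates on deviances of order 10^3 and only burns
cycles. Initial values: `mu` from least squares of the link-transformed
response, `sigma` from the residual spread, `nu = 1`, `tau = 2` (with a
`nu = 0` fallback start if the likelihood is degenerate at `nu = 1`).
Degenerate inputs fail fast with named errors: constant design columns,
fewer than about 50 usable records, non-positive measurements. With the
normal family, identity link and no smooths, the fit reduces to ordinary
least squares (verified to `1e-6` in the tests). Record order affects
coefficients only at the optimizer's resolution (about `1e-6`; the tests
assert `1e-5`).

Effective df per parameter is the trace `tr((Z'WZ + P)^{-1} Z'WZ)` at the
converged weights (equal to the column count for unpenalised parameters),
and `SBC = -2 loglik + df log(n)` uses the unpenalised log-likelihood.

## Model selection and diagnostics

`select_model()` fits a candidate menu and ranks by ascending SBC, then
applies two rules in the spirit of "lowest SBC *and* df with acceptable
residuals": a converged candidate within `delta_SBC = 2` of the best but
with strictly lower total df displaces it (2 is the conventional
"no-meaningful-difference" evidence band), and candidates whose in-sample
quantile residuals are off-centre (|mean| >= 0.1) or mis-scaled
(|var - 1| >= 0.15) are vetoed unless nothing survives. The full ranking is
always returned for audit. The default menu (`default_model_menu()`)
crosses family {BCCG, BCPE} with spline placement {none, mu,
mu + sigma}, a constant-vs-log(age) skewness model and (BCPE only) a
constant-vs-log(age) kurtosis model, with the median always on
log(height) + log(age) — spanning every structural form in the printed
equations. The published model-menu tables themselves were not reproduced
in the available text, so the menu is configurable rather than fixed.

Quantile residuals are deterministic for these continuous families and
equal the Z-scores under the fitted model exactly — the tests assert
`1e-12` agreement with `zscore_for()` on the exported equation set.
`worm_plot_data()` bins records into age quantiles (equal counts +/-1) and
returns per-bin detrended QQ coordinates. Its calibrated null property is
that every worm is *centred on zero* (max per-bin mean deviation below
0.15 at 1000 records per bin): individual tail order statistics fluctuate
by several tenths even under perfect normality, so no useful band applies
to single points. `centile_curves()` evaluates non-crossing reference
centiles along an age grid at a fixed height (default: the sex median).

## Validation statistics

`summarize_validation()` computes, per index and sex, each subject's
predicted value, percent predicted and Z-score, and reports mean and SD of
Z alongside medians and quartiles (type-7, linear-interpolation quantiles —
the original analysis software's convention is unknowable, so ours is fixed
and documented). The published validation tables caption their Z column
"median (Q1-Q3)" but print "0.06 (0.99)"-style pairs discussed as mean and
SD; both summaries are therefore emitted. `suitability_check()` applies
the strict |mean Z| < 0.5 rule. `compare_equation_sets()` ranks sets by
|mean Z| (ties by |SD - 1|) and labels the bias direction — negative mean Z
means the set predicts high, i.e. overestimates. `mann_whitney_u()` uses
midranks, a tie-corrected normal approximation with continuity correction,
and complete enumeration of group assignments when the smaller sample has
at most 8 observations (the pipeline default compares raw index values
between phases, not Z-scores). `sample_size_check()` encodes the
300-total / 150-per-sex validation minimum. `ks_normality()` wraps the
classical one-sample Kolmogorov-Smirnov test against the standard normal.

## Problem sizes in the test suite

The suite exercises the study conditions at sizes chosen to make
Monte-Carlo tolerances meaningful while keeping a laptop run short:
in-sample Z-score moments on one cohort of 10,000; parameter recovery on
about 5,000 records per sex; SBC selection consistency over 20 replicates
of about 1,000 fitted records; suitability over 20 replicates of 1,000;
comparator ranking at 2,000 records against +/-5% and +/-10%
median-shifted copies. At these sizes the well-conditioned quantities —
the log(age) coefficient, sigma, nu, the fitted median surface (within 2%
everywhere), residual moments — recover tightly. The intercept and
log(height) coefficient individually do not, and cannot: the adult height
range spans barely 15 cm, so log(height) is nearly collinear with the
intercept and their individual sampling SDs (about 0.2-0.4 for the
intercept at n = 5000) dwarf any tight recovery target, for any estimator.
The median *surface* they jointly define is what the package asserts.

## Known limitations

- The packaged ISE is incomplete by necessity: its declared age-spline
  terms evaluate as zero until refitted on real data, so packaged
  predictions are exact only up to those unpublished smooth corrections
  (the FVC equations, which declare no splines, are complete).
- The generator's FEV1-consistency compromise described above.
- BCPE fits with very heavy tails (`tau` well below 1) are outside the
  tested envelope, as are cohorts smaller than about 50 records per sex.
- Only height and age enter the models, matching the source equations; no
  other covariates are supported.
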