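---
title: "Modelling drug response from longitudinal health records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling drug response from longitudinal health records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxresponse)
```

## The problem

Pharmacogenetic studies ask whether genotype modulates the effect of a drug
on a biomarker — whether, say, carriers of a variant experience a larger
LDL-cholesterol reduction after starting a statin. Randomized trials with
genotyping are small; biobanks coupled to primary-care records are large but
messy: prescriptions arrive as free-text-annotated drug codes at irregular
dates, biomarker measures follow no protocol, and patients switch drugs,
take same-class co-medications or stop refilling. `pgxresponse` implements
the full path from such records to pharmacogenetic effect estimates, along
with a synthetic-data generator so that every stage can be validated against
known truth, and a closed-form analysis of the bias introduced by the
common-but-wrong practice of adjusting change scores for baseline levels.

## The longitudinal phenotype model

The generator and the theory share one model for the biomarker level $Y_t$
of a person with allele dosage $G$:

$$Y_t = \beta_0 G + \beta_E E_t + \gamma_E G E_t + D_t(\beta_D + \gamma_D G) + \epsilon_t$$

where $\beta_0$ is the baseline genetic effect, $E_t$ the environment with
effect $\beta_E$ and interaction $\gamma_E$, $D_t \in \{0,1\}$ the drug
indicator, $\beta_D$ the mean drug effect, $\gamma_D$ the pharmacogenetic
effect, and $\epsilon_t$ occasion noise. With `scale = "log"` the linear
predictor is exponentiated, giving multiplicative (relative) drug action.

Writing $Y_{t_0}$ for a pre-treatment (baseline) and $Y_{t_1}$ for a
post-treatment measure, the change score collapses to

$$\Delta Y = Y_{t_1} - Y_{t_0} = \beta_D + \gamma_D G + \delta_{01},$$

with $\delta_{01}$ collecting the environment and occasion residuals, which
are independent of $G$. Everything the variant contributes to the *level*
($\beta_0 G$) cancels, so an ordinary regression of $\Delta Y$ on dosage is
unbiased for $\gamma_D$ — this is the package's "unadjusted" (correct)
model, and the reason the derived difference is deliberately **not**
adjusted for baseline.

### Why baseline adjustment biases the estimate

Decompose the baseline as $Y_0 = \beta_0 G + P + e_0$, where $P$ (variance
$v_p$) collects every component shared by both timepoints — persistent
environment scaled by its effect, polygenic background, other variants —
and $e_0$ (variance $v_o$) is the occasion noise of that one measure. The
population coefficient on $G$ in the joint least-squares of $\Delta Y$ on
$(G, Y_0)$ follows from the $2\times2$ normal equations:

$$E[\hat b_{\text{adj}}] = \gamma_D + \beta_0 \frac{v_o}{v_p + v_o}.$$

The bias term vanishes when $\beta_0 = 0$ or when the baseline is measured
without occasion noise ($v_o \to 0$), and is linear in $\beta_0$; the
strength of the spurious association signal (the squared standardized
effect, i.e. the test's non-centrality) therefore grows *quadratically* in
$\beta_0$. `expected_adjusted_estimate()` and `expected_adjusted_stat()`
expose both quantities, and `bias_curve()` verifies them against brute-force
Monte-Carlo regression:

```{r bias}
p <- bias_model_params(beta0 = 0.5, gammaD = 0, maf = 0.3,
                       var_persistent = 0.5, var_occasion = 0.5)
expected_adjusted_estimate(p)   # pure artifact: gammaD is 0
bias_curve(c(-0.4, 0, 0.4), p, n_per_rep = 5000, reps = 5, seed = 1)
```

The same mechanism is intuitive as regression to the mean: conditional on a
high observed baseline, part of that height is occasion noise that will not
recur, so the next measure falls; a variant (or polygenic score) that truly
raises the underlying level "explains away" part of the observed baseline
and picks up a positive coefficient. The package demonstrates the practical
consequences in two ways:

- `control_signature()` — with $\beta_0 \ne 0,\ \gamma_D = 0$, drug-naive
  controls show a null longitudinal-change association that becomes strongly
  significant upon baseline adjustment, with the *same* expected coefficient
  as in the treated group. A "replicating" hit that also appears in the
  control group is an artifact, not pharmacogenetics.
- `sign_reversal_demo()` — with a polygenic score raising baseline and a
  multiplicative drug effect, higher scores mean larger absolute reductions
  (negative coefficient), yet baseline adjustment *reverses the sign*. Under
  the model algebra the adjusted coefficients of treated and controls are
  tied through the multiplicative factor $e^{\beta_D}$: exactly equal only
  when the drug effect is additive, and proportionally separated otherwise.
  The demo's default emulates a statin-like 35% reduction.

## Cohort emulation: from records to a response cohort

`qc_cascade()` reconstructs regimens and applies the exclusion cascade in a
fixed order, counting each person at their first failing stage so that the
audit conserves exactly (input = survivors + removals):

1. **Co-medication** — same-class drugs within ±365 days of the first
   primary-medication prescription exclude a person; fixed-dose same-class
   combination products always exclude. In the lenient scenario a
   configured add-on (e.g. a sulfonylurea under a metformin analysis)
   present both before and after start becomes a covariate flag instead.
2. **Baseline and post-treatment measures** available in their windows.
   Baseline: 90 days (stringent) or 365 days (lenient) before start through
   7 days after (inclusive); post: 183 days through 548 (stringent) or 730
   (lenient) days, half-open. Either the single closest measure (baseline:
   smallest $|$date − start$|$, ties resolved to the earlier, pre-treatment
   one; post: earliest) or the average of all in-window measures.
3. **Prior record** — some unrelated record at least 730 days before start,
   so a change of provider is not mistaken for a first prescription.
4. **Prescription after the post measure** — the person is still in care.
5. **No drug change** between start and the post measure: stringent
   excludes type *and* dose changes, lenient excludes type changes only and
   keeps the start dose as a covariate (doses are parsed from the free-text
   description; missing doses are imputed by the per-drug median).
6. **Regularity** — the fraction of consecutive 61-day ("two-month")
   windows between start and the post measure containing a refill; a
   trailing partial window counts if at least 30 days long. The default
   threshold is 0.8; a `min_one` mode (at least one refill strictly between
   start and the post measure) is provided for sparser prescription
   sources. The numeric cutoff is a free parameter of the design — reported
   regularities differ widely between record systems — so it is left
   configurable rather than hard-coded.
7. **Minimum baseline** (e.g. LDL ≥ 2 mmol/L) so a floor effect cannot
   masquerade as non-response; thresholds for other biomarkers are
   configurable and unset by default.

Drug types taken by fewer than 20 survivors are then dropped, and cohorts
below 500 persons are flagged with a warning rather than suppressed.

Two structural notes. First, the stringent-within-lenient monotonicity
property (every stringent survivor is a lenient survivor) holds exactly in
single-measure mode, where both scenarios necessarily select the same
baseline and post measures; in average mode the selected post *date* can
differ between scenarios, which moves the regularity interval, so
monotonicity is only asserted for single measures. Second, dates are
integer days from an arbitrary epoch, with half-open windows except the
inclusive "+7 days" baseline bound.

## What the generator emulates, and what it does not

`simulate_ehr()` produces genotypes (binomial dosages at configurable
allele frequencies), persistent-plus-occasion environments, registration
records, Poisson-sampled visit dates, and prescription streams with
configurable refill regularity, co-medication, combination products,
add-ons and switches — every behaviour the cascade filters. Deliberate
simplifications, documented as such:

- The drug effect switches on at the first prescription with no
  pharmacokinetic ramp; the ≥ 183-day post window makes steady state a
  reasonable reading.
- The environment's temporal structure is a single persistent draw per
  person plus i.i.d. occasion noise — the minimal split that gives the
  baseline the variance decomposition the bias theory needs. Real
  autocorrelation structures (seasonality, drift) are not emulated.
- Visits are non-informative: measurement times are independent of
  biomarker values, unlike real records where sick patients are measured
  more often.
- Confounder covariates are generated noise standing in for genotype
  principal components; no relatedness or population structure exists in
  the simulated panel, so plain per-variant least squares estimates the
  same estimand a mixed-model engine would target on real data.

Passing tests on this generator therefore validate the *logic* of the
pipeline and the *algebra* of the estimators, not robustness to structured
missingness or confounding in any particular real record system.

## Numerical and design choices

- **Inverse normal transform** uses the Blom offset,
  $\Phi^{-1}((r - 3/8)/(n + 1/4))$, with ties given mean ranks; the offset
  is configurable since conventions differ.
- **Baseline adjustment** is implemented as joint regression
  ($\Delta Y \sim G + Y_0$), the common practice in association studies,
  rather than two-stage residualization; the two give the same coefficient
  and differ only in the standard error.
- **HbA1c units** convert through the NGSP–IFCC master equation
  (NGSP% = 0.09148 × IFCC + 2.152).
- **Quantile strata** assign boundary values to the lower bin; quintile
  boundaries are computed on the analysis sample.
- **Effect alleles**: the reported effect is per counted allele of the
  dosage; flipping the dosage to $2-g$ flips the sign exactly (tested).
- **Seeds**: one master seed per run; every stochastic stage draws from an
  independently derived substream, so stages can be re-run in isolation and
  identical configurations yield identical outputs.
- **Degenerate inputs**: monomorphic variants are flagged and never fitted;
  non-positive values under the log-relative response drop the row with a
  recorded reason; aliased covariate columns are dropped with a warning.

## Problem sizes used in the packaged checks

The packaged verification suite exercises: estimand recovery on a
3×3 grid of $(\beta_0, \gamma_D)$ with cohorts of 20,000 and 200 replicates
per point; the bias oracle on a 5×5 parameter grid with single Monte-Carlo
fits of $n = 10^6$; negative-control and sign-reversal demonstrations at
20,000 per group; type-I calibration over 1,000 independent null variants;
and an end-to-end statin-like discovery scenario (20 variants, two true
signals) at $n = 20{,}000$ with 20 seeded replicates. These sizes give
Monte-Carlo standard errors a small fraction of the effects being checked
while keeping a full run in the minutes range on one core.

## Known limitations

Cross-class polypharmacy is not modelled; the code map is a toy stand-in
for real drug vocabularies; no LD, relatedness or rare-variant machinery is
included (the variant panel is generated independent, making clumping
unnecessary); and real-cohort effect sizes depend on access-controlled
biobank data, so the package asserts model-implied signs, identities and
calibrations rather than reproducing published magnitudes.
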