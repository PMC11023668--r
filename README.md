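# pgxresponse

Pharmacogenetic drug-response phenotypes from longitudinal health records.

Biobank-linked electronic health records make it possible to ask whether
genotype modulates drug efficacy — for example whether a variant changes the
LDL-cholesterol drop after starting a statin — but turning raw prescription
and measurement streams into a defensible drug-response phenotype takes a
long chain of decisions: reconstructing regimens, excluding co-medicated or
non-adherent patients, selecting baseline and post-treatment measures, and
choosing the regression model. `pgxresponse` implements that chain, a
synthetic-record generator to validate every link against known truth, and
the theory of why one popular modelling choice (adjusting change scores for
baseline) produces spurious genetics.

## The model

Biomarker levels are modelled as

    Y_t = beta0*G + betaE*E_t + gammaE*G*E_t + D_t*(betaD + gammaD*G) + eps_t

with `G` the allele dosage, `D_t` the drug indicator, `beta0` the baseline
genetic effect and `gammaD` the pharmacogenetic effect (optionally on the
log scale for multiplicative drug action). The change score between a
post-treatment and a baseline measure collapses to

    deltaY = betaD + gammaD*G + noise,

so regressing the (covariate-adjusted) difference on dosage — **without**
baseline adjustment — estimates `gammaD` unbiasedly. Appending the baseline
to the covariates instead yields

    E[b_adj] = gammaD + beta0 * v_o / (v_p + v_o),

where `v_o` is the occasion-noise variance and `v_p` the variance shared by
both timepoints: a pure artifact whenever the variant also moves the
baseline, with an association signal that grows as `beta0^2`. The package
provides both the estimators and this closed form, verified against
Monte-Carlo regression.

## Worked example

An end-to-end synthetic study: 6,000 statin initiators, 20 independent
variants of which two (`v03`, `v11`) carry both a baseline and a
pharmacogenetic effect, multiplicative drug action of about −35%:

```r
library(pgxresponse)
sc  <- scenario_statin_like(n = 6000)
res <- run_scenario(sc, seed = 11)
print(res$audit)
#> QC audit (lenient filtering, average measures)
#>   candidates: 5883
#>   removed at comed                     314
#>   removed at baseline_post_measures    351
#>   removed at prior_record                0
#>   removed at rx_after_post               1
#>   removed at drug_change               122
#>   removed at regularity                652
#>   removed at min_baseline                6
#>   removed at drug_group_size             0
#>   survivors:  4437
```

The audit conserves exactly (5,883 candidates = 4,437 survivors + 1,446
stage removals; each person is counted at its first failing stage). The
variant scan flags exactly the two planted signals at the Bonferroni
threshold 0.05/20, and shows the baseline-adjustment bias next to the
correct model:

```r
subset(res$scan, mode == "log_relative" & variant_id %in% c("v03", "v11"))
#>  variant_id             model         mode    beta      se         p    n   eaf
#>         v03 baseline_adjusted log_relative  0.0782 0.00240 2.40e-208 4437 0.304
#>         v03        unadjusted log_relative  0.0509 0.00261  1.55e-81 4437 0.304
#>         v11 baseline_adjusted log_relative -0.0246 0.00290  3.01e-17 4437 0.299
#>         v11        unadjusted log_relative -0.0497 0.00264  2.46e-76 4437 0.299
```

The unadjusted estimates sit on the simulated truths (`gammaD` = +0.05 and
−0.05); the baseline-adjusted estimates are shifted by `beta0 * v_o/(v_p+v_o)`
— inflated for `v03`, attenuated for `v11`.

The polygenic-score sign reversal, with drug-naive controls as the negative
control:

```r
sign_reversal_demo(n = 20000, seed = 3)
#> Sign-reversal demonstration (n = 20000 per group, drug effect = -35.0%)
#>    group                   model     beta      se     p
#>  treated              unadjusted -0.21800 0.00406 0.000
#>  treated       baseline_adjusted  0.17169 0.00352 0.000
#>  control          control_change -0.00201 0.00450 0.654
#>  control control_change_adjusted  0.25783 0.00537 0.000
```

Higher polygenic burden means a *larger* absolute reduction (−0.218 per SD
of score); baseline adjustment reverses the sign (+0.172) and manufactures
the same artifact in untreated controls (+0.258), where the unadjusted
association is null — the signature separating pharmacogenetics from
baseline genetics.

Replication counting over the bundled seven-signal summary fixture:

```r
replication_count_demo()
#> $bonferroni_threshold    0.00714
#> $n_replicated_bonferroni 2
#> $n_replicated_nominal    4
#> $n_concordant_nominal    4
```

See `vignettes/drug-response-modelling.Rmd` for the model, the QC cascade,
the bias algebra and the design choices in full.

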