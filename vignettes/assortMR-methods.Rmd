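---
title: "Disentangling spousal concordance: models and methods in assortMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disentangling spousal concordance: models and methods in assortMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Spouses resemble each other on alcohol consumption far more than chance
predicts. Four mechanisms can produce that resemblance:

1. **Assortative mating** — drinking behaviour itself influences mate
   choice, so similarity exists *before* the couple forms.
2. **Social homogamy** — a shared social or ancestral context (a
   confounder) drives both mate choice and drinking, with no direct effect
   of the behaviour on pairing.
3. **Partner interaction** — spouses converge during the relationship.
4. **Relationship dissolution** — dissimilar couples separate and drop out
   of the sampled population, leaving concordant survivors.

Genetics separates these. A genotype is fixed at conception, so:

* an association between one spouse's genotype at a drinking-related
  variant and the *partner's* phenotype (cross-spouse Mendelian
  randomization) excludes social homogamy, because the genotype is not
  confounded by adult social context;
* genotypic concordance between spouses excludes partner interaction too,
  because no amount of within-relationship influence can change either
  germline.

`assortMR` implements this logic end to end: a couple simulator that can
generate each mechanism (and sequential mixtures), the spouse-pair
derivation used for household-based biobanks, the MR estimator suite,
concordance regressions, stratification diagnostics, and the closed-form
expectations used to validate everything.

## Closed-form expectations

Let P be the phenotype (variance standardized), G a genetic score with
within-individual correlation $\sqrt{h^2}$ with P, and C the spousal
phenotypic correlation produced by assortment. Under joint normality and
linear mate selection, projecting the partner's phenotype and score on the
index member's score gives

$$\mathrm{corr}(G_I, P_{partner}) = C\sqrt{h^2}, \qquad
  \mathrm{corr}(G_I, G_{partner}) = C h^2 .$$

Both are attenuated relative to C unless the score captures all phenotypic
variance — which is why genotype-level estimates of assortment look small,
and why the Wald ratio (outcome-stage slope over exposure-stage slope)
recovers C itself: per effect allele, the exposure stage estimates
$\beta$, the outcome stage $C\beta$, and their ratio is C regardless of
$h^2$ (`mr_rescaling_check()`). `expected_correlations()` returns these
quantities and is the oracle for the simulator tests: on a
$3\times3$ grid of $(C, h^2) \in \{0.1,0.3,0.5\}\times\{0.1,0.3,0.6\}$ at
50,000 couples, the empirical correlations from `simulate_cohort()` agree
with the expectations within three Monte-Carlo standard errors (the
acceptance suite recomputes this).

The derivation assumes single-round assortment under joint normality; it
ignores left-censoring of consumption at zero and any nonlinearity in mate
selection, which is why the simulator offers `censor = FALSE` for
theory-recovery checks (below).

## The couple simulator

`simulate_cohort(sim_config(...))` generates individuals on a
1000 km × 1000 km planar grid (UK-style rounded easting/northing
coordinates; distances are Euclidean km), genotypes, phenotypes,
households and couples.

**Genetics.** One focal variant emulates a low-frequency, large-effect
alcohol-metabolism SNP (ADH1B rs1229984-like): default effect-allele
frequency 2.5% at the grid centre and −4 units/week per allele (the rare
allele suppresses drinking). Its frequency follows a logistic cline,
`logit p = logit(maf_focal) + g_north (north − 500) + g_east (east − 500)`,
and genotypes are drawn in Hardy–Weinberg proportions at each birth
location — so each neighbourhood is in HWE while the pooled cohort shows a
Wahlund heterozygote deficit when the cline is steep. A panel of
`n_pgs_snps` independent variants (default 1000, giving a marker pool
whose relatedness estimator has sampling SD about 1/√M ≈ 0.03) carries
polygenic weights scaled so the score explains `h2_pgs` of phenotypic
variance (default 0.13, a published common-variant heritability for
self-reported consumption). An optional tightly linked block with
configurable pairwise r² exists purely to exercise LD pruning.

**Phenotype.** The latent (formation-time) phenotype is
`mean + beta_focal·g + PGS + confounder + residual`, with the variance
budget specified in fractions (`h2_pgs`, `var_confounder`; impossible
budgets are rejected). Defaults: mean 10, SD 9 units/week — right-skewed
realism is obtained by left-censoring at zero and decomposing the realized
value into integer beverage counts (measures of spirits = 1 unit, glasses
of wine = 2, pints of beer/cider = 2.5), from which the analysis phenotype
is re-derived exactly as for questionnaire data. Censoring plus integer
decomposition attenuates slopes slightly; tests that validate the
closed-form theory therefore set `censor = FALSE` to expose the continuous
value, and tests on the questionnaire scale use direction/recovery
tolerances rather than exact equalities.

**Couple formation.** Members are paired by noisy rank matching: both
sexes are sorted by `standardized score + √v · noise` and paired by rank.
The noise variance v is calibrated by bisection with common random numbers
so that the spousal correlation of the pairing objective hits `assort_C`
(achievable targets only; an unreachable target is flagged and the maximal
pairing used). Under `mechanism = "assortative"` the score is the latent
phenotype; under `"homogamy"` it is the confounder alone — or, with
`homogamy_on = "geography"`, the birth-coordinate projection along the
cline axis, which produces genotypic concordance purely through shared
ancestry-by-geography. `"interaction"` pairs at random and then moves each
realized phenotype toward the couple mean with weight
`min(1, kappa · duration)`; `"dissolution"` pairs at random and removes
couples with probability `plogis(base + lambda·|difference|)`. Mechanisms
compose sequentially (formation → interaction → dissolution). Relationship
durations are uniform on (0, 40) years and couple mean age is
`32 + duration + noise`, so mean age proxies duration by construction —
the spousal age correlation and duration distribution are modelling
choices, not estimates.

**Households and decoys.** Surviving couples share all eight household
matching fields (cohabiting-with-spouse flag, years at address, occupants,
vehicles, accommodation type, rental status, home coordinates rounded to
km); dissolved couples and singles get their own households.
`inject_decoys()` adds the three failure modes the derivation must reject:
same-sex cohabiting pairs, opposite-sex full siblings (genotypes drawn by
Mendelian transmission from simulated parents, expected relatedness 0.5),
and household-key trios.

**Determinism.** A single master seed drives everything through numbered
child streams (geography, marker panel, genotypes, phenotype components,
pairing, durations/dissolution, demographics, questionnaire; decoys use a
dedicated stream), so a configuration is bit-reproducible.

## Spouse-pair derivation

`derive_spouse_pairs()` reproduces the published pipeline in order, with a
per-individual exclusion ledger:

1. **Household matching** — exact equality on all eight fields
   (coordinates compared after rounding to integer km; no fuzziness, since
   none is specified for the original procedure). Keys shared by more than
   two people are excluded wholesale (`key_trio`).
2. **Same-sex filter** — unconfirmed same-sex pairs removed.
3. **Parental-death filter** — pairs where both members report the same
   father's *and* mother's age at death (all four values present) are
   removed as probable relatives; missing values never trigger removal.
4. **Relatedness filter** — the GRM entry
   $\frac{1}{M}\sum_i (g_{ij}-2p_i)(g_{ik}-2p_i)/(2 p_i (1-p_i))$
   over LD-pruned markers (window 50 kb, r² < 0.1; greedy left-to-right
   pass that guarantees every retained within-window pair is below the
   threshold), with allele frequencies taken from the candidate-pair
   sample itself. Pairs with estimate strictly greater than 0.1 are
   excluded — the strict inequality is adopted verbatim from the published
   threshold wording, which does not state otherwise.

Because frequencies and pruning are recomputed from the input genotypes,
re-running the derivation on its own output returns the same set
(idempotence is asserted in the tests).

## Analysis conventions

* **Phenotypic / genotypic / PGS concordance** use one row per couple. The
  reference member is the first listed by default or seeded-random
  (`ref = "random"`); the estimand is symmetric and tests assert the
  choice moves estimates only at Monte-Carlo order. Standard errors are
  conventional OLS/GLM errors without couple clustering, matching the
  original analyses.
* **Cross-spouse MR** uses each individual once in the exposure stage (own
  genotype on own phenotype) and twice in the outcome stage (as reference
  and as partner). The partner's sex is excluded from outcome-stage
  covariates — it is collinear with the index member's sex in
  opposite-sex pairs. Principal components (truncated SVD of the
  centred-scaled dosage matrix, top 10) stand in for the genotyping-array
  PCs of a real cohort.
* **Wald ratio** SE is first-order: `se_outcome / |beta_exposure|`,
  matching the convention in which the printed interval is the
  outcome-stage interval rescaled by the exposure slope; a second-order
  option propagates exposure-stage uncertainty.
* **IVW (fixed effects)** weights ratios by `beta_exposure² / se_outcome²`
  and reports Cochran's Q with `I² = max(0, (Q − (k−1))/Q)`.
* **MR-Egger** is weighted least squares with intercept (weights
  `1/se_outcome²`, exposure betas harmonized positive) with the residual
  variance estimated from the fit (k − 2 df); the intercept is the average
  directional pleiotropic effect.
* **Weighted median** interpolates the inverse-variance-weighted ratio
  order statistics at cumulative weight one half. **Weighted mode** takes
  the argmax of a weighted normal-kernel density over the ratios on a
  fixed 10,000-point grid, bandwidth = `bandwidth_factor` × the modified
  Silverman rule `0.9·min(sd, mad)·k^{-1/5}`. Both get parametric
  bootstrap SEs (default 5000 seeded draws of `Normal(ratio_i, se_i)`);
  the bootstrap default, the bandwidth factor of 1 and the grid argmax are
  package decisions — the original report is silent on them — chosen so
  the point estimates are exactly reproducible.
* **Additive vs dominant coding** is settled by comparing the additive fit
  against the saturated genotype-factor model (F-test) with AIC as the
  tie-breaker; a variant with no detectable effect is flagged rather than
  classified.
* **Outlier rule** for weekly units: mean and SD from the non-zero
  drinkers, pairs removed when either member deviates more than 5 SD.
  Applied two-sided by default (absolute deviation); a one-sided switch
  exists because the original wording ("more than 5 S.D. from the mean")
  is ambiguous.
* **Education recode**: degree → 21 years; leaving age below 15 → 15;
  born outside England/Scotland/Wales → excluded from education-adjusted
  analyses.

## Stratification diagnostics

`hwe_test()` is the 1-df goodness-of-fit chi-square (monomorphic input
returns 0 by convention, flagged). `allele_freq_diff()` is the 2×2
allele-count chi-square without continuity correction.
`within_centre_meta()` estimates genotypic concordance per recruitment
centre and combines by fixed-effects inverse variance; centres under
`min_pairs` (default 50 — the operational meaning of "convergence issues"
in small strata) or with failed regressions are excluded with reasons.
`meta_from_table()` accepts a published-style stratum table and recovers
SEs by the symmetric convention `SE = CI width / 3.92`; the shipped
`inst/extdata/ukb_centre_strata.tsv` carries the published 20-centre
spousal-concordance strata (one row's printed interval is asymmetric
around its beta — likely typographical; the symmetric convention still
reproduces the published combined row to printed precision, as the
acceptance suite verifies). `distance_stratify()` splits pairs at 100 km
of birth distance — exactly-100 km pairs go to the "within" stratum, a
boundary the source leaves unstated — and compares genotypic and MR
estimates across strata with a Z-test.

## Problem sizes and numerical choices in the test-suite

The suites validate at sizes chosen to keep Monte-Carlo error well below
the effects tested: mechanism discrimination at 20,000 couples;
theory-oracle recovery at 50,000 couples per grid cell; estimator oracles
on 100 random small instances at 10⁻¹⁰ agreement plus a 2,000-replicate
check that Cochran's Q holds its nominal level; derivation recall on a
1,350-couple cohort with 45 injected decoy units and a 1,000-marker GRM
pool. The mechanism-discrimination configuration gives the focal variant
20% of phenotypic variance — far more than an ADH1B-like variant — because
the power to detect *genotypic* concordance scales as
$C h^2_{focal}\sqrt{n}$: at realistic effect sizes the published design
needed ~47,000 pairs, and the discrimination property is about the logic,
not the cohort size. The Wahlund power check pools two strata with allele
frequencies 0.4% and 2.4% (Δp = 0.02 around a low-frequency variant) at
n = 200,000: detectability scales as $n\,\mathrm{Var}(p)^2/(\bar p\bar
q)^2$, so the same Δp around a 3% variant would be essentially
undetectable at this n, and the frequencies were fixed once from that
power calculation.

## Limitations

The simulator emulates the statistical structure the analyses assume, not
real questionnaire data: no reporting error or "prefer not to say"
non-response process, no realistic LD beyond the optional test block, no
multi-generation assortment dynamics (single-round pairing only), no
secular trends in assortment, and an idealized linear mate-selection rule.
Passing tests therefore demonstrate that the estimators recover the
mechanisms they target under the stated model — not that any particular
real-world concordance is causal. Mean couple age is a proxy for
relationship length by construction here; in real data that equivalence
is an assumption.
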