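---
title: "Deriving and validating phosphoprotein-anchored gene signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating phosphoprotein-anchored gene signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigscore)
library(dplyr)
```

## The problem

Phosphoprotein measurements (for instance pSTAT3 by reverse-phase protein
array, RPPA) directly read out pathway activation, but most clinical cohorts
only carry transcriptomes. `sigscore` implements the workflow that bridges
the two: anchor a signed gene-expression signature to a protein readout in
one cohort, then use the signature as a transcriptomic surrogate for pathway
activation in cohorts that never saw the protein assay — and ask whether
that surrogate predicts who benefits from a targeted treatment.

The workflow has five stages, each an exported function family:

1. **Group** samples by protein level (`quartile_groups()`,
   `zscore_groups()`, `sd_groups()`, `median_groups()`).
2. **Derive** a signed signature by differential expression between
   protein-high and protein-low samples (`derive_signature()`).
3. **Score** any expression matrix with the signature
   (`score_samples()`): for sample $j$,
   $\mathrm{Sigscore}_j = \sum_{i=1}^{n} S_i \, e_{ij}$, where
   $S_i \in \{-1, +1\}$ is the gene's direction and $e_{ij}$ its
   log-scale expression.
4. **Validate** the score against proteomic truth (`roc_auc()`,
   `pearson_correlation()`).
5. **Model survival**: Kaplan–Meier, log-rank, Cox proportional hazards,
   and the likelihood-ratio test for a treatment-by-score interaction
   (`kaplan_meier()`, `log_rank()`, `cox_fit()`, `interaction_lrt()`).

`run_pipeline()` chains the stages over files and writes a manifest;
`run_transfer_validation()` runs the derive-here/validate-there pattern on
two in-memory cohorts with a sample-leakage guard.

## The robust Welch test

Protein-anchored derivation compares small groups (often quartiles of an
already small cohort), so the test must resist outliers without giving up
calibration. The default test statistic compares group medians,

$$ t^* = \frac{\mathrm{med}(x) - \mathrm{med}(y)}
   {\sqrt{\frac{\pi}{2}\left(\frac{s_x^2}{n_x} + \frac{s_y^2}{n_y}\right)}}, $$

with $s$ the normal-consistent scaled MAD ($1.4826 \times \mathrm{MAD}$).
Two corrections matter and are easy to miss:

* the sampling variance of a median exceeds that of a mean by the factor
  $\pi/2$ for Gaussian data — without it the statistic's null standard
  deviation is about 1.25 and the test rejects roughly 12% of true nulls at
  a nominal 5%;
* the MAD estimates a variance with asymptotic relative efficiency
  $\approx 0.37$, so each group contributes $0.3675\,n_g$ effective degrees
  of freedom to the Welch–Satterthwaite combination, not $n_g - 1$. This
  keeps the far tail — where Benjamini–Hochberg selection actually operates —
  calibrated.

With both corrections the test holds its size (about 4–5% at $\alpha=0.05$
for $n \ge 15$ per group; the suite checks this by simulation). The cost is
power: the median is a less efficient location estimate than the mean, so at
small group sizes the robust mode selects fewer genes than `mode =
"classic"` (the standard Welch t-test, available as a switch). Significant
genes enter the signature with coefficient $+1$ when the high-protein group
sits higher, $-1$ otherwise; a gene whose locations tie exactly is never
selected, because a signed coefficient would be undefined.

## The synthetic cohort generator

No patient-level cohort ships with the package. Instead
`simulate_cohort()` generates data with the joint structure the analysis
assumes, so every stage can be tested against known truth. One latent
Bernoulli activation variable $a_j$ drives everything:

* protein: $\mathrm{protein}_j = \delta_p a_j + \varepsilon$,
* planted gene $i$: $e_{ij} = S_i\,\delta_e\,a_j + \varepsilon$, with signs
  alternating $+1, -1, \dots$ so both signature directions are exercised;
  all other genes are pure noise,
* survival: exponential proportional hazards with linear predictor
  $\beta_T T_j + \beta_a a_j + \beta_{Ta} T_j a_j$ and uniform censoring on
  $[0, \tau]$, with $\tau$ calibrated by bisection to the target censoring
  fraction (derivative-free and reproducible).

Default parameters, chosen once as a realistic regime for an
adjuvant-trial-sized cohort and then left alone: 60 samples, 2000 genes of
which 100 are planted at $\delta_e = 1.5$ SD (the per-gene shift is
deliberately arbitrary — nothing in a real cohort pins it down — and sized so
that recovery tests discriminate), protein shift $\delta_p = 2$ SD (an RPPA
readout dichotomizable into clear "up"/"down" groups presupposes clear
separation; this value yields a score-protein correlation near 0.65, the
regime the workflow is designed for), activation prevalence 0.5, treatment
log HR $-0.5$ with interaction log HR $+1.0$ (treatment benefit lost in
activated tumors), and a 30% censoring target so that simulation studies of
the survival machinery are event-rich and their power is governed by the
effect sizes, not by follow-up. One integer seed drives separate
deterministic streams per component (activation, protein, expression,
clinical covariates, survival, censoring), so enlarging the gene panel
never perturbs the survival draws; the same config is guaranteed to
reproduce a byte-identical cohort.

What the generator does *not* emulate: gene–gene correlation beyond the
shared latent activation, batch and platform effects, probe-level noise,
FFPE degradation, and non-constant baseline hazards. Tests passing on these
cohorts therefore demonstrate the *statistical machinery* — calibration,
recovery, invariances — not robustness to the messiness of real microarray
or RPPA data.

## Grouping rules and their conventions

Three dichotomization rules mirror common practice: upper/lower quartiles
(derivation), z-score beyond $\pm 0.2$ (consortium-style RPPA tables), and
mean $\pm k\cdot$SD (proteomic truth labels for ROC validation, symmetric
cut-offs, default $k = 1$). Conventions fixed here because every downstream
number depends on them:

* quantiles use linear interpolation at index $(n-1)p$ (the default type-7
  convention shared by the major statistical environments);
* values exactly on a quartile boundary join the extreme group, so groups
  are at least quartile-sized and the rule is deterministic;
* score dichotomization sends values tied at the median to `low`, the
  conservative side for a "high score = poor outcome" claim;
* gene symbols are matched case-sensitively after whitespace trimming —
  silent case-folding hides mapping bugs.

## Validation and survival choices

The AUC is computed as the Mann–Whitney $U$ statistic over high/low truth
pairs divided by $n_{pos} n_{neg}$ (ties count $\tfrac12$), which equals the
trapezoidal area under the threshold-sweep ROC curve exactly; the test suite
asserts that equality to $10^{-10}$ on random instances. Its p-value is the
two-sided tie-corrected normal-approximation Mann–Whitney test — a
deterministic choice in the spirit of the standard ROC toolchain, avoiding
bootstrap variance.

Cox models use the Efron tie approximation (the modern default, and more
accurate than Breslow with the heavily tied follow-up times of
formalin-fixed-era cohorts), Wald confidence intervals per covariate, and a
likelihood-ratio test — not a Wald test — for the single interaction
coefficient: the LRT statistic $2(\ell_{full} - \ell_{reduced})$ is
invariant to affine rescaling of a continuous score, so the result does not
depend on the arbitrary scale of a signed-sum score. The partial-likelihood
optimum is verified in the tests against an independently coded Efron score
function (gradient below $10^{-6}$ in max-norm at the fit).

Two places where the analysis could plausibly have been set up differently,
and what this package does:

* **Stratified dichotomization.** When survival analyses are split by ER
  status, the score median can be taken within stratum or cohort-wide; both
  are offered (`dichotomize_scores(stratify_by = )`), within-stratum being
  the default since a cohort-wide median confounds the stratum comparison
  with score-level differences between strata.
* **Cross-platform scoring.** The raw signed sum is the default score,
  exactly as defined. Transferring a signature across array platforms
  realistically requires per-gene standardization; `standardize` and
  `scale_by_n` are explicit opt-ins, never silently applied.

## Numerical and degenerate-input policy

Missing expression values stay missing at I/O time (never imputed, never
zero-filled); each operation declares its own policy — probe collapsing
averages over observed probes, derivation drops genes with fewer than three
observed values in either group (reporting the count), scoring skips a
missing gene value and reports per-sample matched-gene counts. Zero
dispersion with distinct medians yields an infinite statistic with $p = 0$;
zero dispersion with equal medians is an error. Constant covariates,
single-class truth labels, empty treatment arms, and all-identical scores
are all refused with named errors, while an empty derived signature is a
*warning* (with a structured `empty_signature` status downstream) because it
is a legitimate scientific outcome, not a bug.

## Simulation sizes used by the checks

The acceptance-style checks run at the generator's default study
conditions: one seeded cohort for recovery (2000 genes, 100 planted), 50
seed pairs for transfer AUC and 50 null cohorts for the null AUC band, 1000
replicates at $n = 300$ for interaction-LRT calibration and 500 for power —
sizes at which the binomial noise of the reported rates is a small fraction
of the acceptance margins. The null AUC check scores a fixed ±1 signature on
null cohorts against a *balanced* (median-split) protein truth: with the
mean ± 1 SD rule the truth groups would hold only ~13 samples each and the
null AUC would have standard deviation ≈ 0.115, making a ±0.15 band around
0.5 statistically incoherent; the balanced split (SD ≈ 0.065) is the
configuration that band actually describes. Recovery and transfer checks
derive on the generator's ground-truth activation labels: they measure the
derivation engine against truth; the protein-quartile pathway — whose 15v15
groups at $n = 60$ simply lack power for a robust-test derivation at these
effect sizes, often to the point of an empty signature — is exercised
separately by the grouping and pipeline tests.

## Known limitations

* The robust mode trades power for outlier resistance; with fewer than
  ~10 samples per group, prefer `mode = "classic"` or wider grouping rules.
* The exponential hazard in the generator makes the Cox model correctly
  specified up to the latent-versus-score substitution; real-world
  non-proportionality is out of scope, and no proportionality diagnostics
  are provided.
* `correlation_screen()` adjusts p-values per target, jointly across the
  features tested against that target — not across multiple targets.
* The pipeline consumes already-normalized matrices; array preprocessing,
  batch correction, and RPPA quantification belong upstream.
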