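---
title: "Two-stage discovery and replication of SNP-SNP interactions"
author: "epistage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage discovery and replication of SNP-SNP interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epistage)
```

## The design this package implements

Candidate-gene case-control studies of complex diseases increasingly look
beyond marginal SNP effects to *epistasis*: two variants whose joint effect
on risk is non-additive, possibly with no detectable effect of either SNP
alone. `epistage` implements a complete two-stage workflow for such studies
on candidate panels of up to a few thousand biallelic SNPs:

1. **Single-SNP association** — exact Hardy-Weinberg checks in controls,
   unconditional logistic regression with dominant / recessive /
   log-additive codings (reference group: homozygotes of the most frequent
   control allele), covariate adjustment, best-model selection by AIC, and
   a polytomous likelihood-ratio test of odds-ratio heterogeneity across
   disease subtypes.
2. **Discovery interaction scans** — two built-in two-locus detectors:
   classic MDR (cross-validated case:control-ratio cell labeling scored by
   balanced accuracy) and MB-MDR (per-cell covariate-adjusted logistic
   tests assigning each of the nine two-SNP genotype combinations to
   High / Low / neutral risk, scored by the max Wald statistic with
   permutation p-values). External tools plug in as detector callables.
3. **Consensus** — only pairs flagged by at least *k* detectors advance.
4. **Replication by category forcing** — the discovery H/L/O grid is
   applied *unchanged* to an independent series and tested by phenotype
   permutation; p < 0.05 declares replication. A pooled combined analysis
   with a stage covariate follows for replicated pairs.

Because studies of this kind rarely release genotypes, the package carries
a first-class simulator that generates case-control datasets with the
statistical structure the analysis assumes, which is how the package's own
tests and the `analysis/` scripts exercise the pipeline end to end.

## The MB-MDR statistic, precisely

For a SNP pair, samples fall into the nine cells of minor-allele-count
combinations. For each cell with at least `min_cell` samples (default 10)
we fit a logistic regression of case status on the cell-membership
indicator plus covariates; with `adjust_marginal = TRUE` (the default) the
log-additive codings of both SNPs are added so that a pair acting purely
additively cannot masquerade as an interaction. The cell is labeled `H`
when the indicator coefficient is positive with Wald p below `alpha_cell`
(default 0.1), `L` when negative, `O` otherwise; non-convergent or
separated cell fits stay `O`.

The pair statistic is

$$W = \max(W_H, W_L),$$

where $W_H$ is the squared Wald statistic of the indicator "sample lies in
an H cell" in the same covariate-adjusted logistic model (analogously
$W_L$). An absent or degenerate category contributes $-\infty$; if every
cell is neutral the statistic — and its p-value — is *not available*
(`NA`), the same semantics used in the pipeline's report tables.
Significance comes from permuting the phenotype while covariates stay
attached to samples, recomputing categorization and statistic from scratch
each time, with the add-one estimator
$p = (1 + \#\{W_b \ge W_{obs}\})/(B + 1)$. On tiny datasets the
permutation null can be enumerated exactly (`exact = TRUE`).

The `alpha_cell = 0.1` / `min_cell = 10` defaults are the conventional
screening settings of the MB-MDR literature; the max-Wald form of the
statistic and the permute-phenotype-only scheme are declared package
conventions, isolated behind the detector interface so alternatives can be
swapped in. Replication-stage tests re-use the *discovery* grid: only the
two category-level Wald fits are recomputed on the new series, which makes
stage 2 a single pre-specified test per pair and is why the 0.05 threshold
needs no multiplicity correction (the count of forwarded pairs is always
reported alongside).

### Numerical choices

All MB-MDR inner fits run through a compiled IRLS (Newton scoring with
step-halving-free updates, convergence at max coefficient change below
1e-9, 25-iteration cap). Coefficients above 15 in absolute value are
treated as separation; an affected cell test yields `O`, an affected
category fit $-\infty$. Linearly dependent adjustment columns (e.g. a
stage indicator that coincides with country) are dropped by QR rank
detection before fitting. The compiled fits are verified in the test suite
against `stats::glm` and against closed-form 2x2 logistic Wald statistics
to 1e-6. MDR's fold/pair tabulation is likewise compiled; fold assignment
is stratified by case status, the in-fold threshold `T` is the training
fold's case:control ratio, empty cells are low-risk, cells with cases but
no controls high-risk, and pair ties within a fold resolve to the
lexicographically first pair.

## The synthetic-data generator

`simulate_case_control()` draws individuals from a population model —
independent HWE genotypes at configured MAFs (tagSNPs are treated as
independent markers; linkage disequilibrium is deliberately out of scope),
age ~ Normal(47, 12) truncated to [18, 90], 82% female, configurable
country mix — and applies a logistic penetrance: baseline log-odds (default
-2.5, about 7.6% risk), optional per-SNP dominant / recessive /
log-additive effects, an optional 3x3 grid of log-odds offsets for one
designated pair, and covariate effects. Case-control ascertainment is by
rejection sampling until the requested numbers of diseased and
non-diseased individuals are collected, which keeps the sampling semantics
exact at these prevalences. Case subtypes are filled by quota from a
configurable mix (defaults mirror a realistic thyroid-carcinoma series:
roughly half classic PTC, a quarter follicular-variant PTC, the remainder
other PTC and FTC); a per-subtype model override lets a study plant an
interaction only in, say, classic-PTC cases. Missing genotype calls are
injected uniformly at random.

### Purely epistatic penetrance and the shape it forces

`pure_epistasis_model()` builds a pair model whose cells interact while
*every* single-SNP marginal odds ratio is exactly 1. For the `"corner"`
pattern the four carrier-by-carrier cells (both minor-allele counts >= 1)
carry the requested cell log-OR, and compensating offsets on the remaining
cell groups are solved against the HWE cell weights so that the three
genotype-specific marginal penetrances coincide for both SNPs (verified by
exact nine-cell enumeration at build time and in the tests). Two facts
about this construction are worth knowing. First, the balanced solutions
form a one-parameter family; the package anchors the margin
(carrier-by-non-carrier) cells as close to baseline as the balance allows,
a deterministic, well-conditioned choice. Second, balance forces the
origin (non-carrier/non-carrier) cell up toward the corner's risk — an
XOR-flavored geometry that is intrinsic to marginally neutral
carrier-block epistasis, not an artifact: with over half the population in
an elevated-risk block, no low-risk-everywhere-else solution exists. The
`"checkerboard"` pattern alternates +/- the cell log-OR by cell parity and
is exactly balanced at MAF 0.5 by symmetry.

A single minor-minor double-homozygote high-risk cell, the other natural
reading of "corner", holds ~15 samples at MAF 0.3 and 1100 samples and
cannot support a detectable benchmark interaction at realistic effect
sizes; the carrier-block definition keeps the pure-epistasis contract
while making the planted pair recoverable at the study's series sizes.

## What the defaults emulate, and what they do not

The generator's default study is: a 50-SNP candidate panel (MAFs uniform
on 0.1-0.5), discovery 609 cases / 525 controls, replication 969 / 1040,
one pure-epistasis pair at MAF 0.3 with cell log-OR 1.2 planted in
classic-PTC cases, all other SNPs null. Passing tests on these data show
that the machinery is correct and well calibrated (type-I error, exact
permutation enumeration, oracle equality) and that the two-stage design
recovers a planted pure interaction at these sizes. They do *not* show
robustness to features real genotype data have and the generator omits:
linkage disequilibrium between tagSNPs, population stratification,
genotyping error and differential missingness, covariate-genotype
dependence, and effect-size heterogeneity between series. No per-SNP
call-rate or HWE exclusion filters are applied by default, since the
analysis model applies none; `single_snp_scan()` reports the control-HWE
exact p per SNP so users can filter explicitly.

## Parameters that matter

| parameter | where | default | why |
|---|---|---|---|
| `alpha_cell` | `mbmdr_categorize` | 0.1 | conventional MB-MDR cell screen |
| `min_cell` | `mbmdr_categorize` | 10 | cells below this are neutral (unstable fits) |
| `adjust_marginal` | MB-MDR fits | `TRUE` | keeps purely additive pairs at the null level |
| `B_screen` | `mbmdr_scan` | 999 | screening permutations (two-tier: only pairs above `screen_quantile` of observed W are permuted) |
| `screen_quantile` | `mbmdr_scan` | 0.98 | permutation budget concentrates on the top 2% of pairs |
| `B` (confirmatory) | `mbmdr_permutation_p`, `combined_analysis` | caller-set, up to 1e5 | headline p-values for selected pairs |
| `n_folds` | `mdr_scan` | 10 | canonical MDR cross-validation |
| `cvc_min`, `n_perm` | `mdr_flag` | 6 / 100 | declared numeric stand-in for graphical MDR selection criteria |
| `k_required` | `consensus_select` | 3 (2 with only built-ins) | the at-least-k consensus rule |
| `baseline_logit` | `penetrance_model` | -2.5 | ~7.6% population risk |

Two p-value caveats are deliberate surface features: the post-model-
selection single-SNP p is labeled `model-selected` because it is
anti-conservative under the null, and MB-MDR flagging at `perm p < 0.05`
within a scan is a per-pair screen, not a family-wise criterion — the
consensus rule and the independent replication stage carry the error
control, which is what the two-stage simulations in the test suite check.

## Open choices this package had to make

The design leaves several details unstated in the tradition it follows;
each is a declared, documented decision here: best model chosen by minimum
AIC with a fixed dominant-recessive-log-additive tie order; "per-allele"
mapped to the log-additive coding; the replication statistic is the same
forced-category max-Wald as discovery (internal consistency); minor
alleles are anchored to the full control series once at load time so both
stages share a coding, with lexicographic tie-break at frequency 0.5;
missing genotypes are excluded pairwise per SNP or SNP pair, never by
dropping whole samples; the three external detectors of the original
five-method battery (stepwise SNP harvesting, maximum-entropy modeling,
hierarchical SNP hunting) are separate publications and enter through the
plug-in interface rather than reimplementation, with `k_required`
defaulting to 2-of-2 built-ins. Freedman-Lane-style residual permutation
is out of scope; the permutation contract is plain phenotype
exchangeability.

## Problem sizes used by the shipped analyses

The numbered scripts under `analysis/` and the acceptance script run the
full pipeline at the series sizes above with a 50-SNP panel, 10-fold MDR
CV with a 100-permutation flagging null, two-tier MB-MDR at `B_screen`
199-999, replication at B = 999-9999 and combined analysis at B = 9999;
calibration rates use 200-500 replicates at B = 199-200 and the
heterogeneity test 300-1000 replicates at 300 samples per subtype. These
sizes were chosen so a complete run is a desk-scale computation on one
core while keeping every Monte-Carlo assertion inside comfortable
binomial envelopes.
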