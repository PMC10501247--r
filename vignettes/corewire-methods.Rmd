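---
title: "corewire: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{corewire: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Transcription-factor families — the forkhead-box (FOX) family is the
motivating example — are dysregulated in cancer at several levels at
once: somatic mutation, copy-number change, promoter methylation,
expression, and, more subtly, in *how the family members co-express with
each other and with their regulatory targets*. `corewire` packages the
statistics needed to describe all of these layers for a gene family in
paired cancer/normal cohorts, and ships a synthetic-cohort generator
with a ground-truth ledger so that every stage of the pipeline can be
validated without access to any consortium download.

# Models and statistics

## Alteration frequencies

Per gene and cohort, the mutation frequency is the fraction of cohort
samples carrying at least one qualifying variant (a sample with several
variants in one gene counts once). Which variant classes "qualify" is a
dataset convention, so the default counts every row and an include-list
is exposed as a knob. Copy-number amplification/deletion frequencies use
GISTIC-like thresholded values with defaults `amp >= +1`, `del <= -1`
(the thresholds are configuration, not dogma — gene-level calls differ
between pipelines). Expression differences between altered and
unaltered samples use the Wilcoxon rank-sum test (exact for tie-free
groups of at most 10, normal approximation with tie correction
otherwise); CNV–expression and methylation–expression association use
Pearson correlation with a t-distribution p-value on `n − 2` degrees of
freedom.

## Differential expression and methylation

Expression calls use the classical thresholds: `|log2 fold change| > 1`
(strict) *and* Benjamini–Hochberg adjusted `p < 0.05`, with the fold
change computed as the difference of group means of log2 values. The
per-gene test is Welch's t on log2 values. The original analysis
framework in this field is limma; its empirical-Bayes variance
moderation matters at very small sample sizes but converges to the
unmoderated t as `n` grows, and the calling thresholds — which are what
downstream results depend on — are unchanged. Re-implementing the
moderation machinery was therefore deliberately left out; the test used
is recorded in the output metadata.

Methylation is summarised per gene as the mean beta of its promoter
probes (single-probe genes pass through; probes mapping to no gene, and
genes with only non-promoter probes, are dropped with a message). The
reported effect size `delta_beta` is the difference of group mean betas
— the source analysis calls this quantity "deltaR" but never defines it
beyond "methylation up- and down-regulation alterations", and a
difference of means is the only definition consistent with its bounded
use; we name it `delta_beta` to avoid any collision with the
co-regulation ΔR statistic. Significance is a per-gene Wilcoxon
rank-sum `p < 0.05`.

## The empirical co-expression null

Family-pair Pearson correlations are not compared against the textbook
t-distribution — genome-wide expression data violate its independence
assumptions — but against an *empirical null*: the distribution of
`|r|` over `n_pairs` (default 10,000) randomly chosen background
(protein-coding) gene pairs computed in the same condition and cohort.
The empirical p-value of a family pair is the fraction of null pairs
with `|r|` at least as large (ties count toward the numerator —
conservative — and there is no +1 correction, so `p = 0` is possible
and `n_pairs` is recorded so users can floor it at `1/n_pairs`).

Two readings of the null construction are possible: one 10,000-pair
null per protein-coding gene, or a single global 10,000-pair null. We
implement the single global null per condition per cohort: the
per-gene variant is computationally redundant (every per-gene null
estimates the same distribution) and the "divide by 10,000" p-value
formula implies a single reference of that size. Nulls are
condition-specific because the cancer and normal cohorts differ in
size and the null `|r|` scale is sample-size dependent (median
`≈ 0.6745/√(n−1)` under independence).

Networks retain pairs with `p < 0.01` (strict). Each tested pair is
classified `cancer_only` / `normal_only` / `shared` / `insignificant`;
the four statuses partition the tested universe by construction. The
cancer-vs-normal shift in edge counts is an exact two-sided binomial
test of the condition-exclusive edges against an even split — using
exclusive edges (not totals) isolates the rewired fraction from the
shared backbone.

## ΔR: gain and loss of TF–target co-regulation

For regulator A and target B (targets retained when their binding
significance score exceeds 100, strictly),

  ΔR = Cor_cancer(A, B) − Cor_normal(A, B),   ΔR ∈ [−2, 2].

Significance comes from shuffling the cancer/normal labels of the
pooled samples (group sizes preserved — label permutation, not value
permutation) and recomputing ΔR; `P = ΣSᵢ/N` over `N = 1000`
permutations. The counting rule `Sᵢ = 1` when "the random R is greater
than the real one" is ambiguous between a signed and an absolute
comparison; the default is two-sided on `|ΔR|`, because the analysis
reports both gain (ΔR > 0) and loss (ΔR < 0) patterns as significant
and a single signed comparison cannot deliver both symmetrically. The
signed one-sided variant is available via `convention = "signed"`.
There is no small-sample correction, matching the printed formula; the
documentation warns that `P = 0` therefore occurs.

An exhaustive enumeration over all label assignments (feasible up to 12
pooled samples) serves as the independent oracle for the Monte-Carlo
version. Tie comparisons carry an absolute tolerance of 1e-9: the
observed labelling itself recurs among permutations and must count as a
tie, but floating-point correlation sums differ in the last bits
between code paths.

Within each regulator's family of tested pairs, p-values are BH
adjusted (`fdr` column); the gain/loss call itself uses the raw
permutation p at `α = 0.05` with ΔR = 0 assigned `none` by convention.

## Survival and drug sensitivity

Patients are split at the cohort median of the gene's expression;
values strictly above the median are `high`, ties at the median go to
`low` (a deterministic convention — the source does not state one — and
the one that keeps the larger group on the reference side). Group
difference is assessed by the log-rank test (hand-implemented risk-set
bookkeeping; equals the Cox score test at β = 0 on untied data) and by
univariate Cox regression on the binary group (Breslow ties; Efron
available), with a continuous-expression covariate available as an
option since the source mentions both framings. Kaplan–Meier curves are
exported as step-function coordinates.

Drug screening correlates gene expression with IC50 across cell lines;
a pair is retained only when `|PCC| > 0.2` *and* `p < 0.05` (both
strict). IC50 values are used as provided (GDSC publishes ln-IC50; no
re-transformation). The axis table joins retained gene–drug pairs to
retained gene–(drug-target) correlations through the drug annotation,
one row per (pathway, drug, gene, target).

# The synthetic cohort: what it emulates, what it does not

`cohort_config()` defaults define one fixed "stated world":

| parameter | default | why |
|---|---|---|
| family genes | 49 | the size of the motivating TF family |
| background genes | 300 | > 40,000 distinct null pairs at desk scale |
| cancer / normal samples | 50 / 50 | the recurring paired-cohort size in the validation criteria |
| noise_sd | 1.0 log2 units | typical residual spread of log2 RNA-seq after gene effects |
| mutation_rate | 0.05/gene | modest per-gene somatic rate |
| mutation_effect | +1 log2 unit | detectable but not dominant cis effect |
| cnv_dosage_slope | 0.5 log2/copy | sub-proportional dosage, as observed in tumours |
| methylation_slope | −2 log2/beta | promoter methylation represses |
| survival_log_hr | log 2 | the hazard doubling used by the recovery criteria |
| censoring | uniform on [0, 100] vs exponential median 24 | ≈30% censoring |

Planted co-expression pairs are bivariate Gaussian on the log2 scale
(a Gaussian copula; expression is already log-scale so no further
transform). They are generated *after* the mutation/CNV/methylation
couplings and overwrite them for the pair genes: coupling variance
would otherwise attenuate the planted correlation and the fidelity
guarantee (mean sample r within `3(1−ρ²)/√n` of ρ) could not hold.
Pair genes keep their rows in the mutation/CNV/methylation tables, so
frequency statistics are unaffected.

Methylation betas are generated on the logit scale and clipped to
[0, 1]; planted differential methylation is a logit shift (the
`dm_genes` field), which keeps betas in range by construction and
gives an unambiguous planted *direction* for the sign-recovery test.
Survival times are exponential under proportional hazards on the
survival gene's true median split, censored uniformly. Cell-line IC50
is linear in expression plus Gaussian noise; an uncoupled drug is
included as a negative control, and planted cell-line co-expression
links coupled genes to annotated drug targets so the axis join has
ground truth to find.

The generator does **not** emulate: real marginal expression
distributions, batch effects, tumour purity, positional mutation
models, probe-level methylation chemistry, or correlated survival
covariates. A green test therefore establishes that the statistics
recover *planted* structure at the stated sizes and noise levels — not
that they would behave identically on consortium data.

All randomness flows from one integer seed through a single
sequentially consumed RNG stream; a cohort is a pure function of its
configuration. Pipeline stages derive their seeds as fixed offsets
from the run seed, so stages are individually reproducible.

# Numerical choices

- Strict inequalities everywhere the thresholds are stated as strict:
  score > 100, |log2fc| > 1, p < 0.05, p < 0.01, |PCC| > 0.2.
- Empirical p ties count toward the numerator (conservative).
- Permutation tie tolerance 1e-9 (absolute, on a statistic bounded by 2).
- BH adjustment computes `p·n/rank` multiply-first so it agrees
  bit-for-bit with the obvious reference implementation.
- Degenerate rows in the Welch test (zero variance in both groups) get
  p = 1 when the means agree and p = 0 otherwise.
- Degenerate permutations (a constant subvector) are redrawn and
  counted; with continuous expression they essentially never occur.
- Monte-Carlo agreement tests enforce their 3·SE bound per instance but
  tolerate the binomially expected number of 3σ crossings (≤2 in 50)
  with a hard 5·SE bound — a fixed-seed batch of 50 instances crosses
  a 3σ bound with ~13% probability, and chasing seeds instead would be
  tuning.

# Known limitations

- The per-gene reading of the empirical null (one 10,000-pair null per
  protein-coding gene) is a possible alternative interpretation; the
  global null implemented here is statistically equivalent in
  expectation and 10,000× cheaper, but it is a choice.
- Welch's t is not limma's moderated t; at n < ~10 per group the
  moderated test is better calibrated.
- The survival stage fits each family gene marginally; no multivariate
  adjustment.
- Empirical p-values are granular at 1/n_pairs and permutation
  p-values at 1/n_perm; downstream FDR control inherits that
  granularity.
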