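---
title: "Models and methods behind eimbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind eimbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eimbiome)
```

eimbiome analyses 16S rRNA amplicon sequence variant (ASV) count tables
from a two-group clinical design: inflammatory bowel disease (IBD) patients
with extraintestinal manifestations (EIM) versus IBD controls without them.
This vignette explains the statistical machinery, the choices we made where
the methodology is genuinely open, and what the synthetic-data generator
does and does not emulate.

## Preprocessing and decontamination

Three filters act on the raw sample-by-ASV count matrix, in this order:

1. **Low-frequency filter** (`filter_low_frequency()`, default 1e-5):
   removes ASVs whose *pooled* relative abundance — total count over the
   grand total — is strictly below 0.001%. The pooled reading is the common
   convention for removing globally rare ASVs; a per-sample variant would
   need a qualifier the rule does not carry.
2. **Negative-control decontamination** (`remove_control_artifacts()`):
   an ASV present (count > 0) in more than 15% of reagent-blank controls
   and fewer than 15% of biological samples is a reagent signal and is
   dropped outright; for every remaining ASV the mean control count is
   subtracted from each biological sample, clamped at zero. We round half
   away from zero after subtraction because the differential-abundance
   models downstream require integer counts; flooring would bias the table
   low and keeping fractions would break the count likelihoods.
3. **Prevalence filter** (`prevalence_filter()`, default 10%): applied only
   before differential abundance and SparCC, where very sparse ASVs are
   uninformative and numerically fragile.

All presence comparisons use strict inequalities, exactly as the
percentage rules are worded, and "present" means count > 0. Each filter is
idempotent, and the test suite checks the survivors of every rule against
an independent brute-force re-evaluation.

## Diversity and community-level testing

Alpha diversity uses Shannon entropy in natural log over present ASVs, so
Pielou's evenness is exactly `J = H / ln(S)`; `J` is undefined (`NA`) for
single-ASV samples. Groups are compared with the Mann–Whitney test using
the tie-corrected normal approximation.

Both UniFrac variants are computed from first principles on a rooted tree:
unweighted UniFrac is the fraction of branch length leading to tips
present in exactly one community; weighted UniFrac is the branch-length
weighted sum of absolute differences in the fraction of each community
descending from every branch. We default to the *normalized* weighted
variant because it is bounded in [0, 1] and invariant to library size,
which is the common default in the field's toolchains.

PERMANOVA (`permanova()`) partitions the Gower-centred inner-product
matrix `G = -1/2 C D^2 C` by sequential (Type I) sums of squares over
nested hat matrices, mirroring `adonis2`'s `by = "terms"` behaviour; the
test suite asserts exact agreement with `vegan::adonis2` on random inputs.
Significance permutes raw sample identities, and p-values use the "+1"
estimator `(1 + #{F* >= F}) / (1 + B)`, which cannot return zero. Passing
an explicit permutation matrix (e.g. the full group at n = 6) turns the
sampler into an exact test; the suite verifies that path against complete
enumeration.

## The multi-model differential-abundance procedure

Microbiome counts vary wildly in their distributional behaviour from ASV
to ASV: some are equidispersed, most are overdispersed, and many carry
structural zeros beyond what sampling explains. Rather than committing to
one family, each ASV is fit with four candidates **on the same raw count
response**:

| model    | link     | library size | estimated parameters |
|----------|----------|--------------|----------------------|
| gaussian | identity | none         | p + 1 (variance)     |
| poisson  | log      | offset       | p                    |
| negbin   | log      | offset       | p + 1 (dispersion)   |
| zinb     | log      | offset       | p + 2 (dispersion, zero-inflation intercept) |

AIC (`-2 loglik + 2k`, with `k` counting *every* estimated quantity,
including the gaussian variance and the NB dispersion) selects the
reporting model; ties break toward fewer parameters and then a fixed
order. Fitting all four to the same untransformed response is what makes
the AICs comparable — a log-transformed gaussian likelihood would live on
another scale and could not be ranked against the count models. The
gaussian candidate takes no offset; library size adjustment for the three
count models is a log-depth offset, the standard count-model treatment.

The ZINB is the minimal zero-inflated model: an NB count part with the
shared design and offset plus an intercept-only logistic zero part. It is
fit by expectation–maximization — posterior structural-zero probabilities
in the E-step; weighted IRLS steps for the count coefficients and a damped
Newton step for log dispersion in the M-step — iterated until the
observed-data log-likelihood moves by less than 1e-8 (at most 500
iterations). Standard errors come from a numeric Hessian of the full ZINB
log-likelihood at the optimum. When a response has no zeros the zero part
is unidentifiable and the count part equals the NB fit with the mixing
weight pinned at zero.

Per ASV we report the two-sided Wald p-value of the group coefficient,
the log2 fold change (`coef / ln 2` for log-link models;
`log2((mean_EIM + 0.5) / (mean_C + 0.5))` for the gaussian, whose identity
-link coefficient is not a ratio), and the raw difference of group mean
counts. Benjamini–Hochberg adjustment runs across all tested ASVs, and the
reported hit list keeps `q < 0.05` with `|log2FC| > 1` — we read the "log
difference" cutoff as log2, consistent with reporting fold changes in a
Log2 FC column. ASVs whose four candidate fits all fail are collected in a
skip log instead of aborting a 200-ASV run.

### Calibration, and what the generator can and cannot check

Type-I calibration of the procedure is assessed by simulating each ASV
from its own negative binomial law with no group effect (per-ASV means and
dispersions drawn over realistic ranges, NB library sizes): under that
global null the fraction of p < 0.05 sits inside the 99% binomial band
around 5% (2000 tests across 20 replicates). We deliberately do **not**
use the log-normal community generator for the calibration check: a
log-normal mixing distribution has heavier tails than the gamma mixing the
NB family assumes, so Wald tests under it run anti-conservative no matter
how correct the implementation — that is a model-misspecification fact,
not an estimation defect, and conflating the two would make the
calibration test uninterpretable. Effect *recovery* (a planted
log2 FC = +3 ASV is found with q < 0.05 and an estimate in [2, 4] in over
90% of replicates at 60 + 60 samples) and permutation sanity checks do use
the community generator.

## SparCC and co-abundance modules

Sequencing yields compositions, not abundances: naive correlations of
relative abundances are biased by closure. SparCC estimates correlations
of the latent *basis* abundances from the log-ratio variation matrix
`T_ij = var(log(f_i / f_j))`. With the sparsity approximation (most pairs
uncorrelated), basis variances solve the linear system
`t = ((D - 2) I + 1 1') omega^2` with `t_i = sum_j T_ij`, and correlations
follow from `rho_ij = (omega_i^2 + omega_j^2 - T_ij) / (2 omega_i
omega_j)`. Strongly correlated pairs violate the approximation, so the
strongest pair with `|rho|` at or above 0.1 is iteratively excluded from
the system (up to 10 times) and the solution recomputed. Fractions are the
deterministic Dirichlet posterior means `(count + 1) / (total + D)` —
reproducible, strictly positive, and within O(1/depth) of the raw
proportions; the test suite asserts the resulting scale-invariance.
Negative solved basis variances (possible in small systems) are clamped to
1e-10 with a warning, and a component excluded from every pair keeps zero
correlations to its former partners, again with a warning.

Modules are the connected components (size >= 2) of the graph with an edge
wherever `rho >= 0.5` — *signed*, because the defining rule is a
correlation coefficient threshold, not an absolute value; an
absolute-value mode is available as a flag. Module abundance is the sum of
member relative abundances per sample, the simplest summary consistent
with asking whether a whole module is depleted. Its association with EIM
status is a logistic regression of group on
`log10(abundance + delta)` (delta = half the smallest nonzero abundance)
standardized to unit variance: the log makes the heavily right-skewed
abundances usable as a linear predictor, and standardization makes slopes
comparable across modules. Complete separation is detected and flagged
rather than reported as a spurious p-value.

## The synthetic community generator

No public accession exists for the study data, so every stage is exercised
against `generate_community()`, which emulates the statistical structure
the analysis assumes:

- **Basis abundances** are multivariate log-normal. Per-ASV log-means are
  drawn once from N(0, 1.5) to produce the uneven rank-abundance curve
  real communities show; the log-scale correlation is block-diagonal over
  the planted modules (imposed through a Cholesky factor, which is exactly
  the model SparCC assumes, making recovery tests meaningful) and identity
  elsewhere.
- **Group effects** shift EIM-group log-means by `log2_effect * ln 2`;
  structural zeros knock the basis to zero per sample with a per-group
  probability *before* counts are drawn, producing zero inflation beyond
  sampling zeros — the feature that distinguishes ZINB from NB.
- **Counts** are multinomial at a negative-binomially distributed library
  size (mean 25,000, dispersion 5, floored at 1000 reads), so each
  sample's counts sum exactly to its depth and depth variation is
  realistic without degenerate libraries.
- **Contaminants** are reagent-borne, not community members: negative
  controls draw Poisson counts at the stated control means over a
  near-zero baseline, and biological samples pick a contaminant up only
  via carryover (with the stated probability, at control-level expected
  mass).
- **Defaults** are the study's conditions: 65 + 65 biological samples
  (matching the 131-patient cohort), 200 ASVs, 8 negative controls.

Planted effects on module-member ASVs are rejected by default because they
would confound module-recovery tests; `allow_module_effects = TRUE`
overrides this deliberately for module–phenotype association tests, where
a depleted module must be planted.

A single integer seed drives one named stream per generator call
(`withr::with_seed`), so identical parameters give byte-identical output
with no hidden global state.

What the generator does *not* emulate: taxonomy-specific biology,
sequencing error and chimeras, phylogenetic signal in abundances (trees
are random), and the log-normal basis is itself a stand-in — the study
gives no distributional description of its data. Passing recovery tests
therefore demonstrates the pipeline's correctness under its assumed data
model, not performance guarantees on any particular real cohort.

The cohort fixture (`make_cohort_fixture()`) reproduces the enrollment
bookkeeping exactly — 156 enrolled, 25 excluded for unconfirmed EIM
diagnoses, 131 analysed as 86 EIM (60 CD / 26 UC) versus 45 controls
(21 CD / 24 UC), with the reported sex and surgery margins — so the
contingency machinery can be exercised against known totals.

## Numerical choices and degenerate inputs

- Sums of squares, traces and hat matrices in PERMANOVA are exact linear
  algebra; the suite checks `sum(SS) = tr(G)` to 1e-8.
- Fisher's exact p is a direct hypergeometric enumeration with the
  "probability at most observed" two-sided rule (with the customary 1e-7
  relative slack for floating-point ties); the odds ratio is the sample
  `ad/bc`, reported infinite when `bc = 0`.
- Zero-depth samples, all-zero responses, empty tables, single-class
  outcomes, duplicate identifiers and missing tree leaves are rejected
  with errors naming the offender; non-converged model fits are flagged
  and excluded from selection rather than silently reported.
- Chi-square tests are uncorrected by default (a Yates flag exists);
  all-tied rank comparisons return p = 1.

## Problem sizes used in the checks

The test suite runs its heavy simulations at the sizes stated above — 20
replicates of 100-ASV null tables and 40-ASV effect tables at 60 + 60
samples for the differential-abundance checks, D = 50 with n = 200 and
n = 500 for SparCC recovery, and 20 replicates at 65 + 65 for module
association — chosen to match the study-scale conditions the pipeline
targets while keeping a full run of the suite in the low minutes on one
core.

## Known limitations

- The ZINB zero part is intercept-only; covariate-dependent zero
  inflation is out of scope.
- PERMANOVA permutes raw identities only (no strata/blocking).
- SparCC bootstrap pseudo-p-values for individual correlations are not
  implemented; module membership, not edge significance, is the unit of
  inference.
- The Wald tests' calibration degrades under mixing distributions far
  heavier-tailed than the fitted families, as discussed above.
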