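---
title: "Methods: oncofetal miRNA discovery, simulation, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oncofetal miRNA discovery, simulation, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncofetal)
```

This vignette documents the statistical model behind the package, the
assumptions it makes, the synthetic data generator used for validation, and
the rationale for every numerical choice a user may want to question. The
package implements an *oncofetal* screening workflow: it looks for miRNAs
that are expressed in fetal lung (FL) and in lung adenocarcinoma (LUAD) but
are absent from adult non-neoplastic lung (ANL) — a reactivated-development
expression pattern.

## 1. The oncofetal definition

A miRNA is called oncofetal when all three of the following hold:

* **(a) Discovery over-expression.** In a three-group discovery cohort
  (FL, ANL, LUAD), the miRNA is over-expressed in *both* LUAD vs ANL and
  FL vs ANL.
* **(b) Validation over-expression.** In an independent two-group
  validation cohort (ANL, LUAD), the miRNA is over-expressed in LUAD vs
  ANL.
* **(c) Absence from normal adult lung.** The miRNA is *not expressed*
  in the ANL group of either cohort.

`classify_oncofetal()` combines these three pieces of evidence and errors
if the discovery and validation tables disagree on the miRNA universe, so a
silent join mismatch cannot silently change the result.

### Expression positivity

A sample is *positive* for a miRNA when its abundance is at least 1 RPM
(reads per million). A miRNA is *expressed* in a group when at least 10% of
the group's samples are positive. Both thresholds are inclusive
(`>= 1 RPM`, `>= 0.10`), and the fraction is computed exactly, not via a
rounded sample count. These are the only two knobs of
`detect_expressed()`; they are deliberately simple so criterion (c) is easy
to audit.

### Differential expression, two schemes

The discovery and validation cohorts intentionally use different tests,
mirroring a small three-group exploratory design versus a large two-group
confirmatory design:

* **Discovery** (`de_discovery()`): a one-way ANOVA on
  `log2(RPM + 1)` across FL/ANL/LUAD, followed by Fisher's LSD pairwise
  post-hoc tests. The post-hoc p-value is *gated*: it is reported as 1
  whenever the omnibus F test is not significant at `alpha = 0.05`, which
  is what protects LSD's otherwise-unadjusted comparisons. Tukey's HSD is
  available as an alternative post-hoc (`posthoc = "tukey"`). No
  multiple-testing adjustment across miRNAs is applied at this stage —
  discovery is a screen, and the independent validation cohort is the
  error control.
* **Validation** (`de_validation()`): a Welch two-sample t test on
  `log2(RPM + 1)` per miRNA, with Benjamini–Hochberg adjustment across
  miRNAs. Significance uses the *adjusted* p-value.

Both schemes call a miRNA `over`/`under` only when the p-value is strictly
below 0.05 **and** the fold change is strictly above 2 (or below 1/2).
Strict inequalities mean a fold change of exactly 2 is not significant; the
boundary behaviour is pinned by unit tests.

### Fold change

Fold change is computed on the *raw RPM scale*, not the log scale:

```
FC = (mean(RPM_a) + 0.01) / (mean(RPM_b) + 0.01)
```

The epsilon of 0.01 RPM keeps the ratio finite for presence/absence
contrasts (a miRNA at 20 RPM vs 0 RPM gives FC = 2001, not infinity) while
being far below the 1 RPM positivity threshold, so it never changes a call
for miRNAs anywhere near the detection boundary. The log-transform
pseudocount for the tests is 1 (i.e. `log2(RPM + 1)`), the conventional
choice that maps 0 RPM to 0 and is approximately linear near zero.

### Why row-wise vectorized tests

`anova_posthoc()` and `welch_t()` are implemented as vectorized
sums-of-squares over matrix rows rather than `apply()` loops over
`stats::aov()` / `stats::t.test()`. This is purely a performance choice —
the simulation studies run thousands of tests — and correctness is
enforced by the test suite, which checks both functions against
`stats::aov()` and `stats::t.test()` row by row to `1e-10`.

## 2. Genomic localization and congruence

`count_in_region()` counts how many of a set of loci fall inside a genomic
region using **full containment** (both start and end inside the region),
ignoring strand. Containment rather than overlap was chosen because miRNA
loci are ~20 nt — far smaller than any region of interest — so the two
definitions coincide in practice and containment is the stricter, easier to
reason about rule. Locus strings accept both the ASCII hyphen and the
Unicode minus sign (U+2212) as the minus-strand symbol, because published
tables mix the two; `format_locus()` always emits ASCII.

`congruence_table()` cross-tabulates discovery and validation DE status
(`over`/`under`/`ns`, a 3×3 table, or collapsed to significant/not, 2×2)
and `congruence_test()` tests independence with Fisher's exact test. For
tables with total count above `exact_max = 500` (or when the exact network
algorithm runs out of workspace) it falls back to a *seeded* Monte-Carlo
Fisher test with 10^6 draws, so the p-value remains reproducible.

## 3. The panel classifier

`fit_linear_svm()` wraps `e1071::svm(kernel = "linear", scale = FALSE)`
and extracts an explicit linear scoring rule: weights
`w = t(coefs) %*% SV` and intercept `b = -rho`, with the orientation
flipped if necessary so the positive class scores higher. Features are
`log2(RPM + 1)`. The extracted `linear_scorer` is a plain weights-plus-
intercept object: it can be printed, tidied, serialized to JSON
(`write_scorer()` / `read_scorer()`), and applied to new data without
e1071 present.

`oncofetal_panel_scorer()` ships the 13 published panel weights as a
fixed, citable scoring rule with intercept 0 and features `log2(RPM)`
(no pseudocount — the published formula assumes panel miRNAs are
expressed, so RPM > 0).

ROC analysis (`roc_auc()`) computes AUC as the Mann–Whitney rank statistic
with midranks for ties — an O(n log n) closed form, checked in the tests
against a brute-force O(n²) pair count.

## 4. Survival screening

`dichotomize()` splits LUAD patients into RPM-positive (>= 1 RPM,
inclusive, same threshold as expression positivity) and RPM-negative for a
given miRNA. `survival_screen()` runs a log-rank test
(`survival::survdiff`) per panel miRNA and flags those with p < 0.05;
Benjamini–Hochberg adjustment across the panel is available via
`adjust = TRUE` but is off by default because the screen mirrors a
univariate per-marker analysis. Degenerate strata (all patients positive,
or all negative) are reported as `testable = FALSE` rather than dropped,
so the caller can see *why* a marker produced no p-value.

## 5. The synthetic cohort generator

`generate_cohorts()` draws two cohorts matching the intended study shape:

* discovery: FL = 25, ANL = 77, LUAD = 63 samples,
* validation: ANL = 38, LUAD = 389 samples,

with per-sample library sizes uniform on [5×10^6, 2×10^7] reads.

### Count model

Counts are negative binomial. For miRNA *i* in sample *j*,

```
count_ij ~ NB(mu = rpm_i(g_j) * f_i * L_j / 1e6,  size = 1 / dispersion)
```

where `rpm_i(g)` is the class-determined nominal mean RPM of miRNA *i* in
group *g*, `f_i ~ Lognormal(0, sdlog = 0.5)` is a per-miRNA abundance
factor (shared across groups, so it models miRNA-to-miRNA abundance
spread, not differential expression), `L_j` is the library size, and
`dispersion = 0.2` gives realistic overdispersion for miRNA-seq
(coefficient of variation well above Poisson at all depths).

### Planted truth classes

Each simulated miRNA belongs to one of six classes that define where it is
"on" (nominal 50 RPM) versus "off" (nominal 0.05 RPM):

| class | FL | ANL | LUAD | count |
|---|---|---|---|---|
| oncofetal | on | off | on | 13 |
| fetal_only | on | off | off | 30 |
| tumour_only | off | off | on | 30 |
| under_in_both | off | on | off | 20 |
| ubiquitous | on | on | on | 80 |
| silent | off | off | off | 30 |

The generator returns the truth table alongside the matrices, so recovery
sensitivity and false-positive counts can be scored exactly.

### The RPM-mass constraint (a realism detail that matters)

RPM is computed *within the observed matrix*: `normalize_rpm()` divides by
the column sum of the simulated counts, not by the nominal library size.
If the simulated miRNAs accounted for only a small fraction of each
library, every realized RPM would be inflated by the same large factor —
and nominally "silent" miRNAs (0.05 RPM) would cross the 1 RPM positivity
threshold purely as a normalization artifact. To prevent this, the
80 ubiquitous miRNAs are given lognormal (sdlog = 1.5) relative abundances
*scaled per group so that nominal RPM sums to 10^6*. Realized RPM then
matches nominal RPM closely, planted classes behave as designed, and the
matrix looks like a real one: a few dominant ubiquitous species carry most
of the reads, which is exactly the shape of real miRNA-seq libraries.

### What the generator does not model

Known simplifications: no batch effects, no correlated co-regulation
between miRNAs beyond the shared per-miRNA factor, no isomiR ambiguity or
multi-mapping, group means are class-homogeneous (every oncofetal miRNA
has the same nominal on/off levels), and library size is independent of
group. These choices keep the planted truth unambiguous; the generator is
a validation instrument, not a biological emulator.

### Survival generator

`generate_survival()` draws exponential event times with hazard
`baseline_hazard * hazard_ratio^positive` and independent exponential
censoring (`censoring_rate`). Defaults (`baseline_hazard = 0.001`,
`hazard_ratio = 3`, `censoring_rate = 0.002`) give an event fraction near
one half at hazard ratio 3. Calibration is validated on a deliberately
*borderline* marker (mean ~1 RPM, negative binomial noise), because a
strongly expressed planted marker is positive in essentially every LUAD
sample and yields a single stratum — untestable by construction. On the
borderline scenario with n = 379 patients the screen shows type-I error
within 0.05 ± 0.02 over 1000 null replicates and power above 0.9 at hazard
ratio 3 over 200 replicates.

## 6. Reproducibility machinery

All randomness flows from a single integer seed. Independent substreams
are derived as `strtoi(substr(hash(list(seed, purpose)), 1, 7), 16)`,
which keeps every derived seed below 2^31 and makes, e.g., the discovery
cohort draw independent of whether survival data are also generated.
`with_substream()` saves and restores `.Random.seed`, so package
simulations never perturb the caller's RNG state. `run_pipeline()` writes
a `manifest.json` containing the package version, the seed, and a hash of
the full configuration; the test suite asserts that identical
configurations produce byte-identical output files.

## 7. Problem sizes used in validation

The shipped validation (test suite and `scripts/acceptance.R`) uses:
20 independent cohort draws at the full study shape (203 discovery +
427 validation samples, 203 miRNAs) for recovery and classifier transfer;
1000 null and 200 alternative replicates at n = 379 for survival
calibration; and at least 100 random instances per statistical primitive
(BH, Fisher, ANOVA/LSD, Welch, AUC, Kaplan–Meier, log-rank) checked
against brute-force oracles written directly from the textbook
definitions.
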