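---
title: "Classifying pancreatic cyst fluid: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying pancreatic cyst fluid: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancyst)
```

## The clinical problem

Pancreatic cystic lesions (PCL) found on imaging range from harmless
pseudocysts and serous cystadenomas (SCA) to mucinous neoplasms — intraductal
papillary mucinous neoplasms (IPMN) and mucinous cystic neoplasms (MCN) —
that are precursors of pancreatic ductal adenocarcinoma (PDAC). The clinical
question at diagnosis is binary: is the cyst a mucinous pancreatic cystic
neoplasm (mPCN) that needs surveillance or surgery, or a non-mucinous lesion
(nmPCL) that does not? Cyst fluid obtained by EUS-guided fine needle
aspiration is often paucicellular, so cytology alone misses a large fraction
of mucinous lesions; on the packaged surgical cohort cytology identifies 15
of 36 mucinous cases. This package implements and evaluates the two
complementary classification routes — a step-wise clinical algorithm and a
somatic-mutation rule — together with the assay-level machinery each relies
on.

## Data model

A cohort is a pair of tidy tables. The *case* table has one row per
specimen: pathology diagnosis (when resected), dysplasia grade, the
four-tier cytology category (non-diagnostic, negative,
atypical/suspicious, positive, plus an explicit missing state), cyst fluid
CEA and amylase, cyst size, mural nodule, fluid viscosity, EUS impression,
and the semicolon-separated list of genes actually tested. The *variant*
table has one row per somatic call: gene, protein change, mutant allele
frequency (MAF, percent of mutant amplicon), read depth, assay
(PNA-clamp qPCR or NGS), and somatic status. Missing values are explicit
states and are never imputed; a classifier step whose input is missing is
skipped, not guessed at. `validate_cohort()` enforces the structural
invariants (variants only in tested genes, MAF in (0, 100], grade only for
IPMN/MCN).

The packaged reference dataset (`load_table1()`) transcribes the 46-case
surgical cohort exactly as published, including a pseudocyst with an
incidental KRAS mutation and one SCA labelled mucinous by the algorithm;
the fixture is ground truth, not curated. Because per-case MAF, CEA and
size were not published for this cohort, those fields are stored missing
and every reference-cohort analysis is MAF-free. An md5 checksum guards
the packaged files against silent modification.

## The two classifiers

**Clinical algorithm** (`classify_clinical()`). Six features are evaluated
in a fixed, configurable order; the first rule that fires labels the cyst
mPCN, and if none fires it is nmPCL:

1. cytology atypical/suspicious or positive;
2. CEA at or above 192 ng/ml;
3. viscous fluid;
4. mural nodule present;
5. mucinous EUS impression with cyst size at or above 30 mm.

The exact step order of the source algorithm was published only in a
supplement that is not available, so the order here is a reconstruction and
a design choice: cytology goes first because atypical/suspicious and
positive cytology are essentially never seen in non-mucinous cysts (both
tiers are 100% mucinous in the full-cohort summary), CEA second as the
best-performing fluid biomarker, then the physical features. The order is
configurable (`algorithm_config(step_order = ...)`) and every evaluated
step is recorded in the diagnosis's rationale trail. The CEA cut-off is
inclusive at 192 ng/ml — the value is quoted as a threshold without an
inequality direction, and "at or above the cut-off" is the common clinical
reading; 124 ng/ml is noted as the ROC-optimal alternative. The 30 mm size
component is an extrapolation from consensus "worrisome feature" size, since
no size cut-off is printed; it is configurable and documented as such.

**Molecular rule** (`classify_molecular()`). A cyst is mPCN when at least
one retained somatic variant falls in the mucinous gene panel (BRAF, KRAS,
GNAS, PIK3CA, CDKN2A, PTEN, SMAD4, TP53). VHL marks SCA and never counts
toward mucinous; a VHL-only profile is annotated "SCA-suggestive".
Other genes seen in the cohort (ATM, APC, RB1, ...) are deliberately outside
the panel — they follow the published footnote and did not add sensitivity.
An optional MAF gate drops KRAS calls below 1.8%, the ROC-derived threshold
separating incidental low-level KRAS clones (PanIN) from mucinous
neoplasia. The gate is inclusive ("at least 1.8%") because that is the
phrasing used for the 106/117 summary; calls with unreported MAF are not
gated. Enabling the gate can only move labels from mPCN to nmPCL.

**Grade flag** (`grade_flag()`). Low-grade mucinous lesions carry only
single KRAS and/or GNAS mutations; mutations in additional genes, or two
distinct protein changes within KRAS or within GNAS, track with
intermediate/high-grade dysplasia. Mucinous diagnoses are therefore flagged
`elevated_grade_suspicion` under either condition, else
`low_grade_consistent`. On the reference cohort this reproduces the
published structure: no additional-gene mutation in the 17 low-grade cases,
3/9 intermediate, 9/10 high-grade/PDAC.

## Assay-level machinery

**PNA-clamp qPCR** (`clamp_quant` functions). A peptide nucleic acid clamp
suppresses wild-type amplification, so ΔCt = Ct(with clamp) − Ct(without)
grows as mutant fraction falls. Each run carries 100/10/1/0% mutant
controls. Calling: a specimen at least 2 cycles above the 1% control is
wild-type, otherwise mutant; the boundary is inclusive wild-type, exactly as
the rule is stated. Quantification interpolates log10(percent mutant)
piecewise-linearly in ΔCt through the 100/10/1% controls — Ct is log-linear
in template abundance, which is why interpolation is on the log scale; the
published description is comparison-based and states no formula, so the
log-linear curve is this package's design choice. Values below the 100%
control clamp to 100%; at or beyond the 0% control the output floors at the
assay's stated detection limit of 0.01%. The 2-cycle margin is a single
configurable constant; nothing suggests it is target-specific.

**NGS retention rules** (`filter_variants()`). Calls are kept with at least
10 reads (inclusive) and MAF strictly greater than 1% — both bounds exactly
as stated — and only when confirmed somatic; known germline polymorphisms
are always dropped. Annotation is an injectable offline lookup (a packaged
micro-subset of the panel's hotspots), never a network query.
`concordant_calls()` implements the two-pipeline comparison: calls matched
on (gene, protein change), concordant calls averaging the two MAFs. The
0.2% analytic limit of sensitivity is carried as metadata only; it plays no
role in the 1% calling rule.

## Statistics

Accuracy is computed from standard 2×2 tables (`confusion()`), with
sensitivity, specificity, PPV and NPV reported as percentages rounded to
one decimal, half away from zero; any metric with a zero denominator is
reported missing rather than 0 or 100. Categorical comparisons use the
two-tailed Fisher exact test with the probability-at-most-observed
definition of the two-sided p (the mainstream convention; two-sided exact
definitions vary, so this is stated). Continuous comparisons use an exact
Mann-Whitney test: for combined samples of 25 or fewer the full permutation
distribution of the rank sum is computed by dynamic programming over
midranks, so ties are exact; beyond that a tie-corrected normal
approximation with continuity correction is used and the method is recorded.

`roc_threshold()` sweeps every threshold that can matter — midpoints
between consecutive distinct scores plus sentinels — and selects the
maximizer of the Youden index (sensitivity + specificity − 1). Ties break
toward the lower threshold: in a screening context the cheaper error is a
false positive. AUC is trapezoidal and equals the Mann-Whitney
U/(n₁n₂) on tie-free data, which the tests exploit as a cross-check.

## The synthetic cohort generator

Per-case data for the full 318-specimen cohort were never published, so the
generator (`sim_config()`, `generate_cohort()`) emulates its structure for
testing: cyst-type prevalence and grade mix from the surgical series;
low-grade mucinous lesions mutating only KRAS (0.82) and/or GNAS (0.41);
intermediate grade adding one further gene a third of the time and high
grade/PDAC 90% of the time; SCA always VHL; pseudocysts with incidental
KRAS in 20%; log-normal MAF (median 25% in mucinous lesions, 5% for
incidental clones) and log-normal CEA (class medians 2126.7 and 188.9
ng/ml); cytology and viscosity drawn from the published class-conditional
tables; GNAS tested in 182/303 of specimens. Size and amylase are triangular
fits to the published median/range summaries and are approximate by
construction. Mural-nodule and EUS-impression rates are not published at
all; the defaults (nodule in 15% of mucinous vs 3% of non-mucinous cysts;
a correct EUS impression in roughly 70%) are one-time choices of plausible
clinical magnitudes, made before any testing against recovery targets, and
are config, not claims. Dispersions (sdlog 0.9 for MAF, 1.5 for CEA) were
likewise chosen once to reproduce the wide right-skewed published ranges.

What passing recovery tests show is therefore calibration consistency —
the pipeline recovers the rates it was configured with (e.g. a configured
93.3% KRAS-or-GNAS detection probability is recovered as molecular
sensitivity within Monte-Carlo error) — not validation on real patients.
Features of real data the generator does not emulate include correlation
between features beyond class conditioning (e.g. MAF rising with grade),
multifocal cysts, assay failures, and the circularity the source design
acknowledges: in the full cohort the truth standard is itself the clinical
algorithm, which inflates cytology's apparent specificity. The simulator
sidesteps that circularity by scoring both classifiers against the simulated
pathology truth.

## Numerical choices and degenerate inputs

* Problem sizes: property suites run at n = 1000–10000 cases and the
  exhaustive Fisher cross-check covers every 2×2 table with total up to 40;
  both are choices balancing resolution against a few minutes of runtime.
* Classification is deterministic, including the rationale trail; the
  generator is deterministic given its seed.
* Degenerate inputs error early and specifically: all six clinical features
  missing (unclassifiable), empty tested-gene set, variants in untested
  genes, non-monotone clamp calibrations, single-class ROC labels, NGS
  calls missing depth or MAF.
* Known limitations: the clinical step order is a reconstruction, not the
  published supplement; the packaged annotation is a micro-subset sufficient
  for the panel's hotspots, not a COSMIC mirror; the MAF-free reference
  cohort cannot exercise the MAF gate, which is tested synthetically.
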