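---
title: "Family-based MODY variant screening: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based MODY variant screening: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modyscreen)
```

## The problem

Maturity-onset diabetes of the young (MODY) is a monogenic, typically
autosomal-dominant (AD) form of diabetes caused by heterozygous variants in
genes required for pancreatic beta-cell function. In an unselected,
family-based population cohort, finding MODY variants is a phenotype-plus-
genotype exercise: participants must first be classified glycemically from
longitudinal biomarkers, candidate variants must then be filtered on
population frequency, sequencing quality, prior clinical classification and
predicted deleteriousness, and finally each surviving variant must be judged
by how it behaves in families — its penetrance among carriers and whether
its transmission is compatible with dominant inheritance.

`modyscreen` implements that full path as composable, tested functions over
tidy data frames, together with a synthetic family-cohort generator used to
validate every step. The package is modelled on the analysis of the Tehran
Cardiometabolic Genetic Study (TCGS), a 20,002-participant multi-generation
cohort, and ships a deterministic fixture that reproduces that cohort's
published carrier configuration exactly (see *The validation fixture*).

## Glycemic classification

Each visit is classified by the American Diabetes Association thresholds:

* **diabetic** — fasting plasma glucose (FPG) ≥ 126 mg/dl, or 2-hour oral
  glucose tolerance test (OGTT) ≥ 200 mg/dl, or use of glucose-lowering
  agents;
* **pre-diabetic** — FPG 100–125 mg/dl or OGTT 140–199 mg/dl;
* **non-diabetic** — every available measure below the pre-diabetic cutoff;
* **unknown** — no biomarker and no medication record.

Thresholds are closed exactly as printed: FPG 126.0 is diabetic, 125.999 is
pre-diabetic. Three decisions here were genuinely open and are worth
recording:

1. **Missing biomarkers.** The non-diabetic rule conjoins both measures, but
   longitudinal cohorts rarely have both at every visit. By default a visit
   is non-diabetic when all *available* measures are below cutoff;
   `strict_nondiabetic = TRUE` restores the conjunction.
2. **Medication precedence.** A treated patient may have controlled glucose,
   so the medication flag dominates biomarkers. Metformin taken for
   non-diabetic indications is excluded from that rule, mirroring standard
   epidemiological practice.
3. **Medication without biomarkers.** Self-reported treatment alone is
   accepted as sufficient for a diabetic classification; requiring a
   corroborating biomarker would silently reclassify treated participants
   with no laboratory visit.

A participant's lifetime status is the severity maximum over visits
(diabetic > pre-diabetic > non-diabetic > unknown), which makes the
reduction order-invariant and monotone: adding a visit can never lower
severity. Onset age is the exam age of the earliest diabetic visit unless a
self-reported onset is available, which takes precedence — triennial
follow-up only brackets the true onset, and young onsets routinely predate
enrollment.

A participant is a **clinical MODY suspect** when (1) diabetes onset is
before age 25, (2) a first-degree relative is diabetic (the degree is
configurable; second-degree history is also reported), and (3) there is no
evidence of type 1 or type 2 diabetes. With C-peptide and autoantibody data
unavailable in the modelled cohort, criterion (3) is operationalised as
normal-or-under body weight (WHO BMI cutoffs) plus the absence of an
optional insulin-resistance marker flag.

## The two variant pipelines

Both pipelines operate on the 13-gene MODY panel (*HNF4A, GCK, HNF1A, PDX1,
HNF1B, NEUROD1, CEL, INS, ABCC8, KCNJ11, APPL1, RFX6, NKX6-1*).

**Known-variant screen** (`screen_known_variants()`): keep variants with a
ClinVar classification of pathogenic or likely pathogenic (P/LP), cohort
minor allele frequency (MAF) below 0.0015, and mean sequencing depth above
20×. The MAF threshold is a *fraction*, not a percent: published MAF values
up to 0.001422 pass the filter, which is only consistent with the fraction
reading. Both thresholds are exposed as arguments.

**Candidate discovery** (`discover_candidates()`): over panel variants
*not already classified P/LP*, require cohort MAF < 0.001, depth > 20×,
CADD Phred > 20 (a missing CADD score fails), and complete (100%) disease
penetrance. Restricting the pool to non-P/LP variants is a deliberate
design choice: the P/LP set is owned by the known screen, and the discovery
question is specifically whether *unestablished* variants (uncertain risk
alleles, VUS, novel sites) behave causally in this population. Without that
restriction any fully penetrant known pathogenic variant would trivially
reappear as a "candidate". Set `exclude_plp = FALSE` to rank everything.
The four predicates form a conjunction, so filter order cannot change the
survivors; the per-stage waterfall is logged in the result and written to
JSON by `write_screen_report()`.

**Penetrance** is the fraction of carriers with a diabetic phenotype over
*all* carriers, including carriers whose glycemic status is unknown:

$$\mathrm{penetrance} = 100 \times \frac{\#\{\text{carriers with DM}\}}{N},$$

with \(N\) the total carrier count. The all-carriers denominator is the
convention under which the modelled cohort's printed values (e.g. 38% for
8 diabetic among 21 *INS* carriers, two of unknown status) are exactly
reproduced. One published value (61.5% for *GCK*) corresponds instead to
(DM + pre-DM)/N; the package always applies the stated formula — 3/13 =
23.1% for that configuration — and treats the discrepancy as a reporting
inconsistency in the source material, not something to emulate.

A **carrier** is any sample with at least one alternate allele, matching
dominant-acting variant semantics. Cohort MAF is the alternate-allele count
over twice the non-missing sample count, folded to ≤ 0.5.

Cohort-level statistics: `prevalence_among_diabetics()` divides the pooled
distinct carriers by the number of diabetic participants (all carriers in
the numerator by convention of the modelled analysis;
`carriers_only_diabetic = TRUE` restricts it), `spectrum_report()` gives
each variant's share of all carriers, and `suspect_overlap()` intersects
clinical suspects with the P/LP carrier pool.

## Pedigrees and transmission

Pedigrees load from standard 6-column PED files and validate acyclicity,
parent sex consistency and id uniqueness. Relationship degrees follow the
genetic-relatedness convention: degree 1 is parents, children and full
siblings; degree 2 is grandparents, grandchildren, aunts/uncles,
nieces/nephews and *half-siblings*.

`assess_transmission()` evaluates, per carrier family:

* **Mendelian consistency** — no carrier child with both parents genotyped
  non-carrier;
* **co-segregation** — diabetic carriers over carriers with known status;
* **AD compatibility** — every pair of carriers is connected by a pedigree
  path containing no genotyped non-carrier. Ungenotyped individuals on such
  paths are treated as obligate carriers for this check, but they are never
  counted as carriers in penetrance or carrier tallies: only observed
  genotypes count there.
* **transmission lineage** — maternal/paternal where the carrier parental
  side is genotyped or deducible (e.g. a genotyped non-carrier father with
  an untyped mother implies maternal origin), otherwise unresolved.

## The synthetic-data generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes: independent multi-generation families (founder couples,
zero-truncated Poisson sibships with configurable mean, married-in founder
spouses), Mendelian gene dropping of founder variants (each child draws one
allele per parent uniformly at random, so simulated data are
Mendelian-consistent by construction), and penetrance-parameterised
phenotypes. Defaults encode the modelled cohort's conditions: background
rates 15.2% diabetic and 29.1% pre-diabetic, carrier onset ages
\(\mathcal{N}(23.9, 5^2)\) years truncated at 5.

Statuses are realized as concrete biomarkers drawn uniformly inside the
matching ADA band (diabetic FPG in \[126, 250\], pre-diabetic \[100,
125.9\], non-diabetic \[70, 99.4\]; OGTT analogous). Band upper bounds
leave headroom so that rounding to one decimal cannot cross a threshold,
which makes the round trip simulated status → biomarkers → classifier exact
for every individual — a property the suite asserts on every simulated
cohort. A configurable share of carriers is enrolled with all-missing
biomarkers to exercise the unknown-status path.

All randomness flows from a single config seed through deterministic
per-operation substreams, so outputs are byte-identical for a fixed seed
regardless of call order.

What the generator does **not** emulate: linkage disequilibrium,
genotyping error, imputation uncertainty, consanguinity loops,
ascertainment bias, and realistic marginal distributions of age, BMI or
lipids (only their classification-relevant structure). Passing tests
therefore demonstrate correctness of the *logic* under idealised data, not
robustness to every artefact of real cohort data.

## The validation fixture

`tcgs_fixture()` is *constructed*, not simulated: every published tally is
reproduced exactly rather than in expectation, which is what makes it
usable as an oracle. It contains:

* 20,005 participants — 3,043 diabetic, 5,835 pre-diabetic, 11,124
  non-diabetic, plus 3 carriers enrolled with all-missing glycemic data.
  The source tallies are internally inconsistent here: the cohort size is
  quoted as 20,002 with all participants classified, yet three carriers
  are reported with unavailable status. The fixture keeps every printed
  count exact and carries the three unknowns as additional enrollees
  (the diabetic share, 15.21%, still prints as 15.2%).
* Seven panel variants with the published configuration: *INS* 21 carriers
  {8 DM, 8 pre-DM, 3 ND, 2 unknown} in 11 families; *GCK* 13 {3, 5, 4, 1}
  in 7; *HNF1B* c.516C>T 8 {1, 5, 2, 0} in 3; *HNF1B* c.1025C>T (the
  uncertain-risk-allele candidate) 4 diabetic carriers in 1 family; one
  carrier each for *HNF4A*, *HNF1A* (diabetic) and *CEL* (pre-diabetic).
  Where per-family carrier splits were not published, carriers are
  distributed deterministically but arbitrarily.
* Three decoy variants each failing exactly one screen predicate
  (benign classification; MAF 0.0025; depth 15×).
* Fully encoded three-generation pedigrees for the *HNF4A*, *HNF1A* and
  *HNF1B*-candidate families, including untyped transmitting mothers so
  lineage inference resolves maternally, and 25 clinical suspects of whom
  exactly 3 carry P/LP variants.

Published per-variant MAF values imply mutually inconsistent genotyped
denominators, so they cannot all be reproduced from one genotype table;
fixture MAFs are computed from its own 20,003 genotyped samples and all
fall on the correct side of every threshold.

## Numerical and degenerate-input choices

* Percentages are computed from raw floats and only rounded for display.
* Penetrance comparison in discovery uses an absolute tolerance of 1e-9 on
  the percent scale (exact in practice for rational counts).
* Zero carriers make penetrance and prevalence undefined — errors, not
  zeros; an empty carrier set in family counting is 0, not an error.
* Single-observation strata report `NA` standard deviations by default
  (`sd_single = "zero"` switches to 0).
* All-missing genotype columns are an undefined-frequency error; missing
  calls are excluded from MAF denominators site by site.
* Homozygous-alternate-only sites fold to MAF 0.

## Problem sizes used in validation

The fixture is 20,005 rows and runs end-to-end in about a second. The
stochastic suites use 1,000 simulated families for Mendelian checks,
10,000 offspring for the transmission-ratio check (0.5 ± 0.015), 5,000
carriers for penetrance recovery (±2 percentage points, ≈3 binomial SDs),
and 40–50-variant random tables for filter monotonicity and brute-force
pipeline equivalence. The whole suite completes in about a minute on one
CPU.

## Known limitations

* AD-compatibility uses restricted-path connectivity, which can be overly
  permissive in pedigrees where two carrier spouses are connected only
  through a carrier child (two introductions read as one); such loops do
  not occur in the shipped data.
* Family history, and hence MODY suspicion, is computed only within the
  recorded pedigree; participants without pedigree entries get no family
  history rather than an error.
* The imputation-quality score is carried and reported but never filtered
  on — no threshold is established for it in the modelled analysis.
* HbA1c, C-peptide and autoantibody logic is out of scope (unavailable in
  the modelled cohort), as are CADD/ClinVar recomputation and external
  allele-frequency lookups: those are inputs.
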