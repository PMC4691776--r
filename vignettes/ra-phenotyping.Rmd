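---
title: "Methods: rule-based RA phenotyping in primary-care EHR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based RA phenotyping in primary-care EHR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenora)
```

## The phenotyping problem

Primary-care research databases (CPRD and its kin) record diagnoses as
clinical codes and treatments as prescription events. A single RA diagnosis
code is a weak phenotype: general practitioners code suspected disease,
rule-outs and administrative follow-ups, so a one-code definition mixes true
RA with a substantial admixture of non-cases. phenora implements a
two-criterion rule that trades sensitivity for specificity, selecting
*highly probable* RA from everyone with at least one RA code.

A patient with at least one RA diagnosis code is **definite RA** when

* **Criterion 1**: some DMARD prescription in the record has *no alternative
  indication for that drug* coded anywhere for the patient; or
* **Criterion 2**: all of (a) RA codes on at least two distinct calendar
  dates, (b) no alternative diagnosis coded strictly after the final RA
  code, and (c) at least one RA code of severity group 1
  (seropositive/erosive) or 2 (plain RA).

The logic rests on clinical reasoning: DMARDs are specific enough to RA that
a prescription without a competing licensed indication (psoriasis,
inflammatory bowel disease, lupus, transplantation, ...) is strong evidence;
repeated strong coding with no superseding spondyloarthropathy diagnosis is
the coding signature of managed RA.

## Assumptions and interpretive choices

Several points are under-determined by a prose statement of the rule; the
package fixes them as follows and exposes the genuinely contestable ones as
parameters.

* **"Different dates" means distinct calendar days.** Day is the native date
  resolution of these databases; same-day repeat codes count once for
  criterion 2a (they are kept verbatim in the record, though).
* **Alternative-indication search scope.** Whether a disqualifying
  indication must precede the prescription is not fixed by the rule. The
  default searches the *whole record*, before and after the prescription:
  the full patient history is available in these extracts, and the
  whole-record reading is the conservative one for a high-specificity
  phenotype (it disqualifies more prescriptions, never fewer). The
  alternative behaviour is available as
  `alt_indication_scope = "before-prescription"`.
* **Criterion 2b is strictly-after.** An alternative diagnosis coded the
  same day as the last RA code does not supersede it: same-day consultations
  routinely encode differential diagnoses together, and treating ties as
  superseding would discard genuinely ambiguous but managed RA.
* **Criterion 1 accepts any-group RA codes.** Only criterion 2c restricts
  severity groups.
* **Code overlap resolves in favour of RA.** A code present both in the RA
  list and in a condition set is flagged at validation as a warning, but
  during classification it counts only as an RA code — curated lists are
  disjoint, so overlap signals a user error that should not silently
  disqualify prescriptions or supersede diagnoses mid-batch.
* **Selection window is inclusive at both ends**, and the cohort is
  *incident*: a patient whose first RA code precedes the window is excluded
  even if later RA codes fall inside it. The default window is
  1 January 2010 to 31 December 2012, the window under which the algorithm's
  fulfilment behaviour was characterised; it is a parameter everywhere.
* **Optional follow-up cap.** `followup_months` restricts *follow-up*: only
  events up to the index date plus that many calendar months count toward
  either criterion, while pre-index history is never truncated. The default
  is no cap (the full record); 12 months is a reasonable choice when a
  bounded ascertainment period matters, since fulfilment is dominated by
  events close to the index.
* **Age at index** is index year minus year of birth — these extracts carry
  year of birth only, and the age bands are decade-wide, so day-level
  precision is neither possible nor needed. Bands are `<50`, `50-59`,
  `60-69`, `70+` (ASCII labels), with 50/60/70 in the higher band.
* **Follow-up years** divide by 365.25 days.

## Dictionaries

Codes are opaque strings (Read v2, medcode, SNOMED — anything), matched by
exact string equality after whitespace trimming, case-sensitively (Read
codes are case-sensitive). Three CSV families drive the engine:

* `ra_codes.csv` (`code,term,group`): each RA code in exactly one severity
  group 1-4.
* `dmards.csv` (`drug_code,name,class,alt_indications`): conventional or
  biologic, with a semicolon-separated list of alternative-indication
  condition identifiers (possibly empty — such a drug is never
  disqualified). Every identifier must resolve in the condition sets;
  dangling references are load errors because they would silently weaken
  the exclusion.
* `condition_codes.csv`
  (`condition_id,code,term,is_alternative_diagnosis`): condition code sets;
  those flagged true form the alternative-diagnosis set for criterion 2b.
  Polymyalgia rheumatica is deliberately *not* an alternative diagnosis —
  it is itself a diagnosis of exclusion. A code may appear under several
  conditions.

The bundled lists under `inst/extdata/` are illustrative synthetic examples
of the schemas, adequate for the generator and the tests; real studies plug
in their own curated lists.

## The synthetic cohort generator

The generator is *constructive*: every patient is assembled from dictionary
building blocks to satisfy or violate chosen sub-conditions, so the emitted
truth labels are exact rather than statistical, and the whole pipeline is
testable with no access to real records. Eight archetypes cover the three
definite overlap groups (criterion 1 only, criterion 2 only, both) and five
non-definite branches, including one archetype per single broken
sub-condition of criterion 2 (same-date repeat codes for 2a, a late
alternative diagnosis for 2b, weak-group-only coding for 2c). Event layouts
use fixed day offsets from the index date, so edge cases such as same-day
codes are produced deliberately, never left to sampling.

Default mixture weights put 62.8% on both criteria, 15.8% on
criterion-1-only, 7.3% on criterion-2-only and the remaining 14.1% spread
over the non-definite branches — the fulfilment mix observed when the
algorithm was applied to a real incident primary-care RA cohort — so
default simulations have a realistic overall definite fraction (85.9% in
expectation). Demographics use a 66.5% female share (RA is roughly twice as
common in women) and an age at index drawn uniformly on 18-90; index dates
are uniform over the selection window. These are deliberate simplifications.

One seeded RNG stream drives everything; all archetype assignments are drawn
in a single vectorized call before any demographic or date draws, so the
archetype mixture is independent of how demographics are sampled, and a
fixed seed makes the emitted flat files byte-identical across runs.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: consultation-frequency patterns, disease
natural history, miscoding and transfer gaps, realistic marginal
distributions of codes per patient, or any correlation between demographics
and fulfilment. Tests against generated cohorts validate the *logic* of the
pipeline (that the implementation encodes the definitions exactly), not the
algorithm's sensitivity or specificity against chart review, which can only
be measured with access to full medical records.

## Reporting and the homogeneity test

Fulfilment tables give per-stratum and overall counts with explicit
denominators and percentages rendered at one decimal place with **half-up
rounding**, implemented in exact integer arithmetic
(`floor`/remainder comparison on `1000 * x / n`) rather than floating-point
`round()`, which rounds half to even, or `sprintf`, whose tie behaviour is
libc-dependent. Half-up is what published clinical tables use (98.750...%
prints as 98.8).

Stratum comparisons use Pearson's chi-square test of homogeneity without
continuity correction on the strata-by-outcome table (`stats::chisq.test`,
df = strata − 1). The source analyses this package reproduces report
p-values without naming their test; Pearson's chi-square is the standard
choice at these sample sizes and is recorded as an assumption in the table
metadata. Strata with zero members are kept in the table with n = 0 and an
omitted percentage, and are excluded from the test. Unknown-gender patients
appear in overall, age and year strata but not gender strata.

## Numerical and degenerate-input conventions

* Date parsing auto-detects the dialect **per file** (ISO `yyyy-mm-dd` or
  `dd/mm/yyyy`); a file mixing dialects is an error — guessing between
  05/03 and 03/05 silently corrupts cohorts.
* Event streams are stored date-ascending with stable ties; classification
  logic never depends on within-day order.
* An empty code list, a duplicate code (all offenders reported), an
  out-of-range severity group, an orphan event and a missing demographic
  row are hard errors at the boundary where the file is read; batch
  classification collects per-record errors instead of aborting.
* `homogeneity_test` refuses degenerate margins (an empty stratum or an
  all-one/all-zero outcome) rather than returning NaN.
* The classifier itself contains no randomness and no tolerances; two runs
  over the same inputs are identical.

## Verification strategy and problem sizes

The test suite checks the implementation against an independently written
brute-force evaluator that walks the criterion definitions with plain
nested loops: agreement on 10,000 randomly generated small records (up to
six events, code pools mixing RA, condition and unknown codes, short date
ranges to force same-day collisions), plus capped and
before-prescription-scope variants on smaller batches. Generator fidelity
is checked at n = 1000 over ten seeds (classifier output must equal truth
labels with zero discrepancies), mixture sampling at n = 1000 against a
3-sigma binomial band, the reporting arithmetic against a reconstructed
4161-patient overlap table, rounding against an independent closed form on
random numerators up to 10^5, and end-to-end determinism by hashing the
files of two identical simulate-classify-report runs. The acceptance script
runs the full pipeline at n = 4161, the scale of the characterised cohort.

## Known limitations

* The algorithm is designed for specificity; it is unsuitable where a
  sensitive definition is needed (prevalence studies, audit), and its
  sensitivity/specificity cannot be estimated here without chart review.
* NSAID and oral-steroid prescription patterns, considered and rejected in
  the original development of this class of algorithm, are out of scope, as
  is any probabilistic scoring.
* Registration/transfer-out dates and practice quality flags are not
  modelled; follow-up is measured to the last recorded event.
* The generator's demographics are independent of its archetypes by design;
  stratified analyses on synthetic data therefore test table mechanics, not
  epidemiology.
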