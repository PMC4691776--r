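# phenora

Rule-based phenotyping of rheumatoid arthritis (RA) in coded primary-care
EHR databases (CPRD GOLD-style flat files), for epidemiologists who need an
incident RA cohort that contains only highly probable cases rather than
everyone with a single RA code.

## The algorithm

A patient enters the cohort on the date of their **first RA diagnosis code**
(the index date) inside a study window. They are classified as **definite
RA** if they meet at least one of:

- **Criterion 1** — at least one RA diagnosis code and at least one
  prescription of a disease-modifying antirheumatic drug (DMARD) with **no
  alternative indication** for that specific drug anywhere in the record.
  Disqualification is drug-specific: a psoriasis code disqualifies
  methotrexate (licensed for psoriasis) but not a drug whose alternative
  indications do not include psoriasis.
- **Criterion 2** — all three of:
  - (a) RA codes on **two or more distinct calendar dates**;
  - (b) **no alternative diagnosis** (psoriatic arthritis, ankylosing
    spondylitis, other spondyloarthropathy) coded strictly **after the final
    RA code**;
  - (c) at least one RA code in severity **group 1** (seropositive/erosive)
    or **group 2** (plain RA codes), as opposed to only group 3 (systemic
    manifestations) or group 4 (seronegative/weak evidence).

Formally, with flags `c1`, `c2a`, `c2b`, `c2c` per patient:
`c2 = c2a ∧ c2b ∧ c2c` and `definite = c1 ∨ c2`.

The package provides:

- loading/validation of the three dictionary families (RA codes with
  severity groups, DMARDs with per-drug alternative indications, condition
  code sets including the alternative-diagnosis set);
- CPRD-style flat-file I/O, incident cohort selection, follow-up;
- per-patient classification with auditable evidence (qualifying and
  disqualified prescriptions, superseding diagnoses);
- a **constructive synthetic cohort generator** whose patients are built to
  satisfy or violate chosen sub-conditions, giving exact ground-truth labels;
- stratified fulfilment tables (gender, age band, index year) with a Pearson
  chi-square homogeneity test;
- a pipeline CLI (`validate` / `simulate` / `classify` / `report`).

The dictionary files under `inst/extdata/` are **illustrative synthetic
lists** that follow the published schemas; users supply their own curated
code lists for real studies.

## Worked example

Simulate a 1000-patient incident cohort with the default archetype mixture,
classify it, and report fulfilment by age band:

```r
library(phenora)
f <- function(p) system.file("extdata", p, package = "phenora")
conditions <- load_condition_codesets(f("condition_codes.csv"))
dict <- list(ra = load_ra_codelist(f("ra_codes.csv")),
             dmards = load_dmard_dictionary(f("dmards.csv"), conditions),
             conditions = conditions)

sim <- generate_cohort(generator_config(n_patients = 1000, seed = 42), dict)
res <- classify_cohort(sim$records, dict)
res
#> <cohort_classification> 1000 patients classified
#>   definite RA: 859 (85.9%)  [criterion 1 only 144, criterion 2 only 67, both 648]

demo <- data.frame(patient_id = vapply(sim$records, `[[`, "", "patient_id"),
                   gender = vapply(sim$records, `[[`, "", "gender"),
                   year_of_birth = vapply(sim$records, `[[`, 0L, "year_of_birth"))
fulfilment_summary(res$classifications, demo, "age_band", "definite")
#> Fulfilment of flag 'definite' by age_band
#>   <50             384/444    (86.5)
#>   50-59           100/124    (80.6)
#>   60-69           113/133    (85.0)
#>   70+             262/299    (87.6)
#>   all             859/1000   (85.9)
#>   homogeneity: chi-square = 3.785, df = 3, p = 0.286  [Pearson chi-square, no continuity correction (assumed test)]
```

859 of 1000 patients are definite RA (85.9%), split into 144 who qualify
only through a clean DMARD prescription, 67 only through repeated strong
coding, and 648 through both; fulfilment is homogeneous across age bands
(p = 0.286). Each classification carries its evidence:

```r
classify_patient(sim$records[["P000002"]], dict)
#> <ra_classification P000002> definite=FALSE (c1=FALSE c2=FALSE [a=TRUE b=FALSE c=TRUE]) index=2011-09-30
```

This patient has repeated strong RA codes but an alternative diagnosis after
the last one (`c2b = FALSE`), so they are excluded — and the generator's
truth file confirms they were built as the `alt_diag_after` archetype.

From a shell, the same pipeline is:

```sh
Rscript inst/cli/phenora.R validate --ra-codes ra.csv --dmards dmards.csv --conditions conditions.csv
Rscript inst/cli/phenora.R simulate --out data/ --ra-codes ra.csv --dmards dmards.csv --conditions conditions.csv --n-patients 1000 --seed 42
Rscript inst/cli/phenora.R classify --data data/ --ra-codes ra.csv --dmards dmards.csv --conditions conditions.csv
Rscript inst/cli/phenora.R report --classifications data/classifications.csv --patients data/patients.csv
```

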