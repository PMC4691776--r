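# dict: MTX disqualified by pso/ibd/psa codes, HCQ by sle only, RTX by
# nothing; RA1/RA1b strong group 1, RA2 strong group 2, RA3/RA4 weak.

test_that("criterion 1: qualifying DMARD with drug-specific disqualification", {
  dict <- test_dictionaries()

  r <- rec("P1", clin = list(c("2010-03-01", "RA2")),
           ther = list(c("2010-04-01", "MTX")))
  expect_true(evaluate_criterion1(r, dict)$met)

  # no therapy at all
  expect_false(evaluate_criterion1(
    rec("P2", clin = list(c("2010-03-01", "RA2"))), dict)$met)

  # a psoriasis code anywhere disqualifies methotrexate...
  r3 <- rec("P3", clin = list(c("2010-03-01", "RA2"), c("2012-01-01", "PSO1")),
            ther = list(c("2010-04-01", "MTX")))
  c1 <- evaluate_criterion1(r3, dict)
  expect_false(c1$met)
  expect_identical(c1$disqualified$disqualifying_condition, "pso")
  expect_identical(c1$disqualified$disqualifying_code, "PSO1")

  # ...but not hydroxychloroquine, whose indications lack psoriasis
  r4 <- rec("P4", clin = r3$clinical,
            ther = list(c("2010-04-01", "MTX"), c("2010-05-01", "HCQ")))
  c14 <- evaluate_criterion1(r4, dict)
  expect_true(c14$met)
  expect_identical(c14$qualifying$drug_code, "HCQ")
  expect_identical(c14$disqualified$drug_code, "MTX")

  # unknown drug codes are ignored, not errors
  r5 <- rec("P5", clin = list(c("2010-03-01", "RA2")),
            ther = list(c("2010-04-01", "NOT_A_DMARD")))
  expect_false(evaluate_criterion1(r5, dict)$met)

  # a drug with an empty alternative-indication set is never disqualified
  r6 <- rec("P6", clin = list(c("2010-03-01", "RA2"), c("2010-06-01", "PSO1"),
                              c("2011-01-01", "SLE1")),
            ther = list(c("2010-04-01", "RTX")))
  expect_true(evaluate_criterion1(r6, dict)$met)
})

test_that("criterion 1 scope switch: whole-record vs before-prescription", {
  dict <- test_dictionaries()
  # disqualifying code AFTER the prescription
  r <- rec("P1", clin = list(c("2010-03-01", "RA2"), c("2011-01-01", "PSO1")),
           ther = list(c("2010-04-01", "MTX")))
  expect_false(evaluate_criterion1(r, dict,
                                   alt_indication_scope = "whole-record")$met)
  expect_true(evaluate_criterion1(
    r, dict, alt_indication_scope = "before-prescription")$met)
  # disqualifying code before the prescription blocks under both scopes
  r2 <- rec("P2", clin = list(c("2009-01-01", "PSO1"), c("2010-03-01", "RA2")),
            ther = list(c("2010-04-01", "MTX")))
  expect_false(evaluate_criterion1(
    r2, dict, alt_indication_scope = "before-prescription")$met)
})

test_that("criterion 2: distinct dates, strong group, no superseding diagnosis", {
  dict <- test_dictionaries()

  r <- rec("P1", clin = list(c("2010-01-05", "RA4"), c("2010-02-10", "RA1")))
  c2 <- evaluate_criterion2(r, dict)
  expect_true(all(c2$met, c2$c2a, c2$c2b, c2$c2c))

  # two strong codes on the same date: "different dates" violated
  r2 <- rec("P2", clin = list(c("2010-01-05", "RA2"), c("2010-01-05", "RA2")))
  c22 <- evaluate_criterion2(r2, dict)
  expect_false(c22$c2a)
  expect_false(c22$met)
  expect_true(c22$c2b && c22$c2c)

  # weak groups only on distinct dates: c2c fails
  r3 <- rec("P3", clin = list(c("2010-01-05", "RA3"), c("2010-02-10", "RA4")))
  c23 <- evaluate_criterion2(r3, dict)
  expect_true(c23$c2a)
  expect_false(c23$c2c)
  # ... adding a psoriatic-arthritis code after the last RA code also breaks c2b
  r4 <- rec("P4", clin = list(c("2010-01-05", "RA3"), c("2010-02-10", "RA4"),
                              c("2010-06-01", "PSA1")))
  c24 <- evaluate_criterion2(r4, dict)
  expect_false(c24$c2b)
  expect_identical(c24$alt_dx_after$code, "PSA1")

  # same-day alternative diagnosis does NOT supersede (strictly-after rule)
  r5 <- rec("P5", clin = list(c("2010-01-05", "RA2"), c("2010-02-10", "RA2"),
                              c("2010-02-10", "PSA1")))
  expect_true(evaluate_criterion2(r5, dict)$c2b)
  # non-alternative-diagnosis conditions (e.g. lupus) never trigger c2b
  r6 <- rec("P6", clin = list(c("2010-01-05", "RA2"), c("2010-02-10", "RA2"),
                              c("2010-06-01", "SLE1")))
  expect_true(evaluate_criterion2(r6, dict)$c2b)
})

test_that("classification composes the criteria and carries evidence", {
  dict <- test_dictionaries()

  both <- classify_patient(rec("both",
    clin = list(c("2010-01-05", "RA2"), c("2010-02-10", "RA1")),
    ther = list(c("2010-03-01", "HCQ"))), dict)
  expect_true(both$definite && both$c1 && both$c2)
  expect_identical(both$index_date, as.Date("2010-01-05"))
  expect_identical(both$evidence$ra_event_dates_by_group$group1,
                   as.Date("2010-02-10"))
  expect_identical(both$evidence$ra_event_dates_by_group$group2,
                   as.Date("2010-01-05"))

  # single weak code, no DMARD: nothing met
  nothing <- classify_patient(rec("none", clin = list(c("2010-01-05", "RA4"))),
                              dict)
  expect_false(nothing$definite)
  expect_false(nothing$c1 || nothing$c2a || nothing$c2c)
  expect_true(nothing$c2b)

  # clean DMARD but a single RA code: definite via criterion 1 alone
  c1only <- classify_patient(rec("c1only",
    clin = list(c("2010-01-05", "RA2")),
    ther = list(c("2010-02-01", "RTX"))), dict)
  expect_true(c1only$definite && c1only$c1)
  expect_false(c1only$c2)

  # invariant wiring
  for (cl in list(both, nothing, c1only)) {
    expect_identical(cl$c2, cl$c2a && cl$c2b && cl$c2c)
    expect_identical(cl$definite, cl$c1 || cl$c2)
    if (cl$c1) expect_gt(nrow(cl$evidence$qualifying_dmard_events), 0)
    if (!cl$c2b) {
      expect_gt(nrow(
        cl$evidence$alternative_diagnosis_events_after_last_ra_code), 0)
    }
  }

  expect_error(classify_patient(rec("x", clin = list(c("2010-01-01", "PSO1"))),
                                dict), "no RA code")
})

test_that("follow-up cap restricts which events can satisfy the criteria", {
  dict <- test_dictionaries()
  # second RA code and DMARD 14 months after index: full record meets both
  # criteria, a 12-month cap meets neither
  r <- rec("P1", clin = list(c("2010-01-01", "RA2"), c("2011-03-01", "RA2")),
           ther = list(c("2011-03-01", "RTX")))
  full <- classify_patient(r, dict)
  capped <- classify_patient(r, dict, followup_months = 12)
  expect_true(full$definite)
  expect_false(capped$definite)
  expect_false(capped$c2a || capped$c1)
  # pre-index history is never capped
  r2 <- rec("P2", clin = list(c("2005-01-01", "PSO1"),
                              c("2010-01-01", "RA2")),
            ther = list(c("2010-02-01", "MTX")))
  expect_false(classify_patient(r2, dict, followup_months = 12)$c1)
})

test_that("a code shared between the RA list and a condition set counts as RA only", {
  dir <- withr::local_tempdir()
  ra <- load_ra_codelist(test_ra_csv(dir))
  # RA2 wrongly listed under ankylosing spondylitis; psoriasis set holds RA1b
  cond <- load_condition_codesets(write_lines_tmp(
    c("condition_id,code,term,is_alternative_diagnosis",
      "as,RA2,Ankylosing spondylitis,true",
      "as,AS1,Ankylosing spondylitis,true",
      "pso,RA1b,Psoriasis,false"), "cond.csv"))
  dm <- load_dmard_dictionary(write_lines_tmp(
    c("drug_code,name,class,alt_indications",
      "MTX,methotrexate,conventional,pso"), "dm.csv"), cond)
  dict <- list(ra = ra, dmards = dm, conditions = cond)
  # RA2 after the last other RA code must not break c2b, and RA1b must not
  # disqualify methotrexate: the RA interpretation wins
  r <- rec("P1", clin = list(c("2010-01-01", "RA1"), c("2010-02-01", "RA1b"),
                             c("2010-06-01", "RA2")),
           ther = list(c("2010-03-01", "MTX")))
  cl <- classify_patient(r, dict)
  expect_true(cl$c1 && cl$c2b && cl$definite)
})

test_that("batch classification collects errors and attaches overlap counts", {
  dict <- test_dictionaries()
  records <- list(
    both = rec("both", clin = list(c("2010-01-05", "RA2"),
                                   c("2010-02-10", "RA1")),
               ther = list(c("2010-03-01", "HCQ"))),
    c1only = rec("c1only", clin = list(c("2010-01-05", "RA2")),
                 ther = list(c("2010-02-01", "RTX"))),
    none = rec("none", clin = list(c("2010-01-05", "RA4"))))
  res <- classify_cohort(records, dict)
  expect_identical(res$counts,
                   c(definite = 2L, c1_only = 1L, c2_only = 0L, both = 1L))
  expect_identical(res$classifications$patient_id,
                   c("both", "c1only", "none"))

  # empty cohort
  res0 <- classify_cohort(list(), dict)
  expect_identical(nrow(res0$classifications), 0L)
  expect_true(all(res0$counts == 0L))

  # a record without an RA code is collected, not thrown
  res2 <- classify_cohort(c(records,
                            list(bad = rec("bad",
                              clin = list(c("2010-01-01", "PSO1"))))), dict)
  expect_named(res2$errors, "bad")
  expect_identical(nrow(res2$classifications), 3L)
})

test_that("classification output round-trips through classifications.csv", {
  dict <- test_dictionaries()
  res <- classify_cohort(list(
    a = rec("a", clin = list(c("2010-01-05", "RA2"), c("2010-02-10", "RA1"))),
    b = rec("b", clin = list(c("2010-01-05", "RA4")))), dict)
  dir <- withr::local_tempdir()
  paths <- write_classifications(res, dir)
  back <- read_classifications(file.path(dir, "classifications.csv"))
  expect_identical(back, res$classifications)
  ev <- jsonlite::read_json(file.path(dir, "evidence.json"))
  expect_named(ev, c("a", "b"))
  expect_identical(ev$a$index_date, "2010-01-05")
})

test_that("implementation agrees with the brute-force oracle on random records", {
  dict <- test_dictionaries()
  set.seed(42)
  for (i in 1:400) {
    r <- random_record(i, dict)
    got <- flags_of(classify_patient(r, dict))
    expect_identical(got, oracle_classify(r, dict),
                     info = paste("record", i))
  }
  # same property under a 12-month follow-up cap and the alternative scope
  set.seed(43)
  for (i in 1:150) {
    r <- random_record(i, dict)
    expect_identical(
      flags_of(classify_patient(r, dict, followup_months = 12)),
      oracle_classify(r, dict, followup_months = 12),
      info = paste("capped record", i))
    expect_identical(
      flags_of(classify_patient(r, dict,
                                alt_indication_scope = "before-prescription")),
      oracle_classify(r, dict, scope = "before-prescription"),
      info = paste("scoped record", i))
  }
})

test_that("monotonicity: clean DMARDs only help, late alternative diagnoses only hurt c2b", {
  dict <- test_dictionaries()
  set.seed(7)
  for (i in 1:60) {
    r <- random_record(i, dict)
    base <- classify_patient(r, dict)

    # adding a prescription of a drug with no alternative indications can
    # never flip definite TRUE -> FALSE
    r_plus <- r
    r_plus$therapy <- rbind(r_plus$therapy,
                            data.frame(event_date = as.Date("2010-02-15"),
                                       drug_code = "RTX"))
    aug <- classify_patient(r_plus, dict)
    expect_true(!base$definite || aug$definite)

    # adding an alternative diagnosis after the last RA code can flip c2b
    # TRUE -> FALSE only, and never affects c1
    last_ra <- max(r$clinical$event_date[!is.na(ra_group(r$clinical$code,
                                                         dict$ra))])
    r_alt <- r
    r_alt$clinical <- rbind(r_alt$clinical,
                            data.frame(event_date = last_ra + 10,
                                       code = "AS1"))
    alt <- classify_patient(r_alt, dict)
    expect_false(!base$c2b && alt$c2b)
    expect_identical(alt$c1, base$c1)
  }
})

test_that("classification is deterministic", {
  dict <- test_dictionaries()
  set.seed(11)
  records <- lapply(1:25, random_record, dict = dict)
  a <- classify_cohort(records, dict)
  b <- classify_cohort(records, dict)
  expect_identical(a$classifications, b$classifications)
  expect_identical(a$evidence, b$evidence)
})
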