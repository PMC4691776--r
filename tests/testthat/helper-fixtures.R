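# Small controlled dictionaries and record builders, constructed in code at
# test time. Codes are deliberately synthetic (RA1..RA4, PSO1, ...) so tests
# read as the logic they exercise.

write_lines_tmp <- function(lines, name) {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  writeLines(lines, path)
  path
}

# RA list with one code per severity group, plus a second strong code.
test_ra_csv <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "ra_codes.csv")
  writeLines(c("code,term,group",
               "RA1,Seropositive RA,1",
               "RA1b,Erosive RA,1",
               "RA2,Rheumatoid arthritis,2",
               "RA3,Rheumatoid lung,3",
               "RA4,Seronegative RA,4"), path)
  path
}

test_conditions_csv <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "condition_codes.csv")
  writeLines(c("condition_id,code,term,is_alternative_diagnosis",
               "pso,PSO1,Psoriasis,false",
               "ibd,IBD1,Crohn's disease,false",
               "sle,SLE1,Systemic lupus erythematosus,false",
               "psa,PSA1,Psoriatic arthritis,true",
               "as,AS1,Ankylosing spondylitis,true"), path)
  path
}

test_dmards_csv <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "dmards.csv")
  writeLines(c("drug_code,name,class,alt_indications",
               "MTX,methotrexate,conventional,pso;ibd;psa",
               "HCQ,hydroxychloroquine,conventional,sle",
               "RTX,rituximab,biologic,"), path)
  path
}

# The standard dictionary set used across tests: methotrexate is
# disqualified by psoriasis/IBD/psoriatic-arthritis codes, hydroxychloroquine
# only by lupus, rituximab by nothing.
test_dictionaries <- function() {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  conditions <- load_condition_codesets(test_conditions_csv(dir))
  list(ra = load_ra_codelist(test_ra_csv(dir)),
       dmards = load_dmard_dictionary(test_dmards_csv(dir), conditions),
       conditions = conditions)
}

# Compact record builder: clin/ther are lists of c(date, code) pairs, or
# ready-made event data.frames.
rec <- function(id, clin = list(), ther = list(), gender = "F", yob = 1950L) {
  cdf <- if (is.data.frame(clin)) clin else if (length(clin)) {
    data.frame(event_date = as.Date(vapply(clin, `[[`, "", 1)),
               code = vapply(clin, `[[`, "", 2), stringsAsFactors = FALSE)
  } else NULL
  tdf <- if (is.data.frame(ther)) ther else if (length(ther)) {
    data.frame(event_date = as.Date(vapply(ther, `[[`, "", 1)),
               drug_code = vapply(ther, `[[`, "", 2), stringsAsFactors = FALSE)
  } else NULL
  patient_record(id, gender, yob, clinical = cdf, therapy = tdf)
}

flags_of <- function(cl) {
  c(c1 = cl$c1, c2a = cl$c2a, c2b = cl$c2b, c2c = cl$c2c, c2 = cl$c2,
    definite = cl$definite)
}
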