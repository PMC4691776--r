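# Constructive synthetic cohort generator. Each patient is BUILT to satisfy
# or violate specific sub-conditions of the diagnostic algorithm, so the
# emitted truth labels are exact, not statistical: classify_cohort() on the
# generated files must reproduce them patient for patient. Archetype mixing
# is the only stochastic element besides demographics and date placement.

#' Default archetype set covering every branch of the algorithm
#'
#' Eight archetypes: the three definite-RA overlap groups (criterion 1 only,
#' criterion 2 only, both) and five non-definite branches, including one for
#' each single broken sub-condition of criterion 2 (same-date repeat codes
#' breaking 2a, an alternative diagnosis after the last RA code breaking 2b,
#' weak-severity-only codes breaking 2c). Default weights put 15.8% on
#' criterion-1-only, 7.3% on criterion-2-only, 62.8% on both and split the
#' remaining 14.1% over the non-definite branches, mirroring the fulfilment
#' mix observed when the algorithm was applied to a real primary-care
#' incident RA cohort.
#'
#' @return data.frame of class `archetype_set`: columns `name`, intended
#'   flags `c1`, `c2a`, `c2b`, `c2c`, `definite`, and `weight` (sums to 1).
#' @export
default_archetype_set <- function() {
  a <- data.frame(
    name = c("both", "c1_only", "c2_only", "single_code_no_dmard",
             "dmard_disqualified", "same_date_codes", "alt_diag_after",
             "weak_group_only"),
    c1  = c(TRUE,  TRUE,  FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    c2a = c(TRUE,  FALSE, TRUE,  FALSE, FALSE, FALSE, TRUE,  TRUE),
    c2b = c(TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  TRUE,  FALSE, TRUE),
    c2c = c(TRUE,  TRUE,  TRUE,  FALSE, TRUE,  TRUE,  TRUE,  FALSE),
    weight = c(0.628, 0.158, 0.073, 0.029, 0.028, 0.028, 0.028, 0.028),
    stringsAsFactors = FALSE)
  a$definite <- a$c1 | (a$c2a & a$c2b & a$c2c)
  stopifnot(abs(sum(a$weight) - 1) < 1e-9)
  class(a) <- c("archetype_set", "data.frame")
  a
}

#' Generator configuration
#'
#' @param n_patients Number of patients to generate (>= 0).
#' @param seed Integer seed; a fixed seed yields byte-identical output files.
#' @param window Length-2 Date vector: the first-RA-code selection window.
#'   Every generated patient's index date is drawn uniformly inside it.
#' @param weights Named numeric vector of archetype mixture proportions
#'   (names must match the archetype set; must sum to 1 within 1e-9).
#'   `NULL` uses the archetype set's own weights.
#' @param female_prop Proportion of female patients (RA predominates in
#'   women at roughly 2:1 in incident primary-care cohorts).
#' @param age_range Inclusive range of age at index, sampled uniformly;
#'   year of birth is derived as index year minus age.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_patients = 1000L, seed = 1L,
                             window = as.Date(c("2010-01-01", "2012-12-31")),
                             weights = NULL, female_prop = 0.665,
                             age_range = c(18L, 90L)) {
  window <- as.Date(window)
  stopifnot(n_patients >= 0, length(window) == 2L, window[1] <= window[2],
            female_prop >= 0, female_prop <= 1,
            length(age_range) == 2L, age_range[1] >= 18,
            age_range[1] <= age_range[2])
  if (!is.null(weights)) {
    stopifnot(!is.null(names(weights)), all(weights >= 0),
              abs(sum(weights) - 1) < 1e-9)
  }
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 window = window, weights = weights,
                 female_prop = female_prop,
                 age_range = as.integer(age_range)),
            class = "generator_config")
}

#' Generate a synthetic cohort with exact ground-truth labels
#'
#' Emits `patient_record`s (and optionally CPRD-style flat files
#' `patients.csv`, `clinical.csv`, `therapy.csv` plus `truth.csv`) for a
#' mixture of archetypes. Every patient's first RA code lies inside the
#' selection window; classification of the output reproduces the intended
#' flags exactly, per patient, because construction — not sampling — decides
#' which sub-conditions hold.
#'
#' @param config A `generator_config`.
#' @param dictionaries List with `ra`, `dmards`, `conditions`. Must supply
#'   the building blocks the requested archetypes need: at least one
#'   group-1-or-2 ("strong") and one group-3-or-4 ("weak") RA code, a DMARD,
#'   a DMARD with a codeable alternative indication, and an
#'   alternative-diagnosis code.
#' @param archetypes An `archetype_set`; default [default_archetype_set()].
#' @param out_dir If non-NULL, write the four flat files there.
#' @return List of class `synthetic_cohort`: `records` (named list of
#'   `patient_record`), `truth` (data.frame patient_id, archetype, c1, c2a,
#'   c2b, c2c, definite), `config`, and `files` (paths, or NULL).
#' @export
generate_cohort <- function(config, dictionaries,
                            archetypes = default_archetype_set(),
                            out_dir = NULL) {
  stopifnot(inherits(config, "generator_config"),
            inherits(archetypes, "archetype_set"))
  weights <- config$weights
  if (is.null(weights)) {
    weights <- stats::setNames(archetypes$weight, archetypes$name)
  }
  missing <- setdiff(names(weights), archetypes$name)
  if (length(missing)) {
    stop("weights name unknown archetype(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  weights <- weights[match(archetypes$name, names(weights))]
  weights[is.na(weights)] <- 0
  blocks <- generator_blocks(dictionaries,
                             archetypes$name[weights > 0])

  n <- config$n_patients
  set.seed(config$seed)
  # all archetype draws first, in one call, so archetype assignment is
  # independent of how many demographic/date draws each patient consumes
  arch_idx <- if (n > 0) {
    sample.int(nrow(archetypes), n, replace = TRUE, prob = weights)
  } else integer()
  genders <- ifelse(stats::runif(n) < config$female_prop, "F", "M")
  ages <- sample(seq(config$age_range[1], config$age_range[2]), n,
                 replace = TRUE)
  span <- as.integer(config$window[2] - config$window[1])
  t0 <- config$window[1] + sample.int(span + 1L, n, replace = TRUE) - 1L

  records <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    arch <- archetypes$name[arch_idx[i]]
    id <- sprintf("P%06d", i)
    ev <- archetype_events(arch, t0[i], blocks)
    yob <- as.integer(format(t0[i], "%Y")) - ages[i]
    records[[i]] <- patient_record(id, genders[i], yob,
                                   clinical = ev$clinical,
                                   therapy = ev$therapy)
    truth[[i]] <- data.frame(
      patient_id = id, archetype = arch,
      c1 = archetypes$c1[arch_idx[i]], c2a = archetypes$c2a[arch_idx[i]],
      c2b = archetypes$c2b[arch_idx[i]], c2c = archetypes$c2c[arch_idx[i]],
      definite = archetypes$definite[arch_idx[i]], stringsAsFactors = FALSE)
  }
  names(records) <- sprintf("P%06d", seq_len(n))
  truth <- if (n == 0L) {
    data.frame(patient_id = character(), archetype = character(),
               c1 = logical(), c2a = logical(), c2b = logical(),
               c2c = logical(), definite = logical(),
               stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, truth)
    rownames(out) <- NULL
    out
  }
  files <- NULL
  if (!is.null(out_dir)) {
    files <- write_records(records, out_dir)
    truth_out <- truth
    for (fl in c("c1", "c2a", "c2b", "c2c", "definite")) {
      truth_out[[fl]] <- ifelse(truth[[fl]], "true", "false")
    }
    tf <- file.path(out_dir, "truth.csv")
    write_csv_plain(truth_out, tf)
    files <- c(files, tf)
  }
  structure(list(records = records, truth = truth, config = config,
                 files = files),
            class = "synthetic_cohort")
}

#' Read a truth.csv emitted by the generator
#' @param path Path to `truth.csv`.
#' @return data.frame with logical flag columns.
#' @export
read_truth <- function(path) {
  df <- read_dictionary_csv(path, c("patient_id", "archetype", "c1", "c2a",
                                    "c2b", "c2c", "definite"))
  for (fl in c("c1", "c2a", "c2b", "c2c", "definite")) {
    df[[fl]] <- tolower(trimws(df[[fl]])) %in% c("true", "t", "1")
  }
  df
}

# -- internal -----------------------------------------------------------------

# Resolve the dictionary building blocks archetypes are assembled from.
generator_blocks <- function(dictionaries, needed_archetypes) {
  ra <- dictionaries$ra
  dmards <- dictionaries$dmards
  conditions <- dictionaries$conditions
  strong <- ra$code[ra$group %in% c(1L, 2L)]
  weak <- ra$code[ra$group %in% c(3L, 4L)]
  altdx <- setdiff(alternative_diagnosis_codes(conditions), ra$code)
  disq <- NULL
  for (d in seq_len(nrow(dmards))) {
    codes <- setdiff(condition_codes(conditions, dmards$alt_indications[[d]]),
                     ra$code)
    if (length(codes)) {
      disq <- list(drug = dmards$drug_code[d], code = codes[1])
      break
    }
  }
  req <- function(ok, what, archs) {
    if (!ok && any(archs %in% needed_archetypes)) {
      stop("dictionaries lack a building block: ", what,
           " (needed by archetype(s) ",
           paste(intersect(archs, needed_archetypes), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  req(length(strong) > 0, "a group 1 or 2 RA code",
      c("both", "c1_only", "c2_only", "dmard_disqualified",
        "same_date_codes", "alt_diag_after"))
  req(length(weak) > 0, "a group 3 or 4 RA code",
      c("single_code_no_dmard", "same_date_codes", "weak_group_only"))
  req(nrow(dmards) > 0, "a DMARD", c("both", "c1_only"))
  req(!is.null(disq), "a DMARD with a codeable alternative indication",
      "dmard_disqualified")
  req(length(altdx) > 0, "an alternative-diagnosis code", "alt_diag_after")
  list(strong = strong, weak = weak, altdx = altdx, disq = disq,
       dmard = if (nrow(dmards)) dmards$drug_code[1] else NULL)
}

# Deterministic event layout for one patient of a given archetype, anchored
# at index date t0 (the first RA code). Offsets are fixed: edge cases like
# same-day repeats are produced deliberately, never by chance.
archetype_events <- function(arch, t0, blocks) {
  s1 <- blocks$strong[1]
  s2 <- blocks$strong[min(2L, length(blocks$strong))]
  w1 <- blocks$weak[1]
  clin <- function(dates, codes) {
    data.frame(event_date = as.Date(dates, origin = "1970-01-01"),
               code = codes, stringsAsFactors = FALSE)
  }
  ther <- function(dates, drugs) {
    data.frame(event_date = as.Date(dates, origin = "1970-01-01"),
               drug_code = drugs, stringsAsFactors = FALSE)
  }
  empty_ther <- ther(numeric(), character())
  switch(arch,
    both = list(clinical = clin(c(t0, t0 + 35), c(s1, s2)),
                therapy = ther(t0 + 7, blocks$dmard)),
    c1_only = list(clinical = clin(t0, s1),
                   therapy = ther(t0 + 14, blocks$dmard)),
    c2_only = list(clinical = clin(c(t0, t0 + 30), c(s1, s2)),
                   therapy = empty_ther),
    single_code_no_dmard = list(clinical = clin(t0, w1),
                                therapy = empty_ther),
    dmard_disqualified = list(
      # the disqualifying indication is coded before the index so it can
      # never touch criterion 2b, whichever search scope is in force
      clinical = clin(c(t0 - 120, t0), c(blocks$disq$code, s1)),
      therapy = ther(t0 + 7, blocks$disq$drug)),
    same_date_codes = list(clinical = clin(c(t0, t0), c(s1, w1)),
                           therapy = empty_ther),
    alt_diag_after = list(
      clinical = clin(c(t0, t0 + 30, t0 + 90), c(s1, s2, blocks$altdx[1])),
      therapy = empty_ther),
    weak_group_only = list(clinical = clin(c(t0, t0 + 30), c(w1, w1)),
                           therapy = empty_ther),
    stop("unknown archetype: ", arch, call. = FALSE))
}
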