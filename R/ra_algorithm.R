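# The two-criterion diagnostic algorithm for definite RA.
#
# Criterion 1: at least one diagnostic code for RA and at least one
#   prescription of a DMARD with no alternative indication for that drug
#   recorded for the patient.
# Criterion 2: all three of
#   (a) two or more RA diagnosis codes on different calendar dates;
#   (b) no alternative diagnosis coded after the final RA code;
#   (c) at least one RA code in severity group 1 (seropositive/erosive) or
#       group 2 (plain RA codes).
# A patient meeting either criterion is classified as definite RA.
#
# Everything here is deterministic; no randomness, no seeds.

#' Evaluate Criterion 1: qualifying DMARD prescription
#'
#' True iff some therapy event's drug is in the DMARD dictionary and the
#' record contains no clinical code belonging to any alternative-indication
#' condition of that specific drug. Disqualification is drug-specific: a
#' psoriasis code disqualifies methotrexate but not a drug whose
#' alternative-indication set lacks psoriasis. Drug codes absent from the
#' dictionary are ignored, not errors. A code that is also an RA code is
#' never treated as an alternative indication (the RA interpretation wins).
#'
#' @param record A `patient_record` with at least one RA code.
#' @param dictionaries List with elements `ra` (`ra_codelist`), `dmards`
#'   (`dmard_dictionary`), `conditions` (`condition_codesets`).
#' @param followup_months Optional cap: only events dated on or before the
#'   index date plus this many calendar months are considered. Default `NULL`
#'   uses the full record.
#' @param alt_indication_scope `"whole-record"` (default) searches the entire
#'   record for disqualifying codes; `"before-prescription"` only codes dated
#'   on or before the prescription.
#' @return List with `met` (logical), `qualifying` and `disqualified`
#'   data.frames of prescriptions (the latter with the disqualifying
#'   condition and code).
#' @export
evaluate_criterion1 <- function(record, dictionaries, followup_months = NULL,
                                alt_indication_scope = c("whole-record",
                                                         "before-prescription")) {
  alt_indication_scope <- match.arg(alt_indication_scope)
  ev <- capped_events(record, dictionaries$ra, followup_months)
  dmards <- dictionaries$dmards
  conditions <- dictionaries$conditions
  ther <- ev$therapy
  hit <- match(ther$drug_code, dmards$drug_code)
  qualifying <- disqualified <- list()
  for (i in which(!is.na(hit))) {
    d <- hit[i]
    alt_codes <- setdiff(condition_codes(conditions,
                                         dmards$alt_indications[[d]]),
                         dictionaries$ra$code)
    clin <- ev$clinical
    if (alt_indication_scope == "before-prescription") {
      clin <- clin[clin$event_date <= ther$event_date[i], , drop = FALSE]
    }
    bad <- which(clin$code %in% alt_codes)
    row <- data.frame(event_date = ther$event_date[i],
                      drug_code = ther$drug_code[i],
                      drug_name = dmards$name[d], stringsAsFactors = FALSE)
    if (length(bad)) {
      b <- bad[1]
      row$disqualifying_code <- clin$code[b]
      row$disqualifying_condition <- paste(unique(
        conditions$condition_id[conditions$code == clin$code[b] &
          conditions$condition_id %in% dmards$alt_indications[[d]]]),
        collapse = ";")
      row$disqualifying_date <- clin$event_date[b]
      disqualified[[length(disqualified) + 1L]] <- row
    } else {
      qualifying[[length(qualifying) + 1L]] <- row
    }
  }
  list(met = length(qualifying) > 0L,
       qualifying = rbind_or_empty(qualifying,
         c("event_date", "drug_code", "drug_name")),
       disqualified = rbind_or_empty(disqualified,
         c("event_date", "drug_code", "drug_name", "disqualifying_code",
           "disqualifying_condition", "disqualifying_date")))
}

#' Evaluate Criterion 2: repeated codes, strong code, no superseding diagnosis
#'
#' Sub-conditions: `c2a` — RA codes on two or more distinct calendar dates
#' (same-day repeats count once); `c2b` — no clinical event with an
#' alternative-diagnosis code dated strictly after the last RA code (a
#' same-day alternative diagnosis does not disqualify); `c2c` — at least one
#' RA code in severity group 1 or 2. `c2 = c2a & c2b & c2c`.
#'
#' @inheritParams evaluate_criterion1
#' @return List with `met`, `c2a`, `c2b`, `c2c` (logicals),
#'   `ra_dates` (distinct RA-code dates), `alt_dx_after` (data.frame of
#'   alternative-diagnosis events after the last RA code).
#' @export
evaluate_criterion2 <- function(record, dictionaries, followup_months = NULL) {
  ev <- capped_events(record, dictionaries$ra, followup_months)
  grp <- ra_group(ev$clinical$code, dictionaries$ra)
  is_ra <- !is.na(grp)
  ra_dates <- sort(unique(ev$clinical$event_date[is_ra]))
  c2a <- length(ra_dates) >= 2L
  c2c <- any(grp[is_ra] %in% c(1L, 2L))
  alt_codes <- setdiff(alternative_diagnosis_codes(dictionaries$conditions),
                       dictionaries$ra$code)
  if (length(ra_dates)) {
    last_ra <- max(ra_dates)
    after <- ev$clinical$code %in% alt_codes & ev$clinical$event_date > last_ra
  } else {
    after <- rep(FALSE, nrow(ev$clinical))
  }
  c2b <- !any(after)
  list(met = c2a && c2b && c2c, c2a = c2a, c2b = c2b, c2c = c2c,
       ra_dates = ra_dates,
       alt_dx_after = ev$clinical[after, , drop = FALSE])
}

#' Classify one patient against the full definite-RA definition
#'
#' Deterministic evaluation of both criteria, returning the flags and the
#' supporting evidence needed to audit a decision: the index date, RA event
#' dates by severity group, qualifying and disqualified DMARD prescriptions
#' (with the disqualifying condition), and any alternative-diagnosis events
#' after the last RA code.
#'
#' @inheritParams evaluate_criterion1
#' @return An object of class `ra_classification`: list with `patient_id`,
#'   logical flags `c1`, `c2a`, `c2b`, `c2c`, `c2`, `definite`, `index_date`,
#'   and an `evidence` list.
#' @export
classify_patient <- function(record, dictionaries, followup_months = NULL,
                             alt_indication_scope = c("whole-record",
                                                      "before-prescription")) {
  alt_indication_scope <- match.arg(alt_indication_scope)
  idx <- index_date(record, dictionaries$ra)
  if (is.na(idx)) {
    stop("record ", record$patient_id,
         " has no RA code and is not a cohort member", call. = FALSE)
  }
  cr1 <- evaluate_criterion1(record, dictionaries, followup_months,
                             alt_indication_scope)
  cr2 <- evaluate_criterion2(record, dictionaries, followup_months)
  ev <- capped_events(record, dictionaries$ra, followup_months)
  grp <- ra_group(ev$clinical$code, dictionaries$ra)
  by_group <- lapply(1:4, function(g)
    sort(unique(ev$clinical$event_date[!is.na(grp) & grp == g])))
  names(by_group) <- paste0("group", 1:4)
  out <- list(patient_id = record$patient_id,
              c1 = cr1$met, c2a = cr2$c2a, c2b = cr2$c2b, c2c = cr2$c2c,
              c2 = cr2$met, definite = cr1$met || cr2$met,
              index_date = idx,
              evidence = list(
                index_date = idx,
                ra_event_dates_by_group = by_group,
                qualifying_dmard_events = cr1$qualifying,
                disqualified_dmard_events = cr1$disqualified,
                alternative_diagnosis_events_after_last_ra_code =
                  cr2$alt_dx_after))
  class(out) <- "ra_classification"
  out
}

#' @export
print.ra_classification <- function(x, ...) {
  cat(sprintf("<ra_classification %s> definite=%s (c1=%s c2=%s [a=%s b=%s c=%s]) index=%s\n",
              x$patient_id, x$definite, x$c1, x$c2, x$c2a, x$c2b, x$c2c,
              format(x$index_date)))
  invisible(x)
}

#' Classify every member of a cohort
#'
#' Applies [classify_patient()] to each cohort member. Per-record errors are
#' collected, not thrown mid-batch, so one malformed record cannot abort a
#' large run.
#'
#' @param cohort An `ehr_cohort` (from [select_incident_cohort()]) whose
#'   `dictionaries` element is populated, or a plain list of `patient_record`
#'   if `dictionaries` is given.
#' @param dictionaries Optional dictionary list overriding the cohort's.
#' @inheritParams evaluate_criterion1
#' @return An object of class `cohort_classification`: list with
#'   `classifications` (data.frame: patient_id, c1, c2a, c2b, c2c, c2,
#'   definite, index_date, one row per member in cohort order), `evidence`
#'   (named list), `errors` (named character), and `counts` (named integer:
#'   definite, c1_only, c2_only, both).
#' @export
classify_cohort <- function(cohort, dictionaries = NULL,
                            followup_months = NULL,
                            alt_indication_scope = c("whole-record",
                                                     "before-prescription")) {
  alt_indication_scope <- match.arg(alt_indication_scope)
  if (inherits(cohort, "ehr_cohort")) {
    records <- cohort$records
    if (is.null(dictionaries)) dictionaries <- cohort$dictionaries
  } else {
    records <- cohort
  }
  stopifnot(!is.null(dictionaries))
  rows <- vector("list", length(records))
  evidence <- vector("list", length(records))
  errors <- character()
  for (i in seq_along(records)) {
    cl <- tryCatch(
      classify_patient(records[[i]], dictionaries, followup_months,
                       alt_indication_scope),
      error = function(e) e)
    if (inherits(cl, "error")) {
      errors[records[[i]]$patient_id] <- conditionMessage(cl)
      next
    }
    rows[[i]] <- data.frame(patient_id = cl$patient_id, c1 = cl$c1,
                            c2a = cl$c2a, c2b = cl$c2b, c2c = cl$c2c,
                            c2 = cl$c2, definite = cl$definite,
                            index_date = cl$index_date,
                            stringsAsFactors = FALSE)
    evidence[[i]] <- cl$evidence
    names(evidence)[i] <- cl$patient_id
  }
  keep <- !vapply(rows, is.null, TRUE)
  df <- if (any(keep)) {
    out <- do.call(rbind, rows[keep])
    rownames(out) <- NULL
    out
  } else {
    data.frame(patient_id = character(), c1 = logical(), c2a = logical(),
               c2b = logical(), c2c = logical(), c2 = logical(),
               definite = logical(), index_date = as.Date(character()),
               stringsAsFactors = FALSE)
  }
  out <- list(classifications = df, evidence = evidence[keep],
              errors = errors, counts = overlap_counts(df))
  class(out) <- "cohort_classification"
  out
}

#' Criterion-overlap counts for a classified cohort
#'
#' The partition of definite cases by which criteria were met. Satisfies
#' `definite == c1_only + c2_only + both` by construction.
#'
#' @param x A `cohort_classification` or its `classifications` data.frame.
#' @return Named integer vector: `definite`, `c1_only`, `c2_only`, `both`.
#' @export
overlap_counts <- function(x) {
  if (inherits(x, "cohort_classification")) x <- x$classifications
  c(definite = sum(x$definite),
    c1_only = sum(x$c1 & !x$c2),
    c2_only = sum(!x$c1 & x$c2),
    both = sum(x$c1 & x$c2))
}

#' @export
print.cohort_classification <- function(x, ...) {
  n <- nrow(x$classifications)
  cat(sprintf("<cohort_classification> %d patients classified", n))
  if (length(x$errors)) cat(sprintf(" (%d errors)", length(x$errors)))
  cat("\n")
  ct <- x$counts
  pct <- function(k) if (n > 0) format_percentage(k, n) else "-"
  cat(sprintf("  definite RA: %d (%s%%)  [criterion 1 only %d, criterion 2 only %d, both %d]\n",
              ct[["definite"]], pct(ct[["definite"]]), ct[["c1_only"]],
              ct[["c2_only"]], ct[["both"]]))
  invisible(x)
}

#' Write batch classification output
#'
#' `classifications.csv` (patient_id, flags, index_date) plus a JSON evidence
#' sidecar `evidence.json` for the run.
#'
#' @param result A `cohort_classification`.
#' @param dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
write_classifications <- function(result, dir) {
  stopifnot(inherits(result, "cohort_classification"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- result$classifications
  out <- data.frame(patient_id = df$patient_id,
                    c1 = tolower(df$c1), c2a = tolower(df$c2a),
                    c2b = tolower(df$c2b), c2c = tolower(df$c2c),
                    c2 = tolower(df$c2), definite = tolower(df$definite),
                    index_date = format(df$index_date, "%Y-%m-%d"))
  csv <- file.path(dir, "classifications.csv")
  write_csv_plain(out, csv)
  sidecar <- file.path(dir, "evidence.json")
  ev <- lapply(result$evidence, function(e) {
    list(index_date = format(e$index_date, "%Y-%m-%d"),
         ra_event_dates_by_group = lapply(e$ra_event_dates_by_group, format,
                                          "%Y-%m-%d"),
         qualifying_dmard_events = date_cols_to_char(e$qualifying_dmard_events),
         disqualified_dmard_events =
           date_cols_to_char(e$disqualified_dmard_events),
         alternative_diagnosis_events_after_last_ra_code =
           date_cols_to_char(
             e$alternative_diagnosis_events_after_last_ra_code))
  })
  jsonlite::write_json(ev, sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv, sidecar))
}

#' Read a classifications.csv back into the reporting schema
#' @param path Path to a `classifications.csv` written by
#'   [write_classifications()].
#' @return data.frame with logical flag columns and Date `index_date`.
#' @export
read_classifications <- function(path) {
  df <- read_dictionary_csv(path, c("patient_id", "c1", "c2a", "c2b", "c2c",
                                    "c2", "definite", "index_date"))
  for (fl in c("c1", "c2a", "c2b", "c2c", "c2", "definite")) {
    df[[fl]] <- tolower(trimws(df[[fl]])) %in% c("true", "t", "1")
  }
  df$index_date <- as.Date(df$index_date)
  df
}

# -- internal -----------------------------------------------------------------

# Restrict both event streams to dates on or before index + followup_months
# calendar months. Events before the index are always kept: the cap bounds
# follow-up, not history.
capped_events <- function(record, ra, followup_months) {
  clinical <- record$clinical
  therapy <- record$therapy
  if (!is.null(followup_months)) {
    idx <- index_date(record, ra)
    if (!is.na(idx)) {
      cap <- seq(idx, by = paste(followup_months, "months"),
                 length.out = 2L)[2]
      clinical <- clinical[clinical$event_date <= cap, , drop = FALSE]
      therapy <- therapy[therapy$event_date <= cap, , drop = FALSE]
    }
  }
  list(clinical = clinical, therapy = therapy)
}

rbind_or_empty <- function(rows, cols) {
  if (length(rows) == 0L) {
    out <- lapply(cols, function(x) character())
    names(out) <- cols
    out <- as.data.frame(out, stringsAsFactors = FALSE)
    for (cc in grep("date", cols, value = TRUE)) out[[cc]] <- as.Date(character())
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

date_cols_to_char <- function(df) {
  for (cc in names(df)) {
    if (inherits(df[[cc]], "Date")) df[[cc]] <- format(df[[cc]], "%Y-%m-%d")
  }
  df
}
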