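# Patients and their coded event streams, read from CPRD GOLD-style flat
# files: patients.csv (patient_id,gender,year_of_birth),
# clinical.csv (patient_id,event_date,code),
# therapy.csv (patient_id,event_date,drug_code).

#' Construct a patient record
#'
#' A `patient_record` bundles one patient's demographics with date-sorted
#' clinical (diagnosis) and therapy (prescription) event streams. Duplicate
#' identical event rows are kept — repeat same-day codes are legal in
#' primary-care data; distinct-date logic lives in the classification
#' algorithm, not here.
#'
#' @param patient_id Opaque identifier (non-empty string).
#' @param gender One of `"M"`, `"F"`, `"U"`.
#' @param year_of_birth Calendar year of birth.
#' @param clinical data.frame with columns `event_date` (Date), `code`.
#' @param therapy data.frame with columns `event_date` (Date), `drug_code`.
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, gender = "U", year_of_birth = NA_integer_,
                           clinical = NULL, therapy = NULL) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L,
            nzchar(patient_id), gender %in% c("M", "F", "U"))
  if (is.null(clinical)) {
    clinical <- data.frame(event_date = as.Date(character()),
                           code = character(), stringsAsFactors = FALSE)
  }
  if (is.null(therapy)) {
    therapy <- data.frame(event_date = as.Date(character()),
                          drug_code = character(), stringsAsFactors = FALSE)
  }
  stopifnot(inherits(clinical$event_date, "Date"),
            inherits(therapy$event_date, "Date"))
  clinical <- clinical[order(clinical$event_date), , drop = FALSE]
  therapy <- therapy[order(therapy$event_date), , drop = FALSE]
  rownames(clinical) <- rownames(therapy) <- NULL
  yob <- as.integer(year_of_birth)
  ev_years <- as.integer(format(c(clinical$event_date, therapy$event_date),
                                "%Y"))
  if (!is.na(yob) && length(ev_years) && any(ev_years < yob)) {
    stop("patient ", patient_id, ": event predates year of birth",
         call. = FALSE)
  }
  structure(list(patient_id = patient_id, gender = gender,
                 year_of_birth = yob, clinical = clinical, therapy = therapy),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record %s> gender=%s yob=%s, %d clinical / %d therapy events\n",
              x$patient_id, x$gender, x$year_of_birth,
              nrow(x$clinical), nrow(x$therapy)))
  invisible(x)
}

#' Read patient records from CPRD-style flat files
#'
#' Dates may be ISO 8601 (`yyyy-mm-dd`) or CPRD `dd/mm/yyyy`; the dialect is
#' auto-detected per file and must be consistent within a file. Events whose
#' patient id does not appear in the patient table are an error (orphan
#' events), as silently dropping them would bias classification.
#'
#' @param patient_file CSV with header `patient_id,gender,year_of_birth`
#'   (gender M/F/U).
#' @param clinical_file CSV with header `patient_id,event_date,code`.
#' @param therapy_file CSV with header `patient_id,event_date,drug_code`.
#' @return A named list of `patient_record`, in patient-file order.
#' @export
read_records <- function(patient_file, clinical_file, therapy_file) {
  pat <- read_dictionary_csv(patient_file,
                             c("patient_id", "gender", "year_of_birth"))
  pat$patient_id <- trimws(pat$patient_id)
  dup <- unique(pat$patient_id[duplicated(pat$patient_id)])
  if (length(dup)) {
    stop("duplicate patient id(s) in ", patient_file, ": ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_gender <- !(pat$gender %in% c("M", "F", "U"))
  if (any(bad_gender)) {
    stop("invalid gender (expect M/F/U) on row(s) ",
         paste(which(bad_gender), collapse = ", "), " of ", patient_file,
         call. = FALSE)
  }
  clin <- read_dictionary_csv(clinical_file,
                              c("patient_id", "event_date", "code"))
  ther <- read_dictionary_csv(therapy_file,
                              c("patient_id", "event_date", "drug_code"))
  clin$event_date <- parse_event_dates(clin$event_date, clinical_file)
  ther$event_date <- parse_event_dates(ther$event_date, therapy_file)
  for (nm in list(list(clin, clinical_file), list(ther, therapy_file))) {
    orphan <- setdiff(unique(trimws(nm[[1]]$patient_id)), pat$patient_id)
    if (length(orphan)) {
      stop("orphan event(s) in ", nm[[2]], " for unknown patient id(s): ",
           paste(orphan, collapse = ", "), call. = FALSE)
    }
  }
  clin_split <- split(clin[c("event_date", "code")], trimws(clin$patient_id))
  ther_split <- split(ther[c("event_date", "drug_code")],
                      trimws(ther$patient_id))
  records <- lapply(seq_len(nrow(pat)), function(i) {
    id <- pat$patient_id[i]
    patient_record(id, pat$gender[i], pat$year_of_birth[i],
                   clinical = clin_split[[id]], therapy = ther_split[[id]])
  })
  names(records) <- pat$patient_id
  records
}

#' Write patient records to the flat-file schemas
#'
#' Inverse of [read_records()]: a written set of files re-reads to records
#' with every event field preserved exactly. Dates are written in ISO 8601.
#'
#' @param records Named list of `patient_record`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_records <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pat <- data.frame(
    patient_id = vapply(records, `[[`, "", "patient_id"),
    gender = vapply(records, `[[`, "", "gender"),
    year_of_birth = vapply(records, `[[`, 0L, "year_of_birth"))
  clin <- do.call(rbind, lapply(records, function(r) {
    if (nrow(r$clinical) == 0L) return(NULL)
    data.frame(patient_id = r$patient_id,
               event_date = format(r$clinical$event_date, "%Y-%m-%d"),
               code = r$clinical$code)
  }))
  ther <- do.call(rbind, lapply(records, function(r) {
    if (nrow(r$therapy) == 0L) return(NULL)
    data.frame(patient_id = r$patient_id,
               event_date = format(r$therapy$event_date, "%Y-%m-%d"),
               drug_code = r$therapy$drug_code)
  }))
  if (is.null(clin)) {
    clin <- data.frame(patient_id = character(), event_date = character(),
                       code = character())
  }
  if (is.null(ther)) {
    ther <- data.frame(patient_id = character(), event_date = character(),
                       drug_code = character())
  }
  paths <- file.path(dir, c("patients.csv", "clinical.csv", "therapy.csv"))
  write_csv_plain(pat, paths[1])
  write_csv_plain(clin, paths[2])
  write_csv_plain(ther, paths[3])
  invisible(paths)
}

#' Index date: date of the first RA-related code
#'
#' The earliest clinical event whose code is in the RA code list, any
#' severity group 1-4. Alternative-diagnosis or alternative-indication codes
#' never define the index.
#'
#' @param record A `patient_record`.
#' @param ra An `ra_codelist`.
#' @return A `Date`, or `NA` (Date) if the record has no RA code.
#' @export
index_date <- function(record, ra) {
  stopifnot(inherits(record, "patient_record"))
  hits <- record$clinical$event_date[!is.na(ra_group(record$clinical$code, ra))]
  if (length(hits) == 0L) return(as.Date(NA))
  min(hits)
}

#' Select the incident cohort by first-RA-code window
#'
#' Keeps exactly the records whose index date (first RA code anywhere in the
#' record) falls inside `window`, inclusive at both ends. A patient whose
#' first RA code predates the window is excluded even if later RA codes fall
#' inside it: the cohort is incident, not prevalent.
#'
#' @param records Named list of `patient_record`.
#' @param window Length-2 Date vector `c(start, end)`, `start <= end`.
#'   Defaults to the 1 Jan 2010 - 31 Dec 2012 study window.
#' @param ra An `ra_codelist`.
#' @param dictionaries Optional list with elements `ra`, `dmards`,
#'   `conditions`, carried on the cohort for downstream classification.
#' @return An object of class `ehr_cohort`: list with `records` (the selected
#'   subset), `index_dates` (named Date vector), `window`, `dictionaries`.
#' @export
select_incident_cohort <- function(records,
                                   window = as.Date(c("2010-01-01",
                                                      "2012-12-31")),
                                   ra, dictionaries = NULL) {
  window <- as.Date(window)
  stopifnot(length(window) == 2L, !anyNA(window), window[1] <= window[2])
  idx <- as.Date(vapply(records, function(r) as.numeric(index_date(r, ra)),
                        0), origin = "1970-01-01")
  keep <- !is.na(idx) & idx >= window[1] & idx <= window[2]
  out <- structure(list(records = records[keep],
                        index_dates = idx[keep],
                        window = window,
                        dictionaries = dictionaries),
                   class = "ehr_cohort")
  stopifnot(all(out$index_dates >= window[1] & out$index_dates <= window[2]))
  out
}

#' @export
print.ehr_cohort <- function(x, ...) {
  cat(sprintf("<ehr_cohort> %d patients, first-RA-code window %s..%s\n",
              length(x$records), format(x$window[1]), format(x$window[2])))
  invisible(x)
}

#' Follow-up from index date to last recorded event, in years
#'
#' (last event date in either stream - index date) / 365.25.
#'
#' @param record A `patient_record`.
#' @param ra An `ra_codelist`.
#' @return Non-negative numeric (years).
#' @export
follow_up_years <- function(record, ra) {
  idx <- index_date(record, ra)
  if (is.na(idx)) {
    stop("record ", record$patient_id, " has no RA code, hence no index date",
         call. = FALSE)
  }
  last <- max(c(record$clinical$event_date, record$therapy$event_date))
  as.numeric(last - idx) / 365.25
}

# Per-file date dialect detection: all-ISO or all-dd/mm/yyyy; a mixture is an
# error because silent reinterpretation of 05/03 vs 03/05 corrupts cohorts.
parse_event_dates <- function(x, file) {
  x <- trimws(x)
  iso <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  dmy <- grepl("^\\d{2}/\\d{2}/\\d{4}$", x)
  if (length(x) == 0L) return(as.Date(character()))
  if (all(iso)) {
    d <- as.Date(x, format = "%Y-%m-%d")
  } else if (all(dmy)) {
    d <- as.Date(x, format = "%d/%m/%Y")
  } else if (any(iso) && any(dmy)) {
    stop("mixed date dialects within ", file,
         " (ISO yyyy-mm-dd and dd/mm/yyyy); first dd/mm/yyyy at data row ",
         which(dmy)[1], call. = FALSE)
  } else {
    bad <- which(!(iso | dmy))[1]
    stop("unparseable date '", x[bad], "' in ", file, " at data row ", bad,
         call. = FALSE)
  }
  bad <- which(is.na(d))
  if (length(bad)) {
    stop("invalid calendar date '", x[bad[1]], "' in ", file,
         " at data row ", bad[1], call. = FALSE)
  }
  d
}
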