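# Code dictionaries: RA diagnosis codes with severity groups, DMARDs with
# alternative indications, and condition code sets (including the
# alternative-diagnosis set). Codes are opaque strings: the engine is
# terminology-agnostic (Read v2, CPRD medcode, SNOMED all usable). Matching is
# exact string equality after trimming whitespace, case-sensitive.

#' Load an RA diagnosis code list with severity groups
#'
#' Reads a CSV with columns `code,term,group` where `group` is the severity
#' grading of the diagnosis code: 1 = seropositive or erosive RA, 2 = plain
#' RA codes (e.g. RA of knee), 3 = systemic manifestations of RA,
#' 4 = seronegative RA or other weak evidence. Criterion 2c of the diagnostic
#' algorithm requires at least one group 1 or group 2 code; cohort entry
#' (the index date) accepts any group.
#'
#' @param path Path to a UTF-8 CSV file with header `code,term,group`.
#' @return An object of class `ra_codelist`: a data.frame with columns
#'   `code` (character), `term` (character), `group` (integer in 1..4).
#' @examples
#' f <- system.file("extdata", "ra_codes.csv", package = "phenora")
#' ra <- load_ra_codelist(f)
#' table(ra$group)
#' @export
load_ra_codelist <- function(path) {
  df <- read_dictionary_csv(path, c("code", "term", "group"))
  if (nrow(df) == 0L) {
    stop("empty code list: ", path, call. = FALSE)
  }
  df$code <- trimws(df$code)
  bad <- !nzchar(df$code)
  if (any(bad)) {
    stop("empty code value on row(s) ", paste(which(bad), collapse = ", "),
         " of ", path, call. = FALSE)
  }
  grp <- suppressWarnings(as.integer(trimws(df$group)))
  bad <- is.na(grp) | !(grp %in% 1:4) | as.numeric(trimws(df$group)) != grp
  if (any(bad)) {
    stop("severity group must be an integer in 1..4; offending code(s): ",
         paste(df$code[bad], collapse = ", "), call. = FALSE)
  }
  dup <- unique(df$code[duplicated(df$code)])
  if (length(dup)) {
    stop("duplicate code(s) in RA code list: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(code = df$code, term = df$term, group = grp,
                    stringsAsFactors = FALSE)
  class(out) <- c("ra_codelist", "data.frame")
  out
}

#' Look up the severity group of codes in an RA code list
#'
#' @param codes Character vector of clinical codes.
#' @param ra An `ra_codelist`.
#' @return Integer vector the length of `codes`; `NA` for codes that are not
#'   RA codes (never a default group).
#' @export
ra_group <- function(codes, ra) {
  stopifnot(inherits(ra, "ra_codelist"))
  ra$group[match(trimws(codes), ra$code)]
}

#' Load condition code sets (alternative indications and alternative diagnoses)
#'
#' Reads a CSV with columns `condition_id,code,term,is_alternative_diagnosis`.
#' Each condition (e.g. `psoriasis`, `psoriatic_arthritis`) maps to a set of
#' clinical codes. Conditions flagged `true` form the alternative-diagnosis
#' set used by Criterion 2b (psoriatic arthritis, ankylosing spondylitis and
#' other spondyloarthropathies in the reference lists; polymyalgia rheumatica
#' is deliberately not an alternative diagnosis, being itself a diagnosis of
#' exclusion). The same clinical code may legally appear under two different
#' conditions.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return An object of class `condition_codesets`: a data.frame with columns
#'   `condition_id`, `code`, `term`, `is_alternative_diagnosis` (logical).
#' @export
load_condition_codesets <- function(path) {
  df <- read_dictionary_csv(path,
    c("condition_id", "code", "term", "is_alternative_diagnosis"))
  df$condition_id <- trimws(df$condition_id)
  df$code <- trimws(df$code)
  bad <- !nzchar(df$condition_id)
  if (any(bad)) {
    stop("empty condition identifier on row(s) ",
         paste(which(bad), collapse = ", "), " of ", path, call. = FALSE)
  }
  flag_raw <- tolower(trimws(df$is_alternative_diagnosis))
  flag <- ifelse(flag_raw %in% c("true", "t", "1"), TRUE,
          ifelse(flag_raw %in% c("false", "f", "0"), FALSE, NA))
  if (anyNA(flag) && nrow(df) > 0L) {
    stop("malformed is_alternative_diagnosis flag (expect true/false) on ",
         "row(s) ", paste(which(is.na(flag)), collapse = ", "), " of ", path,
         call. = FALSE)
  }
  # a condition must be flagged consistently across its rows
  split_flags <- tapply(flag, df$condition_id, function(x) length(unique(x)))
  if (any(split_flags > 1L)) {
    stop("condition(s) flagged inconsistently: ",
         paste(names(split_flags)[split_flags > 1L], collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(condition_id = df$condition_id, code = df$code,
                    term = df$term,
                    is_alternative_diagnosis = as.logical(flag),
                    stringsAsFactors = FALSE)
  class(out) <- c("condition_codesets", "data.frame")
  out
}

#' Codes belonging to one condition
#' @param conditions A `condition_codesets`.
#' @param condition_id Condition identifier.
#' @return Character vector of codes (empty if the condition is absent).
#' @export
condition_codes <- function(conditions, condition_id) {
  stopifnot(inherits(conditions, "condition_codesets"))
  unique(conditions$code[conditions$condition_id %in% condition_id])
}

#' Codes of all alternative-diagnosis conditions
#' @param conditions A `condition_codesets`.
#' @return Character vector of codes flagged as alternative diagnoses.
#' @export
alternative_diagnosis_codes <- function(conditions) {
  stopifnot(inherits(conditions, "condition_codesets"))
  unique(conditions$code[conditions$is_alternative_diagnosis])
}

#' Load a DMARD dictionary with per-drug alternative indications
#'
#' Reads a CSV with columns `drug_code,name,class,alt_indications`, where
#' `class` is `conventional` or `biologic` and `alt_indications` is a
#' semicolon-separated list of condition identifiers (may be empty). Every
#' identifier must resolve in `conditions`: a prescription of a drug is
#' disqualified as evidence of RA when the record contains a code for any of
#' that drug's alternative indications, so a dangling reference would silently
#' weaken the exclusion and is an error.
#'
#' @param path Path to a UTF-8 CSV file.
#' @param conditions A `condition_codesets` against which alternative
#'   indications are resolved.
#' @return An object of class `dmard_dictionary`: a data.frame with columns
#'   `drug_code`, `name`, `class`, and list-column `alt_indications`.
#' @export
load_dmard_dictionary <- function(path, conditions) {
  stopifnot(inherits(conditions, "condition_codesets"))
  df <- read_dictionary_csv(path,
    c("drug_code", "name", "class", "alt_indications"))
  df$drug_code <- trimws(df$drug_code)
  bad <- !nzchar(df$drug_code)
  if (any(bad)) {
    stop("empty drug code on row(s) ", paste(which(bad), collapse = ", "),
         " of ", path, call. = FALSE)
  }
  dup <- unique(df$drug_code[duplicated(df$drug_code)])
  if (length(dup)) {
    stop("duplicate drug code(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  cls <- trimws(df$class)
  bad <- !(cls %in% c("conventional", "biologic"))
  if (any(bad)) {
    stop("unknown DMARD class token(s): ",
         paste(unique(cls[bad]), collapse = ", "),
         " (expected conventional or biologic)", call. = FALSE)
  }
  alts <- lapply(df$alt_indications, function(s) {
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    unique(parts[nzchar(parts)])
  })
  known <- unique(conditions$condition_id)
  for (i in seq_along(alts)) {
    missing <- setdiff(alts[[i]], known)
    if (length(missing)) {
      stop("drug ", df$drug_code[i], " (", df$name[i],
           ") references undefined condition(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  out <- data.frame(drug_code = df$drug_code, name = df$name, class = cls,
                    stringsAsFactors = FALSE)
  out$alt_indications <- alts
  class(out) <- c("dmard_dictionary", "data.frame")
  out
}

#' Cross-validate the three dictionary families
#'
#' Pure report, never an error. Flags (a) codes shared between the RA list and
#' any condition set — a warning, because a code cannot act as both an RA code
#' and an exclusion trigger, and during classification the RA interpretation
#' wins; (b) conditions never referenced by any DMARD and not flagged as
#' alternative diagnoses; (c) summary counts per severity group and drug class.
#'
#' @param ra An `ra_codelist`.
#' @param dmards A `dmard_dictionary`.
#' @param conditions A `condition_codesets`.
#' @return A list of class `dictionary_validation` with elements
#'   `overlaps` (data.frame code/condition_id), `unreferenced_conditions`
#'   (character), `group_counts` (named integer, groups "1".."4"),
#'   `class_counts` (named integer), `n_warnings`.
#' @export
validate_dictionaries <- function(ra, dmards, conditions) {
  stopifnot(inherits(ra, "ra_codelist"),
            inherits(dmards, "dmard_dictionary"),
            inherits(conditions, "condition_codesets"))
  shared <- conditions[conditions$code %in% ra$code,
                       c("code", "condition_id")]
  rownames(shared) <- NULL
  referenced <- unique(unlist(dmards$alt_indications))
  unref <- setdiff(unique(conditions$condition_id[
    !conditions$is_alternative_diagnosis]), referenced)
  group_counts <- vapply(as.character(1:4),
                         function(g) sum(ra$group == as.integer(g)), 0L)
  class_counts <- c(conventional = sum(dmards$class == "conventional"),
                    biologic = sum(dmards$class == "biologic"))
  out <- list(overlaps = shared,
              unreferenced_conditions = unref,
              group_counts = group_counts,
              class_counts = class_counts,
              n_warnings = nrow(shared) + length(unref))
  class(out) <- "dictionary_validation"
  out
}

#' @export
print.dictionary_validation <- function(x, ...) {
  cat("Dictionary validation report\n")
  cat(sprintf("  RA codes by severity group: %s\n",
              paste(sprintf("%s:%d", names(x$group_counts), x$group_counts),
                    collapse = " ")))
  cat(sprintf("  DMARDs: %d conventional, %d biologic\n",
              x$class_counts[["conventional"]], x$class_counts[["biologic"]]))
  if (nrow(x$overlaps)) {
    cat("  WARNING: codes present in both the RA list and a condition set\n")
    for (i in seq_len(nrow(x$overlaps))) {
      cat(sprintf("    %s (condition %s) - RA interpretation wins\n",
                  x$overlaps$code[i], x$overlaps$condition_id[i]))
    }
  }
  if (length(x$unreferenced_conditions)) {
    cat("  WARNING: conditions never referenced as an alternative indication:",
        paste(x$unreferenced_conditions, collapse = ", "), "\n")
  }
  if (x$n_warnings == 0L) cat("  no warnings\n")
  invisible(x)
}

#' Write dictionaries back to their CSV schemas
#'
#' Inverse of the loaders; a written file re-loads to an identical mapping.
#' @param x Dictionary object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ra_codelist <- function(x, path) {
  stopifnot(inherits(x, "ra_codelist"))
  write_csv_plain(data.frame(code = x$code, term = x$term, group = x$group),
                  path)
}

#' @rdname write_ra_codelist
#' @export
write_condition_codesets <- function(x, path) {
  stopifnot(inherits(x, "condition_codesets"))
  write_csv_plain(data.frame(
    condition_id = x$condition_id, code = x$code, term = x$term,
    is_alternative_diagnosis = ifelse(x$is_alternative_diagnosis,
                                      "true", "false")), path)
}

#' @rdname write_ra_codelist
#' @export
write_dmard_dictionary <- function(x, path) {
  stopifnot(inherits(x, "dmard_dictionary"))
  write_csv_plain(data.frame(
    drug_code = x$drug_code, name = x$name, class = x$class,
    alt_indications = vapply(x$alt_indications, paste, "", collapse = ";")),
    path)
}

# -- internal helpers ---------------------------------------------------------

read_dictionary_csv <- function(path, expected_cols) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8",
                        check.names = FALSE)
  if (!identical(names(df), expected_cols)) {
    stop("malformed header in ", path, ": expected ",
         paste(expected_cols, collapse = ","), " but found ",
         paste(names(df), collapse = ","), call. = FALSE)
  }
  df
}

write_csv_plain <- function(df, path) {
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}
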