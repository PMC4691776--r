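# Independent brute-force evaluator of the diagnostic definition. Written as
# plain nested loops straight from the criterion definitions, sharing no code
# with the package implementation, so agreement between the two is evidence
# that the implementation encodes the definitions correctly.

oracle_classify <- function(record, dict, followup_months = NULL,
                            scope = "whole-record") {
  ra <- dict$ra
  clin <- record$clinical
  ther <- record$therapy

  is_ra_code <- function(code) {
    for (j in seq_along(ra$code)) if (code == ra$code[j]) return(TRUE)
    FALSE
  }
  group_of <- function(code) {
    for (j in seq_along(ra$code)) if (code == ra$code[j]) return(ra$group[j])
    NA_integer_
  }

  # follow-up cap relative to the earliest RA-coded event
  ra_dates_all <- clin$event_date[vapply(clin$code, is_ra_code, TRUE)]
  if (length(ra_dates_all) == 0L) stop("oracle: no RA code")
  idx <- min(ra_dates_all)
  if (!is.null(followup_months)) {
    cap <- seq(idx, by = paste(followup_months, "months"), length.out = 2L)[2]
    clin <- clin[clin$event_date <= cap, , drop = FALSE]
    ther <- ther[ther$event_date <= cap, , drop = FALSE]
  }

  # codes belonging to a condition, with the RA interpretation winning on
  # overlap (an RA code never acts as an exclusion trigger)
  codes_of_condition <- function(cond_id) {
    out <- character()
    for (j in seq_len(nrow(dict$conditions))) {
      if (dict$conditions$condition_id[j] == cond_id &&
          !is_ra_code(dict$conditions$code[j])) {
        out <- c(out, dict$conditions$code[j])
      }
    }
    out
  }

  # criterion 1: some DMARD prescription with no alternative-indication code
  # for that drug anywhere in scope
  c1 <- FALSE
  for (i in seq_len(nrow(ther))) {
    di <- which(dict$dmards$drug_code == ther$drug_code[i])
    if (length(di) == 0L) next
    disqualified <- FALSE
    for (cond in dict$dmards$alt_indications[[di]]) {
      for (code in codes_of_condition(cond)) {
        for (k in seq_len(nrow(clin))) {
          same <- clin$code[k] == code
          in_scope <- scope == "whole-record" ||
            clin$event_date[k] <= ther$event_date[i]
          if (same && in_scope) disqualified <- TRUE
        }
      }
    }
    if (!disqualified) c1 <- TRUE
  }

  ra_rows <- vapply(clin$code, is_ra_code, TRUE)
  ra_dates <- unique(clin$event_date[ra_rows])
  c2a <- length(ra_dates) >= 2L

  c2c <- FALSE
  for (k in which(ra_rows)) {
    if (group_of(clin$code[k]) %in% c(1L, 2L)) c2c <- TRUE
  }

  alt_dx <- character()
  for (j in seq_len(nrow(dict$conditions))) {
    if (dict$conditions$is_alternative_diagnosis[j] &&
        !is_ra_code(dict$conditions$code[j])) {
      alt_dx <- c(alt_dx, dict$conditions$code[j])
    }
  }
  c2b <- TRUE
  if (length(ra_dates)) {
    last_ra <- max(ra_dates)
    for (k in seq_len(nrow(clin))) {
      if (clin$code[k] %in% alt_dx && clin$event_date[k] > last_ra) {
        c2b <- FALSE
      }
    }
  }

  c2 <- c2a && c2b && c2c
  c(c1 = c1, c2a = c2a, c2b = c2b, c2c = c2c, c2 = c2,
    definite = c1 || c2)
}

# Random small record with at least one RA code; the code pool mixes RA,
# condition, and unknown codes, and a short date range forces same-day and
# ordering edge cases.
random_record <- function(i, dict) {
  code_pool <- c(dict$ra$code, unique(dict$conditions$code), "JUNK1")
  drug_pool <- c(dict$dmards$drug_code, "UNKNOWN_DRUG")
  dates <- as.Date("2010-01-01") + 0:45
  n_extra <- sample(0:5, 1)
  n_ther <- sample(0:min(2, n_extra), 1)
  n_clin <- n_extra - n_ther
  clin <- list(c(format(sample(dates, 1)), sample(dict$ra$code, 1)))
  for (k in seq_len(n_clin)) {
    clin[[length(clin) + 1L]] <- c(format(sample(dates, 1)),
                                   sample(code_pool, 1))
  }
  ther <- lapply(seq_len(n_ther), function(k)
    c(format(sample(dates, 1)), sample(drug_pool, 1)))
  rec(sprintf("R%05d", i), clin, ther)
}
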