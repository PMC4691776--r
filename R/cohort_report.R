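# Stratified fulfilment reporting: counts and percentages of algorithm
# fulfilment overall and by gender, age band at index, and index year, with a
# Pearson chi-square test of homogeneity across strata. The test choice is an
# assumption (the source analyses report p-values without naming a test) and
# is recorded in the table metadata.

AGE_BAND_LABELS <- c("<50", "50-59", "60-69", "70+")

#' Age band at index date
#'
#' Age is computed as index year minus year of birth (primary-care extracts
#' supply year of birth only, so day-level age is not derivable). Bands:
#' `<50`, `50-59`, `60-69`, `70+`; boundaries 50, 60, 70 belong to the
#' higher band.
#'
#' @param year_of_birth Integer vector of birth years.
#' @param idx Date (or integer year) vector of index dates, recycled
#'   against `year_of_birth`.
#' @return Factor with levels `<50`, `50-59`, `60-69`, `70+`.
#' @export
age_band <- function(year_of_birth, idx) {
  year <- if (inherits(idx, "Date")) as.integer(format(idx, "%Y"))
          else as.integer(idx)
  age <- year - as.integer(year_of_birth)
  if (any(age < 0, na.rm = TRUE)) {
    stop("negative age: index date precedes year of birth", call. = FALSE)
  }
  cut(age, breaks = c(-1, 49, 59, 69, Inf), labels = AGE_BAND_LABELS)
}

#' Format a percentage to one decimal place, rounding half up
#'
#' Exact integer arithmetic: `100 * numerator / denominator` rounded half-up
#' at the first decimal (so 98.750...% renders as `"98.8"`, not the
#' round-half-even `"98.7"`), rendered with exactly one decimal digit.
#'
#' @param numerator Integer count(s), `0 <= numerator <= denominator`.
#' @param denominator Positive integer total(s).
#' @return Character vector, e.g. `"86.0"`.
#' @examples
#' format_percentage(3577, 4161)  # "86.0"
#' format_percentage(2614, 4161)  # "62.8"
#' @export
format_percentage <- function(numerator, denominator) {
  stopifnot(all(denominator > 0), all(numerator >= 0),
            all(numerator <= denominator))
  # 1000*x/n gives tenths of a percent; exact in doubles for counts < ~9e12
  num <- 1000 * as.numeric(numerator)
  den <- as.numeric(denominator)
  tenths <- num %/% den
  rem <- num %% den
  tenths <- tenths + as.numeric(2 * rem >= den)
  sprintf("%d.%d", as.integer(tenths %/% 10), as.integer(tenths %% 10))
}

#' Pearson chi-square test of homogeneity across strata
#'
#' Tests whether the fulfilment proportion is the same in every stratum,
#' via Pearson's chi-square on the strata-by-(fulfilled, not fulfilled)
#' contingency table, without continuity correction. Degrees of freedom are
#' `strata - 1` for the binary outcome.
#'
#' @param fulfilled Integer vector of fulfilled counts per stratum.
#' @param total Integer vector of stratum totals.
#' @return List: `statistic`, `df`, `p`, `method`.
#' @export
homogeneity_test <- function(fulfilled, total) {
  stopifnot(length(fulfilled) == length(total), length(total) >= 2L,
            all(fulfilled >= 0), all(fulfilled <= total))
  tab <- cbind(fulfilled = fulfilled, not_fulfilled = total - fulfilled)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate margins: a stratum or outcome has zero total",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value),
       method = "Pearson chi-square, no continuity correction (assumed test)")
}

#' Stratified fulfilment table
#'
#' Counts and percentage of patients fulfilling a given algorithm flag,
#' overall or stratified by gender, age band at index, or index year.
#' Unknown-gender patients appear in the overall row and in age/year strata
#' but are omitted from gender strata. Strata with zero members are kept with
#' `n = 0` and the percentage omitted. With two or more populated strata the
#' table carries a homogeneity test.
#'
#' @param classifications data.frame as produced by [classify_cohort()]
#'   (`patient_id`, flag columns, `index_date`).
#' @param demographics data.frame with `patient_id`, `gender` (M/F/U),
#'   `year_of_birth`; every classified patient must appear.
#' @param stratifier One of `"none"`, `"gender"`, `"age_band"`,
#'   `"index_year"`.
#' @param flag One of `"definite"`, `"c1"`, `"c2"`, `"c2a"`, `"c2b"`,
#'   `"c2c"`.
#' @return Object of class `fulfilment_table`: list with `stratifier`,
#'   `flag`, `rows` (data.frame stratum/fulfilled/total/pct), `overall`
#'   (one-row data.frame), `test` (list or NULL).
#' @export
fulfilment_summary <- function(classifications, demographics,
                               stratifier = c("none", "gender", "age_band",
                                              "index_year"),
                               flag = c("definite", "c1", "c2", "c2a", "c2b",
                                        "c2c")) {
  stratifier <- match.arg(stratifier)
  flag <- match.arg(flag)
  m <- match(classifications$patient_id, demographics$patient_id)
  if (anyNA(m)) {
    stop("missing demographics for patient(s): ",
         paste(classifications$patient_id[is.na(m)][1:min(5, sum(is.na(m)))],
               collapse = ", "), call. = FALSE)
  }
  demo <- demographics[m, , drop = FALSE]
  y <- classifications[[flag]]
  overall <- data.frame(stratum = "all", fulfilled = sum(y),
                        total = length(y),
                        pct = if (length(y)) format_percentage(sum(y),
                                                               length(y))
                              else NA_character_,
                        stringsAsFactors = FALSE)
  if (stratifier == "none") {
    out <- list(stratifier = stratifier, flag = flag, rows = overall[0, ],
                overall = overall, test = NULL)
    class(out) <- "fulfilment_table"
    return(out)
  }
  keep <- rep(TRUE, length(y))
  strata <- switch(stratifier,
    gender = {
      keep <- demo$gender %in% c("M", "F")
      factor(demo$gender, levels = c("M", "F"))
    },
    age_band = age_band(demo$year_of_birth, classifications$index_date),
    index_year = {
      yr <- format(classifications$index_date, "%Y")
      factor(yr, levels = sort(unique(yr)))
    })
  yk <- y[keep]
  sk <- strata[keep]
  fulfilled <- as.integer(tapply(yk, sk, sum, default = 0L))
  total <- as.integer(table(sk))
  rows <- data.frame(stratum = levels(sk), fulfilled = fulfilled,
                     total = total,
                     pct = ifelse(total > 0,
                                  format_percentage(fulfilled, pmax(total, 1L)),
                                  NA_character_),
                     stringsAsFactors = FALSE)
  populated <- rows$total > 0
  test <- if (sum(populated) >= 2L && sum(rows$fulfilled) > 0 &&
              sum(rows$total - rows$fulfilled) > 0) {
    homogeneity_test(rows$fulfilled[populated], rows$total[populated])
  } else NULL
  out <- list(stratifier = stratifier, flag = flag, rows = rows,
              overall = overall, test = test)
  class(out) <- "fulfilment_table"
  out
}

#' @export
print.fulfilment_table <- function(x, ...) {
  cat(render_fulfilment_table(x), sep = "\n")
  invisible(x)
}

#' Render a fulfilment table as aligned text
#'
#' Human-readable layout with explicit denominators: `n/N (pct)` per row,
#' the overall row, and the homogeneity test line where available.
#'
#' @param x A `fulfilment_table`.
#' @return Character vector of lines.
#' @export
render_fulfilment_table <- function(x) {
  stopifnot(inherits(x, "fulfilment_table"))
  lines <- sprintf("Fulfilment of flag '%s' by %s", x$flag, x$stratifier)
  fmt_row <- function(r) {
    pct <- if (is.na(r$pct)) "-" else sprintf("(%s)", r$pct)
    sprintf("  %-12s %6d/%-6d %s", r$stratum, r$fulfilled, r$total, pct)
  }
  for (i in seq_len(nrow(x$rows))) lines <- c(lines, fmt_row(x$rows[i, ]))
  lines <- c(lines, fmt_row(x$overall))
  if (!is.null(x$test)) {
    lines <- c(lines, sprintf(
      "  homogeneity: chi-square = %.3f, df = %d, p = %.3f  [%s]",
      x$test$statistic, x$test$df, x$test$p, x$test$method))
  }
  lines
}

#' Long-format report rows for one or more fulfilment tables
#'
#' @param tables List of `fulfilment_table`.
#' @return data.frame with columns
#'   `stratifier,stratum,flag,n,total,pct`.
#' @export
report_long <- function(tables) {
  if (inherits(tables, "fulfilment_table")) tables <- list(tables)
  do.call(rbind, lapply(tables, function(t) {
    rows <- rbind(t$rows, t$overall)
    data.frame(stratifier = t$stratifier, stratum = rows$stratum,
               flag = t$flag, n = rows$fulfilled, total = rows$total,
               pct = rows$pct, stringsAsFactors = FALSE)
  }))
}

#' Write report files
#'
#' `report.csv` in long format plus `report.txt` with the rendered tables.
#'
#' @param tables List of `fulfilment_table`.
#' @param dir Output directory.
#' @return Invisibly, the two paths.
#' @export
write_report <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- report_long(tables)
  long$pct[is.na(long$pct)] <- ""
  csv <- file.path(dir, "report.csv")
  write_csv_plain(long, csv)
  txt <- file.path(dir, "report.txt")
  if (inherits(tables, "fulfilment_table")) tables <- list(tables)
  writeLines(unlist(lapply(tables, function(t)
    c(render_fulfilment_table(t), ""))), txt)
  invisible(c(csv, txt))
}
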