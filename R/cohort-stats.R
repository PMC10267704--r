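#' Summarize the clinical characteristics of a cohort
#'
#' Computes the descriptive summary of a Crohn's disease cohort coded with
#' the Montreal classification: counts and percentages per disease-location
#' code (a patient whose location contains L3 counts toward L3, so combined
#' codes such as "L3+L4" contribute to both L3 and the upper-GI modifier L4
#' and location percentages may sum above 100), per behavior code, sex,
#' pelvic disease, and abdominal surgery, plus the median and range of age.
#' Behavior codes are exclusive, so their percentages sum to 100 up to
#' rounding.
#'
#' @param records Clinical data frame as from [read_clinical_table()].
#' @return Object of class `cohort_summary`: list with `n`, `age`
#'   (median/min/max), `sex`, `location`, `behavior` (each a data frame of
#'   count and percentage), `pelvic_disease`, `abdominal_surgery`.
#' @export
summarize_cohort <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("need at least one clinical record", call. = FALSE)
  }
  n <- nrow(records)
  pct <- function(k) round(100 * k / n, 2)
  loc <- strsplit(records$location, "+", fixed = TRUE)
  loc_counts <- vapply(c("L1", "L2", "L3", "L4"), function(code) {
    sum(vapply(loc, function(l) code %in% l, logical(1L)))
  }, numeric(1L))
  beh_counts <- vapply(c("B1", "B2", "B3"),
                       function(code) sum(records$behavior == code), numeric(1L))
  sex_counts <- c(male = sum(records$sex == "male"),
                  female = sum(records$sex == "female"))
  tab <- function(k) data.frame(n = as.numeric(k), pct = pct(k),
                                row.names = names(k))
  flag_tab <- function(col) {
    if (!col %in% names(records)) return(NULL)
    k <- sum(records[[col]], na.rm = TRUE)
    data.frame(n = k, pct = pct(k))
  }
  structure(list(
    n = n,
    age = list(median = stats::median(records$age),
               min = min(records$age), max = max(records$age)),
    sex = tab(sex_counts),
    location = tab(loc_counts),
    behavior = tab(beh_counts),
    pelvic_disease = flag_tab("pelvic_disease"),
    abdominal_surgery = flag_tab("abdominal_surgery")
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  age: median %g years (range %g-%g)\n",
              x$age$median, x$age$min, x$age$max))
  line <- function(label, d) {
    cat("  ", label, ": ",
        paste(sprintf("%s %d (%.2f%%)", rownames(d), as.integer(d$n), d$pct),
              collapse = ", "), "\n", sep = "")
  }
  line("sex", x$sex)
  line("location", x$location)
  line("behavior", x$behavior)
  if (!is.null(x$pelvic_disease)) {
    cat(sprintf("  pelvic disease: %d (%.2f%%)\n",
                as.integer(x$pelvic_disease$n), x$pelvic_disease$pct))
  }
  if (!is.null(x$abdominal_surgery)) {
    cat(sprintf("  abdominal surgery: %d (%.2f%%)\n",
                as.integer(x$abdominal_surgery$n), x$abdominal_surgery$pct))
  }
  invisible(x)
}

#' Flatten a cohort summary for export
#' @param summary A `cohort_summary`.
#' @return Long data frame with columns `variable`, `level`, `n`, `pct`.
#' @export
cohort_summary_table <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"))
  rows <- list(
    data.frame(variable = "age", level = c("median", "min", "max"),
               n = c(summary$age$median, summary$age$min, summary$age$max),
               pct = NA_real_)
  )
  add <- function(variable, d) {
    if (is.null(d)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable,
      level = if (is.null(rownames(d)) || all(rownames(d) == seq_len(nrow(d))))
        "yes" else rownames(d),
      n = d$n, pct = d$pct)
  }
  add("sex", summary$sex)
  add("location", summary$location)
  add("behavior", summary$behavior)
  add("pelvic_disease", summary$pelvic_disease)
  add("abdominal_surgery", summary$abdominal_surgery)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}

#' Write a cohort summary to disk
#' @param summary A `cohort_summary`.
#' @param tsv_path Output TSV path.
#' @param json_path Optional JSON output path.
#' @return Invisibly, `tsv_path`.
#' @export
write_cohort_summary <- function(summary, tsv_path, json_path = NULL) {
  d <- cohort_summary_table(summary)
  write_tsv(d, tsv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(d, json_path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(tsv_path)
}
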