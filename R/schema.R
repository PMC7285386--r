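# Factor universe, category codings and guideline risk labeling for the
# 16-factor categorical stroke-screening cohort.

#' Missing-value sentinel
#'
#' All sources of absent or uncertain information ("uncertain" in the clinical
#' fields, "null" in the habit fields, empty cells) are normalized to this one
#' token on ingest.
#'
#' @return The canonical missing token, `"?"`.
#' @export
missing_code <- function() "?"

#' Six-level stroke risk labels
#'
#' The fixed label order H, M, Y, T, N, L is used throughout for display,
#' confusion-matrix layout and majority-vote tie-breaking.
#'
#' @return Character vector of the six admissible risk-level codes.
#' @export
risk_levels <- function() c("H", "M", "Y", "T", "N", "L")

#' Default factor schema
#'
#' The 16 coded screening factors: clinical diagnoses (hypertension `Hyte`,
#' dyslipidemia `Dysl`, diabetes `Diab`, atrial fibrillation `AF`), histories
#' (family stroke history `FSH`, own stroke history `SH`, transient ischemic
#' attack `TIA`), demographics (`Gen`, `Age` bands), body-mass-index class
#' `BMIc` (B1 underweight ... B5 severe obesity) and the six daily habits
#' (smoking `Smok`, alcohol `Alco`, tea `Tea`, diet `DT`, sleep duration class
#' `Sleep`, exercise level `Sport`).
#'
#' @return Named list of allowed level codes per factor, with attribute
#'   `missing` holding the missing token. The missing token is never listed
#'   among the levels.
#' @export
default_schema <- function() {
  yn <- c("y", "n")
  schema <- list(
    Hyte  = yn,
    Dysl  = yn,
    Diab  = yn,
    AF    = yn,
    FSH   = yn,
    SH    = yn,
    TIA   = yn,
    Gen   = c("M", "F"),
    Age   = c("[18,30)", "[30,40)", "[40,50)", "[50,60)",
              "[60,70)", "[70,80)", "[80,90)"),
    BMIc  = c("B1", "B2", "B3", "B4", "B5"),
    Smok  = yn,
    Alco  = yn,
    Tea   = yn,
    DT    = c("C1", "C2", "C3"),
    Sleep = c("TS", "TB", "TL"),
    Sport = c("C1", "C2", "C3")
  )
  stopifnot(!vapply(schema, anyDuplicated, 0L) > 0)
  attr(schema, "missing") <- missing_code()
  schema
}

#' Factor codes of a schema
#' @param schema A factor schema, as from [default_schema()].
#' @return Character vector of factor codes in schema order.
#' @export
factor_codes <- function(schema = default_schema()) names(schema)

schema_missing <- function(schema) {
  m <- attr(schema, "missing")
  if (is.null(m)) missing_code() else m
}

#' Validate a cohort table against a schema
#'
#' A cohort table is a data.frame with one character column per factor code
#' (any column order) and an optional `risk` column. Cells must be either a
#' level listed in the schema or the missing token.
#'
#' @param table data.frame to validate.
#' @param schema Factor schema.
#' @param require_risk If TRUE, a fully populated `risk` column is required.
#' @return The table, invisibly, with columns reordered to schema order
#'   (risk last when present).
#' @export
validate_cohort <- function(table, schema = default_schema(),
                            require_risk = FALSE) {
  codes <- factor_codes(schema)
  miss <- schema_missing(schema)
  absent <- setdiff(codes, names(table))
  if (length(absent) > 0)
    stop("cohort is missing factor column(s): ", paste(absent, collapse = ", "))
  extra <- setdiff(names(table), c(codes, "risk", ".synthetic"))
  if (length(extra) > 0)
    stop("unknown column(s) in cohort: ", paste(extra, collapse = ", "))
  for (f in codes) {
    v <- as.character(table[[f]])
    bad <- which(!(v %in% c(schema[[f]], miss)))
    if (length(bad) > 0)
      stop(sprintf("invalid value '%s' for factor %s at row %d",
                   v[bad[1]], f, bad[1]))
  }
  if (require_risk) {
    if (is.null(table$risk))
      stop("cohort has no 'risk' column")
    bad <- which(!(as.character(table$risk) %in% risk_levels()))
    if (length(bad) > 0)
      stop(sprintf("invalid or missing risk label at row %d", bad[1]))
  } else if (!is.null(table$risk)) {
    bad <- which(!(as.character(table$risk) %in% c(risk_levels(), miss)))
    if (length(bad) > 0)
      stop(sprintf("invalid risk label at row %d", bad[1]))
  }
  keep <- c(codes, intersect(c("risk", ".synthetic"), names(table)))
  invisible(table[, keep, drop = FALSE])
}

#' Read a cohort CSV
#'
#' Reads a comma-separated cohort with one column per factor code (order
#' insensitive) plus an optional `risk` column. Cells reading `uncertain`,
#' `null`, `NA` or empty are normalized to the schema missing token.
#'
#' @param path Path to the CSV file.
#' @param schema Factor schema the file must conform to.
#' @return Validated cohort data.frame in schema column order.
#' @export
read_cohort_csv <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = character(0), check.names = FALSE)
  miss <- schema_missing(schema)
  for (j in seq_along(df)) {
    v <- df[[j]]
    v[is.na(v) | v %in% c("", "uncertain", "null", "NA")] <- miss
    df[[j]] <- v
  }
  out <- validate_cohort(df, schema)
  out
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort_csv()]: writing then reading reproduces the table
#' exactly (values and record order). Missing cells carry the literal missing
#' token.
#'
#' @param table Validated cohort data.frame.
#' @param path Output path.
#' @param schema Factor schema.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(table, path, schema = default_schema()) {
  table <- validate_cohort(table, schema)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

# Age-banded sleep-duration table: for each band, hours below `lo` are
# short (TS), [lo, hi) is normal (TB), >= hi is long (TL). Bands are keyed
# by the age (years) at which they start; ages falling between printed
# bands inherit the nearest younger band.
sleep_bands <- function() {
  data.frame(
    age_from = c(0, 1, 6, 14, 18, 64 + 1e-9),
    lo = c(14, 11, 9, 8, 6, 7),
    hi = c(17, 14, 11, 10, 10, 8)
  )
}

#' Categorize sleep duration by age
#'
#' Age-banded coding of nightly sleep hours into short (`TS`), normal (`TB`)
#' and long (`TL`). Adult bands: 18-64 years, normal is 6 to 10 hours;
#' above 64 years, 7 to 8 hours. Hour intervals are closed below and open
#' above.
#'
#' @param age_years Nonnegative age in years (vectorized).
#' @param sleep_hours Nonnegative nightly sleep duration in hours (vectorized).
#' @return Character vector in `{"TS","TB","TL"}`.
#' @export
categorize_sleep <- function(age_years, sleep_hours) {
  stopifnot(all(age_years >= 0), all(sleep_hours >= 0))
  n <- max(length(age_years), length(sleep_hours))
  age_years <- rep_len(age_years, n)
  sleep_hours <- rep_len(sleep_hours, n)
  bands <- sleep_bands()
  band <- findInterval(age_years, bands$age_from)
  lo <- bands$lo[band]
  hi <- bands$hi[band]
  ifelse(sleep_hours < lo, "TS", ifelse(sleep_hours < hi, "TB", "TL"))
}

#' Categorize body-mass index
#'
#' Five-class BMI coding on half-open intervals `[lo, hi)`: `B1` below the
#' first cutpoint up to `B5` at or above the last. Defaults follow the
#' Chinese reference bands (underweight < 18.5, normal, overweight at 24,
#' obesity at 28, severe obesity at 32 kg/m^2).
#'
#' @param bmi Positive BMI value(s) in kg/m^2.
#' @param cutpoints Four strictly ascending thresholds.
#' @return Character vector in `{"B1",...,"B5"}`.
#' @export
categorize_bmi <- function(bmi, cutpoints = c(18.5, 24, 28, 32)) {
  stopifnot(all(bmi > 0))
  if (length(cutpoints) != 4 || any(diff(cutpoints) <= 0))
    stop("cutpoints must be 4 strictly ascending thresholds")
  paste0("B", findInterval(bmi, cutpoints) + 1L)
}

#' Default guideline factor partition
#'
#' Major factors are the clinical diagnoses (hypertension, dyslipidemia,
#' diabetes, atrial fibrillation affirmed); secondary factors are smoking,
#' family stroke history, obesity (BMI class B4 or B5) and low exercise
#' (Sport C3). Stroke history and TIA are deliberately excluded: they are
#' handled by label precedence, not by counting.
#'
#' @return List with elements `major` and `secondary`, each a named list
#'   mapping a factor code to its triggering value set.
#' @export
default_guideline <- function() {
  g <- list(
    major = list(Hyte = "y", Dysl = "y", Diab = "y", AF = "y"),
    secondary = list(Smok = "y", FSH = "y", BMIc = c("B4", "B5"), Sport = "C3")
  )
  validate_guideline(g)
}

#' @rdname default_guideline
#' @param guideline A guideline configuration to validate.
#' @export
validate_guideline <- function(guideline) {
  stopifnot(is.list(guideline$major), is.list(guideline$secondary))
  if (length(intersect(names(guideline$major), names(guideline$secondary))) > 0)
    stop("major and secondary factor sets must be disjoint")
  if (any(c("SH", "TIA") %in% c(names(guideline$major),
                                names(guideline$secondary))))
    stop("SH and TIA are handled by label precedence, not by counting")
  guideline
}

count_satisfied <- function(table, predicates) {
  n <- nrow(table)
  hits <- integer(n)
  for (f in names(predicates)) {
    hits <- hits + as.integer(as.character(table[[f]]) %in% predicates[[f]])
  }
  hits
}

#' Guideline risk labeling
#'
#' Assigns each record one of the six risk levels. Precedence: a stroke
#' history (`SH = y`) gives `Y`; otherwise a prior TIA (`TIA = y`) gives `T`;
#' otherwise the counts of satisfied major (m) and secondary (s) predicates
#' decide: `H` when m >= 2 or (m = 1 and s >= 2); `M` when m = 1 and s < 2;
#' `L` when m = 0 and s >= 2; `N` otherwise. Missing values never satisfy a
#' predicate.
#'
#' @param table Cohort data.frame (one or more records).
#' @param guideline Guideline configuration, as [default_guideline()].
#' @return Character vector of risk levels, one per record.
#' @export
label_risk <- function(table, guideline = default_guideline()) {
  guideline <- validate_guideline(guideline)
  m <- count_satisfied(table, guideline$major)
  s <- count_satisfied(table, guideline$secondary)
  lab <- ifelse(m >= 2 | (m == 1 & s >= 2), "H",
         ifelse(m == 1, "M",
         ifelse(s >= 2, "L", "N")))
  lab[as.character(table$TIA) == "y"] <- "T"
  lab[as.character(table$SH) == "y"] <- "Y"
  lab
}
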