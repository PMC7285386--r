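# Synthetic cohort generation: marginal structure of the 5,599-person
# screening cohort plus optional planted factor -> risk dependencies.

# Printed per-level record counts of the reference cohort. The diet row
# sums to 5626 in the source table (a misprint against the cohort size of
# 5599); marginals are therefore normalized by each factor's own row total.
reference_marginal_counts <- function() {
  list(
    Hyte  = c(y = 1242, n = 3782, "?" = 575),
    Dysl  = c(y = 511,  n = 4508, "?" = 580),
    Diab  = c(y = 403,  n = 4618, "?" = 578),
    AF    = c(y = 75,   n = 4940, "?" = 584),
    FSH   = c(y = 449,  n = 4460, "?" = 690),
    SH    = c(y = 165,  n = 4730, "?" = 704),
    TIA   = c(y = 95,   n = 4350, "?" = 1154),
    Gen   = c(M = 2491, F = 3108),
    BMIc  = c(B1 = 205, B2 = 2926, B3 = 1760, B4 = 520, B5 = 150, "?" = 38),
    Smok  = c(y = 1192, n = 4379, "?" = 28),
    Alco  = c(y = 1065, n = 4500, "?" = 34),
    Tea   = c(y = 1563, n = 3997, "?" = 39),
    DT    = c(C1 = 2812, C2 = 263, C3 = 2181, "?" = 370),
    Sleep = c(TS = 366, TB = 4958, TL = 205, "?" = 70),
    Sport = c(C1 = 1518, C2 = 1624, C3 = 2275, "?" = 182)
  )
}

#' Default factor marginals
#'
#' Per-factor category probabilities matching the reference screening
#' cohort's printed per-level counts (missing token included). Age-band
#' counts are not printed numerically in the source, so the seven adult age
#' bands default to uniform weights.
#'
#' @param age_weights Optional nonnegative weights over the seven age bands
#'   (recycled/normalized); default uniform.
#' @return Named list: factor code -> named probability vector summing to 1.
#' @export
default_marginals <- function(age_weights = NULL) {
  counts <- reference_marginal_counts()
  marg <- lapply(counts, function(x) x / sum(x))
  age_levels <- default_schema()$Age
  if (is.null(age_weights)) age_weights <- rep(1, length(age_levels))
  stopifnot(length(age_weights) == length(age_levels), all(age_weights >= 0))
  marg$Age <- stats::setNames(age_weights / sum(age_weights), age_levels)
  marg[factor_codes(default_schema())]
}

validate_marginals <- function(marginals, schema = default_schema()) {
  miss <- schema_missing(schema)
  for (f in factor_codes(schema)) {
    p <- marginals[[f]]
    if (is.null(p)) stop("marginals missing factor ", f)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("marginal probabilities for ", f,
           " must be nonnegative and sum to 1")
    bad <- setdiff(names(p), c(schema[[f]], miss))
    if (length(bad) > 0)
      stop("marginal for ", f, " names unknown level(s): ",
           paste(bad, collapse = ", "))
  }
  marginals
}

#' Planted factor-to-risk rule
#'
#' A rule `conditions -> target` that fires on each matching simulated record
#' with probability `strength`, overriding its risk label. Planting known
#' dependencies lets downstream structure-recovery tests control exactly what
#' signal a cohort carries.
#'
#' @param conditions Named list/vector: factor code -> required value.
#' @param target Risk level assigned when the rule fires.
#' @param strength Firing probability in `[0, 1]`.
#' @return A `planted_rule` object.
#' @export
planted_rule <- function(conditions, target, strength = 1) {
  conditions <- as.list(conditions)
  if (length(conditions) == 0) stop("conditions must be non-empty")
  if (!(target %in% risk_levels())) stop("unknown risk level: ", target)
  if (strength < 0 || strength > 1) stop("strength must be in [0, 1]")
  structure(list(conditions = conditions, target = target,
                 strength = strength), class = "planted_rule")
}

#' Simulation configuration
#'
#' @param n Number of records (>= 0).
#' @param seed Integer RNG seed; fixed seed gives bit-identical cohorts.
#' @param marginals Per-factor level probabilities, see [default_marginals()].
#' @param planted List of [planted_rule()] objects, applied in list order
#'   (later rules override earlier ones on overlapping records).
#' @param label_mode `"guideline"` labels via [label_risk()]; `"planted"`
#'   starts every record at the baseline level `N` and applies the planted
#'   rules; `"mixture"` labels via the guideline first, then applies planted
#'   overrides.
#' @param guideline Guideline configuration for the guideline/mixture modes.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n, seed = 1L, marginals = default_marginals(),
                       planted = list(),
                       label_mode = c("guideline", "planted", "mixture"),
                       guideline = default_guideline()) {
  label_mode <- match.arg(label_mode)
  stopifnot(n >= 0)
  if (label_mode == "planted" && length(planted) == 0)
    stop("label_mode 'planted' requires at least one planted rule")
  structure(list(n = as.integer(n), seed = as.integer(seed),
                 marginals = validate_marginals(marginals),
                 planted = planted, label_mode = label_mode,
                 guideline = guideline),
            class = "sim_config")
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a labeled cohort
#'
#' Draws each factor independently from its marginal distribution, then labels
#' records according to the configured mode. Factor independence is
#' deliberate: any dependence structure a test relies on must be planted
#' explicitly through the configuration's rules.
#'
#' @param config A [sim_config()].
#' @return Labeled cohort data.frame with `n` records.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  schema <- default_schema()
  codes <- factor_codes(schema)
  with_seed(config$seed, {
    cols <- lapply(codes, function(f) {
      p <- config$marginals[[f]]
      if (config$n == 0) character(0)
      else sample(names(p), config$n, replace = TRUE, prob = p)
    })
    names(cols) <- codes
    df <- as.data.frame(cols, stringsAsFactors = FALSE)
    if (config$n == 0) df$risk <- character(0)
    else df$risk <- switch(config$label_mode,
      guideline = label_risk(df, config$guideline),
      planted = rep("N", config$n),
      mixture = label_risk(df, config$guideline))
    if (config$label_mode %in% c("planted", "mixture") && config$n > 0) {
      for (rule in config$planted) {
        match <- rep(TRUE, config$n)
        for (f in names(rule$conditions))
          match <- match & df[[f]] == rule$conditions[[f]]
        fire <- match & (stats::runif(config$n) < rule$strength)
        df$risk[fire] <- rule$target
      }
    }
    validate_cohort(df, schema, require_risk = TRUE)
    df
  })
}

#' Class counts of a labeled cohort
#'
#' @param table Labeled cohort data.frame.
#' @return Named integer vector over all six risk levels (zeros included),
#'   summing to the record count.
#' @export
class_counts <- function(table) {
  if (is.null(table$risk) ||
      (nrow(table) > 0 && any(!table$risk %in% risk_levels())))
    stop("class_counts requires a fully labeled cohort")
  tab <- table(factor(table$risk, levels = risk_levels()))
  stats::setNames(as.integer(tab), risk_levels())
}
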