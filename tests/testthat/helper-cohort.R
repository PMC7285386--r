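# In-code fixtures: tiny cohorts built from a benign base record.

base_record <- function() {
  list(Hyte = "n", Dysl = "n", Diab = "n", AF = "n", FSH = "n", SH = "n",
       TIA = "n", Gen = "F", Age = "[40,50)", BMIc = "B2", Smok = "n",
       Alco = "n", Tea = "n", DT = "C1", Sleep = "TB", Sport = "C1")
}

# n copies of the base record with column overrides (vectors recycled)
make_cohort <- function(n, ..., risk = NULL) {
  df <- as.data.frame(lapply(base_record(), rep_len, n),
                      stringsAsFactors = FALSE)
  over <- list(...)
  for (f in names(over)) df[[f]] <- rep_len(over[[f]], n)
  if (!is.null(risk)) df$risk <- rep_len(risk, n)
  df
}

# random labeled cohort over a few factors, for property-style tests
random_small_cohort <- function(n, n_classes = 3, seed = 1) {
  set.seed(seed)
  df <- make_cohort(n,
    Hyte = sample(c("y", "n", "?"), n, replace = TRUE),
    Smok = sample(c("y", "n"), n, replace = TRUE),
    Sport = sample(c("C1", "C2", "C3"), n, replace = TRUE),
    DT = sample(c("C1", "C2", "C3"), n, replace = TRUE),
    risk = sample(risk_levels()[seq_len(n_classes)], n, replace = TRUE))
  df
}

# does a record satisfy every condition of a rule?
rule_matches <- function(rule, record) {
  all(vapply(names(rule$conditions), function(f)
    identical(as.character(record[[f]]), rule$conditions[[f]]), TRUE))
}
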