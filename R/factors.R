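# Interpretive factor analytics: split-depth profiles, the factor-pair
# relationship matrix aggregated over extracted rules, above-group-mean
# partner tables, and per-habit risk-level profiles.

collect_depths <- function(node, acc) {
  if (node$kind == "leaf") return(acc)
  acc[[length(acc) + 1]] <- c(factor = node$factor, depth = node$depth)
  for (child in node$children) acc <- collect_depths(child, acc)
  acc
}

#' Frequency-weighted average split depth
#'
#' @param occurrences Named frequency vector; names are 0-based depths.
#' @return `sum(depth * freq) / sum(freq)`. Lower average depth means the
#'   factor is consulted closer to the root, i.e. is more influential.
#' @export
average_depth <- function(occurrences) {
  if (length(occurrences) == 0) stop("empty occurrence mapping")
  stopifnot(all(occurrences >= 1))
  d <- as.numeric(names(occurrences))
  sum(d * occurrences) / sum(occurrences)
}

#' Split-depth profiles of a tree
#'
#' For every factor that appears as a split, tabulates the 0-based depths of
#' its occurrences (the root split is depth 0) and their frequency-weighted
#' mean. Factors absent from the tree are omitted; the total occurrence
#' count equals the number of internal nodes.
#'
#' @param tree A `c45_tree`.
#' @return data.frame with columns `factor`, `frequency`, `average_depth`,
#'   sorted by ascending average depth, plus an `occurrences` attribute
#'   holding the per-factor depth tables.
#' @export
depth_profiles <- function(tree) {
  occ <- collect_depths(tree$root, list())
  if (length(occ) == 0) {
    out <- data.frame(factor = character(0), frequency = integer(0),
                      average_depth = numeric(0))
    attr(out, "occurrences") <- list()
    return(out)
  }
  fac <- vapply(occ, `[[`, "", "factor")
  dep <- as.integer(vapply(occ, `[[`, "", "depth"))
  split_tabs <- lapply(split(dep, fac), function(d) table(d))
  profiles <- lapply(split_tabs, function(tab)
    average_depth(stats::setNames(as.integer(tab), names(tab))))
  out <- data.frame(factor = names(profiles),
                    frequency = vapply(split_tabs, sum, 0),
                    average_depth = unlist(profiles), row.names = NULL)
  out <- out[order(out$average_depth, out$factor), ]
  rownames(out) <- NULL
  attr(out, "occurrences") <- lapply(split_tabs, function(tab)
    stats::setNames(as.integer(tab), names(tab)))
  out
}

#' Factor-pair relationship matrix from rules
#'
#' Every unordered pair of factors co-occurring in a rule's condition set
#' contributes that rule's pair weight, accumulated over all rules into a
#' symmetric nonnegative matrix. Weighting schemes: `"set-size"` (default)
#' gives each pair `1/|factor set|` so long rules spread unit mass;
#' `"depth-sum"` gives `1/(1+d_a) + 1/(1+d_b)` from the two conditions'
#' depths, favoring near-root factors; `"unit"` counts co-occurrences.
#'
#' @param rules List of `risk_rule` objects.
#' @param factors Factor order for the matrix; defaults to the schema
#'   factors that occur in at least one rule.
#' @param scheme Weighting scheme identifier.
#' @return Symmetric numeric matrix of class `relationship_matrix` with a
#'   `scheme` attribute and a zero diagonal.
#' @export
relationship_matrix <- function(rules,
                                factors = NULL,
                                scheme = c("set-size", "depth-sum", "unit")) {
  scheme <- match.arg(scheme)
  if (is.null(factors)) {
    used <- unique(unlist(lapply(rules, `[[`, "factor_set")))
    factors <- intersect(factor_codes(default_schema()), used)
    if (length(factors) == 0) factors <- character(0)
  }
  m <- matrix(0, length(factors), length(factors),
              dimnames = list(factors, factors))
  for (r in rules) {
    fs <- intersect(factors, r$factor_set)
    if (length(fs) < 2) next
    for (i in seq_len(length(fs) - 1)) {
      for (j in seq(i + 1, length(fs))) {
        a <- fs[i]; b <- fs[j]
        w <- switch(scheme,
          "set-size" = 1 / length(r$factor_set),
          "depth-sum" = 1 / (1 + r$depths[[a]]) + 1 / (1 + r$depths[[b]]),
          "unit" = 1)
        m[a, b] <- m[a, b] + w
        m[b, a] <- m[b, a] + w
      }
    }
  }
  structure(m, scheme = scheme,
            class = c("relationship_matrix", "matrix", "array"))
}

#' Mean pair weight of a relationship matrix
#'
#' Arithmetic mean over all unordered factor pairs, zero-weight pairs
#' included.
#'
#' @param matrix A `relationship_matrix` (or any symmetric matrix).
#' @return The mean off-diagonal weight.
#' @export
matrix_mean <- function(matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) < 2) stop("need at least two factors")
  mean(m[upper.tri(m)])
}

#' Partners above a factor's own row mean
#'
#' A factor's "group" is its row of the relationship matrix; partners whose
#' pair weight strictly exceeds the row mean (over all partners, zeros
#' included) are returned, strongest first.
#'
#' @param matrix A `relationship_matrix`.
#' @param factor A factor code present in the matrix.
#' @return data.frame with columns `factor` and `weight`, sorted by weight
#'   descending then matrix order.
#' @export
above_mean_partners <- function(matrix, factor) {
  m <- as.matrix(matrix)
  if (!factor %in% rownames(m)) stop("unknown factor: ", factor)
  row <- m[factor, setdiff(colnames(m), factor)]
  mu <- mean(row)
  keep <- which(row > mu)
  out <- data.frame(factor = names(row)[keep], weight = unname(row[keep]))
  out <- out[order(-out$weight, keep), ]
  rownames(out) <- NULL
  out
}

#' Risk-level profile per habit level
#'
#' For each non-missing level of the given factor, the distribution of risk
#' levels among matching records. Each profile sums to 1; levels with no
#' records are omitted with a warning. Level-vs-level ratios of these
#' profiles are the numeric content of risk-ratio radar charts.
#'
#' @param table Labeled cohort data.frame.
#' @param factor A factor code.
#' @return Named list: level -> named proportion vector over the six risk
#'   levels.
#' @export
habit_risk_profile <- function(table, factor) {
  schema <- default_schema()
  if (!factor %in% factor_codes(schema)) stop("unknown factor: ", factor)
  validate_cohort(table, schema, require_risk = TRUE)
  out <- list()
  for (lev in schema[[factor]]) {
    rows <- table[[factor]] == lev
    if (!any(rows)) {
      warning("no records with ", factor, " = ", lev, "; level omitted")
      next
    }
    cnt <- class_counts(table[rows, , drop = FALSE])
    out[[lev]] <- cnt / sum(cnt)
  }
  out
}

# ---- transcribed reference tables ------------------------------------------

extdata <- function(file) {
  path <- system.file("extdata", file, package = "strokerisk")
  if (path == "") stop("bundled file not found: ", file)
  path
}

#' Reference confusion matrices
#'
#' The cross-validated six-class confusion matrices reported for the
#' original 5,599-person screening cohort (transcribed; 4,891 effective
#' records), for the SMOTE-balanced C4.5 model and the random forest and
#' logistic-regression comparators.
#'
#' @param model Which model's matrix to load.
#' @return A `confusion_matrix` (rows = reference labels, columns =
#'   predictions).
#' @export
reference_confusion <- function(model = c("c45", "random_forest",
                                          "logistic")) {
  model <- match.arg(model)
  file <- paste0("confusion_",
                 c(c45 = "c45", random_forest = "rf",
                   logistic = "logistic")[[model]], ".csv")
  df <- utils::read.csv(extdata(file), row.names = 1, check.names = FALSE)
  as_confusion(as.matrix(df))
}

#' Reference split-depth occurrence counts
#'
#' Per-factor counts of decision-tree split occurrences by depth (root = 0)
#' in the original cohort's 171-node tree.
#'
#' @return data.frame with columns `factor`, `depth`, `frequency`.
#' @export
reference_depth_counts <- function() {
  utils::read.csv(extdata("depth_counts.csv"), stringsAsFactors = FALSE)
}

#' Reference factor relationship matrix
#'
#' The 16-factor symmetric pair-weight matrix reported for the original
#' cohort's 98 extracted rules (transcribed lower triangle, mirrored).
#'
#' @return A `relationship_matrix`.
#' @export
reference_relationship_matrix <- function() {
  df <- utils::read.csv(extdata("relationship_matrix.csv"), row.names = 1,
                        check.names = FALSE)
  m <- as.matrix(df)
  structure(m, scheme = "reference",
            class = c("relationship_matrix", "matrix", "array"))
}
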