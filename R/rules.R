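# Knowledge-based rule extraction: every root-to-leaf path of the decision
# tree becomes one conjunctive IF-THEN rule, so the rule set partitions the
# input space and rule supports sum to the training record count.

new_rule <- function(conditions, predicted, support, confidence) {
  structure(list(conditions = conditions, predicted = predicted,
                 support = support, confidence = confidence,
                 factor_set = unique(names(conditions)),
                 depths = stats::setNames(seq_along(conditions) - 1L,
                                          names(conditions))),
            class = "risk_rule")
}

collect_rules <- function(node, conditions, acc) {
  if (node$kind == "leaf") {
    n <- sum(node$counts)
    conf <- if (n > 0) max(node$counts) / n else 1
    acc[[length(acc) + 1]] <- new_rule(conditions, node$predicted, n, conf)
    return(acc)
  }
  for (v in names(node$children)) {
    cond <- c(conditions, stats::setNames(v, node$factor))
    acc <- collect_rules(node$children[[v]], cond, acc)
  }
  acc
}

#' Extract knowledge-based rules from a tree
#'
#' One rule per leaf, in depth-first traversal order; the rule's conditions
#' are the branch tests from root to leaf (root condition at depth 0), its
#' support the training records reaching the leaf, and its confidence the
#' leaf's majority fraction.
#'
#' @param tree A `c45_tree`.
#' @return List of `risk_rule` objects (length equals the leaf count).
#' @export
extract_rules <- function(tree) {
  collect_rules(tree$root, stats::setNames(character(0), character(0)),
                list())
}

#' Filter rules by factor membership
#'
#' Keeps, in order, the rules whose condition factors intersect the given
#' factor set. This is the reading of "rules related to" a set of habits:
#' at least one condition tests one of them.
#'
#' @param rules List of `risk_rule` objects.
#' @param factors Non-empty character vector of factor codes.
#' @return The matching sub-list.
#' @export
filter_rules <- function(rules, factors) {
  if (length(factors) == 0) stop("factors must be non-empty")
  keep <- vapply(rules, function(r)
    length(intersect(r$factor_set, factors)) > 0, TRUE)
  rules[keep]
}

#' The six daily-habit factor codes
#' @return `c("Smok","Alco","Tea","DT","Sleep","Sport")`.
#' @export
habit_factors <- function() c("Smok", "Alco", "Tea", "DT", "Sleep", "Sport")

#' Count rules containing a factor pair
#'
#' @param rules List of `risk_rule` objects.
#' @param a,b Factor codes.
#' @return Number of rules whose factor set contains both `a` and `b`.
#' @export
rule_cooccurrence <- function(rules, a, b) {
  sum(vapply(rules, function(r) all(c(a, b) %in% r$factor_set), TRUE))
}

format_confidence <- function(q) format(q, digits = 12, scientific = FALSE)

#' Render rules as text
#'
#' One line per rule:
#' `IF f1 = v1 AND f2 = v2 THEN risk = C [support=n, confidence=q]`;
#' a condition-free rule renders its antecedent as `TRUE`. [parse_rules()]
#' reads the format back.
#'
#' @param rules List of `risk_rule` objects.
#' @return Character vector, one element per rule.
#' @export
render_rules <- function(rules) {
  vapply(rules, function(r) {
    ante <- if (length(r$conditions) == 0) "TRUE"
            else paste(names(r$conditions), "=", unlist(r$conditions),
                       collapse = " AND ")
    sprintf("IF %s THEN risk = %s [support=%s, confidence=%s]",
            ante, r$predicted, format(r$support),
            format_confidence(r$confidence))
  }, "")
}

#' @rdname render_rules
#' @param text Character vector of rendered rule lines.
#' @export
parse_rules <- function(text) {
  lapply(text, function(line) {
    m <- regmatches(line, regexec(
      "^IF (.*) THEN risk = (\\w+) \\[support=([0-9.]+), confidence=([0-9.eE+-]+)\\]$",
      line))[[1]]
    if (length(m) != 5) stop("unparsable rule line: ", line)
    ante <- m[2]
    if (identical(ante, "TRUE")) {
      conditions <- stats::setNames(character(0), character(0))
    } else {
      parts <- strsplit(ante, " AND ", fixed = TRUE)[[1]]
      kv <- strsplit(parts, " = ", fixed = TRUE)
      conditions <- stats::setNames(vapply(kv, `[`, "", 2),
                                    vapply(kv, `[`, "", 1))
    }
    new_rule(conditions, m[3], as.numeric(m[4]), as.numeric(m[5]))
  })
}

#' @export
print.risk_rule <- function(x, ...) {
  cat(render_rules(list(x)), "\n")
  invisible(x)
}

#' Write rules as JSON
#'
#' @param rules List of `risk_rule` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
rules_to_json <- function(rules, path) {
  payload <- lapply(rules, function(r)
    list(conditions = as.list(r$conditions), predicted = r$predicted,
         support = r$support, confidence = r$confidence))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
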