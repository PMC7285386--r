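# From-scratch C4.5 learner for nominal factors: entropy / gain-ratio split
# selection, multiway splits with an explicit missing-token branch,
# minimum-leaf control, and confidence-factor pessimistic pruning by
# subtree replacement.

#' Information entropy of a class distribution
#'
#' `-sum p_i log2 p_i` over the classes with nonzero count, in bits.
#' Fractional counts are allowed.
#'
#' @param counts Nonnegative class counts with positive total.
#' @return Entropy in bits, between 0 and log2(number of classes).
#' @export
entropy <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("entropy undefined for an empty distribution")
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

#' Conditional entropy after a split
#'
#' Weighted mean of the partition entropies, `sum |D_j|/|D| * H(D_j)`; empty
#' partitions contribute nothing.
#'
#' @param parent Class counts at the parent node.
#' @param partitions List of class-count vectors, one per branch; totals must
#'   sum to the parent total.
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(parent, partitions) {
  total <- sum(parent)
  subtotals <- vapply(partitions, sum, 0)
  if (abs(sum(subtotals) - total) > 1e-9)
    stop("partition totals do not sum to the parent total")
  nz <- subtotals > 0
  sum(vapply(partitions[nz], entropy, 0) * subtotals[nz]) / total
}

#' Information gain of a split
#'
#' Parent entropy minus conditional entropy; nonnegative up to rounding.
#'
#' @inheritParams conditional_entropy
#' @return Gain in bits.
#' @export
gain <- function(parent, partitions) {
  entropy(parent) - conditional_entropy(parent, partitions)
}

split_info <- function(partitions) {
  subtotals <- vapply(partitions, sum, 0)
  entropy(subtotals)
}

#' Gain ratio of a split
#'
#' The default `"split_info"` mode is the canonical C4.5 criterion,
#' gain divided by the entropy of the branch sizes. The
#' `"conditional_entropy"` mode divides by the post-split conditional entropy
#' instead. A zero denominator disqualifies the candidate: `NA` is returned
#' rather than an error.
#'
#' @inheritParams conditional_entropy
#' @param mode Denominator choice.
#' @return Dimensionless gain ratio, or `NA` for a disqualified candidate.
#' @export
gain_ratio <- function(parent, partitions,
                       mode = c("split_info", "conditional_entropy")) {
  mode <- match.arg(mode)
  g <- gain(parent, partitions)
  denom <- if (mode == "split_info") split_info(partitions)
           else conditional_entropy(parent, partitions)
  if (denom <= 1e-12) return(NA_real_)
  g / denom
}

#' Tree-learning configuration
#'
#' @param confidence_factor Pruning confidence in (0, 0.5]; smaller prunes
#'   harder. 0.25 is the conventional default.
#' @param min_leaf Minimum records per branch for a split to be admissible.
#' @param gain_denominator Gain-ratio denominator mode, see [gain_ratio()].
#' @param use_mean_gain_guard When TRUE (canonical C4.5), only factors whose
#'   gain reaches the mean gain of the candidates compete on gain ratio,
#'   preventing gain-ratio blowups on near-zero-gain splits.
#' @return A `tree_config` list.
#' @export
tree_config <- function(confidence_factor = 0.25, min_leaf = 1L,
                        gain_denominator = c("split_info",
                                             "conditional_entropy"),
                        use_mean_gain_guard = TRUE) {
  stopifnot(confidence_factor > 0, confidence_factor <= 0.5, min_leaf >= 1)
  structure(list(confidence_factor = confidence_factor,
                 min_leaf = as.integer(min_leaf),
                 gain_denominator = match.arg(gain_denominator),
                 use_mean_gain_guard = isTRUE(use_mean_gain_guard)),
            class = "tree_config")
}

node_counts <- function(labels) {
  tab <- table(factor(labels, levels = risk_levels()))
  stats::setNames(as.numeric(tab), risk_levels())
}

majority_class <- function(counts) {
  # ties broken by the fixed risk-level order (which.max takes the first max)
  names(counts)[which.max(counts)]
}

leaf_node <- function(counts, depth) {
  structure(list(kind = "leaf", factor = NULL, children = NULL,
                 predicted = majority_class(counts), counts = counts,
                 depth = depth),
            class = "c45_node")
}

# evaluate one candidate factor at a node; NULL when inadmissible
split_candidate <- function(values, labels, parent_counts, config) {
  tab <- table(values, factor(labels, levels = risk_levels()))
  if (nrow(tab) < 2) return(NULL)
  if (any(rowSums(tab) < config$min_leaf)) return(NULL)
  partitions <- lapply(seq_len(nrow(tab)), function(i) tab[i, ])
  g <- gain(parent_counts, partitions)
  if (g <= 1e-12) return(NULL)
  list(levels = rownames(tab), partitions = partitions, gain = g,
       ratio = gain_ratio(parent_counts, partitions,
                          config$gain_denominator))
}

# order observed branch values: schema level order, missing token last
order_branch_levels <- function(observed, factor, schema) {
  ordered <- c(schema[[factor]], schema_missing(schema))
  intersect(ordered, observed)
}

grow_node <- function(df, depth, config, schema) {
  counts <- node_counts(df$risk)
  if (sum(counts > 0) <= 1) return(leaf_node(counts, depth))
  codes <- factor_codes(schema)
  cands <- lapply(codes, function(f)
    split_candidate(df[[f]], df$risk, counts, config))
  names(cands) <- codes
  cands <- cands[!vapply(cands, is.null, TRUE)]
  if (length(cands) == 0) return(leaf_node(counts, depth))
  gains <- vapply(cands, `[[`, 0, "gain")
  ratios <- vapply(cands, `[[`, 0, "ratio")
  admissible <- !is.na(ratios)
  if (config$use_mean_gain_guard)
    admissible <- admissible & gains >= mean(gains) - 1e-12
  if (!any(admissible)) return(leaf_node(counts, depth))
  # max gain ratio; ties resolved by schema order (which.max takes first)
  r <- ratios
  r[!admissible] <- -Inf
  best <- names(cands)[which.max(r)]
  branch_levels <- order_branch_levels(cands[[best]]$levels, best, schema)
  children <- lapply(branch_levels, function(v)
    grow_node(df[df[[best]] == v, , drop = FALSE], depth + 1L,
              config, schema))
  names(children) <- branch_levels
  structure(list(kind = "internal", factor = best, children = children,
                 predicted = majority_class(counts), counts = counts,
                 depth = depth),
            class = "c45_node")
}

#' Grow a C4.5 decision tree
#'
#' Recursively selects the factor maximizing the gain ratio (subject to the
#' mean-gain guard), creating one child per observed level; missing tokens
#' form their own branch. Growth stops at pure nodes, when no factor yields
#' positive gain, or when a branch would fall below `min_leaf`. Leaves
#' predict the majority class, ties broken by the fixed risk-level order.
#'
#' @param table Labeled cohort data.frame.
#' @param config A [tree_config()].
#' @param prune Prune the grown tree with [prune_tree()]?
#' @return A `c45_tree` object.
#' @export
grow_tree <- function(table, config = tree_config(), prune = FALSE) {
  schema <- default_schema()
  if (nrow(table) == 0) stop("cannot grow a tree from an empty table")
  validate_cohort(table, schema, require_risk = TRUE)
  root <- grow_node(table, 0L, config, schema)
  tree <- structure(list(root = root, config = config,
                         factors = factor_codes(schema)),
                    class = "c45_tree")
  if (prune) tree <- prune_tree(tree, config)
  tree
}

# Extra errors granted by the upper binomial confidence limit at the given
# confidence factor (pessimistic-error correction of classic C4.5).
pessimistic_extra <- function(n, e, cf) {
  if (n == 0) return(0)
  if (e < 1) {
    base <- n * (1 - cf^(1 / n))
    if (e == 0) return(base)
    return(base + e * (pessimistic_extra(n, 1, cf) - base))
  }
  if (e + 0.5 >= n) return(max(n - e, 0))
  z <- stats::qnorm(1 - cf)
  f <- (e + 0.5) / n
  upper <- (f + z^2 / (2 * n) +
            z * sqrt(f / n - f^2 / n + z^2 / (4 * n^2))) / (1 + z^2 / n)
  upper * n - e
}

node_pessimistic_error <- function(counts, cf) {
  n <- sum(counts)
  e <- n - max(counts)
  e + pessimistic_extra(n, e, cf)
}

prune_node <- function(node, cf) {
  if (node$kind == "leaf") return(node)
  node$children <- lapply(node$children, prune_node, cf = cf)
  subtree_err <- sum(vapply(node$children, subtree_pessimistic_error, 0,
                            cf = cf))
  leaf_err <- node_pessimistic_error(node$counts, cf)
  if (leaf_err <= subtree_err + 1e-9) return(leaf_node(node$counts,
                                                       node$depth))
  node
}

subtree_pessimistic_error <- function(node, cf) {
  if (node$kind == "leaf") return(node_pessimistic_error(node$counts, cf))
  sum(vapply(node$children, subtree_pessimistic_error, 0, cf = cf))
}

#' Prune a tree by pessimistic subtree replacement
#'
#' Bottom-up: a subtree collapses to a leaf when the leaf's pessimistic error
#' (upper binomial confidence limit at the configured confidence factor on
#' the node's training error) does not exceed the summed pessimistic error of
#' its children. Pruning never increases the leaf count.
#'
#' @param tree A grown `c45_tree`.
#' @param config A [tree_config()]; only `confidence_factor` is used.
#' @return The pruned `c45_tree`.
#' @export
prune_tree <- function(tree, config = tree$config) {
  tree$root <- prune_node(tree$root, config$confidence_factor)
  tree
}

predict_record <- function(node, record) {
  while (node$kind == "internal") {
    v <- as.character(record[[node$factor]])
    child <- node$children[[v]]
    if (is.null(child)) return(node$predicted)  # unseen value falls through
    node <- child
  }
  node$predicted
}

#' Predict risk levels
#'
#' Follows the branch matching each split factor's value; a value unseen at
#' an internal node during training falls through to that node's majority
#' class.
#'
#' @param object A `c45_tree`.
#' @param newdata Cohort data.frame.
#' @param ... Unused.
#' @return Character vector of predicted risk levels.
#' @export
predict.c45_tree <- function(object, newdata, ...) {
  vapply(seq_len(nrow(newdata)), function(i)
    predict_record(object$root, newdata[i, , drop = FALSE]), "")
}

count_nodes <- function(node) {
  if (node$kind == "leaf") return(c(leaves = 1, size = 1))
  child <- rowSums(vapply(node$children, count_nodes, c(leaves = 0, size = 0)))
  c(leaves = child[["leaves"]], size = child[["size"]] + 1)
}

#' Leaf and node counts of a tree
#'
#' @param tree A `c45_tree`.
#' @return Named integer vector `c(leaves =, size =)` where size counts all
#'   nodes (internal plus leaves).
#' @export
tree_stats <- function(tree) {
  st <- count_nodes(tree$root)
  stats::setNames(as.integer(st), names(st))
}

print_node <- function(node, prefix, file) {
  if (node$kind == "leaf") return(invisible())
  for (v in names(node$children)) {
    child <- node$children[[v]]
    line <- paste0(prefix, node$factor, " = ", v)
    if (child$kind == "leaf") {
      n <- sum(child$counts)
      e <- n - max(child$counts)
      line <- paste0(line, ": ", child$predicted, " (", format(n),
                     if (e > 0) paste0("/", format(e)) else "", ")")
      cat(line, "\n", sep = "")
    } else {
      cat(line, "\n", sep = "")
      print_node(child, paste0(prefix, "|   "), file)
    }
  }
  invisible()
}

#' @export
print.c45_tree <- function(x, ...) {
  st <- tree_stats(x)
  if (x$root$kind == "leaf") {
    cat(": ", x$root$predicted, " (", sum(x$root$counts), ")\n", sep = "")
  } else {
    print_node(x$root, "", stdout())
  }
  cat("\nNumber of leaves: ", st[["leaves"]],
      "\nSize of the tree: ", st[["size"]], "\n", sep = "")
  invisible(x)
}

node_to_list <- function(node) {
  out <- list(kind = node$kind, depth = node$depth,
              predicted = node$predicted,
              counts = as.list(node$counts))
  if (node$kind == "internal") {
    out$factor <- node$factor
    out$children <- lapply(node$children, node_to_list)
  }
  out
}

node_from_list <- function(x) {
  counts <- stats::setNames(as.numeric(unlist(x$counts)), names(x$counts))
  node <- list(kind = x$kind, factor = x$factor,
               children = NULL, predicted = x$predicted,
               counts = counts, depth = as.integer(x$depth))
  if (identical(x$kind, "internal"))
    node$children <- lapply(x$children, node_from_list)
  structure(node, class = "c45_node")
}

#' Serialize / restore a tree as JSON
#'
#' @param tree A `c45_tree`.
#' @param path Output (input) file path.
#' @return `tree_to_json` invisibly returns `path`; `tree_from_json` returns
#'   the restored `c45_tree`.
#' @export
tree_to_json <- function(tree, path) {
  payload <- list(config = unclass(tree$config), factors = tree$factors,
                  root = node_to_list(tree$root))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname tree_to_json
#' @export
tree_from_json <- function(path) {
  x <- jsonlite::read_json(path)
  config <- do.call(tree_config, x$config[c("confidence_factor", "min_leaf",
                                            "gain_denominator",
                                            "use_mean_gain_guard")])
  structure(list(root = node_from_list(x$root), config = config,
                 factors = unlist(x$factors)),
            class = "c45_tree")
}
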