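# Class-imbalance gate and nominal-feature SMOTE oversampling.
#
# The gate compares the largest and smallest class counts; when their ratio
# reaches 3 the cohort is declared unbalanced and minority classes are grown
# with synthetic records built from within-class nearest neighbors under
# Hamming distance (all 16 factors are categorical; the missing token counts
# as a level of its own).

#' Balancing configuration
#'
#' @param ratio_threshold Gate: the cohort is unbalanced when
#'   max/min class count >= this value (strict `<` means balanced).
#' @param k_neighbors Neighbors considered per seed record.
#' @param target_ratio Post-balancing max/min ratio to fall strictly below;
#'   must not exceed `ratio_threshold`.
#' @param seed RNG seed for the shuffle, neighbor choice and attribute coins.
#' @return A `balance_config` list.
#' @export
balance_config <- function(ratio_threshold = 3, k_neighbors = 5,
                           target_ratio = ratio_threshold, seed = 1L) {
  stopifnot(ratio_threshold > 1, k_neighbors >= 1,
            target_ratio > 1, target_ratio <= ratio_threshold)
  structure(list(ratio_threshold = ratio_threshold,
                 k_neighbors = as.integer(k_neighbors),
                 target_ratio = target_ratio, seed = as.integer(seed)),
            class = "balance_config")
}

#' Imbalance gate
#'
#' @param counts Named class counts (classes with zero count are ignored).
#' @param threshold Ratio threshold.
#' @return TRUE iff max/min < threshold over the nonzero classes.
#' @export
is_balanced <- function(counts, threshold = 3) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("all class counts are zero")
  max(counts) / min(counts) < threshold
}

#' Nonrepeatable random shuffle
#'
#' Draws every record exactly once in random order (sampling without
#' replacement of the full table), removing any influence of prior sorting
#' or filtering on downstream neighbor construction.
#'
#' @param table Cohort data.frame.
#' @param seed RNG seed.
#' @return The same multiset of records in a new, seed-determined order.
#' @export
shuffle_nonrepeat <- function(table, seed = 1L) {
  with_seed(seed, {
    idx <- sample.int(nrow(table))
    out <- table[idx, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

# target count per class so that max / target falls strictly below ratio
smote_target_count <- function(max_count, target_ratio) {
  tgt <- ceiling(max_count / target_ratio)
  if (max_count / tgt >= target_ratio) tgt <- tgt + 1L
  as.integer(tgt)
}

# k nearest within-class neighbor index lists under Hamming distance over
# the factor columns; ties by record index (stable), self excluded.
hamming_neighbors <- function(values, k) {
  m <- nrow(values)
  d <- matrix(0L, m, m)
  for (j in seq_len(ncol(values))) {
    v <- values[, j]
    d <- d + outer(v, v, "!=")
  }
  lapply(seq_len(m), function(i) {
    ord <- order(d[i, ], seq_len(m))
    ord <- ord[ord != i]
    utils::head(ord, k)
  })
}

#' SMOTE for nominal factors
#'
#' When the imbalance gate trips, each minority class is grown with synthetic
#' records until the max/min class ratio falls strictly below the target.
#' A synthetic record takes each attribute value from either a random seed
#' record of its class or one of that record's k nearest within-class
#' neighbors (Hamming distance over the coded factors), chosen by a fair coin
#' per attribute; it keeps the seed's class label. The majority class is
#' never altered, and every synthetic value occurs in some real record of the
#' same class.
#'
#' @param table Labeled cohort data.frame.
#' @param config A [balance_config()].
#' @return List with `table` (input plus any synthetic records, flagged in a
#'   logical `.synthetic` column) and `report` (class counts before/after,
#'   synthetic counts per class, and whether the gate triggered).
#' @export
smote_nominal <- function(table, config = balance_config()) {
  before <- class_counts(table)
  codes <- factor_codes(default_schema())
  triggered <- !is_balanced(before, config$ratio_threshold)
  out <- table
  if (is.null(out$.synthetic)) out$.synthetic <- rep(FALSE, nrow(out))
  synth_per_class <- stats::setNames(integer(length(before)), names(before))
  if (triggered) {
    out <- shuffle_nonrepeat(out, config$seed)
    max_count <- max(before)
    tgt <- smote_target_count(max_count, config$target_ratio)
    new_rows <- list()
    with_seed(config$seed + 1L, {
      for (cls in names(before)) {
        cnt <- before[[cls]]
        if (cnt == 0 || cnt >= tgt) next
        need <- tgt - cnt
        cls_idx <- which(out$risk == cls & !out$.synthetic)
        vals <- as.matrix(out[cls_idx, codes, drop = FALSE])
        if (length(cls_idx) == 1) {
          nb <- list(1L)  # lone record: neighbor pool collapses to itself
        } else {
          nb <- hamming_neighbors(vals, config$k_neighbors)
        }
        seeds <- sample.int(length(cls_idx), need, replace = TRUE)
        synth <- matrix("", need, length(codes),
                        dimnames = list(NULL, codes))
        for (s in seq_len(need)) {
          i <- seeds[s]
          pool <- nb[[i]]
          if (length(pool) == 0) pool <- i
          j <- pool[sample.int(length(pool), 1)]
          from_seed <- stats::runif(length(codes)) < 0.5
          synth[s, ] <- ifelse(from_seed, vals[i, ], vals[j, ])
        }
        df <- as.data.frame(synth, stringsAsFactors = FALSE)
        df$risk <- rep(cls, need)
        df$.synthetic <- rep(TRUE, need)
        new_rows[[cls]] <- df
        synth_per_class[[cls]] <- need
      }
    })
    if (length(new_rows) > 0)
      out <- rbind(out, do.call(rbind, new_rows))
    rownames(out) <- NULL
  }
  after <- class_counts(out)
  report <- structure(list(before = before, after = after,
                           synthetic_per_class = synth_per_class,
                           triggered = triggered),
                      class = "balance_report")
  list(table = out, report = report)
}

#' @export
print.balance_report <- function(x, ...) {
  cat("balance report (triggered:", x$triggered, ")\n")
  m <- rbind(before = x$before, synthetic = x$synthetic_per_class,
             after = x$after)
  print(m)
  invisible(x)
}
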