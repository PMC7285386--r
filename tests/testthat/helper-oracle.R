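# Independent brute-force oracle for attribute selection: re-derives
# entropy, conditional entropy, gain and gain ratio from first principles
# (no calls into the package's split machinery) and enumerates every factor
# to find the best admissible split at a node.

oracle_entropy <- function(labels) {
  p <- as.vector(table(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# per-factor gain and both gain-ratio variants, by direct enumeration
oracle_split_scores <- function(df, factor) {
  v <- as.character(df[[factor]])
  groups <- split(df$risk, v)
  if (length(groups) < 2) return(NULL)
  n <- nrow(df)
  cond <- sum(vapply(groups, function(g)
    length(g) / n * oracle_entropy(g), 0))
  g <- oracle_entropy(df$risk) - cond
  sizes <- vapply(groups, length, 0L) / n
  si <- -sum(sizes * log2(sizes))
  list(gain = g,
       ratio_split_info = if (si > 1e-12) g / si else NA_real_,
       ratio_cond = if (cond > 1e-12) g / cond else NA_real_,
       sizes = vapply(groups, length, 0L))
}

# best root factor under the same admissibility policy as the learner:
# positive gain, all branches >= min_leaf, optional mean-gain guard,
# defined denominator; ties by schema factor order
oracle_best_factor <- function(df, mode = "split_info", min_leaf = 1,
                               mean_gain_guard = TRUE) {
  codes <- factor_codes(default_schema())
  scores <- lapply(codes, function(f) oracle_split_scores(df, f))
  names(scores) <- codes
  ok <- vapply(scores, function(s)
    !is.null(s) && s$gain > 1e-12 && all(s$sizes >= min_leaf), TRUE)
  scores <- scores[ok]
  if (length(scores) == 0) return(NA_character_)
  gains <- vapply(scores, `[[`, 0, "gain")
  ratios <- vapply(scores, function(s)
    if (mode == "split_info") s$ratio_split_info else s$ratio_cond, 0)
  adm <- !is.na(ratios)
  if (mean_gain_guard) adm <- adm & gains >= mean(gains) - 1e-12
  if (!any(adm)) return(NA_character_)
  ratios[!adm] <- -Inf
  names(scores)[which.max(ratios)]
}
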