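test_that("entropy, conditional entropy and gain match hand evaluation", {
  expect_equal(entropy(c(A = 5, B = 5)), 1)
  expect_equal(entropy(c(A = 7)), 0)
  expect_equal(entropy(c(A = 9, B = 5)), 0.9402859587, tolerance = 1e-9)
  expect_error(entropy(c(A = 0, B = 0)), "empty")

  parent <- c(A = 9, B = 5)
  expect_equal(conditional_entropy(parent, list(parent)), entropy(parent))
  expect_equal(conditional_entropy(parent, list(c(A = 9), c(B = 5))), 0)
  split <- list(c(A = 6, B = 2), c(A = 3, B = 3))
  expect_equal(conditional_entropy(parent, split), 0.8921589283,
               tolerance = 1e-9)
  expect_error(conditional_entropy(parent, list(c(A = 1))), "sum")

  expect_equal(gain(parent, list(parent)), 0)
  expect_equal(gain(parent, list(c(A = 9), c(B = 5))), entropy(parent))
  expect_equal(gain(parent, split), 0.0481270304, tolerance = 1e-9)
})

test_that("gain ratio handles both denominators and disqualification", {
  parent <- c(A = 9, B = 5)
  split <- list(c(A = 6, B = 2), c(A = 3, B = 3))
  expect_equal(gain_ratio(parent, split, "split_info"), 0.0488486155,
               tolerance = 1e-9)
  # balanced two-way split: split info is exactly 1 bit, ratio = gain
  bal <- list(c(A = 5, B = 2), c(A = 4, B = 3))
  expect_equal(gain_ratio(parent, bal, "split_info"), gain(parent, bal))
  # pure partitions: conditional-entropy denominator vanishes
  pure <- list(c(A = 9), c(B = 5))
  expect_true(is.na(gain_ratio(parent, pure, "conditional_entropy")))
  # single-branch split: split info vanishes
  expect_true(is.na(gain_ratio(parent, list(parent), "split_info")))
})

test_that("degenerate tables give single leaves and forced splits", {
  pure <- make_cohort(5, risk = "M")
  tr <- grow_tree(pure)
  expect_equal(tr$root$kind, "leaf")
  expect_equal(tree_stats(tr), c(leaves = 1L, size = 1L))
  expect_equal(predict(tr, make_cohort(3)), rep("M", 3))

  # a perfectly separating factor forces a single split with pure leaves
  co <- make_cohort(10, Smok = rep(c("y", "n"), 5),
                    risk = rep(c("H", "N"), 5))
  tr2 <- grow_tree(co)
  expect_equal(tr2$root$factor, "Smok")
  expect_equal(tree_stats(tr2), c(leaves = 2L, size = 3L))
  expect_equal(predict(tr2, make_cohort(2, Smok = c("y", "n"))),
               c("H", "N"))
})

test_that("root choice matches the brute-force gain-ratio maximizer", {
  # 14-record fixture with two informative factors of different quality
  co <- make_cohort(14,
    Smok = rep(c("y", "n"), c(8, 6)),
    Sport = c("C1", "C2", "C1", "C3", "C2", "C1", "C3", "C2",
              "C1", "C2", "C3", "C3", "C1", "C2"),
    risk = c("H", "H", "H", "N", "H", "H", "N", "H", "N", "N", "N",
             "N", "H", "N"))
  for (mode in c("split_info", "conditional_entropy")) {
    want <- oracle_best_factor(co, mode)
    tr <- grow_tree(co, tree_config(gain_denominator = mode))
    expect_equal(tr$root$factor, want, label = paste("root under", mode))
  }
})

test_that("split choices equal the oracle's on random small fixtures", {
  for (seed in 1:25) {
    co <- random_small_cohort(n = 12 + (seed %% 19), n_classes = 2 + seed %% 3,
                              seed = seed)
    for (mode in c("split_info", "conditional_entropy")) {
      tr <- grow_tree(co, tree_config(gain_denominator = mode))
      want <- oracle_best_factor(co, mode)
      got <- if (tr$root$kind == "leaf") NA_character_ else tr$root$factor
      expect_equal(got, want, label = paste("seed", seed, mode))
      # recurse one level: each child's split must also match the oracle
      if (tr$root$kind == "internal") {
        for (v in names(tr$root$children)) {
          child <- tr$root$children[[v]]
          sub <- co[co[[tr$root$factor]] == v, , drop = FALSE]
          cw <- oracle_best_factor(sub, mode)
          cg <- if (child$kind == "leaf") NA_character_ else child$factor
          expect_equal(cg, cw, label = paste("seed", seed, mode, "child", v))
        }
      }
    }
  }
})

test_that("missing tokens get their own branch", {
  co <- make_cohort(12, Hyte = rep(c("y", "n", "?"), 4),
                    risk = rep(c("H", "N", "M"), 4))
  tr <- grow_tree(co)
  expect_equal(tr$root$factor, "Hyte")
  expect_true("?" %in% names(tr$root$children))
  expect_equal(predict(tr, make_cohort(1, Hyte = "?")), "M")
})

test_that("unpruned trees reproduce conflict-free training labels", {
  # distinct factor combinations by construction, so no label conflicts
  grid <- expand.grid(Smok = c("y", "n"), Sport = c("C1", "C2", "C3"),
                      DT = c("C1", "C2", "C3"), stringsAsFactors = FALSE)
  co <- make_cohort(nrow(grid), Smok = grid$Smok, Sport = grid$Sport,
                    DT = grid$DT)
  set.seed(42)
  co$risk <- sample(c("H", "M", "N"), nrow(co), replace = TRUE)
  tr <- grow_tree(co, tree_config(min_leaf = 1), prune = FALSE)
  expect_equal(predict(tr, co), co$risk)
})

test_that("pruning collapses redundant subtrees and never adds leaves", {
  # all children predict the parent majority -> subtree collapses
  co <- make_cohort(20, Tea = rep(c("y", "n"), 10),
                    risk = rep(c("H", "H", "H", "N"), 5))
  tr <- grow_tree(co, prune = FALSE)
  pr <- prune_tree(tr)
  expect_lte(tree_stats(pr)[["leaves"]], tree_stats(tr)[["leaves"]])

  co2 <- random_small_cohort(60, n_classes = 3, seed = 7)
  grown <- grow_tree(co2, prune = FALSE)
  p25 <- prune_tree(grown, tree_config(confidence_factor = 0.25))
  p49 <- prune_tree(grown, tree_config(confidence_factor = 0.499))
  expect_lte(tree_stats(p25)[["leaves"]], tree_stats(grown)[["leaves"]])
  # near-0.5 confidence prunes no more aggressively than 0.25
  expect_gte(tree_stats(p49)[["leaves"]], tree_stats(p25)[["leaves"]])
})

test_that("noisy single-factor trees prune to sensible leaves", {
  co <- make_cohort(40, Alco = rep(c("y", "n"), 20),
                    risk = rep(c("H", "H", "H", "H", "N", "H", "H", "H"), 5))
  pr <- grow_tree(co, prune = TRUE)
  expect_equal(pr$root$kind, "leaf")
  expect_equal(pr$root$predicted, "H")
})

test_that("trees are deterministic and survive JSON round-trips", {
  co <- random_small_cohort(40, seed = 3)
  t1 <- grow_tree(co, prune = TRUE)
  t2 <- grow_tree(co, prune = TRUE)
  expect_identical(t1, t2)
  path <- withr::local_tempfile(fileext = ".json")
  tree_to_json(t1, path)
  t3 <- tree_from_json(path)
  expect_equal(predict(t3, co), predict(t1, co))
  expect_equal(tree_stats(t3), tree_stats(t1))
})

test_that("tree stats count leaves and all nodes", {
  co <- make_cohort(9, DT = rep(c("C1", "C2", "C3"), 3),
                    risk = rep(c("H", "M", "N"), 3))
  tr <- grow_tree(co)
  expect_equal(tree_stats(tr), c(leaves = 3L, size = 4L))
  st <- tree_stats(grow_tree(random_small_cohort(50, seed = 5)))
  expect_lt(st[["leaves"]], st[["size"]])
})
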