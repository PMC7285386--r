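test_that("average depth is the frequency-weighted mean of split depths", {
  expect_equal(average_depth(c(`3` = 4, `4` = 2, `6` = 1)), 26 / 7)
  expect_equal(average_depth(c(`5` = 1, `6` = 2, `7` = 1)), 6)
  expect_equal(average_depth(c(`8` = 1, `10` = 2, `12` = 1, `13` = 1)), 10.6)
  expect_equal(average_depth(c(`10` = 1, `11` = 3)), 10.75)
  expect_equal(average_depth(c(`4` = 9)), 4)
  expect_error(average_depth(numeric(0)), "empty")
})

test_that("depth profiles mirror the tree's internal nodes", {
  co <- make_cohort(12, Smok = rep(c("y", "n"), 6),
                    Sport = rep(c("C1", "C1", "C2", "C2", "C3", "C3"), 2),
                    risk = c("H", "N", "H", "N", "H", "L",
                             "H", "N", "H", "N", "H", "L"))
  tr <- grow_tree(co, prune = FALSE)
  prof <- depth_profiles(tr)
  expect_setequal(prof$factor, unique(unlist(lapply(
    extract_rules(tr), `[[`, "factor_set"))))
  st <- tree_stats(tr)
  expect_equal(sum(prof$frequency), st[["size"]] - st[["leaves"]])
  # a factor splitting only at the root averages depth zero
  root_row <- prof[prof$factor == tr$root$factor, ]
  if (tr$root$factor %in% prof$factor && root_row$frequency == 1)
    expect_equal(root_row$average_depth, 0)
  # single-leaf tree has no profiles
  expect_equal(nrow(depth_profiles(grow_tree(make_cohort(3, risk = "N")))), 0)
})

test_that("relationship matrix accumulates symmetric scheme weights", {
  r1 <- parse_rules(
    "IF Smok = y AND Sport = C3 THEN risk = H [support=4, confidence=1]")
  m <- relationship_matrix(r1, scheme = "set-size")
  expect_equal(m["Smok", "Sport"], 0.5)
  expect_equal(m["Sport", "Smok"], 0.5)
  expect_equal(attr(m, "scheme"), "set-size")
  expect_equal(unname(diag(m)), c(0, 0))

  # depth-sum weighting uses the conditions' depths (root depth 0)
  md <- relationship_matrix(r1, scheme = "depth-sum")
  expect_equal(md["Smok", "Sport"], 1 / 1 + 1 / 2)
  expect_equal(relationship_matrix(r1, scheme = "unit")["Smok", "Sport"], 1)

  # three-factor rule: every pair gets 1/3 under set-size
  r3 <- parse_rules(paste0("IF Smok = y AND Sport = C3 AND Hyte = y ",
                           "THEN risk = H [support=1, confidence=1]"))
  m3 <- relationship_matrix(r3, scheme = "set-size")
  expect_equal(m3["Smok", "Hyte"], 1 / 3)

  # additivity: duplicating the rule list doubles every weight
  twice <- relationship_matrix(c(r1, r1), scheme = "set-size")
  expect_equal(unclass(twice), unclass(m) * 2, ignore_attr = TRUE)

  # never-co-occurring factors stay at zero
  r2 <- c(r1, parse_rules(
    "IF Hyte = y THEN risk = M [support=2, confidence=1]"))
  m2 <- relationship_matrix(r2, factors = c("Hyte", "Smok", "Sport"))
  expect_equal(m2["Hyte", "Smok"], 0)
  expect_true(isSymmetric(unclass(m2)))
})

test_that("matrix mean averages all unordered pairs", {
  m <- matrix(0.7, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(m) <- 0
  expect_equal(matrix_mean(m), 0.7)
  perm <- sample(4)
  expect_equal(matrix_mean(m[perm, perm]), matrix_mean(m))
  expect_error(matrix_mean(m[1, 1, drop = FALSE]), "two factors")
})

test_that("above-mean partners exceed the row mean, strongest first", {
  ref <- reference_relationship_matrix()
  for (f in c("Smok", "Sport", "Tea")) {
    part <- above_mean_partners(ref, f)
    row <- ref[f, setdiff(colnames(ref), f)]
    expect_true(all(part$weight > mean(row)))
    expect_true(all(diff(part$weight) <= 0))
  }
  const <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(const) <- 0
  # constant off-diagonal row: nothing strictly above its mean
  expect_equal(nrow(above_mean_partners(const, "a")), 0)
  expect_error(above_mean_partners(const, "zz"), "unknown factor")
})

test_that("habit risk profiles are conditional distributions", {
  co <- make_cohort(8, risk = "H")
  prof <- suppressWarnings(habit_risk_profile(co, "Smok"))
  expect_equal(prof$n[["H"]], 1)  # point mass on the only level present
  co2 <- simulate_cohort(sim_config(n = 600, seed = 15))
  prof2 <- suppressWarnings(habit_risk_profile(co2, "Sport"))
  for (p in prof2) expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("a planted doubling of high risk is recovered from profiles", {
  n <- 10000
  set.seed(55)
  co <- make_cohort(n, Smok = sample(c("y", "n"), n, TRUE))
  p_h <- ifelse(co$Smok == "y", 0.5, 0.25)
  co$risk <- ifelse(runif(n) < p_h, "H", "N")
  prof <- habit_risk_profile(co, "Smok")
  ratio <- prof$y[["H"]] / prof$n[["H"]]
  expect_equal(ratio, 2, tolerance = 0.15)
})
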