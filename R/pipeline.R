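# End-to-end orchestration: simulate -> label -> balance -> train -> evaluate
# -> rules -> factor analytics, with one master seed and a reproducibility
# manifest.

#' Derive a stage seed from the master seed
#'
#' A pure function of the master seed and the stage name (FNV-style mix of
#' the name's bytes), so one flag reproduces the whole run while stages stay
#' decoupled.
#'
#' @param master Master integer seed.
#' @param stage Stage name.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(master, stage) {
  h <- 2166136261
  for (b in utf8ToInt(stage)) h <- ((h * 16777619) %% 2147483647 + b) %% 2147483647
  as.integer((as.numeric(master) %% 2147483647 + h) %% 2147483646 + 1)
}

fnv1a32 <- function(text) {
  h <- 2166136261
  for (b in utf8ToInt(text)) {
    h <- bitwXor(as.integer(h %% 2^31), b) + (h %/% 2^31) * 2^31
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Pipeline configuration
#'
#' @param sim A [sim_config()] describing the cohort to simulate (or NULL
#'   when `cohort` is supplied to [run_pipeline()] directly).
#' @param balance A [balance_config()].
#' @param tree A [tree_config()].
#' @param folds Cross-validation fold count.
#' @param scheme Relationship-matrix weighting scheme.
#' @param paper_mode Balance the whole table before folding (see
#'   [cross_validate()]).
#' @param seed Master seed; every stage seed derives from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, balance = balance_config(),
                            tree = tree_config(), folds = 10L,
                            scheme = "set-size", paper_mode = FALSE,
                            seed = 1L) {
  structure(list(sim = sim, balance = balance, tree = tree,
                 folds = as.integer(folds), scheme = scheme,
                 paper_mode = isTRUE(paper_mode), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level blocks: `sim` (n, label_mode, planted rules with
#' conditions/target/strength), `balance`, `tree`, and scalars `folds`,
#' `scheme`, `paper_mode`, `seed`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  # YAML 1.1 reads bare y/n as booleans; those are level codes here, so the
  # bool handlers give the factor tokens back verbatim
  keep_yn <- function(default) function(x)
    if (x %in% c("y", "n", "Y", "N")) x else default
  y <- yaml::read_yaml(path, handlers = list(
    "bool#yes" = keep_yn(TRUE), "bool#no" = keep_yn(FALSE)))
  seed <- if (is.null(y$seed)) 1L else as.integer(y$seed)
  sim <- NULL
  if (!is.null(y$sim)) {
    planted <- lapply(y$sim$planted, function(p)
      planted_rule(p$conditions, p$target,
                   if (is.null(p$strength)) 1 else p$strength))
    sim <- sim_config(n = y$sim$n, seed = stage_seed(seed, "simulate"),
                      planted = planted,
                      label_mode = if (is.null(y$sim$label_mode)) "guideline"
                                   else y$sim$label_mode)
  }
  balance <- do.call(balance_config,
                     c(y$balance, list(seed = stage_seed(seed, "balance"))))
  tree <- do.call(tree_config, as.list(y$tree))
  pipeline_config(sim = sim, balance = balance, tree = tree,
                  folds = if (is.null(y$folds)) 10L else y$folds,
                  scheme = if (is.null(y$scheme)) "set-size" else y$scheme,
                  paper_mode = isTRUE(y$paper_mode), seed = seed)
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a labeled cohort, applies the imbalance gate and
#' SMOTE, trains and prunes the C4.5 tree on the balanced cohort,
#' cross-validates, extracts knowledge-based rules, computes depth profiles,
#' the relationship matrix and habit risk profiles, and writes every
#' artifact plus a manifest to `outdir`. Identical configuration gives
#' byte-identical artifact payloads.
#'
#' @param config A [pipeline_config()].
#' @param outdir Writable output directory (created if absent).
#' @param cohort Optional pre-built labeled cohort; overrides `config$sim`.
#' @return The manifest, invisibly (config hash, seeds, effective n, balance
#'   report, tree stats, metrics, rule counts).
#' @export
run_pipeline <- function(config, outdir, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                               digits = NA)
  cfg_hash <- fnv1a32(as.character(cfg_json))

  if (is.null(cohort)) {
    if (is.null(config$sim)) stop("stage simulate failed: no sim config and no cohort")
    sim <- config$sim
    sim$seed <- stage_seed(config$seed, "simulate")
    cohort <- simulate_cohort(sim)
  }
  write_cohort_csv(cohort, file.path(outdir, "cohort.csv"))

  bal_cfg <- config$balance
  bal_cfg$seed <- stage_seed(config$seed, "balance")
  balanced <- smote_nominal(cohort, bal_cfg)
  write_cohort_csv(balanced$table, file.path(outdir, "balanced.csv"))

  tree <- grow_tree(balanced$table, config$tree, prune = TRUE)
  tree_to_json(tree, file.path(outdir, "tree.json"))

  cv <- cross_validate(cohort, config$tree, bal_cfg, folds = config$folds,
                       seed = stage_seed(config$seed, "evaluate"),
                       paper_mode = config$paper_mode)
  metrics <- list(
    accuracy = cv$report$accuracy, kappa = cv$report$kappa,
    per_class = cv$report$per_class,
    confusion = as.data.frame.matrix(unclass(cv$confusion)),
    folds = cv$folds, n = cv$n, paper_mode = config$paper_mode)
  jsonlite::write_json(metrics, file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  rules <- extract_rules(tree)
  writeLines(render_rules(rules), file.path(outdir, "rules.txt"))
  rules_to_json(rules, file.path(outdir, "rules.json"))
  habit_rules <- filter_rules(rules, habit_factors())

  profiles <- depth_profiles(tree)
  rel <- relationship_matrix(rules, scheme = config$scheme)
  habits <- lapply(stats::setNames(nm = habit_factors()), function(f)
    lapply(habit_risk_profile(cohort, f), as.list))
  factors_out <- list(
    depth_profiles = profiles,
    relationship_matrix = as.data.frame.matrix(unclass(rel)),
    scheme = attr(rel, "scheme"),
    matrix_mean = if (nrow(rel) >= 2) matrix_mean(rel) else NA,
    habit_profiles = habits)
  jsonlite::write_json(factors_out, file.path(outdir, "factors.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame.matrix(unclass(rel)),
                   file.path(outdir, "relationship_matrix.csv"))

  manifest <- list(
    config_hash = cfg_hash,
    seed = config$seed,
    stage_seeds = list(simulate = stage_seed(config$seed, "simulate"),
                       balance = stage_seed(config$seed, "balance"),
                       evaluate = stage_seed(config$seed, "evaluate")),
    n = nrow(cohort),
    balance = list(before = as.list(balanced$report$before),
                   after = as.list(balanced$report$after),
                   triggered = balanced$report$triggered),
    tree = as.list(tree_stats(tree)),
    rules = length(rules),
    habit_rules = length(habit_rules),
    accuracy = cv$report$accuracy,
    kappa = cv$report$kappa)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

unclass_deep <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}
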