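#' Configuration of a full modelling experiment
#'
#' One global seed fans out deterministically to the simulation, each
#' strategy's fitting, and the importance permutation, so a rerun with
#' the same config is bit-identical.
#'
#' @param strategies subset of `ens`, `mars`, `mann`, `rivpacs-dfa`,
#'   `rivpacs-rf`.
#' @param filter a [filter_config()].
#' @param ens,mars,mann,rivpacs per-strategy configurations (seeds are
#'   overridden by the fan-out).
#' @param threshold O/E probability cut-off.
#' @param seed global seed.
#' @param benchmark named list of arguments forwarded to
#'   [synthetic_benchmark()] (sizes, perturbation rates); the default
#'   reference shapes are used when empty.
#' @param out_dir optional directory: when set, [run_experiment()]
#'   writes every table as CSV plus a manifest.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(strategies = c("ens", "mars", "mann",
                                      "rivpacs-dfa", "rivpacs-rf"),
                       filter = filter_config(),
                       ens = ens_config(), mars = mars_config(),
                       mann = mann_config(),
                       rivpacs = rivpacs_config(),
                       threshold = 0.5, seed = 1L,
                       benchmark = list(), out_dir = NULL) {
  known <- c("ens", "mars", "mann", "rivpacs-dfa", "rivpacs-rf")
  bad <- setdiff(strategies, known)
  if (length(bad))
    stop("unknown strategy: ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")")
  structure(list(strategies = strategies, filter = filter, ens = ens,
                 mars = mars, mann = mann, rivpacs = rivpacs,
                 threshold = threshold, seed = as.integer(seed),
                 benchmark = benchmark, out_dir = out_dir),
            class = "run_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Recognized top-level keys mirror the [run_config()] arguments;
#' sub-config keys mirror the corresponding `*_config()` arguments.
#' Keys not given keep their defaults.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$strategies)) args$strategies <- unlist(y$strategies)
  if (!is.null(y$threshold)) args$threshold <- y$threshold
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$out_dir)) args$out_dir <- y$out_dir
  if (!is.null(y$benchmark)) args$benchmark <- y$benchmark
  if (!is.null(y$filter)) args$filter <- do.call(filter_config, y$filter)
  if (!is.null(y$ens)) args$ens <- do.call(ens_config, y$ens)
  if (!is.null(y$mars)) args$mars <- do.call(mars_config, y$mars)
  if (!is.null(y$mann)) args$mann <- do.call(mann_config, y$mann)
  if (!is.null(y$rivpacs)) args$rivpacs <- do.call(rivpacs_config, y$rivpacs)
  do.call(run_config, args)
}

fit_strategy <- function(name, assemblage, predictors, cfg) {
  switch(name,
    "ens" = {
      c2 <- cfg$ens; c2$seed <- derive_seed(cfg$seed, "ens")
      ens_sdm(assemblage, predictors, c2)
    },
    "mars" = {
      c2 <- cfg$mars; c2$seed <- derive_seed(cfg$seed, "mars")
      mars_sdm(assemblage, predictors, c2)
    },
    "mann" = {
      c2 <- cfg$mann; c2$seed <- derive_seed(cfg$seed, "mann")
      mann_sdm(assemblage, predictors, c2)
    },
    "rivpacs-dfa" = {
      c2 <- cfg$rivpacs; c2$classifier <- "lda_stepwise_aic"
      c2$seed <- derive_seed(cfg$seed, "rivpacs-dfa")
      rivpacs_sdm(assemblage, predictors, c2)
    },
    "rivpacs-rf" = {
      c2 <- cfg$rivpacs; c2$classifier <- "random_forest"
      c2$seed <- derive_seed(cfg$seed, "rivpacs-rf")
      rivpacs_sdm(assemblage, predictors, c2)
    })
}

#' Run the full simulate-prepare-fit-evaluate experiment
#'
#' Generates the synthetic benchmark suite, prepares the training data
#' (taxonomic filtering, collinearity screen), fits every configured
#' strategy, predicts every dataset role, and evaluates species- and
#' assemblage-level performance, variable importance and the
#' cross-strategy ANOVA. When `cfg$out_dir` is set, all tables are
#' written as CSV along with a manifest (config dump + hash, seed,
#' package version).
#'
#' @param cfg a [run_config()].
#' @return list of class `"experiment_report"`: `bundles`, `models`,
#'   `predictions` (strategy x role), `species_metrics`,
#'   `assemblage_summaries`, `indices`, `importance`,
#'   `anova` (per-species AUC on the training role), `manifest`.
#' @export
run_experiment <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  bundles <- do.call(synthetic_benchmark,
                     c(list(seed = derive_seed(cfg$seed, "benchmark")),
                       cfg$benchmark))
  training <- bundles$training
  occ <- filter_taxa(training$assemblage, cfg$filter)
  env <- screen_collinear(training$predictors, cfg$filter)
  species <- colnames(occ); vars <- colnames(env)
  project <- function(b) {
    list(assemblage = assemblage_matrix(
           unclass(b$assemblage)[, species, drop = FALSE]),
         predictors = unclass(b$predictors)[, vars, drop = FALSE])
  }
  prepared <- lapply(bundles, project)

  models <- list(); predictions <- list()
  sp_metrics <- list(); summaries <- list(); indices <- list()
  for (st in cfg$strategies) {
    models[[st]] <- fit_strategy(st, prepared$training$assemblage,
                                 predictor_table(prepared$training$predictors),
                                 cfg)
    for (role in names(prepared)) {
      P <- predict(models[[st]], prepared[[role]]$predictors)
      predictions[[st]][[role]] <- P
      sm <- species_metrics(prepared[[role]]$assemblage, P, cfg$threshold)
      sm <- data.frame(strategy = st, role = role, sm)
      sp_metrics[[length(sp_metrics) + 1L]] <- sm
      ix <- assemblage_indices(prepared[[role]]$assemblage, P, cfg$threshold)
      indices[[st]][[role]] <- ix
      summaries[[length(summaries) + 1L]] <-
        data.frame(strategy = st, role = role, assemblage_summary(ix))
    }
  }
  sp_metrics <- do.call(rbind, sp_metrics)
  summaries <- do.call(rbind, summaries)

  imp <- lapply(names(models), function(st) {
    sc <- if (inherits(models[[st]], "ens_sdm"))
      importance_scores(models[[st]], prepared$training$predictors,
                        seed = derive_seed(cfg$seed, "importance"))
    else importance_scores(models[[st]])
    importance_ranks(sc)
  })
  names(imp) <- names(models)
  rank_mat <- matrix(NA_real_, length(vars), length(imp),
                     dimnames = list(vars, names(imp)))
  for (st in names(imp)) rank_mat[names(imp[[st]]), st] <- imp[[st]]
  importance <- aggregate_ranks(rank_mat)

  anova <- NULL
  if (length(cfg$strategies) >= 2L) {
    tr <- sp_metrics[sp_metrics$role == "training" & !is.na(sp_metrics$auc), ]
    anova <- compare_strategies(tr$auc, tr$strategy)
  }

  manifest <- data.frame(
    key = c("seed", "strategies", "threshold", "package_version", "config_hash"),
    value = c(cfg$seed, paste(cfg$strategies, collapse = "+"), cfg$threshold,
              as.character(utils::packageVersion("refstream")),
              config_hash(cfg)))
  report <- structure(list(bundles = bundles, models = models,
                           predictions = predictions,
                           species_metrics = sp_metrics,
                           assemblage_summaries = summaries,
                           indices = indices, importance = importance,
                           anova = anova, manifest = manifest,
                           config = cfg),
                      class = "experiment_report")
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

# Content hash of the configuration via a temporary YAML dump.
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$species_metrics,
                   file.path(out_dir, "species_metrics.csv"), row.names = FALSE)
  utils::write.csv(report$assemblage_summaries,
                   file.path(out_dir, "assemblage_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(report$importance,
                   file.path(out_dir, "importance.csv"), row.names = FALSE)
  for (st in names(report$predictions)) {
    for (role in names(report$predictions[[st]])) {
      P <- report$predictions[[st]][[role]]
      utils::write.csv(data.frame(site = rownames(P), P, check.names = FALSE),
                       file.path(out_dir, sprintf("predictions_%s_%s.csv", st, role)),
                       row.names = FALSE)
      utils::write.csv(report$indices[[st]][[role]],
                       file.path(out_dir, sprintf("oe_%s_%s.csv", st, role)),
                       row.names = FALSE)
    }
  }
  utils::write.csv(report$manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment report:", paste(names(x$models), collapse = ", "), "\n")
  cat(sprintf("  %d dataset roles, %d species metric rows\n",
              length(x$bundles), nrow(x$species_metrics)))
  invisible(x)
}

#' Formatted comparison tables with best-value flags
#'
#' Produces the assemblage-level and species-level comparison tables
#' (one row per dataset role x strategy) with the best value per
#' role/metric flagged. Direction conventions: mean O/E, slope best
#' closest to 1; intercept closest to 0; SD, bandwidth and Bray--Curtis
#' lower-better; r-squared, AUC, kappa, sensitivity, specificity and
#' CCR higher-better.
#'
#' @param report an `"experiment_report"`.
#' @return list with data frames `assemblage` and `species`, each with
#'   a `best_*` logical column per metric.
#' @export
report_tables <- function(report) {
  if (is.null(report$assemblage_summaries) ||
      nrow(report$assemblage_summaries) == 0L)
    stop("empty results: nothing to report")
  asm <- report$assemblage_summaries
  directions <- c(mean_oe = "one", sd_oe = "low", bandwidth = "low",
                  r2 = "high", slope = "one", intercept = "zero",
                  mean_bc = "low", sd_bc = "low")
  for (m in names(directions)) {
    flag <- logical(nrow(asm))
    for (role in unique(asm$role)) {
      rows <- which(asm$role == role)
      v <- asm[rows, m]
      score <- switch(directions[[m]], one = abs(v - 1), zero = abs(v),
                      low = v, high = -v)
      flag[rows[which.min(score)]] <- TRUE
    }
    asm[[paste0("best_", m)]] <- flag
  }
  spm <- stats::aggregate(cbind(auc, kappa, se, sp, ccr) ~ strategy + role,
                          data = report$species_metrics, FUN = mean,
                          na.rm = TRUE, na.action = stats::na.pass)
  for (m in c("auc", "kappa", "se", "sp", "ccr")) {
    flag <- logical(nrow(spm))
    for (role in unique(spm$role)) {
      rows <- which(spm$role == role)
      flag[rows[which.max(spm[rows, m])]] <- TRUE
    }
    spm[[paste0("best_", m)]] <- flag
  }
  list(assemblage = asm, species = spm)
}
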