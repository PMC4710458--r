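#' Configuration for the single-species ensemble strategy
#'
#' @param algorithms learner families used to generate candidates.
#' @param n_repeats random split-validation repeats per algorithm
#'   (default 10, giving 50 candidates per species with all five
#'   families).
#' @param holdout_fraction fraction of sites withheld per repeat
#'   (default 0.2; one fold of an implicit 5-fold scheme).
#' @param tss_primary,tss_fallback true-skill-statistic retention
#'   thresholds: candidates with TSS > `tss_primary` are retained; if
#'   none qualify the rule falls back to `tss_fallback`, and failing
#'   that the single best candidate is kept.
#' @param tss_threshold `"optimized"` (default) computes each
#'   candidate's holdout TSS at the binarization threshold maximizing
#'   TSS over the observed predicted values; `"fixed"` uses 0.5.
#' @param control learner hyperparameters (sensible defaults, frozen
#'   here so runs are reproducible): `rf_ntree`, `xgb_nrounds`,
#'   `xgb_depth`, `xgb_eta`, `nnet_size`, `nnet_decay`, `nnet_maxit`,
#'   `mars_degree`, `mars_max_basis`, `mars_max_knots`, `mars_penalty`.
#' @param seed integer master seed; per-species, per-candidate seeds
#'   derive from it.
#' @return list of class `"ens_config"`.
#' @export
ens_config <- function(algorithms = c("linear-logistic", "random-forest",
                                      "boosted-trees", "neural-net",
                                      "adaptive-splines"),
                       n_repeats = 10L, holdout_fraction = 0.2,
                       tss_primary = 0.8, tss_fallback = 0.7,
                       tss_threshold = c("optimized", "fixed"),
                       control = list(), seed = 1L) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  stopifnot(holdout_fraction > 0, holdout_fraction < 1,
            tss_fallback <= tss_primary, n_repeats >= 1L)
  defaults <- list(rf_ntree = 200L, xgb_nrounds = 60L, xgb_depth = 3L,
                   xgb_eta = 0.3, nnet_size = 5L, nnet_decay = 0.01,
                   nnet_maxit = 300L, mars_degree = 1L, mars_max_basis = 11L,
                   mars_max_knots = 7L, mars_penalty = 2)
  control <- utils::modifyList(defaults, control)
  structure(list(algorithms = algorithms, n_repeats = as.integer(n_repeats),
                 holdout_fraction = holdout_fraction,
                 tss_primary = tss_primary, tss_fallback = tss_fallback,
                 tss_threshold = match.arg(tss_threshold),
                 control = control, seed = as.integer(seed)),
            class = "ens_config")
}

#' True skill statistic from a confusion matrix
#'
#' TSS = sensitivity + specificity - 1; a prevalence-insensitive
#' measure of binary prediction skill, used as the candidate-retention
#' criterion for the ensemble.
#'
#' @param tp,fn,tn,fp non-negative confusion-matrix counts. Both classes
#'   must be represented (`tp + fn >= 1` and `tn + fp >= 1`).
#' @return list with `se`, `sp`, `tss`.
#' @examples
#' true_skill_statistic(tp = 40, fn = 10, tn = 35, fp = 15)  # TSS 0.5
#' @export
true_skill_statistic <- function(tp, fn, tn, fp) {
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0)
  if (tp + fn < 1 || tn + fp < 1)
    stop("TSS is undefined when a class is empty (tp+fn and tn+fp must be >= 1)")
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  list(se = se, sp = sp, tss = se + sp - 1)
}

# Holdout TSS at the threshold maximizing TSS over observed predicted
# values (or at a fixed 0.5). Presence is called when p >= threshold.
best_tss <- function(obs, p, rule = "optimized") {
  n1 <- sum(obs == 1); n0 <- sum(obs == 0)
  if (n1 == 0 || n0 == 0)
    stop("TSS is undefined on single-class holdout data")
  thresholds <- if (rule == "fixed") 0.5 else sort(unique(p))
  best <- list(tss = -Inf)
  for (t in thresholds) {
    pred <- as.integer(p >= t)
    tp <- sum(pred == 1 & obs == 1); fn <- sum(pred == 0 & obs == 1)
    tn <- sum(pred == 0 & obs == 0); fp <- sum(pred == 1 & obs == 0)
    r <- true_skill_statistic(tp, fn, tn, fp)
    if (r$tss > best$tss) best <- c(r, threshold = t)
  }
  best
}

# ---- learners --------------------------------------------------------------

fit_learner <- function(algorithm, X, y, control, seed) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  switch(algorithm,
    "linear-logistic" = {
      fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                             family = stats::binomial()))
      cf <- fit$coefficients; cf[is.na(cf)] <- 0
      list(algorithm = algorithm, coef = cf)
    },
    "random-forest" = {
      fit <- randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                        ntree = control$rf_ntree)
      list(algorithm = algorithm, fit = fit)
    },
    "boosted-trees" = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = control$xgb_depth, eta = control$xgb_eta,
                      nthread = 1),
        data = dtrain, nrounds = control$xgb_nrounds, verbose = 0)
      list(algorithm = algorithm, fit = fit)
    },
    "neural-net" = {
      ctr <- colMeans(X)
      scl <- apply(X, 2L, stats::sd); scl[scl == 0] <- 1
      Xs <- scale(X, ctr, scl)
      fit <- nnet::nnet(Xs, y, size = control$nnet_size,
                        decay = control$nnet_decay, maxit = control$nnet_maxit,
                        entropy = TRUE, trace = FALSE)
      list(algorithm = algorithm, fit = fit, center = ctr, scale = scl)
    },
    "adaptive-splines" = {
      cfg <- mars_config(penalty = control$mars_penalty,
                         max_degree = control$mars_degree,
                         max_basis = control$mars_max_basis,
                         max_knots = control$mars_max_knots)
      fit <- mars_fit_engine(X, matrix(y, ncol = 1L), cfg)
      list(algorithm = algorithm, terms = fit$terms,
           coef = fit$coefficients[, 1L])
    },
    stop("unknown algorithm: ", algorithm))
}

predict_learner <- function(member, X) {
  switch(member$algorithm,
    "linear-logistic" = as.vector(stats::plogis(cbind(1, X) %*% member$coef)),
    "random-forest" = unname(stats::predict(member$fit, X, type = "prob")[, "1"]),
    "boosted-trees" = as.vector(stats::predict(member$fit, xgboost::xgb.DMatrix(X))),
    "neural-net" = as.vector(stats::predict(member$fit,
                                            scale(X, member$center, member$scale))),
    "adaptive-splines" = {
      B <- mars_basis(member$terms, X)
      as.vector(stats::plogis(B %*% member$coef))
    })
}

#' Generate cross-validated candidate models for one species
#'
#' For each algorithm x repeat, sites are split into a training portion
#' and a holdout (stratified by presence/absence so low-prevalence
#' species keep presences on both sides), the learner fit on the
#' training portion only, and the holdout TSS computed. Candidates
#' whose learner fails, or whose holdout cannot support a TSS, are
#' flagged and excluded downstream. With the default five algorithms
#' and 10 repeats this yields 50 candidate models per species.
#'
#' @param y binary occurrence vector with both classes present.
#' @param X predictor matrix aligned to `y`.
#' @param cfg an [ens_config()].
#' @return list of candidate records: `algorithm`, `repeat_index`,
#'   `tss`, `se`, `sp`, `threshold`, `failed`, `member` (the fitted
#'   learner, predicting with its split-trained fit).
#' @export
fit_species_candidates <- function(y, X, cfg = ens_config()) {
  if (length(unique(y)) < 2L) stop("species has a single class; cannot be modelled")
  X <- as.matrix(unclass(X)); storage.mode(X) <- "double"
  records <- list()
  idx1 <- which(y == 1); idx0 <- which(y == 0)
  for (alg in cfg$algorithms) {
    for (r in seq_len(cfg$n_repeats)) {
      sd <- derive_seed(cfg$seed, paste0(alg, "_rep", r))
      old <- local_seed(sd)
      h1 <- sample(idx1, max(1L, round(cfg$holdout_fraction * length(idx1))))
      h0 <- sample(idx0, max(1L, round(cfg$holdout_fraction * length(idx0))))
      restore_seed(old)
      hold <- c(h1, h0)
      rec <- list(algorithm = alg, repeat_index = r, failed = FALSE,
                  tss = NA_real_, se = NA_real_, sp = NA_real_,
                  threshold = NA_real_, member = NULL)
      out <- tryCatch({
        member <- fit_learner(alg, X[-hold, , drop = FALSE], y[-hold],
                              cfg$control, seed = derive_seed(sd, "fit"))
        p <- predict_learner(member, X[hold, , drop = FALSE])
        b <- best_tss(y[hold], p, cfg$tss_threshold)
        rec$member <- member
        rec$tss <- b$tss; rec$se <- b$se; rec$sp <- b$sp
        rec$threshold <- b$threshold
        rec
      }, error = function(e) {
        rec$failed <- TRUE
        rec$message <- conditionMessage(e)
        rec
      })
      records[[length(records) + 1L]] <- out
    }
  }
  records
}

#' Candidate retention by TSS thresholds
#'
#' Retains all candidates with TSS above the primary threshold; if none
#' qualify, all above the fallback threshold; if still none, the single
#' best candidate (flagged `best-available`).
#'
#' @param tss numeric vector of candidate TSS values (NA = failed
#'   candidate, never retained).
#' @param tss_primary,tss_fallback thresholds (defaults 0.8 / 0.7).
#' @return list with `retained` (integer indices into `tss`) and `rule`
#'   (`"primary"`, `"fallback"` or `"best-available"`).
#' @export
retain_candidates <- function(tss, tss_primary = 0.8, tss_fallback = 0.7) {
  ok <- which(!is.na(tss))
  if (!length(ok)) stop("no successful candidates to retain")
  prim <- ok[tss[ok] > tss_primary]
  if (length(prim)) return(list(retained = prim, rule = "primary"))
  fall <- ok[tss[ok] > tss_fallback]
  if (length(fall)) return(list(retained = fall, rule = "fallback"))
  list(retained = ok[which.max(tss[ok])], rule = "best-available")
}

#' Fit the single-species ensemble strategy
#'
#' Per species: generate candidate models across the configured learner
#' families by repeated split-validation, retain candidates by TSS, and
#' predict as the unweighted arithmetic mean of retained members'
#' probability predictions. Only the split-trained fits ever predict;
#' members are never refit on the full data.
#'
#' @param assemblage an [assemblage_matrix()].
#' @param predictors a [predictor_table()] aligned with it.
#' @param config an [ens_config()].
#' @return object of class `"ens_sdm"`.
#' @export
ens_sdm <- function(assemblage, predictors, config = ens_config()) {
  Y <- unclass(assemblage)
  X <- unclass(predictors); storage.mode(X) <- "double"
  if (nrow(X) != nrow(Y)) stop("assemblage and predictors are misaligned")
  species <- colnames(Y)
  fits <- vector("list", length(species)); names(fits) <- species
  for (s in species) {
    cfg_s <- config
    cfg_s$seed <- derive_seed(config$seed, s)
    cands <- fit_species_candidates(Y[, s], X, cfg_s)
    tss <- vapply(cands, function(cc) cc$tss, 0)
    ret <- retain_candidates(tss, config$tss_primary, config$tss_fallback)
    fits[[s]] <- list(
      candidates = data.frame(
        species = s,
        algorithm = vapply(cands, `[[`, "", "algorithm"),
        repeat_index = vapply(cands, `[[`, 0L, "repeat_index"),
        tss = tss,
        threshold = vapply(cands, function(cc) cc$threshold, 0),
        failed = vapply(cands, `[[`, FALSE, "failed"),
        retained = seq_along(cands) %in% ret$retained),
      members = lapply(cands[ret$retained], `[[`, "member"),
      rule = ret$rule)
  }
  structure(list(species = fits, variables = colnames(X), config = config),
            class = c("ens_sdm", "stream_sdm"))
}

#' @export
print.ens_sdm <- function(x, ...) {
  n_ret <- vapply(x$species, function(s) length(s$members), 0L)
  rules <- vapply(x$species, `[[`, "", "rule")
  cat(sprintf("Single-species ensemble: %d species, %d candidates each\n",
              length(x$species), length(x$config$algorithms) * x$config$n_repeats))
  cat(sprintf("  retained members: median %d (range %d-%d); rules: %s\n",
              as.integer(stats::median(n_ret)), min(n_ret), max(n_ret),
              paste(sprintf("%s=%d", names(table(rules)), table(rules)),
                    collapse = ", ")))
  invisible(x)
}

#' Per-species candidate ledger
#'
#' @param object a fitted [ens_sdm()].
#' @return data frame of every candidate: species, algorithm, repeat,
#'   holdout TSS and threshold, failure flag, retention flag, rule.
#' @export
candidate_ledger <- function(object) {
  out <- do.call(rbind, lapply(object$species, `[[`, "candidates"))
  out$rule <- rep(vapply(object$species, `[[`, "", "rule"),
                  vapply(object$species, function(s) nrow(s$candidates), 0L))
  rownames(out) <- NULL
  out
}

# Arithmetic mean of member prediction vectors.
ens_average <- function(member_preds) {
  Reduce(`+`, member_preds) / length(member_preds)
}

#' @rdname predict.mars_sdm
#' @export
predict.ens_sdm <- function(object, newdata, ...) {
  X <- check_variables(newdata, object$variables)
  P <- vapply(object$species, function(s) {
    ens_average(lapply(s$members, function(m) predict_learner(m, X)))
  }, numeric(nrow(X)))
  dim(P) <- c(nrow(X), length(object$species))
  dimnames(P) <- list(rownames(X), names(object$species))
  P
}
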