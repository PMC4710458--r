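#' Configuration for the multi-response neural network
#'
#' @param hidden_grid hidden-layer sizes searched (0 = a direct
#'   input-to-output logistic layer). The default is a coarse subset of
#'   the 0--20 range; supply the full range for an exhaustive search.
#' @param decay_grid weight-decay (squared-weight penalty) values; the
#'   default grid spans 0.001--0.1 and contains 0.03.
#' @param n_restarts random-initialization restarts for the final fit
#'   (default 10); the restart with the best mean species AUC is kept.
#' @param cv_folds folds for the structure search (default 3).
#' @param maxit optimizer iteration cap per fit.
#' @param seed integer seed.
#' @return list of class `"mann_config"`.
#' @export
mann_config <- function(hidden_grid = c(0L, 1L, 3L, 5L, 7L, 10L),
                        decay_grid = c(0.001, 0.003, 0.01, 0.03, 0.1),
                        n_restarts = 10L, cv_folds = 3L, maxit = 300L,
                        seed = 1L) {
  stopifnot(n_restarts >= 1L, all(hidden_grid >= 0L), all(decay_grid > 0),
            cv_folds >= 2L)
  structure(list(hidden_grid = as.integer(hidden_grid),
                 decay_grid = decay_grid, n_restarts = as.integer(n_restarts),
                 cv_folds = as.integer(cv_folds), maxit = as.integer(maxit),
                 seed = as.integer(seed)),
            class = "mann_config")
}

fit_nnet_once <- function(Xs, Y, hidden, decay, maxit, seed) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  if (hidden == 0L) {
    nnet::nnet(Xs, Y, size = 0L, skip = TRUE, decay = decay, maxit = maxit,
               entropy = TRUE, trace = FALSE, MaxNWts = 5000L)
  } else {
    nnet::nnet(Xs, Y, size = hidden, decay = decay, maxit = maxit,
               entropy = TRUE, trace = FALSE, MaxNWts = 5000L)
  }
}

mean_species_auc <- function(Y, P) {
  aucs <- vapply(seq_len(ncol(Y)), function(s) auc_rank(Y[, s], P[, s]), 0)
  mean(aucs, na.rm = TRUE)
}

#' Fit the multi-response neural network strategy
#'
#' A single-hidden-layer feed-forward network with logistic output
#' units, one per species, and squared-weight decay on all weights.
#' Predictors are standardized internally (so predictions are invariant
#' to affine rescaling of the inputs). The network structure -- hidden
#' node count and decay weight -- is selected by the highest mean
#' cross-validated per-species AUC over the configured grid; the final
#' model is the best of `n_restarts` random initializations on the full
#' training data, again by mean species AUC.
#'
#' @param assemblage an [assemblage_matrix()].
#' @param predictors a [predictor_table()] aligned with it.
#' @param config a [mann_config()].
#' @return object of class `"mann_sdm"` with a `selection_report` data
#'   frame of grid scores.
#' @export
mann_sdm <- function(assemblage, predictors, config = mann_config()) {
  Y <- unclass(assemblage); storage.mode(Y) <- "double"
  X <- unclass(predictors); storage.mode(X) <- "double"
  if (nrow(X) != nrow(Y)) stop("assemblage and predictors are misaligned")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd); scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)

  grid <- expand.grid(hidden = config$hidden_grid, decay = config$decay_grid)
  old <- local_seed(derive_seed(config$seed, "mann_folds"))
  folds <- sample(rep_len(seq_len(config$cv_folds), nrow(X)))
  restore_seed(old)
  grid$mean_cv_auc <- NA_real_
  for (gi in seq_len(nrow(grid))) {
    P <- matrix(NA_real_, nrow(X), ncol(Y))
    ok <- TRUE
    for (f in seq_len(config$cv_folds)) {
      tr <- folds != f
      fit <- tryCatch(
        fit_nnet_once(Xs[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                      grid$hidden[gi], grid$decay[gi], config$maxit,
                      derive_seed(config$seed, paste0("cv", gi, "_", f))),
        error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      P[!tr, ] <- stats::predict(fit, Xs[!tr, , drop = FALSE])
    }
    if (ok) grid$mean_cv_auc[gi] <- mean_species_auc(Y, P)
  }
  if (all(is.na(grid$mean_cv_auc))) stop("all network structures failed to fit")
  best <- which.max(grid$mean_cv_auc)

  fits <- list(); scores <- numeric()
  for (r in seq_len(config$n_restarts)) {
    fit <- tryCatch(
      fit_nnet_once(Xs, Y, grid$hidden[best], grid$decay[best], config$maxit,
                    derive_seed(config$seed, paste0("restart", r))),
      error = function(e) NULL)
    if (is.null(fit)) next
    fits[[length(fits) + 1L]] <- fit
    scores <- c(scores, mean_species_auc(Y, stats::predict(fit, Xs)))
  }
  if (!length(fits)) stop("all restarts failed to converge")
  final <- fits[[which.max(scores)]]
  structure(list(fit = final, hidden = grid$hidden[best],
                 decay = grid$decay[best], center = ctr, scale = scl,
                 selection_report = grid,
                 restart_scores = scores,
                 variables = colnames(X), species = colnames(Y),
                 config = config),
            class = c("mann_sdm", "stream_sdm"))
}

#' @export
print.mann_sdm <- function(x, ...) {
  cat(sprintf("Multi-response neural network: %d species, %d hidden nodes, decay %g\n",
              length(x$species), x$hidden, x$decay))
  cat(sprintf("  structure search: %d grid points, best mean CV AUC %.3f; best of %d restarts\n",
              nrow(x$selection_report),
              max(x$selection_report$mean_cv_auc, na.rm = TRUE),
              length(x$restart_scores)))
  invisible(x)
}

#' @rdname predict.mars_sdm
#' @export
predict.mann_sdm <- function(object, newdata, ...) {
  X <- check_variables(newdata, object$variables)
  Xs <- scale(X, object$center, object$scale)
  P <- stats::predict(object$fit, Xs)
  colnames(P) <- object$species
  rownames(P) <- rownames(X)
  P
}
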