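#' O/E taxonomic completeness at a probability threshold
#'
#' The expected richness `E` is the sum of modelled occurrence
#' probabilities exceeding the threshold; the observed richness `O`
#' counts how many of those same taxa were actually recorded. Their
#' ratio is the taxonomic-completeness index (O/E). When no probability
#' exceeds the threshold the index is undefined for that site and
#' flagged (`defined = FALSE`); such sites are excluded from summaries.
#'
#' @param obs binary observation vector for one site.
#' @param p occurrence-probability vector over the same species, in the
#'   same order.
#' @param threshold probability cut-off (default 0.5, the conventional
#'   bioassessment choice).
#' @return list with `O`, `E`, `oe`, `bc` (Bray--Curtis, all taxa
#'   included), and `defined`.
#' @examples
#' oe_index(c(1, 1, 1), c(0.9, 0.6, 0.4))  # E = 1.5, O = 2, O/E = 1.33
#' @export
oe_index <- function(obs, p, threshold = 0.5) {
  if (length(obs) != length(p)) stop("obs and p are misaligned")
  stopifnot(all(obs %in% c(0, 1)), all(p >= 0), all(p <= 1))
  sel <- p > threshold
  E <- sum(p[sel])
  O <- sum(obs[sel])
  bc <- if (sum(obs) + sum(p) == 0) NA_real_ else bray_curtis(obs, p)
  if (!any(sel))
    return(list(O = 0, E = 0, oe = NA_real_, bc = bc, defined = FALSE))
  list(O = O, E = E, oe = O / E, bc = bc, defined = TRUE)
}

#' Bray--Curtis dissimilarity between observed and predicted assemblage
#'
#' `BC = sum(|obs - p|) / sum(obs + p)`, with all species included
#' (probabilities are not thresholded or binarized). 0 means perfect
#' agreement, 1 total mismatch.
#'
#' @param obs binary observation vector.
#' @param p probability vector over the same species.
#' @return BC in `[0, 1]`.
#' @export
bray_curtis <- function(obs, p) {
  if (length(obs) != length(p)) stop("obs and p are misaligned")
  denom <- sum(obs + p)
  if (denom == 0) stop("Bray-Curtis is undefined when both vectors are all zero")
  sum(abs(obs - p)) / denom
}

#' Per-site reference-condition indices for a whole dataset
#'
#' @param assemblage an [assemblage_matrix()] of observations.
#' @param predictions aligned site x species probability matrix.
#' @param threshold O/E probability cut-off (default 0.5).
#' @return data frame with one row per site: `site`, `O`, `E`, `oe`,
#'   `bc`, `defined`.
#' @export
assemblage_indices <- function(assemblage, predictions, threshold = 0.5) {
  M <- unclass(assemblage)
  if (!identical(dim(M), dim(predictions)))
    stop("assemblage and predictions have different shapes")
  if (!is.null(colnames(M)) && !is.null(colnames(predictions)) &&
      !identical(colnames(M), colnames(predictions)))
    predictions <- predictions[, colnames(M), drop = FALSE]
  rows <- lapply(seq_len(nrow(M)), function(i)
    oe_index(M[i, ], predictions[i, ], threshold))
  data.frame(site = rownames(M),
             O = vapply(rows, `[[`, 0, "O"),
             E = vapply(rows, `[[`, 0, "E"),
             oe = vapply(rows, `[[`, 0, "oe"),
             bc = vapply(rows, `[[`, 0, "bc"),
             defined = vapply(rows, `[[`, FALSE, "defined"),
             row.names = NULL)
}

# Rank-based AUC; tied predictions get half credit. NA when obs has a
# single class.
auc_rank <- function(obs, p) {
  n1 <- sum(obs == 1); n0 <- sum(obs == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)
  (sum(r[obs == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Species-level evaluation metrics
#'
#' For each species: AUC (rank-based probability that a random presence
#' outranks a random absence, ties counted half), and threshold-based
#' sensitivity, specificity, correct classification rate and Cohen's
#' kappa (presence called when `p > threshold`). Metrics undefined for a
#' species (single-class observations) are NA and should be excluded
#' from cross-species averages.
#'
#' @param assemblage observed [assemblage_matrix()].
#' @param predictions aligned probability matrix.
#' @param threshold binarization cut-off (default 0.5).
#' @return data frame: `species`, `prevalence`, `auc`, `se`, `sp`,
#'   `ccr`, `kappa`, `threshold`.
#' @export
species_metrics <- function(assemblage, predictions, threshold = 0.5) {
  M <- unclass(assemblage)
  if (!is.null(colnames(M)) && !is.null(colnames(predictions)))
    predictions <- predictions[, colnames(M), drop = FALSE]
  out <- lapply(seq_len(ncol(M)), function(s) {
    obs <- M[, s]; p <- predictions[, s]
    pred <- as.integer(p > threshold)
    tp <- sum(pred == 1 & obs == 1); fn <- sum(pred == 0 & obs == 1)
    tn <- sum(pred == 0 & obs == 0); fp <- sum(pred == 1 & obs == 0)
    n <- length(obs)
    se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    ccr <- (tp + tn) / n
    pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
    kappa <- if (pe < 1) (ccr - pe) / (1 - pe) else NA_real_
    data.frame(species = colnames(M)[s], prevalence = mean(obs),
               auc = auc_rank(obs, p), se = se, sp = sp, ccr = ccr,
               kappa = kappa, threshold = threshold)
  })
  do.call(rbind, out)
}

#' Assemblage-level summary of O/E and Bray--Curtis indices
#'
#' Summaries follow the standard bioassessment battery: accuracy (mean
#' O/E), precision (SD and the 90th-minus-10th percentile "bandwidth",
#' percentiles by linear interpolation between order statistics), fit
#' (squared Pearson correlation of O and E) and bias (least-squares
#' regression of O on E).
#'
#' @param indices data frame from [assemblage_indices()] (needs >= 3
#'   sites with a defined O/E).
#' @return one-row data frame: `n_sites`, `n_defined`, `mean_oe`,
#'   `sd_oe`, `bandwidth`, `r2`, `slope`, `intercept`, `mean_bc`,
#'   `sd_bc`.
#' @export
assemblage_summary <- function(indices) {
  def <- indices[indices$defined, , drop = FALSE]
  if (nrow(def) < 3L) stop("need at least 3 sites with a defined O/E")
  oe <- def$oe
  if (stats::sd(def$E) > 0) {
    slope <- stats::cov(def$O, def$E) / stats::var(def$E)
    intercept <- mean(def$O) - slope * mean(def$E)
    r2 <- if (stats::sd(def$O) > 0) stats::cor(def$O, def$E)^2 else NA_real_
  } else {
    slope <- intercept <- r2 <- NA_real_
  }
  data.frame(n_sites = nrow(indices), n_defined = nrow(def),
             mean_oe = mean(oe), sd_oe = stats::sd(oe),
             bandwidth = stats::quantile(oe, 0.9, type = 7, names = FALSE) -
               stats::quantile(oe, 0.1, type = 7, names = FALSE),
             r2 = r2, slope = slope, intercept = intercept,
             mean_bc = mean(indices$bc, na.rm = TRUE),
             sd_bc = stats::sd(indices$bc, na.rm = TRUE))
}

# ---- variable importance ---------------------------------------------------

#' Strategy-specific predictor-variable importance
#'
#' Importance is extracted the way each strategy's own literature does
#' it: single-species ensembles by single-variable permutation (mean
#' absolute change in predicted probability over all species and
#' sites); the adaptive-splines model by the deviance lost when the
#' basis functions involving a variable are removed and the species
#' mappings refit; the neural network by the connection-weight method
#' (input-to-hidden times hidden-to-output products summed over
#' species); the discriminant-analysis classifier by the F-to-remove
#' statistic from the partial Wilks' lambda; and the random-forest
#' classifier by total Gini impurity decrease. Use
#' [importance_ranks()] to convert scores to within-strategy ranks and
#' [aggregate_ranks()] to average ranks across strategies.
#'
#' @param object a fitted strategy model.
#' @param newdata predictors used for permutation (ensemble method;
#'   defaults to refusing silently absent data).
#' @param seed integer seed for the permutation method.
#' @param ... unused.
#' @return named numeric vector of non-negative scores (higher = more
#'   important); variables a strategy did not retain are absent.
#' @export
importance_scores <- function(object, ...) UseMethod("importance_scores")

#' @rdname importance_scores
#' @export
importance_scores.ens_sdm <- function(object, newdata, seed = 1L, ...) {
  X <- check_variables(newdata, object$variables)
  base <- predict(object, X)
  old <- local_seed(derive_seed(seed, "perm"))
  on.exit(restore_seed(old))
  scores <- vapply(object$variables, function(v) {
    Xp <- X
    Xp[, v] <- X[sample(nrow(X)), v]
    mean(abs(predict(object, Xp) - base))
  }, 0)
  scores
}

#' @rdname importance_scores
#' @export
importance_scores.mars_sdm <- function(object, ...) {
  B <- object$training$B; Y <- object$training$Y
  dev_of <- function(cols) {
    coefs <- mars_refit(B[, cols, drop = FALSE], Y)
    P <- stats::plogis(B[, cols, drop = FALSE] %*% coefs)
    P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
    -2 * sum(Y * log(P) + (1 - Y) * log(1 - P))
  }
  full <- dev_of(seq_len(ncol(B)))
  vars <- unique(unlist(lapply(object$terms, function(t)
    vapply(t, `[[`, "", "var"))))
  if (!length(vars)) return(stats::setNames(numeric(0), character(0)))
  scores <- vapply(vars, function(v) {
    keep <- which(vapply(object$terms, function(t)
      !any(vapply(t, `[[`, "", "var") == v), TRUE))
    max(0, dev_of(keep) - full)
  }, 0)
  scores
}

#' @rdname importance_scores
#' @export
importance_scores.mann_sdm <- function(object, ...) {
  fit <- object$fit
  w <- stats::coef(fit)           # named: "i1->h1", "h1->o2", "b->h1", ...
  p <- length(object$variables); S <- length(object$species)
  if (object$hidden == 0L) {
    scores <- vapply(seq_len(p), function(i) {
      sum(abs(w[grep(sprintf("^i%d->o\\d+$", i), names(w))]))
    }, 0)
  } else {
    h <- object$hidden
    W_ih <- matrix(0, p, h); W_ho <- matrix(0, h, S)
    for (i in seq_len(p)) for (j in seq_len(h)) {
      nm <- sprintf("i%d->h%d", i, j)
      if (nm %in% names(w)) W_ih[i, j] <- w[[nm]]
    }
    for (j in seq_len(h)) for (s in seq_len(S)) {
      nm <- sprintf("h%d->o%d", j, s)
      if (nm %in% names(w)) W_ho[j, s] <- w[[nm]]
    }
    contrib <- W_ih %*% W_ho      # p x S signed contributions
    scores <- rowSums(abs(contrib))
  }
  stats::setNames(scores, object$variables)
}

#' @rdname importance_scores
#' @export
importance_scores.rivpacs_sdm <- function(object, ...) {
  mm <- object$membership
  if (mm$method == "random_forest") {
    imp <- randomForest::importance(mm$fit)[, "MeanDecreaseGini"]
    return(imp)
  }
  X <- mm$training$X[, mm$variables, drop = FALSE]
  grp <- mm$training$labels
  n <- nrow(X); G <- nlevels(grp); p <- ncol(X)
  wilks <- function(cols) {
    Xv <- X[, cols, drop = FALSE]
    Tm <- stats::cov(Xv) * (n - 1)
    W <- matrix(0, length(cols), length(cols))
    for (g in levels(grp)) {
      Xg <- Xv[grp == g, , drop = FALSE]
      if (nrow(Xg) > 1L) W <- W + stats::cov(Xg) * (nrow(Xg) - 1)
    }
    det(W) / det(Tm)
  }
  lam_full <- wilks(seq_len(p))
  scores <- vapply(seq_len(p), function(j) {
    lam_red <- wilks(setdiff(seq_len(p), j))
    # F-to-remove from the partial Wilks' lambda
    ((n - G - p + 1) / (G - 1)) * (lam_red / lam_full - 1)
  }, 0)
  stats::setNames(pmax(scores, 0), colnames(X))
}

#' Convert importance scores to within-strategy ranks
#'
#' @param scores named numeric vector from [importance_scores()].
#' @return named integer ranks, 1 = most important; ties broken by
#'   score order then name (deterministic permutation of 1..k).
#' @export
importance_ranks <- function(scores) {
  if (!length(scores)) return(stats::setNames(integer(0), character(0)))
  ord <- order(-scores, names(scores))
  rk <- integer(length(scores))
  rk[ord] <- seq_along(scores)
  stats::setNames(rk, names(scores))
}

#' Average variable-importance ranks across strategies
#'
#' Each strategy contributes its within-strategy rank (1 = most
#' important) for the variables it retained; the average is taken over
#' the strategies that ranked a variable, and variables a strategy did
#' not retain stay absent (NA) rather than being penalized.
#'
#' @param ranks matrix or data frame, variables in rows, strategies in
#'   columns, NA where a strategy did not retain the variable.
#' @return data frame sorted by average rank: `variable`, the
#'   per-strategy ranks, `average`.
#' @export
aggregate_ranks <- function(ranks) {
  rk <- as.matrix(as.data.frame(ranks))
  storage.mode(rk) <- "double"
  avg <- rowMeans(rk, na.rm = TRUE)
  out <- data.frame(variable = rownames(rk), as.data.frame(rk),
                    average = avg, row.names = NULL, check.names = FALSE)
  out[order(out$average, out$variable), , drop = FALSE]
}

# ---- strategy comparison ---------------------------------------------------

#' One-way ANOVA with Tukey grouping letters across strategies
#'
#' @param values numeric vector of a per-unit evaluation metric (one
#'   unit = one species or one site).
#' @param strategy factor/character of the strategy each value belongs
#'   to (>= 2 strategies with >= 2 units each).
#' @param alpha significance level for the Tukey letters (default
#'   0.05).
#' @return list: `F`, `p`, `tukey` (pairwise table), `letters` (named
#'   character; strategies sharing a letter do not differ
#'   significantly), `degenerate` (TRUE when the data had no variance).
#' @export
compare_strategies <- function(values, strategy, alpha = 0.05) {
  strategy <- factor(strategy)
  keep <- !is.na(values)
  values <- values[keep]; strategy <- droplevels(strategy[keep])
  if (nlevels(strategy) < 2L) stop("need at least 2 strategies")
  if (any(table(strategy) < 2L)) stop("need at least 2 units per strategy")
  if (stats::var(values) == 0) {
    return(list(F = 0, p = NA_real_, tukey = NULL,
                letters = stats::setNames(rep("a", nlevels(strategy)),
                                          levels(strategy)),
                degenerate = TRUE))
  }
  fit <- stats::aov(values ~ strategy)
  tab <- summary(fit)[[1L]]
  tk <- stats::TukeyHSD(fit)$strategy
  # rows of the Tukey table follow combn() order: "lvl_j-lvl_i" for
  # every i < j (strategy names may themselves contain "-", so the
  # pairs are reconstructed rather than parsed from the row names)
  cmb <- utils::combn(levels(strategy), 2L)
  pmat <- matrix(1, nlevels(strategy), nlevels(strategy),
                 dimnames = list(levels(strategy), levels(strategy)))
  for (k in seq_len(ncol(cmb))) {
    pmat[cmb[1L, k], cmb[2L, k]] <- pmat[cmb[2L, k], cmb[1L, k]] <-
      tk[k, "p adj"]
  }
  list(F = tab[["F value"]][1L], p = tab[["Pr(>F)"]][1L], tukey = tk,
       letters = tukey_letters(pmat, tapply(values, strategy, mean), alpha),
       degenerate = FALSE)
}

# Insert-and-absorb letter assignment from a pairwise p-value matrix.
tukey_letters <- function(pmat, means, alpha) {
  grps <- names(sort(means, decreasing = TRUE))
  sets <- list()
  for (g in grps) {
    placed <- FALSE
    for (k in seq_along(sets)) {
      if (all(pmat[g, sets[[k]]] >= alpha)) {
        sets[[k]] <- c(sets[[k]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1L]] <- g
  }
  # absorb subsets
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i != j && keep[i] && keep[j] && all(sets[[i]] %in% sets[[j]]))
      keep[i] <- FALSE
  }
  sets <- sets[keep]
  letters_out <- stats::setNames(rep("", length(grps)), grps)
  for (k in seq_along(sets)) {
    for (g in sets[[k]])
      letters_out[g] <- paste0(letters_out[g], letters[k])
  }
  letters_out[names(means)]
}
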