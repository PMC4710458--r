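#' Configuration for the multi-response adaptive-splines model
#'
#' @param penalty generalized-cross-validation cost per basis function
#'   (default 2). Effective parameters are counted as
#'   `basis_count + penalty * (basis_count - 1)`.
#' @param penalty_grid candidate penalties compared by mean
#'   cross-validated per-species AUC when `select_penalty = TRUE`.
#' @param max_degree maximum interaction order (1 = additive, 2 = first
#'   order interactions; default 2).
#' @param max_basis cap on the number of basis functions grown in the
#'   forward pass (including the intercept).
#' @param max_knots candidate knots per variable (quantiles of the
#'   observed values).
#' @param cv_folds folds for penalty selection.
#' @param select_penalty run the penalty-grid cross-validation before
#'   the final fit (default FALSE: fit at `penalty` directly).
#' @param seed integer seed for fold assignment.
#' @return list of class `"mars_config"`.
#' @export
mars_config <- function(penalty = 2, penalty_grid = c(0.5, 1, 1.5, 2, 2.5),
                        max_degree = 2L, max_basis = 21L, max_knots = 15L,
                        cv_folds = 5L, select_penalty = FALSE, seed = 1L) {
  stopifnot(penalty > 0, max_degree %in% c(1L, 2L), max_basis >= 3L,
            max_knots >= 2L, cv_folds >= 2L)
  structure(list(penalty = penalty, penalty_grid = penalty_grid,
                 max_degree = as.integer(max_degree),
                 max_basis = as.integer(max_basis),
                 max_knots = as.integer(max_knots),
                 cv_folds = as.integer(cv_folds),
                 select_penalty = isTRUE(select_penalty),
                 seed = as.integer(seed)),
            class = "mars_config")
}

# ---- basis machinery -------------------------------------------------------
# A term is a list of hinge factors (var, knot, dir); the intercept is the
# empty term. All species share the one basis.

term_label <- function(term) {
  if (!length(term)) return("(intercept)")
  paste(vapply(term, function(f) {
    if (f$dir > 0) sprintf("h(%s-%.4g)", f$var, f$knot)
    else sprintf("h(%.4g-%s)", f$knot, f$var)
  }, ""), collapse = "*")
}

term_column <- function(term, X) {
  b <- rep(1, nrow(X))
  for (f in term) {
    x <- X[, f$var]
    b <- b * pmax(0, f$dir * (x - f$knot))
  }
  b
}

mars_basis <- function(terms, X) {
  B <- vapply(terms, function(tt) term_column(tt, X), numeric(nrow(X)))
  dim(B) <- c(nrow(X), length(terms))
  colnames(B) <- vapply(terms, term_label, "")
  B
}

fit_sse <- function(B, Y) {
  fit <- stats::lm.fit(B, Y)
  sum(fit$residuals^2)
}

mars_forward <- function(X, Y, max_degree = 2L, max_basis = 21L,
                         max_knots = 15L) {
  n <- nrow(X)
  knots <- lapply(seq_len(ncol(X)), function(j) {
    q <- unique(stats::quantile(X[, j], probs = seq(0.05, 0.95,
                                                    length.out = max_knots),
                                type = 7, names = FALSE))
    q
  })
  names(knots) <- colnames(X)
  terms <- list(list())            # intercept
  B <- mars_basis(terms, X)
  sse <- fit_sse(B, Y)
  while (length(terms) + 2L <= max_basis) {
    best <- NULL
    for (m in seq_along(terms)) {
      parent <- terms[[m]]
      if (length(parent) >= max_degree) next
      used <- vapply(parent, function(f) f$var, "")
      for (v in setdiff(colnames(X), used)) {
        xv <- X[, v]
        pb <- B[, m]
        for (k in knots[[v]]) {
          b1 <- pb * pmax(0, xv - k)
          b2 <- pb * pmax(0, k - xv)
          if (sum(b1^2) < 1e-10 && sum(b2^2) < 1e-10) next
          s <- fit_sse(cbind(B, b1, b2), Y)
          if (is.null(best) || s < best$sse - 1e-12)
            best <- list(sse = s, parent = m, var = v, knot = k)
        }
      }
    }
    if (is.null(best) || best$sse >= sse * (1 - 1e-6)) break
    parent <- terms[[best$parent]]
    t1 <- c(parent, list(list(var = best$var, knot = best$knot, dir = 1)))
    t2 <- c(parent, list(list(var = best$var, knot = best$knot, dir = -1)))
    terms <- c(terms, list(t1), list(t2))
    B <- mars_basis(terms, X)
    sse <- best$sse
  }
  list(terms = terms, B = B)
}

# GCV on the stacked multi-response regression: N = sites x species
# cells; each basis function costs one coefficient per species plus a
# shared knot cost of `penalty`. For a single response this is the
# standard effective-parameter count M + penalty * (M - 1).
mars_prune <- function(B, Y, terms, penalty) {
  N <- nrow(B) * ncol(Y)
  S <- ncol(Y)
  gcv <- function(cols) {
    M <- length(cols)
    C <- S * M + penalty * (M - 1)
    if (C >= N) return(Inf)
    (fit_sse(B[, cols, drop = FALSE], Y) / N) / (1 - C / N)^2
  }
  cols <- seq_len(ncol(B))
  best_cols <- cols
  best_gcv <- gcv(cols)
  while (length(cols) > 1L) {
    cand <- setdiff(cols, 1L)       # intercept never pruned
    g <- vapply(cand, function(cc) gcv(setdiff(cols, cc)), 0)
    drop <- cand[which.min(g)]
    cols <- setdiff(cols, drop)
    if (min(g) < best_gcv) {
      best_gcv <- min(g)
      best_cols <- cols
    }
  }
  sort(best_cols)
}

# Per-response logistic refits on the (shared) retained basis. A constant
# response keeps an intercept-only mapping equal to its prevalence.
mars_refit <- function(B, Y) {
  S <- ncol(Y)
  coefs <- matrix(0, ncol(B), S, dimnames = list(colnames(B), colnames(Y)))
  for (s in seq_len(S)) {
    y <- Y[, s]
    if (stats::var(y) == 0) {
      coefs[1L, s] <- stats::qlogis(min(max(mean(y), 1e-8), 1 - 1e-8))
      next
    }
    fit <- suppressWarnings(stats::glm.fit(B, y, family = stats::binomial()))
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    coefs[, s] <- cf
  }
  coefs
}

mars_fit_engine <- function(X, Y, cfg) {
  fw <- mars_forward(X, Y, cfg$max_degree, cfg$max_basis, cfg$max_knots)
  keep <- mars_prune(fw$B, Y, fw$terms, cfg$penalty)
  terms <- fw$terms[keep]
  B <- fw$B[, keep, drop = FALSE]
  coefs <- mars_refit(B, Y)
  list(terms = terms, coefficients = coefs, basis = B)
}

#' Fit the multi-response adaptive-splines model
#'
#' Grows paired hinge basis functions forward, choosing each split to
#' minimize the squared error summed over *all* species responses, so
#' that every species shares one basis ("predict and assemble
#' together"). The basis is then pruned backward by generalized cross
#' validation with a cost of `penalty` per basis function, and each
#' species gets a logistic regression refit on the retained basis, so
#' predictions are probabilities.
#'
#' With `select_penalty = TRUE` the penalty grid is first compared by
#' mean cross-validated per-species AUC and the winner used for the
#' final fit (the grid scores are kept in the returned
#' `selection_report`).
#'
#' @param assemblage an [assemblage_matrix()] (>= 2 species).
#' @param predictors a [predictor_table()] aligned with it.
#' @param config a [mars_config()].
#' @return object of class `"mars_sdm"`.
#' @export
mars_sdm <- function(assemblage, predictors, config = mars_config()) {
  if (ncol(assemblage) < 2L && config$select_penalty)
    stop("penalty selection needs at least 2 species")
  X <- unclass(predictors); storage.mode(X) <- "double"
  Y <- unclass(assemblage); storage.mode(Y) <- "double"
  if (nrow(X) != nrow(Y)) stop("assemblage and predictors are misaligned")
  report <- NULL
  penalty <- config$penalty
  if (config$select_penalty) {
    old <- local_seed(derive_seed(config$seed, "mars_cv"))
    folds <- sample(rep_len(seq_len(config$cv_folds), nrow(X)))
    restore_seed(old)
    scores <- matrix(NA_real_, length(config$penalty_grid), 1L)
    cvpred <- lapply(config$penalty_grid, function(p) matrix(NA_real_, nrow(X), ncol(Y)))
    for (f in seq_len(config$cv_folds)) {
      tr <- folds != f
      fw <- mars_forward(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                         config$max_degree, config$max_basis, config$max_knots)
      for (gi in seq_along(config$penalty_grid)) {
        cfg_g <- config; cfg_g$penalty <- config$penalty_grid[gi]
        keep <- mars_prune(fw$B, Y[tr, , drop = FALSE], fw$terms, cfg_g$penalty)
        coefs <- mars_refit(fw$B[, keep, drop = FALSE], Y[tr, , drop = FALSE])
        Bh <- mars_basis(fw$terms[keep], X[!tr, , drop = FALSE])
        cvpred[[gi]][!tr, ] <- stats::plogis(Bh %*% coefs)
      }
    }
    grid_auc <- vapply(cvpred, function(P) {
      aucs <- vapply(seq_len(ncol(Y)), function(s) auc_rank(Y[, s], P[, s]), 0)
      mean(aucs, na.rm = TRUE)
    }, 0)
    report <- data.frame(penalty = config$penalty_grid, mean_cv_auc = grid_auc)
    penalty <- config$penalty_grid[which.max(grid_auc)]
  }
  cfg <- config; cfg$penalty <- penalty
  fit <- mars_fit_engine(X, Y, cfg)
  structure(list(terms = fit$terms, coefficients = fit$coefficients,
                 penalty = penalty, selection_report = report,
                 variables = colnames(X), species = colnames(Y),
                 training = list(B = fit$basis, Y = Y),
                 config = config),
            class = c("mars_sdm", "stream_sdm"))
}

#' @export
print.mars_sdm <- function(x, ...) {
  cat(sprintf("Multi-response adaptive-splines model: %d species, %d basis functions (penalty %.2g)\n",
              length(x$species), length(x$terms), x$penalty))
  cat("  basis:", paste(vapply(x$terms, term_label, ""), collapse = ", "), "\n")
  if (!is.null(x$selection_report)) {
    cat("  penalty selection (mean CV AUC):\n")
    print(x$selection_report, row.names = FALSE)
  }
  invisible(x)
}

#' Predict occurrence probabilities from a fitted strategy
#'
#' @param object a fitted model.
#' @param newdata a [predictor_table()] (or matrix) containing the
#'   training variables.
#' @param ... unused.
#' @return site x species matrix of probabilities in `[0, 1]`.
#' @export
predict.mars_sdm <- function(object, newdata, ...) {
  X <- check_variables(newdata, object$variables)
  B <- mars_basis(object$terms, X)
  P <- stats::plogis(B %*% object$coefficients)
  rownames(P) <- rownames(X)
  P
}

# Shared guard: newdata must contain every training variable.
check_variables <- function(newdata, variables) {
  X <- unclass(newdata)
  X <- as.matrix(X)
  missing <- setdiff(variables, colnames(X))
  if (length(missing))
    stop("newdata is missing variables: ", paste(missing, collapse = ", "))
  X[, variables, drop = FALSE]
}

# Knots retained for a given variable (used by tests and importance).
mars_knots <- function(object, variable) {
  out <- numeric()
  for (term in object$terms)
    for (f in term) if (f$var == variable) out <- c(out, f$knot)
  unique(out)
}
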