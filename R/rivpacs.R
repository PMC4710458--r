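#' Sorensen dissimilarity between sites
#'
#' `d(i, j) = 1 - 2a / (2a + b + c)` where `a` is the number of species
#' shared by the two sites and `b`, `c` the numbers unique to each.
#' Two empty sites are assigned `d = 0` by convention (recorded in the
#' `empty_pairs` attribute) so that sites left empty by filtering remain
#' clusterable.
#'
#' @param m an [assemblage_matrix()] with >= 2 sites.
#' @return symmetric site x site matrix with zero diagonal, values in
#'   `[0, 1]`.
#' @export
sorensen_matrix <- function(m) {
  M <- unclass(m); storage.mode(M) <- "double"
  if (nrow(M) < 2L) stop("need at least 2 sites")
  A <- M %*% t(M)                       # shared presences
  r <- rowSums(M)
  denom <- outer(r, r, `+`)             # 2a + b + c
  d <- 1 - 2 * A / denom
  empty <- denom == 0
  d[empty] <- 0
  diag(d) <- 0
  dimnames(d) <- list(rownames(M), rownames(M))
  attr(d, "empty_pairs") <- sum(empty[upper.tri(empty)])
  d
}

#' Flexible-beta agglomerative clustering
#'
#' Agglomerative clustering under the Lance--Williams update with the
#' flexible-beta scheme. The default, size-weighted variant ("flexible
#' UPGMA") uses `alpha_i = (1 - beta) n_i / (n_i + n_j)`,
#' `alpha_j = (1 - beta) n_j / (n_i + n_j)`, `gamma = 0`; the
#' size-unweighted variant (`weighted = FALSE`) uses
#' `alpha_i = alpha_j = (1 - beta)/2`. Either way
#' `alpha_i + alpha_j + beta = 1`, which guarantees monotone
#' (non-inverting) merge heights. `beta = -0.6` is space-dilating and
#' favours evenly sized groups. Ties are broken towards the lowest
#' cluster index pair, making the tree deterministic.
#'
#' @param d symmetric dissimilarity matrix (or `dist`).
#' @param beta flexible-beta parameter (< 1; default -0.6).
#' @param weighted use cluster-size weights (default TRUE).
#' @return an object of class `"hclust"` (so [stats::cutree()],
#'   [stats::cophenetic()] and plotting work as usual).
#' @export
flexible_beta_cluster <- function(d, beta = -0.6, weighted = TRUE) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(isSymmetric(unname(d)), beta < 1)
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  D <- unname(d)
  size <- rep(1L, n)
  id <- -seq_len(n)                    # hclust merge encoding
  active <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- c(NA_integer_, NA_integer_); bd <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        if (D[i, j] < bd - 1e-12) { bd <- D[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- bd
    ni <- size[i]; nj <- size[j]
    if (weighted) {
      ai <- (1 - beta) * ni / (ni + nj)
      aj <- (1 - beta) * nj / (ni + nj)
    } else {
      ai <- aj <- (1 - beta) / 2
    }
    others <- setdiff(active, c(i, j))
    D[i, others] <- ai * D[i, others] + aj * D[j, others] + beta * bd
    D[others, i] <- D[i, others]
    size[i] <- ni + nj
    id[i] <- step
    active <- setdiff(active, j)
  }
  ord <- hclust_order(merge)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = if (weighted)
                   sprintf("flexible UPGMA (beta=%g)", beta)
                 else sprintf("flexible beta (unweighted, beta=%g)", beta),
                 dist.method = "sorensen", call = match.call()),
            class = "hclust")
}

# Leaf ordering compatible with the merge matrix (iterative expansion).
hclust_order <- function(merge) {
  n <- nrow(merge) + 1L
  expand <- function(k) {
    if (k < 0L) return(-k)
    c(expand(merge[k, 1L]), expand(merge[k, 2L]))
  }
  expand(n - 1L)
}

#' Cut a merge tree into assemblage groups
#'
#' Cuts the tree into `n_groups` groups, then merges any group smaller
#' than `min_group_size` into its nearest group by average cophenetic
#' dissimilarity (merges are recorded in the `merge_note` attribute).
#'
#' @param tree an `"hclust"` object from [flexible_beta_cluster()].
#' @param n_groups number of groups (default 6).
#' @param min_group_size smallest admissible group (default 2).
#' @return integer group label per site (named), labels contiguous from
#'   1.
#' @export
cut_groups <- function(tree, n_groups = 6L, min_group_size = 2L) {
  n <- length(tree$labels)
  if (n_groups > n) stop("cannot cut ", n, " sites into ", n_groups, " groups")
  labels <- stats::cutree(tree, k = n_groups)
  notes <- character()
  if (min_group_size > 1L && n_groups > 1L) {
    coph <- as.matrix(stats::cophenetic(tree))
    repeat {
      sizes <- table(labels)
      small <- names(sizes)[sizes < min_group_size]
      if (!length(small) || length(sizes) == 1L) break
      g <- small[1L]
      members <- names(labels)[labels == as.integer(g)]
      other_groups <- setdiff(names(sizes), g)
      avg <- vapply(other_groups, function(h) {
        mean(coph[members, names(labels)[labels == as.integer(h)], drop = FALSE])
      }, 0)
      target <- other_groups[which.min(avg)]
      notes <- c(notes, sprintf("group %s (n=%d) merged into group %s",
                                g, length(members), target))
      labels[labels == as.integer(g)] <- as.integer(target)
    }
  }
  relab <- match(labels, sort(unique(labels)))
  names(relab) <- names(labels)
  attr(relab, "merge_note") <- notes
  relab
}

#' Per-group species occurrence frequencies
#'
#' @param m an [assemblage_matrix()].
#' @param labels integer group label per site.
#' @return species x group matrix `f` with
#'   `f[s, g]` = occupied group-`g` sites / group size.
#' @export
group_frequencies <- function(m, labels) {
  M <- unclass(m)
  if (length(labels) != nrow(M)) stop("labels do not cover every site")
  groups <- sort(unique(labels))
  sizes <- table(factor(labels, levels = groups))
  if (any(sizes == 0)) stop("empty group")
  counts <- rowsum(M, group = factor(labels, levels = groups))
  f <- t(counts / as.vector(sizes))
  colnames(f) <- paste0("g", groups)
  f
}

#' Group-membership classifier
#'
#' Two classifiers predict the probability that a new site belongs to
#' each assemblage group from its environmental predictors:
#' \describe{
#'   \item{lda_stepwise_aic}{linear discriminant analysis (proportional
#'     priors) with backward stepwise variable elimination. Because
#'     classical discriminant analysis has no canonical AIC, the AIC is
#'     defined on the multinomial assignment likelihood of the posterior
#'     probabilities, with `(G - 1)(p + 1)` parameters for `p` retained
#'     variables and `G` groups; the variable whose removal most
#'     improves AIC is dropped until no removal improves it.}
#'   \item{random_forest}{a random-forest classifier; class votes give
#'     the membership probabilities.}
#' }
#' Membership probability rows are normalized to sum to one.
#'
#' @param X a [predictor_table()] (or matrix) of training sites.
#' @param labels group label per site.
#' @param method classifier.
#' @param ntree random-forest trees.
#' @param seed integer seed (random forest).
#' @return object of class `"membership_model"`.
#' @export
fit_membership <- function(X, labels,
                           method = c("lda_stepwise_aic", "random_forest"),
                           ntree = 500L, seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(unclass(X)); storage.mode(X) <- "double"
  grp <- factor(labels)
  if (nlevels(grp) < 2L) stop("need at least 2 groups")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance variable(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (method == "lda_stepwise_aic") {
    G <- nlevels(grp)
    aic_of <- function(vars) {
      fit <- suppressWarnings(MASS::lda(X[, vars, drop = FALSE], grouping = grp))
      post <- stats::predict(fit, X[, vars, drop = FALSE])$posterior
      ll <- sum(log(pmax(post[cbind(seq_along(grp), as.integer(grp))], 1e-12)))
      -2 * ll + 2 * (G - 1) * (length(vars) + 1)
    }
    vars <- colnames(X)
    current <- aic_of(vars)
    step_log <- data.frame(removed = NA_character_, aic = current)
    while (length(vars) > 1L) {
      cand <- vapply(vars, function(v) aic_of(setdiff(vars, v)), 0)
      if (min(cand) >= current) break
      drop <- vars[which.min(cand)]
      vars <- setdiff(vars, drop)
      current <- min(cand)
      step_log <- rbind(step_log, data.frame(removed = drop, aic = current))
    }
    fit <- suppressWarnings(MASS::lda(X[, vars, drop = FALSE], grouping = grp))
    structure(list(method = method, fit = fit, variables = vars,
                   groups = levels(grp), step_log = step_log,
                   training = list(X = X, labels = grp)),
              class = "membership_model")
  } else {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
    fit <- randomForest::randomForest(X, grp, ntree = ntree)
    structure(list(method = method, fit = fit, variables = colnames(X),
                   groups = levels(grp), training = list(X = X, labels = grp)),
              class = "membership_model")
  }
}

#' Membership probabilities for new sites
#'
#' @param mm a fitted [fit_membership()] model.
#' @param X predictors for the new sites.
#' @return site x group probability matrix, rows summing to 1.
#' @export
predict_membership <- function(mm, X) {
  X <- check_variables(X, mm$variables)
  P <- if (mm$method == "lda_stepwise_aic") {
    stats::predict(mm$fit, X)$posterior
  } else {
    stats::predict(mm$fit, X, type = "prob")
  }
  P <- P[, mm$groups, drop = FALSE]
  P / rowSums(P)
}

#' Configuration for the community-classification strategy
#'
#' @param beta flexible-beta clustering parameter (default -0.6).
#' @param n_groups number of assemblage groups (default 6).
#' @param min_group_size smallest admissible group (default 2).
#' @param classifier `"lda_stepwise_aic"` (discriminant analysis) or
#'   `"random_forest"`.
#' @param weighted size-weighted Lance--Williams update (default TRUE).
#' @param ntree random-forest trees.
#' @param seed integer seed.
#' @return list of class `"rivpacs_config"`.
#' @export
rivpacs_config <- function(beta = -0.6, n_groups = 6L, min_group_size = 2L,
                           classifier = c("lda_stepwise_aic", "random_forest"),
                           weighted = TRUE, ntree = 500L, seed = 1L) {
  stopifnot(beta < 1, n_groups >= 2L)
  structure(list(beta = beta, n_groups = as.integer(n_groups),
                 min_group_size = as.integer(min_group_size),
                 classifier = match.arg(classifier), weighted = weighted,
                 ntree = as.integer(ntree), seed = as.integer(seed)),
            class = "rivpacs_config")
}

#' Fit a RIVPACS-style community-classification model
#'
#' Classifies the training biota into assemblage groups (Sorensen
#' dissimilarity, flexible-beta clustering, fixed-height cut), fits a
#' group-membership classifier on the environmental predictors, and
#' predicts each species at a new site as its membership-weighted
#' average group frequency:
#' `p_s(x) = sum_g P(g | x) * f[s, g]`.
#'
#' @param assemblage an [assemblage_matrix()].
#' @param predictors a [predictor_table()] aligned with it.
#' @param config a [rivpacs_config()].
#' @return object of class `"rivpacs_sdm"`.
#' @export
rivpacs_sdm <- function(assemblage, predictors, config = rivpacs_config()) {
  if (nrow(assemblage) != nrow(predictors))
    stop("assemblage and predictors are misaligned")
  d <- sorensen_matrix(assemblage)
  tree <- flexible_beta_cluster(d, beta = config$beta,
                                weighted = config$weighted)
  labels <- cut_groups(tree, config$n_groups, config$min_group_size)
  f <- group_frequencies(assemblage, labels)
  mm <- fit_membership(predictors, labels, method = config$classifier,
                       ntree = config$ntree, seed = config$seed)
  structure(list(tree = tree, labels = labels, frequencies = f,
                 membership = mm, variables = mm$variables,
                 config = config),
            class = c("rivpacs_sdm", "stream_sdm"))
}

#' @export
print.rivpacs_sdm <- function(x, ...) {
  cat(sprintf("RIVPACS community model: %d groups (%s classifier), %d species\n",
              ncol(x$frequencies),
              if (x$membership$method == "lda_stepwise_aic") "discriminant"
              else "random-forest",
              nrow(x$frequencies)))
  cat("  group sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname predict.mars_sdm
#' @export
predict.rivpacs_sdm <- function(object, newdata, ...) {
  P <- predict_membership(object$membership, newdata)
  out <- P %*% t(object$frequencies)
  rownames(out) <- rownames(P)
  out
}

#' Species predictable at a probability threshold
#'
#' Species whose maximum within-group frequency exceeds the threshold:
#' the only taxa a community-classification model can contribute to the
#' expected assemblage at that threshold (under a degenerate, one-group
#' membership).
#'
#' @param f species x group frequency matrix (or a fitted
#'   [rivpacs_sdm()]).
#' @param threshold probability cut-off (default 0.5).
#' @return character vector of species ids (its length is the
#'   predictable-taxa count).
#' @export
predictable_taxa <- function(f, threshold = 0.5) {
  if (inherits(f, "rivpacs_sdm")) f <- f$frequencies
  rownames(f)[apply(f, 1L, max) > threshold]
}

#' Silhouette widths for a candidate grouping
#'
#' A descriptive aid for choosing the number of assemblage groups: the
#' silhouette width of site i is `(b_i - a_i) / max(a_i, b_i)` with
#' `a_i` the mean dissimilarity to its own group and `b_i` the smallest
#' mean dissimilarity to another group. The report assists the choice
#' of `n_groups`; it never decides it.
#'
#' @param d symmetric dissimilarity matrix (e.g. [sorensen_matrix()]).
#' @param labels group label per site.
#' @return data frame with per-site widths plus a `mean_width`
#'   attribute.
#' @export
silhouette_widths <- function(d, labels) {
  d <- as.matrix(d)
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("need at least 2 groups")
  w <- vapply(seq_along(labels), function(i) {
    own <- which(labels == labels[i]); own <- setdiff(own, i)
    a <- if (length(own)) mean(d[i, own]) else 0
    b <- min(vapply(setdiff(groups, labels[i]), function(g)
      mean(d[i, labels == g]), 0))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
  out <- data.frame(site = rownames(d), group = labels, width = w,
                    row.names = NULL)
  attr(out, "mean_width") <- mean(w)
  out
}
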