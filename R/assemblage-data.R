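#' Site-by-species presence-absence matrix
#'
#' Constructs the binary occurrence table that is the response for every
#' modelling strategy in the package. Rows are sites, columns species.
#'
#' @param x a matrix or data frame coercible to a numeric matrix with
#'   values in \{0, 1\}.
#' @param site_ids,species_ids optional identifiers; default to the
#'   dimnames of `x`, or `site1..n` / `sp1..m` when absent.
#' @return an integer matrix of class `"assemblage_matrix"` with unique
#'   row (site) and column (species) names.
#' @examples
#' m <- assemblage_matrix(rbind(a = c(1, 0), b = c(0, 1)))
#' prevalence(m)
#' @export
assemblage_matrix <- function(x, site_ids = NULL, species_ids = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("an assemblage matrix needs at least one site and one species")
  storage.mode(x) <- "double"
  bad <- which(!(x %in% c(0, 1)) | is.na(x))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(x)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(x)) + 1L
    stop(sprintf("non-binary occurrence value %s at site row %d, species column %d",
                 format(x[bad[1L]]), i, j))
  }
  storage.mode(x) <- "integer"
  if (!is.null(site_ids)) rownames(x) <- site_ids
  if (is.null(rownames(x))) rownames(x) <- paste0("site", seq_len(nrow(x)))
  if (!is.null(species_ids)) colnames(x) <- species_ids
  if (is.null(colnames(x))) colnames(x) <- paste0("sp", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)))
    stop("duplicate site id: ", rownames(x)[duplicated(rownames(x))][1L])
  if (anyDuplicated(colnames(x)))
    stop("duplicate species id: ", colnames(x)[duplicated(colnames(x))][1L])
  structure(x, class = c("assemblage_matrix", class(matrix())))
}

#' @export
print.assemblage_matrix <- function(x, ...) {
  cat(sprintf("Assemblage matrix: %d sites x %d species (%.1f%% occupancy)\n",
              nrow(x), ncol(x), 100 * mean(x)))
  invisible(x)
}

#' Site-by-variable environmental predictor table
#'
#' @param x numeric matrix or data frame, sites in rows, predictors in
#'   columns. Missing values are not allowed: predictors are consumed as
#'   prepared upstream.
#' @param site_ids,variable_ids optional identifiers (defaults as in
#'   [assemblage_matrix()]).
#' @return a numeric matrix of class `"predictor_table"` carrying a
#'   `transform_log` attribute (a list recording per-variable transforms
#'   applied by [transform_predictors()]).
#' @export
predictor_table <- function(x, site_ids = NULL, variable_ids = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    idx <- which(is.na(x))[1L]
    stop(sprintf("missing predictor value at row %d, column %d",
                 ((idx - 1L) %% nrow(x)) + 1L, ((idx - 1L) %/% nrow(x)) + 1L))
  }
  if (!is.null(site_ids)) rownames(x) <- site_ids
  if (is.null(rownames(x))) rownames(x) <- paste0("site", seq_len(nrow(x)))
  if (!is.null(variable_ids)) colnames(x) <- variable_ids
  if (is.null(colnames(x))) colnames(x) <- paste0("env", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)))
    stop("duplicate site id: ", rownames(x)[duplicated(rownames(x))][1L])
  if (anyDuplicated(colnames(x)))
    stop("duplicate variable id: ", colnames(x)[duplicated(colnames(x))][1L])
  if (is.null(attr(x, "transform_log"))) attr(x, "transform_log") <- list()
  structure(x, class = c("predictor_table", class(matrix())))
}

#' @export
print.predictor_table <- function(x, ...) {
  cat(sprintf("Predictor table: %d sites x %d variables\n", nrow(x), ncol(x)))
  tl <- attr(x, "transform_log")
  if (length(tl))
    cat("  transformed:", paste(names(tl), collapse = ", "), "\n")
  invisible(x)
}

#' Bundle an assemblage with its predictors under a dataset role
#'
#' Datasets play one of five roles in the evaluation design: `training`
#' (model calibration), and the four external evaluation roles `space`
#' (spatial holdout), `season` (other sampling season), `time`
#' (repeated visits over years) and `method` (different sampling
#' protocol). Only `time` bundles may contain repeated rows per site,
#' distinguished by `sample_labels`.
#'
#' @param assemblage an [assemblage_matrix()].
#' @param predictors a [predictor_table()] with rows aligned 1:1 to the
#'   assemblage rows.
#' @param role one of `"training"`, `"space"`, `"season"`, `"time"`,
#'   `"method"`.
#' @param sample_labels optional per-row occasion identifiers (required
#'   when a site appears more than once).
#' @param site_ids optional per-row site identifiers; defaults to the
#'   assemblage row names. For `time` bundles rows of the same site share
#'   a site id.
#' @return a list of class `"dataset_bundle"`.
#' @export
dataset_bundle <- function(assemblage, predictors,
                           role = c("training", "space", "season", "time", "method"),
                           sample_labels = NULL, site_ids = NULL) {
  role <- match.arg(role)
  if (nrow(assemblage) != nrow(predictors))
    stop("assemblage and predictor tables have different numbers of rows")
  if (is.null(site_ids)) site_ids <- rownames(assemblage)
  if (anyDuplicated(site_ids) && role != "time")
    stop("repeated-visit rows (duplicate site ids) are only allowed for role = 'time'")
  structure(list(role = role, assemblage = assemblage, predictors = predictors,
                 site_ids = site_ids, sample_labels = sample_labels),
            class = "dataset_bundle")
}

#' @export
print.dataset_bundle <- function(x, ...) {
  cat(sprintf("<dataset_bundle role=%s> %d rows (%d sites), %d species, %d predictors\n",
              x$role, nrow(x$assemblage), length(unique(x$site_ids)),
              ncol(x$assemblage), ncol(x$predictors)))
  invisible(x)
}

#' Data-preparation configuration
#'
#' @param exclusion_list species identifiers to drop a priori (e.g. alien
#'   species and estuarine vagrants).
#' @param min_occurrences minimum number of occupied sites for a species
#'   to be retained (default 2: singletons cannot be modelled by every
#'   strategy).
#' @param r_threshold absolute Pearson correlation above which one member
#'   of a predictor pair is dropped (default 0.8).
#' @param priority_order optional character vector of variable ids, most
#'   preferred first; used to break collinearity ties. Variables absent
#'   from it rank below all listed ones.
#' @return a list of class `"filter_config"`.
#' @export
filter_config <- function(exclusion_list = character(), min_occurrences = 2L,
                          r_threshold = 0.8, priority_order = NULL) {
  stopifnot(min_occurrences >= 1L, r_threshold > 0, r_threshold <= 1)
  structure(list(exclusion_list = as.character(exclusion_list),
                 min_occurrences = as.integer(min_occurrences),
                 r_threshold = r_threshold,
                 priority_order = priority_order),
            class = "filter_config")
}

#' Read / write assemblage and predictor tables as CSV
#'
#' Comma-separated, UTF-8, header row required, first column the site
#' identifier. `read_assemblage()` rejects non-binary cells with an error
#' naming the offending row and column.
#'
#' @param path file path.
#' @return `read_assemblage()` an [assemblage_matrix()];
#'   `read_predictors()` a [predictor_table()].
#' @export
read_assemblage <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a site-id column plus at least one species column")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate site id in ", path, ": ",
                               ids[duplicated(ids)][1L])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  bad <- which(!(vals %in% c(0, 1)) | is.na(vals))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(vals)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(vals)) + 1L
    stop(sprintf("non-binary value %s in %s at row '%s', column '%s'",
                 format(df[i, j + 1L]), path, ids[i], colnames(vals)[j]))
  }
  assemblage_matrix(vals, site_ids = ids)
}

#' @rdname read_assemblage
#' @param m table to write.
#' @export
write_assemblage <- function(m, path) {
  df <- data.frame(site = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_assemblage
#' @export
read_predictors <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a site-id column plus at least one variable column")
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  predictor_table(vals, site_ids = ids)
}

#' @rdname read_assemblage
#' @export
write_predictors <- function(m, path) {
  df <- data.frame(site = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Taxonomic filtering of the response matrix
#'
#' Drops species on an a priori exclusion list and species occurring at
#' fewer than `min_occurrences` sites. Sites are never dropped, even if
#' left empty (empty sites remain scoreable: O may be 0).
#'
#' @param m an [assemblage_matrix()].
#' @param cfg a [filter_config()].
#' @return the filtered matrix, with a `filter_report` attribute: a data
#'   frame of dropped (or noted) species and the reason.
#' @export
filter_taxa <- function(m, cfg = filter_config()) {
  report <- data.frame(species = character(), reason = character(),
                       stringsAsFactors = FALSE)
  excl <- intersect(cfg$exclusion_list, colnames(m))
  missing_excl <- setdiff(cfg$exclusion_list, colnames(m))
  if (length(missing_excl))
    report <- rbind(report, data.frame(species = missing_excl,
                                       reason = "excluded (not present; no-op)"))
  if (length(excl))
    report <- rbind(report, data.frame(species = excl, reason = "excluded a priori"))
  keep <- setdiff(colnames(m), excl)
  counts <- colSums(m[, keep, drop = FALSE])
  rare <- keep[counts < cfg$min_occurrences]
  if (length(rare))
    report <- rbind(report, data.frame(
      species = rare,
      reason = sprintf("fewer than %d occurrences", cfg$min_occurrences)))
  keep <- setdiff(keep, rare)
  if (!length(keep)) stop("all species removed by filtering")
  out <- assemblage_matrix(unclass(m)[, keep, drop = FALSE])
  attr(out, "filter_report") <- report
  out
}

#' Species prevalence
#'
#' @param m an [assemblage_matrix()].
#' @return named numeric vector: fraction of sites occupied per species.
#' @export
prevalence <- function(m) colMeans(unclass(m))

#' Column-wise predictor transforms
#'
#' Applies the usual distributional transforms ahead of methods that
#' assume approximate normality (e.g. the discriminant-analysis
#' classifier). Supported transforms: `"identity"`, `"log10"` (as
#' log10(x + c)), `"sqrt"`, `"asin_sqrt"` (arcsine square root, for
#' proportions). The applied transform and offset are recorded in the
#' table's `transform_log` so values can be back-transformed for
#' reporting.
#'
#' @param x a [predictor_table()].
#' @param transforms named character vector, names = variable ids.
#' @param offset constant c for the log10 transform (default 1).
#' @return the transformed [predictor_table()].
#' @export
transform_predictors <- function(x, transforms, offset = 1) {
  tl <- attr(x, "transform_log")
  unknown <- setdiff(names(transforms), colnames(x))
  if (length(unknown)) stop("unknown variable in transform spec: ", unknown[1L])
  out <- unclass(x)
  for (v in names(transforms)) {
    tr <- match.arg(transforms[[v]], c("identity", "log10", "sqrt", "asin_sqrt"))
    col <- out[, v]
    val <- switch(tr,
      identity = col,
      log10 = {
        if (any(col + offset <= 0))
          stop(sprintf("log10 domain violation for variable '%s' at site '%s'",
                       v, rownames(x)[which(col + offset <= 0)[1L]]))
        log10(col + offset)
      },
      sqrt = {
        if (any(col < 0))
          stop(sprintf("sqrt domain violation for variable '%s' at site '%s'",
                       v, rownames(x)[which(col < 0)[1L]]))
        sqrt(col)
      },
      asin_sqrt = {
        if (any(col < 0 | col > 1))
          stop(sprintf("arcsine-sqrt domain violation for variable '%s' at site '%s'",
                       v, rownames(x)[which(col < 0 | col > 1)[1L]]))
        asin(sqrt(col))
      })
    out[, v] <- val
    if (tr != "identity") tl[[v]] <- list(transform = tr, offset = offset)
  }
  out <- predictor_table(out)
  attr(out, "transform_log") <- tl
  out
}

#' Invert recorded predictor transforms
#'
#' @param x a transformed [predictor_table()].
#' @return the table on the original measurement scale.
#' @export
inverse_transform_predictors <- function(x) {
  tl <- attr(x, "transform_log")
  out <- unclass(x)
  for (v in names(tl)) {
    rec <- tl[[v]]
    out[, v] <- switch(rec$transform,
                       log10 = 10^out[, v] - rec$offset,
                       sqrt = out[, v]^2,
                       asin_sqrt = sin(out[, v])^2)
  }
  res <- predictor_table(out)
  attr(res, "transform_log") <- list()
  res
}

#' Collinearity screen on the predictor table
#'
#' Repeatedly drops one member of the predictor pair with the largest
#' absolute Pearson correlation above `r_threshold` until no pair
#' violates it. The member dropped is the one lower in
#' `priority_order`; with no order given, the member with the larger
#' mean absolute correlation with all other variables (a deterministic
#' stand-in for the expert choice the screen would otherwise need).
#' Zero-variance columns are dropped up front with a report note, not an
#' error.
#'
#' @param x a [predictor_table()] with at least 2 variables and 3 sites.
#' @param cfg a [filter_config()]; only `r_threshold` and
#'   `priority_order` are used.
#' @return the screened table with a `screen_report` attribute: data
#'   frame of dropped variables, the partner that triggered each drop,
#'   and the offending correlation.
#' @export
screen_collinear <- function(x, cfg = filter_config()) {
  if (ncol(x) < 2L) stop("need at least 2 variables to screen")
  if (nrow(x) < 3L) stop("need at least 3 sites to estimate correlations")
  report <- data.frame(dropped = character(), partner = character(),
                       r = numeric(), stringsAsFactors = FALSE)
  vals <- unclass(x)
  sds <- apply(vals, 2L, stats::sd)
  if (any(sds == 0)) {
    zv <- colnames(vals)[sds == 0]
    report <- rbind(report, data.frame(dropped = zv, partner = NA_character_,
                                       r = NA_real_))
    vals <- vals[, sds > 0, drop = FALSE]
    if (ncol(vals) < 2L) {
      out <- predictor_table(vals)
      attr(out, "transform_log") <- attr(x, "transform_log")
      attr(out, "screen_report") <- report
      return(out)
    }
  }
  rank_of <- function(v) {
    if (is.null(cfg$priority_order)) return(NA_integer_)
    i <- match(v, cfg$priority_order)
    if (is.na(i)) length(cfg$priority_order) + 1L else i
  }
  repeat {
    cm <- abs(stats::cor(vals))
    diag(cm) <- 0
    if (max(cm) <= cfg$r_threshold) break
    idx <- which(cm == max(cm), arr.ind = TRUE)[1L, ]
    v1 <- colnames(vals)[idx[1L]]; v2 <- colnames(vals)[idx[2L]]
    if (!is.null(cfg$priority_order)) {
      drop <- if (rank_of(v1) > rank_of(v2)) v1 else v2
    } else {
      drop <- if (mean(cm[, v1]) >= mean(cm[, v2])) v1 else v2
    }
    partner <- setdiff(c(v1, v2), drop)
    report <- rbind(report, data.frame(dropped = drop, partner = partner,
                                       r = cm[v1, v2]))
    vals <- vals[, setdiff(colnames(vals), drop), drop = FALSE]
    if (ncol(vals) < 2L) break
  }
  out <- predictor_table(vals)
  attr(out, "transform_log") <- attr(x, "transform_log")
  attr(out, "screen_report") <- report
  out
}

#' Random site-level training/holdout split
#'
#' Splits a bundle into a training bundle and a spatial-holdout bundle.
#' The split is by site, so repeated-visit rows always travel together.
#' The training side receives `ceiling(fraction * n_sites)` sites, so an
#' 80% split of 128 sites yields 103 training and 25 holdout sites.
#'
#' @param bundle a [dataset_bundle()].
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed; the split is reproducible per seed.
#' @return list with elements `training` and `holdout`, both
#'   [dataset_bundle()]s (holdout role = `"space"`).
#' @export
split_sites <- function(bundle, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  sites <- unique(bundle$site_ids)
  n_train <- as.integer(ceiling(fraction * length(sites)))
  if (n_train == 0L || n_train == length(sites))
    stop("fraction yields an empty partition")
  old <- local_seed(seed)
  train_sites <- sort(sample(sites, n_train))
  restore_seed(old)
  take <- function(rows, role) {
    pred <- predictor_table(unclass(bundle$predictors)[rows, , drop = FALSE])
    Z <- attr(bundle$predictors, "latent_axes")
    if (!is.null(Z)) attr(pred, "latent_axes") <- Z[rows, , drop = FALSE]
    dataset_bundle(
      assemblage_matrix(unclass(bundle$assemblage)[rows, , drop = FALSE]),
      pred,
      # repeated-visit rows keep their role (duplicate site ids are
      # only legal under role = "time")
      role = if (bundle$role == "time") "time" else role,
      sample_labels = bundle$sample_labels[rows],
      site_ids = bundle$site_ids[rows])
  }
  in_train <- bundle$site_ids %in% train_sites
  list(training = take(which(in_train), "training"),
       holdout = take(which(!in_train), "space"))
}

# Seed hygiene: set a local seed, hand back the previous RNG state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# Deterministic fan-out of one user seed into per-stage seeds (kept
# below 2^31 - 1).
derive_seed <- function(seed, stage) {
  (as.double(seed) * 48271 + sum(utf8ToInt(as.character(stage)))) %% 2147483647
}
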