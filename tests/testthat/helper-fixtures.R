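# Shared fixtures, built in code.

# Tiny assemblage with known counts.
tiny_assemblage <- function() {
  assemblage_matrix(rbind(
    s1 = c(1, 1, 0),
    s2 = c(1, 0, 0),
    s3 = c(0, 1, 0),
    s4 = c(1, 0, 0)),
    species_ids = c("spA", "spB", "spC"))
}

# An easy, low-noise two-gradient system: six informative predictors,
# strong loadings, used wherever a strategy must demonstrably recover
# the niche structure.
easy_system <- function(n_sites = 300, seed = 11) {
  sp <- gradient_spec(n_sites = n_sites, n_variables = 6, latent_axes = 2,
                      loadings = cbind(c(1, 0, 0.9, 0.5, 0.2, 0),
                                       c(0, 1, 0.1, 0.5, 0.2, 0)),
                      noise_sd = 0.1)
  simulate_bundle(sp, default_species_pool(), seed = seed)
}

# Independent O(n^2) pair-counting AUC oracle.
auc_pairs <- function(obs, p) {
  pos <- p[obs == 1]; neg <- p[obs == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Independent naive Lance-Williams agglomeration: recomputes the full
# distance matrix from scratch at every step.
naive_flexible_cluster <- function(d, beta = -0.6, weighted = TRUE) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  D <- d
  heights <- numeric(0)
  merges <- list()
  sizes <- rep(1, n)
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- c(NA, NA); bd <- Inf
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
      if (D[i, j] < bd - 1e-12) { bd <- D[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bd)
    merges[[length(merges) + 1L]] <- sort(c(clusters[[i]][1], clusters[[j]][1]))
    ni <- sizes[i]; nj <- sizes[j]
    if (weighted) {
      ai <- (1 - beta) * ni / (ni + nj); aj <- (1 - beta) * nj / (ni + nj)
    } else ai <- aj <- (1 - beta) / 2
    newrow <- ai * D[i, ] + aj * D[j, ] + beta * bd
    D[i, ] <- newrow; D[, i] <- newrow; D[i, i] <- 0
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    sizes[i] <- ni + nj
    keep <- setdiff(seq_len(k), j)
    clusters <- clusters[keep]
    D <- D[keep, keep, drop = FALSE]
    sizes <- sizes[keep]
  }
  heights
}

expect_no_na <- function(x) expect_false(anyNA(x))
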