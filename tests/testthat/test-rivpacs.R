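test_that("Sorensen dissimilarity matches hand arithmetic and vegan", {
  m <- assemblage_matrix(rbind(a = c(1, 1, 0), b = c(1, 0, 1)))
  d <- sorensen_matrix(m)
  expect_equal(d["a", "b"], 0.5)   # a=1, b=1, c=1 -> 1 - 2/4

  ident <- assemblage_matrix(rbind(x = c(1, 0, 1), y = c(1, 0, 1)))
  expect_equal(sorensen_matrix(ident)["x", "y"], 0)

  disj <- assemblage_matrix(rbind(x = c(1, 1, 0, 0), y = c(0, 0, 1, 1)))
  expect_equal(sorensen_matrix(disj)["x", "y"], 1)

  # empty-site convention
  em <- assemblage_matrix(rbind(x = c(0, 0), y = c(0, 0), z = c(1, 0)))
  dm <- sorensen_matrix(em)
  expect_equal(dm["x", "y"], 0)
  expect_equal(attr(dm, "empty_pairs"), 1L)

  skip_if_not_installed("vegan")
  set.seed(2)
  mm <- assemblage_matrix(matrix(rbinom(80, 1, 0.4), 8, 10))
  ours <- sorensen_matrix(mm)
  ref <- as.matrix(vegan::vegdist(unclass(mm), method = "bray", binary = TRUE))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("flexible-beta clustering reproduces the hand-computed update", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 0.1
  d["A", "C"] <- d["C", "A"] <- 0.9
  d["B", "C"] <- d["C", "B"] <- 0.8
  tree <- flexible_beta_cluster(d, beta = -0.6)
  expect_equal(tree$height[1], 0.1)
  # alpha_i = alpha_j = (1 - beta)/2 = 0.8 for equal singleton sizes:
  # d(AB, C) = 0.8 * 0.9 + 0.8 * 0.8 + (-0.6) * 0.1 = 1.30
  # (the space-dilating beta pushes heights above the input range)
  expect_equal(tree$height[2], 1.30)
  expect_equal(tree$merge[1, ], c(-2L, -1L))
})

test_that("merge heights never invert and the tree matches a naive oracle", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(4:7, 1)
    m <- matrix(rbinom(n * 12, 1, 0.5), n, 12)
    rownames(m) <- paste0("s", seq_len(n))
    m[rowSums(m) == 0, 1] <- 1
    d <- sorensen_matrix(assemblage_matrix(m))
    for (w in c(TRUE, FALSE)) {
      tree <- flexible_beta_cluster(d, beta = -0.6, weighted = w)
      expect_true(all(diff(tree$height) >= -1e-12))
      expect_equal(tree$height,
                   naive_flexible_cluster(d, beta = -0.6, weighted = w),
                   tolerance = 1e-12)
    }
  }
})

test_that("equidistant points cluster deterministically under the tie rule", {
  d <- matrix(0.5, 4, 4); diag(d) <- 0
  dimnames(d) <- list(letters[1:4], letters[1:4])
  t1 <- flexible_beta_cluster(d)
  t2 <- flexible_beta_cluster(d)
  expect_identical(t1$merge, t2$merge)
  expect_equal(t1$merge[1, ], c(-2L, -1L))  # lowest index pair first
})

test_that("cutting the tree recovers planted structure and respects bounds", {
  # two well-separated blobs
  blob <- rbind(matrix(rbinom(60, 1, c(rep(0.95, 6), rep(0.05, 6))), 10, 12,
                       byrow = TRUE),
                matrix(rbinom(60, 1, c(rep(0.05, 6), rep(0.95, 6))), 10, 12,
                       byrow = TRUE))
  rownames(blob) <- paste0("s", 1:20)
  set.seed(3)
  blob[rowSums(blob) == 0, 1] <- 1
  tree <- flexible_beta_cluster(sorensen_matrix(assemblage_matrix(blob)))
  lab <- cut_groups(tree, n_groups = 2, min_group_size = 2)
  expect_equal(length(unique(lab[1:10])), 1L)
  expect_equal(length(unique(lab[11:20])), 1L)
  expect_false(lab[1] == lab[20])

  # singleton and single-group cuts
  m <- assemblage_matrix(matrix(rbinom(60, 1, 0.5), 6, 10))
  tr <- flexible_beta_cluster(sorensen_matrix(m))
  expect_length(unique(cut_groups(tr, n_groups = 6, min_group_size = 1)), 6L)
  expect_length(unique(cut_groups(tr, n_groups = 1, min_group_size = 1)), 1L)
  expect_error(cut_groups(tr, n_groups = 10), "cannot cut")

  # undersized groups get merged and logged
  lab2 <- cut_groups(tr, n_groups = 5, min_group_size = 3)
  expect_true(all(table(lab2) >= 3 | length(unique(lab2)) == 1))
})

test_that("group frequencies are exact occupancy fractions", {
  m <- assemblage_matrix(rbind(s1 = c(1, 0), s2 = c(1, 1)))
  f <- group_frequencies(m, c(1, 1))
  expect_equal(unname(f[, 1]), c(1.0, 0.5))

  m2 <- assemblage_matrix(rbind(s1 = c(1, 0), s2 = c(0, 0), s3 = c(1, 0),
                                s4 = c(0, 0)))
  f2 <- group_frequencies(m2, c(1, 1, 2, 2))
  expect_equal(unname(f2["sp2", ]), c(0, 0))
  # brute-force recount
  for (g in 1:2) {
    rows <- which(c(1, 1, 2, 2) == g)
    expect_equal(unname(f2[, g]),
                 unname(colSums(unclass(m2)[rows, , drop = FALSE]) / length(rows)))
  }
})

test_that("membership models return normalized probabilities and select signal", {
  set.seed(50)
  n <- 90
  lab <- rep(1:3, each = n / 3)
  X <- cbind(signal = lab * 2 + rnorm(n, sd = 0.3),
             n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n), n4 = rnorm(n))
  lda_fit <- fit_membership(X, lab, method = "lda_stepwise_aic")
  expect_true("signal" %in% lda_fit$variables)
  expect_false(all(c("n1", "n2", "n3", "n4") %in% lda_fit$variables))

  rf_fit <- fit_membership(X, lab, method = "random_forest", seed = 4)
  newX <- cbind(signal = runif(100, 0, 8), n1 = rnorm(100), n2 = rnorm(100),
                n3 = rnorm(100), n4 = rnorm(100))
  for (mm in list(lda_fit, rf_fit)) {
    P <- predict_membership(mm, newX)
    expect_equal(unname(rowSums(P)), rep(1, 100), tolerance = 1e-9)
  }

  rf_fit2 <- fit_membership(X, lab, method = "random_forest", seed = 4)
  expect_identical(predict_membership(rf_fit2, newX),
                   predict_membership(rf_fit, newX))
})

test_that("group-weighted prediction obeys its algebra and bounds", {
  f <- rbind(spA = c(0.9, 0.1), spB = c(0.2, 0.6))
  # degenerate membership returns the group column
  P1 <- matrix(c(1, 0), 1)
  expect_equal(as.vector(P1 %*% t(f)), unname(f[, 1]))
  # uniform membership over two groups averages the frequencies
  Pu <- matrix(c(0.5, 0.5), 1)
  expect_equal(as.vector(Pu %*% t(f))[2], 0.4)
  # bounds on random memberships
  set.seed(9)
  Pm <- matrix(runif(2000), 1000, 2); Pm <- Pm / rowSums(Pm)
  pred <- Pm %*% t(f)
  for (s in rownames(f)) {
    expect_true(all(pred[, s] >= min(f[s, ]) - 1e-12))
    expect_true(all(pred[, s] <= max(f[s, ]) + 1e-12))
  }
})

test_that("the full community model is deterministic end to end", {
  b <- easy_system(n_sites = 80, seed = 41)
  occ <- filter_taxa(b$assemblage)
  cfg <- rivpacs_config(n_groups = 4, classifier = "random_forest", seed = 12)
  f1 <- rivpacs_sdm(occ, b$predictors, cfg)
  f2 <- rivpacs_sdm(occ, b$predictors, cfg)
  expect_identical(f1$labels, f2$labels)
  expect_identical(f1$frequencies, f2$frequencies)
  expect_identical(predict(f1, b$predictors), predict(f2, b$predictors))
})

test_that("predictable taxa counts species exceeding the frequency threshold", {
  f <- rbind(spA = c(0.9, 0.1), spB = c(0.4, 0.45))
  expect_identical(predictable_taxa(f, 0.5), "spA")
  f2 <- rbind(spA = c(0.9, 0.1), spB = c(0, 0.2), spC = c(0, 0))
  expect_setequal(predictable_taxa(f2, 0), c("spA", "spB"))
})

test_that("silhouette widths separate planted blobs and are bounded", {
  set.seed(12)
  blob <- rbind(matrix(rbinom(60, 1, c(rep(0.95, 6), rep(0.05, 6))), 10, 12,
                       byrow = TRUE),
                matrix(rbinom(60, 1, c(rep(0.05, 6), rep(0.95, 6))), 10, 12,
                       byrow = TRUE))
  rownames(blob) <- paste0("s", 1:20)
  blob[rowSums(blob) == 0, 1] <- 1
  d <- sorensen_matrix(assemblage_matrix(blob))
  good <- silhouette_widths(d, rep(1:2, each = 10))
  bad <- silhouette_widths(d, rep(1:2, times = 10))
  expect_true(all(good$width >= -1 & good$width <= 1))
  expect_gt(attr(good, "mean_width"), attr(bad, "mean_width"))
})
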