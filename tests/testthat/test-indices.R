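test_that("O/E follows its definition, including undefined and zero cases", {
  r <- oe_index(c(1, 1, 1), c(0.9, 0.6, 0.4))
  expect_equal(r$E, 1.5)
  expect_equal(r$O, 2)
  expect_equal(r$oe, 2 / 1.5)
  expect_true(r$defined)

  # none of the predicted taxa observed
  r0 <- oe_index(c(0, 0, 1), c(0.9, 0.8, 0.2))
  expect_equal(r0$oe, 0)

  # no probability above threshold -> undefined, flagged
  ru <- oe_index(c(1, 0), c(0.4, 0.3))
  expect_false(ru$defined)
  expect_true(is.na(ru$oe))

  expect_error(oe_index(c(1, 0), c(0.5, 0.5, 0.5)), "misaligned")

  # bound: with m taxa above t = 0.5, t*m < E <= m
  set.seed(14)
  for (i in 1:25) {
    p <- runif(12); obs <- rbinom(12, 1, 0.5)
    m <- sum(p > 0.5)
    r <- oe_index(obs, p)
    if (m > 0) {
      expect_gt(r$E, 0.5 * m)
      expect_lte(r$E, m)
    } else expect_false(r$defined)
  }
})

test_that("Bray-Curtis matches hand cases and its contract", {
  expect_equal(bray_curtis(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(1, 0), c(0.5, 0.5)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "undefined")

  # invariance to species reordering
  set.seed(6)
  obs <- rbinom(20, 1, 0.4); p <- runif(20)
  perm <- sample(20)
  expect_equal(bray_curtis(obs, p), bray_curtis(obs[perm], p[perm]))
  expect_equal(oe_index(obs, p)$oe, oe_index(obs[perm], p[perm])$oe)
})

test_that("species metrics match their definitions and the AUC pair-counting oracle", {
  obs <- c(1, 1, 1, 0, 0, 0)
  perfect <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.3)
  m <- species_metrics(assemblage_matrix(matrix(obs, ncol = 1)),
                       matrix(perfect, ncol = 1))
  expect_equal(m$auc, 1)
  expect_equal(m$se, 1)
  expect_equal(m$sp, 1)
  expect_equal(m$ccr, 1)
  expect_equal(m$kappa, 1)

  # constant predictor: AUC is 0.5 by the tie convention
  mc <- species_metrics(assemblage_matrix(matrix(obs, ncol = 1)),
                        matrix(rep(0.4, 6), ncol = 1))
  expect_equal(mc$auc, 0.5)

  # rank AUC equals the O(n^2) oracle on random vectors with ties
  set.seed(23)
  for (i in 1:50) {
    o <- rbinom(30, 1, runif(1, 0.2, 0.8))
    if (length(unique(o)) < 2) next
    p <- round(runif(30), 1)      # coarse grid forces ties
    expect_equal(refstream:::auc_rank(o, p), auc_pairs(o, p))
  }

  # AUC is invariant under strictly monotone transforms of p
  o <- rbinom(40, 1, 0.5); o[1:2] <- c(0, 1)
  p <- runif(40)
  expect_equal(refstream:::auc_rank(o, plogis(5 * p - 2)),
               refstream:::auc_rank(o, p))

  # single-class species yields NA metrics, not an error
  ms <- species_metrics(assemblage_matrix(matrix(c(1, 1, 1), ncol = 1)),
                        matrix(c(0.9, 0.2, 0.6), ncol = 1))
  expect_true(is.na(ms$auc))
  expect_true(is.na(ms$sp))
  expect_false(is.na(ms$se))
})

test_that("assemblage summary computes the Table-style battery", {
  oe <- data.frame(site = 1:3, O = c(1, 2, 3), E = c(2, 2, 2),
                   oe = c(0.5, 1.0, 1.5), bc = c(0.2, 0.3, 0.4),
                   defined = TRUE)
  s <- assemblage_summary(oe)
  expect_equal(s$mean_oe, 1)
  expect_equal(s$sd_oe, sd(c(0.5, 1, 1.5)))
  expect_equal(s$bandwidth,
               quantile(c(0.5, 1, 1.5), 0.9, type = 7, names = FALSE) -
               quantile(c(0.5, 1, 1.5), 0.1, type = 7, names = FALSE))

  # all O = E: perfect accuracy line
  oe2 <- data.frame(site = 1:4, O = c(1, 2, 3, 4), E = c(1, 2, 3, 4),
                    oe = 1, bc = 0.1, defined = TRUE)
  s2 <- assemblage_summary(oe2)
  expect_equal(s2$slope, 1)
  expect_equal(s2$intercept, 0)
  expect_equal(s2$r2, 1)
  expect_equal(s2$sd_oe, 0)
  expect_equal(s2$bandwidth, 0)

  # duplicating every site leaves the mean unchanged exactly, and the
  # interpolated percentile bandwidth unchanged to within the spacing
  # of adjacent order statistics
  set.seed(71)
  oe_big <- data.frame(site = 1:200, O = 1, E = 1, oe = rnorm(200, 1, 0.2),
                       bc = runif(200, 0, 0.5), defined = TRUE)
  s_big <- assemblage_summary(oe_big)
  s_dup <- assemblage_summary(rbind(oe_big, oe_big))
  expect_equal(s_dup$mean_oe, s_big$mean_oe)
  gap <- max(diff(sort(oe_big$oe)))
  expect_lt(abs(s_dup$bandwidth - s_big$bandwidth), 2 * gap)

  expect_error(assemblage_summary(oe[1:2, ]), "at least 3")
})

test_that("rank aggregation averages over the strategies that ranked a variable", {
  rk <- rbind(elevation = c(1, 6, 1, 1, 1),
              distance = c(6, 7, 2, NA, 3),
              solo = c(4, NA, NA, NA, NA))
  agg <- aggregate_ranks(rk)
  expect_equal(agg$average[agg$variable == "elevation"], 2.0)
  expect_equal(agg$average[agg$variable == "distance"], 4.5)
  expect_equal(agg$average[agg$variable == "solo"], 4)
  expect_identical(agg$variable[1], "elevation")
})

test_that("the bundled published rank table reproduces its printed averages exactly", {
  rk <- example_importance_ranks()
  agg <- aggregate_ranks(rk)
  printed <- c(
    "Mean segment elevation" = 2.0,
    "Catchment average slope" = 3.4,
    "Distance to outlet (the sea)" = 4.5,
    "Mean annual runoff" = 4.5,
    "Catchment shape (elongation ratio)" = 5.0,
    "Maximum upstream elevation" = 6.7,
    "Stream and sub-catchment average annual rainfall" = 6.7,
    "Stream and sub-catchment hottest month mean temperature" = 7.0,
    "Average slope of downstream flow path" = 8.7,
    "Catchment relief ratio" = 8.7,
    "Catchment percentage unconsolidated rocks" = 10.5,
    "Catchment percentage igneous rocks" = 12.3,
    "Modelled annual terrestrial mean net primary productivity" = 12.3,
    "Coefficient of variation of monthly totals of accumulated soil water surplus" = 13.0,
    "Stream and valley percentage siliciclastic/undifferentiated sedimentary rocks" = 13.0,
    "Stream and valley percentage unconsolidated rocks" = 15.3,
    "Catchment percentage metamorphic rocks" = 16.7,
    "Stream and valley percentage metamorphic rocks" = 18.3,
    "Stream and valley percentage mixed sedimentary and igneous rocks" = 18.7,
    "Catchment percentage mixed sedimentary and igneous rocks" = 19.0)
  got <- round(agg$average[match(names(printed), agg$variable)], 1)
  expect_equal(got, unname(printed))
})

test_that("importance methods put the informative variable first on a one-gradient fixture", {
  sp <- gradient_spec(n_sites = 250, n_variables = 4, latent_axes = 1,
                      loadings = matrix(c(1, 0, 0, 0), 4, 1), noise_sd = 0.2)
  pool <- list(
    a = species_niche(0.8, 0.9, 0.9, "gaussian"),
    b = species_niche(-0.8, 0.9, 0.9, "gaussian"),
    c = species_niche(0, 1.2, 0.8, "logistic"),
    d = species_niche(0.3, 1.0, 0.85, "gaussian"))
  b <- simulate_bundle(sp, pool, seed = 61)
  occ <- b$assemblage; env <- b$predictors
  informative <- colnames(unclass(env))[1]

  mars_fit <- mars_sdm(occ, env)
  rk_mars <- importance_ranks(importance_scores(mars_fit))
  expect_identical(names(which(rk_mars == 1)), informative)

  mann_fit <- mann_sdm(occ, env, mann_config(hidden_grid = 3, decay_grid = 0.03,
                                             n_restarts = 2, cv_folds = 2, seed = 3))
  rk_mann <- importance_ranks(importance_scores(mann_fit))
  expect_identical(names(which(rk_mann == 1)), informative)

  ens_fit <- ens_sdm(occ, env,
                     ens_config(algorithms = c("linear-logistic", "random-forest"),
                                n_repeats = 2, seed = 5))
  sc_ens <- importance_scores(ens_fit, env, seed = 10)
  rk_ens <- importance_ranks(sc_ens)
  expect_identical(names(which(rk_ens == 1)), informative)
  # permutation importance is seeded
  expect_identical(sc_ens, importance_scores(ens_fit, env, seed = 10))

  for (cl in c("lda_stepwise_aic", "random_forest")) {
    rv <- rivpacs_sdm(occ, env, rivpacs_config(n_groups = 3, classifier = cl,
                                               seed = 2))
    rk <- importance_ranks(importance_scores(rv))
    expect_identical(names(which(rk == 1)), informative)
  }
})

test_that("strategy comparison reproduces textbook one-way ANOVA arithmetic", {
  # identical groups: F = 0, one shared letter
  v <- rep(c(1, 2, 3), 2)
  g <- rep(c("A", "B"), each = 3)
  r <- compare_strategies(v, g)
  expect_equal(r$F, 0)
  expect_identical(unname(r$letters), c("a", "a"))

  # hand computation on a 2 x 3 toy table
  v2 <- c(1, 2, 3, 5, 6, 7); g2 <- rep(c("A", "B"), each = 3)
  gm <- mean(v2)
  ssb <- 3 * ((2 - gm)^2 + (6 - gm)^2)
  ssw <- sum((v2 - rep(c(2, 6), each = 3))^2)
  f_hand <- (ssb / 1) / (ssw / 4)
  r2 <- compare_strategies(v2, g2)
  expect_equal(r2$F, f_hand)

  # well-separated groups earn distinct letters
  set.seed(4)
  v3 <- c(rnorm(8, 0, 0.1), rnorm(8, 5, 0.1), rnorm(8, 10, 0.1))
  g3 <- rep(c("A", "B", "C"), each = 8)
  r3 <- compare_strategies(v3, g3)
  expect_length(unique(r3$letters), 3L)

  # degenerate variance is flagged
  rd <- compare_strategies(rep(1, 6), rep(c("A", "B"), each = 3))
  expect_true(rd$degenerate)
})
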