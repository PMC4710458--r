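test_that("assemblage CSV round-trip is identity and bad cells are located", {
  m <- assemblage_matrix(rbind(a = c(1, 0), b = c(0, 1)),
                         species_ids = c("x", "y"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_assemblage(m, path)
  back <- read_assemblage(path)
  expect_identical(unclass(back), unclass(m))

  df <- utils::read.csv(path, check.names = FALSE)
  df[1, 2] <- 2
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, bad, row.names = FALSE)
  expect_error(read_assemblage(bad), "non-binary.*row 'a'.*column 'x'")

  df2 <- utils::read.csv(path, check.names = FALSE)
  df2[2, 1] <- "a"
  dup <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df2, dup, row.names = FALSE)
  expect_error(read_assemblage(dup), "duplicate site id")
})

test_that("predictor CSV round-trip is identity", {
  x <- predictor_table(matrix(rnorm(12), 4, 3,
                              dimnames = list(paste0("s", 1:4), c("a", "b", "c"))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_predictors(x, path)
  back <- read_predictors(path)
  expect_equal(unclass(back), unclass(x), tolerance = 1e-12,
               ignore_attr = "transform_log")
})

test_that("taxonomic filtering drops by count and exclusion list, and is idempotent", {
  m <- assemblage_matrix(
    matrix(c(rep(1, 5), 0,
             1, rep(0, 5),
             rep(0, 6)), 6, 3),
    species_ids = c("common", "single", "absent"))
  f <- filter_taxa(m, filter_config(min_occurrences = 2))
  expect_identical(colnames(f), "common")
  rep1 <- attr(f, "filter_report")
  expect_setequal(rep1$species, c("single", "absent"))

  # excluding a species that is not in the table is a no-op with a note
  f2 <- filter_taxa(m, filter_config(exclusion_list = "ghost", min_occurrences = 1))
  expect_identical(colnames(f2), c("common", "single"))
  expect_true(any(grepl("no-op", attr(f2, "filter_report")$reason)))

  # idempotence
  cfg <- filter_config(min_occurrences = 2)
  once <- filter_taxa(m, cfg)
  twice <- filter_taxa(once, cfg)
  expect_equal(unclass(twice), unclass(once), ignore_attr = TRUE)

  expect_error(filter_taxa(m, filter_config(min_occurrences = 10)),
               "all species removed")
})

test_that("prevalence is the occupied fraction and is order-invariant", {
  m <- tiny_assemblage()
  expect_equal(unname(prevalence(m)), c(3, 2, 0) / 4)
  perm <- assemblage_matrix(unclass(m)[c(3, 1, 4, 2), ])
  expect_equal(prevalence(perm), prevalence(m))
  allones <- assemblage_matrix(matrix(1, 5, 1))
  expect_equal(unname(prevalence(allones)), 1)
})

test_that("predictor transforms apply column-wise, log their action, and invert", {
  x <- predictor_table(cbind(a = c(0, 9, 99), b = c(1, 4, 9), c = c(0, 0.25, 1)))
  tr <- transform_predictors(x, c(a = "log10", b = "sqrt", c = "asin_sqrt"))
  expect_equal(unname(unclass(tr)[, "a"]), c(0, 1, 2))
  expect_equal(unname(unclass(tr)[, "b"]), c(1, 2, 3))
  expect_equal(unname(unclass(tr)[, "c"]), asin(sqrt(c(0, 0.25, 1))))
  expect_named(attr(tr, "transform_log"), c("a", "b", "c"))

  back <- inverse_transform_predictors(tr)
  expect_equal(unclass(back), unclass(x), tolerance = 1e-10,
               ignore_attr = TRUE)

  ident <- transform_predictors(x, c(a = "identity"))
  expect_equal(unclass(ident), unclass(x), ignore_attr = TRUE)

  neg <- predictor_table(cbind(a = c(-1, 2, 3)))
  expect_error(transform_predictors(neg, c(a = "sqrt")), "domain violation.*'a'")
})

test_that("collinearity screen enforces the pairwise bound", {
  set.seed(42)
  base <- rnorm(30)
  x <- predictor_table(cbind(v1 = base, v2 = base, v3 = rnorm(30)))
  scr <- screen_collinear(x, filter_config(r_threshold = 0.8))
  # exactly one of the identical pair dropped
  expect_equal(sum(c("v1", "v2") %in% colnames(scr)), 1L)
  expect_true("v3" %in% colnames(scr))

  # boundary: r just below threshold keeps both
  a <- rnorm(200)
  b <- a * 0.79 + rnorm(200) * sqrt(1 - 0.79^2)
  r <- cor(a, b)
  xb <- predictor_table(cbind(a = a, b = b))
  scr_b <- screen_collinear(xb, filter_config(r_threshold = max(r + 0.001, 0.8)))
  expect_equal(ncol(scr_b), 2L)

  # brute-force check on 10 random correlated columns
  set.seed(7)
  z <- rnorm(60)
  rc <- sapply(1:10, function(i) z * runif(1, 0.4, 1) + rnorm(60, sd = 0.5))
  colnames(rc) <- paste0("r", 1:10)
  scr10 <- screen_collinear(predictor_table(rc), filter_config(r_threshold = 0.8))
  cm <- abs(cor(unclass(scr10)))
  diag(cm) <- 0
  expect_lte(max(cm), 0.8)

  # idempotence
  scr10b <- screen_collinear(scr10, filter_config(r_threshold = 0.8))
  expect_identical(colnames(scr10b), colnames(scr10))

  # zero-variance column is reported, not an error
  xz <- predictor_table(cbind(k = rep(1, 30), v = rnorm(30), w = rnorm(30)))
  scr_z <- screen_collinear(xz)
  expect_false("k" %in% colnames(scr_z))
  expect_true("k" %in% attr(scr_z, "screen_report")$dropped)

  # priority order decides who is dropped
  xp <- predictor_table(cbind(v1 = base, v2 = base + rnorm(30, sd = 1e-6)))
  scr_p <- screen_collinear(xp, filter_config(priority_order = c("v2", "v1")))
  expect_identical(colnames(scr_p), "v2")
})

test_that("site split honours the 80/20 shape, determinism and the partition law", {
  b <- simulate_bundle(gradient_spec(n_sites = 128), seed = 3)
  parts <- split_sites(b, fraction = 0.8, seed = 9)
  expect_equal(nrow(parts$training$assemblage), 103L)
  expect_equal(nrow(parts$holdout$assemblage), 25L)
  expect_identical(parts$holdout$role, "space")

  again <- split_sites(b, fraction = 0.8, seed = 9)
  expect_identical(again$training$site_ids, parts$training$site_ids)

  expect_setequal(c(parts$training$site_ids, parts$holdout$site_ids), b$site_ids)
  expect_length(intersect(parts$training$site_ids, parts$holdout$site_ids), 0L)

  expect_error(split_sites(b, fraction = 0.9999, seed = 1), "empty partition")
})

test_that("repeated-visit rows stay with their site in a split", {
  bm <- synthetic_benchmark(seed = 2, n_time_sites = 6, n_occasions = 4)
  tb <- bm$time
  parts <- split_sites(tb, fraction = 0.5, seed = 4)
  expect_length(intersect(parts$training$site_ids, parts$holdout$site_ids), 0L)
  expect_equal(sort(unique(c(parts$training$site_ids, parts$holdout$site_ids))),
               sort(unique(tb$site_ids)))
})

test_that("dataset bundle enforces the closed role set and duplicate-row rule", {
  m <- tiny_assemblage()
  x <- predictor_table(matrix(rnorm(8), 4, 2), site_ids = rownames(m))
  expect_error(dataset_bundle(m, x, role = "banana"))
  expect_error(dataset_bundle(m, x, role = "space",
                              site_ids = c("a", "a", "b", "c")),
               "only allowed for role = 'time'")
  expect_silent(dataset_bundle(m, x, role = "time",
                               site_ids = c("a", "a", "b", "c")))
})
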